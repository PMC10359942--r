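# One-frame fixture: a few cells on a biased field, built from simulator
# tracks so nuclear intensities are realistic.
.one_frame <- function(n_cells = 6, noise = 0, bias = c(0.15, 0.10),
                       bg = 20, seed = 13) {
  coh <- simulate_cohort(sim_config("glucose_depletion",
                                    n_mothers = n_cells, seed = seed,
                                    measurement_noise = 0, horizon = 24))
  # one row per mother (her first frame), all placed on a common frame
  tracks <- coh$tracks[is.na(parent_id)][, .SD[1], by = cell_id]
  tracks[, time_h := 0]
  ip <- image_params(width = 220L, height = 220L, bias_coefs = bias,
                     background_level = bg, read_noise_sd = noise)
  rf <- render_field(tracks, 0, ip, seed = seed)
  list(rf = rf, ip = ip, tracks = tracks)
}

test_that("a rendered noise-free cell re-measures exactly", {
  fx <- .one_frame(n_cells = 1, noise = 0, bias = c(0, 0), bg = 0)
  tru <- fx$rf$truth
  m <- measure_cell(fx$rf$channels, c(tru$x, tru$y), fx$ip)
  expect_equal(m$cdt1_nuc, tru$cdt1, tolerance = 1e-12)
  expect_equal(m$h1_nuc, tru$h1, tolerance = 1e-12)
  expect_equal(m$cdk2_nuc, tru$cdk2_nuc, tolerance = 1e-12)
  expect_equal(m$cdk2_cyt, tru$cdk2_cyt, tolerance = 1e-12)
  expect_equal(m$cdk2_ratio, tru$cdk2_cyt / tru$cdk2_nuc, tolerance = 1e-12)
})

test_that("disk and ring pixel sets are disjoint for any center", {
  ip <- image_params(width = 64L, height = 64L)
  for (cx in c(12.0, 20.3, 31.7)) {
    for (cy in c(15.0, 28.6)) {
      disk <- cyclefate:::.mask_pixels(cx, cy, 0, ip$nuclear_radius, ip)
      ring <- cyclefate:::.mask_pixels(cx, cy, ip$nuclear_radius,
                                       ip$nuclear_radius + ip$ring_width, ip)
      expect_length(intersect(disk, ring), 0)
      expect_gt(length(ring), 0)
    }
  }
})

test_that("uniform disk 100 / ring 60 gives CDK2 ratio 0.6", {
  ip <- image_params(width = 64L, height = 64L)
  img <- matrix(0, 64, 64)
  disk <- cyclefate:::.mask_pixels(32, 32, 0, ip$nuclear_radius, ip)
  ring <- cyclefate:::.mask_pixels(32, 32, ip$nuclear_radius,
                                   ip$nuclear_radius + ip$ring_width, ip)
  img[disk] <- 100; img[ring] <- 60
  m <- measure_cell(list(cdk2 = img), c(32, 32), ip)
  expect_equal(m$cdk2_ratio, 0.6)
})

test_that("edge and neighbor contamination are flagged", {
  ip <- image_params(width = 64L, height = 64L)
  img <- matrix(10, 64, 64)
  edge <- measure_cell(list(cdk2 = img), c(3, 32), ip)
  expect_true(edge$edge_clipped)
  expect_true(is.na(edge$cdk2_cyt))
  near <- measure_cell(list(cdk2 = img), c(32, 32), ip,
                       other_centers = data.frame(x = 40, y = 32))
  expect_true(near$contaminated)
  far <- measure_cell(list(cdk2 = img), c(32, 32), ip,
                      other_centers = data.frame(x = 60, y = 10))
  expect_false(far$contaminated)
})

test_that("flatten_background removes a known linear bias", {
  fx <- .one_frame(n_cells = 4, noise = 0, bias = c(0.3, 0.2), bg = 25)
  img <- fx$rf$channels$h1
  corr <- flatten_background(img, fx$ip)
  bias_true <- cyclefate:::.bias_field(fx$ip)
  est <- attr(corr, "bias")
  # residual bias amplitude < 5% of the applied bias amplitude
  resid <- bias_true / mean(bias_true) / est
  expect_lt(diff(range(resid)), 0.05 * diff(range(bias_true)))
  expect_true(all(corr >= 0))
  # flat empty image corrects to ~0
  flat <- matrix(5, 128, 128)
  cf <- flatten_background(flat, fx$ip)
  expect_lt(max(abs(cf)), 1e-6)
  # an all-zero image cannot support a bias estimate: skipped with a warning
  expect_warning(flatten_background(matrix(0, 128, 128), fx$ip),
                 "no background")
  # bias-free image (small flat background) is nearly unchanged inside the
  # cells: the estimated bias is flat and only the background is removed
  fx0 <- .one_frame(n_cells = 4, noise = 0, bias = c(0, 0), bg = 0.5)
  c0 <- flatten_background(fx0$rf$channels$h1, fx0$ip)
  raw0 <- fx0$rf$channels$h1
  nz <- raw0 > 50
  expect_lt(max(abs(c0[nz] - raw0[nz]) / raw0[nz]), 0.01)
})

test_that("LoG detection finds rendered nuclei", {
  fx <- .one_frame(n_cells = 1, noise = 0, bias = c(0, 0), bg = 0)
  det <- detect_nuclei(fx$rf$channels$h1, fx$ip)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$x - fx$rf$truth$x)^2 + (det$y - fx$rf$truth$y)^2), 1)
  # blank frame: no detections
  expect_equal(nrow(detect_nuclei(matrix(0, 64, 64),
                                  image_params(width = 64L, height = 64L))),
               0L)
  # many cells with bias and background, after flattening
  fx20 <- .one_frame(n_cells = 10, noise = 1, bias = c(0.15, 0.1), bg = 20,
                     seed = 29)
  corr <- flatten_background(fx20$rf$channels$h1, fx20$ip)
  det20 <- detect_nuclei(corr, fx20$ip)
  tru <- fx20$rf$truth
  expect_equal(nrow(det20), nrow(tru))
  dmin <- vapply(seq_len(nrow(tru)), function(i)
    min(sqrt((det20$x - tru$x[i])^2 + (det20$y - tru$y[i])^2)), numeric(1))
  expect_gte(mean(dmin <= 2), 0.95)
})

test_that("mutual-NN linking follows drifting cells and finds divisions", {
  # stationary cells: one track per cell spanning all frames
  det <- rep(list(data.frame(x = c(10, 40, 70), y = c(10, 40, 70))), 6)
  lk <- link_tracks(det, max_disp = 5)
  expect_equal(length(unique(lk$tracks$track_id)), 3L)
  expect_true(all(lk$tracks[, .N, by = track_id]$N == 6L))
  expect_equal(nrow(lk$divisions), 0L)
  # slow drift below max_disp: links stay correct
  set.seed(3)
  pos <- matrix(c(20, 20, 60, 60, 20, 60), ncol = 2, byrow = TRUE)
  det2 <- lapply(1:10, function(f) {
    pos <<- pos + matrix(rnorm(6, sd = 1), ncol = 2)
    data.frame(x = pos[, 1], y = pos[, 2])
  })
  lk2 <- link_tracks(det2, max_disp = 5)
  expect_equal(length(unique(lk2$tracks$track_id)), 3L)
  # one division: a parent splitting into two nearby children
  det3 <- list(data.frame(x = 30, y = 30),
               data.frame(x = 30, y = 30),
               data.frame(x = c(27, 33), y = c(30, 30)),
               data.frame(x = c(26, 34), y = c(30, 30)))
  lk3 <- link_tracks(det3, max_disp = 6)
  expect_equal(nrow(lk3$divisions), 1L)
  expect_equal(lk3$divisions$frame, 3L)
})

test_that("render -> quantify -> fate reproduces ground-truth fates", {
  # first-generation daughters, each re-based to its own birth so every
  # rendered track spans a full 14 h assessment window
  coh <- simulate_cohort(sim_config("glucose_depletion", n_mothers = 7,
                                    seed = 97, horizon = 40))
  g1 <- coh$truth[generation == 1L]
  tracks <- coh$tracks[cell_id %in% g1$cell_id]
  tracks[, time_h := time_h - min(time_h), by = cell_id]
  tracks <- tracks[time_h <= 14]
  ip <- image_params(width = 200L, height = 200L, read_noise_sd = 2)
  st <- render_stack(tracks, ip, seed = 97)
  q <- quantify_stack(st$frames, st$times, ip)
  # match measured tracks to truth via first-frame positions
  tru1 <- st$truth[frame == 1]
  q1 <- q[time_h == st$times[1]]
  near <- vapply(seq_len(nrow(q1)), function(i)
    tru1$cell_id[which.min((tru1$x - q1$x[i])^2 + (tru1$y - q1$y[i])^2)],
    character(1))
  map <- stats::setNames(near, q1$cell_id)
  fate_truth <- stats::setNames(g1$fate, g1$cell_id)
  res <- q[, {
    ratio <- cdk2_activity(cdk2_nuc, cdk2_cyt)
    fc <- classify_fate(ratio, time_h, cdt1, fate_params())
    list(binary = fc$binary)
  }, by = cell_id]
  res <- res[binary %in% c("quiescent", "proliferative")]
  res[, truth := fate_truth[map[cell_id]]]
  expect_gte(nrow(res), 10)
  expect_gte(mean(res$binary == res$truth), 0.95)
})
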