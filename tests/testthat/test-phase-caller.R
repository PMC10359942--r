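test_that("smooth_trace is a centered moving average with shrunk ends", {
  expect_error(smooth_trace(numeric(0)), "empty")
  expect_error(smooth_trace(1:5, 4), "odd")
  x <- c(5, 5, 5, 5, 5)
  expect_equal(smooth_trace(x, 5), x)          # constant in, constant out
  y <- rnorm(20)
  expect_equal(smooth_trace(y, 1), y)          # window 1 = identity
  # linear ramp: symmetric windows leave interior values unchanged
  r <- seq(0, 10, by = 0.5)
  sm <- smooth_trace(r, 5)
  expect_equal(sm[3:(length(r) - 2)], r[3:(length(r) - 2)])
  # brute-force oracle on random data
  z <- rnorm(15)
  sm <- smooth_trace(z, 5)
  for (i in seq_along(z)) {
    h <- min(2, i - 1, length(z) - i)
    expect_equal(sm[i], mean(z[(i - h):(i + h)]))
  }
})

test_that("detect_peak finds the apex, breaking ties to the earliest", {
  tt <- seq(0, 20, by = 0.25)
  tri <- pmax(0, 10 - abs(tt - 10))
  pk <- detect_peak(tri, tt)
  expect_equal(pk$peak_time, 10)
  # two equal maxima: earliest wins
  v <- rep(0, length(tt)); v[tt == 5] <- 3; v[tt == 8] <- 3
  expect_equal(detect_peak(v, tt)$peak_time, 5)
  # all-equal trace is flagged
  expect_true(detect_peak(rep(2, 30), seq_len(30))$no_peak)
  expect_error(detect_peak(1:2, 1:2), "3 samples")
})

test_that("call_phases recovers constructed boundaries and labels", {
  tr <- triangle_track(b1 = 5, b2 = 11, b3 = 13, t_end = 13.75)
  ann <- call_phases(tr, division_time = 13.8, birth_time = 0)
  expect_equal(ann$t_g1s, 5, tolerance = 0.26)
  expect_equal(ann$t_sg2, 11, tolerance = 0.26)
  expect_equal(ann$t_g2m, 13, tolerance = 0.26)
  expect_equal(unname(ann$durations["G1"]), 5, tolerance = 0.3)
  # half-open intervals: every frame gets exactly one label
  expect_true(all(ann$labels %in% c("G1", "S", "G2", "M")))
  expect_equal(ann$labels[tr$time_h < ann$t_g1s],
               rep("G1", sum(tr$time_h < ann$t_g1s)))
  # idempotence
  ann2 <- call_phases(tr, division_time = 13.8, birth_time = 0)
  expect_identical(ann[names(ann) != "flag"], ann2[names(ann2) != "flag"])
})

test_that("call_phases rejects missing channels and short tracks", {
  tr <- triangle_track()
  expect_error(call_phases(tr[, !"slbp"]), "slbp")
  expect_error(call_phases(tr[1:5]), "8 frames")
})

test_that("flat Geminin means G1 throughout, boundaries truncated", {
  tt <- seq(0, 12, by = 0.25)
  tr <- data.table::data.table(
    cell_id = "q", time_h = tt,
    cdt1 = 10 + 5 * tt, geminin = rep(0, length(tt)),
    slbp = rep(10, length(tt)), h1 = rep(100, length(tt)))
  ann <- call_phases(tr)
  expect_true(all(ann$labels == "G1"))
  expect_equal(ann$flag, "no_geminin_onset")
  expect_true(all(ann$truncated))
})

test_that("misordered waveform peaks give undetermined labels with a flag", {
  tt <- seq(0, 12, by = 0.25)
  gem <- dnorm(tt, 5, 1); slbp <- dnorm(tt, 9, 1)  # SLBP after Geminin
  tr <- data.table::data.table(
    cell_id = "bad", time_h = tt, cdt1 = pmax(1 - tt / 3, 0.05),
    geminin = gem / max(gem) * 100, slbp = slbp / max(slbp) * 100,
    h1 = rep(100, length(tt)))
  ann <- call_phases(tr)
  expect_equal(ann$flag, "unresolvable_boundary_ordering")
  expect_true(all(ann$labels == "undetermined"))
})

test_that("noise-free simulated boundaries are recovered within one frame", {
  coh <- noisefree_control()
  ph <- cohort_phases(coh)
  tr <- merge(ph, coh$truth, by = "cell_id")
  dt <- coh$config$sampling_interval
  ok <- tr[!trunc_s & !trunc_g2 & !trunc_m,
           abs(t_g1s.x - t_g1s.y) <= dt + 1e-9 &
             abs(t_sg2.x - t_sg2.y) <= dt + 1e-9 &
             abs(t_g2m.x - t_g2m.y) <= dt + 1e-9]
  expect_gt(length(ok), 400)
  expect_gte(mean(ok), 0.99)
})

test_that("boundary error grows continuously with measurement noise", {
  err_at <- function(sigma) {
    coh <- simulate_cohort(sim_config("control", n_mothers = 25, seed = 87,
                                      measurement_noise = sigma))
    ph <- cohort_phases(coh)
    tr <- merge(ph, coh$truth, by = "cell_id")
    tr[trunc_s == FALSE, mean(abs(t_g1s.x - t_g1s.y))]
  }
  e0 <- err_at(0); e1 <- err_at(0.05); e2 <- err_at(0.25)
  expect_lte(e0, 0.126)        # within half a frame on average at sigma = 0
  expect_lte(e0, e1 + 0.05)    # no jumps: error grows roughly monotonically
  expect_lt(e1, e2)
})

test_that("phase_duration_summary summarizes untruncated durations only", {
  ann <- data.table::data.table(
    d_g1 = c(2, 4, 7), d_s = c(NA, NA, NA),
    d_g2 = c(1, 1, 1), d_m = c(0.5, 0.5, 0.5),
    trunc_g1 = c(FALSE, FALSE, TRUE), trunc_s = TRUE,
    trunc_g2 = FALSE, trunc_m = FALSE)
  s <- phase_duration_summary(ann, followup = "none")
  expect_equal(s[s$phase == "G1"]$mean_h, 3)      # {2,4}: truncated excluded
  expect_equal(s[s$phase == "G1"]$sd_h, sqrt(2))
  expect_equal(s[s$phase == "G1"]$n, 2L)
  expect_equal(s[s$phase == "S"]$n, 0L)           # all truncated: no mean
  expect_true(is.na(s[s$phase == "S"]$mean_h))
  expect_error(phase_duration_summary(ann[0]), "no annotations")
})
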