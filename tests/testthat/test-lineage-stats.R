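test_that("align_to_mitosis anchors lineages at the first division", {
  coh <- small_depletion()
  anchored <- align_to_mitosis(coh$tracks, coh$lineage)
  # mothers occupy negative anchored time, first-generation daughters
  # positive
  mothers <- coh$truth[generation == 0L & !is.na(division_h), cell_id]
  g1 <- coh$truth[generation == 1L, cell_id]
  expect_true(all(anchored[cell_id %in% mothers, time_rel] < 0))
  expect_true(all(anchored[cell_id %in% g1, time_rel] > 0))
  # a mother dividing at t spans [t_start - t, 0)
  m1 <- mothers[1]
  div <- coh$lineage[parent_id == m1, division_time_h[1]]
  tr <- anchored[cell_id == m1]
  expect_equal(tr$time_rel, tr$time_h - div)
  # alignment conserves sample counts
  expect_equal(nrow(anchored) +
                 sum(coh$tracks$cell_id %in% attr(anchored, "excluded")),
               nrow(coh$tracks))
  # heatmap-style ordering: G1-captured mothers ranked by true G1 remainder
  # have monotone anchored track starts (sort-order property)
  mo <- coh$truth[generation == 0L & stage_at_treatment == "G1" &
                    !is.na(division_h)]
  starts <- anchored[cell_id %in% mo$cell_id, min(time_rel), by = cell_id]
  m <- merge(starts, mo[, .(cell_id, division_h)], by = "cell_id")
  # anchored start = -division time: ordering by time-to-mitosis reverses
  expect_equal(order(m$V1), order(-m$division_h))
})

test_that("window_mean uses [-w, 0) and (0, w] and drops empty windows", {
  # ramp p21 = t on (0, 5] sampled every 0.25 h: 20 samples, mean 2.625
  tt <- seq(0.25, 5, by = 0.25)
  expect_equal(window_mean(tt, tt, "post", 5), 2.625)
  # constant trace
  expect_equal(window_mean(seq(-4, -0.25, 0.25),
                           rep(7, 16), "pre", 5), 7)
  # empty window
  expect_true(is.na(window_mean(c(6, 7), c(1, 2), "post", 5)))
  # boundary membership: 0 belongs to neither window, w to post, -w to pre
  expect_equal(window_mean(c(-5, 0, 5), c(1, 10, 100), "post", 5), 100)
  expect_equal(window_mean(c(-5, 0, 5), c(1, 10, 100), "pre", 5), 1)
})

test_that("mother_daughter_correlation matches brute force and edge rules", {
  set.seed(42)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50, sd = 0.3)
  got <- mother_daughter_correlation(x, y)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, brute, tolerance = 1e-12)
  # exact halving, no noise: r = 1
  expect_equal(mother_daughter_correlation(x, x / 2)$r, 1)
  # shuffled pairing: r ~ 0
  rs <- replicate(50, mother_daughter_correlation(x, sample(y))$r)
  expect_lt(abs(mean(rs)), 0.1)
  # degenerate input
  expect_error(mother_daughter_correlation(1:2, 2:3), "3 complete pairs")
  flag <- mother_daughter_correlation(rep(1, 5), 1:5)
  expect_true(is.na(flag$r))
  expect_equal(flag$flag, "zero_variance")
})

test_that("sibling_discrepancy matches hand-computed values", {
  x <- c(1, 2, 3)
  expect_equal(sibling_discrepancy(x, x)$D, 0)
  expect_equal(sibling_discrepancy(x, x)$R2, 1)
  d <- sibling_discrepancy(c(1, 2, 3), c(3, 2, 1))
  expect_equal(d$D, 4)       # 2*8 / (2 + 2)
  expect_equal(d$R2, -3)
  flagged <- sibling_discrepancy(c(2, 2), c(2, 2))
  expect_true(is.na(flagged$D))
  expect_equal(flagged$flag, "both_series_constant")
})

test_that("sibling discrepancy invariances hold on random series", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    x <- rnorm(n, 10, 3); y <- rnorm(n, 10, 3)
    D <- sibling_discrepancy(x, y)$D
    expect_gte(D, 0)
    # symmetry
    expect_equal(sibling_discrepancy(y, x)$D, D, tolerance = 1e-12)
    # common additive shift
    c0 <- rnorm(1, sd = 50)
    expect_equal(sibling_discrepancy(x + c0, y + c0)$D, D,
                 tolerance = 1e-9)
    # common positive rescaling
    s0 <- exp(rnorm(1))
    expect_equal(sibling_discrepancy(s0 * x, s0 * y)$D, D,
                 tolerance = 1e-9)
  }
  # D = 0 iff x == y
  x <- rnorm(10)
  expect_equal(sibling_discrepancy(x, x)$D, 0)
  expect_gt(sibling_discrepancy(x, x + 0.01)$D, 0)
})

test_that("concordance_table counts and conserves pairs", {
  tab <- concordance_table(
    fate_a = c("quiescent", "quiescent", "proliferative", "quiescent"),
    fate_b = c("quiescent", "proliferative", "proliferative",
               "indeterminate"),
    group = c("G1", "S", "S", "S"))
  g1 <- tab[tab$group == "G1"]
  s <- tab[tab$group == "S"]
  expect_equal(g1$concordant, 1L)
  expect_equal(s$concordant, 1L)
  expect_equal(s$discordant, 1L)
  expect_equal(s$excluded, 1L)
  expect_equal(tab$n_pairs, tab$concordant + tab$discordant)
})

test_that("S-group sibling fates are independent (2p(1-p) discordance)", {
  cfgs <- lapply(1:6, function(s)
    sim_config("glucose_depletion", n_mothers = 120, seed = 6000 + s,
               stage_probs = c(G1 = 0, S = 1)))
  disc <- unlist(lapply(cfgs, function(cfg) {
    coh <- simulate_cohort(cfg)
    g1 <- coh$truth[generation == 1L]
    pr <- g1[, .(d = fate[1] != fate[2]), by = parent_id]
    pr$d
  }))
  p <- 0.5122
  expected <- 2 * p * (1 - p)
  expect_lt(abs(mean(disc) - expected),
            3 * sqrt(expected * (1 - expected) / length(disc)))
})

test_that("proliferation_vs_time bins, correlates and flags degenerate input", {
  # two clean bins: |r| = 1
  t2 <- c(rep(0.5, 3), rep(2, 3))
  f2 <- c(rep(list(c(TRUE, TRUE)), 3), rep(list(c(FALSE, FALSE)), 3))
  pv <- proliferation_vs_time(t2, f2, bin_width = 1.3)
  expect_equal(abs(pv$r), 1)
  expect_equal(pv$table$percent_proliferating, c(100, 0))
  # all mothers in one bin: undefined, flagged
  pv1 <- proliferation_vs_time(rep(0.5, 5),
                               rep(list(TRUE), 5), bin_width = 1.3)
  expect_true(is.na(pv1$r))
  # fates independent of time: r ~ 0 over many draws (null r has
  # SD ~ 1/sqrt(bins - 1) ~ 0.35 per draw; 100 draws give SE ~ 0.035)
  set.seed(5)
  rs <- replicate(100, {
    tm <- runif(120, 0, 12)
    ff <- lapply(seq_len(120), function(i) runif(2) < 0.5)
    proliferation_vs_time(tm, ff)$r
  })
  expect_lt(abs(mean(rs)), 0.12)
})

test_that("built-in fate/time coupling yields a strong inverse relation", {
  coh <- cached_cohort("depl_big", function()
    simulate_cohort(sim_config("glucose_depletion", n_mothers = 500,
                               seed = 640)))
  fts <- cohort_fates(coh)
  mo <- coh$truth[generation == 0L & !is.na(division_h)]
  fate_of <- stats::setNames(fts$binary, fts$cell_id)
  kid_map <- split(coh$lineage$cell_id, coh$lineage$parent_id)
  dp <- lapply(mo$cell_id, function(id) {
    f <- fate_of[kid_map[[id]]]
    f <- f[f %in% c("quiescent", "proliferative")]
    f == "proliferative"
  })
  pv <- proliferation_vs_time(mo$division_h, dp)
  expect_lt(pv$r, 0)                 # inverse relation
  expect_gte(abs(pv$r), 0.9)
})

test_that("parameter recovery: fate fractions converge over seeds", {
  # daughters within a pair share the mother-level p21 factors, so the
  # independent unit for the G1 (inheritance) group is the sibling pair;
  # pool several seeded cohorts and check a binomial band at the pair count
  cohs <- c(list(cached_cohort("depl_big", function()
    simulate_cohort(sim_config("glucose_depletion", n_mothers = 500,
                               seed = 640)))),
    lapply(c(641, 642), function(s)
      simulate_cohort(sim_config("glucose_depletion", n_mothers = 250,
                                 seed = s))))
  calls <- data.table::rbindlist(lapply(cohs, function(coh)
    cohort_fates(coh)[generation == 1L]))
  fts <- suppressWarnings(cohort_fate_fractions(calls, "group"))
  for (st in c("G1", "S")) {
    p <- cohs[[1]]$config$fate_probs[[st]]
    row <- fts[group == st]
    n_eff <- row$n / 2
    expect_lt(abs(row$fraction_quiescent - p),
              1.96 * sqrt(p * (1 - p) / n_eff))
  }
})
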