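suppressMessages(library(data.table))

# Small cohorts shared across test files; built once per test run.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, builder) {
  if (!exists(key, .cohort_cache)) assign(key, builder(), .cohort_cache)
  get(key, .cohort_cache)
}

small_depletion <- function() {
  cached_cohort("depl", function()
    simulate_cohort(sim_config("glucose_depletion", n_mothers = 80,
                               seed = 421)))
}

small_control <- function() {
  cached_cohort("ctrl", function()
    simulate_cohort(sim_config("control", n_mothers = 40, seed = 422)))
}

noisefree_control <- function() {
  cached_cohort("nf", function()
    simulate_cohort(sim_config("control", n_mothers = 60, seed = 423,
                               measurement_noise = 0)))
}

# Synthetic single-cell track with exact, known boundaries (for oracle tests
# that must not depend on the simulator).
triangle_track <- function(b1 = 5, b2 = 11, b3 = 13, t_end = 13.75,
                           dt = 0.25) {
  tt <- seq(0, t_end, by = dt)
  cdt1 <- ifelse(tt < b1, 0.05 + 0.95 * tt / b1,
                 pmax(1 - 0.95 * (tt - b1) / (b2 - b1), 0.05))
  gem <- ifelse(tt < b1, 0.02,
                ifelse(tt < b3, 0.02 + 0.98 * (tt - b1) / (b3 - b1),
                       pmax(1 - 0.98 / (b3 - b1) * (tt - b3), 0.02)))
  slbp <- ifelse(tt < b1, 0.1,
                 ifelse(tt < b2, 0.1 + 0.9 * (tt - b1) / (b2 - b1),
                        pmax(1 - 0.9 / (b2 - b1) * (tt - b2), 0.1)))
  h1 <- ifelse(tt >= b3, 1.8, 1)
  data.table(cell_id = "c1", time_h = tt, cdt1 = 100 * cdt1,
             geminin = 100 * gem, slbp = 100 * slbp, h1 = 100 * h1)
}

# Assemble (mother pre, daughter post) window means and sibling series for
# one cohort, as used for inheritance statistics.
g1_inheritance_data <- function(cohort, fates) {
  ld <- lineage_p21_data(cohort, fates)
  p <- ld$pairs
  md <- rbind(p[group == "G1" & fate1 == "quiescent",
                .(pre = mother_pre, post = post1)],
              p[group == "G1" & fate2 == "quiescent",
                .(pre = mother_pre, post = post2)])
  list(pairs = p, md = md[is.finite(pre) & is.finite(post)],
       series = ld$window_series)
}
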