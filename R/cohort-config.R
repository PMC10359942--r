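# Condition-specific phase-duration moments (hours, mean and SD) for actively
# cycling hTERT-RPE1-like cells under normal culture and under glucose
# depletion. Durations are sampled from normals truncated below at 0.25 h whose
# location/scale are moment-matched so the sampled mean/SD equal these values.
.PHASE_MOMENTS <- list(
  control = data.frame(
    phase = c("G1", "S", "G2", "M"),
    mean  = c(4.92, 5.59, 2.19, 0.81),
    sd    = c(2.09, 1.52, 0.93, 0.13)
  ),
  glucose_depletion = data.frame(
    phase = c("G1", "S", "G2", "M"),
    mean  = c(7.39, 6.23, 3.74, 0.84),
    sd    = c(4.38, 2.05, 1.42, 0.23)
  )
)
.PHASE_MOMENTS$p21_degradation <- .PHASE_MOMENTS$glucose_depletion

# Probability that a first-generation daughter enters quiescence, conditional
# on the mother's cell-cycle stage when treatment started. Under glucose
# depletion these are the observed stage-grouped quiescent fractions; under
# control conditions quiescence is rare and stage-independent.
.FATE_PROBS <- list(
  control           = c(G1 = 0.0714, S = 0.0714),
  glucose_depletion = c(G1 = 0.8654, S = 0.5122),
  p21_degradation   = c(G1 = 0.8654, S = 0.5122)
)

# Fraction of captured mothers in G1 (vs S) at treatment onset. The depletion
# default is calibrated so the stage mixture reproduces the overall 64.93%
# daughter quiescence observed in an unsynchronized depletion cohort:
# w * 0.8654 + (1 - w) * 0.5122 = 0.6493  =>  w = 0.3882.
.STAGE_PROB_G1 <- 0.3882

# Internal seed for the deterministic Monte-Carlo quadrature that converts
# fate probabilities into p21 quiescence thresholds. Unrelated to cohort seeds.
.THRESHOLD_MC_SEED <- 772003
.THRESHOLD_MC_N <- 200000L

#' Build a synthetic-cohort configuration
#'
#' Assembles and validates the full parameterization of a simulated cohort of
#' lineage-linked reporter trajectories: sampling, condition-specific phase
#' duration distributions, stage-at-treatment capture mix, daughter fate
#' mixtures, p21 accumulation/inheritance parameters, CDK2 trace shape and
#' measurement noise. All stochastic defaults are fixed properties of the
#' simulated study conditions; see the methods vignette for their rationale.
#'
#' @param condition One of `"control"`, `"glucose_depletion"`,
#'   `"p21_degradation"`.
#' @param n_mothers Number of mother cells captured at treatment onset (t = 0).
#' @param seed Integer RNG seed for the cohort.
#' @param sampling_interval Imaging interval in hours (default 0.25 = 15 min).
#' @param horizon Observation span in hours (default 48).
#' @param stage_probs Named numeric `c(G1 = , S = )` capture proportions of
#'   mother stage at treatment; must sum to 1.
#' @param stage_assignment `"stratified"` (default) fixes the cohort's stage
#'   composition at the configured proportions (emulating the observed
#'   composition of a tracked cohort, and matching the binomial sampling
#'   assumption behind n-daughter quiescence fractions); `"bernoulli"` draws
#'   each mother's stage independently.
#' @param fate_probs Named numeric `c(G1 = , S = )` daughter quiescence
#'   probability given mother stage; defaults per condition.
#' @param quiescent_baseline CDK2 cytoplasm/nucleus ratio of quiescent cells.
#' @param cdk2_peak CDK2 ratio reached at mitosis by proliferating cells.
#' @param measurement_noise Multiplicative lognormal sigma applied per frame
#'   and channel (0 disables noise).
#' @param p21 Optional named list overriding p21 dynamics parameters; see
#'   Details.
#' @param iaa_time Hours at which induced p21 degradation starts
#'   (`p21_degradation` condition only).
#'
#' @details
#' The `p21` list supports: `basal` (a.u. baseline), `mother_g2m_level`
#' (median G2/M plateau of G1-captured mothers, a.u.), `s_mother_scale`
#' (relative plateau of S-captured mothers), `bio_sd_log` (mother-level
#' biological log-SD), `exposure_slope` (per-hour coupling of log p21 output
#' to the mother's time to mitosis, i.e. her glucose-depletion exposure),
#' `transmission_sd_log` (mother-to-daughter transmission noise shared by the
#' two siblings), `split_sd_log` (per-sibling division asymmetry),
#' `denovo_level` and `denovo_sd_log` (S-group daughters' independent de novo
#' accumulation), `denovo_time` (hours to reach the de novo plateau), and
#' `decay_halflife` (p21 decay in proliferating daughters).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(condition = c("control", "glucose_depletion",
                                     "p21_degradation"),
                       n_mothers,
                       seed,
                       sampling_interval = 0.25,
                       horizon = 48,
                       stage_probs = c(G1 = .STAGE_PROB_G1,
                                       S  = 1 - .STAGE_PROB_G1),
                       stage_assignment = c("stratified", "bernoulli"),
                       fate_probs = NULL,
                       quiescent_baseline = 0.6,
                       cdk2_peak = 1.75,
                       measurement_noise = 0.05,
                       p21 = list(),
                       iaa_time = 24) {
  condition <- match.arg(condition)
  stage_assignment <- match.arg(stage_assignment)
  if (missing(n_mothers) || length(n_mothers) != 1L || !is.finite(n_mothers) ||
      n_mothers < 1 || n_mothers != round(n_mothers)) {
    stop("n_mothers must be a positive integer")
  }
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("an integer seed is required (no silent clock seeding)")
  }
  if (sampling_interval <= 0 || horizon <= 0) {
    stop("sampling_interval and horizon must be positive")
  }
  n_steps <- horizon / sampling_interval
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("sampling_interval must divide horizon")
  }
  stopifnot(all(c("G1", "S") %in% names(stage_probs)))
  stage_probs <- stage_probs[c("G1", "S")]
  if (any(stage_probs < 0) || abs(sum(stage_probs) - 1) > 1e-8) {
    stop("stage_probs must be non-negative and sum to 1")
  }
  if (is.null(fate_probs)) fate_probs <- .FATE_PROBS[[condition]]
  stopifnot(all(c("G1", "S") %in% names(fate_probs)))
  fate_probs <- fate_probs[c("G1", "S")]
  if (any(fate_probs < 0 | fate_probs > 1)) stop("fate probabilities must lie in [0, 1]")
  if (quiescent_baseline <= 0 || cdk2_peak <= quiescent_baseline) {
    stop("require 0 < quiescent_baseline < cdk2_peak")
  }
  if (measurement_noise < 0) stop("measurement_noise must be >= 0")

  p21_defaults <- list(
    basal = 5,
    mother_g2m_level = 100,
    s_mother_scale = 0.2,
    bio_sd_log = 0.245,
    exposure_slope = 0.06,
    transmission_sd_log = 0.09,
    split_sd_log = 0.05,
    denovo_level = 60,
    denovo_sd_log = 0.5,
    denovo_time = 10,
    decay_halflife = 3
  )
  unknown <- setdiff(names(p21), names(p21_defaults))
  if (length(unknown)) stop("unknown p21 parameter(s): ",
                            paste(unknown, collapse = ", "))
  p21_par <- utils::modifyList(p21_defaults, p21)

  mom <- .PHASE_MOMENTS[[condition]]
  durations <- lapply(seq_len(nrow(mom)), function(i) {
    mm <- tnorm_match(mom$mean[i], mom$sd[i], lower = 0.25)
    list(mean = mom$mean[i], sd = mom$sd[i],
         location = mm$location, scale = mm$scale, lower = 0.25)
  })
  names(durations) <- mom$phase

  cfg <- structure(list(
    condition = condition,
    n_mothers = as.integer(n_mothers),
    seed = as.integer(seed),
    sampling_interval = sampling_interval,
    horizon = horizon,
    stage_probs = stage_probs,
    stage_assignment = stage_assignment,
    fate_probs = fate_probs,
    durations = durations,
    quiescent_baseline = quiescent_baseline,
    cdk2_peak = cdk2_peak,
    measurement_noise = measurement_noise,
    p21 = p21_par,
    iaa_time = iaa_time,
    g0_cdt1_time = 12
  ), class = "sim_config")

  cfg$mean_time_to_mitosis <- c(
    G1 = 0.5 * durations$G1$mean + durations$S$mean + durations$G2$mean +
      durations$M$mean,
    S = 0.5 * durations$S$mean + durations$G2$mean + durations$M$mean
  )
  cfg$thresholds <- .fate_thresholds(cfg)
  cfg
}

# Draw time-to-mitosis for a captured mother of the given stage (vectorized).
.draw_time_to_mitosis <- function(n, stage, durations) {
  u <- runif(n)
  dG1 <- rtnorm(n, durations$G1$location, durations$G1$scale, durations$G1$lower)
  dS  <- rtnorm(n, durations$S$location,  durations$S$scale,  durations$S$lower)
  dG2 <- rtnorm(n, durations$G2$location, durations$G2$scale, durations$G2$lower)
  dM  <- rtnorm(n, durations$M$location,  durations$M$scale,  durations$M$lower)
  if (stage == "G1") u * dG1 + dS + dG2 + dM else u * dS + dG2 + dM
}

# Convert the configured fate probabilities into p21 thresholds by Monte-Carlo
# quadrature of the simulated p21-at-birth distributions under a fixed internal
# seed (a deterministic numerical step, independent of the cohort seed).
.fate_thresholds <- function(cfg) {
  p <- cfg$p21
  with_seed(.THRESHOLD_MC_SEED, {
    n <- .THRESHOLD_MC_N
    # G1-captured mothers: daughters inherit half the mother's G2/M plateau.
    t_g1 <- .draw_time_to_mitosis(n, "G1", cfg$durations)
    l_m <- p$mother_g2m_level *
      exp(p$exposure_slope * (t_g1 - cfg$mean_time_to_mitosis[["G1"]]) +
            p$bio_sd_log * rnorm(n))
    x <- 0.5 * l_m *
      exp(p$transmission_sd_log * rnorm(n) - p$transmission_sd_log^2 / 2) *
      exp(p$split_sd_log * rnorm(n) - p$split_sd_log^2 / 2)
    thr_g1 <- unname(quantile(x, 1 - cfg$fate_probs[["G1"]], names = FALSE))
    # S-captured mothers: daughters accumulate p21 de novo, independently.
    t_s <- .draw_time_to_mitosis(n, "S", cfg$durations)
    y <- p$denovo_level *
      exp(p$exposure_slope * (t_s - cfg$mean_time_to_mitosis[["S"]]) +
            p$denovo_sd_log * rnorm(n) - p$denovo_sd_log^2 / 2)
    thr_s <- unname(quantile(y, 1 - cfg$fate_probs[["S"]], names = FALSE))
    # Later generations: de novo accumulation without exposure coupling, at the
    # S-group (depletion) or control quiescence probability.
    p_late <- cfg$fate_probs[["S"]]
    y2 <- p$denovo_level * exp(p$denovo_sd_log * rnorm(n) - p$denovo_sd_log^2 / 2)
    thr_late <- unname(quantile(y2, 1 - p_late, names = FALSE))
    c(G1 = thr_g1, S = thr_s, late = thr_late)
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$condition, "| n_mothers =", x$n_mothers,
      "| seed =", x$seed, "\n")
  cat("  sampling", x$sampling_interval, "h over", x$horizon, "h;",
      "noise sigma =", x$measurement_noise, "\n")
  cat("  stage probs G1/S:", paste(round(x$stage_probs, 4), collapse = "/"),
      " fate probs (quiescent) G1/S:",
      paste(round(x$fate_probs, 4), collapse = "/"), "\n")
  invisible(x)
}
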