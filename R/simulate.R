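#' Simulate a lineage-linked reporter-trajectory cohort
#'
#' Generates mother cells captured mid-cycle at treatment onset (t = 0), lets
#' every mother complete her current cycle with condition-specific phase
#' durations, divides her into two daughters, and assigns each daughter a
#' proliferative or quiescent fate. Fate arises mechanistically from p21 at
#' birth: daughters of G1-captured mothers inherit half of the mother's G2/M
#' p21 plateau (shared transmission noise plus a small per-sibling split
#' asymmetry) and enter quiescence when the inherited level exceeds a
#' threshold; daughters of S-captured mothers accumulate p21 de novo and
#' independently. Proliferating daughters run further full cycles until the
#' observation horizon. All reporter channels (Cdt1, Geminin, SLBP, H1, the
#' CDK2 sensor nuclear/cytoplasmic signals and p21) are sampled on the imaging
#' grid with multiplicative lognormal measurement noise.
#'
#' @param config A [sim_config()] object.
#' @return A `cell_cohort` list with elements `tracks` (wide per-frame
#'   data.table), `lineage` (daughter, parent, division time), `truth`
#'   (per-cell ground-truth table) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  mean_cycle <- sum(vapply(cfg$durations, `[[`, numeric(1), "mean"))
  short_horizon <- cfg$horizon < mean_cycle

  grid <- seq(0, cfg$horizon, by = cfg$sampling_interval)

  stack <- vector("list", cfg$n_mothers)
  for (i in seq_len(cfg$n_mothers)) {
    stack[[i]] <- list(path = paste0("m", i), parent = NA_character_,
                       generation = 0L, mother_index = i,
                       root_stage = NA_character_, inherit = NULL)
  }
  cells <- list()
  tracks <- list()
  k <- 0L
  while (length(stack)) {
    sp <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    res <- .sim_cell(cfg, sp, grid)
    k <- k + 1L
    cells[[k]] <- res$rec
    tracks[[k]] <- res$track
    if (length(res$children)) stack <- c(stack, res$children)
  }

  truth <- data.table::rbindlist(cells)
  data.table::setorder(truth, cell_id)
  tracks <- data.table::rbindlist(tracks)
  data.table::setorder(tracks, cell_id, time_h)
  lineage <- truth[!is.na(parent_id),
                   .(cell_id, parent_id, division_time_h = birth_h)]
  data.table::setorder(lineage, parent_id, cell_id)

  structure(list(tracks = tracks, lineage = lineage, truth = truth,
                 config = cfg, short_horizon = short_horizon),
            class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat("<cell_cohort>", x$config$condition, "|", nrow(x$truth), "cells (",
      sum(x$truth$generation == 0L), "mothers ),",
      nrow(x$tracks), "frames\n")
  invisible(x)
}

# ---- internal: one cell -------------------------------------------------------

.sim_cell <- function(cfg, sp, grid) {
  p <- cfg$p21
  seed_substream(cfg$seed, sp$path)

  if (sp$generation == 0L) {
    u_stage <- runif(1)
    stage <- if (cfg$stage_assignment == "stratified") {
      # quota pattern: mother i is in G1 iff the running G1 quota advances
      # at i; every cohort prefix then holds round(i * p) G1 mothers, so
      # enlarging a cohort never reassigns existing mothers
      i <- sp$mother_index
      pg <- cfg$stage_probs[["G1"]]
      if (round(i * pg) > round((i - 1) * pg)) "G1" else "S"
    } else {
      if (u_stage < cfg$stage_probs[["G1"]]) "G1" else "S"
    }
    u <- runif(1)  # remaining fraction of the current phase
  } else {
    stage <- sp$root_stage
    v_split <- rnorm(1)
  }
  d <- vapply(c("G1", "S", "G2", "M"), function(ph) {
    dd <- cfg$durations[[ph]]
    rtnorm(1L, dd$location, dd$scale, dd$lower)
  }, numeric(1))
  amp <- 100 * exp(0.1 * rnorm(5) - 0.005)  # Cdt1, Geminin, SLBP, H1, CDK2 nuc
  z_bio <- rnorm(1)
  w_trans <- rnorm(1)

  if (sp$generation == 0L) {
    # birth before observation so that at t = 0 the mother sits at the drawn
    # stage with remaining fraction u of that phase
    birth <- if (stage == "G1") -(1 - u) * d[["G1"]] else
      -(d[["G1"]] + (1 - u) * d[["S"]])
    fate <- "proliferative"
    kind <- "divider"
    # G2/M p21 plateau: exposure-coupled under depletion for G1-captured
    # mothers; low for S-captured mothers and under control conditions
    t_div <- birth + sum(d)
    if (cfg$condition != "control" && stage == "G1") {
      plateau <- p$mother_g2m_level *
        exp(p$exposure_slope * (t_div - cfg$mean_time_to_mitosis[["G1"]]) +
              p$bio_sd_log * z_bio)
    } else {
      sc <- if (cfg$condition == "control") 0.1 else p$s_mother_scale
      plateau <- sc * p$mother_g2m_level * exp(p$bio_sd_log * z_bio)
    }
    p21_birth <- p$basal
    p21_kind <- "mother"
    trans_factor <- exp(p$transmission_sd_log * w_trans -
                          p$transmission_sd_log^2 / 2)
  } else {
    birth <- sp$inherit$division
    mech <- sp$inherit$mechanism
    if (mech == "inherit") {
      p21_birth <- sp$inherit$half_plateau * sp$inherit$trans_factor *
        exp(p$split_sd_log * v_split - p$split_sd_log^2 / 2)
      thr <- cfg$thresholds[["G1"]]
      p21_kind <- "inherited"
    } else if (mech == "denovo") {
      p21_birth <- p$denovo_level *
        exp(p$exposure_slope * (sp$inherit$mother_t_div -
                                  cfg$mean_time_to_mitosis[["S"]]) +
              p$denovo_sd_log * v_split - p$denovo_sd_log^2 / 2)
      thr <- cfg$thresholds[["S"]]
      p21_kind <- "denovo"
    } else {
      p21_birth <- p$denovo_level *
        exp(p$denovo_sd_log * v_split - p$denovo_sd_log^2 / 2)
      thr <- cfg$thresholds[["late"]]
      p21_kind <- "denovo"
    }
    quiescent <- p21_birth > thr
    fate <- if (quiescent) "quiescent" else "proliferative"
    kind <- if (quiescent) "quiescent" else "divider"
    plateau <- NA_real_
    trans_factor <- exp(p$transmission_sd_log * w_trans -
                          p$transmission_sd_log^2 / 2)
  }

  if (kind == "divider") {
    b1 <- birth + d[["G1"]]; b2 <- b1 + d[["S"]]
    b3 <- b2 + d[["G2"]]; b4 <- b3 + d[["M"]]
    divides <- b4 <= cfg$horizon
  } else {
    b1 <- b2 <- b3 <- b4 <- NA_real_
    divides <- FALSE
  }

  idx <- grid >= max(birth, 0) & (if (divides) grid < b4 else TRUE)
  tt <- grid[idx]
  nfr <- length(tt)

  track <- NULL
  if (nfr > 0L) {
    sig <- .cell_signals(cfg, tt, kind, birth, b1, b2, b3, b4,
                         amp, p21_kind, p21_birth, plateau,
                         if (sp$generation == 0L) stage else sp$root_stage)
    if (cfg$measurement_noise > 0) {
      s <- cfg$measurement_noise
      noise <- matrix(exp(s * rnorm(nfr * 7L) - s^2 / 2), nrow = nfr)
      for (j in seq_len(7L)) sig[[j]] <- sig[[j]] * noise[, j]
    }
    track <- data.table::data.table(
      cell_id = sp$path, parent_id = sp$parent, time_h = tt,
      cdt1 = sig$cdt1, geminin = sig$geminin, slbp = sig$slbp, h1 = sig$h1,
      cdk2_nuc = sig$nuc, cdk2_cyt = sig$cyt, p21 = sig$p21)
  }

  rec <- data.table::data.table(
    cell_id = sp$path, parent_id = sp$parent, generation = sp$generation,
    stage_at_treatment = if (sp$generation == 0L) stage else sp$root_stage,
    fate = if (sp$generation == 0L) NA_character_ else fate,
    birth_h = birth, division_h = if (divides) b4 else NA_real_,
    t_g1s = b1, t_sg2 = b2, t_g2m = b3,
    p21_birth = p21_birth,
    censored = (kind == "divider" && !divides) || kind == "quiescent",
    n_frames = nfr)

  children <- list()
  if (divides) {
    if (sp$generation == 0L) {
      mech <- if (cfg$condition == "control") "late"
      else if (stage == "G1") "inherit" else "denovo"
    } else {
      mech <- "late"
    }
    inherit <- list(division = b4, mechanism = mech,
                    half_plateau = 0.5 * plateau,
                    trans_factor = trans_factor,
                    mother_t_div = b4)
    for (j in 1:2) {
      children[[j]] <- list(
        path = paste0(sp$path, ".", j), parent = sp$path,
        generation = sp$generation + 1L,
        root_stage = if (sp$generation == 0L) stage else sp$root_stage,
        inherit = inherit)
    }
  }
  list(rec = rec, track = track, children = children)
}

# Noise-free channel values for one cell on its sampled times.
.cell_signals <- function(cfg, tt, kind, b0, b1, b2, b3, b4,
                          amp, p21_kind, p21_birth, plateau, stage) {
  p <- cfg$p21
  A <- amp
  n <- length(tt)
  if (kind == "divider") {
    dG1 <- b1 - b0; dS <- b2 - b1; dG2 <- b3 - b2; dM <- b4 - b3
    cdt1 <- ifelse(tt < b1, 0.05 + 0.95 * (tt - b0) / dG1,
                   ifelse(tt < b2, pmax(1 - 0.95 * (tt - b1) / dS, 0.05), 0.05))
    rg <- 0.98 / (b3 - b1)  # symmetric rise/fall around the Geminin peak
    geminin <- ifelse(tt < b1, 0.02,
                      ifelse(tt < b3, 0.02 + rg * (tt - b1),
                             pmax(1 - rg * (tt - b3), 0.02)))
    rs <- 0.9 / dS          # symmetric rise/fall around the SLBP peak
    slbp <- ifelse(tt < b1, 0.1,
                   ifelse(tt < b2, 0.1 + rs * (tt - b1),
                          pmax(1 - rs * (tt - b2), 0.1)))
    h1 <- ifelse(tt >= b3, 1.8, 1)  # chromatin-condensation signature in M
    ratio <- cfg$quiescent_baseline +
      (cfg$cdk2_peak - cfg$quiescent_baseline) * (tt - b0) / (b4 - b0)
    p21 <- .p21_profile(cfg, tt, p21_kind, b0, b1, b2, b4, p21_birth, plateau)
  } else {
    # quiescent daughter: G0/G1-like, Cdt1 accumulates, no Geminin onset
    cdt1 <- 0.05 + 0.95 * pmin((tt - b0) / cfg$g0_cdt1_time, 1)
    geminin <- rep(0.02, n)
    slbp <- rep(0.1, n)
    h1 <- rep(1, n)
    ratio <- rep(cfg$quiescent_baseline, n)
    if (cfg$condition == "p21_degradation") {
      rise <- pmin(pmax((tt - (cfg$iaa_time + 2)) / 8, 0), 1)
      ratio <- ratio + (1.2 - cfg$quiescent_baseline) * rise
    }
    if (p21_kind == "inherited") {
      p21 <- rep(p21_birth, n)
    } else {
      p21 <- 0.05 * p21_birth +
        0.95 * p21_birth * pmin((tt - b0) / p$denovo_time, 1)
    }
  }
  if (cfg$condition == "p21_degradation") {
    p21 <- p21 * ifelse(tt < cfg$iaa_time, 1,
                        2^(-(tt - cfg$iaa_time) / (1 / 3)))
  }
  list(cdt1 = A[1] * cdt1, geminin = A[2] * geminin, slbp = A[3] * slbp,
       h1 = A[4] * h1, nuc = rep(A[5], n), cyt = A[5] * ratio, p21 = p21)
}

# p21 time course of dividing cells.
.p21_profile <- function(cfg, tt, p21_kind, b0, b1, b2, b4, p21_birth, plateau) {
  p <- cfg$p21
  if (p21_kind == "mother") {
    # modest G1 rise, S suppression, robust G2/M accumulation to the plateau
    basal <- p$basal
    ifelse(tt < b1, basal * (1 + 0.5 * (tt - b0) / (b1 - b0)),
           ifelse(tt < b2, basal * (1.5 - 0.5 * (tt - b1) / (b2 - b1)),
                  basal + (plateau - basal) * (tt - b2) / (b4 - b2)))
  } else {
    # proliferating daughter: inherited or de-novo level, degraded from S entry
    base <- if (p21_kind == "inherited") rep(p21_birth, length(tt)) else
      0.05 * p21_birth + 0.95 * p21_birth * pmin((tt - b0) / p$denovo_time, 1)
    base * 2^(-pmax(0, tt - b1) / p$decay_halflife)
  }
}
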