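#' Detect the peak of a reporter trace
#'
#' Locates the global maximum of the smoothed trace, then refines it to the
#' raw-trace maximum within half a smoothing window. The refinement removes
#' the bias a moving average introduces when the rise and fall slopes around
#' the apex differ (the smoothed maximum drifts toward the gentler side).
#' Ties are broken to the earliest time. An all-equal trace is flagged as
#' having no peak.
#'
#' @param values Numeric trace (>= 3 samples).
#' @param times Sampling times (hours), same length.
#' @param window Smoothing window in frames (odd; 1 = no smoothing).
#' @return List with `peak_time`, `peak_value`, `index`, and `no_peak` flag.
#' @export
detect_peak <- function(values, times, window = 1L) {
  if (length(values) < 3L) stop("need at least 3 samples")
  stopifnot(length(values) == length(times))
  sm <- smooth_trace(values, window)
  if (diff(range(sm)) == 0) {
    return(list(peak_time = NA_real_, peak_value = sm[1], index = NA_integer_,
                no_peak = TRUE))
  }
  i <- which.max(sm)  # which.max takes the earliest of tied maxima
  if (window > 1L) {
    h <- window %/% 2L
    lo <- max(1L, i - h); hi <- min(length(values), i + h)
    i <- lo - 1L + which.max(values[lo:hi])
  }
  list(peak_time = times[i], peak_value = values[i], index = i,
       no_peak = FALSE)
}

# Robust per-cell maximum (98th percentile) used for normalization, so single
# aberrant frames do not define the scale.
.robust_max <- function(x) quantile(x, 0.98, names = FALSE, type = 7)

#' Call cell-cycle phases from Fucci4 reporter trajectories
#'
#' Assigns per-frame G1/S/G2/M labels and phase boundaries from the reporter
#' waveform rules: G1 runs while Cdt1 is high or increasing and Geminin low;
#' the G1/S boundary is the Cdt1 peak (coinciding with Geminin onset); S ends
#' at the SLBP peak; G2 spans SLBP peak to Geminin peak; M runs from the
#' Geminin peak to division. Intervals are half-open (a boundary frame belongs
#' to the later phase). Phases cut by the observation window are flagged
#' truncated and carry no duration.
#'
#' @param track data.table/data.frame with columns `time_h`, `cdt1`,
#'   `geminin`, `slbp`, `h1` (one cell), and optionally `cell_id`,
#'   `parent_id`.
#' @param division_time Division time in hours from the lineage table
#'   (authoritative when available), or `NA`.
#' @param birth_time Exact birth time in hours (the mother's recorded division
#'   time) when known, or `NA`. Using the recorded event rather than the first
#'   sampled frame keeps G1 durations free of frame-snapping bias.
#' @param smooth_window Smoothing window in frames.
#' @param gem_low_frac Geminin level (fraction of its robust max) below which
#'   Geminin counts as "low".
#' @return A list of class `phase_annotation`: per-frame `labels`, boundary
#'   times (`t_g1s`, `t_sg2`, `t_g2m`, `t_div`), durations (`d_g1` ... `d_m`),
#'   per-phase `truncated` flags, H1-derived M onset (`m_onset_h1`) and a
#'   `flag` diagnostic.
#' @export
call_phases <- function(track, division_time = NA_real_,
                        birth_time = NA_real_,
                        smooth_window = 5L, gem_low_frac = 0.2) {
  need <- c("cdt1", "geminin", "slbp", "h1")
  miss <- setdiff(need, names(track))
  if (length(miss)) stop("track is missing channel(s): ",
                         paste(miss, collapse = ", "))
  tt <- track$time_h
  n <- length(tt)
  if (n < 8L) stop("track too short for phase calling (need >= 8 frames)")

  cdt1 <- smooth_trace(track$cdt1, smooth_window)
  gem  <- smooth_trace(track$geminin, smooth_window)
  slbp <- smooth_trace(track$slbp, smooth_window)
  h1   <- smooth_trace(track$h1, smooth_window)

  # per-cell normalization to each channel's own (robust) maximum
  cdt1_n <- cdt1 / .robust_max(cdt1)
  gem_n  <- gem / .robust_max(gem)
  slbp_n <- slbp / .robust_max(slbp)

  dt <- if (n > 1L) tt[2] - tt[1] else NA_real_
  labels <- rep("undetermined", n)
  flag <- ""

  # Geminin onset exists only when the channel has real dynamic range;
  # a flat (never-induced) Geminin trace means the cell stayed in G1/G0.
  gem_lo <- quantile(gem, 0.05, names = FALSE)
  gem_dynamic <- .robust_max(gem) > 3 * max(gem_lo, 1e-12)
  onset_idx <- if (gem_dynamic) {
    ii <- which(gem_n >= gem_low_frac)
    if (length(ii)) ii[1] else NA_integer_
  } else NA_integer_

  # H1 mitotic signature: sustained excursion of H1 above 1.4x its median
  h1_hi <- h1 > 1.4 * median(h1)
  m_onset_h1 <- if (any(h1_hi)) tt[which(h1_hi)[1]] else NA_real_

  if (!gem_dynamic || is.na(onset_idx)) {
    labels[] <- "G1"
    ann <- .phase_annotation(track, labels, NA_real_, NA_real_, NA_real_,
                             division_time, birth_time, tt, dt, m_onset_h1,
                             flag = "no_geminin_onset")
    return(ann)
  }

  pk_gem  <- detect_peak(track$geminin, tt, smooth_window)
  pk_slbp <- detect_peak(track$slbp, tt, smooth_window)
  # Cdt1 peak searched before the Geminin peak: Cdt1 can transiently rebound
  # in daughters after the mother's track is cut
  pk_cdt1 <- detect_peak(track$cdt1[seq_len(pk_gem$index)],
                         tt[seq_len(pk_gem$index)], smooth_window)

  t_g1s <- pk_cdt1$peak_time
  t_sg2 <- pk_slbp$peak_time
  t_g2m <- pk_gem$peak_time
  if (any(is.na(c(t_g1s, t_sg2, t_g2m))) ||
      !(t_g1s <= t_sg2 && t_sg2 <= t_g2m)) {
    ann <- .phase_annotation(track, labels, NA_real_, NA_real_, NA_real_,
                             division_time, birth_time, tt, dt, m_onset_h1,
                             flag = "unresolvable_boundary_ordering")
    return(ann)
  }

  labels[tt <  t_g1s] <- "G1"
  labels[tt >= t_g1s & tt < t_sg2] <- "S"
  labels[tt >= t_sg2 & tt < t_g2m] <- "G2"
  labels[tt >= t_g2m] <- "M"

  .phase_annotation(track, labels, t_g1s, t_sg2, t_g2m, division_time,
                    birth_time, tt, dt, m_onset_h1, flag = flag)
}

# Assemble the annotation object: boundary observability decides truncation.
.phase_annotation <- function(track, labels, t_g1s, t_sg2, t_g2m,
                              division_time, birth_time, tt, dt,
                              m_onset_h1, flag) {
  n <- length(tt)
  first_t <- tt[1]; last_t <- tt[n]
  div_known <- is.finite(division_time)
  birth_known <- is.finite(birth_time)

  # A boundary is observed when it was detected strictly inside the track
  # (a "peak" sitting on the first or last frame means the true extremum lies
  # outside the observation window).
  interior <- function(b) is.finite(b) && b > first_t && b < last_t

  start_obs <- c(G1 = birth_known,
                 S  = interior(t_g1s),
                 G2 = interior(t_sg2),
                 M  = interior(t_g2m))
  end_obs <- c(G1 = interior(t_g1s),
               S  = interior(t_sg2),
               G2 = interior(t_g2m),
               M  = div_known)
  truncated <- !(start_obs & end_obs)

  dur <- c(G1 = if (!truncated[["G1"]]) t_g1s - birth_time else NA_real_,
           S  = if (!truncated[["S"]])  t_sg2 - t_g1s else NA_real_,
           G2 = if (!truncated[["G2"]]) t_g2m - t_sg2 else NA_real_,
           M  = if (!truncated[["M"]])  division_time - t_g2m else NA_real_)

  structure(list(
    cell_id = if ("cell_id" %in% names(track)) track$cell_id[1] else NA,
    labels = labels, times = tt,
    t_g1s = t_g1s, t_sg2 = t_sg2, t_g2m = t_g2m,
    t_div = if (div_known) division_time else NA_real_,
    birth_time = if (birth_known) birth_time else NA_real_,
    m_onset_h1 = m_onset_h1,
    durations = dur, truncated = truncated, flag = flag,
    span_h = last_t - first_t
  ), class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat("<phase_annotation>", if (!is.na(x$cell_id)) x$cell_id else "",
      "| boundaries G1/S:", round(x$t_g1s, 2), " S/G2:", round(x$t_sg2, 2),
      " G2/M:", round(x$t_g2m, 2), " div:", round(x$t_div, 2), "\n")
  if (nzchar(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Call phases for every cell of a cohort
#'
#' Runs [call_phases()] on each cell, taking division times and births from
#' the lineage table (authoritative over waveform-derived signatures).
#'
#' @param cohort A `cell_cohort`, or a list with `tracks` and `lineage`.
#' @param smooth_window Smoothing window in frames.
#' @return data.table with one row per cell: boundaries, durations and
#'   truncation flags.
#' @export
cohort_phases <- function(cohort, smooth_window = 5L) {
  tracks <- cohort$tracks
  lineage <- cohort$lineage
  # a cell's own division time is the recorded birth time of its daughters
  first_kid <- lineage[!duplicated(parent_id)]
  div_of_parent <- stats::setNames(first_kid$division_time_h,
                                   first_kid$parent_id)
  birth_of <- stats::setNames(lineage$division_time_h, lineage$cell_id)

  out <- tracks[, {
    id <- cell_id[1]
    div_t <- if (id %in% names(div_of_parent)) div_of_parent[[id]] else NA_real_
    birth <- if (id %in% names(birth_of)) birth_of[[id]] else NA_real_
    if (.N >= 8L) {
      ann <- call_phases(.SD, division_time = div_t, birth_time = birth,
                         smooth_window = smooth_window)
      list(t_g1s = ann$t_g1s, t_sg2 = ann$t_sg2, t_g2m = ann$t_g2m,
           t_div = ann$t_div, birth_h = ann$birth_time,
           span_h = ann$span_h,
           d_g1 = ann$durations[["G1"]], d_s = ann$durations[["S"]],
           d_g2 = ann$durations[["G2"]], d_m = ann$durations[["M"]],
           trunc_g1 = ann$truncated[["G1"]], trunc_s = ann$truncated[["S"]],
           trunc_g2 = ann$truncated[["G2"]], trunc_m = ann$truncated[["M"]],
           flag = ann$flag)
    } else {
      list(t_g1s = NA_real_, t_sg2 = NA_real_, t_g2m = NA_real_,
           t_div = NA_real_, birth_h = birth,
           span_h = if (.N > 1L) time_h[.N] - time_h[1] else 0,
           d_g1 = NA_real_, d_s = NA_real_,
           d_g2 = NA_real_, d_m = NA_real_,
           trunc_g1 = TRUE, trunc_s = TRUE, trunc_g2 = TRUE, trunc_m = TRUE,
           flag = "too_short")
    }
  }, by = cell_id]
  out
}

#' Summarize phase durations over a cohort
#'
#' Means and SDs are computed over untruncated durations only; phases clipped
#' by the observation window would otherwise bias the estimates downward.
#'
#' Cells born so late that a long phase could not have completed before the
#' window end would still bias the summary (only their short phases survive
#' truncation). With `followup = "complete-cycle"` (the default), durations
#' from cells with a recorded birth are kept only when the cell was observable
#' for at least the longest fully observed cell cycle in the data set, so no
#' included cell could have had any observed cycle length censored away.
#' Cells without a recorded birth (mothers captured mid-cycle) are bounded by
#' their own recorded division and are always kept.
#'
#' @param annotations data.table from [cohort_phases()], or a list of
#'   `phase_annotation` objects.
#' @param followup `"complete-cycle"` (default) or `"none"`, or a numeric
#'   minimum follow-up in hours.
#' @return data.table with columns `phase`, `mean_h`, `sd_h`, `n`.
#' @export
phase_duration_summary <- function(annotations, followup = "complete-cycle") {
  if (is.list(annotations) && !is.data.frame(annotations) &&
      all(vapply(annotations, inherits, logical(1), "phase_annotation"))) {
    annotations <- data.table::rbindlist(lapply(annotations, function(a) {
      data.table::data.table(
        birth_h = a$birth_time, span_h = a$span_h,
        d_g1 = a$durations[["G1"]], d_s = a$durations[["S"]],
        d_g2 = a$durations[["G2"]], d_m = a$durations[["M"]],
        trunc_g1 = a$truncated[["G1"]], trunc_s = a$truncated[["S"]],
        trunc_g2 = a$truncated[["G2"]], trunc_m = a$truncated[["M"]])
    }))
  }
  if (!nrow(annotations)) stop("no annotations to summarize")
  annotations <- data.table::as.data.table(annotations)
  if (!identical(followup, "none") &&
      all(c("birth_h", "span_h") %in% names(annotations))) {
    min_follow <- if (is.numeric(followup)) {
      followup
    } else {
      cyc <- annotations[, d_g1 + d_s + d_g2 + d_m]
      if (all(is.na(cyc))) -Inf else max(cyc, na.rm = TRUE)
    }
    born <- is.finite(annotations$birth_h)
    # observation window end: latest frame observed anywhere in the data set
    window_end <- annotations[, max(ifelse(born, birth_h, 0) + span_h)]
    potential <- window_end - annotations$birth_h
    annotations <- annotations[!born | potential >= min_follow - 1e-9]
  }
  cols <- list(G1 = c("d_g1", "trunc_g1"), S = c("d_s", "trunc_s"),
               G2 = c("d_g2", "trunc_g2"), M = c("d_m", "trunc_m"))
  res <- lapply(names(cols), function(ph) {
    d <- annotations[[cols[[ph]][1]]]
    tr <- annotations[[cols[[ph]][2]]]
    d <- d[!tr & !is.na(d)]
    data.table::data.table(
      phase = ph, mean_h = if (length(d)) mean(d) else NA_real_,
      sd_h = if (length(d) > 1) sd(d) else NA_real_, n = length(d))
  })
  data.table::rbindlist(res)
}
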