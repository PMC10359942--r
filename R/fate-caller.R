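#' Fate-classification parameters
#'
#' @param ratio_threshold CDK2 cytoplasm/nucleus ratio below which activity
#'   counts as low (default 0.8).
#' @param min_window Hours the smoothed ratio must stay below the threshold to
#'   call quiescence (default 10).
#' @param cdt1_peak_fraction Fraction of the per-cell Cdt1 maximum below which
#'   the trace must subsequently fall for the Cdt1 peak to count as reached
#'   (default 0.9).
#' @param smooth_window Frames for ratio/Cdt1 smoothing.
#' @param slope_min Minimum rolling slope (ratio units per hour) counting as
#'   an increase for the three-state scheme.
#' @param sustained_hours Hours over which the rise must be sustained.
#' @return List of class `fate_params`.
#' @export
fate_params <- function(ratio_threshold = 0.8, min_window = 10,
                        cdt1_peak_fraction = 0.9, smooth_window = 5L,
                        slope_min = 0.01, sustained_hours = 2) {
  stopifnot(ratio_threshold > 0, min_window > 0,
            cdt1_peak_fraction > 0, cdt1_peak_fraction <= 1)
  structure(list(ratio_threshold = ratio_threshold, min_window = min_window,
                 cdt1_peak_fraction = cdt1_peak_fraction,
                 smooth_window = as.integer(smooth_window),
                 slope_min = slope_min, sustained_hours = sustained_hours),
            class = "fate_params")
}

#' CDK2 activity from the DHB sensor signals
#'
#' Elementwise cytoplasmic/nuclear ratio. Frames whose nuclear signal falls
#' below `floor` are masked (`NA`) rather than divided.
#'
#' @param nuc_trace,cyt_trace Nuclear and cytoplasmic mean intensities.
#' @param floor Nuclear intensity floor (a.u.).
#' @return Numeric ratio trace.
#' @export
cdk2_activity <- function(nuc_trace, cyt_trace, floor = 1e-6) {
  if (length(nuc_trace) != length(cyt_trace)) {
    stop("nuclear and cytoplasmic traces must have the same length")
  }
  out <- ifelse(nuc_trace < floor, NA_real_, cyt_trace / nuc_trace)
  out
}

# Longest contiguous spell (hours, first-to-last frame) where `x < thr`.
.longest_below <- function(x, times, thr) {
  below <- !is.na(x) & x < thr
  if (!any(below)) return(0)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spans <- times[ends[r$values]] - times[starts[r$values]]
  max(spans)
}

#' Classify a cell as quiescent or proliferative
#'
#' Binary rule: a cell is quiescent when its smoothed CDK2 activity stays
#' below `ratio_threshold` for a contiguous interval longer than `min_window`
#' hours (evaluated from cell birth); otherwise it is proliferating. The
#' three-state scheme additionally calls cells whose activity shows a
#' sustained rise but whose Cdt1 never passes its peak as G1-arrested.
#'
#' @param ratio_trace CDK2 cytoplasm/nucleus ratio per frame.
#' @param times Sampling times (hours).
#' @param cdt1_trace Cdt1 reporter trace (same length), or `NULL` (three-state
#'   call then falls back to the binary one).
#' @param params A [fate_params()] object.
#' @param censored Logical: track ends at the observation horizon without a
#'   recorded division.
#' @param divided Logical: the track ends in a recorded division. A dividing
#'   cell is classifiable however short its track, since division rules out
#'   quiescence under the threshold rule.
#' @return List of class `fate_call`: `binary`, `three_state`,
#'   `longest_subthreshold_h`, `reached_cdt1_peak`, `censored`,
#'   `indeterminate`.
#' @export
classify_fate <- function(ratio_trace, times, cdt1_trace = NULL,
                          params = fate_params(), censored = FALSE,
                          divided = FALSE) {
  stopifnot(length(ratio_trace) == length(times))
  span <- times[length(times)] - times[1]
  # an undivided cell observed for no more than min_window can never satisfy
  # "below threshold for MORE than min_window": indeterminate
  if (!divided && span <= params$min_window) {
    return(structure(list(binary = "indeterminate",
                          three_state = "indeterminate",
                          longest_subthreshold_h = NA_real_,
                          reached_cdt1_peak = NA, censored = censored,
                          indeterminate = TRUE), class = "fate_call"))
  }
  sm <- smooth_trace(ratio_trace, params$smooth_window)
  low <- .longest_below(sm, times, params$ratio_threshold)
  binary <- if (low > params$min_window) "quiescent" else "proliferative"

  # sustained rise: rolling slope positive over >= sustained_hours
  dt <- times[2] - times[1]
  k <- max(2L, ceiling(params$sustained_hours / dt))
  slopes <- rolling_slope(sm, times, params$smooth_window)
  pos <- !is.na(slopes) & slopes > params$slope_min
  r <- rle(pos)
  rising <- any(r$lengths[r$values] >= k)

  reached <- NA
  if (!is.null(cdt1_trace)) {
    cd <- smooth_trace(cdt1_trace, params$smooth_window)
    i_max <- which.max(cd)
    # the peak counts as reached only if the trace then falls back below the
    # peak fraction (a still-climbing Cdt1 has not peaked yet)
    reached <- i_max < length(cd) &&
      min(cd[i_max:length(cd)]) < params$cdt1_peak_fraction * cd[i_max]
  }

  three <- if (!rising) "quiescent"
  else if (isTRUE(reached)) "proliferative"
  else "G1_arrest"
  # the binary 0.8/10-h rule is authoritative: a cell it calls quiescent is
  # never reported as three-state proliferative (S-phase arrest maps to
  # G1_arrest)
  if (binary == "quiescent" && three == "proliferative") three <- "G1_arrest"

  structure(list(binary = binary, three_state = three,
                 longest_subthreshold_h = low,
                 reached_cdt1_peak = reached, censored = censored,
                 indeterminate = FALSE), class = "fate_call")
}

#' @export
print.fate_call <- function(x, ...) {
  cat("<fate_call>", x$binary, "/", x$three_state,
      "| below-threshold", round(x$longest_subthreshold_h, 2), "h\n")
  invisible(x)
}

#' Classify fates of all daughter cells in a cohort
#'
#' Computes the CDK2 activity trace of every cell with a recorded parent and
#' applies [classify_fate()]. First-generation daughters carry their mother's
#' stage at treatment as `group`.
#'
#' @param cohort A `cell_cohort` (or list with `tracks`, `lineage`, `truth`).
#' @param params A [fate_params()] object.
#' @return data.table: `cell_id`, `parent_id`, `generation`, `group`,
#'   `binary`, `three_state`, `longest_subthreshold_h`, `censored`.
#' @export
cohort_fates <- function(cohort, params = fate_params()) {
  tracks <- cohort$tracks
  truth <- cohort$truth
  horizon <- if (!is.null(cohort$config)) cohort$config$horizon else
    max(tracks$time_h)
  daughters <- truth[!is.na(parent_id)]
  gen_of <- stats::setNames(daughters$generation, daughters$cell_id)
  stage_of <- stats::setNames(daughters$stage_at_treatment, daughters$cell_id)
  div_of <- stats::setNames(daughters$division_h, daughters$cell_id)

  dt_tracks <- tracks[cell_id %in% daughters$cell_id]
  out <- dt_tracks[, {
    id <- cell_id[1]
    ratio <- cdk2_activity(cdk2_nuc, cdk2_cyt)
    div <- !is.na(div_of[[id]])
    fc <- classify_fate(ratio, time_h, cdt1, params, censored = !div,
                        divided = div)
    list(parent_id = parent_id[1], generation = gen_of[[id]],
         group = stage_of[[id]], binary = fc$binary,
         three_state = fc$three_state,
         longest_subthreshold_h = fc$longest_subthreshold_h,
         censored = fc$censored)
  }, by = cell_id]
  out
}

#' Per-group quiescent fractions with binomial confidence intervals
#'
#' @param calls data.table with a `binary` column (from [cohort_fates()]) and
#'   the grouping column named by `grouping`.
#' @param grouping Column name to group by (default `"group"`).
#' @param conf_level Confidence level for the exact binomial CI.
#' @return data.table: group, `n`, `n_quiescent`, `fraction_quiescent`,
#'   `fraction_proliferative`, `ci_lo`, `ci_hi`.
#' @export
cohort_fate_fractions <- function(calls, grouping = "group",
                                  conf_level = 0.95) {
  stopifnot(grouping %in% names(calls))
  d <- data.table::as.data.table(calls)[binary %in% c("quiescent",
                                                      "proliferative")]
  empty <- data.table::as.data.table(calls)[
    !binary %in% c("quiescent", "proliferative")]
  if (nrow(empty)) warning(nrow(empty), " indeterminate call(s) excluded")
  if (!nrow(d)) stop("no determinate calls")
  out <- d[, {
    nq <- sum(binary == "quiescent")
    ci <- stats::binom.test(nq, .N, conf.level = conf_level)$conf.int
    list(n = .N, n_quiescent = nq,
         fraction_quiescent = nq / .N,
         fraction_proliferative = 1 - nq / .N,
         ci_lo = ci[1], ci_hi = ci[2])
  }, by = grouping]
  out
}
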