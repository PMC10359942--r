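#' Lineage-statistics parameters
#'
#' @param anchor_window_pre Hours before mitosis for mother window means.
#' @param anchor_window_post Hours after mitosis for daughter window means.
#' @param bin_width Hours per bin for the time-to-mitosis analysis.
#' @return List of class `lineage_params`.
#' @export
lineage_params <- function(anchor_window_pre = 5, anchor_window_post = 5,
                           bin_width = 1.3) {
  stopifnot(anchor_window_pre > 0, anchor_window_post > 0, bin_width > 0)
  structure(list(anchor_window_pre = anchor_window_pre,
                 anchor_window_post = anchor_window_post,
                 bin_width = bin_width), class = "lineage_params")
}

#' Anchor trajectories to the first mitosis of their lineage
#'
#' Shifts every cell's time axis so the founding mother's division sits at
#' time 0: mothers occupy negative anchored time, daughters positive. Cells
#' whose founding mother never divided within the observation window are
#' excluded (and reported via the `excluded` attribute).
#'
#' @param tracks Per-frame track table (`cell_id`, `parent_id`, `time_h`, ...).
#' @param lineage Lineage table (`cell_id`, `parent_id`, `division_time_h`).
#' @return The track table with an added `time_rel` column, ordered as input.
#' @export
align_to_mitosis <- function(tracks, lineage) {
  tracks <- data.table::as.data.table(tracks)
  parent_of <- stats::setNames(lineage$parent_id, lineage$cell_id)
  root_of <- function(id) {
    while (id %in% names(parent_of)) id <- parent_of[[id]]
    id
  }
  ids <- unique(tracks$cell_id)
  roots <- vapply(ids, root_of, character(1))
  first_kid <- lineage[!duplicated(parent_id)]
  div_of_root <- stats::setNames(first_kid$division_time_h,
                                 first_kid$parent_id)
  anchor <- div_of_root[roots]
  names(anchor) <- ids
  excluded <- ids[is.na(anchor)]
  out <- tracks[cell_id %in% ids[!is.na(anchor)]]
  out[, time_rel := time_h - anchor[cell_id]]
  attr(out, "excluded") <- excluded
  out
}

#' Mean signal in a fixed window around mitosis
#'
#' Pre-mitosis windows are `[-width, 0)` (mother side), post-mitosis windows
#' `(0, width]` (daughter side), on the anchored time axis.
#'
#' @param times Anchored times (hours, mitosis at 0).
#' @param values Signal values.
#' @param side `"pre"` or `"post"`.
#' @param width Window width in hours.
#' @return Scalar mean, or `NA` when the window holds no sample.
#' @export
window_mean <- function(times, values, side = c("pre", "post"), width = 5) {
  side <- match.arg(side)
  keep <- if (side == "pre") times >= -width & times < 0 else
    times > 0 & times <= width
  if (!any(keep)) return(NA_real_)
  mean(values[keep])
}

#' Pearson correlation of mother and daughter window means
#'
#' @param pre_means Mother-side window means (one per pair).
#' @param post_means Daughter-side window means, same length.
#' @return List: `r`, `p_value`, `n`, `flag` (non-empty when r is undefined).
#' @export
mother_daughter_correlation <- function(pre_means, post_means) {
  stopifnot(length(pre_means) == length(post_means))
  ok <- is.finite(pre_means) & is.finite(post_means)
  x <- pre_means[ok]; y <- post_means[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                flag = "zero_variance"))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       flag = "")
}

#' Sibling discrepancy statistic
#'
#' For a non-ordered sibling pair's p21 series, the discrepancy
#' `D = 2 * sum((x - y)^2) / (sum((x - mean(x))^2) + sum((y - mean(y))^2))`
#' is 0 for identical siblings, symmetric in the pair, and invariant to a
#' common additive shift and to common rescaling. The resemblance `R2 = 1 - D`
#' is reported alongside (1 for identical siblings).
#'
#' @param x,y Equal-length numeric series (length >= 2).
#' @return List: `D`, `R2`, `flag` (non-empty when both series are constant
#'   and D is undefined).
#' @export
sibling_discrepancy <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  den <- sum((x - mean(x))^2) + sum((y - mean(y))^2)
  if (den == 0) {
    return(list(D = NA_real_, R2 = NA_real_, flag = "both_series_constant"))
  }
  D <- 2 * sum((x - y)^2) / den
  list(D = D, R2 = 1 - D, flag = "")
}

#' Pooled sibling discrepancy for a group of pairs
#'
#' Concatenates the pair series within a group and evaluates the discrepancy
#' on the pooled series, so the denominator carries the between-pair spread of
#' p21 levels; per-pair statistics are returned alongside.
#'
#' @param pairs List of pairs, each a list/data.frame with elements `x` and
#'   `y` (equal-length series).
#' @return List: `D_pooled`, `R2_pooled`, `per_pair` (data.table of per-pair
#'   `D` and `R2`), `n_pairs`.
#' @export
sibling_group_discrepancy <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  xs <- unlist(lapply(pairs, `[[`, "x"))
  ys <- unlist(lapply(pairs, `[[`, "y"))
  pooled <- sibling_discrepancy(xs, ys)
  per <- data.table::rbindlist(lapply(seq_along(pairs), function(i) {
    d <- sibling_discrepancy(pairs[[i]]$x, pairs[[i]]$y)
    data.table::data.table(pair = i, D = d$D, R2 = d$R2)
  }))
  list(D_pooled = pooled$D, R2_pooled = pooled$R2, per_pair = per,
       n_pairs = length(pairs))
}

#' Sibling fate concordance counts by group
#'
#' A pair is concordant when both siblings are quiescent or both
#' proliferative. Pairs with an indeterminate fate are excluded and counted.
#'
#' @param fate_a,fate_b Fate of each sibling (`"quiescent"`/
#'   `"proliferative"`, anything else = indeterminate).
#' @param group Grouping vector (e.g. mother stage at treatment).
#' @return data.table: group, `n_pairs`, `concordant`, `discordant`,
#'   `excluded`.
#' @export
concordance_table <- function(fate_a, fate_b, group) {
  stopifnot(length(fate_a) == length(fate_b),
            length(fate_a) == length(group))
  ok_lv <- c("quiescent", "proliferative")
  d <- data.table::data.table(a = fate_a, b = fate_b, group = group)
  d[, determinate := a %in% ok_lv & b %in% ok_lv]
  d[, concordant := determinate & a == b]
  d[, .(n_pairs = sum(determinate),
        concordant = sum(concordant),
        discordant = sum(determinate & !concordant),
        excluded = sum(!determinate)), by = group]
}

#' Daughter proliferation versus mother time to mitosis
#'
#' Bins mothers by their time to first mitosis (right-open bins of
#' `bin_width` hours starting at 0), computes the percentage of proliferating
#' daughters per bin, and correlates that percentage with the bin centers.
#' Bins holding fewer than `min_mothers` mothers are dropped from the
#' correlation.
#'
#' @param time_to_mitosis Hours from treatment to the mother's division, one
#'   per mother.
#' @param daughter_prolif List (one element per mother) of logical vectors:
#'   daughter proliferative?
#' @param bin_width Bin width in hours.
#' @param min_mothers Minimum mothers per retained bin.
#' @return List: `table` (per-bin center, mothers, daughters, percent
#'   proliferating), `r`, `p_value`, `flag`.
#' @export
proliferation_vs_time <- function(time_to_mitosis, daughter_prolif,
                                  bin_width = 1.3, min_mothers = 2L) {
  stopifnot(length(time_to_mitosis) == length(daughter_prolif))
  bin <- floor(time_to_mitosis / bin_width)
  d <- data.table::data.table(
    bin = bin,
    n_prolif = vapply(daughter_prolif, sum, numeric(1)),
    n_d = vapply(daughter_prolif, length, numeric(1)))
  tab <- d[, .(n_mothers = .N, n_daughters = sum(n_d),
               percent_proliferating = 100 * sum(n_prolif) / sum(n_d)),
           by = bin]
  tab[, bin_center := (bin + 0.5) * bin_width]
  data.table::setorder(tab, bin)
  keep <- tab[n_mothers >= min_mothers]
  if (nrow(keep) < 2L) {
    return(list(table = tab[], r = NA_real_, p_value = NA_real_,
                flag = "fewer_than_two_bins"))
  }
  if (sd(keep$percent_proliferating) == 0 || sd(keep$bin_center) == 0) {
    return(list(table = tab[], r = NA_real_, p_value = NA_real_,
                flag = "zero_variance"))
  }
  r <- stats::cor(keep$bin_center, keep$percent_proliferating)
  p <- if (nrow(keep) >= 3L) {
    cor.test(keep$bin_center, keep$percent_proliferating)$p.value
  } else NA_real_
  list(table = tab[], r = r, p_value = p, flag = "")
}

#' Mother-daughter and sibling p21 statistics for a simulated cohort
#'
#' Convenience wrapper assembling, per first-generation daughter pair: the
#' mother's pre-mitosis p21 window mean, each daughter's post-mitosis window
#' mean and window series, fates, and the mother's stage group.
#'
#' @param cohort A `cell_cohort`.
#' @param fates Fate table from [cohort_fates()] (computed if `NULL`).
#' @param params A [lineage_params()] object.
#' @return List: `pairs` (per-pair data.table), `window_series` (named list of
#'   post-mitosis p21 series per daughter).
#' @export
lineage_p21_data <- function(cohort, fates = NULL, params = lineage_params()) {
  if (is.null(fates)) fates <- cohort_fates(cohort)
  anchored <- align_to_mitosis(cohort$tracks, cohort$lineage)
  truth <- cohort$truth
  g1 <- truth[generation == 1L]
  mothers <- truth[generation == 0L & !is.na(division_h)]

  fate_of <- stats::setNames(fates$binary, fates$cell_id)
  pre <- anchored[cell_id %in% mothers$cell_id,
                  .(pre_mean = window_mean(time_rel, p21, "pre",
                                           params$anchor_window_pre)),
                  by = cell_id]
  pre_of <- stats::setNames(pre$pre_mean, pre$cell_id)

  dpost <- anchored[cell_id %in% g1$cell_id]
  post <- dpost[, .(post_mean = window_mean(time_rel, p21, "post",
                                            params$anchor_window_post)),
                by = cell_id]
  post_of <- stats::setNames(post$post_mean, post$cell_id)
  win <- dpost[time_rel > 0 & time_rel <= params$anchor_window_post]
  data.table::setorder(win, cell_id, time_rel)
  series <- split(win$p21, win$cell_id)

  pairs <- g1[, .(cell_id = sort(cell_id)), by = parent_id]
  pairs <- pairs[, .(sib1 = cell_id[1], sib2 = cell_id[2]), by = parent_id]
  pairs <- pairs[!is.na(sib2)]
  stage_of_mother <- stats::setNames(truth$stage_at_treatment, truth$cell_id)
  lookup <- function(map, key) unname(map[key])
  pairs[, `:=`(
    group = lookup(stage_of_mother, parent_id),
    mother_pre = lookup(pre_of, parent_id),
    post1 = lookup(post_of, sib1), post2 = lookup(post_of, sib2),
    fate1 = lookup(fate_of, sib1), fate2 = lookup(fate_of, sib2))]
  pairs[, concordant := fate1 == fate2 &
          fate1 %in% c("quiescent", "proliferative") &
          fate2 %in% c("quiescent", "proliferative")]
  list(pairs = pairs[], window_series = series)
}
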