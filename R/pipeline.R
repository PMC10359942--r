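#' Run the full analysis pipeline on a simulated cohort
#'
#' One-command end-to-end run: simulate the cohort, write the stage CSVs,
#' call phases, classify fates, compute the lineage statistics
#' (mother-daughter inheritance correlation, sibling concordance and
#' discrepancy, proliferation versus time to mitosis), and write a summary
#' JSON plus a run manifest with file digests. Stages run in order; a stage
#' failure aborts with the failing stage named, keeping partial outputs.
#'
#' @param config A [sim_config()] object or the path of a YAML/JSON config.
#' @param out_dir Output directory.
#' @param fate_pars [fate_params()].
#' @param lineage_pars [lineage_params()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, out_dir, fate_pars = fate_params(),
                         lineage_pars = lineage_params()) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", simulate_cohort(config))
  stage("write_cohort", write_cohort(cohort, out_dir))

  annotations <- stage("phases", cohort_phases(cohort))
  stage("write_phases",
        write_annotations_csv(annotations,
                              file.path(out_dir, "phases.csv")))
  durations <- stage("phase_summary", phase_duration_summary(annotations))

  fates <- stage("fate", cohort_fates(cohort, fate_pars))
  stage("write_fates",
        write_fates_csv(fates, file.path(out_dir, "fates.csv")))
  gen1 <- fates[generation == 1L]
  fractions <- stage("fate_fractions", suppressWarnings(
    cohort_fate_fractions(gen1, "group")))
  overall <- gen1[binary %in% c("quiescent", "proliferative")]

  lstats <- stage("lineage", .lineage_summary(cohort, fates, lineage_pars))
  stage("write_pairs",
        write_annotations_csv(lstats$pairs,
                              file.path(out_dir, "sibling_pairs.csv")))

  summary <- list(
    condition = config$condition,
    n_mothers = config$n_mothers,
    seed = config$seed,
    n_cells = nrow(cohort$truth),
    phase_durations = as.data.frame(durations),
    fate_fractions = as.data.frame(fractions),
    overall_quiescent_fraction = mean(overall$binary == "quiescent"),
    lineage = lstats$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclefate")),
    created = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    condition = config$condition,
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(csv|yaml)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

# Lineage-level statistics bundle used by run_pipeline and the analysis
# scripts.
.lineage_summary <- function(cohort, fates, lineage_pars = lineage_params()) {
  ld <- lineage_p21_data(cohort, fates, lineage_pars)
  p <- ld$pairs

  conc <- concordance_table(p$fate1, p$fate2, p$group)

  md <- rbind(p[group == "G1" & fate1 == "quiescent",
                .(pre = mother_pre, post = post1)],
              p[group == "G1" & fate2 == "quiescent",
                .(pre = mother_pre, post = post2)])
  md <- md[is.finite(pre) & is.finite(post)]
  md_cor <- if (nrow(md) >= 3L) {
    mother_daughter_correlation(md$pre, md$post)
  } else list(r = NA_real_, p_value = NA_real_, n = nrow(md), flag = "n<3")

  sib <- .sibling_series_pairs(ld, group = "G1", concordant_only = TRUE,
                               fate = "quiescent")
  sib_stats <- if (length(sib)) sibling_group_discrepancy(sib) else
    list(D_pooled = NA_real_, R2_pooled = NA_real_, n_pairs = 0L)

  mo <- cohort$truth[generation == 0L & !is.na(division_h)]
  fate_of <- stats::setNames(fates$binary, fates$cell_id)
  kid_map <- split(cohort$lineage$cell_id, cohort$lineage$parent_id)
  dp <- lapply(mo$cell_id, function(id) {
    f <- fate_of[kid_map[[id]]]
    f <- f[!is.na(f) & f %in% c("quiescent", "proliferative")]
    f == "proliferative"
  })
  pv <- if (nrow(mo) >= 4L) {
    proliferation_vs_time(mo$division_h, dp, lineage_pars$bin_width)
  } else list(r = NA_real_, p_value = NA_real_, flag = "too_few_mothers",
              table = NULL)

  list(pairs = p,
       summary = list(
         concordance = as.data.frame(conc),
         mother_daughter_r = md_cor$r,
         mother_daughter_p = md_cor$p_value,
         mother_daughter_n = md_cor$n,
         sibling_D_pooled = sib_stats$D_pooled,
         sibling_R2_pooled = sib_stats$R2_pooled,
         sibling_n_pairs = sib_stats$n_pairs,
         prolif_vs_time_r = pv$r,
         prolif_vs_time_p = pv$p_value))
}

# Extract post-mitosis p21 window series for sibling pairs of one group.
.sibling_series_pairs <- function(ld, group = "G1", concordant_only = TRUE,
                                  fate = NULL) {
  p <- ld$pairs
  sel <- p$group == group
  if (concordant_only) sel <- sel & p$concordant
  if (!is.null(fate)) sel <- sel & p$fate1 == fate
  p <- p[sel & !is.na(sel)]
  sers <- ld$window_series
  out <- lapply(seq_len(nrow(p)), function(i) {
    x <- sers[[p$sib1[i]]]
    y <- sers[[p$sib2[i]]]
    if (is.null(x) || is.null(y) || length(x) < 2L ||
        length(x) != length(y)) return(NULL)
    list(x = x, y = y)
  })
  out[!vapply(out, is.null, logical(1))]
}
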