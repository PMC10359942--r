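# Track tables travel as long-format CSV (cell_id, parent_id, time_h,
# channel, value); inside the package they are wide (one column per channel).
.TRACK_CHANNELS <- c("cdt1", "geminin", "slbp", "h1",
                     "cdk2_nuc", "cdk2_cyt", "p21")

.check_columns <- function(d, need, what) {
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

.check_numeric <- function(d, cols, what) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(d[[cl]]))
    bad <- which(is.na(v) & !is.na(d[[cl]]) & d[[cl]] != "NA")
    if (length(bad)) {
      stop(what, ": non-numeric value in column '", cl, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    data.table::set(d, j = cl, value = v)
  }
  d
}

#' Write / read track tables
#'
#' Tracks are serialized as long-format CSV with columns `cell_id`,
#' `parent_id`, `time_h`, `channel`, `value`; times are written with 4
#' decimal places. `read_tracks_csv()` validates the schema (naming any
#' missing column), rejects malformed numeric fields with their row numbers,
#' and returns the wide per-frame table used throughout the package.
#'
#' @param tracks Wide track table (as in a `cell_cohort`).
#' @param path File path.
#' @return `write_tracks_csv()` returns `path` invisibly;
#'   `read_tracks_csv()` returns a wide data.table.
#' @export
write_tracks_csv <- function(tracks, path) {
  long <- data.table::melt(
    data.table::as.data.table(tracks),
    id.vars = c("cell_id", "parent_id", "time_h"),
    measure.vars = intersect(.TRACK_CHANNELS, names(tracks)),
    variable.name = "channel", value.name = "value",
    variable.factor = FALSE)
  data.table::setorder(long, cell_id, channel, time_h)
  long[, time_h := sprintf("%.4f", time_h)]
  data.table::fwrite(long, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  long <- data.table::fread(path, colClasses = list(character = "cell_id"))
  .check_columns(long, c("cell_id", "parent_id", "time_h", "channel",
                         "value"), "track CSV")
  if (!is.character(long$parent_id)) {
    long[, parent_id := as.character(parent_id)]
  }
  long[parent_id == "", parent_id := NA_character_]
  long <- .check_numeric(long, c("time_h", "value"), "track CSV")
  bad_ch <- setdiff(unique(long$channel), .TRACK_CHANNELS)
  if (length(bad_ch)) {
    stop("track CSV: unknown channel(s): ", paste(bad_ch, collapse = ", "))
  }
  wide <- data.table::dcast(long, cell_id + parent_id + time_h ~ channel,
                            value.var = "value")
  if (is.logical(wide$parent_id)) wide[, parent_id := NA_character_]
  data.table::setorder(wide, cell_id, time_h)
  wide[]
}

#' Write / read lineage tables
#'
#' Lineage CSV columns: `cell_id` (daughter), `parent_id`,
#' `division_time_h`. Sibling pairs share `parent_id` and division time.
#'
#' @param lineage Lineage data.table.
#' @param path File path.
#' @export
write_lineage_csv <- function(lineage, path) {
  out <- data.table::as.data.table(lineage)[
    , .(cell_id, parent_id, division_time_h = sprintf("%.4f",
                                                      division_time_h))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_lineage_csv
#' @export
read_lineage_csv <- function(path) {
  d <- data.table::fread(path, colClasses = list(character = c("cell_id",
                                                               "parent_id")))
  .check_columns(d, c("cell_id", "parent_id", "division_time_h"),
                 "lineage CSV")
  d <- .check_numeric(d, "division_time_h", "lineage CSV")
  # each mother must have exactly two recorded daughters
  nk <- d[, .N, by = parent_id]
  bad <- nk[N != 2L]
  if (nrow(bad)) {
    stop("lineage CSV: mother(s) without exactly 2 daughters: ",
         paste(utils::head(bad$parent_id, 5), collapse = ", "))
  }
  data.table::setorder(d, parent_id, cell_id)
  d[]
}

#' Write per-frame phase annotations and per-cell boundaries
#'
#' @param annotations Per-cell annotation table from [cohort_phases()].
#' @param path File path.
#' @export
write_annotations_csv <- function(annotations, path) {
  out <- data.table::copy(data.table::as.data.table(annotations))
  num <- names(out)[vapply(out, is.numeric, logical(1))]
  for (cl in num) data.table::set(out, j = cl,
                                  value = round(out[[cl]], 4))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Write / read fate-call tables
#'
#' @param fates Fate table from [cohort_fates()].
#' @param path File path.
#' @export
write_fates_csv <- function(fates, path) {
  data.table::fwrite(data.table::as.data.table(fates), path)
  invisible(path)
}

#' @rdname write_fates_csv
#' @export
read_fates_csv <- function(path) {
  d <- data.table::fread(path, colClasses = list(character = "cell_id"))
  .check_columns(d, c("cell_id", "binary"), "fate CSV")
  d[]
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path (`.yaml` or `.json`).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$durations <- lapply(x$durations, unclass)
  x$stage_probs <- as.list(x$stage_probs)
  x$fate_probs <- as.list(x$fate_probs)
  x$thresholds <- as.list(x$thresholds)
  x$mean_time_to_mitosis <- as.list(x$mean_time_to_mitosis)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  .check_columns(x, c("condition", "n_mothers", "seed"), "config file")
  keep <- intersect(names(x), c("condition", "n_mothers", "seed",
                                "sampling_interval", "horizon",
                                "stage_assignment",
                                "quiescent_baseline", "cdk2_peak",
                                "measurement_noise", "iaa_time"))
  args <- x[keep]
  if (!is.null(x$stage_probs)) {
    args$stage_probs <- unlist(x$stage_probs)
  }
  if (!is.null(x$fate_probs)) {
    args$fate_probs <- unlist(x$fate_probs)
  }
  if (!is.null(x$p21)) args$p21 <- x$p21
  do.call(sim_config, args)
}

#' Write a cohort to a directory of CSV files
#'
#' @param cohort A `cell_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracks = file.path(dir, "tracks.csv"),
             lineage = file.path(dir, "lineage.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  write_tracks_csv(cohort$tracks, paths[["tracks"]])
  write_lineage_csv(cohort$lineage, paths[["lineage"]])
  tr <- data.table::copy(cohort$truth)
  for (cl in names(tr)[vapply(tr, is.numeric, logical(1))]) {
    data.table::set(tr, j = cl, value = round(tr[[cl]], 4))
  }
  data.table::fwrite(tr, paths[["truth"]])
  write_config(cohort$config, paths[["config"]])
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tracks <- read_tracks_csv(file.path(dir, "tracks.csv"))
  lineage <- read_lineage_csv(file.path(dir, "lineage.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    data.table::fread(truth_path,
                      colClasses = list(character = c("cell_id",
                                                      "parent_id")))
  } else NULL
  if (!is.null(truth)) truth[parent_id == "", parent_id := NA_character_]
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) read_config(cfg_path) else NULL
  structure(list(tracks = tracks, lineage = lineage, truth = truth,
                 config = config), class = "cell_cohort")
}

#' Write / read multi-channel image stacks as TIFF
#'
#' One TIFF page per channel per frame (frame-major order), with a sidecar
#' JSON channel map recording channel names, frame count and pixel size.
#'
#' @param frames List of frames; each frame is a named list of numeric
#'   matrices (one per channel).
#' @param path TIFF file path; the channel map is written to
#'   `paste0(path, ".json")`.
#' @param pixel_size Microns per pixel, stored in the sidecar.
#' @export
write_image_stack <- function(frames, path, pixel_size = 0.55) {
  stopifnot(length(frames) >= 1L)
  channels <- names(frames[[1]])
  for (fr in frames) stopifnot(identical(names(fr), channels))
  # writeTIFF stores float pages in [0, 1]; rescale by the stack maximum and
  # record the scale in the sidecar so intensities round-trip in a.u.
  scale <- max(1, max(vapply(frames, function(fr)
    max(vapply(fr, max, numeric(1))), numeric(1))))
  pages <- lapply(unlist(lapply(frames, function(fr) fr[channels]),
                         recursive = FALSE),
                  function(m) m / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(channels = channels, n_frames = length(frames),
                            intensity_scale = scale,
                            pixel_size_um = pixel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  stopifnot(length(pages) == nch * meta$n_frames)
  frames <- vector("list", meta$n_frames)
  for (i in seq_len(meta$n_frames)) {
    fr <- pages[((i - 1L) * nch + 1L):(i * nch)]
    fr <- lapply(fr, function(m) m * meta$intensity_scale)
    names(fr) <- meta$channels
    frames[[i]] <- fr
  }
  attr(frames, "pixel_size_um") <- meta$pixel_size_um
  frames
}
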