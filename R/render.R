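#' Image-rendering and quantification parameters
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Microns per pixel (default 0.55).
#' @param nuclear_radius Nuclear disk radius in pixels (default 5).
#' @param ring_width Width of the cytoplasmic annulus outward from the
#'   nuclear boundary, in pixels (default 2).
#' @param log_sigma Laplacian-of-Gaussian scale in pixels; defaults to
#'   `nuclear_radius / sqrt(2)` (scale-matched blob detection).
#' @param background_tile Tile size in pixels for background estimation.
#' @param bias_coefs Length-2 multiplicative illumination-bias gradient
#'   (relative change across the field in x and y).
#' @param background_level Additive global background (a.u.).
#' @param read_noise_sd Additive Gaussian pixel noise SD (a.u.).
#' @param drift_px Per-frame random cell drift SD in pixels.
#' @return List of class `image_params`.
#' @export
image_params <- function(width = 256L, height = 256L, pixel_size = 0.55,
                         nuclear_radius = 5L, ring_width = 2L,
                         log_sigma = NULL, background_tile = 32L,
                         bias_coefs = c(0.15, 0.10), background_level = 20,
                         read_noise_sd = 0, drift_px = 0.3) {
  stopifnot(nuclear_radius >= 1, ring_width >= 1, pixel_size > 0)
  if (is.null(log_sigma)) log_sigma <- nuclear_radius / sqrt(2)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size,
                 nuclear_radius = as.integer(nuclear_radius),
                 ring_width = as.integer(ring_width), log_sigma = log_sigma,
                 background_tile = as.integer(background_tile),
                 bias_coefs = bias_coefs,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd, drift_px = drift_px),
            class = "image_params")
}

# Multiplicative illumination-bias surface (smooth gradient across the field).
.bias_field <- function(params) {
  x <- matrix(rep(seq_len(params$width), each = params$height),
              nrow = params$height)
  y <- matrix(rep(seq_len(params$height), times = params$width),
              nrow = params$height)
  1 + params$bias_coefs[1] * (x / params$width - 0.5) +
    params$bias_coefs[2] * (y / params$height - 0.5)
}

# Deterministic non-overlapping cell placement on the field; one position and
# per-frame drift per cell, drawn from the cell's own substream.
.place_cells <- function(cell_ids, params, seed, n_frames) {
  margin <- params$nuclear_radius + params$ring_width + 2L
  min_sep <- 2 * (params$nuclear_radius + params$ring_width) + 3
  placed <- matrix(numeric(0), ncol = 2)
  out <- vector("list", length(cell_ids))
  for (i in seq_along(cell_ids)) {
    seed_substream(seed, paste0("render:", cell_ids[i]))
    ok <- FALSE
    for (try in 1:200) {
      cx <- runif(1, margin + 1, params$width - margin)
      cy <- runif(1, margin + 1, params$height - margin)
      if (!nrow(placed) ||
          min(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)) >= min_sep) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("field too small for requested cell count")
    placed <- rbind(placed, c(cx, cy))
    drift <- matrix(rnorm(2L * n_frames, sd = params$drift_px),
                    ncol = 2)
    out[[i]] <- list(x = cx + cumsum(drift[, 1]),
                     y = cy + cumsum(drift[, 2]))
  }
  names(out) <- cell_ids
  out
}

#' Render one multi-channel field from reporter tracks
#'
#' Each cell alive at the frame is drawn as a nuclear disk carrying the
#' nuclear channel intensities (Cdt1, Geminin, SLBP, H1, the nuclear CDK2
#' sensor signal, p21) surrounded by a cytoplasmic annulus carrying the
#' cytoplasmic CDK2 signal, over a smooth multiplicative illumination bias
#' and an additive global background.
#'
#' @param tracks Wide track table (one row per cell and frame).
#' @param frame_time Time (hours) of the frame to render.
#' @param params [image_params()].
#' @param positions Cell placement from the internal placement routine; when
#'   `NULL`, cells are placed deterministically from `seed`.
#' @param frame_index Index into the per-frame drift series (1-based).
#' @param seed Cohort seed used for placement.
#' @return List: `channels` (named list of matrices), `truth` (data.table of
#'   per-cell centers and rendered mean intensities).
#' @export
render_field <- function(tracks, frame_time, params = image_params(),
                         positions = NULL, frame_index = 1L, seed = 1L) {
  tracks <- data.table::as.data.table(tracks)
  fr <- tracks[abs(time_h - frame_time) < 1e-9]
  if (!nrow(fr)) stop("no cells alive at the requested frame time")
  if (is.null(positions)) {
    positions <- .place_cells(unique(fr$cell_id), params, seed, frame_index)
  }
  chans <- c("cdt1", "geminin", "slbp", "h1", "p21")
  imgs <- lapply(c(chans, "cdk2"), function(ch)
    matrix(0, nrow = params$height, ncol = params$width))
  names(imgs) <- c(chans, "cdk2")

  r <- params$nuclear_radius
  rw <- params$ring_width
  truth <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    row <- fr[i]
    pos <- positions[[row$cell_id]]
    if (is.null(pos)) next
    cx <- pos$x[min(frame_index, length(pos$x))]
    cy <- pos$y[min(frame_index, length(pos$y))]
    px <- .disk_pixels(cx, cy, r, params)
    ring <- .ring_pixels(cx, cy, r, rw, params)
    for (ch in chans) {
      imgs[[ch]][px] <- imgs[[ch]][px] + row[[ch]]
    }
    # CDK2 sensor: nuclear signal in the disk, cytoplasmic in the annulus
    imgs[["cdk2"]][px] <- imgs[["cdk2"]][px] + row$cdk2_nuc
    imgs[["cdk2"]][ring] <- imgs[["cdk2"]][ring] + row$cdk2_cyt
    truth[[i]] <- data.table::data.table(
      cell_id = row$cell_id, x = cx, y = cy,
      cdt1 = row$cdt1, geminin = row$geminin, slbp = row$slbp, h1 = row$h1,
      cdk2_nuc = row$cdk2_nuc, cdk2_cyt = row$cdk2_cyt, p21 = row$p21)
  }
  truth <- data.table::rbindlist(truth)

  bias <- .bias_field(params)
  if (params$read_noise_sd > 0) {
    seed_substream(seed, paste0("render-noise:", frame_index))
  }
  imgs <- lapply(imgs, function(m) {
    m <- (m + params$background_level) * bias
    if (params$read_noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), sd = params$read_noise_sd),
                      nrow = nrow(m))
    }
    pmax(m, 0)
  })
  list(channels = imgs, truth = truth)
}

# Linear-index pixel sets for the nuclear disk and cytoplasmic annulus.
# Pixel centers sit at integer (row = y, col = x), 1-based here; the
# quantification module uses the same geometry, so disk and ring re-measure
# exactly the rendered pixel sets.
.disk_pixels <- function(cx, cy, r, params) {
  .mask_pixels(cx, cy, 0, r, params)
}

.ring_pixels <- function(cx, cy, r, rw, params) {
  .mask_pixels(cx, cy, r, r + rw, params)
}

.mask_pixels <- function(cx, cy, r_in, r_out, params) {
  xs <- max(1L, floor(cx - r_out)):min(params$width, ceiling(cx + r_out))
  ys <- max(1L, floor(cy - r_out)):min(params$height, ceiling(cy + r_out))
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  d2 <- (gx - cx)^2 + (gy - cy)^2
  keep <- d2 <= r_out^2 & d2 > r_in^2
  (gx[keep] - 1L) * params$height + gy[keep]
}

#' Render a frame sequence for a set of tracks
#'
#' Renders every sampled frame between `t_start` and `t_end`, with cell
#' placements drawn once and per-frame Brownian drift, so the stack can be
#' re-quantified and linked into tracks.
#'
#' @param tracks Wide track table.
#' @param params [image_params()].
#' @param seed Placement/drift seed.
#' @param t_start,t_end Time range (hours); defaults to the full track range.
#' @return List: `frames` (list of channel lists), `truth` (data.table over
#'   frames), `times` (frame times).
#' @export
render_stack <- function(tracks, params = image_params(), seed = 1L,
                         t_start = NULL, t_end = NULL) {
  tracks <- data.table::as.data.table(tracks)
  times <- sort(unique(tracks$time_h))
  if (!is.null(t_start)) times <- times[times >= t_start - 1e-9]
  if (!is.null(t_end)) times <- times[times <= t_end + 1e-9]
  stopifnot(length(times) >= 1L)
  positions <- .place_cells(unique(tracks$cell_id), params, seed,
                            length(times))
  frames <- vector("list", length(times))
  truths <- vector("list", length(times))
  for (k in seq_along(times)) {
    rf <- render_field(tracks, times[k], params, positions = positions,
                       frame_index = k, seed = seed)
    frames[[k]] <- rf$channels
    rf$truth[, `:=`(frame = k, time_h = times[k])]
    truths[[k]] <- rf$truth
  }
  list(frames = frames, truth = data.table::rbindlist(truths),
       times = times)
}
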