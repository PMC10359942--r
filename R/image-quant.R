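#' Flatten illumination bias and subtract global background
#'
#' Estimates a smooth multiplicative bias surface from the low-intensity
#' (background) content of the image: the field is tiled, each tile is
#' summarized by a low percentile (robust to cell pixels), the coarse surface
#' is smoothed with a 3x3 mean filter and bilinearly interpolated to full
#' resolution, and the image is divided by the normalized surface. A global
#' background (median of non-cell pixels) is then subtracted and the result
#' clamped at zero.
#'
#' @param image Numeric matrix.
#' @param params [image_params()] (uses `background_tile`).
#' @return Corrected matrix; attributes `bias` (estimated surface) and
#'   `background` (subtracted level). If no background can be estimated the
#'   image is returned unchanged with a warning.
#' @export
flatten_background <- function(image, params = image_params()) {
  ts <- params$background_tile
  nr <- nrow(image); nc <- ncol(image)
  if (nr <= ts || nc <= ts) stop("image not larger than background_tile")
  ri <- ceiling(seq_len(nr) / ts)
  ci <- ceiling(seq_len(nc) / ts)
  ntr <- max(ri); ntc <- max(ci)
  coarse <- matrix(NA_real_, ntr, ntc)
  for (i in seq_len(ntr)) {
    for (j in seq_len(ntc)) {
      v <- image[ri == i, ci == j]
      coarse[i, j] <- quantile(v, 0.2, names = FALSE)
    }
  }
  if (all(!is.finite(coarse)) || max(coarse) <= 0) {
    warning("no background detected; correction skipped")
    return(image)
  }
  coarse <- .mean3x3(coarse)
  # bilinear interpolation of tile centers to pixel resolution
  centers_r <- (seq_len(ntr) - 0.5) * ts
  centers_c <- (seq_len(ntc) - 0.5) * ts
  bias <- .bilinear(coarse, centers_r, centers_c, nr, nc)
  bias <- bias / mean(bias)
  corrected <- image / bias
  thr <- .otsu(corrected)
  bg_px <- corrected[corrected <= thr]
  bg <- if (length(bg_px)) median(bg_px) else 0
  out <- pmax(corrected - bg, 0)
  attr(out, "bias") <- bias
  attr(out, "background") <- bg
  out
}

# 3x3 mean with symmetrically shrunk windows at the borders, so linear
# surfaces (the common illumination gradients) pass through unchanged.
.mean3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    hi <- min(1, i - 1, nr - i)
    for (j in seq_len(nc)) {
      hj <- min(1, j - 1, nc - j)
      out[i, j] <- mean(m[(i - hi):(i + hi), (j - hj):(j + hj)])
    }
  }
  out
}

# Bilinear interpolation of the tile-center grid, with linear extrapolation
# beyond the outermost tile centers (tiles are equally spaced).
.bilinear <- function(coarse, centers_r, centers_c, nr, nc) {
  rr <- seq_len(nr); cc <- seq_len(nc)
  ts_r <- if (length(centers_r) > 1) diff(centers_r[1:2]) else 1
  ts_c <- if (length(centers_c) > 1) diff(centers_c[1:2]) else 1
  fi <- (rr - centers_r[1]) / ts_r + 1
  fj <- (cc - centers_c[1]) / ts_c + 1
  i0 <- pmin(floor(fi), nrow(coarse) - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(fj), ncol(coarse) - 1L); j0 <- pmax(j0, 1L)
  wi <- fi - i0; wj <- fj - j0
  m00 <- coarse[cbind(rep(i0, nc), rep(j0, each = nr))]
  m10 <- coarse[cbind(rep(i0 + 1L, nc), rep(j0, each = nr))]
  m01 <- coarse[cbind(rep(i0, nc), rep(j0 + 1L, each = nr))]
  m11 <- coarse[cbind(rep(i0 + 1L, nc), rep(j0 + 1L, each = nr))]
  wi_m <- rep(wi, nc); wj_m <- rep(wj, each = nr)
  v <- m00 * (1 - wi_m) * (1 - wj_m) + m10 * wi_m * (1 - wj_m) +
    m01 * (1 - wi_m) * wj_m + m11 * wi_m * wj_m
  matrix(v, nr, nc)
}

# Otsu threshold on a numeric matrix (256-bin histogram).
.otsu <- function(x, breaks = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * breaks) + 1L,
                     breaks), nbins = breaks)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(breaks))
  mu_t <- mu[breaks]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  r[1] + k / breaks * diff(r)
}

# Laplacian-of-Gaussian kernel (sum-zero); bright blobs of radius
# sigma * sqrt(2) give strong negative responses, so detection uses -LoG.
.log_kernel <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  xs <- -half:half
  g <- outer(xs, xs, function(x, y) {
    r2 <- x^2 + y^2
    (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  })
  g - mean(g)
}

#' Detect nuclei by Laplacian-of-Gaussian filtering
#'
#' Convolves the (background-corrected) nuclear channel with a LoG kernel at
#' the configured scale, keeps local maxima of the blob response above an
#' Otsu-derived threshold, and enforces a minimum center separation of twice
#' the nuclear radius (greedy, strongest response first).
#'
#' @param h1_channel Numeric matrix (nuclear/histone channel).
#' @param params [image_params()].
#' @return data.table with `x`, `y` (pixel coordinates, matrix column/row)
#'   and `response`.
#' @export
detect_nuclei <- function(h1_channel, params = image_params()) {
  if (all(h1_channel == 0)) {
    return(data.table::data.table(x = numeric(0), y = numeric(0),
                                  response = numeric(0)))
  }
  k <- .log_kernel(params$log_sigma)
  resp <- -.convolve2(h1_channel, k)
  thr <- .otsu(pmax(resp, 0))
  if (thr <= 0) thr <- max(resp) * 0.5
  # 3x3 local maxima above threshold
  nr <- nrow(resp); nc <- ncol(resp)
  cand <- which(resp > thr)
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    idx <- cand[ii]
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    nb <- resp[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
    keep[ii] <- resp[i, j] >= max(nb)
  }
  cand <- cand[keep]
  if (!length(cand)) {
    return(data.table::data.table(x = numeric(0), y = numeric(0),
                                  response = numeric(0)))
  }
  ys <- ((cand - 1L) %% nr) + 1L
  xs <- ((cand - 1L) %/% nr) + 1L
  ord <- order(resp[cand], decreasing = TRUE)
  xs <- xs[ord]; ys <- ys[ord]; rs <- resp[cand][ord]
  min_sep <- 2 * params$nuclear_radius
  sel <- integer(0)
  for (ii in seq_along(xs)) {
    if (!length(sel) ||
        min(sqrt((xs[sel] - xs[ii])^2 + (ys[sel] - ys[ii])^2)) >= min_sep) {
      sel <- c(sel, ii)
    }
  }
  data.table::data.table(x = as.numeric(xs[sel]), y = as.numeric(ys[sel]),
                         response = rs[sel])
}

# 2-D convolution; uses EBImage's FFT filter when available, otherwise a
# direct (small-kernel) fallback.
.convolve2 <- function(image, kernel) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    EBImage::filter2(image, kernel, boundary = "replicate")
  } else {
    nr <- nrow(image); nc <- ncol(image)
    kh <- (nrow(kernel) - 1L) %/% 2L
    pad <- matrix(0, nr + 2L * kh, nc + 2L * kh)
    pad[kh + seq_len(nr), kh + seq_len(nc)] <- image
    pad[seq_len(kh), ] <- pad[rep(kh + 1L, kh), ]
    pad[nr + kh + seq_len(kh), ] <- pad[rep(nr + kh, kh), ]
    pad[, seq_len(kh)] <- pad[, rep(kh + 1L, kh)]
    pad[, nc + kh + seq_len(kh)] <- pad[, rep(nc + kh, kh)]
    out <- matrix(0, nr, nc)
    for (a in seq_len(nrow(kernel))) {
      for (b in seq_len(ncol(kernel))) {
        out <- out + kernel[a, b] *
          pad[(a - 1L) + seq_len(nr), (b - 1L) + seq_len(nc)]
      }
    }
    out
  }
}

#' Measure one cell at a detected center
#'
#' Nuclear means over the fixed-radius disk; cytoplasmic CDK2 mean over the
#' annulus extending `ring_width` pixels outward from the disk. Disk and ring
#' pixel sets are disjoint by construction. Edge-clipped cells are flagged
#' and their ring mean omitted; a neighboring center inside the ring flags
#' the measurement as contaminated.
#'
#' @param channels Named list of matrices (must include the sensor channel
#'   named `cdk2` when a CDK2 ratio is wanted).
#' @param center Numeric `c(x, y)` in pixel coordinates.
#' @param params [image_params()].
#' @param other_centers Optional matrix/data.frame of other cell centers
#'   (columns x, y) for contamination checks.
#' @return data.table with one row: per-channel nuclear means (columns
#'   `<channel>_nuc`), `cdk2_cyt`, `cdk2_ratio`, `edge_clipped`,
#'   `contaminated`.
#' @export
measure_cell <- function(channels, center, params = image_params(),
                         other_centers = NULL) {
  r <- params$nuclear_radius; rw <- params$ring_width
  cx <- center[1]; cy <- center[2]
  h <- params$height; w <- params$width
  stopifnot(nrow(channels[[1]]) == h, ncol(channels[[1]]) == w)
  edge <- cx < r + rw + 1 || cy < r + rw + 1 ||
    cx > w - r - rw || cy > h - r - rw
  disk <- .mask_pixels(cx, cy, 0, r, params)
  ring <- if (!edge) .mask_pixels(cx, cy, r, r + rw, params) else integer(0)

  contaminated <- FALSE
  if (!is.null(other_centers) && NROW(other_centers) > 0) {
    oc <- as.matrix(other_centers[, c("x", "y"), drop = FALSE])
    d <- sqrt((oc[, 1] - cx)^2 + (oc[, 2] - cy)^2)
    contaminated <- any(d > 1e-9 & d < 2 * r + rw)
  }

  out <- data.table::data.table(x = cx, y = cy)
  for (ch in names(channels)) {
    out[[paste0(ch, "_nuc")]] <- mean(channels[[ch]][disk])
  }
  out$cdk2_cyt <- if (!edge && "cdk2" %in% names(channels)) {
    mean(channels[["cdk2"]][ring])
  } else NA_real_
  out$cdk2_ratio <- if ("cdk2" %in% names(channels)) {
    out$cdk2_cyt / out$cdk2_nuc
  } else NA_real_
  out$edge_clipped <- edge
  out$contaminated <- contaminated
  out
}

#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames under a
#' maximum displacement; unlinked detections start new tracks. A division is
#' recorded when a newly started track begins within `max_disp` of a track
#' present in the previous frame (the nearby track's continuation and the
#' new track are its two children).
#'
#' @param detections List (one element per frame) of data.tables/data.frames
#'   with columns `x`, `y`.
#' @param max_disp Maximum displacement per frame, in pixels.
#' @return List: `tracks` (data.table `track_id`, `frame`, `x`, `y`),
#'   `divisions` (data.table `parent`, `child1`, `child2`, `frame`).
#' @export
link_tracks <- function(detections, max_disp = 5) {
  stopifnot(length(detections) >= 2L)
  detections <- lapply(detections, function(d) {
    d <- data.table::as.data.table(d)
    stopifnot(all(c("x", "y") %in% names(d)))
    d
  })
  next_id <- 0L
  new_id <- function() {
    next_id <<- next_id + 1L
    next_id
  }
  d1 <- detections[[1]]
  cur_ids <- vapply(seq_len(nrow(d1)), function(i) new_id(), integer(1))
  rows <- list(data.table::data.table(track_id = cur_ids, frame = 1L,
                                      x = d1$x, y = d1$y))
  divisions <- list()
  for (f in 2L:length(detections)) {
    a <- detections[[f - 1L]]; b <- detections[[f]]
    na <- nrow(a); nb <- nrow(b)
    ids_b <- rep(NA_integer_, nb)
    if (na > 0L && nb > 0L) {
      dm <- outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2
      dm <- sqrt(dm)
      nn_ab <- apply(dm, 1L, which.min)
      nn_ba <- apply(dm, 2L, which.min)
      for (i in seq_len(na)) {
        j <- nn_ab[i]
        if (nn_ba[j] == i && dm[i, j] <= max_disp) ids_b[j] <- cur_ids[i]
      }
    }
    # new tracks; division when the new track starts next to a frame-(f-1)
    # track (mitosis splits one object into two nearby ones)
    for (j in which(is.na(ids_b))) {
      ids_b[j] <- new_id()
      if (na > 0L) {
        d <- sqrt((a$x - b$x[j])^2 + (a$y - b$y[j])^2)
        i <- which.min(d)
        if (d[i] <= max_disp) {
          sibling <- ids_b[which(ids_b == cur_ids[i])]
          divisions[[length(divisions) + 1L]] <- data.table::data.table(
            parent = cur_ids[i],
            child1 = if (length(sibling)) sibling[1] else NA_integer_,
            child2 = ids_b[j], frame = f)
        }
      }
    }
    rows[[f]] <- data.table::data.table(track_id = ids_b, frame = f,
                                        x = b$x, y = b$y)
    cur_ids <- ids_b
  }
  list(tracks = data.table::rbindlist(rows),
       divisions = if (length(divisions)) data.table::rbindlist(divisions)
       else data.table::data.table(parent = integer(0), child1 = integer(0),
                                   child2 = integer(0), frame = integer(0)))
}

#' Quantify a rendered stack into reporter tracks
#'
#' Full measurement chain: per-frame background flattening of every channel,
#' nuclear detection on the H1 channel, disk/ring measurement per detection,
#' and frame-to-frame linking. The output uses the track-table schema, so
#' phase and fate calling run unchanged on measured data.
#'
#' @param frames List of frames (named channel matrices), e.g. from
#'   [render_stack()] or [read_image_stack()].
#' @param times Frame times in hours.
#' @param params [image_params()].
#' @param max_disp Maximum linking displacement (pixels/frame).
#' @param flatten Apply [flatten_background()] per channel first.
#' @return data.table in track-table form (`cell_id` = track id, `time_h`,
#'   channel columns) plus `x`, `y`, QC flags.
#' @export
quantify_stack <- function(frames, times, params = image_params(),
                           max_disp = 5, flatten = TRUE) {
  stopifnot(length(frames) == length(times))
  dets <- vector("list", length(frames))
  meas <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    ch <- frames[[f]]
    if (flatten) ch <- lapply(ch, flatten_background, params = params)
    det <- detect_nuclei(ch$h1, params)
    dets[[f]] <- det
    if (nrow(det)) {
      mm <- data.table::rbindlist(lapply(seq_len(nrow(det)), function(i) {
        measure_cell(ch, c(det$x[i], det$y[i]), params,
                     other_centers = det[-i])
      }))
      mm[, frame := f]
      meas[[f]] <- mm
    }
  }
  lk <- link_tracks(dets, max_disp = max_disp)
  m <- data.table::rbindlist(meas)
  tr <- merge(lk$tracks, m, by = c("frame", "x", "y"), all.x = TRUE)
  out <- tr[, .(
    cell_id = sprintf("t%04d", track_id), parent_id = NA_character_,
    time_h = times[frame], frame, x, y,
    cdt1 = cdt1_nuc, geminin = geminin_nuc, slbp = slbp_nuc, h1 = h1_nuc,
    cdk2_nuc = cdk2_nuc, cdk2_cyt = cdk2_cyt, p21 = p21_nuc,
    edge_clipped, contaminated)]
  data.table::setorder(out, cell_id, time_h)
  attr(out, "divisions") <- lk$divisions
  out[]
}
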