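shiftn <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  # replicate edges so Hessian estimates stay sane at the border
  if (dy == 1) out[1, ] <- out[2, ]
  if (dy == -1) out[ny, ] <- out[ny - 1, ]
  if (dx == 1) out[, 1] <- out[, 2]
  if (dx == -1) out[, nx] <- out[, nx - 1]
  out
}

# scale-normalized bright-ridge Hessian response at one Gaussian scale
ridge_response_sigma <- function(img, sigma) {
  sm <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  Ixx <- shiftn(sm, 0, 1) - 2 * sm + shiftn(sm, 0, -1)
  Iyy <- shiftn(sm, 1, 0) - 2 * sm + shiftn(sm, -1, 0)
  Ixy <- (shiftn(sm, 1, 1) + shiftn(sm, -1, -1) -
            shiftn(sm, 1, -1) - shiftn(sm, -1, 1)) / 4
  lam_min <- (Ixx + Iyy) / 2 - sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  sigma^2 * pmax(0, -lam_min)
}

#' Detect actin filaments in one fluorescence frame
#'
#' Multiscale Hessian ridge enhancement tuned to fibers in the configured
#' width band (scales sigma = width/2.355 for integer widths in the band,
#' max-pooled), thresholding of the ridge response (Otsu by default),
#' connected components, Zhang-Suen skeletonization, pruning of skeleton
#' branches to the longest simple path, and sub-pixel arc-length midpoint
#' extraction. Components whose mean width (component area over skeleton
#' length) falls outside the band, or whose skeleton is shorter than
#' \code{min_length_px}, are dropped.
#'
#' Coordinates are pixel centers, origin top-left, x right / y down, 1-based.
#'
#' @param frame Numeric matrix ([y, x]) of a single-channel image.
#' @param width_band_px Fiber width band (px), default \code{c(2, 6)}; must
#'   lie within [1, 20].
#' @param threshold \code{"otsu"} (default) or a numeric quantile in (0, 1)
#'   of the positive ridge response.
#' @param min_length_px Minimum skeleton path length (default 8 px).
#' @param width_slack Multiplicative slack on the width band for the mask
#'   width, which is broader than the underlying fiber (default 1.5).
#' @return A data.frame of class \code{frame_detection}: \code{x_mid},
#'   \code{y_mid}, \code{length_px}, \code{width_px}; the pruned skeleton
#'   paths are in attribute \code{paths}. An empty frame yields zero rows.
#' @export
detect_filaments <- function(frame, width_band_px = c(2, 6),
                             threshold = "otsu", min_length_px = 8,
                             width_slack = 1.5) {
  stopifnot(is.matrix(frame), length(width_band_px) == 2)
  if (width_band_px[1] < 1 || width_band_px[2] > 20)
    stop("width band must lie within [1, 20] px")
  img <- frame / max(frame, 1)
  if (stats::sd(img) == 0) {
    out <- data.frame(x_mid = numeric(0), y_mid = numeric(0),
                      length_px = numeric(0), width_px = numeric(0))
    return(structure(out, class = c("frame_detection", "data.frame"),
                     paths = list()))
  }
  widths <- seq(ceiling(width_band_px[1]), floor(width_band_px[2]))
  resp <- matrix(0, nrow(img), ncol(img))
  for (wd in widths) resp <- pmax(resp, ridge_response_sigma(img, wd / 2.355))

  if (identical(threshold, "otsu")) {
    r <- resp / max(resp)
    thr <- EBImage::otsu(r, range = c(0, 1)) * max(resp)
  } else {
    thr <- stats::quantile(resp[resp > 0], threshold)
  }
  # Otsu always splits the histogram, so floor the threshold at the response
  # noise level; an empty frame must yield an empty mask
  noise_floor <- stats::median(resp) + 6 * stats::mad(resp)
  mask <- resp > max(thr, noise_floor)
  lab <- EBImage::imageData(EBImage::bwlabel(mask))

  dets <- list(); paths <- list()
  for (id in seq_len(max(lab))) {
    px <- which(lab == id, arr.ind = TRUE)
    npix <- nrow(px)
    if (npix < min_length_px) next
    # skeletonize on a padded bounding-box crop, then shift back
    y0 <- min(px[, 1]) - 1L; x0 <- min(px[, 2]) - 1L
    crop <- matrix(FALSE, max(px[, 1]) - y0 + 2L, max(px[, 2]) - x0 + 2L)
    crop[cbind(px[, 1] - y0 + 1L, px[, 2] - x0 + 1L)] <- TRUE
    path <- prune_skeleton(skeletonize_mask(crop))
    if (is.null(path) || nrow(path) < 2) next
    path$x <- path$x + x0 - 1L
    path$y <- path$y + y0 - 1L
    len <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
    if (len < min_length_px) next
    width <- npix / len
    if (width < width_band_px[1] / width_slack ||
        width > width_band_px[2] * width_slack) next
    mid <- path_midpoint(path)
    dets[[length(dets) + 1]] <- data.frame(
      x_mid = unname(mid["x"]), y_mid = unname(mid["y"]),
      length_px = len, width_px = width)
    paths[[length(paths) + 1]] <- path
  }
  out <- if (length(dets)) do.call(rbind, dets) else
    data.frame(x_mid = numeric(0), y_mid = numeric(0),
               length_px = numeric(0), width_px = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("frame_detection", "data.frame"), paths = paths)
}

#' Detect filaments across all frames of a movie
#'
#' @param movie A \code{motility_movie} or a list of frame matrices.
#' @param ... Passed to \code{\link{detect_filaments}}.
#' @return Data.frame with columns \code{frame}, \code{x}, \code{y},
#'   \code{length_px}, \code{width_px}.
#' @export
detect_movie <- function(movie, ...) {
  frames <- if (inherits(movie, "motility_movie")) movie$frames else movie
  out <- lapply(seq_along(frames), function(f) {
    d <- detect_filaments(frames[[f]], ...)
    if (nrow(d) == 0) return(NULL)
    data.frame(frame = f, x = d$x_mid, y = d$y_mid,
               length_px = d$length_px, width_px = d$width_px)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(frame = integer(0), x = numeric(0),
                                      y = numeric(0), length_px = numeric(0),
                                      width_px = numeric(0))
  out
}

#' Link per-frame detections into filament tracks
#'
#' Frame-to-frame correspondence by linear assignment: linking costs are
#' squared midpoint displacements, gated at \code{gate_px} (per frame
#' elapsed); births and deaths enter the square cost matrix at
#' \code{birth_death_factor * gate_px^2} so that a displacement above the
#' gate terminates the track and starts a new one. Tracks may bridge up to
#' \code{gap_frames} missed detections.
#'
#' @param detections Data.frame with \code{frame}, \code{x}, \code{y}.
#' @param gate_px Gating radius per elapsed frame (default 15 px).
#' @param gap_frames Maximum bridged gap (frames; default 0).
#' @param birth_death_factor Birth/death cost as a multiple of the squared
#'   gate (default 1.05).
#' @return Data.frame of class \code{filament_tracks}: \code{track},
#'   \code{frame}, \code{x}, \code{y}, with strictly increasing frames and at
#'   most one point per frame within each track.
#' @export
link_tracks <- function(detections, gate_px = 15, gap_frames = 0,
                        birth_death_factor = 1.05) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2) stop("need detections in at least 2 frames")

  tracks <- list()    # each: list(points = data.frame, last_frame)
  active <- integer(0)
  for (f in frames) {
    d <- detections[detections$frame == f, , drop = FALSE]
    m <- nrow(d)
    cand <- active[vapply(tracks[active], function(tr)
      f - tr$last_frame <= gap_frames + 1, TRUE)]
    n <- length(cand)
    assigned_det <- rep(FALSE, m)
    if (n > 0 && m > 0) {
      C <- matrix(Inf, n, m)
      for (i in seq_len(n)) {
        tr <- tracks[[cand[i]]]
        lp <- tr$points[nrow(tr$points), ]
        el <- f - tr$last_frame
        dx <- d$x - lp$x; dy <- d$y - lp$y
        d2 <- dx^2 + dy^2
        C[i, d2 <= (gate_px * el)^2] <- d2[d2 <= (gate_px * el)^2]
      }
      bd <- birth_death_factor * gate_px^2
      full <- matrix(Inf, n + m, n + m)
      full[seq_len(n), seq_len(m)] <- C
      for (i in seq_len(n)) full[i, m + i] <- bd            # death
      for (j in seq_len(m)) full[n + j, j] <- bd            # birth
      lr <- t(C); lr[is.finite(lr)] <- 0                    # auxiliary block
      full[n + seq_len(m), m + seq_len(n)] <- lr
      sol <- solve_lap(full)
      for (i in seq_len(n)) {
        j <- sol$assignment[i]
        if (j <= m) {
          k <- cand[i]
          tracks[[k]]$points <- rbind(tracks[[k]]$points,
                                      data.frame(frame = f, x = d$x[j], y = d$y[j]))
          tracks[[k]]$last_frame <- f
          assigned_det[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned_det)) {
      tracks[[length(tracks) + 1]] <- list(
        points = data.frame(frame = f, x = d$x[j], y = d$y[j]),
        last_frame = f)
    }
    active <- which(vapply(tracks, function(tr)
      f - tr$last_frame <= gap_frames, TRUE) |
        vapply(tracks, function(tr) tr$last_frame == f, TRUE))
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(k)
    cbind(track = k, tracks[[k]]$points)))
  rownames(out) <- NULL
  structure(out, class = c("filament_tracks", "data.frame"))
}

#' Per-track and per-video gliding velocities
#'
#' Per-track velocity is the median frame-to-frame midpoint speed
#' (displacement over elapsed frames) scaled by the pixel size and frame
#' interval; the median is robust to the single corrupted steps that filament
#' crossings produce (\code{estimator = "mean"} gives the plain average).
#' Tracks shorter than \code{min_track_len} points are excluded; an optional
#' minimum-speed filter exists but is off by default.
#'
#' @param tracks A \code{\link{link_tracks}} result.
#' @param pixel_size Pixel size (um/px).
#' @param frame_interval Frame interval (s).
#' @param min_track_len Minimum points per track (default 5).
#' @param min_speed Optional minimum speed filter (um/s; default 0 = off).
#' @param estimator Per-track step summary: \code{"median"} (default) or
#'   \code{"mean"}.
#' @return A list of class \code{velocity_summary}: \code{per_track}
#'   (data.frame track, n_points, velocity_um_s), \code{mean_um_s},
#'   \code{sd_um_s}, \code{n_tracks}, \code{pixel_size},
#'   \code{frame_interval}.
#' @export
compute_velocities <- function(tracks, pixel_size, frame_interval = 1,
                               min_track_len = 5, min_speed = 0,
                               estimator = c("median", "mean")) {
  stopifnot(pixel_size > 0, frame_interval > 0)
  estimator <- match.arg(estimator)
  step_summary <- if (estimator == "median") stats::median else mean
  per <- lapply(split(tracks, tracks$track), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < min_track_len) return(NULL)
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$frame)
    data.frame(track = tr$track[1], n_points = nrow(tr),
               velocity_um_s = step_summary(step) * pixel_size / frame_interval)
  })
  per <- do.call(rbind, per)
  if (!is.null(per) && min_speed > 0)
    per <- per[per$velocity_um_s >= min_speed, , drop = FALSE]
  if (is.null(per) || nrow(per) == 0)
    stop("no tracks satisfy the minimum length (", min_track_len, " points)")
  rownames(per) <- NULL
  structure(list(per_track = per, mean_um_s = mean(per$velocity_um_s),
                 sd_um_s = stats::sd(per$velocity_um_s),
                 n_tracks = nrow(per), pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "velocity_summary")
}
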