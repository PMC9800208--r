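#' Configuration for the in vitro motility movie simulator
#'
#' @param frame_count Number of frames (default 30).
#' @param frame_interval Frame interval (s; default 1).
#' @param pixel_size Pixel size (um/px; default 0.108).
#' @param filament_count Number of filaments (default 20).
#' @param filament_length_px Length range (px), sampled uniformly.
#' @param filament_width_px Filament width, FWHM (px); the default band the
#'   detector targets is 2-6 px.
#' @param speed_um_s Gliding speed (um/s).
#' @param background,signal Background level and peak filament intensity
#'   (photon counts per pixel per frame).
#' @param image_size Frame size in px, \code{c(ny, nx)}.
#' @return A validated list of class \code{movie_sim_config}.
#' @export
movie_sim_config <- function(frame_count = 30, frame_interval = 1,
                             pixel_size = 0.108, filament_count = 20,
                             filament_length_px = c(15, 40),
                             filament_width_px = 4, speed_um_s = 0.5,
                             background = 100, signal = 400,
                             image_size = c(512, 512)) {
  if (frame_count < 2) stop("frame_count must be >= 2")
  if (filament_width_px < 2 || filament_width_px > 6)
    warning("filament width outside the default 2-6 px detection band")
  stopifnot(frame_interval > 0, pixel_size > 0, filament_count >= 1,
            speed_um_s >= 0, length(image_size) == 2)
  structure(list(frame_count = frame_count, frame_interval = frame_interval,
                 pixel_size = pixel_size, filament_count = filament_count,
                 filament_length_px = filament_length_px,
                 filament_width_px = filament_width_px,
                 speed_um_s = speed_um_s, background = background,
                 signal = signal, image_size = image_size),
            class = "movie_sim_config")
}

# analytic rendering of one straight Gaussian-profile filament into `img`:
# intensity = peak * exp(-d_perp^2 / 2 sigma^2) *
#             [Phi((s + L/2)/sigma) - Phi((s - L/2)/sigma)] (end caps),
# where (s, d_perp) are pixel coordinates along/across the filament axis.
render_filament <- function(img, cx, cy, phi, L, sigma, peak) {
  ny <- nrow(img); nx <- ncol(img)
  pad <- ceiling(L / 2 + 4 * sigma)
  x0 <- max(1L, floor(cx - pad)); x1 <- min(nx, ceiling(cx + pad))
  y0 <- max(1L, floor(cy - pad)); y1 <- min(ny, ceiling(cy + pad))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  s <- dx * cos(phi) + dy * sin(phi)
  d <- -dx * sin(phi) + dy * cos(phi)
  cap <- stats::pnorm((s + L / 2) / sigma) - stats::pnorm((s - L / 2) / sigma)
  img[ys, xs] <- img[ys, xs] + peak * exp(-d^2 / (2 * sigma^2)) * cap
  img
}

#' Simulate a fluorescence motility movie with ground-truth tracks
#'
#' Renders straight actin filaments with Gaussian cross-section (sigma =
#' width/2.355) translating along their own axis at the configured speed,
#' with per-pixel analytic Gaussian integration for sub-pixel ground truth
#' and Poisson photon noise. Filaments are placed so their full trajectory
#' stays inside the frame whenever geometrically possible; any filament whose
#' midpoint would leave the frame is culled and flagged in the ground truth.
#'
#' @param cfg A \code{\link{movie_sim_config}}.
#' @param seed Integer seed.
#' @return A list of class \code{motility_movie}: \code{frames} (list of
#'   ny x nx count matrices), \code{truth} (data.frame: filament, frame,
#'   x_px, y_px, culled), \code{cfg}, \code{seed}. Coordinates are pixel
#'   centers, origin top-left, x right / y down, 1-based.
#' @export
make_motility_movie <- function(cfg, seed) {
  stopifnot(inherits(cfg, "movie_sim_config"))
  set.seed(as.integer(seed))
  ny <- cfg$image_size[1]; nx <- cfg$image_size[2]
  sigma <- cfg$filament_width_px / 2.355
  step_px <- cfg$speed_um_s * cfg$frame_interval / cfg$pixel_size
  travel <- step_px * (cfg$frame_count - 1)

  nf <- cfg$filament_count
  L <- stats::runif(nf, cfg$filament_length_px[1], cfg$filament_length_px[2])
  phi <- stats::runif(nf, 0, 2 * pi)
  margin <- L / 2 + 4 * sigma + 2
  cx0 <- cy0 <- numeric(nf)
  culled <- logical(nf)
  for (i in seq_len(nf)) {
    # feasible start box so start and end midpoints stay `margin` from edges
    lox <- margin[i] - min(0, travel * cos(phi[i]))
    hix <- nx - margin[i] - max(0, travel * cos(phi[i]))
    loy <- margin[i] - min(0, travel * sin(phi[i]))
    hiy <- ny - margin[i] - max(0, travel * sin(phi[i]))
    if (lox >= hix || loy >= hiy) {  # trajectory cannot fit: place and flag
      cx0[i] <- stats::runif(1, margin[i], nx - margin[i])
      cy0[i] <- stats::runif(1, margin[i], ny - margin[i])
      culled[i] <- TRUE
    } else {
      cx0[i] <- stats::runif(1, lox, hix)
      cy0[i] <- stats::runif(1, loy, hiy)
    }
  }

  frames <- vector("list", cfg$frame_count)
  truth <- vector("list", cfg$frame_count)
  for (f in seq_len(cfg$frame_count)) {
    img <- matrix(0, ny, nx)
    t <- (f - 1) * step_px
    cx <- cx0 + t * cos(phi); cy <- cy0 + t * sin(phi)
    for (i in seq_len(nf))
      img <- render_filament(img, cx[i], cy[i], phi[i], L[i], sigma, cfg$signal)
    lambda <- img + cfg$background
    frames[[f]] <- matrix(stats::rpois(length(lambda), lambda), ny, nx)
    truth[[f]] <- data.frame(filament = seq_len(nf), frame = f,
                             x_px = cx, y_px = cy, culled = culled)
  }
  structure(list(frames = frames, truth = do.call(rbind, truth),
                 cfg = cfg, seed = seed),
            class = "motility_movie")
}

#' Write a motility movie as a multi-page 16-bit grayscale TIFF
#'
#' @param movie A \code{motility_movie}.
#' @param path Output TIFF path.
#' @param max_count Count mapped to full scale (default the movie maximum).
#' @return \code{path}, invisibly.
#' @export
write_movie_tiff <- function(movie, path, max_count = NULL) {
  stopifnot(inherits(movie, "motility_movie"))
  if (is.null(max_count)) max_count <- max(vapply(movie$frames, max, 0))
  pages <- lapply(movie$frames, function(f) pmin(f / max_count, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a list of matrices
#'
#' @param path TIFF path.
#' @return List of numeric matrices (values in [0, 1] as stored).
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
}
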