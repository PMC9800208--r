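#' Simulate a mant-ATP single-turnover fluorescence decay
#'
#' Emulates the SRX/DRX single-turnover protocol: mant-ATP bound to myosin
#' fluoresces at a plateau until excess unlabeled ATP is injected (the chase,
#' default 60 s), after which the signal decays as a two-state mixture
#' \code{p_srx*exp(-k_slow t') + (1-p_srx)*exp(-k_fast t')} with
#' \code{t'} re-zeroed at the chase. SRX and DRX are treated as a static
#' mixture per trace (interconversion during the chase is not modeled).
#'
#' @param p_srx SRX (slow-phase) fraction, in [0, 1].
#' @param k_slow SRX single-turnover rate (1/s); must be < \code{k_fast}.
#' @param k_fast DRX single-turnover rate (1/s).
#' @param duration_s Post-chase monitoring time (default 940 s).
#' @param dt_s Sampling interval (default 1 s).
#' @param chase_time_s Chase injection time (default 60 s); the pre-chase
#'   plateau segment is included in the trace.
#' @param plateau Pre-chase fluorescence level (AU; default 1).
#' @param noise_sd Gaussian noise SD, in units of the plateau.
#' @param seed Integer seed.
#' @return A \code{\link{new_trace}} spanning 0 to
#'   \code{chase_time_s + duration_s}; metadata stores the chase time and the
#'   ground truth (\code{p_srx}, \code{k_slow}, \code{k_fast}).
#' @export
make_turnover_decay <- function(p_srx, k_slow, k_fast,
                                duration_s = 940, dt_s = 1,
                                chase_time_s = 60, plateau = 1,
                                noise_sd = 0.01, seed = 1) {
  if (k_slow >= k_fast)
    stop("k_slow must be < k_fast (phase labels would be ambiguous)")
  stopifnot(p_srx >= 0, p_srx <= 1, k_slow > 0, plateau > 0)
  set.seed(as.integer(seed))
  t <- seq(0, chase_time_s + duration_s, by = dt_s)
  post <- t >= chase_time_s
  tp <- t[post] - chase_time_s
  y <- numeric(length(t))
  y[!post] <- plateau
  y[post] <- plateau * (p_srx * exp(-k_slow * tp) + (1 - p_srx) * exp(-k_fast * tp))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd * plateau)
  new_trace(t, y, meta = list(
    assay = "single_turnover", chase_time_s = chase_time_s,
    p_srx_true = p_srx, k_slow_true = k_slow, k_fast_true = k_fast,
    plateau = plateau, noise_sd = noise_sd, seed = seed
  ))
}
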