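#' Simulate ATP-induced actomyosin dissociation transients
#'
#' Pyrene-actin fluorescence is quenched by bound myosin S1, so ATP-induced
#' dissociation appears as a rising single exponential. Each trace follows
#' \code{amplitude * (1 - exp(-k_obs t))} plus Gaussian noise, with
#' \code{k_obs = K1*k_plus2*[ATP] / (1 + K1*[ATP])} evaluated at that trace's
#' ATP concentration. The true \code{k_obs} is stored in the trace metadata.
#'
#' @param K1 ATP-binding equilibrium constant (1/uM).
#' @param k_plus2 Maximal ATP-induced dissociation rate (1/s).
#' @param atp_list ATP concentrations after mixing (uM), one trace each.
#' @param amplitude Fluorescence amplitude (AU; default 1).
#' @param noise_sd Gaussian noise SD (AU).
#' @param seed Integer seed.
#' @param n_points Samples per trace (default 400).
#' @param span_k Trace duration in multiples of \code{1/k_obs} (default 8).
#' @param temperature_C Recorded in metadata (default 20).
#' @return List of \code{\link{new_trace}} objects; metadata carries
#'   \code{nucleotide = "ATP"}, \code{conc_uM}, \code{k_obs_true},
#'   \code{amplitude}, \code{seed}.
#' @export
make_dissociation_transients <- function(K1, k_plus2, atp_list,
                                         amplitude = 1, noise_sd = 0.02,
                                         seed = 1, n_points = 400,
                                         span_k = 8, temperature_C = 20) {
  if (length(atp_list) == 0) stop("atp_list must contain at least one [ATP]")
  stopifnot(K1 > 0, k_plus2 > 0, all(atp_list > 0))
  set.seed(as.integer(seed))
  lapply(seq_along(atp_list), function(i) {
    atp <- atp_list[i]
    k <- k_plus2 * K1 * atp / (1 + K1 * atp)
    t <- seq(0, span_k / k, length.out = n_points)
    y <- amplitude * (1 - exp(-k * t))
    if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
    new_trace(t, y, meta = list(
      nucleotide = "ATP", conc_uM = atp, k_obs_true = k,
      amplitude = amplitude, direction = "rising",
      temperature_C = temperature_C, noise_sd = noise_sd, seed = seed
    ))
  })
}

#' Simulate ADP-competition dissociation transients
#'
#' At fixed subsaturating ATP, increasing ADP competes for the nucleotide
#' pocket and slows dissociation: \code{k_obs = k0 / (1 + [ADP]/K_ADP)}.
#'
#' @param k0 Observed rate at zero ADP (1/s).
#' @param K_ADP ADP dissociation constant (uM).
#' @param adp_list ADP concentrations after mixing (uM).
#' @param fixed_atp Fixed ATP concentration recorded in metadata (uM).
#' @inheritParams make_dissociation_transients
#' @return List of \code{\link{new_trace}} objects with
#'   \code{nucleotide = "ADP"} metadata and true \code{k_obs}.
#' @export
make_adp_competition_transients <- function(k0, K_ADP, adp_list,
                                            amplitude = 1, noise_sd = 0.02,
                                            seed = 1, n_points = 400,
                                            span_k = 8, fixed_atp = 20,
                                            temperature_C = 20) {
  if (K_ADP <= 0) stop("K_ADP must be > 0")
  if (length(adp_list) == 0) stop("adp_list must contain at least one [ADP]")
  stopifnot(k0 > 0, all(adp_list >= 0))
  set.seed(as.integer(seed))
  lapply(seq_along(adp_list), function(i) {
    adp <- adp_list[i]
    k <- k0 / (1 + adp / K_ADP)
    t <- seq(0, span_k / k, length.out = n_points)
    y <- amplitude * (1 - exp(-k * t))
    if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
    new_trace(t, y, meta = list(
      nucleotide = "ADP", conc_uM = adp, fixed_atp_uM = fixed_atp,
      k_obs_true = k, amplitude = amplitude, direction = "rising",
      temperature_C = temperature_C, noise_sd = noise_sd, seed = seed
    ))
  })
}
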