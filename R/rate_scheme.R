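#' Ground-truth kinetic parameters of the myosin chemomechanical cycle
#'
#' A \code{rate_scheme} bundles the rate and equilibrium constants that define
#' one myosin construct's chemomechanical cycle, plus the mechanical substep
#' sizes and the SRX/DRX relaxed-state parameters. It is the single source of
#' truth consumed by every synthetic-data generator, so that each analysis
#' module can be validated by parameter recovery.
#'
#' Conventions:
#' \itemize{
#'   \item \code{K1} is the equilibrium constant of the initial reversible
#'     ATP-binding step (1/uM); \code{1/K1} is the ATP affinity in uM.
#'   \item \code{K_ADP} is stored directly in uM as the ADP concentration at
#'     which ATP-induced dissociation is half-inhibited in the competition
#'     assay. The microscopic rates \code{k_plusADP}/\code{k_minusADP} are
#'     optional; when both are supplied they must satisfy
#'     \code{K_ADP = k_minusADP / k_plusADP} (off-rate over on-rate, the
#'     dissociation-constant convention that carries units of uM).
#' }
#'
#' @param kcat Maximal actin-activated ATPase rate per head (1/s). Optional;
#'   when omitted it is derived from the serial cycle rates at saturation.
#' @param K1 ATP-binding equilibrium constant (1/uM).
#' @param k_plus2 Maximal ATP-induced actomyosin dissociation rate (1/s).
#' @param K_ADP ADP dissociation constant (uM).
#' @param k_plusADP,k_minusADP Optional microscopic ADP binding (1/(uM s)) and
#'   release (1/s) rates.
#' @param k_hyd Hydrolysis rate (1/s).
#' @param k_attach Actin attachment pseudo-rate at the reference actin
#'   concentration (1/s).
#' @param k_Pi Phosphate release rate (1/s).
#' @param d1,d2 Working-stroke substep displacements (nm).
#' @param k_srx_in,k_srx_out DRX to SRX and SRX to DRX interconversion rates
#'   (1/s); default 0 (static mixture).
#' @param k_basal_drx,k_basal_srx Single-turnover (basal) ATP release rates of
#'   the DRX and SRX states (1/s).
#' @param p_srx Stationary SRX fraction, in [0, 1].
#'
#' @return An object of class \code{rate_scheme} (a validated named list).
#' @examples
#' sc <- rate_scheme(K1 = 1 / 79.8, k_plus2 = 520.7, K_ADP = 120.7)
#' analytic_kcat(sc, atp = 4000)
#' @export
rate_scheme <- function(kcat = NULL,
                        K1 = 1 / 157.3,
                        k_plus2 = 181.2,
                        K_ADP = 17.0,
                        k_plusADP = NULL,
                        k_minusADP = NULL,
                        k_hyd = 100,
                        k_attach = 5,
                        k_Pi = 75,
                        d1 = 4,
                        d2 = 2,
                        k_srx_in = 0,
                        k_srx_out = 0,
                        k_basal_drx = 0.03,
                        k_basal_srx = 0.003,
                        p_srx = 0.5) {
  sc <- list(
    kcat = kcat, K1 = K1, k_plus2 = k_plus2, K_ADP = K_ADP,
    k_plusADP = k_plusADP, k_minusADP = k_minusADP,
    k_hyd = k_hyd, k_attach = k_attach, k_Pi = k_Pi,
    d1 = d1, d2 = d2,
    k_srx_in = k_srx_in, k_srx_out = k_srx_out,
    k_basal_drx = k_basal_drx, k_basal_srx = k_basal_srx,
    p_srx = p_srx
  )
  class(sc) <- "rate_scheme"
  validate_rate_scheme(sc)
  sc
}

validate_rate_scheme <- function(sc) {
  num <- c("K1", "k_plus2", "K_ADP", "k_hyd", "k_attach", "k_Pi",
           "k_srx_in", "k_srx_out", "k_basal_drx", "k_basal_srx", "p_srx")
  for (f in num) {
    v <- sc[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("rate_scheme field '", f, "' must be a single finite number")
    if (v < 0) stop("rate_scheme field '", f, "' must be >= 0")
  }
  if (sc$p_srx > 1) stop("p_srx must lie in [0, 1]")
  if (!is.null(sc$k_plusADP) && !is.null(sc$k_minusADP)) {
    implied <- sc$k_minusADP / sc$k_plusADP
    if (abs(implied - sc$K_ADP) > 1e-6 * max(1, sc$K_ADP))
      stop("K_ADP inconsistent with k_minusADP / k_plusADP (", implied, ")")
  }
  invisible(sc)
}

#' @export
print.rate_scheme <- function(x, ...) {
  cat("Myosin chemomechanical rate scheme\n")
  cat(sprintf("  ATP binding: K1 = %.4g 1/uM (1/K1 = %.4g uM), k+2 = %.4g 1/s\n",
              x$K1, 1 / x$K1, x$k_plus2))
  cat(sprintf("  ADP: K_ADP = %.4g uM\n", x$K_ADP))
  cat(sprintf("  Cycle: k_hyd = %.4g, k_attach = %.4g, k_Pi = %.4g 1/s\n",
              x$k_hyd, x$k_attach, x$k_Pi))
  cat(sprintf("  Substeps: d1 = %.3g nm, d2 = %.3g nm\n", x$d1, x$d2))
  cat(sprintf("  Relaxed states: p_SRX = %.3g, k_DRX = %.4g, k_SRX = %.4g 1/s\n",
              x$p_srx, x$k_basal_drx, x$k_basal_srx))
  if (!is.null(x$kcat)) cat(sprintf("  kcat override: %.4g 1/s\n", x$kcat))
  invisible(x)
}

#' Serial-cycle state exit rates for a rate scheme
#'
#' Expresses the cycle as a serial loop of first-order steps: ATP-induced
#' dissociation from actin at the given [ATP], ATP hydrolysis, re-attachment
#' to actin, phosphate release, and ADP release. Each entry is the total exit
#' rate (1/s) of one cycle state.
#'
#' @param scheme A \code{rate_scheme}.
#' @param atp ATP concentration (uM); the dissociation step proceeds at
#'   \code{k_plus2 * K1 * atp / (1 + K1 * atp)}.
#' @param adp Competing ADP concentration (uM); slows the dissociation step by
#'   \code{1/(1 + adp/K_ADP)}.
#' @return Named numeric vector of state exit rates (1/s).
#' @export
cycle_rates <- function(scheme, atp = 4000, adp = 0) {
  stopifnot(inherits(scheme, "rate_scheme"), atp >= 0, adp >= 0)
  k_diss <- scheme$k_plus2 * scheme$K1 * atp / (1 + scheme$K1 * atp)
  k_diss <- k_diss / (1 + adp / scheme$K_ADP)
  k_adp_release <- if (!is.null(scheme$k_minusADP)) scheme$k_minusADP else {
    # without microscopic ADP rates, ADP release is folded into attachment;
    # use a fast placeholder so the serial sum is dominated by the slow steps
    1e6
  }
  c(dissociation = k_diss,
    hydrolysis = scheme$k_hyd,
    attachment = scheme$k_attach,
    phosphate_release = scheme$k_Pi,
    adp_release = k_adp_release)
}

#' Analytic steady-state cycling rate of a scheme
#'
#' For a serial loop of exponential steps the mean cycle period is the sum of
#' the mean state dwells, so \code{kcat = 1 / sum(1/rate_i)}. When the scheme
#' carries an explicit \code{kcat} that value is returned directly.
#'
#' @inheritParams cycle_rates
#' @return Steady-state cycling rate (1/s); its reciprocal is the cycle time.
#' @export
analytic_kcat <- function(scheme, atp = 4000, adp = 0) {
  if (!is.null(scheme$kcat)) return(scheme$kcat)
  r <- cycle_rates(scheme, atp = atp, adp = adp)
  if (any(r <= 0)) stop("zero exit rate in a cycle state: cycle never completes")
  1 / sum(1 / r)
}

#' Published kinetic parameters for the MYH7b study constructs
#'
#' Reference steady-state, transient-kinetic, single-turnover, trap and
#' motility parameters for human beta-cardiac myosin (beta-MyHC) S1, human
#' MYH7b S1 and python MYH7b S1, as reported in the primary literature for
#' these constructs. Used to parameterize recovery studies and to derive
#' cross-construct cycle metrics. Values that were not measured for a
#' construct in the source study are \code{NA}.
#'
#' @return A data.frame with one row per construct and columns:
#'   \code{construct}, \code{kcat} (1/s), \code{Km} (uM actin),
#'   \code{efficiency} (1/(s uM), as published), \code{K1k2} (1/(uM s)),
#'   \code{k_plus2} (1/s), \code{invK1} (uM), \code{K_ADP} (uM),
#'   \code{pct_srx} (percent), \code{detach_rate_1uM} (1/s at 1 uM ATP),
#'   \code{step_nm} (nm), \code{velocity_um_s} (um/s).
#' @export
myh7b_reference_params <- function() {
  data.frame(
    construct = c("beta_MyHC", "human_MYH7b", "python_MYH7b"),
    kcat = c(1.57, 0.80, 0.60),
    Km = c(93.4, 35.9, 79.3),
    efficiency = c(0.025, 0.023, 0.008),
    K1k2 = c(4.4, 6.7, 1.2),
    k_plus2 = c(991, 520.7, 181.2),
    invK1 = c(365.7, 79.8, 157.3),
    K_ADP = c(6.1, 120.7, 17.0),
    pct_srx = c(14.4, 82.9, 46.4),
    detach_rate_1uM = c(NA, 9.9, 3.7),
    step_nm = c(NA, 5.3, 4.8),
    velocity_um_s = c(1.017, 0.597, 0.536),
    stringsAsFactors = FALSE
  )
}
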