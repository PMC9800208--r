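#' Simulate an NADH-coupled ATPase plate
#'
#' Generates synthetic plate-reader absorbance traces for the NADH-coupled
#' actin-activated ATPase assay. Each activity well consumes NADH at a rate
#' set by the Michaelis-Menten law \code{basal + kcat*[actin]/(Km+[actin])}
#' (per head) times the amount of myosin, so A340 falls linearly until the
#' NADH pool is exhausted, after which the trace flattens (late-time
#' curvature). A standards block follows a 2-fold NADH dilution series used
#' downstream to calibrate nmol NADH per absorbance unit.
#'
#' @param kcat Maximal actin-activated rate per head (1/s).
#' @param Km Apparent actin affinity (uM).
#' @param basal Actin-free (basal) ATPase rate (1/s).
#' @param actin_concs Actin concentrations (uM) of the activity wells.
#' @param myosin_conc Final myosin concentration (uM; default 0.4).
#' @param nadh_mM_start Top NADH standard concentration (mM; default 1).
#' @param n_standards Standards in the 2-fold series (default 8, i.e. 1 to
#'   0.0078 mM).
#' @param nadh_assay_mM NADH concentration in the coupled assay wells (mM).
#' @param well_volume_uL Reaction volume per well (uL).
#' @param path_cm Optical path length (cm) of the filled well.
#' @param duration_s,dt_s Read length and interval (default 1 h at 30 s).
#' @param noise_sd Gaussian absorbance noise SD (AU).
#' @param seed Integer seed.
#' @return A list of class \code{atpase_plate}: \code{time} (s),
#'   \code{absorbance} (time x wells matrix), \code{well_map} (data.frame:
#'   well, role = activity/basal/standard, actin_uM, nadh_mM), and
#'   \code{ground_truth} (true per-well rates in 1/s and AU/s, the conversion
#'   factor, kcat, Km, basal, seed, noise model).
#' @export
make_atpase_plate <- function(kcat, Km, basal = 0.02,
                              actin_concs = c(10, 20, 30, 45, 60, 80, 100),
                              myosin_conc = 0.4,
                              nadh_mM_start = 1, n_standards = 8,
                              nadh_assay_mM = 1,
                              well_volume_uL = 30, path_cm = 0.5,
                              duration_s = 3600, dt_s = 30,
                              noise_sd = 0.002, seed = 1) {
  if (any(actin_concs < 0) || myosin_conc < 0 || nadh_mM_start < 0)
    stop("concentrations must be nonnegative")
  stopifnot(kcat >= 0, Km > 0, basal >= 0, length(actin_concs) >= 1)
  set.seed(as.integer(seed))

  eps_mM_cm <- 6.22                      # NADH extinction at 340 nm, AU/(mM cm)
  conv <- well_volume_uL / (eps_mM_cm * path_cm)   # nmol NADH per AU
  time <- seq(0, duration_s, by = dt_s)
  nmol_myosin <- myosin_conc * well_volume_uL / 1000

  rate_s <- c(basal + kcat * actin_concs / (Km + actin_concs), basal)
  roles <- c(rep("activity", length(actin_concs)), "basal")
  actin <- c(actin_concs, 0)
  n_act <- length(rate_s)

  nmol0 <- nadh_assay_mM * well_volume_uL
  abs_act <- vapply(seq_len(n_act), function(i) {
    consumed <- rate_s[i] * nmol_myosin * time     # nmol NADH oxidized
    pmax(nmol0 - consumed, 0) / conv
  }, numeric(length(time)))

  std_mM <- nadh_mM_start / 2^(seq_len(n_standards) - 1)
  abs_std <- vapply(std_mM, function(c0) {
    rep(c0 * well_volume_uL / conv, length(time))
  }, numeric(length(time)))

  A <- cbind(abs_act, abs_std)
  if (noise_sd > 0) A <- A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow(A))
  colnames(A) <- sprintf("W%02d", seq_len(ncol(A)))

  well_map <- data.frame(
    well = colnames(A),
    role = c(roles, rep("standard", n_standards)),
    actin_uM = c(actin, rep(NA_real_, n_standards)),
    nadh_mM = c(rep(NA_real_, n_act), std_mM),
    stringsAsFactors = FALSE
  )
  structure(list(
    time = time, absorbance = A, well_map = well_map,
    myosin_conc = myosin_conc, well_volume_uL = well_volume_uL,
    ground_truth = list(
      kcat = kcat, Km = Km, basal = basal,
      rate_s = stats::setNames(rate_s, colnames(A)[seq_len(n_act)]),
      slope_AU_s = stats::setNames(-rate_s * nmol_myosin / conv,
                                   colnames(A)[seq_len(n_act)]),
      conv_nmol_per_AU = conv, seed = seed,
      noise_model = list(type = "gaussian", sd_AU = noise_sd)
    )
  ), class = "atpase_plate")
}
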