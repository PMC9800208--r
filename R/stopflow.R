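#' Fit a single-exponential stopped-flow transient
#'
#' Fits \code{y = A*(1 - exp(-k t)) + c} (rising, the pyrene-dissociation
#' sign) or \code{y = A*exp(-k t) + c} per the trace's \code{direction}
#' metadata, with starting values from log-linearized data. Transients whose
#' span covers less than 3/k of the process are flagged truncated.
#'
#' @param trace A \code{\link{new_trace}}; metadata fields used when present:
#'   \code{direction} ("rising"/"decaying"), \code{conc_uM}, \code{nucleotide}.
#' @return A list of class \code{kobs_point}: \code{k_obs}, \code{k_se},
#'   \code{amplitude}, \code{offset}, \code{conc_uM}, \code{nucleotide},
#'   \code{truncated}, \code{converged}.
#' @export
fit_transient_exponential <- function(trace) {
  stopifnot(inherits(trace, "myo_trace"))
  meta <- trace_meta(trace)
  t <- trace$time; y <- trace$signal
  rising <- is.null(meta$direction) || identical(meta$direction, "rising")

  # log-linearized initialization: residual from the asymptote decays as exp(-kt)
  y_inf <- if (rising) max(y) else min(y)
  resid0 <- abs(y_inf - y)
  pos <- resid0 > max(resid0) * 1e-3
  k0 <- tryCatch({
    f <- stats::lm(log(resid0[pos]) ~ t[pos])
    max(-unname(stats::coef(f)[2]), 1e-6)
  }, error = function(e) 1 / max(t))
  A0 <- abs(y_inf - y[1])

  model <- if (rising) y ~ A * (1 - exp(-k * t)) + c else y ~ A * exp(-k * t) + c
  fit <- try(minpack.lm::nlsLM(model,
                               start = list(A = A0, k = k0, c = y[1] * rising),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(k_obs = NA_real_, k_se = NA_real_, converged = FALSE,
                          conc_uM = meta$conc_uM, nucleotide = meta$nucleotide,
                          truncated = NA), class = "kobs_point"))
  co <- summary(fit)$coefficients
  k <- co["k", "Estimate"]
  structure(list(k_obs = k, k_se = co["k", "Std. Error"],
                 amplitude = co["A", "Estimate"], offset = co["c", "Estimate"],
                 conc_uM = meta$conc_uM, nucleotide = meta$nucleotide,
                 truncated = k * max(t) < 3, converged = TRUE),
            class = "kobs_point")
}

kobs_table <- function(points) {
  if (is.data.frame(points)) return(points)
  data.frame(conc_uM = vapply(points, `[[`, 0, "conc_uM"),
             k_obs = vapply(points, `[[`, 0, "k_obs"),
             k_se = vapply(points, function(p)
               if (is.null(p$k_se) || is.na(p$k_se)) NA_real_ else p$k_se, 0))
}

#' Fit the ATP dependence of the dissociation rate
#'
#' Two estimates are produced and cross-checked: (a) a linear regression
#' through the origin over the low-ATP subset ([ATP] <= 0.2/K1 from a pilot
#' hyperbolic fit, minimum 3 points) giving the second-order ATP-binding rate
#' K1k2; and (b) the full hyperbolic fit
#' \code{k_obs = K1k2*[ATP]/(1 + K1*[ATP])} giving the maximal dissociation
#' rate k_plus2 = K1k2/K1 and ATP affinity 1/K1. The internal-consistency
#' check compares the linear K1k2 with k_plus2/(1/K1).
#'
#' @param points List of \code{kobs_point} or a data.frame with
#'   \code{conc_uM}, \code{k_obs} and optional \code{k_se}.
#' @param weighted Weight by 1/SE^2 when SEs are available (default TRUE).
#' @return A list of class \code{atp_dependence_fit}: \code{K1k2} (linear
#'   estimate, 1/(uM s)) with \code{K1k2_se}, \code{k_plus2} and
#'   \code{invK1} (uM) with SEs from the hyperbolic fit, \code{K1k2_hyp},
#'   \code{n_linear}, \code{consistent} (within 2x combined SE),
#'   \code{hyperbolic_identifiable}.
#' @export
fit_atp_dependence <- function(points, weighted = TRUE) {
  pts <- kobs_table(points)
  pts <- pts[is.finite(pts$k_obs), ]
  if (nrow(pts) < 5) stop("need at least 5 ATP concentrations")
  atp <- pts$conc_uM; k <- pts$k_obs
  w <- if (weighted && all(is.finite(pts$k_se)) && all(pts$k_se > 0))
    1 / pts$k_se^2 else rep(1, nrow(pts))

  # pilot hyperbolic fit for the linear-regime cut
  st <- list(K1k2 = k[which.min(atp)] / min(atp), K1 = 1 / stats::median(atp))
  hyp <- try(minpack.lm::nlsLM(k ~ K1k2 * atp / (1 + K1 * atp), start = st,
                               weights = w, lower = c(1e-12, 1e-12),
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             silent = TRUE)
  if (inherits(hyp, "try-error")) stop("hyperbolic fit did not converge")
  co <- summary(hyp)$coefficients
  K1k2_h <- co["K1k2", "Estimate"]; K1 <- co["K1", "Estimate"]
  invK1 <- 1 / K1
  k_plus2 <- K1k2_h / K1
  # delta-method SEs for the derived quantities
  V <- stats::vcov(hyp)
  se_invK1 <- sqrt(V["K1", "K1"]) / K1^2
  g <- c(1 / K1, -K1k2_h / K1^2)
  se_kp2 <- sqrt(drop(t(g) %*% V %*% g))

  identifiable <- max(atp) * K1 > 0.5   # data must reach visible curvature
  low <- atp <= 0.2 * invK1
  if (sum(low) < 3) low <- rank(atp, ties.method = "first") <= 3
  lin <- stats::lm(k ~ 0 + atp, subset = low, weights = w)
  K1k2_lin <- unname(stats::coef(lin)[1])
  K1k2_lin_se <- summary(lin)$coefficients[1, 2]

  # the through-origin estimator carries a bounded downward curvature
  # systematic, K1k2*(1 - fbar) with fbar the weighted mean of 1/(1+K1*a)
  # over the low subset; it enters the consistency budget as a systematic
  fbar <- sum((w * atp^2 / (1 + K1 * atp))[low]) / sum((w * atp^2)[low])
  curv_sys <- K1k2_h * (1 - fbar)
  comb_se <- sqrt(K1k2_lin_se^2 + curv_sys^2 + (se_kp2 / invK1)^2 +
                    (k_plus2 * se_invK1 / invK1^2)^2)
  structure(list(K1k2 = K1k2_lin, K1k2_se = K1k2_lin_se,
                 K1k2_hyp = K1k2_h, k_plus2 = k_plus2, k_plus2_se = se_kp2,
                 invK1 = invK1, invK1_se = se_invK1,
                 n_linear = sum(low),
                 consistent = abs(K1k2_lin - k_plus2 / invK1) <= 2 * comb_se,
                 hyperbolic_identifiable = identifiable,
                 points = pts),
            class = "atp_dependence_fit")
}

#' Fit the ADP-competition model
#'
#' Fits \code{k_obs = k0 / (1 + [ADP]/K_ADP)}, the hyperbolic competition
#' between ATP and ADP for the nucleotide pocket at fixed ATP. \code{k0} is
#' fitted unless supplied.
#'
#' @param points List of \code{kobs_point} or data.frame (\code{conc_uM} is
#'   [ADP] in uM).
#' @param k0 Known zero-ADP rate (1/s), or NULL to fit it.
#' @param weighted Weight by 1/SE^2 when SEs are available.
#' @return A list of class \code{adp_competition_fit}: \code{K_ADP} (uM) with
#'   \code{K_ADP_ci} (95 pct), \code{k0}, \code{model_violation} (TRUE when
#'   k_obs increases with [ADP]).
#' @export
fit_adp_competition <- function(points, k0 = NULL, weighted = TRUE) {
  pts <- kobs_table(points)
  pts <- pts[is.finite(pts$k_obs), ]
  if (nrow(pts) < 4) stop("need at least 4 ADP concentrations")
  if (is.null(k0) && !any(pts$conc_uM == 0))
    stop("supply k0 or include an [ADP] = 0 point")
  adp <- pts$conc_uM; k <- pts$k_obs
  w <- if (weighted && all(is.finite(pts$k_se)) && all(pts$k_se > 0))
    1 / pts$k_se^2 else rep(1, nrow(pts))
  violation <- unname(stats::coef(stats::lm(k ~ adp))[2]) > 0

  if (is.null(k0)) {
    st <- list(k0 = max(k), K_ADP = stats::median(adp[adp > 0]))
    fit <- minpack.lm::nlsLM(k ~ k0 / (1 + adp / K_ADP), start = st,
                             weights = w, lower = c(1e-12, 1e-12),
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    co <- summary(fit)$coefficients
    k0_est <- co["k0", "Estimate"]
    Kd <- co["K_ADP", "Estimate"]; Kse <- co["K_ADP", "Std. Error"]
  } else {
    k0_est <- k0
    st <- list(K_ADP = stats::median(adp[adp > 0]))
    fit <- minpack.lm::nlsLM(k ~ k0_est / (1 + adp / K_ADP), start = st,
                             weights = w, lower = 1e-12,
                             control = minpack.lm::nls.lm.control(maxiter = 300))
    co <- summary(fit)$coefficients
    Kd <- co["K_ADP", "Estimate"]; Kse <- co["K_ADP", "Std. Error"]
  }
  z <- stats::qnorm(0.975)
  structure(list(K_ADP = Kd, K_ADP_se = Kse, K_ADP_ci = Kd + c(-1, 1) * z * Kse,
                 k0 = k0_est, k0_fixed = !is.null(k0),
                 model_violation = violation, points = pts),
            class = "adp_competition_fit")
}
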