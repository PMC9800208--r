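#' Fit the NADH standard curve
#'
#' Ordinary least-squares line of nmol NADH against absorbance across the
#' standards block; the slope is the plate's conversion factor (nmol NADH per
#' absorbance unit) used to turn A340 slopes into ATP consumption rates.
#'
#' @param nadh_mM Standard concentrations (mM); at least 3 distinct values.
#' @param absorbance Mean absorbance (AU) of each standard well.
#' @param well_volume_uL Well volume (uL) converting mM to nmol.
#' @return A list of class \code{nadh_standard}: \code{conversion_factor}
#'   (nmol/AU), \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{concentrations}, \code{absorbances}.
#' @export
fit_nadh_standard <- function(nadh_mM, absorbance, well_volume_uL = 30) {
  stopifnot(length(nadh_mM) == length(absorbance))
  if (length(unique(nadh_mM)) < 3)
    stop("need at least 3 distinct standard concentrations")
  if (diff(range(absorbance)) == 0)
    stop("all standard absorbances equal: standard curve is rank-deficient")
  nmol <- nadh_mM * well_volume_uL
  fit <- stats::lm(nmol ~ absorbance)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("standard-curve slope must be positive")
  structure(list(conversion_factor = slope, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 concentrations = nadh_mM, absorbances = absorbance),
            class = "nadh_standard")
}

# rolling k-point regression slopes at each start position (vectorized)
rolling_slopes <- function(t, y, k = 5) {
  n <- length(t)
  m <- n - k + 1
  vapply(seq_len(m), function(i) {
    idx <- i:(i + k - 1)
    tt <- t[idx] - mean(t[idx])
    sum(tt * y[idx]) / sum(tt^2)
  }, 0)
}

#' Extract an ATPase rate from one absorbance trace
#'
#' Selects the linear range of A340 versus time, converts its slope to nmol
#' ATP/s through the NADH conversion factor, and divides by nmol myosin to
#' yield a per-head rate in 1/s. The linear range is the longest contiguous
#' window of at least \code{min_window} samples whose rolling 5-point local
#' slopes all stay within \code{slope_tol} of the window's global slope and
#' whose R-squared is at least \code{r2_min}; ties go to the earliest window
#' (initial velocity before NADH depletion).
#'
#' @param time Time vector (s).
#' @param absorbance Absorbance vector (AU), same length (>= 10 samples).
#' Both criteria are floored by the trace's own noise level (estimated
#' robustly from first differences) so that slow wells, whose slope sits at
#' the noise floor, are judged against noise rather than rejected outright:
#' the local-slope band is \code{max(slope_tol*|slope|, 3*SE_local)} and a
#' window whose residual scatter does not exceed the noise is accepted even
#' when its R-squared falls below \code{r2_min}.
#'
#' @param standard A \code{\link{fit_nadh_standard}} result.
#' @param myosin_conc Myosin concentration (uM).
#' @param well_volume_uL Well volume (uL).
#' @param min_window Minimum window length in samples (default 10).
#' @param slope_tol Relative local-slope tolerance (default 0.05).
#' @param r2_min Minimum window R-squared (default 0.995).
#' @return A list of class \code{atpase_rate}: \code{rate_s} (1/s, positive
#'   for NADH consumption), \code{slope_AU_s}, \code{window} (start/end
#'   indices), \code{r_squared}, \code{rejected}, \code{reason}.
#' @export
extract_rate <- function(time, absorbance, standard, myosin_conc,
                         well_volume_uL = 30, min_window = 10,
                         slope_tol = 0.05, r2_min = 0.995) {
  stopifnot(inherits(standard, "nadh_standard"), myosin_conc > 0)
  n <- length(time)
  if (n < 10) stop("trace must have at least 10 samples")
  t <- as.numeric(time); y <- as.numeric(absorbance)

  # cumulative sums for O(1) regression statistics over any window
  ct <- c(0, cumsum(t)); cy <- c(0, cumsum(y))
  ctt <- c(0, cumsum(t * t)); cty <- c(0, cumsum(t * y))
  cyy <- c(0, cumsum(y * y))

  loc <- rolling_slopes(t, y, 5)            # local slope starting at index i
  # robust noise estimate; first differences cancel the linear trend
  sd_noise <- stats::mad(diff(y)) / sqrt(2)
  dt <- stats::median(diff(t))
  se_local <- sd_noise / (dt * sqrt(10))    # SE of a 5-point local slope

  best <- NULL
  for (i in seq_len(n - min_window + 1)) {
    if (!is.null(best) && (n - i + 1) <= best$len) break
    js <- (i + min_window - 1):n            # candidate window ends
    m <- js - i + 1
    st <- ct[js + 1] - ct[i]; sy <- cy[js + 1] - cy[i]
    stt <- ctt[js + 1] - ctt[i]; sty <- cty[js + 1] - cty[i]
    syy <- cyy[js + 1] - cyy[i]
    sxx <- stt - st^2 / m
    sxy <- sty - st * sy / m
    syy0 <- syy - sy^2 / m
    slope <- sxy / sxx
    r2 <- ifelse(syy0 <= 0, 1, sxy^2 / (sxx * pmax(syy0, .Machine$double.xmin)))
    resid_sd <- sqrt(pmax(syy0 - sxy^2 / sxx, 0) / pmax(m - 2, 1))
    # running extrema of local slopes whose 5-point window fits inside [i, j]
    locmax <- cummax(loc[i:(n - 4)]); locmin <- cummin(loc[i:(n - 4)])
    k <- js - 4 - i + 1                     # index of last local start in [i, j]
    tol <- pmax(slope_tol * abs(slope), 3 * se_local)
    valid <- (r2 >= r2_min | resid_sd <= 1.2 * sd_noise + 1e-12) &
      locmax[k] <= slope + tol & locmin[k] >= slope - tol
    if (any(valid)) {
      len <- max(m[valid])
      if (is.null(best) || len > best$len) {
        j <- js[valid][which.max(m[valid])]
        idx <- which(js == j)
        best <- list(i = i, j = j, len = len,
                     slope = slope[idx], r2 = r2[idx])
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(rate_s = NA_real_, slope_AU_s = NA_real_,
                          window = c(NA, NA), r_squared = NA_real_,
                          rejected = TRUE,
                          reason = "no window satisfied the linearity criterion"),
                     class = "atpase_rate"))
  }
  nmol_myosin <- myosin_conc * well_volume_uL / 1000
  rate <- -best$slope * standard$conversion_factor / nmol_myosin
  structure(list(rate_s = rate, slope_AU_s = best$slope,
                 window = c(best$i, best$j), r_squared = best$r2,
                 rejected = FALSE, reason = NA_character_),
            class = "atpase_rate")
}

#' Subtract the basal (actin-free) rate from activity points
#'
#' @param points Data.frame with columns \code{actin_uM}, \code{rate_s} and
#'   logical \code{basal_subtracted} (absent columns are added).
#' @param basal_rate Basal ATPase rate (1/s) to subtract from every point.
#' @return The points with \code{rate_s} reduced by \code{basal_rate} and the
#'   flag set. Negative results are kept (never clipped).
#' @export
subtract_basal <- function(points, basal_rate) {
  stopifnot(is.data.frame(points), is.numeric(basal_rate))
  if (is.null(points$basal_subtracted)) points$basal_subtracted <- FALSE
  if (any(points$basal_subtracted))
    stop("basal rate already subtracted from these points")
  points$rate_s <- points$rate_s - basal_rate
  points$basal_subtracted <- TRUE
  points
}

#' Fit the Michaelis-Menten law to activity points
#'
#' Nonlinear least squares of \code{rate = kcat*[actin]/(Km+[actin])} with
#' 95 percent confidence intervals from the parameter covariance. Fits whose
#' relative CI half-width on kcat or Km exceeds \code{max_rel_ci}, or whose
#' Km exceeds \code{km_factor} times the largest tested actin concentration,
#' are flagged rejected (ambiguous) rather than silently reported.
#'
#' @param points Data.frame with \code{actin_uM} and \code{rate_s}; at least
#'   4 distinct actin concentrations.
#' @param max_rel_ci Ambiguity bound on relative CI half-width (default 1).
#' @param km_factor Ambiguity bound on Km as a multiple of max actin.
#' @return A list of class \code{mm_fit}: \code{kcat}, \code{kcat_ci},
#'   \code{Km}, \code{Km_ci}, \code{kcat_se}, \code{Km_se}, \code{t_cycle},
#'   \code{efficiency}, \code{rejected}, \code{reason}, \code{points}.
#' @export
fit_michaelis_menten <- function(points, max_rel_ci = 1, km_factor = 10) {
  stopifnot(is.data.frame(points))
  a <- points$actin_uM; v <- points$rate_s
  if (length(unique(a)) < 4)
    stop("need at least 4 distinct actin concentrations")
  start <- list(kcat = max(v) * 1.2,
                Km = max(stats::median(a), 1e-3))
  fit <- try(minpack.lm::nlsLM(v ~ kcat * a / (Km + a), start = start,
                               lower = c(1e-9, 1e-9),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(kcat = NA_real_, Km = NA_real_, rejected = TRUE,
                          reason = "non-convergence", points = points),
                     class = "mm_fit"))
  co <- summary(fit)$coefficients
  kcat <- co["kcat", "Estimate"]; Km <- co["Km", "Estimate"]
  kse <- co["kcat", "Std. Error"]; mse <- co["Km", "Std. Error"]
  z <- stats::qt(0.975, df = max(length(v) - 2, 1))
  rejected <- FALSE; reason <- NA_character_
  if (z * kse / kcat > max_rel_ci || z * mse / Km > max_rel_ci) {
    rejected <- TRUE; reason <- "ambiguous: CI half-width exceeds 100% of estimate"
  } else if (Km > km_factor * max(a)) {
    rejected <- TRUE
    reason <- sprintf("ambiguous: Km beyond %gx the largest tested [actin]", km_factor)
  }
  structure(list(kcat = kcat, kcat_ci = kcat + c(-1, 1) * z * kse,
                 Km = Km, Km_ci = Km + c(-1, 1) * z * mse,
                 kcat_se = kse, Km_se = mse,
                 t_cycle = 1 / kcat, efficiency = kcat / Km,
                 rejected = rejected, reason = reason, points = points),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit\n")
  if (is.na(x$kcat)) { cat("  rejected:", x$reason, "\n"); return(invisible(x)) }
  cat(sprintf("  kcat = %.3g 1/s  [%.3g, %.3g]\n", x$kcat, x$kcat_ci[1], x$kcat_ci[2]))
  cat(sprintf("  Km   = %.3g uM   [%.3g, %.3g]\n", x$Km, x$Km_ci[1], x$Km_ci[2]))
  cat(sprintf("  t_cycle = %.3g s, efficiency = %.3g 1/(s uM)\n",
              x$t_cycle, x$efficiency))
  if (x$rejected) cat("  REJECTED:", x$reason, "\n")
  invisible(x)
}

#' Analyze a full ATPase plate
#'
#' Convenience pipeline: fits the standards block, extracts per-well rates,
#' subtracts the basal (actin-free) well's rate from each activity point, and
#' fits the Michaelis-Menten law.
#'
#' @param plate An \code{\link{make_atpase_plate}} object or an equivalent
#'   list with \code{time}, \code{absorbance}, \code{well_map},
#'   \code{myosin_conc}, \code{well_volume_uL}.
#' @param ... Passed to \code{\link{fit_michaelis_menten}}.
#' @return List: \code{standard}, \code{points} (basal-subtracted activity
#'   points), \code{basal_rate}, \code{fit} (an \code{mm_fit}),
#'   \code{rejected_wells}.
#' @export
analyze_atpase_plate <- function(plate, ...) {
  wm <- plate$well_map
  std <- wm$role == "standard"
  std_abs <- colMeans(plate$absorbance[, wm$well[std], drop = FALSE])
  standard <- fit_nadh_standard(wm$nadh_mM[std], std_abs,
                                well_volume_uL = plate$well_volume_uL)
  act_wells <- wm$well[wm$role %in% c("activity", "basal")]
  rates <- lapply(act_wells, function(w)
    extract_rate(plate$time, plate$absorbance[, w], standard,
                 plate$myosin_conc, plate$well_volume_uL))
  names(rates) <- act_wells
  ok <- !vapply(rates, `[[`, TRUE, "rejected")
  basal_w <- wm$well[wm$role == "basal"]
  basal_rate <- if (length(basal_w) && ok[basal_w])
    rates[[basal_w]]$rate_s else 0
  act <- wm$role == "activity" & wm$well %in% names(ok)[ok]
  points <- data.frame(actin_uM = wm$actin_uM[act],
                       rate_s = vapply(rates[wm$well[act]], `[[`, 0, "rate_s"),
                       basal_subtracted = FALSE,
                       row.names = NULL)
  points <- subtract_basal(points, basal_rate)
  list(standard = standard, points = points, basal_rate = basal_rate,
       fit = fit_michaelis_menten(points, ...),
       rejected_wells = names(ok)[!ok])
}

#' Derived cycle metrics and pairwise construct comparisons
#'
#' Computes the total cycle time \code{t_cycle = 1/kcat}, catalytic
#' efficiency \code{kcat/Km}, and pairwise percent differences between
#' constructs (with the larger value as reference:
#' \code{100*(A - B)/A}) for both kcat and Km.
#'
#' @param fits A data.frame with columns \code{construct}, \code{kcat},
#'   \code{Km}, or a named list of \code{mm_fit} objects.
#' @return List with \code{metrics} (construct, kcat, Km, t_cycle,
#'   efficiency) and \code{pairwise} (reference, other, pct_kcat_decrease,
#'   pct_Km_decrease, kcat_ratio).
#' @export
derive_cycle_metrics <- function(fits) {
  if (!is.data.frame(fits)) {
    fits <- data.frame(
      construct = names(fits),
      kcat = vapply(fits, `[[`, 0, "kcat"),
      Km = vapply(fits, `[[`, 0, "Km"), row.names = NULL)
  }
  if (any(fits$kcat <= 0)) stop("kcat must be positive")
  metrics <- data.frame(construct = fits$construct, kcat = fits$kcat,
                        Km = fits$Km, t_cycle = 1 / fits$kcat,
                        efficiency = fits$kcat / fits$Km)
  pairs <- utils::combn(seq_len(nrow(fits)), 2)
  pct_drop <- function(x, i, j) {        # larger value as reference
    a <- max(x[i], x[j]); b <- min(x[i], x[j])
    100 * (a - b) / a
  }
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (fits$kcat[j] > fits$kcat[i]) { tmp <- i; i <- j; j <- tmp }
    data.frame(reference = fits$construct[i], other = fits$construct[j],
               pct_kcat_decrease = pct_drop(fits$kcat, i, j),
               pct_Km_decrease = pct_drop(fits$Km, i, j),
               kcat_ratio = fits$kcat[i] / fits$kcat[j])
  }))
  list(metrics = metrics, pairwise = pairwise)
}
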