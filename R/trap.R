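#' Calibrate trap stiffness from the power spectrum
#'
#' Fits the exact sampled-Lorentzian (AR(1)) spectrum
#' \code{S(f) = C / (1 - 2 a cos(2 pi f / fs) + a^2)} to the log-binned
#' one-sided periodogram of an event-free bead-position recording; this is
#' the alias-free discrete-time form of the Lorentzian, so the corner
#' frequency \code{fc = -log(a) fs / (2 pi)} is unbiased even when it is a
#' sizable fraction of the Nyquist frequency. The bead positional variance is
#' the analytic integral \code{C fs / (2 (1 - a^2))} and the stiffness
#' follows from equipartition, \code{kappa = kBT / variance}.
#'
#' @param recording A \code{trap_recording} or a numeric position vector (nm).
#' @param sample_rate Sampling rate (Hz); taken from the recording if absent.
#' @param f_max Upper fit frequency (Hz); default a quarter of the sampling
#'   rate to stay clear of aliasing roll-off.
#' @param n_bins Log-spaced frequency bins (default 60).
#' @param temperature_C Bath temperature for kBT (default 25).
#' @return A list of class \code{stiffness_fit}: \code{stiffness} (pN/nm),
#'   \code{corner_freq} (Hz) with \code{corner_freq_se}, \code{variance_nm2},
#'   \code{S0}, \code{unidentifiable} (TRUE when the spectrum is white over
#'   the fit band), \code{poor_fit}.
#' @export
calibrate_stiffness <- function(recording, sample_rate = NULL, f_max = NULL,
                                n_bins = 60, temperature_C = 25) {
  if (inherits(recording, "trap_recording")) {
    x <- recording$position
    if (is.null(sample_rate)) sample_rate <- recording$sample_rate
  } else x <- as.numeric(recording)
  stopifnot(!is.null(sample_rate))
  n <- length(x)
  if (n / sample_rate < 5) stop("need at least 5 s of event-free data")
  if (is.null(f_max)) f_max <- sample_rate / 4

  X <- stats::fft(x - mean(x))
  half <- 2:floor(n / 2)
  psd <- (2 / (sample_rate * n)) * Mod(X[half])^2   # one-sided, nm^2/Hz
  freq <- (half - 1) * sample_rate / n
  keep <- freq <= f_max
  psd <- psd[keep]; freq <- freq[keep]

  # log-spaced binning tames the exponential periodogram scatter; fit the
  # bin means in log space, weighted by the number of raw points per bin
  edges <- exp(seq(log(freq[1]), log(max(freq)), length.out = n_bins + 1))
  bin <- findInterval(freq, edges, rightmost.closed = TRUE)
  fb <- as.numeric(tapply(freq, bin, mean))
  pb <- as.numeric(tapply(psd, bin, mean))
  wb <- as.numeric(tapply(freq, bin, length))
  lp <- log(pb)
  omega <- 2 * pi * fb / sample_rate

  S0_0 <- mean(pb[fb < stats::quantile(fb, 0.1)])
  fc_0 <- fb[which.min(abs(pb - S0_0 / 2))]
  a0 <- min(exp(-2 * pi * fc_0 / sample_rate), 0.99)
  fit <- try(minpack.lm::nlsLM(
    lp ~ lC - log(1 - 2 * a * cos(omega) + a^2),
    start = list(lC = log(S0_0 * (1 - a0)^2), a = a0),
    lower = c(-Inf, 1e-6), upper = c(Inf, 1 - 1e-9), weights = wb,
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(stiffness = NA_real_, corner_freq = NA_real_,
                          unidentifiable = TRUE, poor_fit = TRUE),
                     class = "stiffness_fit"))
  co <- summary(fit)$coefficients
  a <- co["a", "Estimate"]; a_se <- co["a", "Std. Error"]
  C <- exp(co["lC", "Estimate"])
  fc <- -log(a) * sample_rate / (2 * pi)
  fc_se <- a_se / a * sample_rate / (2 * pi)   # delta method
  unident <- fc > 0.9 * f_max || fc_se > fc
  variance <- C * sample_rate / (2 * (1 - a^2))
  kBT <- 1.380649e-2 * (273.15 + temperature_C)  # pN nm
  r2 <- 1 - sum(stats::resid(fit)^2 * wb) / sum((lp - mean(lp))^2 * wb)
  structure(list(stiffness = kBT / variance, corner_freq = fc,
                 corner_freq_se = fc_se, variance_nm2 = variance,
                 S0 = C / (1 - a)^2, unidentifiable = unident,
                 poor_fit = r2 < 0.8, r_squared = r2),
            class = "stiffness_fit")
}

# centered running variance over a w-sample window via cumulative sums
running_variance <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  i0 <- pmax(0L, seq_len(n) - (w %/% 2) - 1L)
  i1 <- pmin(n, seq_len(n) + (w - w %/% 2) - 1L)
  m <- i1 - i0
  s <- cs[i1 + 1L] - cs[i0 + 1L]
  s2 <- cs2[i1 + 1L] - cs2[i0 + 1L]
  (s2 - s^2 / m) / (m - 1)
}

# last-observation-carried-forward over a 0/1/2 zone code (0 = hold)
locf_zone <- function(z) {
  idx <- seq_along(z)
  idx[z == 0] <- 0L
  idx <- cummax(idx)
  out <- rep(2L, length(z))          # before any crossing: free
  out[idx > 0] <- z[idx[idx > 0]]
  out
}

#' Detect actomyosin binding events by variance and mean shift
#'
#' Binding of myosin to the trapped dumbbell reduces the positional variance
#' of the bead and shifts its mean. Detection runs a windowed variance with
#' hysteresis: a bound state is entered when the running variance falls below
#' \code{theta_enter} times the free-baseline variance and left when it rises
#' above \code{theta_exit} times it. Events shorter than the dead time (one
#' analysis window) are discarded. Two displacements are reported per event,
#' both relative to the flanking baseline mean: \code{step_nm}, the total
#' step measured over the terminal part of the bound segment where the
#' working stroke has completed, and \code{mean_shift_nm}, the mean shift of
#' the whole bound segment.
#'
#' @param recording A \code{trap_recording} or numeric position vector (nm).
#' @param sample_rate Sampling rate (Hz) when a bare vector is given.
#' @param window_s Variance window (s; default 0.005), also the dead time.
#' @param theta_enter,theta_exit Hysteresis thresholds as fractions of the
#'   free variance (defaults 0.5 and 0.75).
#' @param free_variance Free-baseline variance (nm^2); estimated as the
#'   median running variance when NULL.
#' @return A data.frame of class \code{binding_events} with columns
#'   \code{start_s}, \code{end_s}, \code{duration_s}, \code{step_nm},
#'   \code{mean_shift_nm}, \code{variance_ratio}; attributes \code{deadtime_s},
#'   \code{free_variance}, \code{sample_rate}.
#' @export
detect_events <- function(recording, sample_rate = NULL, window_s = 0.005,
                          theta_enter = 0.5, theta_exit = 0.75,
                          free_variance = NULL) {
  if (inherits(recording, "trap_recording")) {
    x <- recording$position
    if (is.null(sample_rate)) sample_rate <- recording$sample_rate
  } else x <- as.numeric(recording)
  stopifnot(!is.null(sample_rate), theta_enter < theta_exit)
  fs <- sample_rate
  w <- max(8L, as.integer(round(window_s * fs)))
  v <- running_variance(x, w)
  if (is.null(free_variance)) free_variance <- stats::median(v)
  if (!is.finite(free_variance) || free_variance <= 0)
    stop("free baseline variance not estimable from this trace")

  z <- integer(length(v))                    # 1 = below enter, 2 = above exit
  z[v < theta_enter * free_variance] <- 1L
  z[v > theta_exit * free_variance] <- 2L
  bound <- locf_zone(z) == 1L

  r <- rle(bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= w
  starts <- starts[keep]; ends <- ends[keep]

  # refine each edge by a two-segment Gaussian changepoint (mean AND
  # variance) within one window of the hysteresis crossing; the variance drop
  # is unique to the binding transition, so the substep (a mean-only change)
  # cannot capture the edge, and zero-step events still refine correctly
  refine_edge <- function(i) {
    lo <- max(1L, i - w); hi <- min(length(x), i + w)
    seg <- x[lo:hi]; m <- length(seg)
    if (m < 8) return(i)
    cs <- cumsum(seg); cs2 <- cumsum(seg^2)
    k <- 4:(m - 4)
    v1 <- pmax((cs2[k] - cs[k]^2 / k) / k, 1e-12)
    v2 <- pmax(((cs2[m] - cs2[k]) - (cs[m] - cs[k])^2 / (m - k)) / (m - k),
               1e-12)
    cost <- k * log(v1) + (m - k) * log(v2)
    cost0 <- m * log(max((cs2[m] - cs[m]^2 / m) / m, 1e-12))
    if (min(cost) > cost0 - 2) return(i)   # no credible changepoint
    lo + k[which.min(cost)] - 1L
  }
  if (length(starts)) {
    # two passes: the second pass re-centers the window on the first pass's
    # estimate, which rescues edges that sit near the first window's border.
    # The changepoint split index is the last sample of the first segment:
    # for a start edge that is the final free sample, so the event begins
    # one sample later; for an end edge it is the final bound sample.
    starts <- vapply(starts, function(i) refine_edge(refine_edge(i)), 1L) + 1L
    ends <- pmax(vapply(ends, function(i) refine_edge(refine_edge(i)), 1L),
                 starts + 1L)
  }

  half <- w %/% 2
  ev <- lapply(seq_along(starts), function(i) {
    i0 <- starts[i]; i1 <- ends[i]
    c0 <- min(i0 + half, i1); c1 <- max(i1 - half, i0)
    core <- x[c0:c1]                                    # clear of edge smear
    pre <- x[max(1L, i0 - 3L * w):max(1L, i0 - w)]
    post <- x[min(length(x), i1 + w):min(length(x), i1 + 3L * w)]
    base <- mean(c(pre, post))
    # total step: bound level once the working stroke has completed,
    # measured over the terminal part of the event
    t1 <- max(c0, c1 - 2L * w)
    data.frame(start_s = (i0 - 1) / fs, end_s = i1 / fs,
               duration_s = (i1 - i0 + 1) / fs,
               step_nm = mean(x[t1:c1]) - base,
               mean_shift_nm = mean(core) - base,
               variance_ratio = stats::var(core) / free_variance)
  })
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0), step_nm = numeric(0),
               mean_shift_nm = numeric(0), variance_ratio = numeric(0))
  structure(out, class = c("binding_events", "data.frame"),
            deadtime_s = w / fs, free_variance = free_variance,
            sample_rate = fs)
}

#' Summarize working-stroke step sizes
#'
#' @param events A \code{binding_events} data.frame (or any data.frame with a
#'   \code{step_nm} column).
#' @param orient Sign-orient the steps so the mean is positive before
#'   summarizing (actin polarity is arbitrary between assemblies).
#' @return A list of class \code{step_summary}: \code{mean_nm},
#'   \code{sem_nm}, \code{sd_nm}, \code{n}, \code{ecdf} (function).
#' @export
summarize_steps <- function(events, orient = TRUE) {
  s <- events$step_nm
  if (length(s) < 10)
    warning("fewer than 10 events: step statistics have wide uncertainty")
  if (orient && length(s) > 0 && mean(s) < 0) s <- -s
  structure(list(mean_nm = mean(s), sem_nm = stats::sd(s) / sqrt(length(s)),
                 sd_nm = stats::sd(s), n = length(s),
                 ecdf = stats::ecdf(s)),
            class = "step_summary")
}

#' Maximum-likelihood detachment rate from event durations
#'
#' For durations left-truncated at the detector dead time the exponential
#' likelihood is \code{prod(k * exp(-k (t_i - deadtime)))}, maximized at
#' \code{k = 1/(mean(t) - deadtime)}. The 95 percent confidence interval is a
#' nonparametric bootstrap over events.
#'
#' @param durations Event durations (s), all at least \code{deadtime}.
#' @param deadtime Detector dead time (s).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @return A list of class \code{detachment_fit}: \code{rate} (1/s),
#'   \code{ci} (bootstrap percentile interval), \code{n_events},
#'   \code{deadtime}.
#' @export
fit_detachment_rate <- function(durations, deadtime = 0, n_boot = 1000,
                                conf = 0.95) {
  durations <- as.numeric(durations)
  if (length(durations) < 10) stop("need at least 10 event durations")
  if (any(durations < deadtime))
    stop("all durations must be >= the dead time")
  mle <- function(d) 1 / (mean(d) - deadtime)
  rate <- mle(durations)
  boot <- vapply(seq_len(n_boot), function(b)
    mle(sample(durations, replace = TRUE)), 0)
  a <- (1 - conf) / 2
  structure(list(rate = rate,
                 ci = unname(stats::quantile(boot, c(a, 1 - a))),
                 n_events = length(durations), deadtime = deadtime,
                 conf = conf),
            class = "detachment_fit")
}

#' Time-forward and time-reversed ensemble averages of binding events
#'
#' Aligns events at attachment (time-forward) and at detachment
#' (time-reversed) and averages the bead position across events. Events
#' shorter than the averaging span (default the median duration) are extended
#' by holding the bound-level mean adjacent to the far edge. The bound level
#' at each alignment instant is measured by fitting a single exponential to
#' the ensemble trace, excluding a guard band next to the alignment point
#' (changepoint selection bias inflates the first fraction of a millisecond
#' of the forward edge; detection jitter lets free samples leak into the
#' reversed edge), and extrapolating back to the alignment instant. The
#' second substep is the displacement difference between the
#' reversed-average level at detachment and the forward-average level at
#' attachment (\code{d2 = level_rev - level_fwd}); \code{d_total =
#' level_rev} and \code{d1 = d_total - d2}. The reported noise floor
#' \code{d2_se} is a 10-block jackknife over events, which captures the
#' event-to-event variability that the ensemble-fit covariance misses.
#'
#' @param recording A \code{trap_recording} or numeric position vector (nm).
#' @param events A \code{binding_events} data.frame (detected or ground
#'   truth with \code{start_s}/\code{end_s}).
#' @param sample_rate Sampling rate (Hz) when a bare vector is given.
#' @param span_s Averaging span (s); default the median event duration.
#' @param baseline_s Pre/post baseline window included around the alignment
#'   points (default 0.02 s).
#' @param edge_guard_s Guard excluded from the reversed-edge level fit
#'   (default 0.005 s, the detector dead time).
#' @param fwd_guard_s Guard excluded from the forward-edge level fit
#'   (default 0.001 s).
#' @param min_events Minimum events required (default 50).
#' @return A list of class \code{ensemble_average}: \code{forward} and
#'   \code{reversed} (data.frames time_s/position_nm), \code{d_total},
#'   \code{d1}, \code{d2}, \code{d2_se} (noise floor), \code{two_substep},
#'   \code{n_events}, \code{span_s}.
#' @export
ensemble_average <- function(recording, events, sample_rate = NULL,
                             span_s = NULL, baseline_s = 0.02,
                             edge_guard_s = 0.005, fwd_guard_s = 0.001,
                             min_events = 50) {
  if (inherits(recording, "trap_recording")) {
    x <- recording$position
    if (is.null(sample_rate)) sample_rate <- recording$sample_rate
  } else x <- as.numeric(recording)
  stopifnot(!is.null(sample_rate))
  fs <- sample_rate
  ne <- nrow(events)
  if (ne < min_events)
    stop("need at least ", min_events, " events for a stable ensemble average")
  if (is.null(span_s)) span_s <- stats::median(events$duration_s)
  ns <- as.integer(round(span_s * fs))
  nb <- as.integer(round(baseline_s * fs))
  nl <- max(2L, as.integer(round(edge_guard_s * fs)))
  n <- length(x)

  fwd <- matrix(NA_real_, ne, nb + ns)
  rev <- matrix(NA_real_, ne, ns + nb)
  base_ev <- lvl_f <- lvl_r <- numeric(ne)
  for (i in seq_len(ne)) {
    i0 <- as.integer(round(events$start_s[i] * fs)) + 1L
    i1 <- as.integer(round(events$end_s[i] * fs))
    if (i1 <= i0) { base_ev[i] <- NA; next }
    len <- i1 - i0 + 1L
    hold_end <- mean(x[max(i0, i1 - nl + 1L):i1])    # terminal bound level
    hold_start <- mean(x[i0:min(i1, i0 + nl - 1L)])  # initial bound level
    # forward: baseline_s before attachment, span after; extend with hold_end
    pre_idx <- (i0 - nb):(i0 - 1L)
    seg <- x[i0:min(i1, i0 + ns - 1L)]
    if (length(seg) < ns) seg <- c(seg, rep(hold_end, ns - length(seg)))
    fwd[i, ] <- c(ifelse(pre_idx >= 1, x[pmax(pre_idx, 1L)], NA), seg)
    # reversed: span before detachment, baseline_s after; extend with hold_start
    segr <- x[max(i0, i1 - ns + 1L):i1]
    if (length(segr) < ns) segr <- c(rep(hold_start, ns - length(segr)), segr)
    post_idx <- (i1 + 1L):(i1 + nb)
    rev[i, ] <- c(segr, ifelse(post_idx <= n, x[pmin(post_idx, n)], NA))
    base_ev[i] <- mean(x[pmax(pre_idx, 1L)])
    lvl_f[i] <- hold_start
    lvl_r[i] <- hold_end
  }
  ok <- is.finite(base_ev)
  fwd <- fwd[ok, , drop = FALSE]; rev <- rev[ok, , drop = FALSE]
  base <- mean(base_ev[ok])
  mf <- colMeans(fwd, na.rm = TRUE) - base
  mr <- colMeans(rev, na.rm = TRUE) - base

  # bound level at each alignment instant: exponential extrapolation to the
  # edge, excluding a guard band next to the alignment point (see above)
  extrap_level <- function(y, tt, guard) {
    use <- tt >= guard
    early <- use & tt <= guard + max(3 * edge_guard_s, 0.003)
    fallback <- list(level = mean(y[early]),
                     se = stats::sd(y[use]) / sqrt(sum(use)))
    yy <- y[use]; ttu <- tt[use] - guard
    A0 <- mean(yy[ttu > max(ttu) * 0.7])
    B0 <- A0 - yy[1]
    fit <- try(minpack.lm::nlsLM(yy ~ A - B * exp(-lam * ttu),
                                 start = list(A = A0, B = B0,
                                              lam = 3 / max(ttu)),
                                 control = minpack.lm::nls.lm.control(maxiter = 200)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(fallback)
    co <- stats::coef(fit); V <- stats::vcov(fit)
    # extrapolate to the alignment instant, guard earlier than the fit start
    if (unname(co["lam"]) * guard > 1) return(fallback)  # unsafe extrapolation
    eg <- exp(unname(co["lam"]) * guard)
    level <- unname(co["A"] - co["B"] * eg)
    se <- sqrt(V["A", "A"] + eg^2 * V["B", "B"] - 2 * eg * V["A", "B"])
    if (!is.finite(level) || !is.finite(se)) return(fallback)
    list(level = level, se = se)
  }
  t_f <- (seq_len(ns) - 1) / fs                    # time from the alignment edge
  d2_of <- function(mf_, mr_) {
    lf <- extrap_level(mf_[nb + seq_len(ns)], t_f, fwd_guard_s)
    lr <- extrap_level(mr_[seq_len(ns)][ns:1], t_f, edge_guard_s)
    c(fwd = lf$level, rev = lr$level)
  }
  lv <- d2_of(mf, mr)
  level_fwd <- lv["fwd"]; level_rev <- lv["rev"]
  d_total <- unname(level_rev)
  d2 <- unname(level_rev - level_fwd)
  d1 <- d_total - d2

  # noise floor by 10-block jackknife over events
  J <- min(10L, sum(ok))
  blk <- rep(seq_len(J), length.out = sum(ok))
  d2_jk <- vapply(seq_len(J), function(j) {
    keep <- blk != j
    mfj <- colMeans(fwd[keep, , drop = FALSE], na.rm = TRUE) - base
    mrj <- colMeans(rev[keep, , drop = FALSE], na.rm = TRUE) - base
    v <- d2_of(mfj, mrj)
    unname(v["rev"] - v["fwd"])
  }, 0)
  d2_se <- sqrt((J - 1) / J * sum((d2_jk - mean(d2_jk))^2))
  structure(list(
    forward = data.frame(time_s = (seq_len(nb + ns) - nb - 1) / fs,
                         position_nm = mf),
    reversed = data.frame(time_s = (seq_len(ns + nb) - ns) / fs,
                          position_nm = mr),
    d_total = d_total, d1 = d1, d2 = d2, d2_se = d2_se,
    two_substep = d2 > 2 * d2_se, n_events = sum(ok), span_s = span_s),
    class = "ensemble_average")
}

#' Detachment rate from detected events with sharp censoring
#'
#' Event detection is soft near the detector dead time: events only slightly
#' longer than one analysis window are found with reduced probability, which
#' would bias a truncated-exponential fit anchored at the window length.
#' This wrapper censors the detected durations at \code{censor_factor} times
#' the detector dead time (where recall is essentially complete and the
#' estimate is robust to the analysis sampling rate) and fits the
#' truncated-exponential MLE there.
#'
#' @param events A \code{\link{detect_events}} result.
#' @param censor_factor Censoring point as a multiple of the dead time
#'   (default 3).
#' @param ... Passed to \code{\link{fit_detachment_rate}}.
#' @return A \code{detachment_fit}.
#' @export
fit_detachment_from_events <- function(events, censor_factor = 3, ...) {
  dt <- attr(events, "deadtime_s") * censor_factor
  d <- events$duration_s[events$duration_s >= dt]
  fit_detachment_rate(d, deadtime = dt, ...)
}
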