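kBT_pN_nm <- 4.11  # thermal energy at 25 C, pN nm

#' Configuration for the optical-trap trace simulator
#'
#' @param sample_rate Sampling rate (Hz; default 20000).
#' @param filter_cutoff Anti-alias filter cutoff (Hz; default 10000); must
#'   satisfy \code{sample_rate >= 2 * filter_cutoff}.
#' @param stiffness Trap stiffness (pN/nm; default 0.04).
#' @param corner_freq Corner frequency of the bead's Lorentzian spectrum
#'   (Hz; default 2500, typical of a two-trap dumbbell with ~0.5 um beads).
#' @param free_variance Bead positional variance while detached (nm^2);
#'   default the equipartition value \code{kBT/stiffness}.
#' @param bound_variance Variance while myosin is bound (nm^2); must be less
#'   than \code{free_variance}. Default \code{free_variance/4}.
#' @param event_rate Poisson rate of attachment starts (1/s).
#' @param atp ATP concentration (uM).
#' @param K1k2 Second-order ATP-binding rate (1/(uM s)) used to derive the
#'   detachment rate at subsaturating ATP when \code{detach_rate} is NULL.
#' @param detach_rate Detachment rate (1/s); overrides \code{K1k2 * atp}.
#' @param d1,d2 Working-stroke substep displacements (nm).
#' @param substep_delay_rate Rate (1/s) of the exponential delay between
#'   attachment (first substep) and the second substep.
#' @return A validated list of class \code{trap_sim_config}.
#' @export
trap_sim_config <- function(sample_rate = 20000, filter_cutoff = 10000,
                            stiffness = 0.04, corner_freq = 2500,
                            free_variance = NULL, bound_variance = NULL,
                            event_rate = 0.5, atp = 1,
                            K1k2 = 6.7, detach_rate = NULL,
                            d1 = 4, d2 = 2, substep_delay_rate = 50) {
  if (is.null(free_variance)) free_variance <- kBT_pN_nm / stiffness
  if (is.null(bound_variance)) bound_variance <- free_variance / 4
  if (is.null(detach_rate)) detach_rate <- K1k2 * atp
  if (bound_variance >= free_variance)
    stop("bound_variance must be < free_variance")
  if (sample_rate < 2 * filter_cutoff)
    stop("sample_rate must be >= 2 * filter_cutoff (Nyquist)")
  stopifnot(stiffness > 0, corner_freq > 0, event_rate >= 0, detach_rate > 0,
            substep_delay_rate > 0)
  structure(list(sample_rate = sample_rate, filter_cutoff = filter_cutoff,
                 stiffness = stiffness, corner_freq = corner_freq,
                 free_variance = free_variance, bound_variance = bound_variance,
                 event_rate = event_rate, atp = atp, K1k2 = K1k2,
                 detach_rate = detach_rate, d1 = d1, d2 = d2,
                 substep_delay_rate = substep_delay_rate),
            class = "trap_sim_config")
}

#' Simulate a three-bead optical-trap bead-position recording
#'
#' The detached baseline is an Ornstein-Uhlenbeck process with the configured
#' variance and corner frequency (Lorentzian spectrum). During binding events
#' the positional variance drops to \code{bound_variance} and the mean shifts
#' by \code{d1} at attachment and by a further \code{d2} after an exponential
#' delay. Event starts are Poisson; attachment durations are exponential with
#' the configured detachment rate.
#'
#' @param cfg A \code{\link{trap_sim_config}}.
#' @param duration_s Recording length (s).
#' @param seed Integer seed.
#' @return A list of class \code{trap_recording}: \code{position} (nm, one
#'   sample per tick), \code{sample_rate}, \code{stiffness}, \code{cfg}, and
#'   \code{events} (ground-truth data.frame: start_s, end_s, duration_s,
#'   substep_delay_s, step1_nm, step2_nm). A recording long enough for zero
#'   events returns an empty ground-truth table with a warning.
#' @export
make_trap_trace <- function(cfg, duration_s, seed) {
  stopifnot(inherits(cfg, "trap_sim_config"), duration_s > 0)
  set.seed(as.integer(seed))
  fs <- cfg$sample_rate
  n <- as.integer(round(duration_s * fs))

  # exact OU discretization: x[k+1] = a x[k] + sd_innov * N(0,1)
  theta <- 2 * pi * cfg$corner_freq
  a <- exp(-theta / fs)
  innov_sd <- sqrt(cfg$free_variance * (1 - a^2))
  x <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), a,
                                method = "recursive",
                                init = stats::rnorm(1, 0, sqrt(cfg$free_variance))))

  # Poisson event schedule (no overlap: next gap starts after the event ends)
  starts <- ends <- delays <- numeric(0)
  t <- 0
  if (cfg$event_rate > 0) {
    repeat {
      t0 <- t + stats::rexp(1, cfg$event_rate)
      if (t0 >= duration_s) break
      dur <- stats::rexp(1, cfg$detach_rate)
      t1 <- min(t0 + dur, duration_s)
      starts <- c(starts, t0); ends <- c(ends, t1)
      delays <- c(delays, stats::rexp(1, cfg$substep_delay_rate))
      t <- t1
    }
  }
  if (length(starts) == 0 && cfg$event_rate > 0)
    warning("recording too short to hold an event at the configured rates")

  ratio <- sqrt(cfg$bound_variance / cfg$free_variance)
  for (i in seq_along(starts)) {
    i0 <- max(1L, as.integer(floor(starts[i] * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(ends[i] * fs)))
    if (i1 < i0) next
    idx <- i0:i1
    x[idx] <- x[idx] * ratio + cfg$d1
    isub <- as.integer(floor((starts[i] + delays[i]) * fs)) + 1L
    if (isub <= i1) x[isub:i1] <- x[isub:i1] + cfg$d2
  }

  events <- data.frame(
    start_s = starts, end_s = ends, duration_s = ends - starts,
    substep_delay_s = delays,
    step1_nm = rep(cfg$d1, length(starts)),
    step2_nm = ifelse(delays < (ends - starts), cfg$d2, 0)
  )
  structure(list(position = x, sample_rate = fs, stiffness = cfg$stiffness,
                 cfg = cfg, events = events, seed = seed),
            class = "trap_recording")
}
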