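#' Predicted unloaded sliding velocity from step size and attached time
#'
#' In the detachment-limited model of unloaded filament sliding the velocity
#' is set by the working-stroke displacement d and the actin-attached time
#' t_on at saturating ATP: \code{v = d / t_on}. Used as a cross-assay
#' consistency diagnostic between the trap and motility modules.
#'
#' @param d_total Working-stroke displacement (nm), > 0.
#' @param t_on Attached duration (s), > 0.
#' @return Velocity in um/s.
#' @export
predict_unloaded_velocity <- function(d_total, t_on) {
  if (any(d_total <= 0) || any(t_on <= 0))
    stop("d_total and t_on must be positive")
  (d_total * 1e-3) / t_on
}

#' Cross-construct report of derived cycle metrics
#'
#' From per-construct steady-state and transient-kinetic parameters (fitted
#' by this package or published values, e.g.
#' \code{\link{myh7b_reference_params}}) computes every derived quantity of
#' the cycle comparison: total cycle times, pairwise percent decreases in
#' kcat and Km, catalytic efficiencies, and the cross-construct ratios of the
#' maximal dissociation rate k_plus2 and the ATP affinity 1/K1.
#'
#' @param params Data.frame with columns \code{construct}, \code{kcat},
#'   \code{Km} and optionally \code{k_plus2}, \code{invK1}.
#' @return A list of class \code{construct_report}: \code{metrics},
#'   \code{pairwise} (from \code{\link{derive_cycle_metrics}}),
#'   \code{k_plus2_ratio} and \code{invK1_ratio} (pairwise ratio tables,
#'   larger value over smaller), \code{params}.
#' @export
construct_report <- function(params) {
  stopifnot(all(c("construct", "kcat", "Km") %in% names(params)))
  cm <- derive_cycle_metrics(params[, c("construct", "kcat", "Km")])
  ratio_table <- function(field) {
    if (!field %in% names(params) || all(is.na(params[[field]]))) return(NULL)
    p <- params[!is.na(params[[field]]), ]
    if (nrow(p) < 2) return(NULL)
    pairs <- utils::combn(seq_len(nrow(p)), 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      hi <- if (p[[field]][i] >= p[[field]][j]) i else j
      lo <- if (hi == i) j else i
      data.frame(larger = p$construct[hi], smaller = p$construct[lo],
                 ratio = p[[field]][hi] / p[[field]][lo])
    }))
  }
  structure(list(metrics = cm$metrics, pairwise = cm$pairwise,
                 k_plus2_ratio = ratio_table("k_plus2"),
                 invK1_ratio = ratio_table("invK1"),
                 params = params),
            class = "construct_report")
}

#' @export
print.construct_report <- function(x, ...) {
  cat("Construct report: derived cycle metrics\n")
  print(x$metrics, row.names = FALSE)
  cat("\nPairwise comparisons (larger kcat as reference)\n")
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$k_plus2_ratio)) {
    cat("\nk_plus2 ratios\n"); print(x$k_plus2_ratio, row.names = FALSE)
  }
  if (!is.null(x$invK1_ratio)) {
    cat("\nATP affinity (1/K1) ratios\n"); print(x$invK1_ratio, row.names = FALSE)
  }
  invisible(x)
}

#' Simulate-then-analyze round trip for one assay
#'
#' Generates a synthetic dataset for the requested assay from known
#' ground-truth parameters, runs the corresponding analysis pipeline, and
#' returns both the estimates and the truth for recovery checks. Every
#' stochastic element derives from \code{seed}.
#'
#' @param assay One of \code{"atpase"}, \code{"stopflow_atp"},
#'   \code{"stopflow_adp"}, \code{"turnover"}, \code{"trap"},
#'   \code{"motility"}, \code{"msm"}.
#' @param seed Integer seed.
#' @param ... Overrides of the assay's generator parameters (see the
#'   corresponding \code{make_*} function).
#' @return A list: \code{truth} (generator parameters), \code{estimate}
#'   (analysis result), \code{assay}, \code{seed}.
#' @export
run_roundtrip <- function(assay = c("atpase", "stopflow_atp", "stopflow_adp",
                                    "turnover", "trap", "motility", "msm"),
                          seed = 1, ...) {
  assay <- match.arg(assay)
  args <- list(...)
  g <- function(name, default) if (name %in% names(args)) args[[name]] else default
  res <- switch(assay,
    atpase = {
      kcat <- g("kcat", 0.80); Km <- g("Km", 35.9); basal <- g("basal", 0.02)
      plate <- make_atpase_plate(kcat, Km, basal,
                                 noise_sd = g("noise_sd", 0.002), seed = seed)
      ana <- analyze_atpase_plate(plate)
      list(truth = list(kcat = kcat, Km = Km, basal = basal), estimate = ana$fit)
    },
    stopflow_atp = {
      K1 <- g("K1", 1 / 79.8); k_plus2 <- g("k_plus2", 520.7)
      # series places three points deep in the linear regime (a few uM) and
      # the rest spanning the curvature up to saturation
      atp <- g("atp_list", c(1, 2, 5, 40, 80, 160, 320, 640, 1000))
      traces <- make_dissociation_transients(K1, k_plus2, atp,
                                             noise_sd = g("noise_sd", 0.02),
                                             seed = seed)
      pts <- lapply(traces, fit_transient_exponential)
      list(truth = list(K1 = K1, k_plus2 = k_plus2, K1k2 = K1 * k_plus2),
           estimate = fit_atp_dependence(pts))
    },
    stopflow_adp = {
      k0 <- g("k0", 100); K_ADP <- g("K_ADP", 120.7)
      adp <- g("adp_list", c(0, 25, 50, 100, 200, 400, 800))
      traces <- make_adp_competition_transients(k0, K_ADP, adp,
                                                noise_sd = g("noise_sd", 0.02),
                                                seed = seed)
      pts <- lapply(traces, fit_transient_exponential)
      list(truth = list(k0 = k0, K_ADP = K_ADP),
           estimate = fit_adp_competition(pts))
    },
    turnover = {
      p <- g("p_srx", 0.829)
      ks <- g("k_slow", 0.003); kf <- g("k_fast", 0.03)
      tr <- make_turnover_decay(p, ks, kf, noise_sd = g("noise_sd", 0.01),
                                seed = seed)
      list(truth = list(p_srx = p, k_slow = ks, k_fast = kf),
           estimate = fit_single_turnover(tr))
    },
    trap = {
      cfg <- do.call(trap_sim_config,
                     args[names(args) %in% names(formals(trap_sim_config))])
      rec <- make_trap_trace(cfg, duration_s = g("duration_s", 60), seed = seed)
      ev <- detect_events(rec)
      list(truth = list(cfg = cfg, events = rec$events),
           estimate = list(events = ev, steps = summarize_steps(ev)))
    },
    motility = {
      cfg <- do.call(movie_sim_config,
                     args[names(args) %in% names(formals(movie_sim_config))])
      mov <- make_motility_movie(cfg, seed = seed)
      det <- detect_movie(mov)
      trk <- link_tracks(det, gate_px = g("gate_px", 15),
                         gap_frames = g("gap_frames", 1))
      # >= 10 of 30 frames: excludes the short-lived ghost tracks that
      # filament crossings leave behind
      list(truth = list(cfg = cfg, tracks = mov$truth),
           estimate = compute_velocities(trk, cfg$pixel_size,
                                         cfg$frame_interval,
                                         min_track_len = g("min_track_len", 10)))
    },
    msm = {
      T_true <- g("T_true", matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
      n <- g("n_steps", 1e5)
      traj <- make_state_trajectory(T_true, n, seed = seed)
      list(truth = list(T = T_true),
           estimate = estimate_transition_matrix(
             count_transitions(traj, lag = 1, n_states = nrow(T_true))))
    })
  c(res, list(assay = assay, seed = seed))
}
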