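# shared helpers for synthetic-data tests

# overlap-match detected events to ground-truth events; returns the truth
# index per detection (NA where unmatched)
match_events <- function(detected, truth) {
  vapply(seq_len(nrow(detected)), function(i) {
    ov <- pmin(detected$end_s[i], truth$end_s) -
      pmax(detected$start_s[i], truth$start_s)
    j <- which.max(ov)
    if (length(j) && ov[j] > 0) j else NA_integer_
  }, 1L)
}

# render a synthetic frame with straight filaments (list of lists with
# cx, cy, phi, L) on a constant background, optionally Poisson noise
render_frame <- function(filaments, ny = 128, nx = 128, sigma = 4 / 2.355,
                         peak = 400, background = 100, noisy = FALSE,
                         seed = 1) {
  img <- matrix(0, ny, nx)
  for (f in filaments)
    img <- myocycle:::render_filament(img, f$cx, f$cy, f$phi, f$L, sigma, peak)
  img <- img + background
  if (noisy) {
    set.seed(seed)
    img <- matrix(stats::rpois(length(img), img), ny, nx)
  }
  img
}

# brute-force minimum assignment cost by permutation enumeration (n <= 7)
brute_force_lap <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(ncol(cost)))[]) {
    val <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (val < best) best <- val
  }
  best
}
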