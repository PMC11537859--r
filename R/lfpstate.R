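#' LFP brain-state series
#'
#' A 1-Hz series of the LF/HF band-amplitude ratio of the local field
#' potential, the derived state metric `r = log10(LF/HF) - 1`, and the
#' binary brain-state label: `"L"` (LF-dominant, synchronized) when the
#' ratio exceeds 10, else `"H"` (HF-dominant, activated).  A ratio of
#' exactly 10 (`r = 0`) is labeled `"H"`.
#'
#' @param t window times in seconds (1-s intervals).
#' @param ratio positive LF/HF values (`Inf` allowed for degenerate
#'   inputs with zero HF amplitude).
#' @return An object of class `lfp_state_series` with elements `t`,
#'   `ratio`, `r`, `label`.
#' @export
lfp_state_series <- function(t, ratio) {
  if (length(t) != length(ratio)) stop("`t` and `ratio` lengths differ")
  if (any(is.na(ratio)) || any(ratio < 0))
    stop("`ratio` must be non-negative")
  r <- log10(ratio) - 1
  structure(
    list(t = t, ratio = ratio, r = r,
         label = ifelse(ratio > 10, "L", "H")),
    class = "lfp_state_series")
}

#' @export
print.lfp_state_series <- function(x, ...) {
  cat(sprintf("lfp_state_series: %d s, %d L / %d H\n", length(x$t),
              sum(x$label == "L"), sum(x$label == "H")))
  invisible(x)
}

#' LF/HF band-amplitude ratio of a raw LFP signal
#'
#' Computes, per non-overlapping 1-s window, the ratio of the average
#' Fourier amplitude in the low-frequency band (1-10 Hz) to that in the
#' high-frequency band (30-90 Hz, excluding the 58-62 Hz line-noise
#' region, both bands inclusive of their edges), and derives the state
#' metric and H/L labels.  A rectangular window is the default; a Hann
#' taper is available.
#'
#' @param signal numeric LFP trace.
#' @param fs sampling rate in Hz (>= 200 so the 90-Hz band edge is
#'   resolvable).
#' @param taper `"rect"` (default) or `"hann"`.
#' @return An [lfp_state_series()], one row per complete second.
#' @export
lf_hf_ratio <- function(signal, fs = 2000, taper = c("rect", "hann")) {
  taper <- match.arg(taper)
  if (fs < 200) stop("`fs` must be >= 200 Hz")
  n <- as.integer(round(fs))
  n_win <- length(signal) %/% n
  if (n_win < 1L) stop("signal shorter than one 1-s window")
  freqs <- seq_len(n) - 1L            # 1-s window => 1-Hz resolution
  lf_bins <- which(freqs >= 1 & freqs <= 10)
  hf_bins <- which(freqs >= 30 & freqs <= 90 & !(freqs >= 58 & freqs <= 62))
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) else rep(1, n)
  ratio <- vapply(seq_len(n_win), function(k) {
    x <- signal[((k - 1L) * n + 1L):(k * n)] * w
    amp <- Mod(stats::fft(x))
    lf <- mean(amp[lf_bins]); hf <- mean(amp[hf_bins])
    if (hf == 0) {
      warning("zero HF amplitude in window ", k, "; ratio set to Inf")
      return(Inf)
    }
    lf / hf
  }, numeric(1))
  lfp_state_series(t = seq_len(n_win), ratio = ratio)
}

#' Order spiking states by LFP-state co-occurrence
#'
#' Maps each spiking bin to the 1-s LFP window containing its left edge,
#' counts per state the seconds labeled H versus L, and ranks states by
#' the Laplace-smoothed occupancy ratio `P(H|s) / P(L|s)` in descending
#' order (H-affine states first).  Ties are broken by state index; states
#' never observed within the LFP coverage are placed last and flagged.
#'
#' @param map_states integer per-bin MAP spiking states.
#' @param lfp an [lfp_state_series()].
#' @param n_states number of states (default `max(map_states)`).
#' @param bin_width spiking bin duration in seconds.
#' @return A list: `perm` (new order of old state indices; apply with
#'   [reorder_states()]), `hl_ratio` (per-state smoothed P(H|s)/P(L|s)),
#'   `lh_time_ratio` (per-state smoothed L:H time ratio, the Fig-style
#'   affinity scale), `observed` (logical per state).
#' @export
order_states_by_lfp <- function(map_states, lfp, n_states = max(map_states),
                                bin_width = 0.040) {
  stopifnot(inherits(lfp, "lfp_state_series"))
  sec <- floor((seq_along(map_states) - 1) * bin_width) + 1L
  keep <- sec <= length(lfp$label)
  st <- factor(map_states[keep], levels = seq_len(n_states))
  lab <- lfp$label[sec[keep]]
  n_h <- tabulate(st[lab == "H"], n_states)
  n_l <- tabulate(st[lab == "L"], n_states)
  observed <- (n_h + n_l) > 0
  hl_ratio <- (n_h + 1) / (n_l + 1)      # Laplace smoothing
  key <- ifelse(observed, hl_ratio, -Inf) # unobserved states go last
  perm <- order(-key, seq_len(n_states))
  list(perm = perm, hl_ratio = hl_ratio, lh_time_ratio = 1 / hl_ratio,
       observed = observed)
}

#' Transition graph of common state transitions
#'
#' Directed edge list of off-diagonal transitions with probability
#' strictly greater than `edge_threshold` (self-transitions are never
#' included), as used to display the state-transition structure.
#'
#' @param A row-stochastic transition matrix.
#' @param edge_threshold minimum (exclusive) transition probability.
#' @return A data.frame with columns `from`, `to`, `weight`.
#' @export
transition_graph <- function(A, edge_threshold = 0.05) {
  check_stochastic(A)
  idx <- which(A > edge_threshold & row(A) != col(A), arr.ind = TRUE)
  out <- data.frame(from = idx[, 1], to = idx[, 2], weight = A[idx])
  out[order(out$from, out$to), , drop = FALSE]
}
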