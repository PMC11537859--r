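#' Whisking-energy series
#'
#' A 25-Hz non-negative whisking (motion) energy series with a fixed
#' per-recording detection threshold and segment boundaries.  Frame `k`
#' covers the same 40 ms as spike-count bin `k`.
#'
#' @param energy non-negative numeric energy per frame.
#' @param threshold fixed detection threshold; if `NULL` it is set with
#'   [whisk_threshold()].
#' @param segment_id per-frame segment ids (non-decreasing); default one
#'   segment.
#' @param frame_rate frames per second (default 25).
#' @return An object of class `whisk_series`.
#' @export
whisk_series <- function(energy, threshold = NULL, segment_id = NULL,
                         frame_rate = 25) {
  if (any(is.na(energy)) || any(energy < 0))
    stop("`energy` must be non-negative")
  segment_id <- segment_id %||% rep(1L, length(energy))
  if (length(segment_id) != length(energy))
    stop("`segment_id` must have one id per frame")
  if (is.unsorted(segment_id)) stop("`segment_id` must be non-decreasing")
  threshold <- threshold %||% whisk_threshold(energy)
  structure(
    list(energy = energy, threshold = threshold,
         segment_id = as.integer(segment_id), frame_rate = frame_rate),
    class = "whisk_series")
}

#' @export
print.whisk_series <- function(x, ...) {
  cat(sprintf(
    "whisk_series: %d frames (%.1f s), threshold %.3g, %.1f%% whisking\n",
    length(x$energy), length(x$energy) / x$frame_rate, x$threshold,
    100 * mean(x$energy >= x$threshold)))
  invisible(x)
}

#' Fixed whisking detection threshold
#'
#' Midpoint between the two modes of a two-component split of the energy
#' distribution (2-means on the values), emulating the per-recording
#' fixed threshold chosen by eye in practice.
#'
#' @param energy non-negative numeric energy values.
#' @return A single threshold value.
#' @export
whisk_threshold <- function(energy) {
  if (length(unique(energy)) < 2L) return(max(energy) + 1)
  km <- kmeans(energy, centers = range(energy), iter.max = 50L)
  mean(km$centers)
}

#' Detect whisking onsets
#'
#' An onset is a transition frame `k` such that frames `k` and `k + 1`
#' are at or above the threshold, frame `k - 1` is below it (so `k` is
#' the first frame of its bout), at least 9 of the 10 preceding frames
#' (400 ms) are below it, and `k` lies at least 500 ms from both edges
#' of its recording segment (candidates nearer an edge are discarded).
#'
#' @param whisk a [whisk_series()].
#' @return Integer vector of onset frame indices (possibly empty).
#' @export
detect_onsets <- function(whisk) {
  stopifnot(inherits(whisk, "whisk_series"))
  fp <- 1 / whisk$frame_rate               # frame period, 40 ms
  edge_frames <- ceiling(0.5 / fp)         # 500 ms
  onsets <- integer(0)
  for (sid in unique(whisk$segment_id)) {
    idx <- which(whisk$segment_id == sid)
    e <- whisk$energy[idx]
    n <- length(e)
    above <- e >= whisk$threshold
    if (n < 12L) next
    for (k in 11:(n - 1L)) {
      if (!(above[k] && above[k + 1L]) || above[k - 1L]) next
      if (sum(!above[(k - 10L):(k - 1L)]) < 9L) next
      if ((k - 1L) * fp < 0.5) next        # within 500 ms of segment start
      if ((n - k) * fp < 0.5) next         # within 500 ms of segment end
      onsets <- c(onsets, idx[k])
    }
  }
  onsets
}

#' Equipartition discretization of whisking energy
#'
#' Discretizes the energy into `n_bins` labels `0..n_bins-1` at empirical
#' quantiles, breaking ties by stable rank order so bin occupancies are
#' equal within one frame.  The labels depend only on ranks, so any
#' monotone transform of the energy leaves them unchanged.
#'
#' @param energy numeric energy values (`length >= n_bins`).
#' @param n_bins number of bins (default 4).
#' @return Integer labels in `0..n_bins-1`.
#' @export
equipartition_bins <- function(energy, n_bins = 4L) {
  n <- length(energy)
  if (n < n_bins) stop("need at least `n_bins` frames")
  if (length(unique(energy)) < 2L) {
    warning("constant energy series; all frames assigned bin 0")
    return(rep(0L, n))
  }
  r <- rank(energy, ties.method = "first")
  as.integer(floor((r - 1) * n_bins / n))
}

#' Plug-in mutual information between two discrete series
#'
#' `MI = sum_xy p(x, y) log2[p(x, y) / (p(x) p(y))]` on the empirical
#' joint distribution, in bits per bin, with an error bar estimated by
#' recomputing MI on `n_resample` random half-samples of the data and a
#' first-order (Miller-Madow) upward-bias bound
#' `(|X| - 1)(|Y| - 1) / (2 N ln 2)` reported for interpretation (no
#' bias correction is applied).
#'
#' @param x_labels,y_labels equal-length discrete label vectors.
#' @param n_resample number of half-data resamples for the error bar
#'   (default 50; 0 skips it).
#' @param seed RNG seed.
#' @return A list: `mi` (bits), `sd` (half-sample SD), `bias_bound`
#'   (bits), `n`.
#' @export
mutual_information <- function(x_labels, y_labels, n_resample = 50L,
                               seed = NULL) {
  n <- length(x_labels)
  if (n == 0L) stop("empty label series")
  if (length(y_labels) != n) stop("label series lengths differ")
  mi_plugin <- function(x, y) {
    joint <- table(x, y) / length(x)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    mi <- sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    stopifnot(mi >= -1e-12, mi <= min(hx, hy) + 1e-9)
    max(mi, 0)
  }
  mi <- mi_plugin(x_labels, y_labels)
  kx <- length(unique(x_labels)); ky <- length(unique(y_labels))
  bias <- (kx - 1) * (ky - 1) / (2 * n * log(2))
  s <- NA_real_
  if (n_resample > 0L) {
    s <- with_seed(seed, {
      half <- vapply(seq_len(n_resample), function(r) {
        idx <- sample.int(n, n %/% 2L)
        mi_plugin(x_labels[idx], y_labels[idx])
      }, numeric(1))
      sd(half)
    })
  }
  list(mi = mi, sd = s, bias_bound = bias, n = n)
}

#' Compare whisking information carried by spiking states versus LFP state
#'
#' Computes the mutual information between the 4-bin equipartition
#' whisking labels and (a) the per-bin MAP spiking states and (b) the
#' binary LFP label, with the 1-Hz LFP label repeated across the 25
#' 40-ms bins of its second.  Bins beyond the LFP coverage are dropped
#' from both comparisons so the two MIs use identical samples.
#'
#' @param whisk_bins integer whisking labels per 40-ms bin (e.g. from
#'   [equipartition_bins()]).
#' @param map_states integer per-bin MAP spiking states.
#' @param lfp an [lfp_state_series()].
#' @param n_resample,seed passed to [mutual_information()].
#' @return A list: `mi_states`, `mi_lfp` (each a [mutual_information()]
#'   result).
#' @export
compare_whisk_information <- function(whisk_bins, map_states, lfp,
                                      n_resample = 50L, seed = NULL) {
  stopifnot(inherits(lfp, "lfp_state_series"))
  if (length(whisk_bins) != length(map_states))
    stop("whisking and state series lengths differ")
  per_sec <- 25L
  lfp_per_bin <- rep(lfp$label, each = per_sec)
  n <- min(length(whisk_bins), length(lfp_per_bin))
  if (n == 0L) stop("no overlap between series")
  list(mi_states = mutual_information(whisk_bins[seq_len(n)],
                                      map_states[seq_len(n)],
                                      n_resample, seed),
       mi_lfp = mutual_information(whisk_bins[seq_len(n)],
                                   lfp_per_bin[seq_len(n)],
                                   n_resample, seed))
}
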