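#' Table of sensory-evoked trials
#'
#' Per-trial container for the evoked-response analysis: the stimulus
#' time, a 1-s pre-stimulus spike raster (40-ms bins per neuron), and
#' spike counts in the pre-stimulus (-20..0 ms) and post-stimulus
#' (5..25 ms) analysis windows.  An optional ground-truth pre-stimulus
#' state is carried by synthetic trials.
#'
#' @param stim_time numeric stimulus times (seconds).
#' @param pre_raster integer array, neurons x pre-bins x trials.
#' @param pre_count,post_count integer matrices, trials x neurons, of
#'   window spike counts.
#' @param bin_width raster bin duration in seconds.
#' @param pre_window,post_window analysis windows in seconds relative to
#'   the stimulus.
#' @param true_state optional integer ground-truth states.
#' @return An object of class `trial_table`.
#' @export
trial_table <- function(stim_time, pre_raster, pre_count, post_count,
                        bin_width = 0.040,
                        pre_window = c(-0.020, 0),
                        post_window = c(0.005, 0.025),
                        true_state = NULL) {
  n_trials <- length(stim_time)
  if (dim(pre_raster)[3] != n_trials && n_trials > 0)
    stop("`pre_raster` third dimension must be the trial count")
  if (nrow(pre_count) != n_trials || nrow(post_count) != n_trials)
    stop("window count matrices must have one row per trial")
  if (any(pre_count < 0) || any(post_count < 0) || any(pre_raster < 0))
    stop("spike counts must be non-negative")
  structure(
    list(stim_time = stim_time, pre_raster = pre_raster,
         pre_count = pre_count, post_count = post_count,
         bin_width = bin_width, pre_window = pre_window,
         post_window = post_window, true_state = true_state),
    class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("trial_table: %d trials, %d neurons, %d pre-stimulus bins\n",
              length(x$stim_time), ncol(x$pre_count), dim(x$pre_raster)[2]))
  invisible(x)
}

#' Number of trials in a trial table
#' @param trials a [trial_table()].
#' @return Integer trial count.
#' @export
n_trials <- function(trials) length(trials$stim_time)

#' Assign each trial's pre-stimulus spiking state
#'
#' Runs forward-backward on each trial's pre-stimulus raster (optionally
#' restricted to the final `window_bins` bins, e.g. 12 bins for a 480-ms
#' window) and assigns the state with the highest posterior probability
#' in the final pre-stimulus bin (-40..0 ms); posterior ties go to the
#' lowest state index.
#'
#' @param params an [hmm_params()].
#' @param trials a [trial_table()].
#' @param window_bins number of final pre-stimulus bins to decode over;
#'   default all (the full 1-s window).
#' @return Integer vector of per-trial states.
#' @export
assign_prestim_state <- function(params, trials, window_bins = NULL) {
  stopifnot(inherits(params, "hmm_params"), inherits(trials, "trial_table"))
  nb <- dim(trials$pre_raster)[2]
  window_bins <- window_bins %||% nb
  if (window_bins < 1L || window_bins > nb)
    stop("`window_bins` must lie in 1..n_pre_bins")
  use <- (nb - window_bins + 1L):nb
  vapply(seq_len(n_trials(trials)), function(k) {
    cnt <- trials$pre_raster[, use, k, drop = FALSE]
    dim(cnt) <- dim(cnt)[1:2]
    fb <- forward_backward(params, cnt)
    g <- fb$gamma[nrow(fb$gamma), ]
    which.max(g)   # which.max takes the first (lowest) index on ties
  }, integer(1))
}

#' Evoked spike count of each trial and neuron
#'
#' The post-stimulus window count minus the pre-stimulus window count
#' (may be negative).
#'
#' @param trials a [trial_table()].
#' @return Integer matrix, trials x neurons.
#' @export
evoked_count <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  trials$post_count - trials$pre_count
}

#' Shuffle test for state-dependent evoked responses
#'
#' For every neuron and pre-stimulus state, compares the empirical mean
#' evoked count over the trials assigned to that state against a null
#' built by randomly permuting the state labels over trials (preserving
#' per-state trial counts), repeated `n_shuffles` times.  The percentile
#' is `100 * (#shuffle means below + 0.5 * #ties) / n_shuffles`;
#' responses are labeled `"facilitated"` above 99.5, `"suppressed"`
#' below 0.5 (the two-tailed 1% criterion), else `"ns"`.  States with no
#' assigned trials are skipped and flagged `"no_trials"`.
#'
#' @param trials a [trial_table()].
#' @param states integer per-trial pre-stimulus states (e.g. from
#'   [assign_prestim_state()]).
#' @param n_states number of states (default `max(states)`).
#' @param n_shuffles number of label permutations (default 200; fewer is
#'   allowed with a warning since percentile resolution degrades).
#' @param seed RNG seed.
#' @return An object of class `state_dependence_result`: a data.frame
#'   with columns `neuron`, `state`, `n_trials`, `mean_evoked`,
#'   `percentile`, `label`.
#' @export
state_dependence_test <- function(trials, states, n_states = max(states),
                                  n_shuffles = 200L, seed = NULL) {
  stopifnot(inherits(trials, "trial_table"))
  nt <- n_trials(trials)
  if (length(states) != nt)
    stop("`states` must have one entry per trial")
  if (n_shuffles < 200L)
    warning("fewer than 200 shuffles degrades percentile resolution")
  ev <- evoked_count(trials)                       # trials x neurons
  nc <- ncol(ev)
  st <- factor(states, levels = seq_len(n_states))
  n_per_state <- tabulate(st, n_states)
  state_means <- function(labels) {
    # states x neurons matrix of per-state mean evoked counts
    t(matrix(vapply(seq_len(n_states), function(s) {
      if (n_per_state[s] == 0L) return(rep(NA_real_, nc))
      colMeans(ev[labels == s, , drop = FALSE])
    }, numeric(nc)), nrow = nc))
  }
  emp <- state_means(st)
  with_seed(seed, {
    below <- array(0L, dim = c(n_states, nc))
    ties <- array(0L, dim = c(n_states, nc))
    for (r in seq_len(n_shuffles)) {
      shuf <- state_means(st[sample.int(nt)])
      below <- below + (shuf < emp - 1e-12)
      ties <- ties + (abs(shuf - emp) <= 1e-12)
    }
    pct <- 100 * (below + 0.5 * ties) / n_shuffles
    out <- data.frame(
      neuron = rep(seq_len(nc), each = n_states),
      state = rep(seq_len(n_states), nc),
      n_trials = rep(n_per_state, nc),
      mean_evoked = as.vector(emp),
      percentile = as.vector(pct))
    out$label <- ifelse(out$n_trials == 0L, "no_trials",
                 ifelse(out$percentile > 99.5, "facilitated",
                 ifelse(out$percentile < 0.5, "suppressed", "ns")))
    out$percentile[out$n_trials == 0L] <- NA_real_
    class(out) <- c("state_dependence_result", "data.frame")
    out
  })
}

#' Trial-shuffle control for the state-dependence test
#'
#' Permutes the state labels once (destroying any real state-response
#' coupling while preserving per-state trial counts), then reruns the
#' full shuffle test.  Detection counts under this control estimate the
#' empirical false-positive baseline of the criterion (nominally 1%).
#'
#' @inheritParams state_dependence_test
#' @return A `state_dependence_result` (as [state_dependence_test()]).
#' @export
trial_shuffle_control <- function(trials, states, n_states = max(states),
                                  n_shuffles = 200L, seed = NULL) {
  nt <- n_trials(trials)
  if (length(states) != nt)
    stop("`states` must have one entry per trial")
  with_seed(seed, {
    perm_states <- states[sample.int(nt)]
    state_dependence_test(trials, perm_states, n_states = n_states,
                          n_shuffles = n_shuffles)
  })
}

#' Summarize detected states by LFP affinity
#'
#' For the states carrying facilitated versus suppressed responses,
#' collects the log10 of each state's L:H time ratio (how much more time
#' the state spends in LFP state L than H) and reports the median ratios.
#' Positive log ratios are L-affine states, negative H-affine.
#'
#' @param results a `state_dependence_result`.
#' @param lh_time_ratio per-state L:H time ratios (e.g.
#'   `order_states_by_lfp(...)$lh_time_ratio`).
#' @return A list: `facilitated` and `suppressed` (data.frames with
#'   `state`, `n_neurons`, `log10_lh_ratio`), `median_ratio_facilitated`,
#'   `median_ratio_suppressed` (on the ratio scale; `NA` when empty).
#' @export
summarize_by_lfp_affinity <- function(results, lh_time_ratio) {
  stopifnot(inherits(results, "state_dependence_result"))
  one <- function(lbl) {
    sub <- results[results$label == lbl, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(state = integer(0), n_neurons = integer(0),
                        log10_lh_ratio = numeric(0)))
    agg <- as.data.frame(table(state = sub$state), stringsAsFactors = FALSE)
    st <- as.integer(agg$state)
    data.frame(state = st, n_neurons = agg$Freq,
               log10_lh_ratio = log10(lh_time_ratio[st]))
  }
  fac <- one("facilitated"); sup <- one("suppressed")
  med <- function(d) if (nrow(d) == 0L) NA_real_ else
    median(rep(10^d$log10_lh_ratio, d$n_neurons))
  list(facilitated = fac, suppressed = sup,
       median_ratio_facilitated = med(fac),
       median_ratio_suppressed = med(sup))
}
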