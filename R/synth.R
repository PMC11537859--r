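#' Ground-truth configuration for synthetic recordings
#'
#' Describes the generative world used to validate the analysis pipeline:
#' a sticky Markov chain over spiking states organized in two groups (one
#' affine to LFP state H, one to LFP state L), product-Poisson emissions
#' with fast-spiking (FS) neurons firing at higher rates and with larger
#' across-state variation than regular-spiking (RS) neurons, an LF/HF
#' series coupled to the state group, whisking bouts driven by a subset of
#' states, and state-gain-modulated evoked responses.
#'
#' Defaults describe a desk-scale awake-cortex-like recording: 7 states
#' (3 H-affine, 4 L-affine), 30 neurons of which 8 FS, 40-ms bins,
#' RS rates log-normal with median 1 spike/s, FS rates scaled by 4 and
#' across-state dispersion doubled, state group dwell times of a few
#' seconds, and whisking driven by the first two (H-affine) states.
#'
#' @param n_states number of latent states.
#' @param n_neurons number of neurons.
#' @param n_fs number of FS-labeled neurons (listed first).
#' @param bin_width bin duration in seconds.
#' @param n_bins number of spontaneous bins to simulate.
#' @param group_map per-state label `"H"` or `"L"` (LFP-state affinity).
#' @param within_group_stickiness minimum within-group transition mass per
#'   row of `A`.
#' @param cross_group_rate total cross-group transition mass per row
#'   (0 gives an exactly block-diagonal `A`); must satisfy
#'   `within_group_stickiness + cross_group_rate <= 1`.
#' @param fs_rate_scale multiplicative rate scale for FS neurons.
#' @param fs_cv_scale multiplicative scale on the across-state log-rate
#'   dispersion of FS neurons.
#' @param whisk_states states that drive whisking bouts.
#' @param evoked_gain per-state multiplicative evoked-response gain
#'   (>= -1; post-stimulus rate is `lam * (1 + gain)`).
#' @param n_trials number of evoked trials.
#' @param n_segments number of contiguous recording segments the
#'   spontaneous bins are divided into.
#' @param lfp_noise_sd SD (log10 units) of the LF/HF metric around its
#'   group mean.
#' @param whisk_base,whisk_bout,whisk_noise_sd baseline and bout levels of
#'   whisking energy and the log-normal noise SD around them.
#' @param rs_median_rate,rs_rate_sdlog median (spikes/s) and log-SD of the
#'   RS base-rate distribution.
#' @param state_sdlog log-SD of per-neuron across-state rate multipliers
#'   (RS; FS gets `state_sdlog * fs_cv_scale`).
#' @param state_global_sdlog log-SD of the population-wide per-state rate
#'   multiplier (creates overall rate differences between states).
#' @param seed master RNG seed.
#' @return An object of class `ground_truth_config`.
#' @export
ground_truth_config <- function(n_states = 7L, n_neurons = 30L, n_fs = 8L,
                                bin_width = 0.040, n_bins = 15000L,
                                group_map = NULL,
                                within_group_stickiness = 0.98,
                                cross_group_rate = 0.02,
                                fs_rate_scale = 4, fs_cv_scale = 2,
                                whisk_states = c(1L, 2L),
                                evoked_gain = NULL,
                                n_trials = 300L, n_segments = 8L,
                                lfp_noise_sd = 0.2,
                                whisk_base = 0.1, whisk_bout = 1.0,
                                whisk_noise_sd = 0.3,
                                rs_median_rate = 1, rs_rate_sdlog = 0.6,
                                state_sdlog = 0.4,
                                state_global_sdlog = 0.3,
                                seed = 1L) {
  if (n_states < 1L || n_neurons < 1L) stop("need >= 1 state and neuron")
  if (n_fs < 0L || n_fs > n_neurons) stop("`n_fs` must be in 0..n_neurons")
  if (is.null(group_map)) {
    group_map <- if (n_states == 1L) "H" else
      c(rep("H", ceiling(n_states * 3 / 7)),
        rep("L", n_states - ceiling(n_states * 3 / 7)))
  }
  if (length(group_map) != n_states)
    stop("`group_map` must have one label per state")
  if (!all(group_map %in% c("H", "L")))
    stop("`group_map` labels must be \"H\" or \"L\"")
  if (length(unique(group_map)) == 2L && n_states < 2L)
    stop("two state groups require at least two states")
  if (within_group_stickiness <= 0 || within_group_stickiness >= 1)
    stop("`within_group_stickiness` must lie in (0, 1)")
  if (cross_group_rate < 0 || cross_group_rate >= 1)
    stop("`cross_group_rate` must lie in [0, 1)")
  if (within_group_stickiness + cross_group_rate > 1)
    stop("stickiness + cross-group rate cannot exceed 1")
  if (fs_rate_scale <= 0 || fs_cv_scale <= 0)
    stop("FS scales must be positive")
  if (length(whisk_states) && !all(whisk_states %in% seq_len(n_states)))
    stop("`whisk_states` must be a subset of the state indices")
  evoked_gain <- evoked_gain %||% rep(1, n_states)
  if (length(evoked_gain) != n_states)
    stop("`evoked_gain` must have one entry per state")
  if (any(evoked_gain < -1))
    stop("`evoked_gain` below -1 implies negative rates")
  structure(
    list(n_states = as.integer(n_states), n_neurons = as.integer(n_neurons),
         n_fs = as.integer(n_fs), bin_width = bin_width,
         n_bins = as.integer(n_bins), group_map = group_map,
         within_group_stickiness = within_group_stickiness,
         cross_group_rate = cross_group_rate,
         fs_rate_scale = fs_rate_scale, fs_cv_scale = fs_cv_scale,
         whisk_states = as.integer(whisk_states),
         evoked_gain = evoked_gain, n_trials = as.integer(n_trials),
         n_segments = as.integer(n_segments), lfp_noise_sd = lfp_noise_sd,
         whisk_base = whisk_base, whisk_bout = whisk_bout,
         whisk_noise_sd = whisk_noise_sd,
         rs_median_rate = rs_median_rate, rs_rate_sdlog = rs_rate_sdlog,
         state_sdlog = state_sdlog,
         state_global_sdlog = state_global_sdlog,
         seed = as.integer(seed)),
    class = "ground_truth_config")
}

#' Sample ground-truth HMM parameters
#'
#' Draws a transition matrix with near-block structure over the two
#' LFP-affinity groups and per-neuron per-state Poisson rates.  Each row
#' of `A` places `1 - cross_group_rate` of its mass within the row state's
#' group (so at least `within_group_stickiness`), most of it on the
#' diagonal; off-diagonal within-group and cross-group masses are spread
#' with Dirichlet weights so the matrix varies across seeds.  RS base
#' rates are log-normal (median `rs_median_rate`); FS rates are scaled by
#' `fs_rate_scale` and their across-state log-dispersion by
#' `fs_cv_scale`.
#'
#' @param config a [ground_truth_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return An [hmm_params()] with attributes `group_map` and `cell_type`.
#' @export
sample_hmm_params <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ground_truth_config"))
  ns <- config$n_states; nc <- config$n_neurons
  with_seed(seed %||% config$seed, {
    A <- matrix(0, ns, ns)
    for (i in seq_len(ns)) {
      same <- setdiff(which(config$group_map == config$group_map[i]), i)
      other <- which(config$group_map != config$group_map[i])
      cross <- if (length(other)) config$cross_group_rate else 0
      within <- 1 - cross
      self <- within * 0.9
      if (length(same)) {
        w <- rgamma(length(same), 5)
        A[i, same] <- (within - self) * w / sum(w)
      } else self <- within
      if (length(other)) {
        w <- rgamma(length(other), 5)
        A[i, other] <- cross * w / sum(w)
      }
      A[i, i] <- 1 - sum(A[i, -i])
    }
    cell_type <- c(rep("FS", config$n_fs), rep("RS", nc - config$n_fs))
    fs <- cell_type == "FS"
    base <- rlnorm(nc, log(config$rs_median_rate), config$rs_rate_sdlog)
    base[fs] <- base[fs] * config$fs_rate_scale
    sd_state <- ifelse(fs, config$state_sdlog * config$fs_cv_scale,
                       config$state_sdlog)
    mult <- matrix(rlnorm(nc * ns, 0, rep(sd_state, ns)), nc, ns)
    g_state <- rlnorm(ns, 0, config$state_global_sdlog)
    lam <- base * mult * matrix(g_state, nc, ns, byrow = TRUE)
    params <- hmm_params(A, lam, config$bin_width)
    attr(params, "group_map") <- config$group_map
    attr(params, "cell_type") <- cell_type
    params
  })
}

#' Simulate a Poisson-HMM
#'
#' Samples a latent Markov state sequence under `A` (started from its
#' stationary distribution unless `init` is given) and, optionally,
#' conditionally independent Poisson spike counts
#' `counts[n, t] ~ Poisson(lam[n, s_t] * bin_width)`.
#'
#' @param params an [hmm_params()].
#' @param n_bins number of bins to simulate.
#' @param seed RNG seed.
#' @param init optional fixed 1-based start state.
#' @param emit if `FALSE`, skip emission sampling (`counts = NULL`).
#' @return A list with `states` (integer vector) and `counts`
#'   (NC x n_bins integer matrix or `NULL`).
#' @export
simulate_hmm <- function(params, n_bins, seed = NULL, init = NULL,
                         emit = TRUE) {
  stopifnot(inherits(params, "hmm_params"))
  check_stochastic(params$A)
  if (n_bins < 1L) stop("`n_bins` must be >= 1")
  with_seed(seed, {
    if (is.null(init)) {
      pi0 <- stationary_dist(params$A)
      init <- sample.int(params$n_states, 1L, prob = pi0)
    }
    states <- if (n_bins == 1L) init else
      .sim_chain_core(params$A, init - 1L, runif(n_bins - 1L))
    counts <- NULL
    if (emit) {
      mu <- params$lam[, states, drop = FALSE] * params$bin_width
      counts <- matrix(rpois(length(mu), mu), nrow = params$n_neurons)
    }
    list(states = as.integer(states), counts = counts)
  })
}

#' Synthesize a 1-Hz LF/HF metric series coupled to the state group
#'
#' Emits one LF/HF value per second of the state sequence.  Seconds whose
#' majority state is L-affine draw `log10(LF/HF)` around 1.5 and H-affine
#' seconds around 0.5 (so at `noise_sd = 0`, thresholding the ratio at 10
#' recovers the majority group exactly); ties go to H.
#'
#' @param state_seq integer state sequence at `bin_width` resolution.
#' @param group_map per-state `"H"`/`"L"` labels.
#' @param noise_sd Gaussian SD on the log10 ratio.
#' @param seed RNG seed.
#' @param bin_width bin duration in seconds.
#' @return An [lfp_state_series()] with one row per whole second.
#' @export
synth_lfp_metric <- function(state_seq, group_map, noise_sd = 0.2,
                             seed = NULL, bin_width = 0.040) {
  if (length(state_seq) == 0L) stop("empty state sequence")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  per_sec <- round(1 / bin_width)
  n_sec <- length(state_seq) %/% per_sec
  if (n_sec == 0L) stop("state sequence shorter than one second")
  with_seed(seed, {
    grp <- group_map[state_seq[seq_len(n_sec * per_sec)]]
    grp <- matrix(grp, nrow = per_sec)
    maj_l <- colSums(grp == "L") > per_sec / 2
    log10_ratio <- ifelse(maj_l, 1.5, 0.5) + rnorm(n_sec, 0, noise_sd)
    lfp_state_series(t = seq_len(n_sec), ratio = 10^log10_ratio)
  })
}

#' Synthesize a 25-Hz whisking-energy series driven by spiking states
#'
#' Frame `k` covers bin `k` exactly (both 40 ms).  Energy fluctuates
#' log-normally around `bout_level` while the state is in `whisk_states`
#' and around `base_level` otherwise; the series is non-negative.
#'
#' @param state_seq integer state sequence (one per 40-ms bin).
#' @param whisk_states states that drive whisking bouts.
#' @param base_level,bout_level energy levels (`bout_level > base_level`).
#' @param noise_sd log-normal noise SD (0 gives the exact levels).
#' @param seed RNG seed.
#' @param segment_id optional per-frame segment ids (for onset edge
#'   rules); defaults to one segment.
#' @return A [whisk_series()].
#' @export
synth_whisking <- function(state_seq, whisk_states, base_level = 0.1,
                           bout_level = 1.0, noise_sd = 0.3, seed = NULL,
                           segment_id = NULL) {
  if (base_level < 0 || bout_level <= base_level)
    stop("need 0 <= base_level < bout_level")
  ns <- max(state_seq)
  if (length(whisk_states) && !all(whisk_states %in% seq_len(ns)))
    stop("`whisk_states` must be a subset of the state indices")
  with_seed(seed, {
    level <- ifelse(state_seq %in% whisk_states, bout_level, base_level)
    energy <- level * exp(rnorm(length(state_seq), 0, noise_sd))
    whisk_series(energy,
                 threshold = (base_level + bout_level) / 2,
                 segment_id = segment_id)
  })
}

#' Synthesize evoked trials with state-dependent gains
#'
#' Each trial carries a true pre-stimulus state drawn from the stationary
#' distribution of `A`, a 1-s pre-stimulus raster generated from the
#' chain conditioned to end in that state (sampled through the reversed
#' chain, which is exact under stationarity), and spike counts in the
#' pre-stimulus (-20..0 ms) and post-stimulus (5..25 ms) analysis
#' windows.  Window counts are Poisson with rates `lam[n, s]` (pre) and
#' `lam[n, s] * (1 + evoked_gain[s])` (post), drawn independently of the
#' binned raster given the state.
#'
#' @param params an [hmm_params()].
#' @param n_trials number of trials (0 allowed).
#' @param pre_window,post_window analysis windows in seconds relative to
#'   the stimulus.
#' @param evoked_gain per-state gain (>= -1), length `n_states`.
#' @param seed RNG seed.
#' @param pre_duration pre-stimulus raster duration in seconds.
#' @return A [trial_table()].
#' @export
synth_evoked_trials <- function(params, n_trials,
                                pre_window = c(-0.020, 0),
                                post_window = c(0.005, 0.025),
                                evoked_gain = NULL, seed = NULL,
                                pre_duration = 1.0) {
  stopifnot(inherits(params, "hmm_params"))
  ns <- params$n_states; nc <- params$n_neurons
  evoked_gain <- evoked_gain %||% rep(0, ns)
  if (length(evoked_gain) != ns)
    stop("`evoked_gain` must have one entry per state")
  if (any(evoked_gain < -1))
    stop("`evoked_gain` below -1 implies negative rates")
  n_pre_bins <- round(pre_duration / params$bin_width)
  pre_len <- diff(pre_window); post_len <- diff(post_window)
  if (pre_len <= 0 || post_len <= 0) stop("windows must have positive length")
  pi0 <- stationary_dist(params$A)
  # time-reversed transition matrix: R[j, i] = P(s_{t-1} = i | s_t = j)
  rev_A <- t(params$A * pi0) / pmax(pi0, .Machine$double.eps)
  rev_A <- rev_A / pmax(rowSums(rev_A), .Machine$double.eps)
  with_seed(seed, {
    true_state <- if (n_trials > 0)
      sample.int(ns, n_trials, replace = TRUE, prob = pi0) else integer(0)
    pre_raster <- array(0L, dim = c(nc, n_pre_bins, n_trials))
    pre_count <- matrix(0L, n_trials, nc)
    post_count <- matrix(0L, n_trials, nc)
    for (k in seq_len(n_trials)) {
      st <- integer(n_pre_bins)
      st[n_pre_bins] <- true_state[k]
      if (n_pre_bins > 1L && ns > 1L)
        for (t in (n_pre_bins - 1L):1L)
          st[t] <- sample.int(ns, 1L, prob = rev_A[st[t + 1L], ])
      if (ns == 1L) st[] <- 1L
      mu <- params$lam[, st, drop = FALSE] * params$bin_width
      pre_raster[, , k] <- matrix(rpois(length(mu), mu), nc)
      s <- true_state[k]
      pre_count[k, ] <- rpois(nc, params$lam[, s] * pre_len)
      post_count[k, ] <- rpois(nc, params$lam[, s] *
                                 (1 + evoked_gain[s]) * post_len)
    }
    trial_table(stim_time = if (n_trials > 0) 3 * seq_len(n_trials)
                            else numeric(0),
                pre_raster = pre_raster, pre_count = pre_count,
                post_count = post_count, bin_width = params$bin_width,
                pre_window = pre_window, post_window = post_window,
                true_state = true_state)
  })
}

#' Generate a complete synthetic recording
#'
#' Assembles the full ground-truth world of a [ground_truth_config()]:
#' HMM parameters, a spontaneous raster cut into contiguous segments, the
#' 1-Hz LF/HF metric coupled to the state groups, the 25-Hz whisking
#' series driven by `whisk_states`, and a table of evoked trials with
#' per-state gains.  All stage seeds derive deterministically from
#' `config$seed`.
#'
#' @param config a [ground_truth_config()].
#' @return An object of class `synthetic_recording`: `raster`,
#'   `true_states`, `true_params`, `lfp`, `whisk`, `trials`, `config`.
#' @export
synth_recording <- function(config) {
  stopifnot(inherits(config, "ground_truth_config"))
  params <- sample_hmm_params(config)
  sim <- simulate_hmm(params, config$n_bins, seed = config$seed + 1L)
  seg <- rep(seq_len(config$n_segments),
             each = ceiling(config$n_bins / config$n_segments),
             length.out = config$n_bins)
  raster <- spike_raster(sim$counts, config$bin_width,
                         attr(params, "cell_type"), seg)
  lfp <- synth_lfp_metric(sim$states, config$group_map,
                          config$lfp_noise_sd, seed = config$seed + 2L,
                          bin_width = config$bin_width)
  whisk <- synth_whisking(sim$states, config$whisk_states,
                          config$whisk_base, config$whisk_bout,
                          config$whisk_noise_sd, seed = config$seed + 3L,
                          segment_id = seg)
  trials <- synth_evoked_trials(params, config$n_trials,
                                evoked_gain = config$evoked_gain,
                                seed = config$seed + 4L)
  structure(
    list(raster = raster, true_states = sim$states, true_params = params,
         lfp = lfp, whisk = whisk, trials = trials, config = config),
    class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf(
    "synthetic_recording: %d states, %d neurons, %d bins, %d trials\n",
    x$config$n_states, x$config$n_neurons, x$config$n_bins,
    x$config$n_trials))
  invisible(x)
}

#' Synthesize a raw 2-kHz LFP signal coupled to the state group
#'
#' Optional raw-signal mode used to exercise the spectral pipeline in
#' [lf_hf_ratio()].  Each second is a sum of band-limited sinusoids:
#' L-affine seconds carry strong 2-6 Hz components and weak gamma,
#' H-affine seconds the reverse, plus white noise.
#'
#' @param state_seq integer state sequence at `bin_width` resolution.
#' @param group_map per-state `"H"`/`"L"` labels.
#' @param fs sampling rate in Hz (default 2000).
#' @param noise_sd white-noise SD.
#' @param seed RNG seed.
#' @param bin_width bin duration in seconds.
#' @return Numeric signal of length `fs * floor(T * bin_width)`.
#' @export
synth_lfp_signal <- function(state_seq, group_map, fs = 2000,
                             noise_sd = 0.1, seed = NULL,
                             bin_width = 0.040) {
  if (length(state_seq) == 0L) stop("empty state sequence")
  per_sec <- round(1 / bin_width)
  n_sec <- length(state_seq) %/% per_sec
  if (n_sec == 0L) stop("state sequence shorter than one second")
  with_seed(seed, {
    grp <- matrix(group_map[state_seq[seq_len(n_sec * per_sec)]],
                  nrow = per_sec)
    maj_l <- colSums(grp == "L") > per_sec / 2
    tt <- seq(0, 1 - 1 / fs, by = 1 / fs)
    out <- lapply(seq_len(n_sec), function(k) {
      lf_amp <- if (maj_l[k]) 10 else 0.5
      hf_amp <- if (maj_l[k]) 0.5 else 4
      ph <- runif(4, 0, 2 * pi)
      lf_amp * (sin(2 * pi * 3 * tt + ph[1]) +
                  0.7 * sin(2 * pi * 5 * tt + ph[2])) +
        hf_amp * (sin(2 * pi * 40 * tt + ph[3]) +
                    0.7 * sin(2 * pi * 70 * tt + ph[4])) +
        rnorm(fs, 0, noise_sd)
    })
    unlist(out)
  })
}
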