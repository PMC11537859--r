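#' Train/test split by alternating segments
#'
#' Deterministic split of recording segments: the 1st, 3rd, 5th, ...
#' segments (in order of appearance) form the training set and the 2nd,
#' 4th, 6th, ... the test set.
#'
#' @param raster a [spike_raster()] with at least two segments.
#' @return A list with `train` and `test` segment-id vectors.
#' @export
split_segments <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  ids <- unique(raster$segment_id)
  if (length(ids) < 2L)
    stop("need at least two segments to split; subdivide the recording")
  odd <- seq_along(ids) %% 2L == 1L
  list(train = ids[odd], test = ids[!odd])
}

#' Test-set likelihood curve across model sizes
#'
#' For each number of states, fits the model on the training segments and
#' evaluates the normalized log-likelihood on the test segments, together
#' with the gain over the one-state (constant-rate) model, the simulation
#' ceiling (likelihood of fresh data generated from the fitted model,
#' mean +/- SD over repetitions), and the full-shuffle floor (likelihood
#' of the test data with every neuron's counts independently permuted in
#' time).  A fit failure at one model size is recorded as `NA` without
#' aborting the rest of the curve.
#'
#' @param raster a [spike_raster()].
#' @param split a split from [split_segments()].
#' @param n_states_range model sizes to evaluate (default `1:15`).
#' @param n_restarts,tol,max_iter EM settings passed to [fit_em()].
#' @param ceiling_reps simulation-ceiling repetitions per model size.
#' @param seed RNG seed.
#' @return An object of class `likelihood_report`: a data.frame with
#'   columns `n_states`, `test_loglik`, `gain`, `ceiling_mean`,
#'   `ceiling_sd`, `shuffle_loglik`, plus attributes `one_state`
#'   (baseline normalized log-likelihood) and `fits` (fitted parameters
#'   per model size).
#' @export
likelihood_curve <- function(raster, split, n_states_range = 1:15,
                             n_restarts = 3L, tol = 1e-6, max_iter = 200L,
                             ceiling_reps = 3L, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  train <- raster_subset(raster, split$train)
  test <- raster_subset(raster, split$test)
  with_seed(seed, {
    base_fit <- fit_em(train, 1L, n_restarts = 1L, tol = tol,
                       max_iter = max_iter)
    base_ll <- loglik_normalized(base_fit$params, test)
    fits <- vector("list", length(n_states_range))
    rows <- lapply(seq_along(n_states_range), function(i) {
      ns <- n_states_range[i]
      tryCatch({
        fit <- fit_em(train, ns, n_restarts = n_restarts, tol = tol,
                      max_iter = max_iter)
        fits[[i]] <<- fit$params
        ll <- loglik_normalized(fit$params, test)
        ceil <- simulation_ceiling(fit$params, ncol(test$counts),
                                   n_reps = ceiling_reps)
        shuf <- full_shuffle_control(fit$params, test)
        data.frame(n_states = ns, test_loglik = ll, gain = ll - base_ll,
                   ceiling_mean = ceil$mean, ceiling_sd = ceil$sd,
                   shuffle_loglik = shuf)
      }, error = function(e) {
        warning(sprintf("fit with %d states failed: %s", ns,
                        conditionMessage(e)))
        data.frame(n_states = ns, test_loglik = NA_real_, gain = NA_real_,
                   ceiling_mean = NA_real_, ceiling_sd = NA_real_,
                   shuffle_loglik = NA_real_)
      })
    })
    out <- do.call(rbind, rows)
    attr(out, "one_state") <- base_ll
    attr(out, "fits") <- fits
    class(out) <- c("likelihood_report", "data.frame")
    out
  })
}

#' Simulation ceiling of model performance
#'
#' Normalized log-likelihood of fresh observations generated from the
#' model itself, at the same data length as the recording: an estimate of
#' the best achievable fit ("idealized case"), reported as mean +/- SD
#' over repetitions.
#'
#' @param params an [hmm_params()].
#' @param data_length number of bins per repetition.
#' @param n_reps number of repetitions (>= 1; with 1 the SD is reported
#'   as 0 with a warning).
#' @param seed RNG seed.
#' @return A list: `values`, `mean`, `sd`.
#' @export
simulation_ceiling <- function(params, data_length, n_reps = 5L,
                               seed = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  if (n_reps < 1L) stop("`n_reps` must be >= 1")
  with_seed(seed, {
    vals <- vapply(seq_len(n_reps), function(r) {
      sim <- simulate_hmm(params, data_length)
      loglik_normalized(params, spike_raster(sim$counts, params$bin_width))
    }, numeric(1))
    s <- if (n_reps == 1L) {
      warning("simulation ceiling SD undefined with n_reps = 1; reported 0")
      0
    } else sd(vals)
    list(values = vals, mean = mean(vals), sd = s)
  })
}

#' Full-shuffle likelihood floor
#'
#' Independently permutes each neuron's count series in time (destroying
#' temporal and cross-neuron state structure while preserving every
#' neuron's count marginal) and recomputes the normalized log-likelihood
#' under the model.
#'
#' @param params an [hmm_params()].
#' @param raster a [spike_raster()].
#' @param seed RNG seed.
#' @return Normalized log-likelihood of the shuffled data.
#' @export
full_shuffle_control <- function(params, raster, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  with_seed(seed, {
    nt <- ncol(raster$counts)
    shuf <- t(apply(raster$counts, 1L, function(y) y[sample.int(nt)]))
    loglik_normalized(params, spike_raster(shuf, raster$bin_width,
                                           raster$cell_type,
                                           raster$segment_id))
  })
}

#' Single-neuron shuffle likelihood loss
#'
#' Permutes one neuron's count series in time (all segments jointly by
#' default), leaving the rest of the population intact, and measures the
#' drop in normalized log-likelihood relative to the original data,
#' averaged over shuffles.  A larger loss means the neuron's timing is
#' more strongly coupled to the population state.
#'
#' @param params an [hmm_params()].
#' @param raster a [spike_raster()].
#' @param neuron_idx neuron to shuffle.
#' @param n_shuffles number of independent permutations (default 10).
#' @param seed RNG seed.
#' @param within_segments if `TRUE`, permute within each segment
#'   separately instead of across the whole series.
#' @return A list: `delta_ll` (original minus mean shuffled normalized
#'   log-likelihood), `loglik_data`, `loglik_shuffled` (per shuffle).
#' @export
single_neuron_shuffle_loss <- function(params, raster, neuron_idx,
                                       n_shuffles = 10L, seed = NULL,
                                       within_segments = FALSE) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!(neuron_idx %in% seq_len(nrow(raster$counts))))
    stop("`neuron_idx` out of range")
  orig <- loglik_normalized(params, raster)
  with_seed(seed, {
    nt <- ncol(raster$counts)
    lls <- vapply(seq_len(n_shuffles), function(r) {
      cnt <- raster$counts
      if (within_segments) {
        for (sid in unique(raster$segment_id)) {
          idx <- which(raster$segment_id == sid)
          cnt[neuron_idx, idx] <- cnt[neuron_idx, idx[sample.int(length(idx))]]
        }
      } else {
        cnt[neuron_idx, ] <- cnt[neuron_idx, sample.int(nt)]
      }
      loglik_normalized(params, spike_raster(cnt, raster$bin_width,
                                             raster$cell_type,
                                             raster$segment_id))
    }, numeric(1))
    list(delta_ll = orig - mean(lls), loglik_data = orig,
         loglik_shuffled = lls)
  })
}

#' Coefficient of variation of a neuron's state-dependent rates
#'
#' SD over states divided by the mean over states of `lam[n, ]`, using
#' the population (n-denominator) SD.  Measures how strongly a neuron's
#' rate varies with the latent state; scale-invariant.
#'
#' @param params an [hmm_params()].
#' @param neuron_idx neuron index.
#' @return Non-negative scalar.
#' @export
rate_cv <- function(params, neuron_idx) {
  stopifnot(inherits(params, "hmm_params"))
  if (!(neuron_idx %in% seq_len(params$n_neurons)))
    stop("`neuron_idx` out of range")
  lam <- params$lam[neuron_idx, ]
  m <- mean(lam)
  if (m <= 0) stop("zero-mean rate vector")
  sqrt(mean((lam - m)^2)) / m
}

#' Hierarchical bootstrap contrast between FS and RS neurons
#'
#' Two-level bootstrap for nested data (neurons within recordings):
#' recordings are resampled with replacement, then neurons within each
#' resampled recording with replacement.  The statistic is
#' `mean(FS) - mean(RS)`.  The one-sided p-value is the fraction of
#' bootstrap statistics <= 0 (direction FS > RS); a two-sided p and the
#' z-score (bootstrap mean / bootstrap SD) are also reported.  A resample
#' that loses one group entirely is redrawn.
#'
#' @param values per-neuron metric.
#' @param group per-neuron `"FS"`/`"RS"` labels (both present).
#' @param cluster per-neuron recording id (>= 2 clusters).
#' @param n_boot number of bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @return A list: `p_boot` (one-sided), `p_two`, `z`, `stat_obs`,
#'   `boot_stats`.
#' @export
hierarchical_bootstrap <- function(values, group, cluster,
                                   n_boot = 10000L, seed = NULL) {
  if (length(values) != length(group) || length(values) != length(cluster))
    stop("`values`, `group`, `cluster` must have equal length")
  if (!all(group %in% c("FS", "RS")) || length(unique(group)) < 2L)
    stop("`group` must contain both FS and RS labels")
  cl_ids <- unique(cluster)
  if (length(cl_ids) < 2L) stop("need at least two clusters")
  idx_by_cl <- lapply(cl_ids, function(cl) which(cluster == cl))
  is_fs <- group == "FS"
  stat_obs <- mean(values[is_fs]) - mean(values[!is_fs])
  n_cl <- length(cl_ids)
  with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(b) {
      for (try in seq_len(100L)) {
        cls <- sample.int(n_cl, n_cl, replace = TRUE)
        idx <- unlist(lapply(cls, function(k) {
          ix <- idx_by_cl[[k]]
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }))
        f <- is_fs[idx]
        if (any(f) && any(!f))
          return(mean(values[idx][f]) - mean(values[idx][!f]))
      }
      stop("could not draw a resample containing both groups")
    }, numeric(1))
    bsd <- sd(boot)
    list(p_boot = mean(boot <= 0),
         p_two = 2 * min(mean(boot <= 0), mean(boot >= 0)),
         z = if (bsd > 0) mean(boot) / bsd else Inf,
         stat_obs = stat_obs, boot_stats = boot)
  })
}
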