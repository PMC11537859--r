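#' Poisson-HMM parameters
#'
#' Parameters of a hidden Markov model with conditionally independent
#' Poisson emissions: a row-stochastic transition matrix
#' `A[i, j] = P(s(t + bin_width) = j | s(t) = i)` and a matrix of firing
#' rates `lam[n, s]` (spikes/second) for each neuron `n` and state `s`.
#' Rates are stored in spikes/second and converted to expected counts per
#' bin by `bin_width` at the emission; use [rates_per_bin()] for the
#' spikes-per-bin view.
#'
#' @param A NS x NS transition matrix, rows summing to 1.
#' @param lam NC x NS matrix of non-negative rates in spikes/second.
#'   Rates below the floor `1e-3` spikes/s are raised to it.
#' @param bin_width bin duration in seconds (default 0.040).
#' @return An object of class `hmm_params` with elements `A`, `lam`,
#'   `n_states`, `n_neurons`, `bin_width`.
#' @export
hmm_params <- function(A, lam, bin_width = 0.040) {
  A <- as.matrix(A); lam <- as.matrix(lam)
  if (nrow(A) != ncol(A)) stop("`A` must be square")
  check_stochastic(A)
  if (ncol(lam) != nrow(A))
    stop("`lam` must have one column per state")
  if (any(lam < 0)) stop("rates must be non-negative")
  lam <- pmax(lam, RATE_FLOOR)
  structure(
    list(A = A, lam = lam, n_states = nrow(A), n_neurons = nrow(lam),
         bin_width = bin_width),
    class = "hmm_params")
}

# Rate floor (spikes/s) applied in constructors and the EM M-step so a state
# that captures a silent neuron cannot produce log(0).
RATE_FLOOR <- 1e-3

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d states, %d neurons, %.0f ms bins\n",
              x$n_states, x$n_neurons, x$bin_width * 1000))
  cat(sprintf("  mean rate per state (spikes/bin): %s\n",
              paste(sprintf("%.2f", colMeans(x$lam) * x$bin_width),
                    collapse = " ")))
  invisible(x)
}

#' Expected spikes per bin
#'
#' The `lam * bin_width` view of the rate parameters (spikes per bin), the
#' scale on which state-dependent rate patterns are usually displayed.
#'
#' @param params an [hmm_params()].
#' @return NC x NS matrix of expected counts per bin.
#' @export
rates_per_bin <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  params$lam * params$bin_width
}

#' Per-state Poisson emission log-probability of one count vector
#'
#' For spike counts `y` observed in one bin, returns the log-probability of
#' `y` under each state's product-Poisson emission:
#' `sum_n [ y_n log(lam_n(s) * bin_width) - lam_n(s) * bin_width - log(y_n!) ]`.
#'
#' @param params an [hmm_params()].
#' @param counts_t integer vector of per-neuron counts for a single bin.
#' @return Numeric vector of length `n_states`.
#' @export
emission_logprob <- function(params, counts_t) {
  stopifnot(inherits(params, "hmm_params"))
  if (length(counts_t) != params$n_neurons)
    stop("`counts_t` must have one count per neuron")
  if (any(is.na(counts_t)) || any(counts_t < 0) ||
      any(counts_t != round(counts_t)))
    stop("counts must be non-negative integers")
  mu <- params$lam * params$bin_width      # NC x NS
  drop(counts_t %*% log(mu)) - colSums(mu) - sum(lgamma(counts_t + 1))
}

# Emission log-probability matrix for a whole segment: T x NS.
emission_logprob_matrix <- function(params, counts) {
  mu <- params$lam * params$bin_width
  ll <- t(counts) %*% log(mu)
  sweep(ll, 2L, colSums(mu)) - colSums(lgamma(counts + 1))
}

#' Posterior state decoding by the forward-backward algorithm
#'
#' Computes per-bin posterior state probabilities
#' `gamma[t, s] = P(s_t = s | y_1:T)` and the marginal log-likelihood of
#' the observations.  Multiple segments in the raster are treated as
#' independent chains sharing parameters: each segment starts from
#' `init` (by default the stationary distribution of `A`), posteriors are
#' concatenated and log-likelihoods summed.  The recursion uses per-bin
#' rescaling, so arbitrarily long segments do not underflow.
#'
#' @param params an [hmm_params()].
#' @param raster a [spike_raster()] (or a bare NC x T count matrix, taken
#'   as one segment).
#' @param init initial state distribution; default `stationary_dist(A)`.
#' @return An object of class `state_posterior`: `gamma` (T x NS),
#'   `loglik` (total), `map_states` (per-bin argmax, ties to the lowest
#'   state index), `xi` (expected transition counts, summed).
#' @export
forward_backward <- function(params, raster, init = NULL) {
  stopifnot(inherits(params, "hmm_params"))
  if (is.matrix(raster)) raster <- spike_raster(raster, params$bin_width)
  if (nrow(raster$counts) != params$n_neurons)
    stop("raster and params disagree on the number of neurons")
  if (abs(raster$bin_width - params$bin_width) > 1e-12)
    stop("raster and params disagree on bin width")
  init <- init %||% stationary_dist(params$A)
  if (length(init) != params$n_states || any(init < 0) ||
      abs(sum(init) - 1) > 1e-6)
    stop("`init` must be a distribution over states")
  segs <- segment_counts(raster)
  gam <- vector("list", length(segs))
  xi <- matrix(0, params$n_states, params$n_states)
  loglik <- 0
  for (k in seq_along(segs)) {
    logB <- emission_logprob_matrix(params, segs[[k]])
    fb <- .fb_core(logB, params$A, init, TRUE)
    gam[[k]] <- fb$gamma
    xi <- xi + fb$xi
    loglik <- loglik + fb$loglik
  }
  gamma <- do.call(rbind, gam)
  structure(
    list(gamma = gamma, loglik = loglik,
         map_states = max.col(gamma, ties.method = "first"), xi = xi),
    class = "state_posterior")
}

#' @export
print.state_posterior <- function(x, ...) {
  cat(sprintf("state_posterior: %d bins x %d states, loglik = %.2f\n",
              nrow(x$gamma), ncol(x$gamma), x$loglik))
  invisible(x)
}

#' Maximum a posteriori state per bin
#'
#' Argmax over the posterior `gamma` rows; ties are broken to the lowest
#' state index.
#'
#' @param posterior a `state_posterior` from [forward_backward()].
#' @return Integer vector of per-bin states.
#' @export
map_state_per_bin <- function(posterior) {
  stopifnot(inherits(posterior, "state_posterior"))
  max.col(posterior$gamma, ties.method = "first")
}

#' Fit a Poisson-HMM by Baum-Welch EM
#'
#' Estimates `A` and `lam` on a (possibly multi-segment) raster.  Each
#' segment is an independent chain sharing parameters.  During fitting the
#' initial state distribution of every segment is held fixed at uniform,
#' which preserves the EM monotonicity guarantee; downstream inference on
#' fresh data uses the stationary distribution of the fitted `A`.  The
#' M-step is the Poisson rate update
#' `lam[n, s] = sum_t gamma[t, s] y[n, t] / (bin_width * sum_t gamma[t, s])`
#' with a floor of `1e-3` spikes/s, and the transition update normalizes
#' expected transition counts.  Initialization partitions bins by
#' population count into `n_states` quantile groups (a k-means-style
#' split) and perturbs the implied rates independently per restart.
#'
#' @param raster a [spike_raster()].
#' @param n_states number of latent states (>= 1).
#' @param n_restarts number of random restarts (best train log-likelihood
#'   wins); default 5.
#' @param tol relative train log-likelihood change declaring convergence;
#'   default 1e-6.
#' @param max_iter maximum EM iterations per restart; default 500.
#' @param seed RNG seed for initialization.
#' @return A list: `params` (fitted [hmm_params()]), `loglik_trace`
#'   (train log-likelihood per iteration, best restart), `converged`
#'   (logical; `FALSE` means `max_iter` was hit and the best-so-far fit is
#'   returned), `restart_loglik` (final log-likelihood of every restart).
#' @export
fit_em <- function(raster, n_states, n_restarts = 5L, tol = 1e-6,
                   max_iter = 500L, seed = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (n_states < 1L) stop("`n_states` must be >= 1")
  nt <- ncol(raster$counts)
  if (nt < n_states) stop("raster has fewer bins than states")
  segs <- segment_counts(raster)
  with_seed(seed, {
    best <- NULL
    restart_ll <- numeric(n_restarts)
    for (r in seq_len(n_restarts)) {
      fit <- em_once(segs, n_states, raster$bin_width, tol, max_iter)
      restart_ll[r] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (!best$converged)
      warning(sprintf("EM did not converge within %d iterations; %s",
                      max_iter, "returning best fit so far"))
    list(params = best$params, loglik_trace = best$trace,
         converged = best$converged, restart_loglik = restart_ll)
  })
}

# One EM run from a random initialization (uses the caller's RNG stream).
em_once <- function(segs, ns, dt, tol, max_iter) {
  counts_all <- do.call(cbind, segs)
  nc <- nrow(counts_all); nt <- ncol(counts_all)

  # quantile partition of bins by population count, then per-restart jitter
  pop <- colSums(counts_all)
  grp <- if (ns == 1L) rep(1L, nt) else
    as.integer(cut(rank(pop, ties.method = "first"),
                   breaks = ns, labels = FALSE))
  lam <- sapply(seq_len(ns), function(s) {
    idx <- which(grp == s)
    rowSums(counts_all[, idx, drop = FALSE]) / (length(idx) * dt)
  })
  lam <- matrix(lam, nc, ns) * matrix(exp(rnorm(nc * ns, 0, 0.15)), nc, ns)
  lam <- pmax(lam, RATE_FLOOR)
  A <- matrix(0.2 / max(ns - 1, 1), ns, ns) *
    matrix(rlnorm(ns * ns, 0, 0.1), ns, ns)
  diag(A) <- 0
  A <- A * (0.2 / pmax(rowSums(A), .Machine$double.eps))
  diag(A) <- 1 - rowSums(A)
  if (ns == 1L) A <- matrix(1, 1, 1)

  pi0 <- rep(1 / ns, ns)   # fixed during EM (monotonicity guarantee)
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xi <- matrix(0, ns, ns)
    occ <- numeric(ns)
    ysum <- matrix(0, nc, ns)
    loglik <- 0
    for (seg in segs) {
      logB <- emission_logprob_matrix(list(lam = lam, bin_width = dt), seg)
      fb <- .fb_core(logB, A, pi0, TRUE)
      xi <- xi + fb$xi
      occ <- occ + colSums(fb$gamma)
      ysum <- ysum + seg %*% fb$gamma
      loglik <- loglik + fb$loglik
    }
    trace <- c(trace, loglik)
    if (is.finite(prev) &&
        abs(loglik - prev) < tol * abs(prev) + 1e-12) {
      converged <- TRUE
      break
    }
    prev <- loglik
    # M-step
    if (ns > 1L) {
      rs <- rowSums(xi)
      A <- xi / pmax(rs, .Machine$double.eps)
      A[rs == 0, ] <- 1 / ns      # state never visited: keep it reachable
      A <- A / rowSums(A)
    }
    lam <- pmax(sweep(ysum, 2L, pmax(occ, .Machine$double.eps) * dt, "/"),
                RATE_FLOOR)
  }
  list(params = hmm_params(A, lam, dt), loglik = trace[length(trace)],
       trace = trace, converged = converged)
}

#' Normalized test-set log-likelihood
#'
#' Total log-likelihood of a raster under the model, summed over all
#' segments (each an independent chain started from the stationary
#' distribution of `A`) and divided by the number of bins times the number
#' of neurons.
#'
#' @param params an [hmm_params()].
#' @param raster a [spike_raster()].
#' @return A single number (log-likelihood per bin per neuron).
#' @export
loglik_normalized <- function(params, raster) {
  stopifnot(inherits(raster, "spike_raster"))
  nt <- ncol(raster$counts)
  if (nt == 0L) stop("empty raster")
  fb <- forward_backward(params, raster)
  fb$loglik / (nt * params$n_neurons)
}

#' Bhattacharyya overlap between two spiking states
#'
#' Overlap between the product-Poisson emission distributions of two
#' states.  Per neuron the Bhattacharyya distance between Poisson
#' distributions with per-bin means `lam_a * bin_width` and
#' `lam_b * bin_width` is
#' `D_n = (sqrt(lam_a * bin_width) - sqrt(lam_b * bin_width))^2 / 2`;
#' distances add over neurons because emissions are conditionally
#' independent, and the coefficient is `BC = exp(-sum_n D_n)`, ranging
#' from 0 (no overlap) to 1 (identical states).
#'
#' @param params an [hmm_params()].
#' @param state_a,state_b state indices.
#' @return The Bhattacharyya coefficient in `[0, 1]`.
#' @export
bhattacharyya <- function(params, state_a, state_b) {
  stopifnot(inherits(params, "hmm_params"))
  ns <- params$n_states
  if (!(state_a %in% seq_len(ns)) || !(state_b %in% seq_len(ns)))
    stop("state index out of range")
  mu <- params$lam * params$bin_width
  d <- 0.5 * (sqrt(mu[, state_a]) - sqrt(mu[, state_b]))^2
  exp(-sum(d))
}

#' Pairwise Bhattacharyya coefficients
#'
#' @param params an [hmm_params()].
#' @return NS x NS symmetric matrix of coefficients (unit diagonal).
#' @export
bhattacharyya_matrix <- function(params) {
  ns <- params$n_states
  outer(seq_len(ns), seq_len(ns),
        Vectorize(function(a, b) bhattacharyya(params, a, b)))
}

#' Order states by mean firing rate
#'
#' Returns the permutation that sorts states by ascending mean rate across
#' neurons (state 1 lowest).  Apply it with [reorder_states()] so `A`
#' (rows and columns) and `lam` (columns) stay consistent.
#'
#' @param params an [hmm_params()].
#' @return Integer permutation of `1:n_states`.
#' @export
sort_states <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  m <- colMeans(params$lam)
  order(m, seq_along(m))
}

#' Apply a state permutation to HMM parameters
#'
#' @param params an [hmm_params()].
#' @param perm permutation of `1:n_states` (new order of old indices).
#' @return Re-ordered [hmm_params()].
#' @export
reorder_states <- function(params, perm) {
  stopifnot(inherits(params, "hmm_params"))
  if (!setequal(perm, seq_len(params$n_states)))
    stop("`perm` must be a permutation of the state indices")
  hmm_params(params$A[perm, perm, drop = FALSE],
             params$lam[, perm, drop = FALSE], params$bin_width)
}
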