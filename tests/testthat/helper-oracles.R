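# Independent oracles and small fixture builders used across test files.

# Exhaustive-path forward-backward oracle: enumerates all NS^T state paths
# and marginalizes the joint directly.  Only feasible for tiny problems,
# which is the point: it shares no code with the recursive implementation.
enum_forward_backward <- function(A, lam, dt, counts, pi0 = NULL) {
  ns <- nrow(A); nt <- ncol(counts)
  if (is.null(pi0)) {
    e <- eigen(t(A))
    v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
    pi0 <- v / sum(v)
  }
  logB <- sapply(seq_len(ns), function(s)
    colSums(dpois(counts, lam[, s, drop = FALSE] %*% rep(1, nt) * dt,
                  log = TRUE)))
  logB <- matrix(logB, nt, ns)
  paths <- as.matrix(expand.grid(rep(list(seq_len(ns)), nt)))
  logp <- apply(paths, 1L, function(pth) {
    lp <- log(pi0[pth[1]]) + logB[1, pth[1]]
    if (nt > 1) for (t in 2:nt)
      lp <- lp + log(A[pth[t - 1], pth[t]]) + logB[t, pth[t]]
    lp
  })
  m <- max(logp)
  loglik <- m + log(sum(exp(logp - m)))
  w <- exp(logp - loglik)
  gamma <- matrix(0, nt, ns)
  for (t in seq_len(nt))
    for (s in seq_len(ns))
      gamma[t, s] <- sum(w[paths[, t] == s])
  list(gamma = gamma, loglik = loglik)
}

# Truncated-sum Bhattacharyya-coefficient oracle for product-Poisson
# states: per neuron sum_k sqrt(P(k) Q(k)), truncated at k_max.
bc_truncated_oracle <- function(mu_a, mu_b, k_max = 100L) {
  per_neuron <- vapply(seq_along(mu_a), function(n) {
    k <- 0:k_max
    sum(sqrt(dpois(k, mu_a[n]) * dpois(k, mu_b[n])))
  }, numeric(1))
  prod(per_neuron)
}

# Small hand-set two-state world used by several HMM tests.
tiny_world <- function() {
  A <- matrix(c(0.9, 0.1,
                0.2, 0.8), 2, 2, byrow = TRUE)
  lam <- matrix(c(1, 8,
                  5, 1,
                  2, 12), 3, 2, byrow = TRUE)
  hmm_params(A, lam, bin_width = 0.040)
}

# A raster with well-separated states (population rate ratio >= 5).
separated_raster <- function(n_bins = 2000, seed = 1) {
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  lam <- matrix(c(rep(1.5, 8), rep(12, 8)), 8, 2)
  p <- hmm_params(A, lam)
  sim <- simulate_hmm(p, n_bins, seed = seed)
  list(params = p, states = sim$states,
       raster = spike_raster(sim$counts))
}
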