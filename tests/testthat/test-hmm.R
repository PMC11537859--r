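test_that("emission log-probability matches the Poisson closed form", {
  # one neuron, one state, lam*dt = 1, y = 1: P = e^-1, log P = -1
  p <- hmm_params(matrix(1), matrix(25), bin_width = 0.040)
  expect_equal(emission_logprob(p, 1L), -1)

  # all-zero counts: entry s = -sum_n lam_n(s) * dt
  p2 <- tiny_world()
  expect_equal(emission_logprob(p2, c(0L, 0L, 0L)),
               -colSums(p2$lam * p2$bin_width))

  # arbitrary counts against a hand-coded pmf product oracle
  y <- c(3L, 0L, 2L)
  mu <- p2$lam * p2$bin_width
  oracle <- vapply(1:2, function(s)
    prod(mu[, s]^y * exp(-mu[, s]) / factorial(y)), numeric(1))
  expect_equal(exp(emission_logprob(p2, y)), oracle, tolerance = 1e-12)

  expect_error(emission_logprob(p2, c(1L, -1L, 0L)), "non-negative")
  expect_error(emission_logprob(p2, c(1.5, 0, 0)), "integer")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(42)
  for (case in 1:6) {
    ns <- sample(2:3, 1)
    nt <- sample(2:8, 1)
    nc <- sample(1:4, 1)
    A <- matrix(rgamma(ns * ns, 1), ns)
    A <- A / rowSums(A)
    lam <- matrix(rgamma(nc * ns, 2, 0.5), nc, ns) + 0.2
    p <- hmm_params(A, lam)
    counts <- matrix(rpois(nc * nt, 1), nc, nt)
    fb <- forward_backward(p, counts)
    oracle <- enum_forward_backward(A, p$lam, p$bin_width, counts)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-9)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-9)
  }
})

test_that("forward-backward handles the one-state and separated cases", {
  # NS = 1: gamma is all ones and loglik is the summed emission term
  p1 <- hmm_params(matrix(1), matrix(c(2, 5), 2, 1))
  counts <- matrix(rpois(20, 0.2), 2, 10)
  fb <- forward_backward(p1, counts)
  expect_true(all(fb$gamma == 1))
  expect_equal(fb$loglik,
               sum(sapply(1:10, function(t)
                 emission_logprob(p1, counts[, t]))))

  # strongly separated rates: posterior mass concentrates on the truth
  w <- separated_raster(n_bins = 2000, seed = 7)
  fb2 <- forward_backward(w$params, w$raster)
  mass_on_truth <- fb2$gamma[cbind(seq_along(w$states), w$states)]
  expect_gt(mean(mass_on_truth), 0.95)
  expect_gt(mean(map_state_per_bin(fb2) == w$states), 0.9)
})

test_that("MAP states break posterior ties to the lowest index", {
  post <- structure(list(gamma = rbind(c(0.2, 0.8), c(0.5, 0.5))),
                    class = "state_posterior")
  expect_identical(map_state_per_bin(post), c(2L, 1L))
})

test_that("one-state EM recovers the closed-form Poisson MLE", {
  set.seed(3)
  counts <- matrix(rpois(5 * 400, c(0.1, 0.5, 1, 2, 0.05)), 5, 400)
  ras <- spike_raster(counts)
  fit <- fit_em(ras, 1L, n_restarts = 1L, seed = 1)
  expect_equal(drop(fit$params$lam),
               pmax(rowSums(counts) / (400 * 0.040), 1e-3),
               tolerance = 1e-8)
  mu <- fit$params$lam * 0.040
  closed <- sum(counts * log(mu[, rep(1, 400)]) - c(mu) - lgamma(counts + 1))
  expect_equal(loglik_normalized(fit$params, ras), closed / (400 * 5),
               tolerance = 1e-8)
})

test_that("EM training log-likelihood is non-decreasing", {
  w <- separated_raster(n_bins = 3000, seed = 11)
  fit <- fit_em(w$raster, 2L, n_restarts = 2L, seed = 5)
  steps <- diff(fit$loglik_trace)
  expect_true(all(steps >= -1e-8 * abs(fit$loglik_trace[-1])))
})

test_that("parameter recovery error shrinks with recording length", {
  A <- matrix(c(0.92, 0.05, 0.03,
                0.04, 0.90, 0.06,
                0.05, 0.05, 0.90), 3, 3, byrow = TRUE)
  set.seed(21)
  lam <- matrix(rlnorm(12 * 3, log(3), 0.7), 12, 3)
  p <- hmm_params(A, lam)
  err <- vapply(c(5e3, 5e4), function(nt) {
    sim <- simulate_hmm(p, nt, seed = nt)
    fit <- fit_em(spike_raster(sim$counts), 3L, n_restarts = 3L,
                  seed = 22)
    perm <- spikestate:::match_states(p$lam, fit$params$lam)
    median(abs(fit$params$lam[, perm] - p$lam) / p$lam)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("overfitting a multi-state model to one-state data gains nothing", {
  set.seed(9)
  lam1 <- matrix(c(0.5, 1, 2, 4, 1.5, 0.8), 6, 1)
  p1 <- hmm_params(matrix(1), lam1)
  train <- simulate_hmm(p1, 6000, seed = 31)$counts
  test <- simulate_hmm(p1, 6000, seed = 32)$counts
  fit1 <- fit_em(spike_raster(train), 1L, n_restarts = 1L, seed = 1)
  # an overfit model may legitimately hit max_iter without converging
  fit7 <- suppressWarnings(fit_em(spike_raster(train), 7L, n_restarts = 2L,
                                  seed = 2, max_iter = 100L))
  ll1 <- loglik_normalized(fit1$params, spike_raster(test))
  ll7 <- loglik_normalized(fit7$params, spike_raster(test))
  # no spurious gain beyond small-sample noise
  expect_lt(abs(ll7 - ll1), 0.005)
})

test_that("Bhattacharyya coefficient matches closed form and oracle", {
  p <- tiny_world()
  expect_identical(bhattacharyya(p, 1, 1), 1)
  expect_identical(bhattacharyya(p, 2, 2), 1)

  # single neuron, mu_a = 1, mu_b = 4: D = (2 - 1)^2 / 2, BC = exp(-1/2)
  ps <- hmm_params(matrix(c(0.5, 0.5, 0.5, 0.5), 2),
                   matrix(c(25, 100), 1, 2))
  expect_equal(bhattacharyya(ps, 1, 2), exp(-0.5), tolerance = 1e-12)
  expect_equal(bhattacharyya(ps, 1, 2),
               bc_truncated_oracle(1, 4), tolerance = 1e-10)

  # adding strongly differing neurons shrinks the overlap monotonically
  set.seed(13)
  lam_a <- rlnorm(12, log(1), 0.3); lam_b <- lam_a * 100
  bc_k <- vapply(1:12, function(k) {
    pk <- hmm_params(matrix(c(0.5, 0.5, 0.5, 0.5), 2),
                     cbind(lam_a[1:k], lam_b[1:k]))
    bhattacharyya(pk, 1, 2)
  }, numeric(1))
  expect_true(all(diff(bc_k) < 0))
  expect_lt(bc_k[12], 1e-6)
})

test_that("states sort by ascending mean rate and resorting is idempotent", {
  A <- diag(3)[c(2, 3, 1), ]  # any stochastic matrix
  lam <- matrix(c(3, 1, 2,
                  3, 1, 2), 2, 3, byrow = TRUE)
  p <- hmm_params(A, lam)
  expect_identical(sort_states(p), c(2L, 3L, 1L))
  sorted <- reorder_states(p, sort_states(p))
  expect_identical(sort_states(sorted), 1:3)
  expect_equal(sorted$lam, lam[, c(2, 3, 1)])
  # A rows and columns move together
  expect_equal(sorted$A, p$A[c(2, 3, 1), c(2, 3, 1)])
})

test_that("normalized likelihood is invariant to duplicating the data", {
  w <- separated_raster(n_bins = 500, seed = 3)
  r1 <- w$raster
  r2 <- spike_raster(cbind(r1$counts, r1$counts), r1$bin_width,
                     r1$cell_type, rep(1:2, each = 500))
  expect_equal(loglik_normalized(w$params, r2),
               loglik_normalized(w$params, r1), tolerance = 1e-12)
})

test_that("normalized likelihood approaches the simulation ceiling", {
  # evaluating long data simulated from the model approaches the model's
  # entropy-rate estimate from an independent long simulation
  p <- tiny_world()
  sim1 <- simulate_hmm(p, 2e5, seed = 41)
  sim2 <- simulate_hmm(p, 2e5, seed = 42)
  ll1 <- loglik_normalized(p, spike_raster(sim1$counts))
  ll2 <- loglik_normalized(p, spike_raster(sim2$counts))
  expect_lt(abs(ll1 - ll2), 0.005)
})
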