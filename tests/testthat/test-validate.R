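make_segmented_raster <- function(n_seg, bins_per_seg = 50, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(4 * n_seg * bins_per_seg, 0.5), 4)
  spike_raster(counts, segment_id = rep(seq_len(n_seg),
                                        each = bins_per_seg))
}

test_that("segments split alternately into train and test", {
  expect_identical(split_segments(make_segmented_raster(4)),
                   list(train = c(1L, 3L), test = c(2L, 4L)))
  expect_identical(split_segments(make_segmented_raster(2)),
                   list(train = 1L, test = 2L))
  expect_identical(split_segments(make_segmented_raster(5)),
                   list(train = c(1L, 3L, 5L), test = c(2L, 4L)))
  expect_error(split_segments(make_segmented_raster(1)), "subdivide")
})

test_that("likelihood curve finds no structure in one-state data", {
  set.seed(5)
  lam <- matrix(c(0.5, 1, 2, 3, 1.5), 5, 1)
  sim <- simulate_hmm(hmm_params(matrix(1), lam), 4000, seed = 51)
  ras <- spike_raster(sim$counts, segment_id = rep(1:4, each = 1000))
  cur <- suppressWarnings(   # overfit sizes may hit max_iter
    likelihood_curve(ras, split_segments(ras), n_states_range = c(1, 3),
                     n_restarts = 2L, ceiling_reps = 2L, seed = 52))
  expect_lt(abs(cur$gain[cur$n_states == 3]), 0.005)
  # exchangeable data: the shuffle floor matches the data likelihood
  expect_lt(abs(cur$shuffle_loglik[1] - cur$test_loglik[1]), 0.005)
})

test_that("likelihood curve is invariant to neuron order", {
  w <- separated_raster(n_bins = 2000, seed = 6)
  ras <- spike_raster(w$raster$counts, segment_id = rep(1:4, each = 500))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  ras_p <- spike_raster(w$raster$counts[perm, ],
                        segment_id = rep(1:4, each = 500))
  c1 <- suppressWarnings(  # single ceiling rep reports SD = 0 + warning
    likelihood_curve(ras, split_segments(ras), n_states_range = 2,
                     n_restarts = 1L, ceiling_reps = 1L, seed = 3))
  c2 <- suppressWarnings(
    likelihood_curve(ras_p, split_segments(ras_p), n_states_range = 2,
                     n_restarts = 1L, ceiling_reps = 1L, seed = 3))
  expect_equal(c1$test_loglik, c2$test_loglik, tolerance = 1e-3)
})

test_that("a multi-state world beats the one-state model on held-out data", {
  cfg <- ground_truth_config(n_states = 4, n_neurons = 15, n_fs = 4,
                             group_map = c("H", "H", "L", "L"),
                             state_sdlog = 0.6, n_bins = 12000, seed = 61)
  rec <- synth_recording(cfg)
  cur <- likelihood_curve(rec$raster, split_segments(rec$raster),
                          n_states_range = c(2, 4, 6), n_restarts = 2L,
                          ceiling_reps = 2L, seed = 62)
  expect_true(all(cur$gain > 0))
  # gain plateaus at the generating size: going beyond adds little
  g4 <- cur$gain[cur$n_states == 4]; g6 <- cur$gain[cur$n_states == 6]
  expect_lt(g6 - g4, 0.25 * g4)
})

test_that("simulation ceiling behaves as a self-consistency check", {
  p <- tiny_world()
  ceil <- simulation_ceiling(p, 5000, n_reps = 4, seed = 7)
  sim <- simulate_hmm(p, 5000, seed = 8)
  ll <- loglik_normalized(p, spike_raster(sim$counts))
  expect_lt(abs(ll - ceil$mean), 4 * max(ceil$sd, 1e-3))
  expect_warning(simulation_ceiling(p, 500, n_reps = 1, seed = 9), "SD")

  # more similar state rate patterns lower the ceiling (entropy argument):
  # spreading rates apart makes states easier to identify
  lam_close <- matrix(c(2, 2.2, 4, 4.4, 3, 3.1), 3, 2)
  lam_far <- matrix(c(1, 8, 6, 1.5, 2, 12), 3, 2)
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  c_close <- simulation_ceiling(hmm_params(A, lam_close), 5000,
                                n_reps = 3, seed = 10)
  c_far <- simulation_ceiling(hmm_params(A, lam_far), 5000,
                              n_reps = 3, seed = 11)
  # compare each against its own shuffle floor: the far model gains more
  sim_c <- simulate_hmm(hmm_params(A, lam_close), 5000, seed = 12)
  sim_f <- simulate_hmm(hmm_params(A, lam_far), 5000, seed = 13)
  gap_close <- c_close$mean -
    full_shuffle_control(hmm_params(A, lam_close),
                         spike_raster(sim_c$counts), seed = 14)
  gap_far <- c_far$mean -
    full_shuffle_control(hmm_params(A, lam_far),
                         spike_raster(sim_f$counts), seed = 15)
  expect_gt(gap_far, gap_close)
})

test_that("the full shuffle preserves marginals but destroys structure", {
  w <- separated_raster(n_bins = 4000, seed = 16)
  ll_data <- loglik_normalized(w$params, w$raster)
  ll_shuf <- full_shuffle_control(w$params, w$raster, seed = 17)
  expect_lt(ll_shuf, ll_data)
  # totals per neuron unchanged
  with_shuffle <- spikestate:::with_seed(18, {
    nt <- ncol(w$raster$counts)
    t(apply(w$raster$counts, 1, function(y) y[sample.int(nt)]))
  })
  expect_identical(rowSums(with_shuffle), rowSums(w$raster$counts))
})

test_that("single-neuron shuffle loss isolates state-coupled neurons", {
  # constant count series: permutation is the identity, loss exactly 0
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)
  lam <- matrix(c(2, 10, 25, 25), 2, 2, byrow = TRUE)  # neuron 2 flat
  p <- hmm_params(A, lam)
  cnt <- rbind(rpois(500, 1), rep(1L, 500))
  loss_const <- single_neuron_shuffle_loss(p, spike_raster(cnt), 2,
                                           n_shuffles = 3, seed = 19)
  expect_identical(loss_const$delta_ll, 0)

  # a neuron with identical rates in every state contributes ~nothing
  sim <- simulate_hmm(p, 6000, seed = 20)
  ras <- spike_raster(sim$counts)
  loss_flat <- single_neuron_shuffle_loss(p, ras, 2, n_shuffles = 5,
                                          seed = 21)
  loss_coupled <- single_neuron_shuffle_loss(p, ras, 1, n_shuffles = 5,
                                             seed = 22)
  expect_lt(abs(loss_flat$delta_ll), 1e-3)
  expect_gt(loss_coupled$delta_ll, 10 * abs(loss_flat$delta_ll))
  # loss is non-negative in expectation on model-generated data
  expect_gt(loss_coupled$delta_ll, 0)
})

test_that("rate CV follows its definition and conventions", {
  p <- hmm_params(matrix(c(0.5, 0.5, 0.5, 0.5), 2),
                  matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE))
  expect_identical(rate_cv(p, 1), 0)        # constant row
  expect_equal(rate_cv(p, 2), 0.5)          # SD = 1 (population), mean = 2
  p_scaled <- hmm_params(p$A, p$lam * 7.3)
  expect_equal(rate_cv(p_scaled, 2), rate_cv(p, 2), tolerance = 1e-12)
})

test_that("hierarchical bootstrap is calibrated and detects separation", {
  # identical groups: p near 0.5, z near 0
  set.seed(23)
  vals <- rep(rnorm(30), 2)
  grp <- rep(c("FS", "RS"), each = 30)
  cl <- rep(rep(1:3, each = 10), 2)
  hb <- hierarchical_bootstrap(vals, grp, cl, n_boot = 500, seed = 24)
  expect_gt(hb$p_boot, 0.2); expect_lt(hb$p_boot, 0.8)
  expect_lt(abs(hb$z), 1)

  # complete separation across all clusters: p below 1/n_boot
  vals2 <- c(rnorm(30, 10, 0.1), rnorm(30, 0, 0.1))
  hb2 <- hierarchical_bootstrap(vals2, grp, cl, n_boot = 500, seed = 25)
  expect_lt(hb2$p_boot, 1 / 500)
  expect_error(hierarchical_bootstrap(vals, rep("FS", 60), cl), "both")
})

test_that("hierarchical bootstrap holds its type-I error rate", {
  set.seed(26)
  n_rep <- 500
  rej <- vapply(seq_len(n_rep), function(r) {
    cl <- rep(1:5, each = 20)
    grp <- rep(c(rep("FS", 6), rep("RS", 14)), 5)
    hb <- hierarchical_bootstrap(rnorm(100), grp, cl, n_boot = 200)
    hb$p_boot < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.07)
})

test_that("hierarchical bootstrap has power against a 1-SD shift", {
  set.seed(27)
  n_rep <- 200
  hits <- vapply(seq_len(n_rep), function(r) {
    cl <- rep(1:2, each = 30)
    grp <- rep(c(rep("FS", 15), rep("RS", 15)), 2)
    vals <- rnorm(60) + ifelse(grp == "FS", 1, 0)
    hierarchical_bootstrap(vals, grp, cl, n_boot = 200)$p_boot < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
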