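# A flat-rate world for calibration/power tests of the shuffle test: all
# neurons share the rate across states, so any state-dependence comes only
# from the injected gains.
flat_params <- function(ns = 3, nc = 6, rate = 30) {
  A <- matrix(0.1 / (ns - 1), ns, ns)
  diag(A) <- 0.9
  hmm_params(A, matrix(rate, nc, ns))
}

test_that("pre-stimulus state assignment follows the final-bin posterior", {
  # one state: always state 1
  p1 <- hmm_params(matrix(1), matrix(c(2, 3), 2, 1))
  tr1 <- synth_evoked_trials(p1, 10, seed = 1)
  expect_true(all(assign_prestim_state(p1, tr1) == 1L))

  # strongly separated rates: assignment recovers the true state
  w <- separated_raster(10, 1)
  tr <- synth_evoked_trials(w$params, 300, seed = 2)
  dec <- assign_prestim_state(w$params, tr)
  expect_gt(mean(dec == tr$true_state), 0.95)
  # and a shortened decoding window gives the same final-bin rule
  dec_short <- assign_prestim_state(w$params, tr, window_bins = 12)
  expect_gt(mean(dec_short == dec), 0.95)

  # exact posterior tie (identical states): lowest index wins
  p_tie <- hmm_params(matrix(0.5, 2, 2), matrix(c(2, 2), 1, 2))
  tr_tie <- synth_evoked_trials(p_tie, 5, seed = 3)
  expect_true(all(assign_prestim_state(p_tie, tr_tie) == 1L))
})

test_that("evoked counts difference the two analysis windows", {
  p <- tiny_world()
  tr <- synth_evoked_trials(p, 50, seed = 4)
  ev <- evoked_count(tr)
  expect_identical(ev, tr$post_count - tr$pre_count)
  expect_identical(colSums(ev),
                   colSums(tr$post_count) - colSums(tr$pre_count))
  tr$post_count[1, 1] <- 3L; tr$pre_count[1, 1] <- 1L
  expect_identical(evoked_count(tr)[1, 1], 2L)
  tr$post_count[2, 1] <- 0L; tr$pre_count[2, 1] <- 2L
  expect_identical(evoked_count(tr)[2, 1], -2L)
})

test_that("a response above every shuffle is flagged facilitated", {
  p <- flat_params(ns = 2, nc = 1, rate = 10)
  tr <- synth_evoked_trials(p, 200, evoked_gain = c(8, 0), seed = 5)
  res <- state_dependence_test(tr, tr$true_state, n_states = 2,
                               n_shuffles = 200, seed = 6)
  r1 <- res[res$state == 1, ]
  expect_identical(r1$label, "facilitated")
  expect_gt(r1$percentile, 99.5)
})

test_that("the shuffle test is calibrated under a state-independent null", {
  set.seed(7)
  n_pairs <- 0; n_flag <- 0
  pcts <- c()
  p <- flat_params(ns = 5, nc = 20, rate = 15)
  for (r in 1:6) {
    tr <- synth_evoked_trials(p, 150, evoked_gain = rep(0, 5),
                              seed = 700 + r)
    res <- state_dependence_test(tr, tr$true_state, n_states = 5,
                                 n_shuffles = 200, seed = 800 + r)
    ok <- res$label != "no_trials"
    n_pairs <- n_pairs + sum(ok)
    n_flag <- n_flag + sum(res$label[ok] %in% c("facilitated", "suppressed"))
    pcts <- c(pcts, res$percentile[ok])
  }
  expect_gte(n_pairs, 500)
  rate <- n_flag / n_pairs
  expect_gte(rate, 0.000)
  expect_lte(rate, 0.025)
  # percentiles roughly uniform on (0, 100) under the null
  ks <- suppressWarnings(stats::ks.test(pcts / 100, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("states with doubled gain are detected in most replicates", {
  p <- flat_params(ns = 3, nc = 6, rate = 30)
  hits <- vapply(1:20, function(r) {
    tr <- synth_evoked_trials(p, 750, evoked_gain = c(2, 1, 1),
                              seed = 900 + r)
    res <- state_dependence_test(tr, tr$true_state, n_states = 3,
                                 n_shuffles = 200, seed = 950 + r)
    r1 <- res[res$state == 1, ]
    mean(r1$label == "facilitated") > 0.5
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("the trial-shuffle control behaves like the null", {
  p <- flat_params(ns = 4, nc = 15, rate = 12)
  tr <- synth_evoked_trials(p, 200, evoked_gain = c(0, 1, 2, 3), seed = 8)
  res <- trial_shuffle_control(tr, tr$true_state, n_states = 4,
                               n_shuffles = 200, seed = 9)
  # per-state trial counts preserved exactly under the permutation
  expect_identical(sort(unique(res$n_trials)),
                   sort(unique(tabulate(tr$true_state, 4))))
  frac <- mean(res$label %in% c("facilitated", "suppressed"))
  expect_lte(frac, 0.03)
  # two seeds give statistically indistinguishable detection counts
  res2 <- trial_shuffle_control(tr, tr$true_state, n_states = 4,
                                n_shuffles = 200, seed = 10)
  n1 <- sum(res$label != "ns"); n2 <- sum(res2$label != "ns")
  if (n1 + n2 > 0)
    expect_gt(stats::binom.test(n1, n1 + n2, p = 0.5)$p.value, 0.01)
})

test_that("decisions are invariant to neuron relabeling and trial order", {
  # strong gain contrast so every neuron-state pair sits far from the
  # percentile cutoffs: label decisions cannot depend on the particular
  # draws of the shuffle null
  p <- flat_params(ns = 3, nc = 8, rate = 25)
  tr <- synth_evoked_trials(p, 240, evoked_gain = c(0, 8, 0), seed = 11)
  res <- state_dependence_test(tr, tr$true_state, n_states = 3, seed = 12)
  # neuron relabeling: per-neuron results move with the neuron
  nperm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  tr_n <- tr
  tr_n$pre_raster <- tr$pre_raster[nperm, , , drop = FALSE]
  tr_n$pre_count <- tr$pre_count[, nperm, drop = FALSE]
  tr_n$post_count <- tr$post_count[, nperm, drop = FALSE]
  res_n <- state_dependence_test(tr_n, tr$true_state, n_states = 3,
                                 seed = 12)
  for (j in seq_along(nperm))
    expect_identical(res_n$label[res_n$neuron == j],
                     res$label[res$neuron == nperm[j]])
  # trial order permutation
  set.seed(13)
  perm <- sample(seq_len(240))
  tr_p <- tr
  tr_p$stim_time <- tr$stim_time
  tr_p$pre_raster <- tr$pre_raster[, , perm, drop = FALSE]
  tr_p$pre_count <- tr$pre_count[perm, , drop = FALSE]
  tr_p$post_count <- tr$post_count[perm, , drop = FALSE]
  res_p <- state_dependence_test(tr_p, tr$true_state[perm], n_states = 3,
                                 seed = 12)
  expect_equal(res_p$mean_evoked, res$mean_evoked)
  expect_identical(res_p$label, res$label)
})

test_that("affinity summary ties detections to LFP state groups", {
  res <- data.frame(neuron = c(1, 1, 2, 3),
                    state = c(1, 3, 3, 2),
                    n_trials = 20, mean_evoked = c(1, -1, -1, 2),
                    percentile = c(100, 0, 0, 100),
                    label = c("facilitated", "suppressed", "suppressed",
                              "facilitated"))
  class(res) <- c("state_dependence_result", "data.frame")
  lh <- c(5, 2, 0.1)   # states 1, 2 L-affine; state 3 H-affine
  s <- summarize_by_lfp_affinity(res, lh)
  expect_gt(s$median_ratio_facilitated, 1)
  expect_lt(s$median_ratio_suppressed, 1)
  expect_true(all(s$facilitated$log10_lh_ratio > 0))
  # empty results produce an empty summary without error
  empty <- res[0, ]
  class(empty) <- c("state_dependence_result", "data.frame")
  s0 <- summarize_by_lfp_affinity(empty, lh)
  expect_identical(nrow(s0$facilitated), 0L)
  expect_true(is.na(s0$median_ratio_facilitated))
})
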