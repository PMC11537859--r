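#' Write a synthetic recording as a directory of delimited text files
#'
#' Layout: `config.txt` (key = value echo, including the seed),
#' `counts.tsv` (bins x neurons, integer), `neurons.tsv` (id, cell_type),
#' `bins.tsv` (bin, segment_id and, when known, true_state), `lfp.tsv`
#' (t, ratio), `whisk.tsv` (frame, energy), `trials.tsv` (trial,
#' stim_time, optional true_state), `trial_pre.tsv` / `trial_post.tsv`
#' (window counts, trials x neurons) and `trial_raster.tsv` (long table:
#' trial, bin, one column per neuron).
#'
#' @param rec a `synthetic_recording` from [synth_recording()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "synthetic_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  cfg <- rec$config
  scalars <- cfg[!vapply(cfg, function(v) length(v) > 1L, logical(1))]
  vecs <- cfg[vapply(cfg, function(v) length(v) > 1L, logical(1))]
  lines <- c(sprintf("%s = %s", names(scalars),
                     vapply(scalars, as.character, character(1))),
             sprintf("%s = %s", names(vecs),
                     vapply(vecs, function(v)
                       paste(v, collapse = ","), character(1))))
  writeLines(lines, file.path(dir, "config.txt"))

  counts <- t(rec$raster$counts)
  colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  tsv(counts, "counts.tsv")
  tsv(data.frame(id = seq_along(rec$raster$cell_type),
                 cell_type = rec$raster$cell_type), "neurons.tsv")
  tsv(data.frame(bin = seq_along(rec$raster$segment_id),
                 segment_id = rec$raster$segment_id,
                 true_state = rec$true_states), "bins.tsv")
  tsv(data.frame(t = rec$lfp$t, ratio = rec$lfp$ratio), "lfp.tsv")
  tsv(data.frame(frame = seq_along(rec$whisk$energy),
                 energy = rec$whisk$energy), "whisk.tsv")
  tr <- rec$trials
  tsv(data.frame(trial = seq_len(n_trials(tr)), stim_time = tr$stim_time,
                 true_state = tr$true_state %||%
                   rep(NA_integer_, n_trials(tr))), "trials.tsv")
  pc <- tr$pre_count; colnames(pc) <- paste0("n", seq_len(ncol(pc)))
  tsv(pc, "trial_pre.tsv")
  qc <- tr$post_count; colnames(qc) <- paste0("n", seq_len(ncol(qc)))
  tsv(qc, "trial_post.tsv")
  nb <- dim(tr$pre_raster)[2]
  long <- do.call(rbind, lapply(seq_len(n_trials(tr)), function(k) {
    m <- t(tr$pre_raster[, , k])
    colnames(m) <- paste0("n", seq_len(ncol(m)))
    cbind(data.frame(trial = k, bin = seq_len(nb)), m)
  }))
  if (is.null(long))
    long <- data.frame(trial = integer(0), bin = integer(0))
  tsv(long, "trial_raster.tsv")
  invisible(dir)
}

#' Read a recording directory
#'
#' Reads the layout written by [write_recording()], validating shapes and
#' signs on load.  The LFP, whisking and trial streams are optional:
#' a missing file yields a `NULL` component, not an error.
#'
#' @param dir directory path.
#' @return A list: `raster` ([spike_raster()]), `true_states` (or
#'   `NULL`), `lfp`, `whisk`, `trials` (each `NULL` when absent).
#' @export
read_recording <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  rd <- function(f) read.table(file.path(dir, f), sep = "\t", header = TRUE,
                               check.names = FALSE)
  has <- function(f) file.exists(file.path(dir, f))
  if (!has("counts.tsv")) stop("missing counts.tsv in ", dir)
  counts <- unname(as.matrix(rd("counts.tsv")))
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative count at bin %d, neuron %d", bad[1, 1],
                 bad[1, 2]))
  cell_type <- NULL
  if (has("neurons.tsv")) {
    neu <- rd("neurons.tsv")
    if (nrow(neu) != ncol(counts))
      stop("neurons.tsv row count does not match counts.tsv columns")
    cell_type <- neu$cell_type
  }
  segment_id <- NULL; true_states <- NULL
  if (has("bins.tsv")) {
    bins <- rd("bins.tsv")
    if (nrow(bins) != nrow(counts))
      stop("bins.tsv row count does not match counts.tsv rows")
    segment_id <- bins$segment_id
    if ("true_state" %in% names(bins)) true_states <- bins$true_state
  }
  raster <- spike_raster(t(counts), cell_type = cell_type,
                         segment_id = segment_id)
  lfp <- NULL
  if (has("lfp.tsv")) {
    d <- rd("lfp.tsv")
    if (is.unsorted(d$t)) stop("lfp.tsv times must be sorted")
    lfp <- lfp_state_series(d$t, d$ratio)
  }
  whisk <- NULL
  if (has("whisk.tsv"))
    whisk <- whisk_series(rd("whisk.tsv")$energy,
                          segment_id = raster$segment_id)
  trials <- NULL
  if (has("trials.tsv")) {
    ti <- rd("trials.tsv")
    if (is.unsorted(ti$stim_time)) stop("trials.tsv times must be sorted")
    pre <- unname(as.matrix(rd("trial_pre.tsv")))
    post <- unname(as.matrix(rd("trial_post.tsv")))
    storage.mode(pre) <- "integer"; storage.mode(post) <- "integer"
    long <- rd("trial_raster.tsv")
    nb <- if (nrow(long)) max(long$bin) else 0L
    nc <- ncol(counts)
    arr <- array(0L, dim = c(nc, nb, nrow(ti)))
    if (nrow(long)) {
      m <- as.matrix(long[, -(1:2), drop = FALSE])
      for (k in seq_len(nrow(ti)))
        arr[, , k] <- t(m[long$trial == k, , drop = FALSE])
    }
    ts <- if ("true_state" %in% names(ti) && !all(is.na(ti$true_state)))
      ti$true_state else NULL
    trials <- trial_table(ti$stim_time, arr, pre, post, true_state = ts)
  }
  list(raster = raster, true_states = true_states, lfp = lfp,
       whisk = whisk, trials = trials)
}

#' Pipeline configuration
#'
#' Bundles the settings of the end-to-end analysis: the model sizes fit
#' for the likelihood curve, the single size used for the downstream
#' state analyses, EM settings, decoder settings, shuffle counts and the
#' master seed from which all stage seeds are derived.
#'
#' @param n_states_fit model sizes for the likelihood curve.
#' @param n_states_analysis model size for the state-based analyses.
#' @param em_restarts,em_tol,em_max_iter EM settings.
#' @param ceiling_reps simulation-ceiling repetitions.
#' @param decoder_folds,decoder_cost decoder settings.
#' @param evoked_shuffles evoked shuffle count (default 200).
#' @param bootstrap_n hierarchical-bootstrap resamples (default 10^4).
#' @param mi_resamples MI half-data resamples (default 50).
#' @param shuffle_loss_n single-neuron shuffle repetitions.
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_states_fit = 1:10, n_states_analysis = 7L,
                       em_restarts = 3L, em_tol = 1e-6, em_max_iter = 200L,
                       ceiling_reps = 3L, decoder_folds = 5L,
                       decoder_cost = 1, evoked_shuffles = 200L,
                       bootstrap_n = 10000L, mi_resamples = 50L,
                       shuffle_loss_n = 5L, seed = 1L) {
  stopifnot(all(n_states_fit >= 1L), n_states_analysis >= 1L,
            em_restarts >= 1L, em_max_iter >= 1L, decoder_folds >= 2L,
            evoked_shuffles >= 1L, mi_resamples >= 0L)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on one recording
#'
#' Executes the stages of the end-to-end workflow in order: segment
#' split, likelihood curve across model sizes (with simulation ceiling
#' and shuffle floor), single-neuron shuffle losses and rate CVs by cell
#' type, LFP-based state ordering and transition graph, decoding of LFP
#' state from the four feature families, the evoked-response shuffle
#' test with its trial-shuffle control, and whisking-onset/MI analyses.
#' Results are returned as a list and, when `out_dir` is given, written
#' as delimited-text tables plus a JSON summary.  A stage failure is
#' caught and logged; stages not depending on it still run.
#'
#' @param rec a recording list as returned by [read_recording()] or a
#'   `synthetic_recording`.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return A list of per-stage results (class `pipeline_result`).
#' @export
run_pipeline <- function(rec, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  raster <- rec$raster
  res <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      message(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      NULL
    })
  }
  split <- stage("split", split_segments(raster))
  res$split <- split

  res$likelihood <- if (!is.null(split))
    stage("likelihood", likelihood_curve(
      raster, split, n_states_range = config$n_states_fit,
      n_restarts = config$em_restarts, tol = config$em_tol,
      max_iter = config$em_max_iter, ceiling_reps = config$ceiling_reps,
      seed = config$seed + 10L))

  ns <- config$n_states_analysis
  fit <- NULL
  if (!is.null(res$likelihood)) {
    i <- match(ns, config$n_states_fit)
    if (!is.na(i)) fit <- attr(res$likelihood, "fits")[[i]]
  }
  if (is.null(fit) && !is.null(split))
    fit <- stage("fit", fit_em(raster_subset(raster, split$train), ns,
                               n_restarts = config$em_restarts,
                               tol = config$em_tol,
                               max_iter = config$em_max_iter,
                               seed = config$seed + 11L)$params)
  res$params <- fit

  if (!is.null(fit)) {
    res$cell_coupling <- stage("cell_coupling", {
      test <- raster_subset(raster, split$test)
      loss <- vapply(seq_len(fit$n_neurons), function(n)
        single_neuron_shuffle_loss(fit, test, n,
                                   n_shuffles = config$shuffle_loss_n,
                                   seed = config$seed + 20L + n)$delta_ll,
        numeric(1))
      cv <- vapply(seq_len(fit$n_neurons), function(n) rate_cv(fit, n),
                   numeric(1))
      data.frame(neuron = seq_len(fit$n_neurons),
                 cell_type = raster$cell_type, shuffle_loss = loss,
                 rate_cv = cv)
    })
  }

  if (!is.null(fit) && !is.null(rec$lfp)) {
    res$state_order <- stage("state_order", {
      fb <- forward_backward(fit, raster)
      order_states_by_lfp(fb$map_states, rec$lfp, n_states = ns)
    })
    res$transition_graph <- stage("graph", {
      p <- if (!is.null(res$state_order))
        reorder_states(fit, res$state_order$perm) else fit
      transition_graph(p$A)
    })
    res$decoding <- stage("decoding", {
      kinds <- c("summed", "vector", "state")
      acc <- lapply(seq_along(kinds), function(i) {
        ds <- build_dataset(raster, rec$lfp, kinds[i], model = fit,
                            seed = config$seed + 30L + i)
        decode_lfp_state(ds, n_folds = config$decoder_folds,
                         cost = config$decoder_cost,
                         seed = config$seed + 40L + i)
      })
      data.frame(feature = kinds,
                 accuracy = vapply(acc, `[[`, numeric(1), "accuracy"),
                 sd = vapply(acc, `[[`, numeric(1), "sd"))
    })
  }

  if (!is.null(fit) && !is.null(rec$trials)) {
    res$evoked <- stage("evoked", {
      states <- assign_prestim_state(fit, rec$trials)
      list(states = states,
           test = state_dependence_test(rec$trials, states, n_states = ns,
                                        n_shuffles = config$evoked_shuffles,
                                        seed = config$seed + 50L),
           control = trial_shuffle_control(rec$trials, states,
                                           n_states = ns,
                                           n_shuffles =
                                             config$evoked_shuffles,
                                           seed = config$seed + 51L))
    })
    if (!is.null(res$evoked) && !is.null(res$state_order))
      res$evoked_by_affinity <- stage("evoked_affinity",
        summarize_by_lfp_affinity(res$evoked$test,
                                  res$state_order$lh_time_ratio))
  }

  if (!is.null(fit) && !is.null(rec$whisk)) {
    res$whisking <- stage("whisking", {
      fb <- forward_backward(fit, raster)
      wb <- equipartition_bins(rec$whisk$energy)
      cmp <- if (!is.null(rec$lfp))
        compare_whisk_information(wb, fb$map_states, rec$lfp,
                                  n_resample = config$mi_resamples,
                                  seed = config$seed + 60L)
      list(onsets = detect_onsets(rec$whisk), mi = cmp)
    })
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# Write the tabular parts of a pipeline result plus a JSON summary.
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  if (!is.null(res$likelihood)) tsv(res$likelihood, "likelihood_curve.tsv")
  if (!is.null(res$cell_coupling)) tsv(res$cell_coupling,
                                       "cell_coupling.tsv")
  if (!is.null(res$transition_graph)) tsv(res$transition_graph,
                                          "transition_graph.tsv")
  if (!is.null(res$decoding)) tsv(res$decoding, "decoding.tsv")
  if (!is.null(res$evoked)) {
    tsv(res$evoked$test, "evoked_test.tsv")
    tsv(res$evoked$control, "evoked_control.tsv")
  }
  if (!is.null(res$params))
    jsonlite::write_json(
      list(n_states = res$params$n_states,
           n_neurons = res$params$n_neurons,
           bin_width = res$params$bin_width,
           A = as.vector(t(res$params$A)),        # row-major
           lam = as.vector(t(res$params$lam))),   # neuron-major
      file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  summ <- list(
    n_states_analysis = res$config$n_states_analysis,
    seed = res$config$seed,
    one_state_loglik = if (!is.null(res$likelihood))
      attr(res$likelihood, "one_state"),
    decoding = res$decoding,
    n_onsets = if (!is.null(res$whisking))
      length(res$whisking$onsets),
    mi_states = if (!is.null(res$whisking) && !is.null(res$whisking$mi))
      res$whisking$mi$mi_states$mi,
    mi_lfp = if (!is.null(res$whisking) && !is.null(res$whisking$mi))
      res$whisking$mi$mi_lfp$mi)
  jsonlite::write_json(summ[!vapply(summ, is.null, logical(1))],
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(out_dir)
}
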