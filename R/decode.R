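#' Build a balanced LFP-state decoding dataset
#'
#' Samples one 40-ms bin per second (the bin whose left edge lies on the
#' second), labels it with the H/L state of the enclosing LFP window, and
#' extracts one of four spiking feature families: the summed population
#' count (`"summed"`), the population count vector (`"vector"`), the
#' inferred spiking-state representation (`"state"`, the posterior
#' probability vector by default or one-hot MAP states), or a single
#' neuron's count (`"single"`).  The majority class is subsampled without
#' replacement so both classes have equal counts (chance accuracy 50%).
#'
#' @param raster a [spike_raster()].
#' @param lfp an [lfp_state_series()].
#' @param feature_kind one of `"summed"`, `"vector"`, `"state"`,
#'   `"single"`.
#' @param model an [hmm_params()], required for `"state"` features.
#' @param neuron neuron index, required for `"single"` features.
#' @param state_encoding `"posterior"` (default) or `"onehot"`.
#' @param seed RNG seed (class balancing).
#' @return An object of class `decode_dataset`: `x` (samples x features),
#'   `y` (factor with levels `H`, `L`), `bins` (sampled bin indices).
#' @export
build_dataset <- function(raster, lfp, feature_kind = c("summed", "vector",
                                                        "state", "single"),
                          model = NULL, neuron = NULL,
                          state_encoding = c("posterior", "onehot"),
                          seed = NULL) {
  feature_kind <- match.arg(feature_kind)
  state_encoding <- match.arg(state_encoding)
  stopifnot(inherits(raster, "spike_raster"),
            inherits(lfp, "lfp_state_series"))
  per_sec <- round(1 / raster$bin_width)
  bins <- seq(1L, ncol(raster$counts), by = per_sec)
  sec <- (bins - 1L) %/% per_sec + 1L
  keep <- sec <= length(lfp$label)
  bins <- bins[keep]; sec <- sec[keep]
  y <- lfp$label[sec]
  x <- switch(feature_kind,
    summed = matrix(colSums(raster$counts[, bins, drop = FALSE]), ncol = 1),
    vector = t(raster$counts[, bins, drop = FALSE]),
    state = {
      if (is.null(model)) stop("`state` features require `model`")
      fb <- forward_backward(model, raster)
      if (state_encoding == "posterior") fb$gamma[bins, , drop = FALSE]
      else {
        ms <- fb$map_states[bins]
        diag(model$n_states)[ms, , drop = FALSE]
      }
    },
    single = {
      if (is.null(neuron)) stop("`single` features require `neuron`")
      matrix(raster$counts[neuron, bins], ncol = 1)
    })
  with_seed(seed, {
    n_h <- sum(y == "H"); n_l <- sum(y == "L")
    n_min <- min(n_h, n_l)
    if (n_min < 20L) stop("fewer than 20 samples in a class")
    keep_idx <- c(sample(which(y == "H"), n_min),
                  sample(which(y == "L"), n_min))
    keep_idx <- sort(keep_idx)
    structure(
      list(x = x[keep_idx, , drop = FALSE],
           y = factor(y[keep_idx], levels = c("H", "L")),
           bins = bins[keep_idx]),
      class = "decode_dataset")
  })
}

#' @export
print.decode_dataset <- function(x, ...) {
  cat(sprintf("decode_dataset: %d samples (%d H / %d L), %d features\n",
              nrow(x$x), sum(x$y == "H"), sum(x$y == "L"), ncol(x$x)))
  invisible(x)
}

# L2-regularized squared-hinge linear SVM (the differentiable member of
# the linear max-margin family), fit by BFGS on standardized features.
# No linear-SVM package is available in the target environment, so this
# small solver is provided in-package.
svm_linear_fit <- function(x, y, cost = 1) {
  yy <- ifelse(y == levels(y)[1L], 1, -1)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  p <- ncol(xs)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    xi <- pmax(0, 1 - yy * (drop(xs %*% w) + b))
    0.5 * sum(w^2) + cost * sum(xi^2)
  }
  grad <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    xi <- pmax(0, 1 - yy * (drop(xs %*% w) + b))
    gw <- w - 2 * cost * drop(crossprod(xs, yy * xi))
    gb <- -2 * cost * sum(yy * xi)
    c(gw, gb)
  }
  fit <- optim(rep(0, p + 1L), obj, grad, method = "BFGS",
               control = list(maxit = 500L, reltol = 1e-10))
  list(w = fit$par[seq_len(p)], b = fit$par[p + 1L], center = ctr,
       scale = scl, levels = levels(y))
}

svm_linear_predict <- function(fit, x) {
  xs <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  score <- drop(xs %*% fit$w) + fit$b
  factor(ifelse(score >= 0, fit$levels[1L], fit$levels[2L]),
         levels = fit$levels)
}

#' Cross-validated decoding of LFP state from spiking features
#'
#' Stratified k-fold cross-validation of a linear max-margin classifier
#' (L2-regularized squared-hinge loss) on a balanced [build_dataset()]
#' dataset.  Chance accuracy is 50% by construction.
#'
#' @param dataset a `decode_dataset`.
#' @param n_folds number of folds (default 5).
#' @param cost regularization weight `C` (default 1).
#' @param seed RNG seed (fold assignment).
#' @return A list: `accuracy` (mean over folds), `sd` (over folds),
#'   `fold_accuracy`.
#' @export
decode_lfp_state <- function(dataset, n_folds = 5L, cost = 1, seed = NULL) {
  stopifnot(inherits(dataset, "decode_dataset"))
  y <- dataset$y
  if (length(unique(y)) < 2L) stop("dataset has a single class")
  with_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    acc <- vapply(seq_len(n_folds), function(k) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L || !any(!tr))
        stop("degenerate fold; use fewer folds")
      fit <- svm_linear_fit(dataset$x[tr, , drop = FALSE], y[tr], cost)
      pred <- svm_linear_predict(fit, dataset$x[!tr, , drop = FALSE])
      mean(pred == y[!tr])
    }, numeric(1))
    list(accuracy = mean(acc), sd = sd(acc), fold_accuracy = acc)
  })
}

#' Permutation-null decoding accuracy
#'
#' Repeatedly permutes the feature rows against the labels and reruns the
#' cross-validated decoder, giving the empirical chance level (50% on a
#' balanced dataset).
#'
#' @param dataset a `decode_dataset`.
#' @param n_perm number of permutations (default 100).
#' @param n_folds,cost passed to [decode_lfp_state()].
#' @param seed RNG seed.
#' @return A list: `accuracy` (mean over permutations), `per_perm`.
#' @export
decode_permutation_null <- function(dataset, n_perm = 100L, n_folds = 5L,
                                    cost = 1, seed = NULL) {
  stopifnot(inherits(dataset, "decode_dataset"))
  with_seed(seed, {
    per <- vapply(seq_len(n_perm), function(r) {
      ds <- dataset
      ds$x <- ds$x[sample.int(nrow(ds$x)), , drop = FALSE]
      decode_lfp_state(ds, n_folds = n_folds, cost = cost)$accuracy
    }, numeric(1))
    list(accuracy = mean(per), per_perm = per)
  })
}
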