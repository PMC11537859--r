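# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.  seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stationary distribution of a row-stochastic matrix: leading left
# eigenvector, with a power-iteration fallback for defective cases.
stationary_dist <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  check_stochastic(A)
  if (nrow(A) == 1L) return(1)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  if (any(!is.finite(v)) || sum(abs(v)) < 1e-12 ||
      (min(v) < -1e-8 && max(v) > 1e-8)) {
    v <- rep(1 / nrow(A), nrow(A))
    for (k in seq_len(2000)) v <- drop(v %*% A)
  }
  v <- abs(v)
  v / sum(v)
}

check_stochastic <- function(A, tol = 1e-9) {
  if (any(A < -tol) || any(A > 1 + tol))
    stop("transition matrix entries must lie in [0, 1]")
  if (any(abs(rowSums(A) - 1) > tol))
    stop("transition matrix rows must sum to 1")
  invisible(A)
}

# All permutations of 1..n (n <= 8); used for exact state matching.
all_permutations <- function(n) {
  if (n > 8L) stop("exact permutation enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    }
  }
  out
}

# Match estimated states to reference states by minimizing the summed
# squared difference between rate columns over all permutations (exact
# assignment optimum for the sizes used here).
match_states <- function(lam_ref, lam_hat) {
  ns <- ncol(lam_ref)
  stopifnot(ncol(lam_hat) == ns)
  perms <- all_permutations(ns)
  cost <- apply(perms, 1L, function(p) sum((lam_ref - lam_hat[, p])^2))
  perms[which.min(cost), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
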