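#' @keywords internal
"_PACKAGE"

# Run code with a local RNG state. Leaves the caller's .Random.seed untouched
# so package functions are deterministic under `seed` without global side
# effects.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n as a matrix (n! rows). Used by the exact
# permutation mode of the Mantel test; guarded to small n.
all_permutations <- function(n) {
  if (n > 8L) stop("exact permutation enumeration limited to n <= 8", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- matrix(0L, nrow(sub), n)
    m[, k] <- n
    m[, -k] <- sub
    out[[k]] <- m
  }
  do.call(rbind, out)
}

# Two-sided permutation p-value with the +1 rule (observed statistic counts
# as one member of the null set).
perm_pvalue <- function(observed, null, two_sided = TRUE) {
  if (two_sided) {
    observed <- abs(observed)
    null <- abs(null)
  }
  (1 + sum(null >= observed - 1e-12)) / (length(null) + 1)
}

stop_if_not_square <- function(d, arg = "d") {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  invisible(TRUE)
}
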