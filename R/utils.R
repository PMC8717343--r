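#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible child seed from a parent seed and a stream label.
## Keeps derived seeds inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587) + 1L
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

## k-nearest-neighbour indices of (qx, qy) among data points (px, py),
## brute force in chunks; ties broken by point index (order() default).
## Returns an n_query x k index matrix.
nearest_k <- function(qx, qy, px, py, k, chunk = 512L) {
  n <- length(px)
  k <- min(k, n)
  nq <- length(qx)
  out <- matrix(NA_integer_, nq, k)
  i <- 1L
  while (i <= nq) {
    j <- min(i + chunk - 1L, nq)
    d2 <- outer(qx[i:j], px, "-")^2 + outer(qy[i:j], py, "-")^2
    out[i:j, ] <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
    i <- j + 1L
  }
  out
}

## Solve a (possibly ill-conditioned) symmetric-augmented linear system,
## falling back to the pseudo-inverse. Returns list(x, singular).
solve_safe <- function(A, b) {
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x))) {
    x <- tryCatch(pracma::pinv(A) %*% b, error = function(e) NULL)
    if (is.null(x)) return(list(x = rep(NA_real_, ncol(A)), singular = TRUE))
    return(list(x = drop(x), singular = TRUE))
  }
  list(x = drop(x), singular = FALSE)
}
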