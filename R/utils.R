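# Internal numerical and RNG helpers shared across modules.

#' Deterministic child seed for a replicate
#'
#' Monte-Carlo drivers in this package consume one root seed and derive a
#' child seed for every replicate, so that any single replicate can be
#' regenerated in isolation.  The scheme is `(root + 10007 * index) mod
#' (2^31 - 1)`: a fixed odd multiplier keeps neighbouring replicates apart in
#' seed space while staying inside R's 32-bit integer range.
#'
#' @param seed Integer root seed.
#' @param index Replicate index (1-based); may be a vector.
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, 1:3)
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) + 10007 * as.double(index)) %% (2^31 - 1))
}

# Run `expr` under `seed` if non-NULL, restoring the caller's RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Ordinary least squares via the normal equations with a QR fallback for
# diagnosing rank deficiency.  Returns coefficients, homoskedastic or
# heteroskedasticity-robust (HC0) standard errors, residuals and sigma2.
# Designs here are tall and well-conditioned (genotype dosages), so the
# Cholesky path is both fast and accurate.
ols_fit <- function(X, y, robust = FALSE) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) {
    stop("design has ", n, " rows but ", p, " columns; not identified", call. = FALSE)
  }
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) {
    qrX <- qr(X)
    if (qrX$rank < p) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
      stop("singular design; offending column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    stop("failed to factorize design cross-product", call. = FALSE)
  }
  XtXi <- chol2inv(R)
  beta <- drop(XtXi %*% crossprod(X, y))
  resid <- drop(y - X %*% beta)
  sigma2 <- sum(resid^2) / (n - p)
  if (robust) {
    meat <- crossprod(X * resid)
    vcov <- XtXi %*% meat %*% XtXi
    se <- sqrt(diag(vcov))
  } else {
    se <- sqrt(sigma2 * diag(XtXi))
  }
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se, sigma2 = sigma2, residuals = resid,
       df = n - p, XtXi = XtXi)
}

# Weighted median of `x` with non-negative weights: the point where the
# cumulative weight first reaches half the total.  If the crossing happens
# exactly at half, average with the next point (standard convention); among
# exactly tied solutions the smaller |x| is preferred by the caller.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (isTRUE(all.equal(cw[i], 0.5)) && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

# Format doubles so that read.table round-trips them bit-exactly.
fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

two_sided_p <- function(est, se) 2 * pnorm(-abs(est / se))

`%||%` <- function(a, b) if (is.null(a)) b else a
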