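# Steps 1-2 of the collider-correction algorithm: turn individual-level data
# into the summary statistics every downstream estimator consumes.
#
# Step 1 regresses Y on X and all SNPs jointly (plus covariates): the
# coefficient on X is the collider-biased observational association beta*,
# the SNP coefficients are the collider-biased direct associations alpha*_j.
# Step 2 regresses X on all SNPs jointly to get the first-stage associations
# beta_xg_j.  Conditioning on X is what makes the errors of alpha*_j
# independent of the first-stage errors - the property every two-sample
# estimator downstream relies on.

new_collider_summary <- function(snp_ids, beta_xg, se_xg, alpha_star,
                                 se_alpha_star, beta_star, se_beta_star,
                                 n, k, meta = list()) {
  # se_xg may be zero (the NOME limit, e.g. synthetic summaries); the
  # response SEs enter as weights and must be strictly positive
  stopifnot(length(beta_xg) == k, length(se_xg) == k,
            length(alpha_star) == k, length(se_alpha_star) == k,
            all(se_xg >= 0), all(se_alpha_star > 0), se_beta_star > 0)
  structure(list(snp_ids = as.character(snp_ids),
                 beta_xg = as.numeric(beta_xg), se_xg = as.numeric(se_xg),
                 alpha_star = as.numeric(alpha_star),
                 se_alpha_star = as.numeric(se_alpha_star),
                 beta_star = beta_star, se_beta_star = se_beta_star,
                 n = n, k = k, meta = meta),
            class = "collider_summary")
}

#' @export
print.collider_summary <- function(x, ...) {
  cat("<collider_summary> k =", x$k, " n =", x$n, "\n",
      " beta* =", signif(x$beta_star, 4),
      "(SE", paste0(signif(x$se_beta_star, 3), ")"), "\n")
  invisible(x)
}

# Common design-matrix assembly and missing-value policy.
check_missing <- function(data, complete_cases) {
  M <- cbind(data$exposure, data$outcome, data$genotypes, data$covariates)
  keep <- stats::complete.cases(M)
  if (all(keep)) return(seq_len(nrow(M)))
  if (!complete_cases) {
    stop(sum(!keep), " row(s) contain missing values; ",
         "set complete_cases = TRUE to drop them explicitly", call. = FALSE)
  }
  message("dropping ", sum(!keep), " incomplete row(s) of ", nrow(M))
  which(keep)
}

#' Collider-biased summary statistics (algorithm steps 1-2)
#'
#' Fits two multivariable ordinary-least-squares regressions: the outcome on
#' the exposure and all SNPs jointly (yielding the conditional observational
#' coefficient \eqn{\hat\beta^*} and the collider-biased direct associations
#' \eqn{\hat\alpha_j^*}), and the exposure on all SNPs jointly (yielding the
#' first-stage associations \eqn{\hat\beta_{XGj}}).  Covariates, when
#' supplied, enter both regressions identically.  The joint first stage is
#' what makes the collider-corrected IVW estimate asymptotically equivalent
#' to two-stage least squares; set `first_stage = "per_snp"` for
#' user-supplied data with pre-pruned independent SNPs if marginal
#' associations are preferred.
#'
#' @param data An `individual_data` object (see [simulate_dataset()],
#'   [read_individual_data()]).
#' @param covariates Optional n x c numeric matrix, overriding
#'   `data$covariates`.
#' @param robust Use heteroskedasticity-robust (HC0) standard errors
#'   (default plain OLS).
#' @param complete_cases Drop rows with missing values (with a message)
#'   instead of erroring.
#' @param first_stage `"joint"` (default) or `"per_snp"`.
#' @return A `collider_summary`.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n = 1000, k = 10, seed = 1))
#' s <- collider_summary(d)
#' s$beta_star
collider_summary <- function(data, covariates = NULL, robust = FALSE,
                             complete_cases = FALSE,
                             first_stage = c("joint", "per_snp")) {
  stopifnot(inherits(data, "individual_data"))
  first_stage <- match.arg(first_stage)
  covariates <- covariates %||% data$covariates
  keep <- check_missing(
    new_individual_data(data$genotypes, data$exposure, data$outcome,
                        covariates = covariates),
    complete_cases)
  G <- data$genotypes[keep, , drop = FALSE]
  X <- data$exposure[keep]
  Y <- data$outcome[keep]
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE] else NULL
  n <- length(Y)
  k <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(k))
  nc <- if (is.null(C)) 0L else ncol(C)
  if (n <= k + 2 + nc) stop("too few rows (", n, ") for ", k,
                                 " SNPs plus exposure and covariates", call. = FALSE)
  D_y <- cbind(`(intercept)` = 1, x = X, G, C)
  fit_y <- ols_fit(D_y, Y, robust = robust)
  D_x <- cbind(`(intercept)` = 1, G, C)
  if (first_stage == "joint") {
    fit_x <- ols_fit(D_x, X, robust = robust)
    bxg <- fit_x$coef[colnames(G)]
    se_xg <- fit_x$se[colnames(G)]
  } else {
    bxg <- se_xg <- numeric(k)
    for (j in seq_len(k)) {
      f <- ols_fit(cbind(1, G[, j], C), X, robust = robust)
      bxg[j] <- f$coef[2]
      se_xg[j] <- f$se[2]
    }
  }
  new_collider_summary(
    snp_ids = colnames(G),
    beta_xg = unname(bxg), se_xg = unname(se_xg),
    alpha_star = unname(fit_y$coef[colnames(G)]),
    se_alpha_star = unname(fit_y$se[colnames(G)]),
    beta_star = unname(fit_y$coef["x"]), se_beta_star = unname(fit_y$se["x"]),
    n = n, k = k,
    meta = list(family = "gaussian",
                covariates = if (is.null(C)) character(0) else colnames(C),
                robust = robust, first_stage = first_stage)
  )
}

#' Standard (marginal) per-SNP summary statistics
#'
#' Per-SNP simple regressions of the outcome on each SNP and of the exposure
#' on each SNP (plus covariates) - the inputs of the "standard" one-sample
#' IVW/Egger/LAD comparators, in which the SNP-outcome associations are
#' *not* conditioned on the exposure and whose errors are therefore
#' correlated with the first-stage errors.
#'
#' @inheritParams collider_summary
#' @return An object of class `standard_summary` with per-SNP `beta_xg`,
#'   `se_xg`, `beta_yg`, `se_yg`, plus `n`, `k`, `snp_ids`.
#' @export
standard_summary <- function(data, covariates = NULL, robust = FALSE,
                             complete_cases = FALSE) {
  stopifnot(inherits(data, "individual_data"))
  covariates <- covariates %||% data$covariates
  keep <- check_missing(
    new_individual_data(data$genotypes, data$exposure, data$outcome,
                        covariates = covariates),
    complete_cases)
  G <- data$genotypes[keep, , drop = FALSE]
  X <- data$exposure[keep]
  Y <- data$outcome[keep]
  C <- if (!is.null(covariates)) as.matrix(covariates)[keep, , drop = FALSE] else NULL
  n <- length(Y)
  k <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(k))
  byg <- se_yg <- bxg <- se_xg <- numeric(k)
  if (is.null(C) && !robust) {
    # closed-form simple regressions, vectorized across SNPs
    Gc <- scale(G, scale = FALSE)
    ssg <- unname(colSums(Gc^2))
    for (v in c("x", "y")) {
      z <- if (v == "x") X else Y
      b <- unname(colSums(Gc * z) / ssg)
      # residual variance of z on (1, G_j)
      rss <- sum((z - mean(z))^2) - b^2 * ssg
      s2 <- rss / (n - 2)
      if (v == "x") { bxg <- b; se_xg <- sqrt(s2 / ssg) }
      else          { byg <- b; se_yg <- sqrt(s2 / ssg) }
    }
  } else {
    for (j in seq_len(k)) {
      fx <- ols_fit(cbind(1, G[, j], C), X, robust = robust)
      fy <- ols_fit(cbind(1, G[, j], C), Y, robust = robust)
      bxg[j] <- fx$coef[2]; se_xg[j] <- fx$se[2]
      byg[j] <- fy$coef[2]; se_yg[j] <- fy$se[2]
    }
  }
  structure(list(snp_ids = colnames(G), beta_xg = bxg, se_xg = se_xg,
                 beta_yg = byg, se_yg = se_yg, n = n, k = k),
            class = "standard_summary")
}

#' Artificial split-sample (two-sample style) summary statistics
#'
#' Randomly partitions the rows, estimates SNP-exposure associations in one
#' part and SNP-outcome associations in the other, mimicking a two-sample
#' design on one-sample data.  This guarantees residual-error independence
#' at the cost of halving the effective sample size for each set of
#' associations; it serves as the efficiency comparator for
#' collider-correction.
#'
#' @inheritParams collider_summary
#' @param fraction Fraction of rows assigned to the exposure-association
#'   split (default 0.5).
#' @param seed Optional seed for the partition.
#' @return An object of class `split_summary` with per-SNP `beta_xg`,
#'   `se_xg` (from split A), `beta_yg`, `se_yg` (from split B), the split
#'   sizes, and the row indices used.
#' @export
split_sample_summary <- function(data, fraction = 0.5, seed = NULL,
                                 covariates = NULL) {
  stopifnot(inherits(data, "individual_data"),
            fraction > 0, fraction < 1)
  n <- length(data$exposure)
  k <- ncol(data$genotypes)
  n_a <- floor(n * fraction)
  if (n_a <= k + 2 || n - n_a <= k + 2) {
    stop("split too small to fit the per-SNP regressions", call. = FALSE)
  }
  idx_a <- with_seed_if(seed, sort(sample.int(n, n_a)))
  idx_b <- setdiff(seq_len(n), idx_a)
  sub <- function(idx) new_individual_data(
    data$genotypes[idx, , drop = FALSE], data$exposure[idx],
    data$outcome[idx],
    covariates = if (!is.null(covariates)) as.matrix(covariates)[idx, , drop = FALSE] else NULL)
  sa <- standard_summary(sub(idx_a))
  sb <- standard_summary(sub(idx_b))
  structure(list(snp_ids = sa$snp_ids,
                 beta_xg = sa$beta_xg, se_xg = sa$se_xg,
                 beta_yg = sb$beta_yg, se_yg = sb$se_yg,
                 n_a = length(idx_a), n_b = length(idx_b), k = k,
                 idx_a = idx_a, idx_b = idx_b),
            class = c("split_summary", "standard_summary"))
}

# Uniform accessor used by the slope estimators and SIMEX: the regression
# response is alpha* for collider summaries and beta_yg for standard/split
# summaries (for which the fitted slope directly estimates beta).
mr_xy <- function(summary) {
  if (inherits(summary, "collider_summary")) {
    list(x = summary$beta_xg, sx = summary$se_xg,
         y = summary$alpha_star, sy = summary$se_alpha_star, k = summary$k)
  } else if (inherits(summary, "standard_summary")) {
    list(x = summary$beta_xg, sx = summary$se_xg,
         y = summary$beta_yg, sy = summary$se_yg, k = summary$k)
  } else {
    stop("unsupported summary object of class ",
         paste(class(summary), collapse = "/"), call. = FALSE)
  }
}

#' Residual-independence diagnostic on simulated data
#'
#' For a simulated dataset with attached truth, computes the across-SNP
#' sample correlation between the first-stage estimation errors
#' \eqn{\hat\delta_j = \hat\beta_{XGj} - \beta_{XGj}} and (a) the standard
#' SNP-outcome residuals
#' \eqn{\hat\epsilon_{YGj} = \hat\beta_{YGj} - \alpha_j - \beta\beta_{XGj}}
#' and (b) the collider-correction residuals
#' \eqn{\hat\theta_j = \hat\alpha_j^* - \alpha_j - (\beta-\beta^*)\beta_{XGj}}.
#' Averaged over replicates, (a) reflects the structural residual
#' correlation while (b) is zero - the property that lets any two-sample
#' method be applied at step 3.
#'
#' @param data A simulated `individual_data` with `truth`.
#' @return List with `corr_standard` and `corr_collider`.
#' @export
residual_independence <- function(data) {
  stopifnot(inherits(data, "individual_data"), !is.null(data$truth))
  tr <- data$truth
  cs <- collider_summary(data)
  ss <- standard_summary(data)
  delta <- cs$beta_xg - tr$effects$beta_xg
  eps <- ss$beta_yg - tr$effects$alpha - tr$config$beta * tr$effects$beta_xg
  theta <- cs$alpha_star - tr$effects$alpha -
    (tr$config$beta - tr$beta_star) * tr$effects$beta_xg
  list(corr_standard = cor(delta, eps), corr_collider = cor(delta, theta))
}
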