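# Step 3 of the algorithm: estimate the collider-correction slope
# (beta - beta*) by regressing the collider-biased SNP-outcome associations
# on the first-stage associations under a chosen loss / pleiotropy
# assumption; and step 4: add the slope back to the observational
# coefficient.  Every estimator consumes the uniform (x, sx, y, sy)
# interface of mr_xy(), so the same code also fits the "standard" and
# split-sample comparator arms (whose fitted slope estimates beta itself).

new_slope_estimate <- function(method, slope, se, phi = 1, df = NA_integer_,
                               intercept = NULL, se_intercept = NULL,
                               converged = TRUE, extras = list()) {
  structure(list(method = method, slope = slope, se_slope = se, phi = phi,
                 df = df, intercept = intercept, se_intercept = se_intercept,
                 converged = converged, extras = extras),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat("<slope_estimate> ", x$method, ": slope =", signif(x$slope, 4),
      "(SE", paste0(signif(x$se_slope, 3), ")"),
      if (!is.null(x$intercept)) paste(" intercept =", signif(x$intercept, 4)) else "",
      " phi =", signif(x$phi, 3),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

check_k <- function(xy, min_k, method) {
  if (xy$k < min_k) stop(method, " requires at least ", min_k, " SNPs", call. = FALSE)
  if (any(xy$sy <= 0) || any(!is.finite(xy$sy))) {
    stop("all response standard errors must be positive and finite", call. = FALSE)
  }
}

#' Collider-corrected IVW slope
#'
#' Weighted least squares of the (collider-biased) SNP-outcome associations
#' on the SNP-exposure associations through the origin, with
#' inverse-variance weights \eqn{1/\sigma^2_{\alpha^*_j}}.  Under
#' multiplicative random effects the residual overdispersion
#' \eqn{\phi = RSS_w/(k-1)} inflates the slope variance whenever it exceeds
#' 1 (it is floored at 1, the fixed-effect value).
#'
#' @param summary A `collider_summary` (slope estimates
#'   \eqn{\beta-\beta^*}) or `standard_summary`/`split_summary` (slope
#'   estimates \eqn{\beta} directly).
#' @param random_effects Apply the multiplicative overdispersion factor
#'   (default TRUE).
#' @return A `slope_estimate`.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n = 2000, k = 20, seed = 3))
#' ivw_slope(collider_summary(d))
ivw_slope <- function(summary, random_effects = TRUE) {
  xy <- mr_xy(summary)
  check_k(xy, 2L, "IVW")
  w <- 1 / xy$sy^2
  sxx <- sum(w * xy$x^2)
  slope <- sum(w * xy$x * xy$y) / sxx
  rss <- sum(w * (xy$y - slope * xy$x)^2)
  phi_raw <- rss / (xy$k - 1)
  phi <- if (random_effects) max(1, phi_raw) else 1
  new_slope_estimate("ivw", slope, sqrt(phi / sxx), phi = phi,
                     df = xy$k - 1L,
                     extras = list(phi_raw = phi_raw, rss_w = rss))
}

#' Collider-corrected MR-Egger slope
#'
#' Weighted least squares of the SNP-outcome associations on an intercept
#' and the SNP-exposure associations.  The free intercept absorbs
#' directional (non-zero mean) pleiotropy; the slope is consistent under
#' the InSIDE assumption.  Overdispersion is handled as in [ivw_slope()]
#' with k - 2 degrees of freedom.
#'
#' @inheritParams ivw_slope
#' @return A `slope_estimate` with `intercept` and `se_intercept`.
#' @export
egger_slope <- function(summary, random_effects = TRUE) {
  xy <- mr_xy(summary)
  check_k(xy, 3L, "MR-Egger")
  if (max(xy$x) - min(xy$x) < .Machine$double.eps^0.5 * max(abs(xy$x), 1)) {
    stop("SNP-exposure associations are (near-)constant; ",
         "Egger design is collinear", call. = FALSE)
  }
  w <- 1 / xy$sy^2
  X <- cbind(1, xy$x)
  XtWX <- crossprod(X, w * X)
  XtWXi <- solve(XtWX)
  b <- drop(XtWXi %*% crossprod(X, w * xy$y))
  rss <- sum(w * (xy$y - drop(X %*% b))^2)
  phi_raw <- rss / (xy$k - 2)
  phi <- if (random_effects) max(1, phi_raw) else 1
  se <- sqrt(phi * diag(XtWXi))
  new_slope_estimate("egger", b[2], se[2], phi = phi, df = xy$k - 2L,
                     intercept = b[1], se_intercept = se[1],
                     extras = list(phi_raw = phi_raw, rss_w = rss))
}

#' Collider-corrected LAD (least-absolute-deviation) slope
#'
#' Minimizes \eqn{\sum_j |y_j - s\,x_j| / \sigma_{y_j}} over the slope `s`
#' with no intercept: the L1 analogue of [ivw_slope()], robust to a
#' minority of InSIDE-violating SNPs (the spirit of the weighted-median
#' estimator, but expressed as a regression model so SIMEX applies).  The
#' minimizer of a weighted L1 line through the origin is a weighted median
#' of the per-SNP ratios \eqn{y_j/x_j} with weights \eqn{|x_j|/\sigma_{y_j}}
#' and is computed exactly; exact ties are broken towards the smallest
#' |slope|.  The standard error comes from a nonparametric bootstrap over
#' SNPs.
#'
#' @inheritParams ivw_slope
#' @param B Bootstrap replicates for the SE (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A `slope_estimate`.
#' @export
lad_slope <- function(summary, B = 1000, seed = NULL) {
  xy <- mr_xy(summary)
  check_k(xy, 2L, "LAD")
  # The weighted L1 loss is piecewise linear in s with breakpoints at the
  # ratios y_j/x_j; its minimizer is the weighted median of the ratios with
  # weights |x_j|/sy_j.  When the weighted median falls on a flat segment
  # (cumulative weight exactly half), every point of the segment is optimal
  # and the point closest to zero is returned (smallest-|slope| tie-break).
  fit1 <- function(x, sy, y) {
    use <- abs(x) > 0
    if (!any(use)) return(NA_real_)
    r <- y[use] / x[use]
    w <- abs(x[use]) / sy[use]
    o <- order(r)
    r <- r[o]
    w <- w[o]
    cw <- cumsum(w) / sum(w)
    i <- which(cw >= 0.5 - 1e-12)[1L]
    if (abs(cw[i] - 0.5) < 1e-12 && i < length(r)) {
      min(max(0, r[i]), r[i + 1L])  # clamp 0 into the flat interval
    } else {
      r[i]
    }
  }
  slope <- fit1(xy$x, xy$sy, xy$y)
  boot <- if (B > 0) {
    with_seed_if(seed, {
      vapply(seq_len(B), function(b) {
        i <- sample.int(xy$k, replace = TRUE)
        fit1(xy$x[i], xy$sy[i], xy$y[i])
      }, 0)
    })
  } else {
    numeric(0)
  }
  se <- if (B > 0) sd(boot, na.rm = TRUE) else NA_real_
  new_slope_estimate("lad", slope, se, phi = 1, df = xy$k - 1L,
                     converged = is.finite(slope),
                     extras = list(B = B, boot_failures = sum(!is.finite(boot))))
}

# Tukey biweight rho, psi and the standardizing constant
# delta = E[psi_c(Z) Z] under Z ~ N(0,1), used to keep the profiled
# overdispersion estimate consistent when residuals are penalized.
tukey_rho <- function(r, c = 4.685) {
  ifelse(abs(r) <= c, c^2 / 6 * (1 - (1 - (r / c)^2)^3), c^2 / 6)
}
tukey_psi <- function(r, c = 4.685) {
  ifelse(abs(r) <= c, r * (1 - (r / c)^2)^2, 0)
}
tukey_delta <- function(c = 4.685) {
  integrate(function(z) tukey_psi(z, c) * z * stats::dnorm(z),
            -Inf, Inf)$value
}

# Standardized profile residuals of the extended model: the variance of
# y_j - s x_j is s^2 sx_j^2 + sy_j^2 + tau2 once first-stage uncertainty
# and (optionally) a pleiotropy variance component are acknowledged.
profile_resid <- function(s, tau2, xy) {
  (xy$y - s * xy$x) / sqrt(s^2 * xy$sx^2 + xy$sy^2 + tau2)
}

#' LIML / RAPS-style profile slope
#'
#' Estimates the slope from the extended model in which the residual
#' standard deviation \eqn{\sqrt{s^2\sigma^2_{XGj} + \sigma^2_{y_j} +
#' z\,\sigma^2_{\alpha^*}}} acknowledges uncertainty in the SNP-exposure
#' associations, making the estimator weak-instrument robust without SIMEX.
#'
#' With `z = 0` the pleiotropy variance is fixed at zero and the weighted
#' sum of squared standardized residuals is minimized over the slope alone:
#' the summary-data LIML estimator, whose minimized objective is the exact
#' Q statistic (see [exact_q()]).  With `z = 1` the overdispersion
#' \eqn{\tau^2 = \sigma^2_{\alpha^*}} is profiled alongside the slope using
#' robustified estimating equations with a Tukey biweight
#' \eqn{\psi}-function (a RAPS-style fit): \eqn{\tau^2} solves
#' \eqn{\sum_j \psi(r_j) r_j = k\,E[\psi(Z)Z]} and the slope solves
#' \eqn{\sum_j \psi(r_j)\, \partial r_j/\partial s = 0}.  The search runs
#' over `slope_ivw` +/- 10 standard errors with multiple starts; all roots
#' found are reported in `extras$roots` and the one with the smallest
#' robust objective is returned (profile likelihoods of this kind can be
#' multimodal, which is flagged rather than hidden).
#'
#' @inheritParams ivw_slope
#' @param z 0 (LIML) or 1 (RAPS-style with profiled overdispersion).
#' @param penalization Residual penalization for `z = 1`; only
#'   `"tukey"` is implemented.
#' @param tukey_c Tukey biweight tuning constant (default 4.685, the
#'   conventional 95%-efficiency value).
#' @param n_starts Number of search subintervals/starts (default 5).
#' @return A `slope_estimate`; `extras` carries `tau2` and all local
#'   solutions.
#' @export
liml_raps_slope <- function(summary, z = 0, penalization = "tukey",
                            tukey_c = 4.685, n_starts = 5) {
  stopifnot(z %in% c(0, 1))
  penalization <- match.arg(penalization, "tukey")
  xy <- mr_xy(summary)
  check_k(xy, 2L, "LIML/RAPS")
  anchor <- ivw_slope(summary)
  lo <- anchor$slope - 10 * anchor$se_slope
  hi <- anchor$slope + 10 * anchor$se_slope

  if (z == 0) {
    obj <- function(s) sum(profile_resid(s, 0, xy)^2)
    # piecewise optimize over n_starts subintervals, keep every local min
    cuts <- seq(lo, hi, length.out = n_starts + 1)
    locs <- lapply(seq_len(n_starts), function(i) {
      optimize(obj, c(cuts[i], cuts[i + 1]), tol = 1e-10)
    })
    vals <- vapply(locs, `[[`, 0, "objective")
    mins <- vapply(locs, `[[`, 0, "minimum")
    s_hat <- mins[which.min(vals)]
    converged <- s_hat > lo + 1e-6 && s_hat < hi - 1e-6
    # curvature-based SE: the objective is a -2 log-likelihood profile
    h <- max(1e-6, 1e-4 * abs(s_hat))
    q2 <- (obj(s_hat + h) - 2 * obj(s_hat) + obj(s_hat - h)) / h^2
    se <- if (q2 > 0) sqrt(2 / q2) else NA_real_
    return(new_slope_estimate("liml", s_hat, se, phi = 1, df = xy$k - 1L,
                              converged = converged,
                              extras = list(q_min = obj(s_hat), tau2 = 0,
                                            roots = s_hat)))
  }

  delta <- tukey_delta(tukey_c)
  tau2_for <- function(s) {
    g <- function(t2) sum(tukey_psi(profile_resid(s, t2, xy), tukey_c) *
                            profile_resid(s, t2, xy)) - xy$k * delta
    if (g(0) <= 0) return(0)
    upper <- max(xy$sy^2)
    while (g(upper) > 0 && upper < 1e8 * max(xy$sy^2)) upper <- upper * 10
    if (g(upper) > 0) return(upper)
    uniroot(g, c(0, upper), tol = 1e-12)$root
  }
  score <- function(s) {
    t2 <- tau2_for(s)
    r <- profile_resid(s, t2, xy)
    v <- sqrt(s^2 * xy$sx^2 + xy$sy^2 + t2)
    drds <- (-xy$x * v - (xy$y - s * xy$x) * s * xy$sx^2 / v) / v^2
    sum(tukey_psi(r, tukey_c) * drds)
  }
  robust_obj <- function(s) sum(tukey_rho(profile_resid(s, tau2_for(s), xy), tukey_c))
  grid <- seq(lo, hi, length.out = 20 * n_starts + 1)
  sc <- vapply(grid, score, 0)
  flips <- which(sc[-1] * sc[-length(sc)] < 0)
  roots <- vapply(flips, function(i) {
    uniroot(score, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  }, 0)
  if (length(roots) == 0) {
    return(new_slope_estimate("raps", anchor$slope, anchor$se_slope,
                              phi = anchor$phi, df = xy$k - 1L,
                              converged = FALSE,
                              extras = list(tau2 = NA_real_, roots = numeric(0))))
  }
  objs <- vapply(roots, robust_obj, 0)
  s_hat <- roots[which.min(objs)]
  t2_hat <- tau2_for(s_hat)
  # sandwich SE from the estimating equation for s at the profiled tau2
  r <- profile_resid(s_hat, t2_hat, xy)
  v <- sqrt(s_hat^2 * xy$sx^2 + xy$sy^2 + t2_hat)
  drds <- (-xy$x * v - (xy$y - s_hat * xy$x) * s_hat * xy$sx^2 / v) / v^2
  h <- max(1e-6, 1e-4 * abs(s_hat))
  A <- (score(s_hat + h) - score(s_hat - h)) / (2 * h)
  Bv <- sum((tukey_psi(r, tukey_c) * drds)^2)
  se <- if (is.finite(A) && A != 0) sqrt(Bv) / abs(A) else NA_real_
  new_slope_estimate("raps", s_hat, se, phi = 1, df = xy$k - 1L,
                     converged = TRUE,
                     extras = list(tau2 = t2_hat, roots = roots,
                                   root_objectives = objs))
}

#' Two-stage least squares on individual-level data
#'
#' The classic one-sample IV estimator: regress the exposure on all SNPs
#' jointly (plus covariates), then the outcome on the genetically predicted
#' exposure, with the second-stage standard error computed from the
#' structural residuals \eqn{Y - \hat\beta X} (the usual TSLS correction).
#' With mutually independent SNPs this is asymptotically equivalent to the
#' collider-corrected IVW causal estimate; it serves as the comparator arm.
#'
#' @inheritParams collider_summary
#' @return A `causal_estimate` with method `"tsls"`.
#' @export
tsls <- function(data, covariates = NULL, complete_cases = FALSE) {
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
  D1 <- cbind(1, G, C)
  f1 <- ols_fit(D1, X)
  Xhat <- drop(D1 %*% f1$coef)
  D2 <- cbind(`(intercept)` = 1, xhat = Xhat, C)
  f2 <- ols_fit(D2, Y)
  b <- unname(f2$coef["xhat"])
  # TSLS-corrected second-stage variance: residuals use the observed X
  D2x <- D2
  D2x[, "xhat"] <- X
  resid <- drop(Y - D2x %*% f2$coef)
  sigma2 <- sum(resid^2) / (n - ncol(D2))
  se <- sqrt(sigma2 * f2$XtXi[2, 2])  # column 2 is xhat
  new_causal_estimate(beta_hat = b, se = se, method = "tsls",
                      components = list(first_stage_f = mean(f1$coef[-1]^2 / f1$se[-1]^2)))
}

new_causal_estimate <- function(beta_hat, se, method, components = list()) {
  structure(list(beta_hat = beta_hat, se = se,
                 p_value = two_sided_p(beta_hat, se),
                 method = method, components = components),
            class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat("<causal_estimate> ", x$method, ": beta =", signif(x$beta_hat, 4),
      "(SE", paste0(signif(x$se, 3), ","),
      "p =", paste0(signif(x$p_value, 3), ")"), "\n")
  invisible(x)
}

#' Causal estimate from a collider-correction slope (algorithm step 4)
#'
#' Adds the fitted collider-correction slope back to the conditional
#' observational coefficient:
#' \eqn{\hat\beta = \hat\beta^* + \widehat{\beta-\beta^*}}.  The default
#' standard error combines the two components as if independent,
#' \eqn{\sqrt{SE(\hat\beta^*)^2 + SE(\widehat{\beta-\beta^*})^2}}; see
#' [causal_bootstrap()] for a paired bootstrap that resamples individuals
#' through all four steps instead.
#'
#' @param slope_est A `slope_estimate` fitted on `summary`.
#' @param summary The `collider_summary` the slope was fitted on.
#' @param df Use a t reference with `slope_est$df` degrees of freedom for
#'   the p-value instead of the normal (default FALSE).
#' @return A `causal_estimate`.
#' @export
causal_estimate <- function(slope_est, summary, df = FALSE) {
  stopifnot(inherits(slope_est, "slope_estimate"),
            inherits(summary, "collider_summary"))
  beta_hat <- summary$beta_star + slope_est$slope
  se <- sqrt(summary$se_beta_star^2 + slope_est$se_slope^2)
  out <- new_causal_estimate(
    beta_hat, se, method = slope_est$method,
    components = list(beta_star = summary$beta_star,
                      se_beta_star = summary$se_beta_star,
                      slope = slope_est$slope,
                      se_slope = slope_est$se_slope,
                      phi = slope_est$phi,
                      converged = slope_est$converged))
  if (df && is.finite(slope_est$df) && slope_est$df > 0) {
    out$p_value <- 2 * stats::pt(-abs(beta_hat / se), df = slope_est$df)
  }
  out
}

#' Paired-bootstrap causal estimate
#'
#' Resamples individuals with replacement and reruns algorithm steps 1-4
#' end to end, giving a standard error for the causal estimate that
#' respects the covariance between \eqn{\hat\beta^*} and the fitted slope
#' (the default in [causal_estimate()] ignores it).
#'
#' @param data An `individual_data`.
#' @param method Slope estimator: `"ivw"`, `"egger"` or `"lad"`.
#' @param B Bootstrap replicates (default 200).
#' @param seed Optional seed.
#' @param ... Passed to the slope estimator.
#' @return A `causal_estimate` whose `se` is the bootstrap standard
#'   deviation; `components$boot` holds the replicate estimates.
#' @export
causal_bootstrap <- function(data, method = c("ivw", "egger", "lad"),
                             B = 200, seed = NULL, ...) {
  method <- match.arg(method)
  fit <- function(d) {
    s <- collider_summary(d)
    sl <- switch(method,
                 ivw = ivw_slope(s, ...),
                 egger = egger_slope(s, ...),
                 lad = lad_slope(s, B = 50, ...))
    s$beta_star + sl$slope
  }
  point <- fit(data)
  n <- length(data$exposure)
  boot <- with_seed_if(seed, vapply(seq_len(B), function(b) {
    i <- sample.int(n, replace = TRUE)
    fit(new_individual_data(data$genotypes[i, , drop = FALSE],
                            data$exposure[i], data$outcome[i],
                            covariates = if (!is.null(data$covariates))
                              data$covariates[i, , drop = FALSE] else NULL))
  }, 0))
  new_causal_estimate(point, sd(boot), method = paste0(method, "+boot"),
                      components = list(boot = boot))
}
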