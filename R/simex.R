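# Simulation-extrapolation (SIMEX) adjustment for weak-instrument dilution.
# Because the collider-correction residuals are independent of the
# first-stage errors, uncertainty in the SNP-exposure associations acts as
# classical measurement error on the regressor: adding *more* synthetic
# error by a factor lambda dilutes the slope along a smooth curve, and
# extrapolating the fitted curve back to lambda = -1 recovers the estimate
# that would be obtained with error-free regressors (NOME satisfied).

#' SIMEX configuration
#'
#' @param lambdas Increasing grid of variance-inflation multipliers,
#'   starting at 0 (default `c(0, 0.5, 1, 1.5, 2)`).
#' @param B Pseudo-datasets per positive lambda (default 100).
#' @param extrapolant `"quadratic"` (default) or `"linear"` model in
#'   lambda for the extrapolation.
#' @param seed Optional seed for the pseudo-noise.
#' @param jackknife_se Estimate the SE of the extrapolated slope by
#'   delete-one jackknife over the B pseudo-replicates (default TRUE;
#'   otherwise the unadjusted estimator's SE is carried over).
#' @return A `simex_config` list.
#' @export
simex_config <- function(lambdas = c(0, 0.5, 1, 1.5, 2), B = 100,
                         extrapolant = c("quadratic", "linear"),
                         seed = NULL, jackknife_se = TRUE) {
  extrapolant <- match.arg(extrapolant)
  stopifnot(length(lambdas) >= 2, lambdas[1] == 0,
            all(diff(lambdas) > 0), B >= 2)
  structure(list(lambdas = lambdas, B = as.integer(B),
                 extrapolant = extrapolant,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 jackknife_se = jackknife_se),
            class = "simex_config")
}

# Fit the extrapolant to (lambda, value) and evaluate at lambda = -1.
simex_extrapolate <- function(lambdas, values, extrapolant = "quadratic") {
  df <- data.frame(l = lambdas, v = values)
  fit <- if (extrapolant == "quadratic" && length(lambdas) >= 3) {
    lm(v ~ l + I(l^2), data = df)
  } else {
    lm(v ~ l, data = df)
  }
  unname(predict(fit, data.frame(l = -1)))
}

#' SIMEX adjustment of a slope estimator
#'
#' For each inflation factor lambda > 0, generates `B` pseudo summaries with
#' SNP-exposure associations
#' \eqn{\hat\beta_{XGj} + \sqrt{\lambda}\,\sigma_{XGj} Z_{jb}}, refits the
#' chosen slope estimator on each, averages per lambda (the lambda = 0 arm
#' is the observed fit, anchoring the curve), fits the extrapolant to the
#' per-lambda means and evaluates it at lambda = -1.
#'
#' This is appropriate for the IVW, Egger and LAD estimators;
#' [liml_raps_slope()] handles first-stage uncertainty internally and needs
#' no SIMEX.  Applied to a *standard* (non-collider) one-sample summary the
#' procedure is anti-conservative - the errors there are correlated, not
#' classical - which is exactly the negative control the simulator
#' reproduces.
#'
#' @param summary A `collider_summary` (or `standard_summary` for the
#'   negative-control arm) with positive `se_xg`.
#' @param method `"ivw"`, `"egger"` or `"lad"`.
#' @param config A [simex_config()].
#' @param ... Passed to the underlying estimator (e.g. `random_effects`).
#' @return A `slope_estimate` with method `"<method>+simex"`; `extras`
#'   holds the lambda grid, per-lambda mean slopes and the unadjusted fit.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n = 2000, k = 20, seed = 5))
#' s <- collider_summary(d)
#' simex_adjust(s, "ivw", simex_config(B = 20, seed = 1))
simex_adjust <- function(summary, method = c("ivw", "egger", "lad"),
                         config = simex_config(), ...) {
  method <- match.arg(method)
  stopifnot(inherits(config, "simex_config"))
  xy <- mr_xy(summary)
  if (any(xy$sx < 0) || any(!is.finite(xy$sx))) {
    stop("SNP-exposure standard errors must be non-negative and finite", call. = FALSE)
  }
  fitter <- switch(method,
                   ivw = function(s) ivw_slope(s, ...),
                   egger = function(s) egger_slope(s, ...),
                   lad = function(s) lad_slope(s, B = 0, ...))
  base <- switch(method,
                 ivw = ivw_slope(summary, ...),
                 egger = egger_slope(summary, ...),
                 lad = lad_slope(summary, B = 200, seed = config$seed, ...))
  if (all(xy$sx == 0)) {
    # NOME already holds: pseudo-data would be identical at every lambda
    out <- base
    out$method <- paste0(method, "+simex")
    out$extras <- c(out$extras, list(lambdas = config$lambdas,
                                     lambda_means = rep(base$slope, length(config$lambdas)),
                                     unadjusted = base))
    return(out)
  }
  perturb <- function(lam) {
    s2 <- summary
    s2$beta_xg <- summary$beta_xg + sqrt(lam) * summary$se_xg * rnorm(xy$k)
    s2
  }
  lams <- config$lambdas
  pos <- lams[lams > 0]
  slopes <- with_seed_if(config$seed, {
    vapply(pos, function(lam) {
      vapply(seq_len(config$B), function(b) {
        tryCatch(fitter(perturb(lam))$slope, error = function(e) NA_real_)
      }, 0)
    }, numeric(config$B))
  })  # B x length(pos)
  fail_frac <- colMeans(!is.finite(slopes))
  if (any(fail_frac > 0.5)) {
    stop("estimator failed on more than half of the pseudo-datasets at lambda = ",
         paste(pos[fail_frac > 0.5], collapse = ", "), call. = FALSE)
  }
  lam_means <- c(base$slope, colMeans(slopes, na.rm = TRUE))
  est <- simex_extrapolate(lams, lam_means, config$extrapolant)
  se <- base$se_slope
  if (config$jackknife_se && config$B >= 3) {
    jk <- vapply(seq_len(config$B), function(b) {
      m <- c(base$slope, colMeans(slopes[-b, , drop = FALSE], na.rm = TRUE))
      simex_extrapolate(lams, m, config$extrapolant)
    }, 0)
    se_extrap <- sqrt((config$B - 1) / config$B * sum((jk - mean(jk))^2))
    # jackknife captures pseudo-noise in the extrapolation; combine with the
    # estimator's own sampling uncertainty
    se <- sqrt(base$se_slope^2 + se_extrap^2)
  }
  new_slope_estimate(paste0(method, "+simex"), est, se,
                     phi = base$phi, df = base$df,
                     intercept = base$intercept,
                     converged = base$converged,
                     extras = list(lambdas = lams, lambda_means = lam_means,
                                   unadjusted = base,
                                   failure_fraction = fail_frac))
}
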