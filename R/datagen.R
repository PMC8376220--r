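# Simulator for the linear structural model underlying collider-correction:
#   X_i = sum_j beta_xg[j] G_ij + e_Xi
#   Y_i = beta X_i + sum_j alpha[j] G_ij + e_Yi
# with (e_X, e_Y) jointly Gaussian through a shared standard-normal
# confounder, bi-allelic independent SNPs, and three pleiotropy regimes.

#' Simulation configuration for the structural model
#'
#' Builds and validates the full set of generative parameters.  The residual
#' (non-genetic) parts of exposure and outcome are parameterized directly by
#' their moments: standard deviations `resid_sd_x`, `resid_sd_y` and
#' correlation `resid_corr`.  A shared standard-normal confounder `U` with
#' loadings chosen to reproduce exactly these moments realizes the
#' correlation (see [confounder_moments()] to map loadings to moments).
#'
#' Defaults are calibrated so that, at the default causal effect
#' `beta = 0.5`, the conditional observational coefficient is
#' \eqn{\beta^* = \beta + \rho\,\sigma_Y/\sigma_X \approx 1.12} and the
#' collider-correction slope \eqn{\beta-\beta^* \approx -0.62}, and so that
#' the 50 SNPs jointly explain 1.5% of exposure variance with a
#' between-SNP effect spread giving \eqn{I^2_{GX}} rising from about 0.1 at
#' n = 5000 to about 0.5 at n = 50000.
#'
#' @param n Number of individuals.
#' @param k Number of SNPs (default 50).
#' @param maf Minor allele frequency, common to all SNPs (default 0.3).
#' @param beta True causal effect of X on Y (outcome units per exposure
#'   unit; default 0.5).
#' @param h2x Fraction of exposure variance explained jointly by the SNPs
#'   (default 0.015).
#' @param resid_sd_x,resid_sd_y Standard deviations of the non-genetic
#'   residual of X and of Y given X (defaults 1 and 0.69).
#' @param resid_corr Correlation between the two residuals, encoding the
#'   shared confounder (default 0.9).
#' @param scenario Pleiotropy regime: `"ivw"` (zero-mean alpha, independent
#'   of the SNP-exposure effects; InSIDE satisfied), `"egger"` (non-zero
#'   mean, independent; InSIDE satisfied), `"lad"` (the first
#'   `n_pleiotropic` alphas non-zero and correlated with the corresponding
#'   SNP-exposure effects; InSIDE violated on that subset), or `"fig3_toy"`
#'   (every alpha correlated with its SNP-exposure effect; InSIDE violated
#'   globally - the residual-independence demonstration preset).
#' @param beta_xg_mean,beta_xg_sd Moments of the Normal distribution the raw
#'   per-SNP exposure effects are drawn from before rescaling to `h2x`
#'   (defaults 0.026 and 0.007).
#' @param pleiotropy_mean,pleiotropy_sd Moments of the pleiotropic effects
#'   alpha_j (defaults depend on `scenario`).
#' @param inside_corr Target correlation between alpha_j and beta_xg_j for
#'   the InSIDE-violating SNPs (scenarios `"lad"`, `"fig3_toy"`).
#' @param n_pleiotropic Number of SNPs with non-zero alpha in scenario
#'   `"lad"` (default 15).
#' @param seed Integer RNG seed stored with the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [scenario_config()] for the named presets with scenario-specific
#'   defaults filled in, [simulate_dataset()] to draw data.
#' @export
sim_config <- function(n, k = 50, maf = 0.3, beta = 0.5, h2x = 0.015,
                       resid_sd_x = 1, resid_sd_y = 0.69, resid_corr = 0.9,
                       scenario = c("ivw", "egger", "lad", "fig3_toy"),
                       beta_xg_mean = 0.026, beta_xg_sd = 0.007,
                       pleiotropy_mean = NULL, pleiotropy_sd = NULL,
                       inside_corr = NULL, n_pleiotropic = 15,
                       seed = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    ivw      = list(pleiotropy_mean = 0,    pleiotropy_sd = 0.004, inside_corr = 0),
    egger    = list(pleiotropy_mean = 0.01, pleiotropy_sd = 0.004, inside_corr = 0),
    lad      = list(pleiotropy_mean = 0.01, pleiotropy_sd = 0.004, inside_corr = 0.5),
    fig3_toy = list(pleiotropy_mean = 0,    pleiotropy_sd = 0.004, inside_corr = 0.45)
  )
  cfg <- list(
    n = as.integer(n), k = as.integer(k), maf = maf, beta = beta, h2x = h2x,
    resid_sd_x = resid_sd_x, resid_sd_y = resid_sd_y, resid_corr = resid_corr,
    scenario = scenario, beta_xg_mean = beta_xg_mean, beta_xg_sd = beta_xg_sd,
    pleiotropy_mean = pleiotropy_mean %||% defaults$pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd %||% defaults$pleiotropy_sd,
    inside_corr = inside_corr %||% defaults$inside_corr,
    n_pleiotropic = if (scenario == "fig3_toy") as.integer(k)
                    else if (scenario == "lad") as.integer(n_pleiotropic)
                    else 0L,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(test, msg) if (!test) stop("invalid simulation config: ", msg, call. = FALSE)
  ok(cfg$n >= 1, "n must be >= 1")
  ok(cfg$k >= 2, "k must be >= 2")
  ok(cfg$maf >= 0 && cfg$maf < 0.5, "maf must lie in [0, 0.5)")
  ok(cfg$h2x >= 0 && cfg$h2x < 1, "h2x must lie in [0, 1)")
  ok(cfg$maf > 0 || cfg$h2x == 0, "h2x > 0 requires maf > 0")
  ok(cfg$resid_corr > -1 && cfg$resid_corr < 1, "resid_corr must lie in (-1, 1)")
  ok(cfg$resid_sd_x > 0 && cfg$resid_sd_y > 0, "residual sds must be positive")
  ok(abs(cfg$inside_corr) <= 1, "inside_corr must lie in [-1, 1]")
  ok(cfg$n_pleiotropic >= 0 && cfg$n_pleiotropic <= cfg$k,
     "n_pleiotropic must lie in [0, k]")
  invisible(cfg)
}

#' Named scenario presets matching the simulation studies
#'
#' Convenience wrapper around [sim_config()] that fills in the
#' scenario-specific defaults.  The `"fig3_toy"` preset additionally sets
#' `beta = 0`, `resid_sd_y = 1` and `resid_corr = 0.5`: it demonstrates the
#' residual-independence property under moderate confounding with InSIDE
#' violated across every SNP, and with a null causal effect the benchmark
#' correlation between first-stage and standard SNP-outcome residuals equals
#' the structural residual correlation of 0.5 exactly.
#'
#' @param scenario One of `"ivw"`, `"egger"`, `"lad"`, `"fig3_toy"`.
#' @param n Number of individuals.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
#' @examples
#' cfg <- scenario_config("ivw", n = 5000, seed = 1)
#' cfg$resid_corr
scenario_config <- function(scenario = c("ivw", "egger", "lad", "fig3_toy"),
                            n, ...) {
  scenario <- match.arg(scenario)
  extra <- list(...)
  if (scenario == "fig3_toy") {
    toy <- list(beta = 0, resid_sd_y = 1, resid_corr = 0.5)
    extra <- modifyList(toy, extra)
  }
  do.call(sim_config, c(list(n = n, scenario = scenario), extra))
}

#' Map confounder loadings to residual moments
#'
#' The structural model can equivalently be written with an explicit scalar
#' confounder `U` entering the exposure with loading `beta_ux` and the
#' outcome with loading `beta_uy`, plus independent noise terms.  Any such
#' triple maps to the bivariate residual moments used by [sim_config()];
#' this helper performs that mapping.
#'
#' @param beta_ux,beta_uy Loadings of the standard-normal confounder on
#'   exposure and outcome.
#' @param sd_ex,sd_ey Standard deviations of the independent noise terms.
#' @return List with `resid_sd_x`, `resid_sd_y`, `resid_corr`.
#' @export
#' @examples
#' confounder_moments(1, 1, 1, 1)  # correlation 0.5
confounder_moments <- function(beta_ux, beta_uy, sd_ex, sd_ey) {
  sx <- sqrt(beta_ux^2 + sd_ex^2)
  sy <- sqrt(beta_uy^2 + sd_ey^2)
  list(resid_sd_x = sx, resid_sd_y = sy,
       resid_corr = beta_ux * beta_uy / (sx * sy))
}

#' Generate a genotype dosage matrix
#'
#' Each entry is drawn independently as Binomial(2, maf): bi-allelic SNPs in
#' Hardy-Weinberg proportions, mutually uncorrelated (no linkage
#' disequilibrium).
#'
#' @param n,k Dimensions (individuals x SNPs).
#' @param maf Minor allele frequency in `[0, 0.5)`.
#' @param seed Optional seed.
#' @return An `n x k` integer matrix with entries in `{0, 1, 2}` and column
#'   names `g1..gk`.
#' @export
generate_genotypes <- function(n, k, maf = 0.3, seed = NULL) {
  if (n < 1 || k < 1) stop("invalid simulation config: non-positive dimensions", call. = FALSE)
  if (maf < 0 || maf >= 0.5) stop("invalid simulation config: maf must lie in [0, 0.5)", call. = FALSE)
  G <- with_seed_if(seed, matrix(rbinom(n * k, 2L, maf), nrow = n, ncol = k))
  colnames(G) <- paste0("g", seq_len(k))
  G
}

#' Draw true per-SNP effect vectors
#'
#' The SNP-exposure effects are drawn from Normal(`beta_xg_mean`,
#' `beta_xg_sd^2`) and rescaled by a common factor so that the variance they
#' explain is exact:
#' \eqn{\sum_j \beta_{XGj}^2 \cdot 2\,maf(1-maf) = h2x\,\sigma_X^2/(1-h2x)},
#' i.e. the SNPs explain exactly `h2x` of the total exposure variance.
#' Pleiotropic effects are drawn per scenario: `"ivw"` mean-zero and
#' independent of the exposure effects; `"egger"` non-zero mean,
#' independent; `"lad"`/`"fig3_toy"` correlated with the corresponding
#' exposure effects at `inside_corr` on the pleiotropic subset (the
#' remainder exactly zero).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (overrides `config$seed`).
#' @return List of class `effect_vectors` with `beta_xg` and `alpha`,
#'   both length `k`.
#' @export
generate_effects <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  with_seed_if(seed, draw_effects(config))
}

# Effect draws on the current RNG stream (no seeding).
draw_effects <- function(config) {
  k <- config$k
  b_raw <- rnorm(k, config$beta_xg_mean, config$beta_xg_sd)
  gvar <- 2 * config$maf * (1 - config$maf)
  beta_xg <- if (config$h2x == 0) {
    rep(0, k)
  } else {
    target <- config$h2x * config$resid_sd_x^2 / (1 - config$h2x)
    b_raw * sqrt(target / sum(b_raw^2 * gvar))
  }
  m <- config$n_pleiotropic
  alpha <- rep(0, k)
  if (config$scenario %in% c("ivw", "egger")) {
    alpha <- config$pleiotropy_mean + config$pleiotropy_sd * rnorm(k)
  } else if (m > 0) {
    c0 <- config$inside_corr
    idx <- seq_len(m)
    zb <- as.numeric(scale(beta_xg[idx]))
    if (any(!is.finite(zb))) zb <- rep(0, m)  # degenerate: no spread
    alpha[idx] <- config$pleiotropy_mean +
      config$pleiotropy_sd * (c0 * zb + sqrt(1 - c0^2) * rnorm(m))
  }
  structure(list(beta_xg = beta_xg, alpha = alpha), class = "effect_vectors")
}

#' Simulate an individual-level dataset
#'
#' Draws genotypes, true effects and correlated residuals, and assembles
#' \eqn{X = G\beta_{XG} + e_X}, \eqn{Y = \beta X + G\alpha + e_Y}.  The
#' residual pair is realized through a shared standard-normal confounder
#' `U`: with \eqn{\rho =} `resid_corr`, each residual is
#' \eqn{\sigma(\sqrt{|\rho|}\,U_{\pm} + \sqrt{1-|\rho|}\,\varepsilon)}, which
#' reproduces the requested moments exactly in distribution.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (overrides `config$seed`).
#' @return An object of class `individual_data`: list with `genotypes`
#'   (n x k dosage matrix), `exposure`, `outcome`, `covariates` (NULL here),
#'   and `truth` (the config, the drawn `effect_vectors`, the realized
#'   reduced-form effects `beta_yg = alpha + beta * beta_xg`, and the
#'   large-sample values `beta_star = beta + rho * sd_y/sd_x` and
#'   `slope = -rho * sd_y/sd_x`).
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n = 500, k = 10, seed = 1))
#' str(d$truth$beta_star)
simulate_dataset <- function(config, seed = NULL) {
  validate_sim_config(config)
  seed <- seed %||% config$seed
  with_seed_if(seed, {
    n <- config$n
    G <- generate_genotypes(n, config$k, config$maf)
    eff <- draw_effects(config)  # continue the same RNG stream
    rho <- config$resid_corr
    a <- sqrt(abs(rho))
    b <- sqrt(1 - abs(rho))
    U <- rnorm(n)
    eX <- config$resid_sd_x * (a * U + b * rnorm(n))
    eY <- config$resid_sd_y * (sign(rho) * a * U + b * rnorm(n))
    X <- drop(G %*% eff$beta_xg) + eX
    Y <- config$beta * X + drop(G %*% eff$alpha) + eY
    truth <- list(
      config = config, effects = eff,
      beta_yg = eff$alpha + config$beta * eff$beta_xg,
      beta_star = config$beta + rho * config$resid_sd_y / config$resid_sd_x,
      slope = -rho * config$resid_sd_y / config$resid_sd_x
    )
    new_individual_data(G, X, Y, covariates = NULL, truth = truth)
  })
}

new_individual_data <- function(genotypes, exposure, outcome,
                                covariates = NULL, truth = NULL) {
  stopifnot(nrow(genotypes) == length(exposure),
            length(exposure) == length(outcome))
  if (!is.null(covariates)) stopifnot(nrow(covariates) == length(exposure))
  structure(list(genotypes = genotypes, exposure = exposure,
                 outcome = outcome, covariates = covariates, truth = truth),
            class = "individual_data")
}

#' Exposure variance explained by the SNPs
#'
#' Adjusted R-squared of the joint OLS of the exposure on all SNPs: the
#' standard (unbiased to first order) estimate of the population fraction
#' of exposure variance the instruments explain, used to check generator
#' calibration against `h2x`.  The raw R-squared, which is inflated by
#' roughly k/n, is returned as the `"raw"` attribute.
#'
#' @param data An `individual_data`.
#' @return Adjusted R-squared (scalar) with attribute `"raw"`.
#' @export
variance_explained <- function(data) {
  stopifnot(inherits(data, "individual_data"))
  G <- data$genotypes
  X <- data$exposure
  n <- length(X)
  k <- ncol(G)
  fit <- ols_fit(cbind(1, G), X)
  rss <- sum(fit$residuals^2)
  tss <- sum((X - mean(X))^2)
  raw <- 1 - rss / tss
  structure(1 - (rss / (n - k - 1)) / (tss / (n - 1)), raw = raw)
}

#' @export
print.individual_data <- function(x, ...) {
  cat("<individual_data> n =", length(x$exposure),
      " k =", ncol(x$genotypes),
      if (!is.null(x$covariates)) paste(" covariates =", ncol(x$covariates)) else "",
      if (!is.null(x$truth)) " (simulated, truth attached)" else "", "\n")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> scenario =", x$scenario,
      " n =", x$n, " k =", x$k, " beta =", x$beta,
      " resid_corr =", x$resid_corr, "\n")
  invisible(x)
}
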