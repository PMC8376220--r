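# Monte-Carlo experiment harness (the simulation-study machinery) and the
# one-call analysis pipeline for user data.

#' Experiment specification
#'
#' @param scenario Simulation scenario: `"ivw"`, `"egger"`, `"lad"` or
#'   `"fig3_toy"`.
#' @param n_grid Increasing vector of sample sizes (default
#'   `c(5000, 20000, 50000)`).
#' @param replicates Independent datasets per sample size (default 1000;
#'   reduce for desk-scale runs).
#' @param arms Character vector of estimator arms; any subset of
#'   `"standard_ivw"`, `"standard_ivw_simex"`, `"cc_ivw"`, `"cc_ivw_simex"`,
#'   `"tsls"`, `"cc_raps"`, `"standard_egger"`, `"standard_egger_simex"`,
#'   `"cc_egger"`, `"cc_egger_simex"`, `"standard_lad"`,
#'   `"standard_lad_simex"`, `"cc_lad"`, `"cc_lad_simex"`,
#'   `"split_ivw"`, `"split_ivw_simex"`.
#' @param seed Root seed; replicate r at the i-th sample size runs under
#'   [child_seed()]`(seed + 1000000 * i, r)`.
#' @param simex A [simex_config()] used by the `*_simex` arms.
#' @param config_args Extra arguments forwarded to [sim_config()].
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(scenario = "ivw",
                            n_grid = c(5000, 20000, 50000),
                            replicates = 1000,
                            arms = c("standard_ivw", "cc_ivw",
                                     "cc_ivw_simex", "tsls"),
                            seed = 1, simex = simex_config(B = 50),
                            config_args = list()) {
  stopifnot(replicates >= 2, all(n_grid > 0), !is.unsorted(n_grid))
  known <- c("standard_ivw", "standard_ivw_simex", "cc_ivw", "cc_ivw_simex",
             "tsls", "cc_raps", "standard_egger", "standard_egger_simex",
             "cc_egger", "cc_egger_simex", "standard_lad",
             "standard_lad_simex", "cc_lad", "cc_lad_simex",
             "split_ivw", "split_ivw_simex")
  bad <- setdiff(arms, known)
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(scenario = scenario, n_grid = n_grid,
                 replicates = as.integer(replicates), arms = arms,
                 seed = as.integer(seed), simex = simex,
                 config_args = config_args),
            class = "experiment_spec")
}

# One replicate: simulate, fit every requested arm, return named estimates
# of the causal effect beta.
run_arms <- function(cfg, arms, simex_cfg, rep_seed) {
  d <- simulate_dataset(cfg, seed = rep_seed)
  cs <- NULL
  ss <- NULL
  need_cs <- any(grepl("^cc_", arms))
  need_ss <- any(grepl("^standard_", arms))
  if (need_cs) cs <- collider_summary(d)
  if (need_ss) ss <- standard_summary(d)
  sx_cfg <- simex_cfg
  sx_cfg$seed <- child_seed(rep_seed, 1)
  est <- function(arm) {
    tryCatch(switch(arm,
      tsls = tsls(d)$beta_hat,
      standard_ivw = ivw_slope(ss)$slope,
      standard_egger = egger_slope(ss)$slope,
      standard_lad = lad_slope(ss, B = 0)$slope,
      standard_ivw_simex = simex_adjust(ss, "ivw", sx_cfg)$slope,
      standard_egger_simex = simex_adjust(ss, "egger", sx_cfg)$slope,
      standard_lad_simex = simex_adjust(ss, "lad", sx_cfg)$slope,
      cc_ivw = cs$beta_star + ivw_slope(cs)$slope,
      cc_egger = cs$beta_star + egger_slope(cs)$slope,
      cc_lad = cs$beta_star + lad_slope(cs, B = 0)$slope,
      cc_raps = cs$beta_star + liml_raps_slope(cs, z = 1)$slope,
      cc_ivw_simex = cs$beta_star + simex_adjust(cs, "ivw", sx_cfg)$slope,
      cc_egger_simex = cs$beta_star + simex_adjust(cs, "egger", sx_cfg)$slope,
      cc_lad_simex = cs$beta_star + simex_adjust(cs, "lad", sx_cfg)$slope,
      split_ivw = {
        sp <- split_sample_summary(d, seed = child_seed(rep_seed, 2))
        ivw_slope(sp)$slope
      },
      split_ivw_simex = {
        sp <- split_sample_summary(d, seed = child_seed(rep_seed, 2))
        simex_adjust(sp, "ivw", sx_cfg)$slope
      }
    ), error = function(e) NA_real_)
  }
  vapply(arms, est, 0)
}

#' Run a Monte-Carlo experiment
#'
#' For every sample size in the grid, simulates `replicates` independent
#' datasets and computes each requested estimator arm's causal estimate,
#' then summarizes the Monte-Carlo mean, standard deviation and mean
#' squared error against the true causal effect.  Single-replicate
#' estimator failures are counted, not fatal; an arm with more than 10%
#' failures at a sample size is marked unreliable.
#'
#' @param spec An [experiment_spec()].
#' @param keep_replicates Also return the per-replicate estimates.
#' @return A data frame with columns `scenario, n, arm, mean, sd, mse,
#'   bias, failures, reliable` (and attribute `"replicates"` when
#'   requested), plus a `"manifest"` attribute recording spec and seed.
#' @export
run_experiment <- function(spec, keep_replicates = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  rows <- list()
  reps_kept <- list()
  for (i in seq_along(spec$n_grid)) {
    n <- spec$n_grid[i]
    cfg <- do.call(sim_config,
                   c(list(n = n, scenario = spec$scenario), spec$config_args))
    beta_true <- cfg$beta
    ests <- vapply(seq_len(spec$replicates), function(r) {
      run_arms(cfg, spec$arms, spec$simex,
               child_seed(spec$seed + 1000000 * i, r))
    }, numeric(length(spec$arms)))
    ests <- matrix(ests, nrow = length(spec$arms),
                   dimnames = list(spec$arms, NULL))
    for (arm in spec$arms) {
      v <- ests[arm, ]
      fails <- sum(!is.finite(v))
      v_ok <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = spec$scenario, n = n, arm = arm,
        mean = mean(v_ok), sd = sd(v_ok),
        mse = mean((v_ok - beta_true)^2),
        bias = mean(v_ok) - beta_true,
        failures = fails,
        reliable = fails <= 0.1 * spec$replicates
      )
      if (fails > 0) {
        warning(sprintf("arm %s at n = %d: %d of %d replicates failed",
                        arm, n, fails, spec$replicates))
      }
    }
    if (keep_replicates) reps_kept[[as.character(n)]] <- ests
  }
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- list(spec = unclass(spec),
                                package_version = as.character(utils::packageVersion("collidermr")))
  if (keep_replicates) attr(out, "replicates") <- reps_kept
  out
}

#' Write an experiment results table with its manifest
#'
#' @param results Output of [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly; writes `results.tsv` and
#'   `manifest.yaml`.
#' @export
write_experiment <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(results, file.path(dir, "results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(attr(results, "manifest"), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Full collider-correction analysis of one dataset
#'
#' Runs algorithm steps 1-4 with every requested method (with and without
#' SIMEX), plus TSLS and the standard one-sample comparators, and collects
#' the instrument diagnostics: the shape of a complete MR results table.
#'
#' @param data An `individual_data` or a path to a TSV written by
#'   [write_individual_data()].
#' @param methods Slope estimators to run (default ivw, egger, lad, raps).
#' @param simex A [simex_config()] for the SIMEX-adjusted variants.
#' @param covariates Optional covariate matrix.
#' @param seed Seed for the stochastic components (SIMEX pseudo-noise, LAD
#'   bootstrap).
#' @return Object of class `cc_report`: list with `table` (data frame:
#'   method, estimate, se, p_value), `diagnostics` (a
#'   [diagnostic_report()]), `beta_star`, `summary` (the
#'   `collider_summary`).
#' @export
end_to_end <- function(data, methods = c("ivw", "egger", "lad", "raps"),
                       simex = simex_config(), covariates = NULL,
                       seed = NULL) {
  if (is.character(data)) data <- read_individual_data(data)
  stopifnot(inherits(data, "individual_data"))
  methods <- match.arg(methods, c("ivw", "egger", "lad", "raps"),
                       several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  cs <- stage("collider_summary", collider_summary(data, covariates = covariates))
  ss <- stage("standard_summary", standard_summary(data, covariates = covariates))
  sx <- simex
  sx$seed <- sx$seed %||% seed
  rows <- list()
  add <- function(method, est, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, estimate = est, se = se,
      p_value = two_sided_p(est, se))
  }
  add("beta_star (observational)", cs$beta_star, cs$se_beta_star)
  ts <- stage("tsls", tsls(data, covariates = covariates))
  add("tsls", ts$beta_hat, ts$se)
  for (m in setdiff(methods, "raps")) {
    fit_std <- switch(m, ivw = ivw_slope(ss), egger = egger_slope(ss),
                      lad = lad_slope(ss, seed = seed))
    add(paste0("standard_", m), fit_std$slope, fit_std$se_slope)
    fit_cc <- switch(m, ivw = ivw_slope(cs), egger = egger_slope(cs),
                     lad = lad_slope(cs, seed = seed))
    ce <- causal_estimate(fit_cc, cs)
    add(paste0("cc_", m), ce$beta_hat, ce$se)
    ce_sx <- causal_estimate(simex_adjust(cs, m, sx), cs)
    add(paste0("cc_", m, "_simex"), ce_sx$beta_hat, ce_sx$se)
  }
  if ("raps" %in% methods) {
    ce <- causal_estimate(liml_raps_slope(cs, z = 1), cs)
    add("cc_raps", ce$beta_hat, ce$se)
  }
  structure(list(table = do.call(rbind, rows),
                 diagnostics = stage("diagnostics", diagnostic_report(cs)),
                 beta_star = cs$beta_star, summary = cs),
            class = "cc_report")
}

#' @export
print.cc_report <- function(x, ...) {
  d <- x$diagnostics
  cat("Collider-correction analysis: k =", d$k, "SNPs\n")
  cat(sprintf("  mean F = %.2f  I2_GX = %.1f%%  Q = %.0f (df %d, p = %.2g)\n",
              d$mean_f, 100 * d$i2gx, d$q_exact, d$q_df, d$q_p))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a `cc_report` as TSV + YAML
#'
#' @param report A `cc_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly; writes `estimates.tsv`, `diagnostics.yaml`
#'   and `outliers.tsv`.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$table, file.path(dir, "estimates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  d <- report$diagnostics
  yaml::write_yaml(list(mean_f = d$mean_f, sum_f = d$sum_f, i2gx = d$i2gx,
                        q_exact = d$q_exact, q_df = d$q_df, q_p = d$q_p,
                        outliers = as.list(d$outliers)),
                   file.path(dir, "diagnostics.yaml"))
  write.table(
    data.frame(snp_id = names(d$per_snp_q), q_contribution = d$per_snp_q),
    file.path(dir, "outliers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
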