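test_that("genotype dosages follow Binomial(2, maf) moments and independence", {
  expect_true(all(generate_genotypes(4, 2, maf = 0, seed = 1) == 0))

  G <- generate_genotypes(100000, 1, maf = 0.3, seed = 7)
  expect_equal(mean(G), 2 * 0.3, tolerance = 0.02)
  expect_equal(var(as.numeric(G)), 2 * 0.3 * 0.7, tolerance = 0.02)

  G2 <- generate_genotypes(10000, 50, maf = 0.3, seed = 8)
  offdiag <- cor(G2)[upper.tri(diag(50))]
  expect_lt(max(abs(offdiag)), 0.05)
  expect_true(all(G2 %in% 0:2))

  expect_error(generate_genotypes(10, 2, maf = 0.7), "maf")
  expect_error(generate_genotypes(0, 2, maf = 0.3), "dimensions")
})

test_that("effect draws hit the variance-explained target exactly and per scenario", {
  cfg <- sim_config(n = 1000, k = 50, seed = 11)
  eff <- generate_effects(cfg)
  gvar <- 2 * cfg$maf * (1 - cfg$maf)
  target <- cfg$h2x * cfg$resid_sd_x^2 / (1 - cfg$h2x)
  expect_equal(sum(eff$beta_xg^2 * gvar), target, tolerance = 1e-12)

  # ivw scenario with no pleiotropy variance: valid instruments
  eff0 <- generate_effects(sim_config(n = 10, k = 20, scenario = "ivw",
                                      pleiotropy_sd = 0, seed = 1))
  expect_identical(eff0$alpha, rep(0, 20))

  # lad scenario: 15 correlated pleiotropic SNPs, the rest exactly zero
  cfg_lad <- sim_config(n = 10, k = 50, scenario = "lad", seed = 5)
  eff_lad <- generate_effects(cfg_lad)
  expect_true(all(eff_lad$alpha[16:50] == 0))
  expect_true(all(eff_lad$alpha[1:15] != 0))
  cors <- vapply(1:300, function(i) {
    e <- generate_effects(cfg_lad, seed = i)
    cor(e$alpha[1:15], e$beta_xg[1:15])
  }, 0)
  expect_equal(mean(cors), 0.5, tolerance = 0.05)

  # egger scenario: alpha independent of beta_xg across replicates
  cfg_eg <- sim_config(n = 10, k = 50, scenario = "egger", seed = 5)
  covs <- vapply(1:500, function(i) {
    e <- generate_effects(cfg_eg, seed = i)
    cov(e$alpha, e$beta_xg)
  }, 0)
  expect_lt(abs(mean(covs)), 3 * sd(covs) / sqrt(500))

  expect_error(sim_config(n = 10, k = 5, scenario = "lad", inside_corr = 1.5),
               "inside_corr")
})

test_that("simulated datasets obey the structural model", {
  # fully null model: X and Y uncorrelated
  d0 <- simulate_dataset(sim_config(n = 20000, k = 10, beta = 0,
                                    pleiotropy_sd = 0, resid_corr = 0,
                                    h2x = 0, seed = 2))
  expect_lt(abs(cor(d0$exposure, d0$outcome)), 0.02)

  # conditional observational coefficient matches beta + rho * sdy / sdx
  d1 <- simulate_dataset(sim_config(n = 1000000, k = 5, beta = 0.5,
                                    resid_sd_x = 1, resid_sd_y = 0.69,
                                    resid_corr = 0.9, pleiotropy_sd = 0,
                                    seed = 3))
  fit <- lm(d1$outcome ~ d1$exposure + d1$genotypes)
  expect_equal(unname(coef(fit)[2]), 0.5 + 0.9 * 0.69, tolerance = 0.005)

  # residual moment contract
  cfg <- sim_config(n = 200000, k = 5, resid_sd_x = 1.3, resid_sd_y = 0.8,
                    resid_corr = -0.4, seed = 4)
  d2 <- simulate_dataset(cfg)
  eX <- d2$exposure - drop(d2$genotypes %*% d2$truth$effects$beta_xg)
  eY <- d2$outcome - cfg$beta * d2$exposure -
    drop(d2$genotypes %*% d2$truth$effects$alpha)
  expect_equal(sd(eX), 1.3, tolerance = 0.01)
  expect_equal(sd(eY), 0.8, tolerance = 0.01)
  expect_equal(cor(eX, eY), -0.4, tolerance = 0.01)
})

test_that("per-SNP regression of Y on G recovers the reduced-form effects", {
  d <- simulate_dataset(sim_config(n = 50000, k = 10, seed = 6))
  ss <- standard_summary(d)
  z <- (ss$beta_yg - d$truth$beta_yg) / ss$se_yg
  # beta_yg_hat is biased away from alpha + beta*beta_xg only through
  # sampling error; standardized errors should look standard normal
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 1.5)
})

test_that("same seed gives byte-identical datasets; different seeds differ", {
  cfg <- sim_config(n = 500, k = 8, seed = 99)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  d2 <- simulate_dataset(cfg, seed = 100)
  expect_false(identical(simulate_dataset(cfg)$exposure, d2$exposure))
})

test_that("confounder loading helper reproduces the residual moments", {
  m <- confounder_moments(1, 1, 1, 1)
  expect_equal(m$resid_corr, 0.5)
  expect_equal(m$resid_sd_x, sqrt(2))

  # loadings -> moments -> simulated residual correlation agree
  cfg <- sim_config(n = 100000, k = 5, resid_sd_x = m$resid_sd_x,
                    resid_sd_y = m$resid_sd_y, resid_corr = m$resid_corr,
                    seed = 12)
  d <- simulate_dataset(cfg)
  eX <- d$exposure - drop(d$genotypes %*% d$truth$effects$beta_xg)
  eY <- d$outcome - cfg$beta * d$exposure -
    drop(d$genotypes %*% d$truth$effects$alpha)
  expect_equal(cor(eX, eY), 0.5, tolerance = 0.015)
})

test_that("fig3_toy preset violates InSIDE globally under a null causal effect", {
  cfg <- scenario_config("fig3_toy", n = 100, seed = 20)
  expect_equal(cfg$beta, 0)
  expect_equal(cfg$resid_corr, 0.5)
  expect_equal(cfg$n_pleiotropic, cfg$k)
  cors <- vapply(1:200, function(i) {
    e <- generate_effects(cfg, seed = i)
    cor(e$alpha, e$beta_xg)
  }, 0)
  expect_equal(mean(cors), 0.45, tolerance = 0.05)
})

test_that("individual data round-trips through TSV with truth sidecar", {
  d <- small_dataset(n = 60, k = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_individual_data(d, path)
  d2 <- read_individual_data(path)
  expect_identical(unname(d$genotypes), unname(d2$genotypes))
  expect_identical(d$exposure, d2$exposure)
  expect_identical(d$outcome, d2$outcome)
  expect_identical(d$truth$effects$beta_xg, d2$truth$effects$beta_xg)
  expect_identical(d$truth$beta_star, d2$truth$beta_star)
  expect_error(read_individual_data("no/such/file.tsv"), "not found")
})

test_that("variance_explained reports adjusted R-squared below the raw value", {
  d <- small_dataset(n = 2000, k = 30, seed = 9)
  v <- variance_explained(d)
  expect_lt(as.numeric(v), attr(v, "raw"))
  expect_gt(as.numeric(v), 0)
})
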