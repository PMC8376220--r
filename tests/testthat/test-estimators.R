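test_that("IVW slope matches the closed-form weighted-LS arithmetic", {
  s <- fixture_summary()  # beta_xg (0.1,0.2,0.3), alpha* (0.05,0.08,0.16), se 0.01
  fit <- ivw_slope(s)
  # equal weights cancel: slope = (0.1*0.05 + 0.2*0.08 + 0.3*0.16) /
  #                               (0.01 + 0.04 + 0.09) = 0.069 / 0.14
  expect_equal(fit$slope, 0.069 / 0.14, tolerance = 1e-12)
  w <- 1 / s$se_alpha_star^2
  expect_equal(fit$slope, wls_oracle(s$beta_xg, s$alpha_star, w),
               tolerance = 1e-12)

  # perfect proportionality: slope exact, phi floored at 1, zero residual
  sp <- fixture_summary(alpha_star = -0.6 * c(0.1, 0.2, 0.3))
  fp <- ivw_slope(sp)
  expect_equal(fp$slope, -0.6, tolerance = 1e-12)
  expect_equal(fp$phi, 1)
  expect_equal(fp$extras$rss_w, 0, tolerance = 1e-20)

  expect_error(ivw_slope(fixture_summary(beta_xg = 0.1,
                                         alpha_star = 0.05,
                                         se_alpha_star = 0.01,
                                         se_xg = 0.01)),
               "at least 2")
})

test_that("IVW random-effects overdispersion inflates the SE when phi > 1", {
  s <- fixture_summary()
  fe <- ivw_slope(s, random_effects = FALSE)
  re <- ivw_slope(s)
  expect_gt(re$phi, 1)
  expect_equal(re$se_slope, fe$se_slope * sqrt(re$phi), tolerance = 1e-12)
})

test_that("Egger slope and intercept match the normal-equations oracle", {
  s <- fixture_summary(beta_xg = c(0.1, 0.2, 0.3, 0.45),
                       alpha_star = c(0.07, 0.06, 0.11, 0.12),
                       se_alpha_star = c(0.01, 0.02, 0.01, 0.03),
                       se_xg = rep(0.02, 4))
  fit <- egger_slope(s)
  w <- 1 / s$se_alpha_star^2
  b <- wls_oracle(s$beta_xg, s$alpha_star, w, intercept = TRUE)
  expect_equal(fit$intercept, b[1], tolerance = 1e-10)
  expect_equal(fit$slope, b[2], tolerance = 1e-10)

  # exact affine data recovered exactly
  se <- fixture_summary(beta_xg = c(0.1, 0.2, 0.3, 0.4),
                        alpha_star = 0.02 - 0.7 * c(0.1, 0.2, 0.3, 0.4),
                        se_alpha_star = rep(0.01, 4), se_xg = rep(0.01, 4))
  fe <- egger_slope(se)
  expect_equal(fe$intercept, 0.02, tolerance = 1e-12)
  expect_equal(fe$slope, -0.7, tolerance = 1e-12)

  expect_error(egger_slope(fixture_summary(beta_xg = rep(0.2, 4),
                                           alpha_star = 1:4 / 100,
                                           se_alpha_star = rep(0.01, 4),
                                           se_xg = rep(0.01, 4))),
               "collinear")
})

test_that("LAD slope equals the ratio-enumeration oracle", {
  # collinear through the origin: exact slope, zero loss
  sc <- fixture_summary(alpha_star = 0.4 * c(0.1, 0.2, 0.3))
  expect_equal(lad_slope(sc, B = 0)$slope, 0.4, tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:20) {
    x <- runif(5, 0.05, 0.5) * sample(c(-1, 1), 5, replace = TRUE)
    y <- -0.3 * x + rnorm(5, sd = 0.05)
    sy <- runif(5, 0.005, 0.05)
    s <- fixture_summary(beta_xg = x, alpha_star = y, se_alpha_star = sy,
                         se_xg = rep(0.01, 5))
    fit <- lad_slope(s, B = 0)
    oracle <- lad_oracle(x, y, sy)
    expect_equal(sum(abs(y - fit$slope * x) / sy),
                 sum(abs(y - oracle * x) / sy), tolerance = 1e-10)
  }
})

test_that("LAD bootstrap SE is seeded and reproducible", {
  s <- fixture_summary(beta_xg = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       alpha_star = c(0.04, 0.1, 0.11, 0.18, 0.26),
                       se_alpha_star = rep(0.02, 5), se_xg = rep(0.01, 5))
  f1 <- lad_slope(s, B = 200, seed = 5)
  f2 <- lad_slope(s, B = 200, seed = 5)
  expect_identical(f1$se_slope, f2$se_slope)
  expect_gt(f1$se_slope, 0)
})

test_that("LIML (z = 0) matches a fine grid search and reduces to IVW under NOME", {
  s <- fixture_summary(beta_xg = c(0.15, 0.22, 0.31),
                       alpha_star = c(-0.09, -0.13, -0.21),
                       se_alpha_star = c(0.012, 0.02, 0.015),
                       se_xg = c(0.03, 0.025, 0.04))
  fit <- liml_raps_slope(s, z = 0)
  grid <- seq(-5, 5, by = 1e-5)
  qvals <- rowSums(vapply(1:3, function(j) {
    (s$alpha_star[j] - grid * s$beta_xg[j])^2 /
      (grid^2 * s$se_xg[j]^2 + s$se_alpha_star[j]^2)
  }, numeric(length(grid))))
  expect_equal(fit$slope, grid[which.min(qvals)], tolerance = 1e-4)
  expect_true(fit$converged)

  # NOME limit with no pleiotropy: LIML objective equals the IVW objective
  sn <- fixture_summary(se_xg = rep(0, 3))
  expect_equal(liml_raps_slope(sn, z = 0)$slope, ivw_slope(sn)$slope,
               tolerance = 1e-6)
})

test_that("RAPS-style fit (z = 1) recovers the slope under overdispersed pleiotropy", {
  set.seed(77)
  k <- 40
  x <- rnorm(k, 0.2, 0.05)
  sy <- rep(0.01, k)
  sx <- rep(0.01, k)
  y <- -0.5 * x + rnorm(k, sd = 0.03)  # pleiotropy variance >> sy
  s <- fixture_summary(beta_xg = x, alpha_star = y, se_alpha_star = sy,
                       se_xg = sx)
  fit <- liml_raps_slope(s, z = 1)
  expect_true(fit$converged)
  expect_equal(fit$slope, -0.5, tolerance = 0.05)
  expect_gt(fit$extras$tau2, 0.0003)  # close to 0.03^2
  expect_lt(fit$extras$tau2, 0.003)
})

test_that("TSLS equals the Wald ratio with one SNP and is consistent with many", {
  d <- simulate_dataset(sim_config(n = 5000, k = 2, seed = 21))
  d1 <- collidermr:::new_individual_data(
    d$genotypes[, 1, drop = FALSE], d$exposure, d$outcome)
  fit <- tsls(d1)
  wald <- cov(d$outcome, d$genotypes[, 1]) / cov(d$exposure, d$genotypes[, 1])
  expect_equal(fit$beta_hat, unname(wald), tolerance = 1e-10)

  dbig <- simulate_dataset(sim_config(n = 1000000, k = 10, beta = 0.5,
                                      pleiotropy_sd = 0, h2x = 0.05,
                                      seed = 22))
  expect_equal(tsls(dbig)$beta_hat, 0.5, tolerance = 0.03)
})

test_that("causal estimate is beta* plus slope with independent-variance SE", {
  s <- fixture_summary()
  fit <- ivw_slope(s)
  ce <- causal_estimate(fit, s)
  expect_identical(ce$beta_hat - fit$slope, s$beta_star)
  expect_equal(ce$se, sqrt(s$se_beta_star^2 + fit$se_slope^2))
  expect_gte(ce$se, s$se_beta_star)

  zero <- fit
  zero$slope <- 0
  expect_identical(causal_estimate(zero, s)$beta_hat, s$beta_star)
})

test_that("weighted-LS slopes are invariant to common SE rescaling but phi is not", {
  s <- fixture_summary()
  s2 <- s
  s2$se_alpha_star <- 3 * s$se_alpha_star
  f1 <- ivw_slope(s)
  f2 <- ivw_slope(s2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$extras$phi_raw, f2$extras$phi_raw)))
  e1 <- egger_slope(s)
  e2 <- egger_slope(s2)
  expect_equal(e1$slope, e2$slope, tolerance = 1e-12)
})

test_that("Egger slope is shift-invariant in alpha*; IVW slope is not", {
  s <- fixture_summary(beta_xg = c(0.1, 0.2, 0.3, 0.4),
                       alpha_star = c(0.07, 0.06, 0.11, 0.12),
                       se_alpha_star = rep(0.01, 4), se_xg = rep(0.01, 4))
  s_shift <- s
  s_shift$alpha_star <- s$alpha_star + 0.5
  expect_equal(egger_slope(s)$slope, egger_slope(s_shift)$slope,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(ivw_slope(s)$slope,
                                ivw_slope(s_shift)$slope)))
})

test_that("no-confounding null gives mean slope near zero for all methods", {
  slopes <- vapply(1:20, function(i) {
    d <- simulate_dataset(sim_config(n = 4000, k = 15, resid_corr = 0,
                                     seed = child_seed(700, i)))
    s <- collider_summary(d)
    c(ivw = ivw_slope(s)$slope, egger = egger_slope(s)$slope,
      lad = lad_slope(s, B = 0)$slope)
  }, numeric(3))
  expect_lt(abs(mean(slopes["ivw", ])), 0.05)
  expect_lt(abs(mean(slopes["egger", ])), 0.12)
  expect_lt(abs(mean(slopes["lad", ])), 0.06)
})

test_that("paired bootstrap causal estimate agrees with the analytic combination", {
  d <- small_dataset(n = 800, k = 8, seed = 30)
  s <- collider_summary(d)
  ana <- causal_estimate(ivw_slope(s), s)
  boot <- causal_bootstrap(d, "ivw", B = 60, seed = 2)
  expect_equal(boot$beta_hat, ana$beta_hat, tolerance = 1e-10)
  expect_lt(abs(boot$se - ana$se), 0.5 * ana$se)  # same order of magnitude
})
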