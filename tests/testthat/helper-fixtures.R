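# Shared fixtures: tiny deterministic summary objects and small simulated
# datasets used across the unit tests.

# Hand-specified collider summary with k SNPs; defaults give the 3-SNP
# worked IVW fixture.
fixture_summary <- function(beta_xg = c(0.1, 0.2, 0.3),
                            alpha_star = c(0.05, 0.08, 0.16),
                            se_alpha_star = rep(0.01, length(beta_xg)),
                            se_xg = rep(0.02, length(beta_xg)),
                            beta_star = 1.0, se_beta_star = 0.01,
                            n = 1000L) {
  k <- length(beta_xg)
  collidermr:::new_collider_summary(
    snp_ids = paste0("g", seq_len(k)),
    beta_xg = beta_xg, se_xg = se_xg,
    alpha_star = alpha_star, se_alpha_star = se_alpha_star,
    beta_star = beta_star, se_beta_star = se_beta_star,
    n = n, k = k)
}

small_dataset <- function(n = 1500, k = 10, seed = 42, ...) {
  simulate_dataset(sim_config(n = n, k = k, seed = seed, ...))
}

# Independent weighted-least-squares oracle: solve the normal equations
# with base solve() on an explicitly built design (with or without
# intercept).  Used to cross-check ivw_slope()/egger_slope().
wls_oracle <- function(x, y, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  unname(drop(solve(crossprod(X, w * X), crossprod(X, w * y))))
}

# Ratio-enumeration oracle for weighted L1 regression through the origin:
# evaluate the loss at every data ratio and return the minimizer (smallest
# |slope| among ties).
lad_oracle <- function(x, y, sy) {
  r <- y / x
  loss <- vapply(r, function(s) sum(abs(y - s * x) / sy), 0)
  cand <- r[loss <= min(loss) * (1 + 1e-12)]
  cand[which.min(abs(cand))]
}
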