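test_that("expected SFS entries reduce to 1/i at neutrality and match quadrature", {
  n <- 10
  expect_equal(expected_sfs_entry(0, 1:(n - 1), n), 1 / (1:(n - 1)), tolerance = 1e-12)
  # independent fine quadrature oracle at S = 1, i = 3, n = 10
  f <- function(x) (1 - exp(-1 * (1 - x))) / ((1 - exp(-1)) * x * (1 - x)) *
    choose(10, 3) * x^3 * (1 - x)^7
  oracle <- stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  expect_equal(expected_sfs_entry(1, 3, 10), oracle, tolerance = 1e-8)
  # strongly deleterious: split-domain oracle around the exp(Sx) boundary layer
  for (S in c(-200, -2000, -20000)) {
    g <- function(x) gbgctools:::sojourn_ratio(S, x) *
      exp(lchoose(20, 1) + (20 - 2) * log1p(-x))
    cut <- 40 / abs(S)
    oracle <- stats::integrate(g, 0, cut, rel.tol = 1e-11)$value +
      stats::integrate(g, cut, 1, rel.tol = 1e-8)$value
    expect_equal(expected_sfs_entry(S, 1, 20), oracle, tolerance = 1e-8)
  }
  # monotone decreasing faster than 1/i when strongly negative
  ent <- expected_sfs_entry(-50, 1:19, 20)
  expect_true(all(diff(ent / (1 / (1:19))) < 0))
})

test_that("the Gamma quantile grid integrates omega_na accurately", {
  # oracle: adaptive quadrature of f(S) against the Gamma density
  shape <- 0.4; meanS <- 2000
  or <- stats::integrate(function(x) fixation_factor(-x) *
                           stats::dgamma(x, shape, scale = meanS / shape),
                         0, Inf, rel.tol = 1e-10)$value
  got <- gbgctools:::omega_na_of(dfe_model("GammaZero", shape = shape, mean = meanS))
  expect_equal(got, or, tolerance = 0.02)
})

test_that("nuisance r_i saturate the combined per-class totals", {
  cfg <- sim_config(seed = 2, theta = 0.02)
  sfs <- simulate_sfs_counts(cfg, 5e4, 1.5e5, seed = 5)
  fit <- fit_dfe(sfs, "GammaZero", n_starts = 2, seed = 1)
  ll <- gbgctools:::sfs_loglik(sfs, fit$theta, fit$model)
  i2 <- 2:(sfs$n - 1)
  expect_equal(ll$r[i2] * (ll$a[i2] + ll$b[i2]),
               sfs$syn_sfs[i2] + sfs$nonsyn_sfs[i2], tolerance = 1e-10)
  expect_equal(ll$r[1], 1)
})

test_that("GammaExpo never fits worse than its nested GammaZero", {
  cfg <- sim_config(seed = 3, theta = 0.02)
  sfs <- simulate_sfs_counts(cfg, 5e4, 1.5e5, seed = 7)
  f0 <- fit_dfe(sfs, "GammaZero", n_starts = 3, seed = 1)
  f1 <- fit_dfe(sfs, "GammaExpo", n_starts = 3, seed = 1)
  expect_gte(f1$loglik, f0$loglik - 1e-4)
})

test_that("alpha and omega decompose the observed dN/dS exactly", {
  cfg <- sim_config(seed = 4, theta = 0.02)
  sfs <- simulate_sfs_counts(cfg, 5e4, 1.5e5, seed = 9)
  sfs$D_syn <- 2000; sfs$D_nonsyn <- 400
  fit <- fit_dfe(sfs, "GammaZero", n_starts = 2, seed = 1)
  ao <- alpha_omega(fit)
  expect_equal(ao$omega_a + ao$omega_na, ao$dnds_obs, tolerance = 1e-10)
  expect_equal(ao$alpha, ao$omega_a / ao$dnds_obs, tolerance = 1e-10)
  # observed dN/dS equal to the model expectation -> alpha = 0
  dnds_model <- gbgctools:::omega_na_of(fit$model)
  ao0 <- alpha_omega(fit, D_syn = 1e4, D_nonsyn = 1e4 * dnds_model *
                       fit$sfs$L_nonsyn / fit$sfs$L_syn)
  expect_equal(ao0$alpha, 0, tolerance = 1e-9)
  expect_equal(ao0$omega_a, 0, tolerance = 1e-9)
  expect_error(alpha_omega(fit, D_syn = 0), "positive")
})

test_that("profile CI contains the MLE and both bounds bracket it", {
  cfg <- sim_config(seed = 5, theta = 0.02)
  sfs <- simulate_sfs_counts(cfg, 5e4, 1.5e5, seed = 11)
  D <- simulate_divergence_counts(cfg, 5e4, 1.5e5, t = 0.1, seed = 12)
  sfs$D_syn <- D$D_syn; sfs$D_nonsyn <- D$D_nonsyn
  fit <- fit_dfe(sfs, "GammaZero", n_starts = 2, seed = 1)
  ci <- profile_ci(fit, "alpha")
  expect_lte(ci$low, ci$point)
  expect_gte(ci$high, ci$point)
  ciw <- profile_ci(fit, "omega_a")
  expect_lte(ciw$low, ciw$point)
  expect_gte(ciw$high, ciw$point)
})

test_that("known class distortions are absorbed by r_i, leaving the DFE stable", {
  cfg <- sim_config(seed = 6, theta = 0.02)
  base <- simulate_sfs_counts(cfg, 2.5e5, 7.5e5, seed = 13)
  fit0 <- fit_dfe(base, "GammaZero", n_starts = 3, seed = 1)
  # integer distortion applied to the very same realised counts
  ci <- rep(c(1L, 2L, 3L), length.out = base$n - 1L)
  ci[1] <- 1L
  dist <- base
  dist$syn_sfs <- base$syn_sfs * ci
  dist$nonsyn_sfs <- base$nonsyn_sfs * ci
  fit1 <- fit_dfe(dist, "GammaZero", n_starts = 3, seed = 1)
  expect_equal(fit1$model$shape, fit0$model$shape, tolerance = 0.15)
  expect_equal(gbgctools:::omega_na_of(fit1$model),
               gbgctools:::omega_na_of(fit0$model), tolerance = 0.15)
  # r_i recovers c_i up to the common scale
  ratio <- (fit1$r / fit0$r) / ci
  expect_lt(max(abs(ratio / stats::median(ratio) - 1)), 0.15)
})
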