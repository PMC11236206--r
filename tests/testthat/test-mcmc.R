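test_that("sampled posterior of s matches the analytic posterior", {
  # N = 1, T = 2, H = 0, eps = 0, p_ext fixed: for the row [1, 1] the
  # likelihood is s * (1 - p)^2, so with a uniform prior the posterior of
  # s is Beta(2, 1) whatever p: mean 2/3, P(s < 0.5) = 1/4
  m <- occupancy_matrix(matrix(c(1L, 1L), 1, 2))
  cfg <- inference_config(n_chains = 2, n_iterations = 6000,
                          n_burnin = 1000, H_max = 0,
                          epsilon_fixed = TRUE, p_ext_fixed = 0.2,
                          seed = 3)
  fit <- fit_posterior(metapop_dataset(m), cfg)
  expect_lt(abs(mean(fit$s) - 2 / 3), 0.02)
  expect_lt(abs(mean(fit$s < 0.5) - 0.25), 0.03)
})

test_that("a seed-bank characteristic event rules out H = 0 exactly", {
  # plants observed in a patch whose own and both neighbours' records
  # were 0 the previous year: probability zero without dormancy
  obs <- matrix(0L, 3, 3)
  obs[, 1] <- 1L   # colonised first year
  obs[2, 3] <- 1L  # recolonisation after a fully empty year
  ds <- metapop_dataset(occupancy_matrix(obs))
  expect_identical(dataset_loglik(ds, H = 0, epsilon = 0,
                                  s = 0.5, p_ext = 0.5), -Inf)
  expect_true(is.finite(dataset_loglik(ds, H = 1, epsilon = 0,
                                       s = 0.5, p_ext = 0.5)))
  cfg <- inference_config(n_chains = 2, n_iterations = 600, n_burnin = 200,
                          epsilon_fixed = TRUE, seed = 4)
  fit <- fit_posterior(ds, cfg)
  expect_identical(sum(fit$H == 0L), 0L)
  expect_equal(summary(fit)$H_prob[["0"]], 0)
})

test_that("fully missing data are rejected as uninformative", {
  m <- occupancy_matrix(matrix(NA_integer_, 3, 4))
  expect_error(fit_posterior(metapop_dataset(m)), "uninformative")
})

test_that("with almost no data the posterior of H returns the prior", {
  m <- matrix(NA_integer_, 2, 3)
  m[1, 1] <- 0L
  cfg <- inference_config(n_chains = 2, n_iterations = 3000, n_burnin = 500,
                          epsilon_fixed = TRUE, seed = 5)
  fit <- fit_posterior(metapop_dataset(occupancy_matrix(m)), cfg)
  hp <- summary(fit)$H_prob
  expect_true(all(abs(hp - 1 / 11) < 0.08))
})

test_that("missing-data augmentation matches exact marginalisation", {
  # 2 patches, 2 years, one missing entry; p_ext fixed so the only
  # continuous unknown is s.  The exact posterior of H integrates the
  # joint enumeration oracle over s (uniform prior) and sums over the
  # two values of the missing entry.
  obs <- matrix(c(1L, 0L, NA, 1L), 2, 2)
  p_fix <- 0.4
  lik_H <- function(H) {
    f <- Vectorize(function(s) {
      o0 <- obs; o0[is.na(o0)] <- 0L
      o1 <- obs; o1[is.na(o1)] <- 1L
      oracle_matrix_lik(o0, s, p_fix, H, 0) +
        oracle_matrix_lik(o1, s, p_fix, H, 0)
    })
    integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  m0 <- lik_H(0); m1 <- lik_H(1)
  want <- m1 / (m0 + m1)
  cfg <- inference_config(n_chains = 2, n_iterations = 8000,
                          n_burnin = 1000, H_max = 1,
                          epsilon_fixed = TRUE, p_ext_fixed = p_fix,
                          n_missing_updates = 4, seed = 6)
  fit <- fit_posterior(metapop_dataset(occupancy_matrix(obs)), cfg)
  expect_lt(abs(mean(fit$H == 1L) - want), 0.03)
  expect_false(is.null(fit$imputations))
  expect_true(all(fit$imputations %in% 0:1))
})

test_that("posterior summaries report means, intervals and H masses", {
  post <- toy_posterior(H = c(0L, 0L, 1L, 1L),
                        p_ext = c(0.4, 0.6, 0.4, 0.6))
  sm <- summary(post)
  expect_equal(sm$H_prob[["0"]], 0.5)
  expect_equal(sm$H_prob[["1"]], 0.5)
  expect_equal(sum(sm$H_prob), 1)
  expect_equal(sm$segments$p_ext_mean, 0.5)
  const <- toy_posterior(H = rep(3L, 4), p_ext = rep(0.3, 4))
  smc <- summary(const)
  expect_equal(smc$segments$p_ext_sd, 0)
  expect_equal(smc$H_prob[["3"]], 1)
})

test_that("inference over pooled street portions shares H across segments", {
  pars <- boa_params(s = 0.5, p_ext = 0.55, H = 1)
  t1 <- boa_simulate(pars, 40, 8, seed = 11)
  t2 <- boa_simulate(boa_params(s = 0.5, p_ext = 0.65, H = 1), 40, 8,
                     seed = 12)
  ds <- metapop_dataset(list(t1$obs, t2$obs), species = "test")
  cfg <- inference_config(n_chains = 2, n_iterations = 800, n_burnin = 300,
                          epsilon_fixed = TRUE, seed = 13)
  fit <- fit_posterior(ds, cfg)
  expect_identical(ncol(fit$p_ext), 2L)
  expect_identical(length(fit$H), 2L * 500L)
  sm <- summary(fit)
  expect_lt(abs(sm$segments$p_ext_mean[1] - 0.55), 0.15)
  expect_lt(abs(sm$segments$p_ext_mean[2] - 0.65), 0.15)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(inference_config(n_iterations = 100, n_burnin = 100))
  expect_error(inference_config(epsilon_max = 0))
  expect_error(inference_config(H_max = -1))
})
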