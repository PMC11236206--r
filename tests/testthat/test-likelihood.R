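test_that("emission probabilities match the model definition", {
  p <- boa_params(s = 0.5, p_ext = 0.3, H = 1, epsilon = 0)
  expect_equal(exp(emission_logprob(1L, 1L, p)), 0.7)
  expect_equal(exp(emission_logprob(1L, 0L, p)), 0.3)
  pe <- boa_params(s = 0.5, p_ext = 0.3, H = 1, epsilon = 0.05)
  expect_equal(exp(emission_logprob(0L, 1L, pe)), 0.05)
  expect_equal(exp(emission_logprob(0L, 0L, pe)), 0.95)
  pe2 <- boa_params(s = 0.5, p_ext = 0.3, H = 0, epsilon = 0.1)
  expect_equal(exp(emission_logprob(1L, 1L, pe2)), 0.73)
  expect_error(emission_logprob(3L, 1L, p), "entries")
})

test_that("single-patch rows reproduce hand-enumerated likelihoods", {
  # H = 0: only a seeded initial patch can explain [1, 1]
  m <- occupancy_matrix(matrix(c(1L, 1L), 1, 2))
  p <- boa_params(s = 0.5, p_ext = 0.2, H = 0)
  expect_equal(exp(patch_loglik(1, m, p)), 0.5 * 0.8^2, tolerance = 1e-12)
  # a recolonisation after an empty year is impossible without dormancy
  m01 <- occupancy_matrix(matrix(c(0L, 1L), 1, 2))
  expect_identical(patch_loglik(1, m01, p), -Inf)
  # with H = 1 only the initial age-1 cohort survives the empty year
  p1 <- boa_params(s = 0.5, p_ext = 0.5, H = 1)
  expect_equal(exp(patch_loglik(1, m01, p1)), 0.0625, tolerance = 1e-12)
})

test_that("dataset likelihood factorises over patches and segments", {
  set.seed(21)
  obs <- occupancy_matrix(matrix(rbinom(12, 1, 0.5), 4, 3))
  ds1 <- metapop_dataset(obs)
  p <- boa_params(s = 0.4, p_ext = 0.5, H = 1)
  ll_sum <- sum(vapply(1:4, function(i) patch_loglik(i, obs, p), numeric(1)))
  expect_equal(dataset_loglik(ds1, H = 1, epsilon = 0, s = 0.4, p_ext = 0.5),
               ll_sum, tolerance = 1e-10)
  ds2 <- metapop_dataset(list(obs, obs))
  expect_equal(dataset_loglik(ds2, H = 1, epsilon = 0,
                              s = c(0.4, 0.4), p_ext = c(0.5, 0.5)),
               2 * ll_sum, tolerance = 1e-10)
})

test_that("likelihood equals joint enumeration over hidden configurations", {
  set.seed(77)
  cases <- expand.grid(N = c(1, 2, 3), Tn = c(2, 3), H = c(0, 1, 2),
                       eps = c(0, 0.05))
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    obs <- matrix(rbinom(cs$N * cs$Tn, 1, 0.5), cs$N, cs$Tn)
    s <- runif(1, 0.2, 0.8); p <- runif(1, 0.2, 0.8)
    want <- oracle_matrix_lik(obs, s, p, cs$H, cs$eps)
    got <- dataset_loglik(metapop_dataset(occupancy_matrix(obs)),
                          H = cs$H, epsilon = cs$eps, s = s, p_ext = p)
    if (want == 0) expect_identical(got, -Inf)
    else expect_lt(abs(exp(got) - want), 1e-10)
  }
})

test_that("likelihood is a normalised distribution over observation matrices", {
  for (cfg in list(list(N = 2, Tn = 2, H = 1, eps = 0),
                   list(N = 2, Tn = 2, H = 1, eps = 0.05),
                   list(N = 1, Tn = 3, H = 2, eps = 0))) {
    s <- 0.37; p <- 0.62
    tot <- sum(vapply(all_binary_matrices(cfg$N, cfg$Tn), function(m) {
      exp(dataset_loglik(metapop_dataset(occupancy_matrix(m)),
                         H = cfg$H, epsilon = cfg$eps, s = s, p_ext = p))
    }, numeric(1)))
    expect_lt(abs(tot - 1), 1e-8)
  }
})

test_that("likelihood is invariant under reversing patch order", {
  set.seed(13)
  obs <- matrix(rbinom(24, 1, 0.4), 6, 4)
  ll <- dataset_loglik(metapop_dataset(occupancy_matrix(obs)),
                       H = 2, epsilon = 0.03, s = 0.5, p_ext = 0.6)
  llr <- dataset_loglik(metapop_dataset(occupancy_matrix(obs[6:1, ])),
                        H = 2, epsilon = 0.03, s = 0.5, p_ext = 0.6)
  expect_equal(ll, llr, tolerance = 1e-12)
})

test_that("likelihood agrees with simulation frequencies", {
  # independent route: empirical distribution of simulated observation
  # matrices versus the exact likelihood, on a 2-patch 2-year system
  pars <- boa_params(s = 0.5, p_ext = 0.5, H = 1)
  n_sim <- 40000
  set.seed(31)
  codes <- replicate(n_sim, {
    o <- boa_simulate(pars, 2, 2)$obs
    sum(as.integer(o) * 2^(0:3))
  })
  freq <- tabulate(codes + 1L, nbins = 16) / n_sim
  for (code in 0:15) {
    bits <- as.integer(intToBits(code))[1:4]
    prob <- exp(dataset_loglik(
      metapop_dataset(occupancy_matrix(matrix(bits, 2, 2))),
      H = 1, epsilon = 0, s = 0.5, p_ext = 0.5))
    se <- sqrt(prob * (1 - prob) / n_sim)
    expect_lt(abs(freq[code + 1] - prob), 4 * se + 1e-4)
  }
})

test_that("missing entries demand imputations covering them", {
  m <- matrix(c(1L, NA, 0L, 1L), 2, 2)
  ds <- metapop_dataset(occupancy_matrix(m))
  expect_error(dataset_loglik(ds, 1, 0, 0.5, 0.5), "imputations")
  ll <- dataset_loglik(ds, 1, 0, 0.5, 0.5, imputations = list(0L))
  m_full <- m; m_full[is.na(m_full)] <- 0L
  expect_equal(ll, dataset_loglik(metapop_dataset(occupancy_matrix(m_full)),
                                  1, 0, 0.5, 0.5))
})
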