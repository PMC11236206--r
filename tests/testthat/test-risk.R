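tab461 <- toy_pc_table(c(0.461, 0.52, 0.55, 0.57, 0.58, 0.59,
                         0.60, 0.60, 0.61, 0.61, 0.62))

test_that("GER counts posterior exceedances of the critical threshold", {
  expect_equal(compute_ger(toy_posterior(rep(0L, 10), rep(0.9, 10)),
                           tab461), 1)
  expect_equal(compute_ger(toy_posterior(rep(0L, 10), rep(0.2, 10)),
                           tab461), 0)
  post <- toy_posterior(rep(0L, 10), rep(c(0.9, 0.1), 5))
  expect_equal(compute_ger(post, tab461), 0.5)
})

test_that("GER equals its mixture decomposition exactly", {
  set.seed(9)
  post <- toy_posterior(sample(0:3, 200, replace = TRUE),
                        runif(200, 0.3, 0.7))
  ger <- compute_ger(post, tab461)
  mix <- 0
  for (h in 0:3) {
    sel <- post$H == h
    if (any(sel))
      mix <- mix + mean(post$p_ext[sel, 1] > tab461$p_c[h + 1]) * mean(sel)
  }
  expect_equal(ger, mix)
})

test_that("H_inf is the smallest non-rejected dormancy duration", {
  # cumulative mass 0.06 at h = 0 already exceeds the 5% level
  post <- toy_posterior(c(rep(0L, 6), rep(5L, 94)), runif(100))
  expect_identical(compute_h_inf(post), 0L)
  # cumulative 0.01, 0.03, 0.53 -> first h reaching 0.05 is 2
  post2 <- toy_posterior(c(rep(0L, 1), rep(1L, 2), rep(2L, 50), rep(3L, 47)),
                         runif(100))
  expect_identical(compute_h_inf(post2), 2L)
  post3 <- toy_posterior(rep(10L, 40), runif(40))
  expect_identical(compute_h_inf(post3), 10L)
})

test_that("MaxGER conditions on the lowest plausible dormancy duration", {
  expect_equal(as.numeric(compute_maxger(
    toy_posterior(rep(0L, 100), rep(0.9, 100)), tab461)), 1)
  expect_equal(as.numeric(compute_maxger(
    toy_posterior(rep(0L, 100), rep(0.2, 100)), tab461)), 0)
  # at H_inf = 0, 3 of 4 draws exceed the threshold
  post <- toy_posterior(rep(0L, 100),
                        c(rep(0.9, 75), rep(0.1, 25)))
  expect_equal(as.numeric(compute_maxger(post, tab461)), 0.75)
})

test_that("MaxGER falls back and flags thin conditioning sets", {
  post <- toy_posterior(c(rep(0L, 3), rep(2L, 37)),
                        c(rep(0.9, 3), rep(0.1, 37)))
  mg <- compute_maxger(post, tab461)  # H_inf = 0 but only 3 draws there
  expect_true(attr(mg, "fallback"))
  expect_identical(attr(mg, "n_cond"), 3L)
  expect_equal(as.numeric(mg), 1)
})

test_that("MaxGER alpha limits bracket the posterior support of H", {
  post <- toy_posterior(c(rep(1L, 5), rep(4L, 95)), runif(100, 0.5, 0.6))
  # alpha -> 1: condition at the posterior-minimal non-rejected h, which
  # becomes the smallest h with cumulative mass ~1s threshold -> h = 1
  expect_identical(compute_h_inf(post, alpha = 0.99), 4L)
  expect_identical(compute_h_inf(post, alpha = 1e-9), 1L)
})

test_that("point-mass posteriors give GER = MaxGER in {0, 1}", {
  for (p in c(0.2, 0.9)) {
    post <- toy_posterior(rep(0L, 60), rep(p, 60))
    g <- compute_ger(post, tab461)
    m <- as.numeric(compute_maxger(post, tab461))
    expect_identical(g, m)
    expect_true(g %in% c(0, 1))
  }
})

test_that("LER is the posterior mean and is bounded by the draws", {
  expect_equal(compute_ler(toy_posterior(rep(0L, 2), c(0.4, 0.6))), 0.5)
  expect_equal(compute_ler(toy_posterior(rep(0L, 3), rep(0.3, 3))), 0.3)
  set.seed(2)
  draws <- runif(50)
  post <- toy_posterior(rep(0L, 50), draws)
  ler <- compute_ler(post)
  expect_equal(ler, compute_ler(toy_posterior(rep(0L, 50), rev(draws))))
  expect_true(ler >= min(draws) && ler <= max(draws))
})

test_that("SMD is the pooled standardised difference of means", {
  expect_equal(compute_smd(0.5, 0.1, 0.5, 0.2), 0)
  expect_equal(compute_smd(0.6, 0.1, 0.4, 0.1), 2)
  expect_equal(compute_smd(0.3, 0.05, 0.5, 0.05), 4)
  expect_equal(compute_smd(0.3, 0, 0.3, 0), 0)
  expect_warning(inf <- compute_smd(0.3, 0, 0.4, 0), "zero pooled")
  expect_identical(inf, Inf)
  expect_error(compute_smd(0.3, -0.1, 0.4, 0.1), "non-negative")
})

test_that("risk reports cover every segment with consistent metrics", {
  set.seed(4)
  post <- toy_posterior(rep(0L, 100),
                        cbind(0.9 + runif(100, -0.01, 0.01),
                              0.2 + runif(100, -0.01, 0.01)))
  rep <- risk_report(post, tab461)
  expect_s3_class(rep, "risk_report")
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$GER, c(1, 0))
  expect_equal(rep$MaxGER, c(1, 0))
  expect_equal(rep$LER, c(0.9, 0.2), tolerance = 0.01)
  expect_identical(rep$H_inf, c(0L, 0L))
  # unknown segment
  expect_error(compute_ler(post, "nope"), "unknown segment")
  # SMD matrix across the two portions
  sm <- summary(post)
  smm <- smd_matrix(sm)
  expect_equal(dim(smm), c(2L, 2L))
  expect_equal(diag(smm), c(0, 0), ignore_attr = TRUE)
  expect_gt(smm[1, 2], 0)
})
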