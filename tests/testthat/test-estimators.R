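test_that("Wald ratios follow the delta method, first and second order", {
  h <- make_harmonized(beta_exposure = c(0.1, 0.2), beta_outcome = c(0.05, 0),
                       se_exposure = 0.005, se_outcome = 0.1)
  wr <- wald_ratios(h)
  expect_equal(wr$ratio, c(0.5, 0))
  expect_equal(wr$se[1], 0.1 / 0.1)

  # second-order SE against a Monte-Carlo propagation oracle
  set.seed(99)
  n_mc <- 1e5
  g_star <- rnorm(n_mc, 0.1, 0.01)
  G_star <- rnorm(n_mc, 0.05, 0.01)
  mc_sd <- sd(G_star / g_star)
  h2 <- make_harmonized(0.1, 0.05, se_exposure = 0.01, se_outcome = 0.01)
  # pad to dodge the zero-beta warning path: single-SNP set is fine here
  wr2 <- wald_ratios(h2, se_order = "second")
  expect_equal(wr2$se, mc_sd, tolerance = 0.05)

  h0 <- make_harmonized(c(0, 0.1, 0.2), c(0.1, 0.05, 0.1))
  expect_warning(wr0 <- wald_ratios(h0), "zero exposure beta")
  expect_equal(nrow(wr0), 2)
})

test_that("IVW equals the intercept-free WLS slope and handles variants", {
  # all ratios equal by construction: exact beta, zero heterogeneity
  h <- make_harmonized(c(0.1, 0.2, 0.5), c(0.05, 0.10, 0.25),
                       se_outcome = 0.1)
  est <- mr_ivw(h, "fixed")
  expect_equal(est$beta, 0.5)
  expect_equal(attr(est, "q"), 0)

  # WLS oracle on random instances, both variants (property test)
  set.seed(7)
  for (i in 1:50) {
    hr <- random_harmonized(k = sample(3:15, 1))
    w <- 1 / hr$se_outcome^2
    oracle <- oracle_wls_through_origin(hr$beta_exposure, hr$beta_outcome, w)
    fixed <- mr_ivw(hr, "fixed")
    expect_equal(fixed$beta, oracle, tolerance = 1e-10)
    mult <- mr_ivw(hr, "multiplicative-random")
    expect_equal(mult$beta, fixed$beta)
    expect_gte(mult$se, fixed$se)
  }

  # duplicated single SNP reduces to its Wald ratio
  hd <- make_harmonized(c(0.1, 0.1), c(0.03, 0.03), se_outcome = 0.05)
  expect_equal(mr_ivw(hd)$beta, 0.3)

  expect_error(mr_ivw(make_harmonized(0.1, 0.05)), "wald_ratios",
               class = "insomniamr_validation_error")
})

test_that("IVW is invariant to outcome-SE rescaling up to the SE factor", {
  set.seed(11)
  hr <- random_harmonized(8)
  base <- mr_ivw(hr, "fixed")
  hr2 <- hr
  hr2$se_outcome <- hr$se_outcome * 3
  scaled <- mr_ivw(hr2, "fixed")
  expect_equal(scaled$beta, base$beta)
  expect_equal(scaled$se, base$se * 3)
})

test_that("MR-Egger recovers exact affine structure and matches WLS", {
  g <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h_prop <- make_harmonized(g, 0.4 * g, se_outcome = 0.05)
  e1 <- mr_egger(h_prop)
  expect_equal(e1$slope$beta, 0.4, tolerance = 1e-12)
  expect_equal(e1$intercept$estimate, 0, tolerance = 1e-12)
  # with an exactly-zero intercept the Egger slope equals IVW(fixed)
  expect_equal(e1$slope$beta, mr_ivw(h_prop, "fixed")$beta, tolerance = 1e-12)

  h_aff <- make_harmonized(g, 0.02 + 0.4 * g, se_outcome = 0.05)
  e2 <- mr_egger(h_aff)
  expect_equal(e2$intercept$estimate, 0.02, tolerance = 1e-12)
  expect_equal(e2$slope$beta, 0.4, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:25) {
    hr <- random_harmonized(10)
    w <- 1 / hr$se_outcome^2
    ref <- oracle_wls_with_intercept(hr$beta_exposure, hr$beta_outcome, w)
    e <- mr_egger(hr)
    expect_equal(e$intercept$estimate, ref[1], tolerance = 1e-10)
    expect_equal(e$slope$beta, ref[2], tolerance = 1e-10)
    # SE oracle: explicit matrix WLS with the same variance floor
    X <- cbind(1, hr$beta_exposure)
    xtwx_inv <- solve(t(X) %*% (w * X))
    resid <- hr$beta_outcome - X %*% ref
    phi <- max(1, sum(w * resid^2) / (nrow(hr) - 2))
    expect_equal(e$intercept$se, sqrt(phi * xtwx_inv[1, 1]),
                 tolerance = 1e-10)
    expect_equal(e$slope$se, sqrt(phi * xtwx_inv[2, 2]), tolerance = 1e-10)
  }

  expect_error(mr_egger(make_harmonized(c(0.1, 0.2), c(0, 0))),
               "at least 3")
  expect_error(mr_egger(make_harmonized(c(0.1, 0.1, 0.1), c(0, 0, 0.1))),
               "collinear")
})

test_that("Egger orientation makes exposure betas non-negative without
           changing Wald ratios", {
  set.seed(3)
  hr <- random_harmonized(8)
  flip <- c(2, 5)
  hr$beta_exposure[flip] <- -hr$beta_exposure[flip]
  hr$beta_outcome[flip] <- -hr$beta_outcome[flip]
  oriented <- orient_exposure(hr)
  expect_true(all(oriented$beta_exposure >= 0))
  expect_equal(wald_ratios(oriented)$ratio, wald_ratios(hr)$ratio)
})

test_that("weighted median interpolates the cumulative weight function", {
  # equal weights, odd k: the plain median
  h3 <- make_harmonized(c(0.1, 0.1, 0.1), c(0.01, 0.02, 0.03),
                        se_outcome = 0.05)
  wm <- mr_weighted_median(h3, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.2)
  # two equal weights: midpoint interpolation
  expect_equal(insomniamr:::weighted_median_point(c(0.1, 0.3), c(1, 1)), 0.2)

  # unequal weights against the quantile-grid oracle
  set.seed(31)
  for (i in 1:25) {
    hr <- random_harmonized(sample(5:12, 1))
    wr <- wald_ratios(hr)
    est <- mr_weighted_median(hr, n_boot = 100, seed = 5)
    expect_equal(est$beta, oracle_weighted_median(wr$ratio, wr$weight),
                 tolerance = 1e-8)
  }
})

test_that("weighted median is order-invariant and demands a seed", {
  set.seed(17)
  hr <- random_harmonized(9)
  a <- mr_weighted_median(hr, n_boot = 300, seed = 42)
  b <- mr_weighted_median(hr[sample(9), ], n_boot = 300, seed = 42)
  expect_equal(a$beta, b$beta)
  expect_equal(a$se, b$se)
  expect_error(mr_weighted_median(hr, n_boot = 300),
               "seed", class = "insomniamr_validation_error")
  expect_warning(mr_weighted_median(hr, n_boot = 50, seed = 1), "n_boot")
})

test_that("mr_all returns one tidy row per estimator", {
  set.seed(2)
  hr <- random_harmonized(10)
  res <- mr_all(hr, n_boot = 200, seed = 3)
  expect_setequal(res$method, c("ivw", "egger-slope", "egger-intercept",
                                "weighted-median"))
  expect_equal(sum(res$method == "ivw"), 2)  # both variants co-reported
  expect_true(all(res$ci_low <= res$beta & res$beta <= res$ci_high))
  expect_equal(res$or, exp(res$beta))
})
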