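make_pregnancy_table <- function() {
  tibble::tibble(
    id = c("w1", "w2", "w2", "w2", "w3"),
    pregnancy_id = c(1L, 1L, 2L, 3L, 1L),
    y = 1:5
  )
}

test_that("one pregnancy per woman is selected uniformly and reproducibly", {
  tab <- make_pregnancy_table()
  out <- select_one_pregnancy(tab, seed = 1)
  expect_equal(nrow(out), 3)                 # one row per distinct woman
  expect_true("w1" %in% out$id)              # single pregnancies always kept
  expect_identical(out, select_one_pregnancy(tab, seed = 1))

  # each of w2's three pregnancies chosen ~1/3 of the time across seeds
  picks <- vapply(1:3000, function(s) {
    select_one_pregnancy(tab, seed = s)$pregnancy_id[2]
  }, integer(1))
  freq <- tabulate(picks, 3) / 3000
  tol <- 3 * sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) < tol))
})

test_that("logistic SNP fit on a 2x2 equals the cross-product log OR", {
  cohort <- expand_counts(
    list(n = 30, g = 1, y = 1), list(n = 70, g = 1, y = 0),
    list(n = 10, g = 0, y = 1), list(n = 90, g = 0, y = 0)
  )
  fit <- fit_snp_trait(cohort, "g", "y", family = "logistic")
  expect_equal(fit$beta, log((30 * 90) / (70 * 10)), tolerance = 1e-8)
  expect_identical(fit$scale, "log-odds")
  expect_true(fit$converged)

  const <- dplyr::mutate(cohort, g = 1)
  expect_error(fit_snp_trait(const, "g", "y", family = "logistic"),
               "zero variance", class = "insomniamr_validation_error")
  expect_error(fit_snp_trait(dplyr::mutate(cohort, y = y + 1), "g", "y",
                             family = "logistic"),
               "binary", class = "insomniamr_validation_error")
})

test_that("the vectorized linear scan matches per-SNP lm() with covariates", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 800, theta = 0.2, seed = 9, n_snps = 6, target_r2 = 0.05,
    exposure_mode = "continuous", outcome_mode = "continuous"
  ))
  snps <- sim$snp_info$rsid
  scan <- snp_associations(sim$cohort, snps, "outcome", family = "linear",
                           covariates = c("age", "pc1"))
  for (s in snps) {
    ref <- lm(stats::reformulate(c(s, "age", "pc1"), "outcome"),
              data = sim$cohort)
    expect_equal(scan$beta[scan$rsid == s],
                 unname(coef(ref)[s]), tolerance = 1e-8)
    expect_equal(scan$se[scan$rsid == s],
                 unname(summary(ref)$coefficients[s, 2]), tolerance = 1e-8)
  }
  # adding an orthogonal covariate leaves the slope essentially unchanged
  plain <- snp_associations(sim$cohort, snps, "outcome", family = "linear")
  expect_equal(scan$beta, plain$beta, tolerance = 0.05)
})

test_that("null linear fits are calibrated: beta within 3 SE of zero", {
  # no genetic effect on the trait at all; check the +/- 3 SE band holds
  # at close to its nominal rate over seeded replicates
  hits <- vapply(1:400, function(s) {
    set.seed(s + 2000)
    g <- rbinom(400, 2, 0.3)
    y <- rnorm(400)
    fit <- fit_snp_trait(tibble::tibble(g = g, y = y), "g", "y",
                         family = "linear")
    abs(fit$beta) < 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.98)  # nominal 99.7%, binomial noise allowed
})

test_that("split cross-over combines its two halves by fixed-effects meta", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 6000, theta = 0.4, seed = 21, n_snps = 12, target_r2 = 0.05,
    exposure_mode = "continuous", outcome_mode = "binary",
    outcome_prevalence = 0.2
  ))
  res <- split_crossover(sim$cohort, sim$snp_info$rsid, "exposure", "outcome",
                         seed = 8)
  expect_identical(res$estimate_label, c("a_on_b", "b_on_a", "combined"))
  ref <- fixed_effects_meta(tibble::tibble(
    study = c("a", "b"), beta = res$beta[1:2], se = res$se[1:2]
  ))
  expect_equal(res$beta[3], ref$beta, tolerance = 1e-12)
  expect_equal(res$se[3], ref$se, tolerance = 1e-12)
  # reproducible under the same seed
  res2 <- split_crossover(sim$cohort, sim$snp_info$rsid, "exposure",
                          "outcome", seed = 8)
  expect_equal(res$beta, res2$beta)

  rare <- dplyr::mutate(sim$cohort, outcome = 0)
  rare$outcome[1:5] <- 1
  expect_error(
    split_crossover(rare, sim$snp_info$rsid, "exposure", "outcome", seed = 1),
    "case count", class = "insomniamr_validation_error"
  )
})

test_that("split cross-over recovers a continuous-mode causal effect", {
  arch_cfg <- sim_config(n_subjects = 2, theta = 0.3, seed = 777,
                         n_snps = 30, target_r2 = 0.05,
                         exposure_mode = "continuous",
                         outcome_mode = "continuous")
  arch <- draw_snp_architecture(arch_cfg)
  betas <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 10000, theta = 0.3, seed = 5000 + s,
                      n_snps = 30, target_r2 = 0.05,
                      exposure_mode = "continuous",
                      outcome_mode = "continuous")
    sim <- simulate_cohort(cfg, architecture = arch)
    split_crossover(sim$cohort, arch$rsid, "exposure", "outcome",
                    seed = 6000 + s, family_outcome = "linear")$beta[3]
  }, numeric(1))
  expect_lt(abs(mean(betas) - 0.3), 0.05)
})

test_that("fetal-genotype adjustment leaves null paths unchanged and flags
           collinearity", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 4000, theta = 0, seed = 33, n_snps = 4, target_r2 = 0.05,
    exposure_mode = "continuous", outcome_mode = "binary",
    outcome_prevalence = 0.2, fetal_genotypes = TRUE
  ))
  cmp <- fetal_adjustment_compare(sim$cohort, sim$snp_info$rsid, "outcome")
  expect_equal(nrow(cmp), 4)
  expect_false(any(cmp$collinear))
  # fetal genotype has no outcome effect here: deltas are noise around 0
  expect_lt(abs(mean(cmp$delta_beta)), 0.05)
  expect_equal(cmp$n, rep(nrow(sim$cohort), 4))  # same subjects both fits

  # pathological: fetal dosage identical to maternal dosage
  patho <- sim$cohort
  patho[paste0("fetal_", sim$snp_info$rsid)] <- patho[sim$snp_info$rsid]
  expect_warning(
    cmp2 <- fetal_adjustment_compare(patho, sim$snp_info$rsid[1], "outcome"),
    "collinear"
  )
  expect_true(cmp2$collinear)

  nofetal <- sim$cohort[, !grepl("^fetal_", names(sim$cohort))]
  expect_error(fetal_adjustment_compare(nofetal, sim$snp_info$rsid, "outcome"),
               "no fetal genotype", class = "insomniamr_validation_error")
})

test_that("crude logistic OR on reconstructed 2x2 counts equals the
           cross-product ratio", {
  # perinatal depression by in-pregnancy insomnia, from printed counts
  cohort <- expand_counts(
    list(n = 242, insomnia = 1, depression = 1),
    list(n = 1207, insomnia = 1, depression = 0),
    list(n = 460, insomnia = 0, depression = 1),
    list(n = 7759, insomnia = 0, depression = 0)
  )
  fit <- multivariable_outcome_regression(cohort, "insomnia", "depression")
  g <- glance(fit)
  cross_product <- (242 * 7759) / (460 * 1207)
  expect_equal(g$or[g$model == "crude"], cross_product, tolerance = 1e-8)
  expect_equal(round(cross_product, 2), 3.38)
})

test_that("confounder-free simulation gives crude approximately equal to
           adjusted, and missing confounders shrink the adjusted n", {
  set.seed(55)
  n <- 4000
  cohort <- tibble::tibble(
    insomnia = rbinom(n, 1, 0.2),
    noise1 = rnorm(n), noise2 = rnorm(n)
  )
  cohort$outcome <- rbinom(n, 1, insomniamr:::expit(-2 + 0.8 * cohort$insomnia))
  cohort$noise1[1:200] <- NA
  fit <- multivariable_outcome_regression(cohort, "insomnia", "outcome",
                                          c("noise1", "noise2"))
  g <- glance(fit)
  expect_lt(abs(log(g$or[1]) - log(g$or[2])), 0.15)
  expect_lt(g$n[2], g$n[1])
  td <- tidy(fit)
  expect_true(all(c("crude", "adjusted") %in% td$model))
  expect_equal(td$conf.high - td$estimate, 1.96 * td$std.error)
})

test_that("characteristics tabulation reproduces printed prevalence cells", {
  # prevalence cells computed as 100 * cases / (cases + controls), half-up
  expect_equal(prevalence_pct(42717, 139034), 23.5)
  expect_equal(prevalence_pct(9113, 89340), 9.3)
  expect_equal(prevalence_pct(4907, 139034), 3.4)

  cohort <- expand_counts(
    list(n = 42717, miscarriage = 1, age = 25),
    list(n = 139034, miscarriage = 0, age = 26)
  )
  tab <- tabulate_characteristics(cohort, continuous = "age",
                                  outcomes = "miscarriage")
  row <- tab[tab$variable == "miscarriage", ]
  expect_equal(row$prevalence, 23.5)
  expect_equal(row$cases + row$controls, nrow(cohort))
  expect_identical(row$formatted, "42,717/139,034 (23.5)")

  # stratified table with missing outcomes keeps the total-N denominator
  strat <- dplyr::bind_rows(
    expand_counts(
      list(n = 242, insomnia = "yes", depression = "case"),
      list(n = 1207, insomnia = "yes", depression = "control"),
      list(n = 460, insomnia = "no", depression = "case"),
      list(n = 7759, insomnia = "no", depression = "control")
    ),
    tibble::tibble(insomnia = "no", depression = NA_character_)[rep(1, 872), ]
  )
  t2 <- tabulate_characteristics(strat, categorical = "depression",
                                 stratifier = "insomnia")
  cell <- t2[t2$stratum == "yes" & t2$level == "case", ]
  expect_equal(cell$n, 242)
  expect_equal(cell$percent, 2.3)  # 242 / 10,540 of total N

  # empty stratum: all-zero rows, no division error
  empty <- tabulate_characteristics(
    tibble::tibble(grp = character(), age = numeric()),
    continuous = "age", stratifier = "grp"
  )
  expect_equal(nrow(empty), 0)
})

test_that("cohort TSVs round-trip through the genotype + phenotype dialect", {
  sim <- simulate_cohort(sim_config(
    n_subjects = 50, theta = 0, seed = 4, n_snps = 3,
    exposure_mode = "continuous", outcome_mode = "continuous"
  ))
  gpath <- withr::local_tempfile(fileext = ".tsv")
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(sim$cohort, sim$snp_info$rsid, gpath, ppath)
  back <- read_cohort(gpath, ppath)
  expect_setequal(names(back), names(sim$cohort))
  expect_equal(back[order(back$id), names(sim$cohort)], sim$cohort,
               tolerance = 1e-12)
})
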