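#' Two-sample parameter-recovery simulation study
#'
#' Repeatedly draws one genetic architecture, simulates two independent
#' continuous-trait samples from it (one for the SNP-exposure, one for the
#' SNP-outcome associations, each of `n_subjects` women), fits the per-SNP
#' linear associations, and runs IVW, the weighted median and MR-Egger on
#' the harmonized pair. Continuous exposure and outcome keep the estimand
#' equal to `theta` (no non-collapsibility), so the replicate means measure
#' estimator bias directly.
#'
#' @param n_reps number of replicates.
#' @param seed integer seed; expanded into per-replicate child seeds.
#' @param n_subjects sample size of each of the two samples per replicate.
#' @param n_snps number of instruments.
#' @param theta true causal effect.
#' @param target_r2 exposure variance explained by the instruments. The
#'   default 0.05 emulates a strongly instrumented continuous exposure
#'   (implied mean F about `n_subjects * target_r2 / n_snps`), keeping
#'   two-sample weak-instrument attenuation second-order.
#' @param pleiotropy pleiotropy regime, see [pleiotropy_none()].
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @return tibble with one row per replicate: `rep`, `ivw`, `wm`,
#'   `egger_slope`, `egger_intercept`.
#' @export
mr_recovery_study <- function(n_reps, seed, n_subjects = 50000, n_snps = 81,
                              theta = 0.3, target_r2 = 0.05,
                              pleiotropy = pleiotropy_none(),
                              n_boot = 100) {
  seeds <- matrix(child_seeds(seed, 3 * n_reps), ncol = 3)
  purrr::map_dfr(seq_len(n_reps), function(i) {
    base <- function(s) sim_config(
      n_subjects = n_subjects, theta = theta, seed = s, n_snps = n_snps,
      target_r2 = target_r2, exposure_mode = "continuous",
      outcome_mode = "continuous", pleiotropy = pleiotropy
    )
    arch <- draw_snp_architecture(base(seeds[i, 1]))
    sim_x <- simulate_cohort(base(seeds[i, 2]), architecture = arch)
    sim_y <- simulate_cohort(base(seeds[i, 3]), architecture = arch)
    exp_tab <- snp_associations(sim_x$cohort, arch$rsid, "exposure",
                                family = "linear", snp_info = arch)
    out_tab <- snp_associations(sim_y$cohort, arch$rsid, "outcome",
                                family = "linear", snp_info = arch)
    h <- harmonize(exp_tab, out_tab)
    egg <- mr_egger(h)
    tibble::tibble(
      rep = i,
      ivw = mr_ivw(h, "multiplicative-random")$beta,
      wm = mr_weighted_median(h, n_boot = n_boot, seed = seeds[i, 1])$beta,
      egger_slope = egg$slope$beta,
      egger_intercept = egg$intercept$estimate
    )
  })
}

#' Null calibration of the IVW test at summary level
#'
#' Simulates summary statistics under the null (`theta = 0`) with balanced
#' horizontal pleiotropy, runs IVW on each replicate, and reports the
#' two-sided rejection rate at `alpha`.
#'
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param n_snps number of instruments.
#' @param target_r2 instrument strength (exposure variance explained).
#' @param pleiotropy_sigma SD of the balanced per-SNP direct effects.
#' @param se_exposure,se_outcome reported summary-statistic SEs.
#' @param n_subjects nominal sample size written into the tables.
#' @param alpha test level.
#' @return list: `rejection_rate`, `pvalues`.
#' @export
mr_null_calibration <- function(n_reps, seed, n_snps = 81,
                                target_r2 = 0.0042,
                                pleiotropy_sigma = 0.01,
                                se_exposure = 0.0016, se_outcome = 0.05,
                                n_subjects = 1e5, alpha = 0.05) {
  seeds <- child_seeds(seed, n_reps)
  pvals <- vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_subjects = n_subjects, theta = 0, seed = seeds[i], n_snps = n_snps,
      target_r2 = target_r2,
      pleiotropy = pleiotropy_balanced(pleiotropy_sigma)
    )
    ss <- simulate_summary_stats(cfg, se_exposure, se_outcome)
    mr_ivw(harmonize(ss$exposure, ss$outcome))$pvalue
  }, numeric(1))
  list(rejection_rate = mean(pvals < alpha), pvalues = pvals)
}

#' Confidence-interval coverage of the multivariable-regression comparator
#'
#' Simulates cohorts with a binary exposure that has no effect on a binary
#' outcome and no confounding, fits the crude and adjusted logistic models,
#' and reports how often the adjusted 95% CI covers the null odds ratio.
#'
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param n_subjects cohort size per replicate.
#' @param exposure_prevalence,outcome_prevalence marginal prevalences.
#' @return list: `coverage`, `covered` (logical per replicate).
#' @export
mvreg_coverage_study <- function(n_reps, seed, n_subjects = 1500,
                                 exposure_prevalence = 0.28,
                                 outcome_prevalence = 0.15) {
  seeds <- child_seeds(seed, n_reps)
  covered <- vapply(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    cohort <- tibble::tibble(
      insomnia = rbinom(n_subjects, 1, exposure_prevalence),
      outcome = rbinom(n_subjects, 1, outcome_prevalence),
      cov1 = rnorm(n_subjects),
      cov2 = rnorm(n_subjects)
    )
    fit <- multivariable_outcome_regression(cohort, "insomnia", "outcome",
                                            c("cov1", "cov2"))
    g <- glance(fit)
    g$or_conf.low[g$model == "adjusted"] <= 1 &&
      g$or_conf.high[g$model == "adjusted"] >= 1
  }, logical(1))
  list(coverage = mean(covered), covered = covered)
}
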