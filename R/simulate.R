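expit <- function(x) 1 / (1 + exp(-x))

# solve the logistic intercept alpha so that mean(expit(alpha + eta)) hits
# the target prevalence, by bisection to |error| < tol
solve_intercept <- function(eta, prevalence, tol = 1e-4, what = "intercept") {
  f <- function(a) mean(expit(a + eta)) - prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    abort(paste0("target prevalence ", prevalence,
                 " unattainable in the ", what, " solve."),
          class = "insomniamr_validation_error")
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  a <- (lo + hi) / 2
  if (abs(f(a)) > tol) {
    abort(paste0("prevalence solve for the ", what,
                 " did not reach tolerance."),
          class = "insomniamr_validation_error")
  }
  a
}

#' Specify a synthetic MR study
#'
#' Bundles the full generative specification for a synthetic cohort or
#' summary-statistic set with the causal structure two-sample MR assumes:
#' independent biallelic instruments with small effects on the exposure, a
#' configurable causal log-odds effect on a binary outcome, horizontal
#' pleiotropy (balanced, directional, or via a proportion of invalid
#' instruments), shared confounding, and optional fetal genotypes.
#'
#' Defaults emulate the insomnia setting: 81 independent instruments
#' jointly explaining 0.42% of exposure variance, a binary exposure of 28%
#' prevalence, and a binary outcome of 5% prevalence.
#'
#' @param n_subjects cohort size.
#' @param theta causal effect of the exposure on the outcome (log odds of
#'   outcome per 1 unit exposure).
#' @param seed integer seed (mandatory).
#' @param n_snps number of instruments (default 81).
#' @param maf_range range the per-SNP allele frequencies are drawn from.
#' @param target_r2 total exposure variance explained by the instruments;
#'   per-SNP effects `a_j` are set to `sqrt(target_r2 / n_snps / (2 f_j (1
#'   - f_j)))` so each SNP contributes equally.
#' @param exposure_mode `"binary-liability"` (logistic exposure, the study
#'   setting) or `"continuous"` (unit-variance exposure, free of
#'   non-collapsibility, used for parameter-recovery checks).
#' @param exposure_prevalence prevalence of the binary exposure.
#' @param outcome_mode `"binary"` (logistic outcome) or `"continuous"`
#'   (linear outcome model, `theta` then a per-unit mean difference).
#' @param outcome_prevalence prevalence of the binary outcome.
#' @param pleiotropy one of `pleiotropy_none()`, `pleiotropy_balanced()`,
#'   `pleiotropy_directional()`.
#' @param confounding list with loadings `on_exposure`, `on_outcome` of a
#'   shared standard-normal confounder.
#' @param fetal_genotypes simulate fetal dosages by Mendelian transmission
#'   of one maternal allele plus a random paternal allele.
#' @param multi_pregnancy_prop proportion of women given a second pregnancy
#'   record (default 0, matching post-selection data).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects, theta, seed, n_snps = 81,
                       maf_range = c(0.05, 0.45), target_r2 = 0.0042,
                       exposure_mode = c("binary-liability", "continuous"),
                       exposure_prevalence = 0.28,
                       outcome_mode = c("binary", "continuous"),
                       outcome_prevalence = 0.05,
                       pleiotropy = pleiotropy_none(),
                       confounding = list(on_exposure = 0, on_outcome = 0),
                       fetal_genotypes = FALSE,
                       multi_pregnancy_prop = 0) {
  exposure_mode <- match.arg(exposure_mode)
  outcome_mode <- match.arg(outcome_mode)
  if (missing(seed)) {
    abort("`seed` is mandatory in a simulation config.",
          class = "insomniamr_validation_error")
  }
  stopifnot(
    n_subjects >= 1, n_snps >= 1,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 0.5 + 1e-9,
    maf_range[1] <= maf_range[2],
    target_r2 > 0, target_r2 < 1,
    exposure_prevalence > 0, exposure_prevalence < 1,
    outcome_prevalence > 0, outcome_prevalence < 1,
    multi_pregnancy_prop >= 0, multi_pregnancy_prop < 1
  )
  structure(
    list(
      n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
      target_r2 = target_r2, exposure_mode = exposure_mode,
      exposure_prevalence = exposure_prevalence,
      outcome_mode = outcome_mode,
      outcome_prevalence = outcome_prevalence,
      theta = theta, pleiotropy = pleiotropy, confounding = confounding,
      fetal_genotypes = fetal_genotypes,
      multi_pregnancy_prop = multi_pregnancy_prop,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Horizontal-pleiotropy regimes for the generator
#'
#' `pleiotropy_none()` gives every SNP a zero direct effect on the outcome.
#' `pleiotropy_balanced(sigma)` draws direct effects `d_j ~ N(0, sigma^2)`
#' (mean-zero, so IVW stays consistent). `pleiotropy_directional(mu, sigma,
#' prop_invalid)` draws `d_j ~ N(mu, sigma^2)` for a proportion
#' `prop_invalid` of the instruments and 0 for the rest, violating the
#' exclusion restriction in one direction.
#'
#' @param sigma pleiotropy standard deviation.
#' @param mu mean directional effect of an invalid instrument.
#' @param prop_invalid proportion of invalid instruments in `[0, 1]`.
#' @return list describing the regime.
#' @export
pleiotropy_none <- function() list(regime = "none")

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(sigma) {
  stopifnot(sigma >= 0)
  list(regime = "balanced", sigma = sigma)
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mu, sigma = 0, prop_invalid = 1) {
  stopifnot(sigma >= 0, prop_invalid >= 0, prop_invalid <= 1)
  list(regime = "directional", mu = mu, sigma = sigma,
       prop_invalid = prop_invalid)
}

#' Draw the per-SNP genetic architecture of a config
#'
#' Samples the allele frequencies, instrument effects `a_j` (scaled so the
#' instruments jointly explain `target_r2` of the exposure) and direct
#' (pleiotropic) outcome effects `d_j` implied by a [sim_config()]. In a
#' two-sample design the same architecture underlies both samples, so this
#' is exposed separately: draw it once, then pass it to [simulate_cohort()]
#' for each independent sample.
#'
#' @param config a [sim_config()]; its `seed` drives the draw.
#' @return tibble: `rsid`, `effect_allele`, `other_allele`, `maf`, `a`, `d`.
#' @export
draw_snp_architecture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  draw_architecture(config)
}

# draw per-SNP architecture (frequencies, instrument effects, direct
# effects) from a config; assumes the RNG is already seeded
draw_architecture <- function(config) {
  k <- config$n_snps
  f <- runif(k, config$maf_range[1], config$maf_range[2])
  # heavy-tailed split of the total instrument r2 across SNPs (squared
  # uniform shares): GWAS lead-SNP effects are heterogeneous, and without
  # spread in the exposure effects the Egger slope is barely identified
  share <- runif(k)^2
  share <- share / sum(share)
  a <- sqrt(config$target_r2 * share / (2 * f * (1 - f)))
  d <- numeric(k)
  pl <- config$pleiotropy
  if (pl$regime == "balanced") {
    d <- rnorm(k, 0, pl$sigma)
  } else if (pl$regime == "directional") {
    invalid <- seq_len(floor(pl$prop_invalid * k))
    d[invalid] <- rnorm(length(invalid), pl$mu, pl$sigma)
  }
  tibble::tibble(
    rsid = sprintf("rs%04d", seq_len(k)),
    effect_allele = "A", other_allele = "G",
    maf = f, a = a, d = d
  )
}

#' Simulate an individual-level cohort
#'
#' Genotypes are `g_j ~ Binomial(2, f_j)` with `f_j ~ Uniform(maf_range)`;
#' a shared confounder `U ~ N(0, 1)` loads on exposure and outcome. In
#' continuous mode the exposure is `X = sum(a_j g_j) + c_x U + e` with the
#' residual variance set so `Var(X) = 1`; in binary-liability mode `X = 1`
#' with probability `expit(alpha_x + sum(a_j g_j) + c_x U)`, the intercept
#' solved by bisection for the target prevalence (|error| < 1e-4). The
#' outcome is `Y = 1` with probability `expit(alpha_y + theta X + sum(d_j
#' g_j) + c_y U)` (binary mode) or `Y = theta X + sum(d_j g_j) + c_y U + e`
#' (continuous mode). Fetal dosages, when requested, transmit one maternal
#' allele (hypergeometric in the dosage) plus one paternal allele drawn at
#' the population frequency.
#'
#' @param config a [sim_config()].
#' @param architecture optional tibble from [draw_snp_architecture()]; when
#'   given, the frequencies and true effects are taken as fixed instead of
#'   redrawn, so several independent samples can share one architecture.
#' @return list of class `cohort_sim`: `cohort` (tibble with `id`, optional
#'   `pregnancy_id`, dosage columns named by rsid, optional fetal dosage
#'   columns `fetal_<rsid>`, `exposure`, `outcome`, covariates `age`,
#'   `pc1`, `pc2`, `confounder`), `snp_info` (rsid, alleles, maf, true
#'   effects `a`, `d`), and `config`.
#' @export
simulate_cohort <- function(config, architecture = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  n <- config$n_subjects
  info <- architecture %||% draw_architecture(config)
  k <- nrow(info)
  G <- matrix(rbinom(n * k, 2, rep(info$maf, each = n)), nrow = n)
  colnames(G) <- info$rsid
  U <- rnorm(n)
  score <- drop(G %*% info$a)
  c_x <- config$confounding$on_exposure
  c_y <- config$confounding$on_outcome
  if (config$exposure_mode == "continuous") {
    var_gen <- sum(info$a^2 * 2 * info$maf * (1 - info$maf))
    var_resid <- 1 - var_gen - c_x^2
    if (var_resid <= 0) {
      abort("instrument and confounder variance exceed 1; cannot scale X.",
            class = "insomniamr_validation_error")
    }
    X <- score + c_x * U + rnorm(n, 0, sqrt(var_resid))
  } else {
    eta_x <- score + c_x * U
    alpha_x <- solve_intercept(eta_x, config$exposure_prevalence,
                               what = "exposure intercept")
    X <- rbinom(n, 1, expit(alpha_x + eta_x))
  }
  direct <- drop(G %*% info$d)
  if (config$outcome_mode == "binary") {
    eta_y <- config$theta * X + direct + c_y * U
    alpha_y <- solve_intercept(eta_y, config$outcome_prevalence,
                               what = "outcome intercept")
    Y <- rbinom(n, 1, expit(alpha_y + eta_y))
  } else {
    Y <- config$theta * X + direct + c_y * U + rnorm(n)
  }
  cohort <- tibble::tibble(
    id = sprintf("w%06d", seq_len(n)),
    exposure = X, outcome = Y,
    age = rnorm(n, 28, 5), pc1 = rnorm(n), pc2 = rnorm(n),
    confounder = U
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(G))
  if (config$fetal_genotypes) {
    # transmitted maternal allele: 0 if g=0, Bernoulli(1/2) if g=1, 1 if g=2
    transmitted <- matrix(
      rbinom(n * k, 1, c(G) / 2), nrow = n
    )
    paternal <- matrix(rbinom(n * k, 1, rep(info$maf, each = n)), nrow = n)
    Fet <- transmitted + paternal
    colnames(Fet) <- paste0("fetal_", info$rsid)
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(Fet))
  }
  if (config$multi_pregnancy_prop > 0) {
    cohort$pregnancy_id <- 1L
    dup <- which(runif(n) < config$multi_pregnancy_prop)
    if (length(dup) > 0) {
      extra <- cohort[dup, , drop = FALSE]
      extra$pregnancy_id <- 2L
      cohort <- dplyr::bind_rows(cohort, extra)
      cohort <- cohort[order(cohort$id, cohort$pregnancy_id), , drop = FALSE]
    }
  }
  structure(list(cohort = cohort, snp_info = info, config = config),
            class = "cohort_sim")
}

#' Simulate summary-statistic association tables directly
#'
#' The fast oracle layer for estimator tests: per SNP,
#' `gamma_hat_j ~ N(a_j, se_exposure^2)` and
#' `Gamma_hat_j ~ N(theta a_j + d_j, se_outcome^2)`, with EAF and sample
#' sizes filled in consistently. No individual-level data are generated.
#'
#' @param config a [sim_config()]; `n_subjects` populates the `n` fields.
#' @param se_exposure,se_outcome reported standard errors (scalar or
#'   per-SNP). Zero is allowed and gives the noise-free limit.
#' @return list: `exposure` and `outcome` association tables (`assoc_tbl`),
#'   `snp_info`.
#' @export
simulate_summary_stats <- function(config, se_exposure, se_outcome) {
  stopifnot(inherits(config, "sim_config"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  info <- draw_architecture(config)
  k <- nrow(info)
  se_exposure <- rep_len(se_exposure, k)
  se_outcome <- rep_len(se_outcome, k)
  gamma_hat <- rnorm(k, info$a, se_exposure)
  Gamma_hat <- rnorm(k, config$theta * info$a + info$d, se_outcome)
  mk <- function(beta, se, scale, trait) {
    se_rep <- ifelse(se > 0, se, 1e-12)  # validator needs se > 0
    as_association_table(
      tibble::tibble(
        rsid = info$rsid, effect_allele = info$effect_allele,
        other_allele = info$other_allele, eaf = info$maf,
        beta = beta, se = se_rep,
        pvalue = p_normal(beta, se_rep), n = config$n_subjects
      ),
      scale = scale, trait = trait, study = "synthetic"
    )
  }
  list(
    exposure = mk(gamma_hat, se_exposure, "linear", "exposure"),
    outcome = mk(Gamma_hat, se_outcome, "log-odds", "outcome"),
    snp_info = info
  )
}
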