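#' Read an individual-level cohort from genotype and phenotype TSVs
#'
#' The genotype file has one row per subject and one dosage column (in
#' `[0, 2]`) per rsid, plus the subject `id` column; the phenotype file
#' carries `id` with exposure, outcomes and covariates. The two are joined
#' on `id`.
#'
#' @param genotype_path,phenotype_path file paths.
#' @param id name of the subject id column (default `"id"`).
#' @return a tibble, one row per subject (per pregnancy if a pregnancy
#'   index column is present).
#' @export
read_cohort <- function(genotype_path, phenotype_path, id = "id") {
  g <- readr::read_tsv(genotype_path, show_col_types = FALSE, progress = FALSE)
  p <- readr::read_tsv(phenotype_path, show_col_types = FALSE, progress = FALSE)
  for (nm in setdiff(names(g), id)) {
    bad <- !is.na(g[[nm]]) & (g[[nm]] < 0 | g[[nm]] > 2)
    if (any(bad)) {
      abort(paste0("dosages outside [0, 2] in column ", nm),
            class = "insomniamr_validation_error")
    }
  }
  dplyr::inner_join(p, g, by = id)
}

#' Write a cohort back to the genotype + phenotype TSV dialect
#'
#' @param cohort cohort tibble.
#' @param snps character vector of rsid (dosage) columns.
#' @param genotype_path,phenotype_path output paths.
#' @param id subject id column.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, snps, genotype_path, phenotype_path,
                         id = "id") {
  readr::write_tsv(cohort[, c(id, snps)], genotype_path, progress = FALSE)
  readr::write_tsv(cohort[, setdiff(names(cohort), snps)], phenotype_path,
                   progress = FALSE)
  invisible(c(genotype_path, phenotype_path))
}

#' Randomly select one pregnancy per woman
#'
#' Cohorts where a small proportion of women contribute more than one
#' pregnancy are reduced to one row per woman, chosen uniformly at random
#' (selecting the first pregnancy instead would bias towards younger age
#' and higher morbidity).
#'
#' @param cohort cohort tibble with a woman id and pregnancy index.
#' @param seed integer seed; the selection is reproducible.
#' @param id woman id column (default `"id"`).
#' @param pregnancy pregnancy index column (default `"pregnancy_id"`).
#' @return cohort tibble with exactly one row per woman.
#' @export
select_one_pregnancy <- function(cohort, seed, id = "id",
                                 pregnancy = "pregnancy_id") {
  if (!pregnancy %in% names(cohort)) {
    abort(paste0("pregnancy index column `", pregnancy, "` not found."),
          class = "insomniamr_validation_error")
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  # draw per-row uniforms, keep the max within each woman: uniform over her
  # pregnancies, and stable under row reordering of other women
  u <- runif(nrow(cohort))
  keep <- unlist(lapply(split(seq_len(nrow(cohort)), cohort[[id]]),
                        function(idx) idx[which.max(u[idx])]),
                 use.names = FALSE)
  out <- cohort[sort(keep), , drop = FALSE]
  stopifnot(!anyDuplicated(out[[id]]))
  out
}

model_frame_for <- function(cohort, vars) {
  missing_vars <- setdiff(vars, names(cohort))
  if (length(missing_vars) > 0) {
    abort(paste0("column(s) not in cohort: ",
                 paste(missing_vars, collapse = ", ")),
          class = "insomniamr_validation_error")
  }
  df <- cohort[, vars, drop = FALSE]
  df[complete.cases(df), , drop = FALSE]
}

#' Estimate one SNP-trait association from individual-level data
#'
#' Fits `trait ~ dosage + covariates` by ordinary least squares
#' (`family = "linear"`, giving risk differences for a binary trait) or by
#' logistic regression (`family = "logistic"`, giving log odds ratios), on
#' complete cases, and returns the dosage term as a one-row association
#' table keyed by the SNP.
#'
#' @param cohort cohort tibble with a dosage column named by `snp`.
#' @param snp rsid (dosage column name).
#' @param trait trait column name; must be 0/1 for logistic fits.
#' @param family `"linear"` or `"logistic"`.
#' @param covariates character vector of covariate column names.
#' @param snp_info optional tibble (`rsid`, `effect_allele`, `other_allele`)
#'   supplying allele labels; dosage columns carry none, so without it the
#'   placeholder pair A/G is used.
#' @return one-row tibble with the `assoc_tbl` columns plus `converged`;
#'   `eaf` is the mean dosage / 2 (the dosage counts effect alleles).
#' @export
fit_snp_trait <- function(cohort, snp, trait,
                          family = c("linear", "logistic"),
                          covariates = character(), snp_info = NULL) {
  family <- match.arg(family)
  df <- model_frame_for(cohort, c(snp, trait, covariates))
  if (var(df[[snp]]) == 0) {
    abort(paste0("dosage for ", snp, " has zero variance."),
          class = "insomniamr_validation_error")
  }
  fml <- stats::reformulate(c(sprintf("`%s`", snp), covariates),
                            response = trait)
  if (family == "linear") {
    fit <- lm(fml, data = df)
    converged <- TRUE
  } else {
    vals <- unique(df[[trait]])
    if (!all(vals %in% c(0, 1))) {
      abort(paste0("trait `", trait, "` must be binary 0/1 for logistic fits."),
            class = "insomniamr_validation_error")
    }
    # tight IRLS contract: deviance tolerance 1e-10 within 100 iterations,
    # non-convergence flagged rather than silently reported
    fit <- glm(fml, data = df, family = binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    converged <- isTRUE(fit$converged)
    if (!converged) {
      warn(paste0("logistic fit for ", snp, " on ", trait,
                  " did not converge; flagging."))
    }
  }
  sm <- summary(fit)$coefficients
  row <- sm[2, , drop = TRUE]
  alleles <- if (!is.null(snp_info) && snp %in% snp_info$rsid) {
    snp_info[match(snp, snp_info$rsid), c("effect_allele", "other_allele")]
  } else {
    tibble::tibble(effect_allele = "A", other_allele = "G")
  }
  tibble::tibble(
    rsid = snp,
    effect_allele = alleles$effect_allele,
    other_allele = alleles$other_allele,
    eaf = mean(df[[snp]]) / 2,
    beta = unname(row[1]),
    se = unname(row[2]),
    pvalue = unname(row[4]),
    n = nrow(df),
    scale = if (family == "linear") "linear" else "log-odds",
    converged = converged
  )
}

# vectorized OLS scan over many SNPs: residualize trait and dosages on the
# covariates once (Frisch-Waugh-Lovell), then per-SNP simple regression.
# Matches per-SNP lm() coefficients and SEs exactly.
fast_linear_scan <- function(cohort, snps, trait, covariates = character()) {
  df <- model_frame_for(cohort, c(snps, trait, covariates))
  n <- nrow(df)
  y <- df[[trait]]
  G <- as.matrix(df[, snps, drop = FALSE])
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(covariates) > 0) {
    X <- cbind(X, stats::model.matrix(
      stats::reformulate(covariates), data = df
    )[, -1, drop = FALSE])
  }
  qx <- qr(X)
  yr <- qr.resid(qx, y)
  Gr <- qr.resid(qx, G)
  sxx <- colSums(Gr^2)
  if (any(sxx == 0)) {
    abort(paste0("dosage has zero residual variance for: ",
                 paste(snps[sxx == 0], collapse = ", ")),
          class = "insomniamr_validation_error")
  }
  beta <- colSums(Gr * yr) / sxx
  df_resid <- n - ncol(X) - 1
  rss <- sum(yr^2) - beta^2 * sxx
  se <- sqrt(rss / df_resid / sxx)
  tibble::tibble(
    rsid = snps,
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(G) / 2,
    beta = unname(beta), se = unname(se),
    pvalue = 2 * pt(-abs(beta / se), df = df_resid),
    n = n, scale = "linear", converged = TRUE
  )
}

#' Estimate associations of many SNPs with one trait
#'
#' Applies [fit_snp_trait()] over a set of SNPs and returns a validated
#' association table. Linear fits use a vectorized residualization that
#' reproduces the per-SNP least-squares fits exactly; logistic fits loop
#' over SNPs.
#'
#' @inheritParams fit_snp_trait
#' @param snps character vector of rsids.
#' @param trait_label,study_label labels stored on the returned table.
#' @return an `assoc_tbl`; non-converged logistic fits are dropped with a
#'   warning (counted in attribute `n_nonconverged`).
#' @export
snp_associations <- function(cohort, snps, trait,
                             family = c("linear", "logistic"),
                             covariates = character(), snp_info = NULL,
                             trait_label = trait, study_label = NULL) {
  family <- match.arg(family)
  rows <- if (family == "linear") {
    fast_linear_scan(cohort, snps, trait, covariates)
  } else {
    purrr::map_dfr(snps, fit_snp_trait, cohort = cohort, trait = trait,
                   family = family, covariates = covariates)
  }
  if (!is.null(snp_info)) {
    idx <- match(rows$rsid, snp_info$rsid)
    ok <- !is.na(idx)
    rows$effect_allele[ok] <- snp_info$effect_allele[idx[ok]]
    rows$other_allele[ok] <- snp_info$other_allele[idx[ok]]
  }
  n_bad <- sum(!rows$converged)
  if (n_bad > 0) {
    warn(paste0("dropping ", n_bad, " non-converged logistic fit(s)."))
    rows <- rows[rows$converged, , drop = FALSE]
  }
  scale <- unique(rows$scale)
  out <- as_association_table(
    rows[, ASSOC_COLS], scale = scale,
    trait = trait_label, study = study_label
  )
  attr(out, "n_nonconverged") <- n_bad
  out
}

#' Split cross-over two-sample MR within one cohort
#'
#' When the SNP-exposure GWAS overlaps the analysis cohort, the cohort is
#' randomly halved (datasets A and B): SNP-exposure associations from A are
#' combined with SNP-outcome associations from B (A on B) and vice versa,
#' each by IVW, and the two cross-estimates are pooled by fixed-effects
#' inverse-variance meta-analysis. This keeps the two samples of each
#' 2-sample MR non-overlapping.
#'
#' @param cohort cohort tibble.
#' @param snps rsids of the instruments (dosage columns).
#' @param exposure,outcome column names; the outcome must be binary when
#'   `family_outcome = "logistic"`.
#' @param seed integer seed for the half-split.
#' @param family_exposure,family_outcome regression families for the two
#'   association stages (defaults: linear exposure, i.e. risk-difference
#'   scale, and logistic outcome).
#' @param covariates covariate columns used in both halves.
#' @param ivw_variant passed to [mr_ivw()].
#' @param min_cases refuse the split when either half has fewer outcome
#'   cases than this (default 10).
#' @return tibble with rows `a_on_b`, `b_on_a`, `combined` (columns of an
#'   `mr_estimate` plus `estimate_label`); the combined row is exactly the
#'   fixed-effects meta-analysis of the two cross-estimates.
#' @export
split_crossover <- function(cohort, snps, exposure, outcome, seed,
                            family_exposure = "linear",
                            family_outcome = "logistic",
                            covariates = character(),
                            ivw_variant = "multiplicative-random",
                            min_cases = 10) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  in_a <- sample.int(n, floor(n / 2))
  halves <- list(a = cohort[in_a, , drop = FALSE],
                 b = cohort[-in_a, , drop = FALSE])
  if (family_outcome == "logistic") {
    cases <- vapply(halves, function(x) sum(x[[outcome]] == 1, na.rm = TRUE),
                    numeric(1))
    if (any(cases < min_cases)) {
      abort(paste0("outcome case count below ", min_cases,
                   " in one half (", paste(cases, collapse = "/"),
                   "); refusing the split."),
            class = "insomniamr_validation_error")
    }
  }
  est_one <- function(exp_half, out_half) {
    exp_tab <- snp_associations(exp_half, snps, exposure,
                                family = family_exposure,
                                covariates = covariates)
    out_tab <- snp_associations(out_half, snps, outcome,
                                family = family_outcome,
                                covariates = covariates)
    mr_ivw(harmonize(exp_tab, out_tab), ivw_variant)
  }
  a_on_b <- est_one(halves$a, halves$b)
  b_on_a <- est_one(halves$b, halves$a)
  meta <- fixed_effects_meta(tibble::tibble(
    study = c("a_on_b", "b_on_a"),
    beta = c(a_on_b$beta, b_on_a$beta),
    se = c(a_on_b$se, b_on_a$se)
  ))
  combined <- new_mr_estimate("ivw", "split-crossover-combined",
                              a_on_b$n_snps, meta$beta, meta$se)
  dplyr::bind_cols(
    tibble::tibble(estimate_label = c("a_on_b", "b_on_a", "combined")),
    dplyr::bind_rows(a_on_b, b_on_a, combined)
  )
}

#' Compare SNP-outcome associations with and without fetal-genotype adjustment
#'
#' Maternal genotype can affect a perinatal outcome through the transmitted
#' fetal genotype; comparing maternal SNP-outcome associations with versus
#' without adjustment for the fetal dosage (in the subset of pairs with
#' fetal data, identical for both fits) bounds that path.
#'
#' @param cohort cohort tibble with maternal dosage columns `snps` and fetal
#'   dosage columns `paste0(fetal_prefix, snps)`.
#' @param snps maternal rsids.
#' @param outcome binary outcome column.
#' @param covariates additional covariates for both fits.
#' @param fetal_prefix prefix of the fetal dosage columns (default
#'   `"fetal_"`).
#' @param family regression family (default logistic).
#' @return tibble with one row per SNP: `rsid`, `beta_unadjusted`,
#'   `se_unadjusted`, `beta_adjusted`, `se_adjusted`, `delta_beta`, `n`,
#'   `collinear`.
#' @export
fetal_adjustment_compare <- function(cohort, snps, outcome,
                                     covariates = character(),
                                     fetal_prefix = "fetal_",
                                     family = "logistic") {
  fetal_cols <- paste0(fetal_prefix, snps)
  missing_cols <- setdiff(fetal_cols, names(cohort))
  if (length(missing_cols) == length(fetal_cols)) {
    abort("no fetal genotype columns found.",
          class = "insomniamr_validation_error")
  }
  purrr::map_dfr(seq_along(snps), function(j) {
    snp <- snps[j]
    fet <- fetal_cols[j]
    sub <- cohort[!is.na(cohort[[fet]]), , drop = FALSE]
    sub <- model_frame_for(sub, c(snp, fet, outcome, covariates))
    unadj <- fit_snp_trait(sub, snp, outcome, family = family,
                           covariates = covariates)
    collinear <- var(sub[[fet]] - sub[[snp]]) == 0
    if (collinear) {
      adj <- tibble::tibble(beta = NA_real_, se = NA_real_)
      warn(paste0("fetal dosage for ", snp,
                  " is collinear with the maternal dosage."))
    } else {
      adj <- fit_snp_trait(sub, snp, outcome, family = family,
                           covariates = c(fet, covariates))
    }
    tibble::tibble(
      rsid = snp,
      beta_unadjusted = unadj$beta, se_unadjusted = unadj$se,
      beta_adjusted = adj$beta, se_adjusted = adj$se,
      delta_beta = adj$beta - unadj$beta,
      n = nrow(sub), collinear = collinear
    )
  })
}

#' Crude and confounder-adjusted logistic regression of an outcome on
#' in-pregnancy insomnia
#'
#' The observational comparator to MR: logistic regression of a binary
#' outcome on the binary exposure, crude and adjusted for the measured
#' confounder block, each on its own complete cases (so the adjusted n is
#' at most the crude n).
#'
#' @param cohort cohort tibble.
#' @param exposure binary exposure column (e.g. insomnia at 18 weeks).
#' @param outcome binary outcome column.
#' @param confounders character vector of confounder columns.
#' @return object of class `mvreg_fit`: list with `crude` and `adjusted`
#'   `glm` fits, `exposure`, `outcome`, and `separation_flagged`. Use
#'   [tidy.mvreg_fit()] / [glance.mvreg_fit()] for tidy summaries.
#' @export
multivariable_outcome_regression <- function(cohort, exposure, outcome,
                                             confounders = character()) {
  df_crude <- model_frame_for(cohort, c(exposure, outcome))
  df_adj <- model_frame_for(cohort, c(exposure, outcome, confounders))
  crude <- glm(stats::reformulate(exposure, response = outcome),
               data = df_crude, family = binomial())
  adjusted <- glm(
    stats::reformulate(c(exposure, confounders), response = outcome),
    data = df_adj, family = binomial()
  )
  # quasi-separation shows up as fitted probabilities at the boundary or
  # an exploding exposure SE
  eps <- 1e-8
  sep <- any(adjusted$fitted.values < eps | adjusted$fitted.values > 1 - eps) ||
    summary(adjusted)$coefficients[2, 2] > 10
  if (sep) warn("possible quasi-separation in the adjusted model.")
  structure(
    list(crude = crude, adjusted = adjusted,
         exposure = exposure, outcome = outcome,
         separation_flagged = sep),
    class = "mvreg_fit"
  )
}

mvreg_term_row <- function(fit, model_label, term_idx) {
  sm <- summary(fit)$coefficients
  est <- sm[term_idx, 1]
  se <- sm[term_idx, 2]
  tibble::tibble(
    model = model_label,
    term = rownames(sm)[term_idx],
    estimate = est, std.error = se,
    conf.low = est - Z95 * se, conf.high = est + Z95 * se,
    p.value = sm[term_idx, 4],
    or = exp(est), or_conf.low = exp(est - Z95 * se),
    or_conf.high = exp(est + Z95 * se)
  )
}

#' @rdname multivariable_outcome_regression
#' @param x an `mvreg_fit`.
#' @param ... unused.
#' @method tidy mvreg_fit
#' @export
tidy.mvreg_fit <- function(x, ...) {
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(nrow(summary(x$crude)$coefficients)),
                   ~ mvreg_term_row(x$crude, "crude", .x)),
    purrr::map_dfr(seq_len(nrow(summary(x$adjusted)$coefficients)),
                   ~ mvreg_term_row(x$adjusted, "adjusted", .x))
  )
}

#' @rdname multivariable_outcome_regression
#' @method glance mvreg_fit
#' @export
glance.mvreg_fit <- function(x, ...) {
  crude <- mvreg_term_row(x$crude, "crude", 2)
  adj <- mvreg_term_row(x$adjusted, "adjusted", 2)
  tibble::tibble(
    model = c("crude", "adjusted"),
    or = c(crude$or, adj$or),
    or_conf.low = c(crude$or_conf.low, adj$or_conf.low),
    or_conf.high = c(crude$or_conf.high, adj$or_conf.high),
    p.value = c(crude$p.value, adj$p.value),
    n = c(stats::nobs(x$crude), stats::nobs(x$adjusted)),
    separation_flagged = x$separation_flagged
  )
}

#' @export
print.mvreg_fit <- function(x, ...) {
  g <- glance(x)
  cat("Multivariable regression of ", x$outcome, " on ", x$exposure, "\n",
      sep = "")
  for (i in 1:2) {
    cat(sprintf("  %-8s OR %.2f (95%% CI %.2f, %.2f), p = %.3g, n = %d\n",
                g$model[i], g$or[i], g$or_conf.low[i], g$or_conf.high[i],
                g$p.value[i], g$n[i]))
  }
  invisible(x)
}

#' Percentage prevalence as printed in characteristics tables
#'
#' `100 * cases / (cases + controls)`, rounded half-up to one decimal.
#'
#' @param cases,controls counts.
#' @param digits decimal places (default 1).
#' @return numeric vector.
#' @export
prevalence_pct <- function(cases, controls, digits = 1) {
  round_half_up(100 * cases / (cases + controls), digits)
}

#' Characteristics table for a cohort
#'
#' Per continuous variable, mean (SD); per categorical variable level,
#' N (% of total N); per binary outcome, N cases / N controls with
#' prevalence `100 * cases / (cases + controls)`. Percentages are rounded
#' half-up to one decimal. With a stratifier, every statistic is computed
#' within each stratum (percentages keep the total-N denominator, as in
#' published baseline tables); empty strata yield all-zero rows.
#'
#' @param cohort cohort tibble.
#' @param continuous,categorical,outcomes character vectors of column names.
#' @param stratifier optional column name to stratify by.
#' @return tidy tibble: `stratum`, `variable`, `level`, `n`, `mean`, `sd`,
#'   `percent`, `cases`, `controls`, `prevalence`, `formatted`.
#' @export
tabulate_characteristics <- function(cohort, continuous = character(),
                                     categorical = character(),
                                     outcomes = character(),
                                     stratifier = NULL) {
  total_n <- nrow(cohort)
  strata <- if (is.null(stratifier)) list(all = cohort) else
    split(cohort, cohort[[stratifier]], drop = FALSE)
  purrr::imap_dfr(strata, function(sub, stratum) {
    rows <- list()
    for (v in continuous) {
      x <- sub[[v]][!is.na(sub[[v]])]
      m <- if (length(x) > 0) mean(x) else 0
      s <- if (length(x) > 1) sd(x) else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = stratum, variable = v, level = NA_character_,
        n = length(x), mean = m, sd = s,
        percent = NA_real_, cases = NA_real_, controls = NA_real_,
        prevalence = NA_real_,
        formatted = sprintf("%.1f (%.1f)", round_half_up(m, 1),
                            round_half_up(s, 1))
      )
    }
    for (v in categorical) {
      lv <- sort(unique(cohort[[v]][!is.na(cohort[[v]])]))
      for (l in lv) {
        cnt <- sum(sub[[v]] == l, na.rm = TRUE)
        pct <- if (total_n > 0) round_half_up(100 * cnt / total_n, 1) else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          stratum = stratum, variable = v, level = as.character(l),
          n = cnt, mean = NA_real_, sd = NA_real_,
          percent = pct, cases = NA_real_, controls = NA_real_,
          prevalence = NA_real_,
          formatted = sprintf("%s (%.1f)", format(cnt, big.mark = ","), pct)
        )
      }
    }
    for (v in outcomes) {
      cases <- sum(sub[[v]] == 1, na.rm = TRUE)
      controls <- sum(sub[[v]] == 0, na.rm = TRUE)
      prev <- if (cases + controls > 0) prevalence_pct(cases, controls) else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = stratum, variable = v, level = NA_character_,
        n = cases + controls, mean = NA_real_, sd = NA_real_,
        percent = NA_real_, cases = cases, controls = controls,
        prevalence = prev,
        formatted = sprintf("%s/%s (%.1f)", format(cases, big.mark = ","),
                            format(controls, big.mark = ","), prev)
      )
    }
    dplyr::bind_rows(rows)
  })
}
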