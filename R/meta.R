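#' Fixed-effects inverse-variance meta-analysis of study estimates
#'
#' Combines per-study causal estimates on the log-odds-ratio scale with
#' weights `w_i = 1 / se_i^2`: `beta = sum(w * beta_i) / sum(w)`,
#' `se = sum(w)^(-1/2)`. Between-study heterogeneity is reported as
#' Cochran's Q with `m - 1` degrees of freedom (a Q p-value below 0.05
#' suggests between-study heterogeneity).
#'
#' @param estimates tibble with one row per study: columns `study`, `beta`,
#'   `se` (extra columns are ignored). All estimates must share one scale;
#'   if a `scale` column is present it must be constant.
#' @return one-row tibble of class `meta_result`: `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `or`, `or_ci_low`, `or_ci_high`, `n_studies`,
#'   `q`, `q_df`, `q_pvalue`. Attribute `contributions` holds per-study
#'   weights and weight shares.
#' @export
fixed_effects_meta <- function(estimates) {
  stopifnot(all(c("study", "beta", "se") %in% names(estimates)))
  if (nrow(estimates) < 1) {
    abort("need at least one study estimate.",
          class = "insomniamr_validation_error")
  }
  if ("scale" %in% names(estimates) &&
      length(unique(estimates$scale)) > 1) {
    abort("study estimates mix effect scales; refuse to combine.",
          class = "insomniamr_validation_error")
  }
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) {
    abort("every study estimate needs a positive finite se.",
          class = "insomniamr_validation_error")
  }
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  m <- nrow(estimates)
  q <- sum(w * (estimates$beta - beta)^2)
  q_df <- m - 1
  out <- tibble::new_tibble(
    tibble::tibble(
      beta = beta, se = se,
      ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
      pvalue = p_normal(beta, se),
      or = exp(beta), or_ci_low = exp(beta - Z95 * se),
      or_ci_high = exp(beta + Z95 * se),
      n_studies = m, q = q, q_df = q_df,
      q_pvalue = if (q_df > 0) pchisq(q, q_df, lower.tail = FALSE) else NA_real_
    ),
    class = "meta_result"
  )
  attr(out, "contributions") <- tibble::tibble(
    study = estimates$study, beta = estimates$beta, se = estimates$se,
    weight = w, weight_share = w / sum(w)
  )
  out
}

#' Leave-one-study-out meta-analysis
#'
#' Recombines the study estimates m times, omitting each study in turn, to
#' assess how much any single cohort drives the pooled estimate. An
#' optional restriction re-runs the analysis within a named subset of
#' studies (e.g. the non-UKB cohorts).
#'
#' @param estimates as in [fixed_effects_meta()], with at least 2 rows.
#' @param restrict optional character vector of study labels; the
#'   leave-one-out cycle is then run within this subset only.
#' @return tibble with one row per omitted study: `omitted_study` plus the
#'   `meta_result` columns.
#' @export
leave_one_study_out <- function(estimates, restrict = NULL) {
  if (!is.null(restrict)) {
    estimates <- estimates[estimates$study %in% restrict, , drop = FALSE]
  }
  if (nrow(estimates) < 2) {
    abort("leave-one-study-out needs at least 2 studies.",
          class = "insomniamr_validation_error")
  }
  purrr::map_dfr(seq_len(nrow(estimates)), function(i) {
    res <- fixed_effects_meta(estimates[-i, , drop = FALSE])
    dplyr::bind_cols(
      tibble::tibble(omitted_study = estimates$study[i]), res
    )
  })
}
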