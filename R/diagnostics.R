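#' Cochran's Q heterogeneity statistic for a harmonized set
#'
#' `Q = sum(w_j * (ratio_j - beta_ref)^2)` over the per-SNP Wald ratios,
#' with inverse-variance weights `w_j = 1 / se_ratio_j^2`. Under homogeneity
#' Q follows a chi-square distribution with `k - 1` degrees of freedom;
#' excess Q suggests one or more SNPs with horizontally pleiotropic effects.
#'
#' @param h a `harmonized_set` with at least 2 retained SNPs.
#' @param beta_ref reference causal estimate: a number or a one-row
#'   `mr_estimate` (defaults to the fixed-effect IVW estimate of `h`).
#' @param se_order passed to [wald_ratios()].
#' @return one-row tibble: `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, beta_ref = NULL, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  hr <- retained(h)
  check_snp_count(hr, 2, "Cochran's Q")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(h, "fixed")
  if (is.data.frame(beta_ref)) beta_ref <- beta_ref$beta
  wr <- wald_ratios(hr, se_order = se_order)
  q <- sum(wr$weight * (wr$ratio - beta_ref)^2)
  df <- nrow(wr) - 1
  tibble::tibble(q = q, df = df, pvalue = pchisq(q, df, lower.tail = FALSE))
}

#' Leave-one-SNP-out sensitivity analysis
#'
#' Recomputes the IVW estimate k times, omitting each SNP in turn. A single
#' influential (e.g. pleiotropic) SNP shows up as the omission that moves
#' the estimate furthest from the full-set value.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @param variant IVW variant, as in [mr_ivw()].
#' @return tibble with one row per omitted SNP: `omitted_rsid` plus the
#'   `mr_estimate` columns; attribute `full` holds the all-SNP estimate.
#' @export
leave_one_snp_out <- function(h, variant = c("multiplicative-random", "fixed")) {
  variant <- match.arg(variant)
  hr <- retained(h)
  check_snp_count(hr, 3, "leave-one-SNP-out")
  full <- mr_ivw(hr, variant)
  out <- purrr::map_dfr(seq_len(nrow(hr)), function(j) {
    est <- mr_ivw(hr[-j, , drop = FALSE], variant)
    dplyr::bind_cols(tibble::tibble(omitted_rsid = hr$rsid[j]), est)
  })
  attr(out, "full") <- full
  out
}

# variance in a trait explained by one SNP, from summary statistics.
# log-odds betas: latent-logit scale, r2 = b^2 v / (b^2 v + pi^2 / 3) with
# v = 2 f (1 - f); linear (risk-difference) betas on a binary trait of
# prevalence p: r2 = b^2 v / (p (1 - p)); linear betas on a continuous
# trait: r2 = b^2 v / trait variance (default 1, the generator's scaling).
snp_r2 <- function(beta, eaf, scale, prevalence = NULL,
                   trait_variance = 1) {
  v <- 2 * eaf * (1 - eaf)
  if (scale == "log-odds") {
    beta^2 * v / (beta^2 * v + pi^2 / 3)
  } else {
    denom <- if (is.null(prevalence)) trait_variance else
      prevalence * (1 - prevalence)
    beta^2 * v / denom
  }
}

#' Steiger directionality filtering
#'
#' Guards against reverse causation by removing instruments that explain
#' substantially more variance in the outcome than in the exposure. Per SNP,
#' the variance explained on each side is computed from summary statistics
#' (see Details), the implied correlations are Fisher z-transformed, and the
#' two-sample statistic
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`
#' is referred to the normal distribution. A SNP is removed iff
#' `r2_outcome > r2_exposure` and the two-sided p-value is below `alpha`.
#'
#' @details For log-odds betas the variance explained uses the latent
#' logistic scale, `r2 = b^2 2f(1-f) / (b^2 2f(1-f) + pi^2/3)`, which needs
#' only summary data. For linear-scale (risk difference) betas on a binary
#' trait the observed-scale formula `r2 = b^2 2f(1-f) / (p(1-p))` is used,
#' with `p` the trait prevalence.
#'
#' @param h a `harmonized_set`; scale tags are taken from its attributes
#'   (overridable).
#' @param alpha removal significance level (default 0.05).
#' @param prevalence_exposure,prevalence_outcome trait prevalences, needed
#'   only for linear-scale sides.
#' @param scale_exposure,scale_outcome optional scale overrides.
#' @return list with `harmonized` (the filtered `harmonized_set`, removed
#'   SNPs flagged `steiger-removed`) and `audit` (tibble: `rsid`,
#'   `r2_exposure`, `r2_outcome`, `z`, `pvalue`, `removed`).
#' @export
steiger_filter <- function(h, alpha = 0.05,
                           prevalence_exposure = NULL,
                           prevalence_outcome = NULL,
                           scale_exposure = NULL, scale_outcome = NULL) {
  scale_exposure <- scale_exposure %||%
    attr(h, "scale_exposure", exact = TRUE) %||% "log-odds"
  scale_outcome <- scale_outcome %||%
    attr(h, "scale_outcome", exact = TRUE) %||% "log-odds"
  hr <- retained(h)
  if (any(!is.finite(hr$n_exposure)) || any(!is.finite(hr$n_outcome))) {
    bad <- hr$rsid[!is.finite(hr$n_exposure) | !is.finite(hr$n_outcome)]
    abort(paste0("sample size missing for SNP(s): ",
                 paste(bad, collapse = ", ")),
          class = "insomniamr_validation_error")
  }
  r2_exp <- snp_r2(hr$beta_exposure, hr$eaf_exposure, scale_exposure,
                   prevalence_exposure)
  r2_out <- snp_r2(hr$beta_outcome, hr$eaf_outcome, scale_outcome,
                   prevalence_outcome)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (hr$n_exposure - 3) + 1 / (hr$n_outcome - 3))
  pval <- 2 * pnorm(-abs(z))
  removed <- r2_out > r2_exp & pval < alpha
  audit <- tibble::tibble(
    rsid = hr$rsid, r2_exposure = r2_exp, r2_outcome = r2_out,
    z = z, pvalue = pval, removed = removed
  )
  idx <- match(hr$rsid[removed], h$rsid)
  h$excluded[idx] <- TRUE
  h$exclusion_reason[idx] <- "steiger-removed"
  list(harmonized = h, audit = audit)
}

#' Instrument-strength diagnostics
#'
#' Per-SNP F-statistic `(beta / se)^2`, per-SNP variance explained
#' `beta^2 * 2 * eaf * (1 - eaf) / exposure_variance`, their mean and total.
#' A mean F near 10 marks the conventional weak-instrument boundary.
#'
#' @param exposure an `assoc_tbl` of SNP-exposure associations on the linear
#'   scale.
#' @param exposure_variance variance of the exposure (for a binary exposure
#'   of prevalence p on the risk-difference scale, `p * (1 - p)`).
#' @return list of class `instrument_strength`: `per_snp` tibble (`rsid`,
#'   `f`, `r2`), `mean_f`, `total_r2`.
#' @export
instrument_strength <- function(exposure, exposure_variance) {
  f <- (exposure$beta / exposure$se)^2
  r2 <- exposure$beta^2 * 2 * exposure$eaf * (1 - exposure$eaf) /
    exposure_variance
  structure(
    list(
      per_snp = tibble::tibble(rsid = exposure$rsid, f = f, r2 = r2),
      mean_f = mean(f),
      total_r2 = sum(r2)
    ),
    class = "instrument_strength"
  )
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf(
    "Instrument strength over %d SNPs: mean F = %.2f, total R^2 = %.4f%%\n",
    nrow(x$per_snp), x$mean_f, 100 * x$total_r2
  ))
  invisible(x)
}

#' @method glance instrument_strength
#' @export
glance.instrument_strength <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x$per_snp), mean_f = x$mean_f,
                 total_r2 = x$total_r2)
}

#' Mean F-statistic implied by aggregate instrument summaries
#'
#' When only the total variance explained by k SNPs in a sample of size n is
#' reported, the mean per-SNP F follows from `F_j = r2_j (n - 2) / (1 - r2_j)`
#' applied at the mean per-SNP r-squared (exact to first order for the small
#' r-squared values typical of complex-trait instruments).
#'
#' @param total_r2 total variance explained by the instruments (proportion).
#' @param n_snps number of instruments.
#' @param n sample size.
#' @return implied mean F-statistic.
#' @export
mean_f_from_r2 <- function(total_r2, n_snps, n) {
  r2 <- total_r2 / n_snps
  r2 * (n - 2) / (1 - r2)
}
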