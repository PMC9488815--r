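new_mr_estimate <- function(method, variant, n_snps, beta, se, pvalue = NULL) {
  tibble::new_tibble(
    tibble::tibble(
      method = method,
      variant = variant,
      n_snps = as.integer(n_snps),
      beta = beta,
      se = se,
      ci_low = beta - Z95 * se,
      ci_high = beta + Z95 * se,
      pvalue = pvalue %||% p_normal(beta, se),
      or = exp(beta),
      or_ci_low = exp(beta - Z95 * se),
      or_ci_high = exp(beta + Z95 * se)
    ),
    class = "mr_estimate"
  )
}

check_snp_count <- function(h, k_min, method) {
  k <- nrow(h)
  if (k < k_min) {
    abort(
      paste0(method, " needs at least ", k_min, " retained SNPs, got ", k,
             if (k_min == 2) "; use wald_ratios() for a single SNP." else "."),
      class = "insomniamr_validation_error"
    )
  }
  k
}

#' Per-SNP Wald ratio estimates
#'
#' The Wald ratio for SNP j is the SNP-outcome association divided by the
#' SNP-exposure association, `ratio_j = beta_outcome_j / beta_exposure_j`.
#' Its first-order (delta-method) standard error is
#' `se_outcome_j / |beta_exposure_j|`; the second-order variant adds the
#' exposure-side uncertainty,
#' `sqrt(se_out^2 / gamma^2 + beta_out^2 * se_exp^2 / gamma^4)`.
#'
#' @param h a `harmonized_set`; excluded rows are ignored. SNPs with a zero
#'   exposure beta are dropped with a warning.
#' @param se_order `"first"` (default) or `"second"` order delta method.
#' @return tibble with columns `rsid`, `ratio`, `se`, `weight`
#'   (`1 / se^2`).
#' @export
wald_ratios <- function(h, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  h <- retained(h)
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    warn(paste0("excluding ", sum(zero),
                " SNP(s) with zero exposure beta from Wald ratios."))
    h <- h[!zero, , drop = FALSE]
  }
  g <- h$beta_exposure
  ratio <- h$beta_outcome / g
  se <- if (se_order == "first") {
    h$se_outcome / abs(g)
  } else {
    sqrt(h$se_outcome^2 / g^2 + h$beta_outcome^2 * h$se_exposure^2 / g^4)
  }
  tibble::tibble(rsid = h$rsid, ratio = ratio, se = se, weight = 1 / se^2)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' The IVW estimator regresses SNP-outcome associations on SNP-exposure
#' associations with weights equal to the inverse SNP-outcome variances and
#' the intercept forced through zero:
#' `beta = sum(g * G / se_out^2) / sum(g^2 / se_out^2)`. The fixed-effect
#' standard error is `(sum(g^2 / se_out^2))^(-1/2)`; the
#' multiplicative-random-effects variant (the default) inflates it by
#' `max(1, sqrt(Q / (k - 1)))` where Q is Cochran's heterogeneity statistic
#' of the Wald ratios about the IVW estimate. Two-sided p-values use the
#' normal distribution.
#'
#' @param h a `harmonized_set` with at least 2 retained SNPs.
#' @param variant `"multiplicative-random"` (default) or `"fixed"`.
#' @return a one-row `mr_estimate` tibble: `method`, `variant`, `n_snps`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `or`, `or_ci_low`,
#'   `or_ci_high`. Attributes `q`, `q_df`, `q_pvalue` carry heterogeneity.
#' @export
mr_ivw <- function(h, variant = c("multiplicative-random", "fixed")) {
  variant <- match.arg(variant)
  hr <- retained(h)
  k <- check_snp_count(hr, 2, "IVW")
  g <- hr$beta_exposure
  G <- hr$beta_outcome
  w <- 1 / hr$se_outcome^2
  beta <- sum(w * g * G) / sum(w * g^2)
  se_fixed <- 1 / sqrt(sum(w * g^2))
  q <- sum(w * (G - beta * g)^2)
  se <- if (variant == "fixed") se_fixed else
    se_fixed * max(1, sqrt(q / (k - 1)))
  out <- new_mr_estimate("ivw", variant, k, beta, se)
  attr(out, "q") <- q
  attr(out, "q_df") <- k - 1
  attr(out, "q_pvalue") <- pchisq(q, k - 1, lower.tail = FALSE)
  out
}

#' MR-Egger regression
#'
#' The same inverse-variance-weighted regression as [mr_ivw()] but with a
#' free intercept: `G_j = b0 + b1 * g_j`, weights `1 / se_out^2`, after
#' orienting the exposure so all `g_j >= 0`. A non-null intercept signals
#' unbalanced horizontal pleiotropy; the slope is the
#' pleiotropy-corrected causal estimate. Standard errors are inflated by
#' `max(1, sqrt(Q_E / (k - 2)))` and p-values use the t distribution with
#' `k - 2` degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @return list of class `mr_egger_result` with elements `slope` (a one-row
#'   `mr_estimate`) and `intercept` (tibble: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`), plus `q`, `q_df`, `q_pvalue`.
#' @export
mr_egger <- function(h) {
  hr <- retained(orient_exposure(h))
  k <- check_snp_count(hr, 3, "MR-Egger")
  g <- hr$beta_exposure
  G <- hr$beta_outcome
  w <- 1 / hr$se_outcome^2
  if (diff(range(g)) == 0) {
    abort("all exposure betas are equal; Egger regression is collinear.",
          class = "insomniamr_validation_error")
  }
  # closed-form weighted least squares with a floored residual scale
  sw <- sum(w)
  gbar <- sum(w * g) / sw
  Gbar <- sum(w * G) / sw
  sxx <- sum(w * (g - gbar)^2)
  slope <- sum(w * (g - gbar) * (G - Gbar)) / sxx
  intercept <- Gbar - slope * gbar
  resid <- G - intercept - slope * g
  q <- sum(w * resid^2)
  phi <- max(1, q / (k - 2))
  se_slope <- sqrt(phi / sxx)
  se_int <- sqrt(phi * (1 / sw + gbar^2 / sxx))
  p_t <- function(est, se) 2 * pt(-abs(est / se), df = k - 2)
  slope_row <- new_mr_estimate("egger-slope", "multiplicative-random", k,
                               slope, se_slope, pvalue = p_t(slope, se_slope))
  structure(
    list(
      slope = slope_row,
      intercept = tibble::tibble(
        estimate = intercept, se = se_int,
        ci_low = intercept - Z95 * se_int,
        ci_high = intercept + Z95 * se_int,
        pvalue = p_t(intercept, se_int)
      ),
      q = q, q_df = k - 2,
      q_pvalue = pchisq(q, k - 2, lower.tail = FALSE)
    ),
    class = "mr_egger_result"
  )
}

# interpolated weighted median of ratios given positive weights
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  k <- length(r)
  if (0.5 >= p[k]) return(r[k])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios, consistent as long as
#' less than 50% of the weight comes from invalid instruments. Ratios are
#' sorted, inverse-variance weights normalized, cumulative weight midpoints
#' `p_j = sum(w_i, i <= j) - w_j / 2` formed, and the estimate read off by
#' linear interpolation where `p` crosses 0.5. The standard error is the
#' standard deviation of the estimate over `n_boot` parametric-bootstrap
#' replicates that redraw both association sets from normal distributions
#' centred on the estimates with their reported SEs.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @param n_boot bootstrap replicates (default 1000; fewer than 100 draws a
#'   warning).
#' @param seed integer seed, mandatory for reproducibility.
#' @param se_order passed to [wald_ratios()]; affects the weights only.
#' @return a one-row `mr_estimate` tibble (method `weighted-median`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed,
                               se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (missing(seed)) {
    abort("`seed` is mandatory for the weighted-median bootstrap.",
          class = "insomniamr_validation_error")
  }
  if (n_boot < 100) warn("n_boot < 100 gives an unstable bootstrap SE.")
  hr <- retained(h)
  check_snp_count(hr, 3, "weighted median")
  hr <- hr[order(hr$rsid), , drop = FALSE]  # input-order invariance
  wr <- wald_ratios(hr, se_order = se_order)
  est <- weighted_median_point(wr$ratio, wr$weight)
  k <- nrow(hr)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  g_star <- matrix(rnorm(k * n_boot, hr$beta_exposure, hr$se_exposure), nrow = k)
  G_star <- matrix(rnorm(k * n_boot, hr$beta_outcome, hr$se_outcome), nrow = k)
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- g_star[, b]
    ok <- g != 0
    ratio <- G_star[ok, b] / g[ok]
    se <- if (se_order == "first") {
      hr$se_outcome[ok] / abs(g[ok])
    } else {
      sqrt(hr$se_outcome[ok]^2 / g[ok]^2 +
             G_star[ok, b]^2 * hr$se_exposure[ok]^2 / g[ok]^4)
    }
    weighted_median_point(ratio, 1 / se^2)
  }, numeric(1))
  new_mr_estimate("weighted-median", "bootstrap", k, est, sd(boots))
}

#' Run all causal estimators on one harmonized set
#'
#' Convenience wrapper returning IVW (both variants), the MR-Egger slope and
#' intercept, and the weighted median in one tidy table, the unit written to
#' the per-outcome results TSV.
#'
#' @inheritParams mr_weighted_median
#' @param n_boot weighted-median bootstrap replicates.
#' @return tibble with one row per estimate; Egger intercept appears as
#'   method `egger-intercept`.
#' @export
mr_all <- function(h, n_boot = 1000, seed) {
  ivw_mr <- mr_ivw(h, "multiplicative-random")
  ivw_f <- mr_ivw(h, "fixed")
  egger <- mr_egger(h)
  wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  int <- egger$intercept
  int_row <- new_mr_estimate("egger-intercept", "multiplicative-random",
                             egger$slope$n_snps, int$estimate, int$se,
                             pvalue = int$pvalue)
  dplyr::bind_rows(ivw_mr, ivw_f, egger$slope, int_row, wm)
}

#' @export
print.mr_egger_result <- function(x, ...) {
  cat("MR-Egger regression (", x$slope$n_snps, " SNPs)\n", sep = "")
  cat(sprintf("  slope     % .4f (se %.4f, p = %.3g)\n",
              x$slope$beta, x$slope$se, x$slope$pvalue))
  cat(sprintf("  intercept % .4f (se %.4f, p = %.3g)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mr_egger_result
#' @export
tidy.mr_egger_result <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope$beta, x$intercept$estimate),
    std.error = c(x$slope$se, x$intercept$se),
    conf.low = c(x$slope$ci_low, x$intercept$ci_low),
    conf.high = c(x$slope$ci_high, x$intercept$ci_high),
    p.value = c(x$slope$pvalue, x$intercept$pvalue)
  )
}

#' @method glance mr_egger_result
#' @export
glance.mr_egger_result <- function(x, ...) {
  tibble::tibble(
    n_snps = x$slope$n_snps, q = x$q, q_df = x$q_df, q_pvalue = x$q_pvalue
  )
}
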