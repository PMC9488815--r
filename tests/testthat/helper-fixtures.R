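# fixtures built in code; all randomness is locally seeded

# small association table with configurable fields
make_assoc <- function(rsid, beta, se,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, pvalue = NULL, n = 10000,
                       scale = "linear", trait = "exposure", study = "test") {
  k <- length(rsid)
  as_association_table(
    tibble::tibble(
      rsid = rsid,
      effect_allele = rep_len(effect_allele, k),
      other_allele = rep_len(other_allele, k),
      eaf = rep_len(eaf, k),
      beta = beta,
      se = rep_len(se, k),
      pvalue = pvalue %||% pmin(1, 2 * stats::pnorm(-abs(beta / se))),
      n = rep_len(n, k)
    ),
    scale = scale, trait = trait, study = study
  )
}

`%||%` <- rlang::`%||%`

# harmonized set straight from exposure/outcome effect vectors (alleles
# already aligned), the shape the estimators consume
make_harmonized <- function(beta_exposure, beta_outcome,
                            se_exposure = 0.01, se_outcome = 0.05,
                            eaf = 0.3, n_exposure = 1e5, n_outcome = 1e5) {
  k <- length(beta_exposure)
  exp_tab <- make_assoc(sprintf("rs%03d", seq_len(k)), beta_exposure,
                        rep_len(se_exposure, k), eaf = eaf, n = n_exposure)
  out_tab <- make_assoc(sprintf("rs%03d", seq_len(k)), beta_outcome,
                        rep_len(se_outcome, k), eaf = eaf, n = n_outcome,
                        scale = "log-odds", trait = "outcome")
  harmonize(exp_tab, out_tab)
}

# random harmonized instance for property tests (RNG assumed seeded)
random_harmonized <- function(k = 10) {
  make_harmonized(
    beta_exposure = runif(k, 0.02, 0.2),
    beta_outcome = rnorm(k, 0, 0.05),
    se_exposure = runif(k, 0.002, 0.01),
    se_outcome = runif(k, 0.02, 0.1),
    eaf = runif(k, 0.05, 0.95)
  )
}

# independent WLS oracles built on lm()'s QR path (the implementation uses
# closed-form sums, so agreement is a genuine cross-check)
oracle_wls_through_origin <- function(g, G, w) {
  unname(coef(lm(G ~ 0 + g, weights = w))[1])
}
oracle_wls_with_intercept <- function(g, G, w) {
  unname(coef(lm(G ~ g, weights = w)))
}

# quantile-grid oracle for the interpolated weighted median: root of the
# piecewise-linear cumulative-weight function at 0.5, found numerically
oracle_weighted_median <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  p <- cumsum(weight[ord] / sum(weight)) - (weight[ord] / sum(weight)) / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  f <- function(x) stats::approx(r, p, xout = x, ties = "ordered")$y - 0.5
  stats::uniroot(f, range(r), tol = 1e-12)$root
}

# reconstruct individual-level rows from 2x2 (or stratified) counts:
# expand_counts(list(n = 3, exposed = 1, case = 0), ...) gives 3 such rows
expand_counts <- function(...) {
  purrr::map_dfr(list(...), function(cell) {
    n <- cell$n
    cell$n <- NULL
    tibble::as_tibble(cell)[rep(1, n), , drop = FALSE]
  })
}
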