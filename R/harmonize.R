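is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align exposure and outcome summary statistics to a common effect allele
#'
#' Two-sample MR regresses SNP-outcome on SNP-exposure associations, so both
#' must refer to the same effect allele. For SNPs whose outcome effect allele
#' equals the exposure *other* allele, the outcome beta is negated and its
#' EAF complemented. Palindromic SNPs (A/T or C/G), whose strand cannot be
#' resolved from alleles alone, are excluded when the exposure EAF lies
#' within `palindromic_eaf_window` of 0.5 and otherwise oriented by frequency
#' agreement. Irreconcilable allele pairs are flagged `allele-mismatch`.
#' SNPs absent from either table are dropped and counted in the
#' `n_dropped_exposure_only` / `n_dropped_outcome_only` attributes.
#'
#' @param exposure,outcome association tables (see [as_association_table()]).
#' @param palindromic_eaf_window half-width of the ambiguity window around an
#'   EAF of 0.5 within which palindromic SNPs are excluded (default 0.08,
#'   i.e. exclusion for exposure EAF in (0.42, 0.58)).
#' @return a tibble of class `harmonized_set` with one row per shared SNP:
#'   `rsid`, `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `n_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `n_outcome`, `excluded`, `exclusion_reason`.
#'   Attributes `scale_exposure` / `scale_outcome` carry the scale tags.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0) {
    abort("exposure and outcome tables share no rsids.",
          class = "insomniamr_validation_error")
  }
  exp_keep <- exposure[match(shared, exposure$rsid), ]
  out_keep <- outcome[match(shared, outcome$rsid), ]

  h <- tibble::tibble(
    rsid = shared,
    effect_allele = exp_keep$effect_allele,
    other_allele = exp_keep$other_allele,
    beta_exposure = exp_keep$beta,
    se_exposure = exp_keep$se,
    eaf_exposure = exp_keep$eaf,
    pvalue_exposure = exp_keep$pvalue,
    n_exposure = exp_keep$n,
    beta_outcome = out_keep$beta,
    se_outcome = out_keep$se,
    eaf_outcome = out_keep$eaf,
    n_outcome = out_keep$n,
    excluded = FALSE,
    exclusion_reason = NA_character_
  )

  same <- out_keep$effect_allele == exp_keep$effect_allele &
    out_keep$other_allele == exp_keep$other_allele
  swapped <- out_keep$effect_allele == exp_keep$other_allele &
    out_keep$other_allele == exp_keep$effect_allele
  pal <- is_palindromic(exp_keep$effect_allele, exp_keep$other_allele)

  # non-palindromic swapped records: flip sign and complement frequency
  flip <- swapped & !pal
  h$beta_outcome[flip] <- -h$beta_outcome[flip]
  h$eaf_outcome[flip] <- 1 - h$eaf_outcome[flip]

  # palindromic records: "swapped" is indistinguishable from a strand flip,
  # so orient by frequency agreement unless the exposure EAF is ambiguous
  ambiguous <- pal & (same | swapped) &
    abs(h$eaf_exposure - 0.5) < palindromic_eaf_window
  h$excluded[ambiguous] <- TRUE
  h$exclusion_reason[ambiguous] <- "palindromic-ambiguous"
  pal_flip <- pal & (same | swapped) & !ambiguous &
    (h$eaf_exposure - 0.5) * (h$eaf_outcome - 0.5) < 0
  h$beta_outcome[pal_flip] <- -h$beta_outcome[pal_flip]
  h$eaf_outcome[pal_flip] <- 1 - h$eaf_outcome[pal_flip]

  mismatch <- !same & !swapped
  h$excluded[mismatch] <- TRUE
  h$exclusion_reason[mismatch] <- "allele-mismatch"

  structure(
    h,
    scale_exposure = assoc_scale(exposure),
    scale_outcome = assoc_scale(outcome),
    n_dropped_exposure_only = sum(!exposure$rsid %in% shared),
    n_dropped_outcome_only = sum(!outcome$rsid %in% shared),
    class = c("harmonized_set", class(tibble::tibble()))
  )
}

# retained (non-excluded) rows of a harmonized set
retained <- function(h) h[!h$excluded, , drop = FALSE]

#' Orient a harmonized set so all exposure effects are non-negative
#'
#' MR-Egger requires a consistent exposure orientation: pairs with a negative
#' SNP-exposure association have both betas negated (and EAFs complemented),
#' which leaves every Wald ratio unchanged.
#'
#' @param h a `harmonized_set`.
#' @return the oriented `harmonized_set`.
#' @export
orient_exposure <- function(h) {
  neg <- !h$excluded & h$beta_exposure < 0
  h$beta_exposure[neg] <- -h$beta_exposure[neg]
  h$beta_outcome[neg] <- -h$beta_outcome[neg]
  h$eaf_exposure[neg] <- 1 - h$eaf_exposure[neg]
  h$eaf_outcome[neg] <- 1 - h$eaf_outcome[neg]
  tmp <- h$effect_allele[neg]
  h$effect_allele[neg] <- h$other_allele[neg]
  h$other_allele[neg] <- tmp
  h
}

#' Greedy LD pruning of an association table
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value and removes
#' every other SNP correlated with it at `r2 >= r2_threshold`, mirroring the
#' instrument-selection step that removes SNPs in linkage disequilibrium at
#' an R-squared threshold of 0.01. Ties on p-value are broken by rsid
#' (lexicographic) so the result does not depend on input row order.
#'
#' @param snps an `assoc_tbl`.
#' @param ld square symmetric matrix of squared correlations with unit
#'   diagonal, dimnames covering every rsid in `snps`.
#' @param r2_threshold removal threshold (default 0.01).
#' @return the pruned `assoc_tbl`, ordered by ascending p-value. Attribute
#'   `n_removed` counts the removed SNPs.
#' @export
prune_ld <- function(snps, ld, r2_threshold = 0.01) {
  ld <- as.matrix(ld)
  missing <- setdiff(snps$rsid, rownames(ld))
  if (length(missing) > 0) {
    abort(paste0("rsid(s) missing from LD matrix: ",
                 paste(missing, collapse = ", ")),
          class = "insomniamr_validation_error")
  }
  ord <- order(snps$pvalue, snps$rsid)
  remaining <- snps$rsid[ord]
  kept <- character(0)
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    r2 <- ld[lead, remaining]
    remaining <- remaining[r2 < r2_threshold & remaining != lead]
  }
  out <- snps[match(kept, snps$rsid), ]
  attr(out, "n_removed") <- nrow(snps) - nrow(out)
  out
}

#' Filter an association table on minor allele frequency
#'
#' SNPs with `min(eaf, 1 - eaf) < min_maf` are removed, as for the two SNPs
#' excluded from one birth cohort at MAF below 1%.
#'
#' @param table an `assoc_tbl`.
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return the filtered `assoc_tbl`; attribute `n_removed` counts removals.
#' @export
filter_maf <- function(table, min_maf = 0.01) {
  maf <- pmin(table$eaf, 1 - table$eaf)
  out <- table[maf >= min_maf, , drop = FALSE]
  attr(out, "n_removed") <- nrow(table) - nrow(out)
  out
}

#' Convert the outcome side of a harmonized set back to an association table
#'
#' Useful for auditing and for checking that harmonization is idempotent.
#'
#' @param h a `harmonized_set`.
#' @param side `"outcome"` (default) or `"exposure"`.
#' @return an `assoc_tbl`.
#' @export
harmonized_side <- function(h, side = c("outcome", "exposure")) {
  side <- match.arg(side)
  pre <- paste0(side, c("_"))
  x <- tibble::tibble(
    rsid = h$rsid,
    effect_allele = h$effect_allele,
    other_allele = h$other_allele,
    eaf = h[[paste0("eaf_", side)]],
    beta = h[[paste0("beta_", side)]],
    se = h[[paste0("se_", side)]],
    pvalue = if (side == "exposure") h$pvalue_exposure else
      p_normal(h$beta_outcome, h$se_outcome),
    n = h[[paste0("n_", side)]]
  )
  as_association_table(
    x,
    scale = attr(h, paste0("scale_", side), exact = TRUE) %||% "log-odds"
  )
}
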