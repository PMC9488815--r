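#' Construct a validated SNP association table
#'
#' An association table holds, for one trait in one study, the estimated
#' association of each SNP with that trait: effect and other allele, effect
#' allele frequency (EAF), per-allele effect estimate with its standard error
#' and p-value, and the analysed sample size. The effect scale is tagged on
#' the table (`"linear"` for risk differences from linear models on a binary
#' trait, `"log-odds"` for logistic-regression coefficients) because the
#' causal estimators must never mix scales within one exposure set.
#'
#' @param x data frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pvalue`, `n` (optionally `n_cases`, `n_controls`).
#' @param scale effect scale tag, `"linear"` or `"log-odds"`.
#' @param trait,study optional labels stored as attributes.
#' @return a tibble of class `assoc_tbl` with attributes `scale`, `trait`,
#'   `study`. Alleles are normalized to uppercase.
#' @export
#' @examples
#' as_association_table(
#'   data.frame(
#'     rsid = "rs1", effect_allele = "a", other_allele = "g",
#'     eaf = 0.3, beta = 0.02, se = 0.005, pvalue = 6e-5, n = 1000
#'   ),
#'   scale = "linear", trait = "insomnia"
#' )
as_association_table <- function(x, scale, trait = NULL, study = NULL) {
  if (!is_scale(scale)) {
    abort("`scale` must be \"linear\" or \"log-odds\".")
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(ASSOC_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "association table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "insomniamr_format_error")
  }
  x$rsid <- as.character(x$rsid)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  validate_association_rows(x)
  extra <- setdiff(names(x), ASSOC_COLS)
  x <- x[, c(ASSOC_COLS, extra)]
  structure(
    x,
    scale = scale,
    trait = trait %||% attr(x, "trait"),
    study = study %||% attr(x, "study"),
    class = c("assoc_tbl", class(tibble::tibble()))
  )
}

validate_association_rows <- function(x) {
  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(
        paste0(what, " in row(s): ", paste(head(idx, 10), collapse = ", "),
               if (length(idx) > 10) " ..." else ""),
        class = "insomniamr_validation_error"
      )
    }
  }
  bad_row(is.na(x$rsid) | x$rsid == "", "missing rsid")
  bad_row(duplicated(x$rsid), "duplicated rsid")
  bad_row(!grepl("^[ACGT]$", x$effect_allele) |
            !grepl("^[ACGT]$", x$other_allele),
          "allele is not a single A/C/G/T base")
  bad_row(x$effect_allele == x$other_allele,
          "effect and other allele are identical")
  bad_row(!is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf outside [0, 1]")
  bad_row(!is.finite(x$beta), "non-finite beta")
  bad_row(!is.finite(x$se) | x$se <= 0, "se not strictly positive")
  bad_row(!is.finite(x$pvalue) | x$pvalue < 0 | x$pvalue > 1,
          "pvalue outside [0, 1]")
  bad_row(!is.finite(x$n) | x$n <= 0, "sample size not positive")
  invisible(x)
}

#' Scale tag of an association table or harmonized set
#'
#' @param x an `assoc_tbl` or harmonized set.
#' @return `"linear"` or `"log-odds"` (possibly `NULL` for hand-built data).
#' @export
assoc_scale <- function(x) attr(x, "scale", exact = TRUE)

#' Read a summary-statistic TSV into an association table
#'
#' The on-disk dialect is UTF-8, tab-delimited, `.` decimal, with a header
#' row naming at least `rsid`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`. Malformed rows are rejected with row-level
#' diagnostics rather than silently dropped.
#'
#' @param path file path.
#' @inheritParams as_association_table
#' @return an `assoc_tbl` (see [as_association_table()]).
#' @export
read_association_table <- function(path, scale, trait = NULL, study = NULL) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_association_table(x, scale = scale, trait = trait, study = study)
}

#' Write an association table as TSV
#'
#' Inverse of [read_association_table()]: the round-trip preserves every
#' field for finite decimal inputs.
#'
#' @param x an `assoc_tbl`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
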