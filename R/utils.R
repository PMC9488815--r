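#' @importFrom rlang %||% abort warn .data
#' @importFrom stats pnorm pchisq pt qnorm rnorm rbinom runif sd setNames
#'   coef lm glm binomial vcov complete.cases median var
#' @importFrom utils head
NULL

# 95% CI multiplier used throughout; reported intervals are estimate +/- 1.96*se
Z95 <- 1.96

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed prevalence tables use
#' conventional half-up rounding, so 23.45 -> 23.5 at one decimal place.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Expand one global seed into reproducible child seeds
#'
#' Every stage of the pipeline draws its own seed from the run seed so that
#' stages stay reproducible independently of how many random draws earlier
#' stages consumed. Child seeds are kept below 2^31.
#'
#' @param seed integer global seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# normal two-sided p-value from an estimate and its SE
p_normal <- function(beta, se) 2 * pnorm(-abs(beta / se))

# shared column order for association tables
ASSOC_COLS <- c(
  "rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "pvalue", "n"
)

is_scale <- function(x) is.character(x) && length(x) == 1 &&
  x %in% c("linear", "log-odds")
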