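test_that("TSV round-trip preserves every field and normalizes alleles", {
  tab <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.02, -0.015, 0.001),
                    se = c(0.005, 0.004, 0.0062),
                    eaf = c(0.31, 0.08, 0.497))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(tab, path)
  back <- read_association_table(path, scale = "linear")
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tab),
               ignore_attr = TRUE)
  expect_identical(assoc_scale(back), "linear")

  # lowercase alleles in the file are accepted and uppercased
  raw <- readLines(path)
  raw[2] <- sub("A\tG", "a\tg", raw[2])
  writeLines(raw, path)
  relaxed <- read_association_table(path, scale = "linear")
  expect_identical(relaxed$effect_allele[1], "A")
  expect_identical(relaxed$other_allele[1], "G")
})

test_that("validation rejects malformed rows with row-level diagnostics", {
  base <- tibble::tibble(
    rsid = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    eaf = 0.2, beta = 0.1, se = c(0.01, 0), pvalue = 0.5, n = 100
  )
  expect_error(as_association_table(base, scale = "linear"),
               "se not strictly positive.*2",
               class = "insomniamr_validation_error")
  expect_error(
    as_association_table(base[, -3], scale = "linear"),
    "missing mandatory column",
    class = "insomniamr_format_error"
  )
  dup <- base
  dup$se <- 0.01
  dup$rsid <- "rs1"
  expect_error(as_association_table(dup, scale = "linear"), "duplicated rsid")
  expect_error(as_association_table(dplyr::mutate(base, se = 0.01),
                                    scale = "risk"),
               "scale")
})

test_that("harmonization flips swapped alleles and flags the unresolvable", {
  exp_tab <- make_assoc(c("rs1", "rs2", "rs3", "rs4"),
                        beta = c(0.05, 0.04, 0.03, 0.02), se = 0.01,
                        effect_allele = c("A", "A", "A", "A"),
                        other_allele = c("G", "G", "T", "G"),
                        eaf = c(0.3, 0.3, 0.50, 0.3))
  out_tab <- as_association_table(tibble::tibble(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    effect_allele = c("A", "G", "A", "A"),
    other_allele = c("G", "A", "T", "C"),
    eaf = c(0.3, 0.30, 0.5, 0.3),
    beta = c(0.2, 0.10, 0.1, 0.1),
    se = 0.05, pvalue = 0.1, n = 5000
  ), scale = "log-odds")
  h <- harmonize(exp_tab, out_tab, palindromic_eaf_window = 0.08)

  expect_equal(h$beta_outcome[h$rsid == "rs1"], 0.2)    # identical alleles
  expect_equal(h$beta_outcome[h$rsid == "rs2"], -0.10)  # swapped: negated
  expect_equal(h$eaf_outcome[h$rsid == "rs2"], 0.70)    # and complemented
  expect_identical(h$exclusion_reason[h$rsid == "rs3"],
                   "palindromic-ambiguous")             # A/T at eaf 0.5
  expect_identical(h$exclusion_reason[h$rsid == "rs4"], "allele-mismatch")

  expect_error(harmonize(exp_tab, make_assoc("rs99", 0.1, 0.1)),
               "share no rsids")
})

test_that("harmonization is idempotent and double swaps cancel", {
  set.seed(41)
  exp_tab <- make_assoc(sprintf("rs%d", 1:6), beta = runif(6, 0.01, 0.1),
                        se = 0.01, eaf = runif(6, 0.1, 0.4))
  out_raw <- tibble::as_tibble(make_assoc(
    sprintf("rs%d", 1:6), beta = rnorm(6, 0, 0.1), se = 0.05,
    eaf = runif(6, 0.1, 0.9), scale = "log-odds"
  ))
  # swap alleles on half the outcome records
  swap <- c(1, 3, 5)
  out_swapped <- out_raw
  out_swapped$effect_allele[swap] <- out_raw$other_allele[swap]
  out_swapped$other_allele[swap] <- out_raw$effect_allele[swap]
  out_swapped$beta[swap] <- -out_raw$beta[swap]
  out_swapped$eaf[swap] <- 1 - out_raw$eaf[swap]
  h1 <- harmonize(exp_tab, as_association_table(out_swapped, "log-odds"))
  h0 <- harmonize(exp_tab, as_association_table(out_raw, "log-odds"))
  # double swap restores the original record exactly
  expect_equal(h1$beta_outcome, h0$beta_outcome)
  expect_equal(h1$eaf_outcome, h0$eaf_outcome)
  # re-harmonizing harmonized output changes nothing
  h2 <- harmonize(exp_tab, harmonized_side(h1, "outcome"))
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$excluded, h1$excluded)
})

test_that("LD pruning keeps the smallest-p SNP of each correlated clump", {
  tab <- make_assoc(c("rsA", "rsB"), beta = c(0.1, 0.08), se = 0.01,
                    pvalue = c(1e-10, 1e-8))
  ld_lo <- matrix(c(1, 0.002, 0.002, 1), 2,
                  dimnames = list(c("rsA", "rsB"), c("rsA", "rsB")))
  expect_equal(nrow(prune_ld(tab, ld_lo, 0.01)), 2)
  ld_hi <- ld_lo; ld_hi[1, 2] <- ld_hi[2, 1] <- 0.5
  kept <- prune_ld(tab, ld_hi, 0.01)
  expect_identical(kept$rsid, "rsA")
  expect_equal(attr(kept, "n_removed"), 1)
  expect_error(prune_ld(tab, ld_hi[1, 1, drop = FALSE]),
               "missing from LD matrix.*rsB")
})

test_that("pruning matches the greedy rule applied by brute force and is
           order-invariant", {
  # 4 SNPs, one correlated triple (rs1-rs2-rs3), rs4 independent
  rsids <- paste0("rs", 1:4)
  ld <- diag(4)
  dimnames(ld) <- list(rsids, rsids)
  ld["rs1", "rs2"] <- ld["rs2", "rs1"] <- 0.6
  ld["rs2", "rs3"] <- ld["rs3", "rs2"] <- 0.3
  ld["rs1", "rs3"] <- ld["rs3", "rs1"] <- 0.004
  tab <- make_assoc(rsids, beta = c(0.1, 0.2, 0.15, 0.05), se = 0.01,
                    pvalue = c(1e-9, 1e-12, 1e-7, 1e-5))
  # brute-force oracle over all 2^4 subsets: the kept set must be the unique
  # maximal pairwise-compatible subset in which every removed SNP conflicts
  # with a kept SNP of strictly better (pvalue, rsid) rank
  rank_of <- function(id) order(order(tab$pvalue, tab$rsid))[match(id, tab$rsid)]
  subsets <- unlist(lapply(0:4, function(m) combn(rsids, m, simplify = FALSE)),
                    recursive = FALSE)
  valid <- Filter(function(s) {
    if (length(s) > 1 && any(ld[s, s][upper.tri(ld[s, s])] >= 0.01)) {
      return(FALSE)
    }
    removed <- setdiff(rsids, s)
    all(vapply(removed, function(x) {
      any(ld[x, s] >= 0.01 & rank_of(s) < rank_of(x))
    }, logical(1)))
  }, subsets)
  expect_length(valid, 1)
  expected <- valid[[1]][order(tab$pvalue[match(valid[[1]], tab$rsid)])]
  got <- prune_ld(tab, ld, 0.01)
  expect_identical(got$rsid, expected)   # rs2 beats the whole triple
  # input row order must not matter
  for (perm in list(4:1, c(2, 4, 1, 3))) {
    got_p <- prune_ld(tab[perm, ], ld, 0.01)
    expect_identical(got_p$rsid, got$rsid)
  }
})

test_that("MAF filter removes rare SNPs symmetrically in eaf", {
  tab <- make_assoc(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.01,
                    eaf = c(0.005, 0.5, 0.995))
  kept <- filter_maf(tab, 0.01)
  expect_identical(kept$rsid, "rs2")
  expect_equal(attr(kept, "n_removed"), 2)
  expect_equal(nrow(filter_maf(tab, 0.001)), 3)
})
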