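#' Pool SNP-level associations across studies
#'
#' Fixed-effects inverse-variance meta-analysis per SNP of several
#' association tables for the same trait (the SNP-level pooling used for
#' the non-UKB cohorts before MR). Only SNPs present in at least one table
#' appear; alleles must already agree (tables produced by [harmonize()]d
#' pipelines or a common imputation panel do).
#'
#' @param tables list of `assoc_tbl`s on a common scale.
#' @return an `assoc_tbl`; `eaf` and `n` are the inverse-variance-weighted
#'   EAF and summed n across contributing studies.
#' @export
pool_snp_associations <- function(tables) {
  scales <- unique(vapply(tables, function(x) assoc_scale(x) %||% "log-odds",
                          character(1)))
  if (length(scales) > 1) {
    abort("cannot pool association tables on different scales.",
          class = "insomniamr_validation_error")
  }
  all_rows <- dplyr::bind_rows(tables)
  pooled <- all_rows |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(
      effect_allele = dplyr::first(.data$effect_allele),
      other_allele = dplyr::first(.data$other_allele),
      eaf = sum(.data$eaf / .data$se^2) / sum(1 / .data$se^2),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n = sum(.data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(pvalue = p_normal(.data$beta, .data$se))
  mism <- all_rows |>
    dplyr::group_by(.data$rsid) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$effect_allele) == 1,
                     .groups = "drop")
  if (any(!mism$ok)) {
    abort(paste0("effect alleles disagree across studies for: ",
                 paste(mism$rsid[!mism$ok], collapse = ", "),
                 "; harmonize the tables first."),
          class = "insomniamr_validation_error")
  }
  as_association_table(pooled[, ASSOC_COLS], scale = scales)
}

default_pipeline_options <- function() {
  list(
    ld_r2_threshold = 0.01,
    min_maf = 0.01,
    palindromic_eaf_window = 0.08,
    steiger_alpha = 0.05,
    ivw_variant = "multiplicative-random",
    n_boot = 1000
  )
}

#' Read and normalize a pipeline configuration
#'
#' The configuration is a YAML document (or an equivalent list) naming the
#' exposure instruments, the per-study inputs, the outcome list and the
#' analysis options. Options not given take the package defaults
#' (LD r-squared 0.01, MAF 0.01, palindromic window 0.08, Steiger alpha
#' 0.05, multiplicative-random IVW, 1000 bootstrap replicates).
#'
#' @param config path to a YAML file or a list.
#' @return normalized config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    abort("pipeline config needs a `seed`.",
          class = "insomniamr_validation_error")
  }
  config$options <- utils::modifyList(default_pipeline_options(),
                                      config$options %||% list())
  if (is.null(config$outcomes) || length(config$outcomes) == 0) {
    abort("pipeline config needs a non-empty `outcomes` list.",
          class = "insomniamr_validation_error")
  }
  if (is.null(config$studies) || length(config$studies) == 0) {
    abort("pipeline config needs at least one study.",
          class = "insomniamr_validation_error")
  }
  config
}

# resolve the exposure table for a study: its own `exposure` block if any,
# else the top-level one; synthetic studies carry their own tables
resolve_exposure <- function(config, study, synth = NULL) {
  if (!is.null(synth)) return(synth$exposure)
  blk <- study$exposure %||% config$exposure
  if (is.null(blk)) {
    abort(paste0("no exposure table for study ", study$name),
          class = "insomniamr_validation_error")
  }
  read_association_table(blk$path, scale = blk$scale %||% "linear",
                         trait = "exposure", study = study$name)
}

run_one_study <- function(config, study, outcome_label, seed, log_line) {
  opts <- config$options
  synth <- NULL
  if (identical(study$type, "synthetic")) {
    cfg <- sim_config(
      n_subjects = study$n_subjects %||% 10000,
      theta = study$theta %||% 0,
      seed = seed,
      n_snps = study$n_snps %||% 81,
      target_r2 = study$target_r2 %||% 0.0042
    )
    synth <- simulate_summary_stats(
      cfg,
      se_exposure = study$se_exposure %||% 0.003,
      se_outcome = study$se_outcome %||% 0.05
    )
    log_line(sprintf("study %s: synthetic summary stats (seed %d)",
                     study$name, seed))
  }
  exposure <- resolve_exposure(config, study, synth)
  outcome <- if (!is.null(synth)) {
    synth$outcome
  } else {
    blk <- study$outcomes[[outcome_label]]
    if (is.null(blk)) return(NULL)  # study does not contribute this outcome
    read_association_table(blk$path, scale = blk$scale %||% "log-odds",
                           trait = outcome_label, study = study$name)
  }

  out_f <- filter_maf(outcome, opts$min_maf)
  log_line(sprintf("study %s / %s: MAF filter removed %d SNP(s)",
                   study$name, outcome_label, attr(out_f, "n_removed")))
  h <- harmonize(exposure, out_f,
                 palindromic_eaf_window = opts$palindromic_eaf_window)
  log_line(sprintf(
    "study %s / %s: harmonized %d SNPs (%d excluded: %s)",
    study$name, outcome_label, sum(!h$excluded), sum(h$excluded),
    paste(unique(stats::na.omit(h$exclusion_reason)), collapse = ", ")
  ))
  ests <- mr_all(h, n_boot = opts$n_boot, seed = seed)
  het <- cochran_q(h)
  st <- steiger_filter(h, alpha = opts$steiger_alpha,
                       prevalence_exposure = config$exposure_prevalence %||% 0.28,
                       prevalence_outcome = config$outcome_prevalence %||% 0.05)
  ivw_steiger <- mr_ivw(st$harmonized, opts$ivw_variant)
  log_line(sprintf("study %s / %s: Steiger removed %d SNP(s) at alpha %g",
                   study$name, outcome_label, sum(st$audit$removed),
                   opts$steiger_alpha))
  loo <- leave_one_snp_out(h, opts$ivw_variant)
  ivw_sf <- tibble::as_tibble(ivw_steiger)
  ivw_sf$variant <- "steiger-filtered"
  label <- function(x) {
    x <- tibble::as_tibble(x)
    x$study <- study$name
    x$outcome <- outcome_label
    dplyr::relocate(x, "study", "outcome")
  }
  list(
    study = study$name,
    estimates = label(dplyr::bind_rows(ests, ivw_sf)),
    heterogeneity = label(het),
    steiger_audit = label(st$audit),
    loo_snp = label(loo)
  )
}

#' Run the full multi-study MR pipeline
#'
#' For every outcome in the configuration: per-study harmonization (with
#' MAF filtering and the configured palindromic window), the IVW /
#' MR-Egger / weighted-median estimates with heterogeneity,
#' leave-one-SNP-out and Steiger-filtered re-runs, then a fixed-effects
#' meta-analysis across studies with leave-one-study-out. Results are
#' returned as tidy tibbles and, when `out_dir` is set, written as one
#' directory per outcome (`results.tsv`, `heterogeneity.tsv`,
#' `steiger_audit.tsv`, `loo_snp.tsv`, `loo_study.tsv`, `meta.tsv`) plus a
#' `run.log` and `manifest.yaml` capturing every seed and threshold. A
#' failing stage is recorded in the bundle and the remaining outcomes still
#' run.
#'
#' @param config YAML path or list, see [read_pipeline_config()].
#' @param out_dir output directory (overrides `config$out_dir`; `NULL`
#'   writes nothing).
#' @return list of class `mr_pipeline_result`: `results`, `meta`,
#'   `heterogeneity`, `steiger_audit`, `loo_snp`, `loo_study`, `failures`,
#'   `seeds`, `log`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  log_lines <- character(0)
  log_line <- function(msg) log_lines <<- c(log_lines, msg)
  opts <- config$options
  log_line(sprintf(
    "options: ld_r2=%g maf=%g palindromic_window=%g steiger_alpha=%g ivw=%s n_boot=%d seed=%d",
    opts$ld_r2_threshold, opts$min_maf, opts$palindromic_eaf_window,
    opts$steiger_alpha, opts$ivw_variant, opts$n_boot, config$seed
  ))
  outcomes <- sort(unlist(config$outcomes))
  # study order must not matter: sort by name, then seed by (outcome, study)
  studies <- config$studies[order(vapply(config$studies, `[[`, "", "name"))]
  seed_grid <- child_seeds(config$seed, length(outcomes) * length(studies))
  seeds <- tibble::tibble(
    outcome = rep(outcomes, each = length(studies)),
    study = rep(vapply(studies, `[[`, "", "name"), length(outcomes)),
    seed = seed_grid
  )
  log_line(paste0("per-stage seeds: ",
                  paste(sprintf("%s/%s=%d", seeds$outcome, seeds$study,
                                seeds$seed), collapse = " ")))
  results <- list(); metas <- list(); hets <- list(); audits <- list()
  loo_snps <- list(); loo_studies <- list(); failures <- list()
  for (oc in outcomes) {
    res <- tryCatch({
      per_study <- purrr::compact(purrr::map(studies, function(st) {
        sd <- seeds$seed[seeds$outcome == oc & seeds$study == st$name]
        run_one_study(config, st, oc, sd, log_line)
      }))
      if (length(per_study) == 0) {
        abort(paste0("no study contributes outcome ", oc))
      }
      study_ivw <- purrr::map_dfr(per_study, function(x) {
        e <- x$estimates
        e <- e[e$method == "ivw" & e$variant == opts$ivw_variant, ]
        tibble::tibble(study = x$study, beta = e$beta, se = e$se)
      })
      meta <- fixed_effects_meta(study_ivw)
      loo_st <- if (nrow(study_ivw) >= 2) {
        x <- leave_one_study_out(study_ivw)
        x$outcome <- oc
        dplyr::relocate(x, "outcome")
      } else NULL
      list(per_study = per_study, meta = meta, loo_study = loo_st)
    }, error = function(e) {
      log_line(sprintf("outcome %s FAILED: %s", oc, conditionMessage(e)))
      failures[[oc]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(res)) next
    results[[oc]] <- purrr::map_dfr(res$per_study, "estimates")
    hets[[oc]] <- purrr::map_dfr(res$per_study, "heterogeneity")
    audits[[oc]] <- purrr::map_dfr(res$per_study, "steiger_audit")
    loo_snps[[oc]] <- purrr::map_dfr(res$per_study, "loo_snp")
    metas[[oc]] <- dplyr::bind_cols(tibble::tibble(outcome = oc), res$meta)
    if (!is.null(res$loo_study)) loo_studies[[oc]] <- res$loo_study
  }
  bundle <- structure(
    list(
      results = dplyr::bind_rows(results),
      meta = dplyr::bind_rows(metas),
      heterogeneity = dplyr::bind_rows(hets),
      steiger_audit = dplyr::bind_rows(audits),
      loo_snp = dplyr::bind_rows(loo_snps),
      loo_study = dplyr::bind_rows(loo_studies),
      failures = failures,
      seeds = seeds,
      log = log_lines,
      config = config
    ),
    class = "mr_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_bundle(bundle, out_dir)
  bundle
}

write_pipeline_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (oc in unique(bundle$meta$outcome)) {
    od <- file.path(out_dir, oc)
    dir.create(od, showWarnings = FALSE)
    pick <- function(x) x[x$outcome == oc, , drop = FALSE]
    readr::write_tsv(pick(bundle$results), file.path(od, "results.tsv"),
                     progress = FALSE)
    readr::write_tsv(pick(bundle$heterogeneity),
                     file.path(od, "heterogeneity.tsv"), progress = FALSE)
    readr::write_tsv(pick(bundle$steiger_audit),
                     file.path(od, "steiger_audit.tsv"), progress = FALSE)
    readr::write_tsv(pick(bundle$loo_snp), file.path(od, "loo_snp.tsv"),
                     progress = FALSE)
    if (nrow(bundle$loo_study) > 0) {
      readr::write_tsv(pick(bundle$loo_study), file.path(od, "loo_study.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(pick(bundle$meta), file.path(od, "meta.tsv"),
                     progress = FALSE)
  }
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  write_manifest(bundle, out_dir)
  invisible(out_dir)
}

# one manifest per result directory: version, effective config, seeds and
# digests of every file input
write_manifest <- function(bundle, out_dir) {
  config <- bundle$config
  paths <- character(0)
  if (!is.null(config$exposure$path)) paths <- c(paths, config$exposure$path)
  for (st in config$studies) {
    for (oc in names(st$outcomes %||% list())) {
      p <- st$outcomes[[oc]]$path
      if (!is.null(p)) paths <- c(paths, p)
    }
  }
  digests <- if (length(paths) > 0) {
    as.list(tools::md5sum(paths[file.exists(paths)]))
  } else list()
  manifest <- list(
    tool = "insomniamr",
    version = as.character(utils::packageVersion("insomniamr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "studies")],
    studies = lapply(config$studies, function(s)
      s[intersect(names(s), c("name", "type", "n_subjects", "theta"))]),
    seeds = stats::setNames(as.list(bundle$seeds$seed),
                            paste(bundle$seeds$outcome, bundle$seeds$study,
                                  sep = "/")),
    input_digests = digests
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
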