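#' Analysis pipeline configuration
#'
#' @param input a [cohort()] object, a path to a delimited cohort file, or
#'   a list of [genotype_counts()] objects (association-only mode).
#' @param outdir output directory for the report bundle.
#' @param snps SNPs to analyse (default: all available).
#' @param exposures named exposure list for the interaction scan (see
#'   [interaction_scan()]); defaults: total cholesterol >= 5 mmol/L,
#'   LDL >= 3 mmol/L, overweight/obesity as BMI >= 25 kg/m2, smoking and
#'   hypertension as recorded flags.
#' @param carrier carrier rule for the interaction scan (see [build_4x2()]).
#' @param alpha_assoc association significance level (default 0.05).
#' @param alpha_inter interaction significance level after Bonferroni
#'   correction (default 0.025).
#' @param horizons survival follow-up horizons in years, ascending
#'   (default `c(5, 10)`).
#' @param seed RNG seed for the bootstrap steps.
#' @param n_boot bootstrap resamples for the LD confidence bounds
#'   (default 1000).
#' @param stages which stages to run, a subset of
#'   `c("assoc", "haplo", "interact", "surv")`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(input, outdir,
                            snps = NULL,
                            exposures = list(tc = 5.0, ldl = 3.0, bmi = 25,
                                             smoking = NULL,
                                             hypertension = NULL),
                            carrier = "major_carrier",
                            alpha_assoc = 0.05, alpha_inter = 0.025,
                            horizons = c(5, 10), seed = 1L, n_boot = 1000L,
                            stages = c("assoc", "haplo", "interact", "surv")) {
  stopifnot(alpha_assoc > 0, alpha_assoc < 1, alpha_inter > 0, alpha_inter < 1,
            all(horizons > 0), !is.unsorted(horizons))
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(input = input, outdir = outdir, snps = snps,
                 exposures = exposures, carrier = carrier,
                 alpha_assoc = alpha_assoc, alpha_inter = alpha_inter,
                 horizons = horizons, seed = as.integer(seed),
                 n_boot = as.integer(n_boot), stages = stages),
            class = "analysis_config")
}

write_report <- function(df, outdir, name) {
  utils::write.table(df, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  jsonlite::write_json(df, file.path(outdir, paste0(name, ".json")),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes association (HWE + inheritance-model contrasts), haplotype/LD
#' block analysis, the gene-environment interaction scan, and survival
#' analysis (when follow-up columns are present), writing per-stage
#' delimited and JSON reports plus a run log into the output directory.
#' Stage errors are caught, logged, and do not stop later stages. The
#' bundle is deterministic for a given input and seed.
#'
#' @param config an [analysis_config()].
#' @return A `pipeline_result` list with per-stage results, `errors`, and
#'   the paths written, invisibly printable.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c("snpcohort pipeline run",
                 paste0("package version: ",
                        as.character(utils::packageVersion("snpcohort"))),
                 paste0("seed: ", config$seed),
                 paste0("stages requested: ", paste(config$stages, collapse = ", ")))
  errors <- character(0)
  results <- list()

  input <- config$input
  counts_only <- is.list(input) && !inherits(input, "cohort") &&
    all(vapply(input, inherits, TRUE, "genotype_counts"))
  dat <- NULL
  if (counts_only) {
    counts <- input
    log_lines <- c(log_lines, "input: genotype counts (association-only mode)")
  } else {
    dat <- if (inherits(input, "cohort")) input else read_cohort(input)
    snps <- config$snps %||% dat$snps$snp_id
    counts <- lapply(snps, function(s) genotype_counts(dat, s))
    names(counts) <- snps
    for (s in snps) {
      n_miss <- sum(is.na(dat$subjects[[s]]))
      if (n_miss > 0)
        log_lines <- c(log_lines, sprintf(
          "exclusions: %d subject(s) dropped pairwise at %s (missing genotype)",
          n_miss, s))
    }
    log_lines <- c(log_lines, sprintf("input: cohort with %d subjects, %d SNP(s)",
                                      nrow(dat$subjects), nrow(dat$snps)))
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("[%s] %s", name, conditionMessage(e)))
      log_lines <<- c(log_lines, sprintf("stage %s: ERROR %s", name,
                                         conditionMessage(e)))
      NULL
    })
  }

  ## association stage
  if ("assoc" %in% config$stages) {
    results$assoc <- run_stage("assoc", {
      rows <- lapply(counts, function(cnt) {
        hc <- hwe_test(cnt, group = "control")
        tab <- model_contrasts(cnt)
        tab$hwe_p_controls <- hc$p_value
        tab$significant <- tab$p_value < config$alpha_assoc
        tab
      })
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      write_report(out, config$outdir, "association")
      log_lines <- c(log_lines, sprintf("stage assoc: %d contrast(s) written",
                                        nrow(out)))
      out
    })
  }

  ## haplotype / LD stage
  if ("haplo" %in% config$stages) {
    results$haplo <- run_stage("haplo", {
      if (counts_only) stop("haplotype stage needs subject-level genotypes")
      snps <- config$snps %||% dat$snps$snp_id
      if (length(snps) < 2) stop("need >= 2 SNPs")
      bp <- gabriel_blocks(dat, snps, n_boot = config$n_boot, seed = config$seed)
      em_snps <- if (length(bp$blocks)) bp$blocks[[1]] else bp$snp_ids[1:2]
      em <- em_haplotypes(dat, em_snps)
      hap <- data.frame(haplotype = em$haplotypes, frequency = em$frequencies)
      write_report(bp$pairs, config$outdir, "ld_pairs")
      write_report(hap, config$outdir, "haplotypes")
      blocks_df <- if (length(bp$blocks))
        data.frame(block = seq_along(bp$blocks),
                   snps = vapply(bp$blocks, paste, "", collapse = ","))
      else data.frame(block = integer(), snps = character())
      write_report(blocks_df, config$outdir, "blocks")
      log_lines <- c(log_lines, sprintf("stage haplo: %d block(s) detected",
                                        length(bp$blocks)))
      list(blocks = bp, em = em)
    })
  }

  ## interaction stage
  if ("interact" %in% config$stages) {
    results$interact <- run_stage("interact", {
      if (counts_only) stop("interaction stage needs subject-level data")
      have <- names(config$exposures) %in% names(dat$subjects)
      exp_use <- config$exposures[have]
      if (!all(have))
        log_lines <- c(log_lines, sprintf(
          "stage interact: exposure(s) %s absent, skipped",
          paste(names(config$exposures)[!have], collapse = ", ")))
      scan <- interaction_scan(dat, snps = config$snps, exposures = exp_use,
                               carrier = config$carrier,
                               alpha = config$alpha_inter)
      write_report(as.data.frame(scan), config$outdir, "interaction")
      log_lines <- c(log_lines, sprintf("stage interact: %d pair(s) evaluated",
                                        nrow(scan)))
      scan
    })
  }

  ## survival stage (optional: needs follow-up columns)
  if ("surv" %in% config$stages) {
    has_surv <- !counts_only && "time" %in% names(dat$subjects) &&
      any(!is.na(dat$subjects$time))
    if (!has_surv) {
      log_lines <- c(log_lines, "stage surv: skipped (no survival columns)")
    } else {
      results$surv <- run_stage("surv", {
        snps <- config$snps %||% dat$snps$snp_id
        rows <- list()
        for (s in snps) for (h in config$horizons) {
          df <- dat$subjects
          keep <- df$status == "case" & !is.na(df$time) & !is.na(df[[s]])
          df <- df[keep, ]
          by_geno <- split(df[c("time", "event")], df[[s]])
          by_geno <- by_geno[vapply(by_geno, nrow, 0L) > 0]
          add <- try(logrank_ksample(by_geno, horizon = h), silent = TRUE)
          rec <- try(logrank_2group(df[df[[s]] == 2L, c("time", "event")],
                                    df[df[[s]] != 2L, c("time", "event")],
                                    horizon = h), silent = TRUE)
          km5 <- km_estimate(df[c("time", "event")], horizon = h)
          rows[[length(rows) + 1]] <- data.frame(
            snp_id = s, horizon = h, n = nrow(df), n_events = km5$n_events,
            surv_end = predict(km5, h),
            additive_chi2 = if (inherits(add, "try-error")) NA_real_ else add$chi2,
            additive_df = if (inherits(add, "try-error")) NA_integer_ else add$df,
            additive_p = if (inherits(add, "try-error")) NA_real_ else add$p_value,
            recessive_z = if (inherits(rec, "try-error")) NA_real_ else rec$z,
            recessive_p = if (inherits(rec, "try-error")) NA_real_ else rec$p_value,
            stringsAsFactors = FALSE)
        }
        out <- do.call(rbind, rows)
        write_report(out, config$outdir, "survival")
        log_lines <- c(log_lines, sprintf("stage surv: %d analysis rows", nrow(out)))
        out
      })
    }
  }

  log_lines <- c(log_lines,
                 if (length(errors)) paste0("completed with ", length(errors),
                                            " stage error(s)")
                 else "completed without errors")
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  structure(list(results = results, errors = errors, outdir = config$outdir,
                 log = log_lines), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run ->", x$outdir, "\n")
  cat("stages completed:", paste(names(x$results), collapse = ", "), "\n")
  if (length(x$errors)) cat("errors:\n", paste(" ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}
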