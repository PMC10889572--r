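#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the design of a small candidate-gene coronary artery
#' disease study: 231 cases and 240 control blood donors; two SNPs in a
#' near-complete-LD block (rs1994016 C>T and rs3825807 A>G) drawn from a
#' common haplotype pool whose margins approximate the study's control
#' minor-allele frequencies (T 0.42, G 0.438), one unlinked SNP
#' (rs7173743 T>C, MAF 0.457); a logistic disease model with a major-allele-carrier main
#' effect, a total-cholesterol effect, and a carrier x cholesterol synergy
#' term; exponential cardiovascular-death times for cases with independent
#' censoring and a 10-year follow-up horizon; and a 4% genotyping failure
#' rate (within the 94-97% completeness typical of TaqMan panels).
#'
#' @param seed integer RNG seed (stored; [simulate_cohort()] applies it).
#' @param n_cases,n_controls target group sizes.
#' @param linked_snps data.frame of the SNPs drawn from `haplotype_pool`
#'   (columns as in [cohort()] `snps`).
#' @param haplotype_pool numeric vector of 4 haplotype frequencies for the
#'   linked pair in binary order (major-major, counted-major,
#'   major-counted, counted-counted); must sum to 1.
#' @param unlinked_snps data.frame of independent SNPs with a `maf` column
#'   (counted-allele frequency; genotypes drawn as HWE binomials).
#' @param disease_model named list of logistic coefficients: `intercept`,
#'   `carrier` (log-OR for the major-allele carrier of the second linked
#'   SNP), `tc` (log-OR for total cholesterol >= `tc_threshold`),
#'   `carrier_tc` (log-OR of the product term), `tc_threshold`.
#' @param covariates named list of distribution parameters: `tc_meanlog`,
#'   `tc_sdlog`, `hdl_meanlog`, `hdl_sdlog`, `tg_meanlog`, `tg_sdlog`
#'   (lognormal lipids, mmol/L), `bmi_mean`, `bmi_sd`, and prevalences
#'   `p_male`, `p_smoking`, `p_hypertension`.
#' @param survival_model named list: `base_hazard` (events/year),
#'   `log_hr_recessive` (log hazard ratio for counted-allele homozygotes of
#'   the second linked SNP), `censor_rate` (competing censoring hazard),
#'   `max_follow_up` (years).
#' @param missing_rate per-call genotyping failure probability in [0, 0.06].
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(seed = 1L,
                              n_cases = 231L, n_controls = 240L,
                              linked_snps = NULL,
                              haplotype_pool = c(0.560, 0.002, 0.018, 0.420),
                              unlinked_snps = NULL,
                              disease_model = list(intercept = -2.0,
                                                   carrier = log(1.3),
                                                   tc = log(1.5),
                                                   carrier_tc = log(2.2),
                                                   tc_threshold = 5.0),
                              covariates = list(tc_meanlog = log(5.1),
                                                tc_sdlog = 0.18,
                                                hdl_meanlog = log(1.25),
                                                hdl_sdlog = 0.20,
                                                tg_meanlog = log(1.5),
                                                tg_sdlog = 0.35,
                                                bmi_mean = 27, bmi_sd = 4,
                                                p_male = 0.75,
                                                p_smoking = 0.45,
                                                p_hypertension = 0.40),
                              survival_model = list(base_hazard = 0.035,
                                                    log_hr_recessive = -0.5,
                                                    censor_rate = 0.02,
                                                    max_follow_up = 10),
                              missing_rate = 0.04) {
  if (is.null(linked_snps))
    linked_snps <- data.frame(
      snp_id = c("rs1994016", "rs3825807"),
      allele_major = c("C", "A"), allele_counted = c("T", "G"),
      chromosome = "15", position = c(78963975L, 78971248L),
      stringsAsFactors = FALSE)
  if (is.null(unlinked_snps))
    unlinked_snps <- data.frame(
      snp_id = "rs7173743", allele_major = "T", allele_counted = "C",
      chromosome = "15", position = 78921498L, maf = 0.457,
      stringsAsFactors = FALSE)
  stopifnot(n_cases > 0, n_controls > 0,
            length(haplotype_pool) == 4, all(haplotype_pool >= 0),
            abs(sum(haplotype_pool) - 1) < 1e-8,
            missing_rate >= 0, missing_rate <= 0.06,
            nrow(linked_snps) == 2)
  if (!is.null(unlinked_snps) && nrow(unlinked_snps))
    stopifnot(all(unlinked_snps$maf >= 0 & unlinked_snps$maf <= 1))
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 linked_snps = linked_snps, haplotype_pool = haplotype_pool,
                 unlinked_snps = unlinked_snps, disease_model = disease_model,
                 covariates = covariates, survival_model = survival_model,
                 missing_rate = missing_rate),
            class = "cohort_sim_config")
}

#' Simulate a case-control cohort with survival follow-up
#'
#' Draws genotypes as two haplotypes per subject from the linked-pair pool
#' (and HWE binomials for unlinked SNPs), lipid and binary covariates from
#' their configured distributions, assigns case/control status by rejection
#' sampling from the logistic disease model until the target group sizes
#' are met, simulates exponential cardiovascular-death times with
#' independent censoring and horizon truncation for cases, and finally
#' applies genotyping missingness. Fully reproducible from the seed.
#'
#' @param config a [cohort_sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param max_attempts cap on candidate draws, as a multiple of the target
#'   cohort size (default 200); exceeded means the disease model makes one
#'   group effectively unreachable and is an error.
#' @return A [cohort()] object with covariates `tc`, `hdl`, `tg`, `ldl`
#'   (Friedewald, `NA` where triglycerides are out of the valid range),
#'   `bmi`, `male`, `smoking`, `hypertension`, and survival columns for
#'   cases.
#' @export
simulate_cohort <- function(config = cohort_sim_config(), seed = config$seed,
                            max_attempts = 200L) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(seed)
  n_target <- config$n_cases + config$n_controls
  batch <- max(500L, 2L * n_target)
  budget <- max_attempts * n_target
  drawn <- 0L
  cases <- list(); controls <- list()
  n_case <- 0L; n_ctrl <- 0L
  cm <- config$covariates; dm <- config$disease_model

  while ((n_case < config$n_cases || n_ctrl < config$n_controls)) {
    if (drawn >= budget)
      stop("attempt budget exhausted: disease model makes the ",
           if (n_case < config$n_cases) "case" else "control",
           " group vanishingly rare under this configuration")
    b <- min(batch, budget - drawn)
    drawn <- drawn + b

    ## linked pair: two haplotypes per subject from the pool
    h1 <- sample.int(4L, b, replace = TRUE, prob = config$haplotype_pool)
    h2 <- sample.int(4L, b, replace = TRUE, prob = config$haplotype_pool)
    bit <- function(h, k) as.integer(bitwAnd(h - 1L, k) > 0L)
    d1 <- bit(h1, 1L) + bit(h2, 1L)   # first linked SNP dosage
    d2 <- bit(h1, 2L) + bit(h2, 2L)   # second linked SNP dosage
    geno <- cbind(d1, d2)
    colnames(geno) <- config$linked_snps$snp_id
    if (!is.null(config$unlinked_snps) && nrow(config$unlinked_snps)) {
      for (i in seq_len(nrow(config$unlinked_snps))) {
        geno <- cbind(geno, stats::rbinom(b, 2L, config$unlinked_snps$maf[i]))
        colnames(geno)[ncol(geno)] <- config$unlinked_snps$snp_id[i]
      }
    }
    tc <- stats::rlnorm(b, cm$tc_meanlog, cm$tc_sdlog)
    hdl <- stats::rlnorm(b, cm$hdl_meanlog, cm$hdl_sdlog)
    tg <- stats::rlnorm(b, cm$tg_meanlog, cm$tg_sdlog)
    bmi <- stats::rnorm(b, cm$bmi_mean, cm$bmi_sd)
    male <- stats::runif(b) < cm$p_male
    smoking <- stats::runif(b) < cm$p_smoking
    hypertension <- stats::runif(b) < cm$p_hypertension

    carrier <- as.integer(geno[, 2] <= 1L)        # major-allele carrier, 2nd linked SNP
    tc_hi <- as.integer(tc >= dm$tc_threshold)
    eta <- dm$intercept + dm$carrier * carrier + dm$tc * tc_hi +
      dm$carrier_tc * carrier * tc_hi
    is_case <- stats::runif(b) < stats::plogis(eta)

    df <- data.frame(tc = tc, hdl = hdl, tg = tg, bmi = bmi, male = male,
                     smoking = smoking, hypertension = hypertension)
    df <- cbind(as.data.frame(geno), df)
    take_case <- which(is_case)[seq_len(min(sum(is_case),
                                            config$n_cases - n_case))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                             config$n_controls - n_ctrl))]
    if (length(take_case)) {
      cases[[length(cases) + 1]] <- df[take_case, , drop = FALSE]
      n_case <- n_case + length(take_case)
    }
    if (length(take_ctrl)) {
      controls[[length(controls) + 1]] <- df[take_ctrl, , drop = FALSE]
      n_ctrl <- n_ctrl + length(take_ctrl)
    }
  }
  case_df <- do.call(rbind, cases)
  ctrl_df <- do.call(rbind, controls)
  case_df$status <- "case"; ctrl_df$status <- "control"
  subj <- rbind(case_df, ctrl_df)
  rownames(subj) <- NULL
  subj$subject_id <- sprintf("S%04d", seq_len(nrow(subj)))

  ## Friedewald LDL where triglycerides are in the formula's validity range
  valid_tg <- subj$tg < 4.5
  subj$ldl <- NA_real_
  subj$ldl[valid_tg] <- friedewald_ldl(subj$tc[valid_tg], subj$hdl[valid_tg],
                                       subj$tg[valid_tg])

  ## survival for cases: exponential death times with genotype hazard ratio,
  ## independent exponential censoring, horizon truncation
  sm <- config$survival_model
  subj$time <- NA_real_; subj$event <- NA
  ci <- which(subj$status == "case")
  rec_hom <- subj[[config$linked_snps$snp_id[2]]][ci] == 2L
  rate <- sm$base_hazard * exp(ifelse(rec_hom, sm$log_hr_recessive, 0))
  t_death <- stats::rexp(length(ci), rate)
  t_cens <- stats::rexp(length(ci), sm$censor_rate)
  t_obs <- pmin(t_death, t_cens, sm$max_follow_up)
  subj$time[ci] <- t_obs
  subj$event[ci] <- t_death <= pmin(t_cens, sm$max_follow_up)

  snp_tab <- config$linked_snps
  if (!is.null(config$unlinked_snps) && nrow(config$unlinked_snps))
    snp_tab <- rbind(snp_tab,
                     config$unlinked_snps[names(config$linked_snps)])
  for (s in snp_tab$snp_id) {
    miss <- stats::runif(nrow(subj)) < config$missing_rate
    subj[[s]][miss] <- NA_integer_
  }
  first <- c("subject_id", "status", snp_tab$snp_id)
  subj <- subj[c(first, setdiff(names(subj), first))]
  cohort(subj, snp_tab)
}

#' Friedewald LDL cholesterol
#'
#' `LDL = TC - HDL - TG / 2.2` (all in mmol/L), valid for triglycerides
#' below 4.5 mmol/L.
#'
#' @param tc,hdl,tg total, HDL cholesterol and triglycerides in mmol/L
#'   (vectorised).
#' @return LDL cholesterol in mmol/L.
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(tg >= 4.5))
    stop("Friedewald formula invalid for triglycerides >= 4.5 mmol/L")
  tc - hdl - tg / 2.2
}

#' Built-in genotype counts of the motivating CAD study
#'
#' The published case/control genotype distributions for the three ADAMTS7
#' SNPs (rs1994016 C>T, rs3825807 A>G, rs7173743 T>C), used as in-package
#' fixtures for the association statistics: per-SNP sample sizes differ
#' because genotyping succeeded for 94-97% of participants.
#'
#' @return Named list of three [genotype_counts()] objects keyed by SNP id.
#' @export
cad_study_counts <- function() {
  mk <- function(id, al, cs, ct)
    genotype_counts_obj(id, al,
                        c(major_hom = cs[1], het = cs[2], minor_hom = cs[3]),
                        c(major_hom = ct[1], het = ct[2], minor_hom = ct[3]))
  list(
    rs1994016 = mk("rs1994016", c("C", "T"), c(85L, 104L, 28L), c(84L, 101L, 47L)),
    rs3825807 = mk("rs3825807", c("A", "G"), c(80L, 108L, 30L), c(78L, 106L, 49L)),
    rs7173743 = mk("rs7173743", c("T", "C"), c(65L, 117L, 36L), c(75L, 103L, 55L)))
}
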