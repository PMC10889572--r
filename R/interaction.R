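#' Build a 4x2 gene-environment classification table
#'
#' Cross-classifies subjects by genotype-risk-carrier status and exposure
#' status, in cases and controls, with the doubly-unexposed (non-carrier,
#' unexposed) class as the fixed reference. Subjects missing the genotype
#' or the exposure variable are excluded pairwise.
#'
#' @param dataset a [cohort()] object.
#' @param snp_id SNP to classify on.
#' @param carrier genotype risk-class rule: `"minor_carrier"` (dosage >= 1),
#'   `"minor_hom"` (dosage == 2), `"major_carrier"` (dosage <= 1, the rule
#'   used for major-allele risk carriers), `"major_hom"` (dosage == 0), or a
#'   single allele character (carrier of that allele).
#' @param exposure covariate name. A numeric covariate is dichotomised with
#'   `threshold` (exposed means value `>= threshold`, inclusive); a logical
#'   covariate is used as is.
#' @param threshold numeric cut-off for a numeric exposure (e.g. total
#'   cholesterol >= 5 mmol/L).
#' @return A `four_by_two` object: `counts` is a 4x2 matrix (rows
#'   `g1e1`, `g1e0`, `g0e1`, `g0e0`; columns `case`, `control`), plus
#'   `labels` describing the genotype contrast and exposure definition.
#' @export
build_4x2 <- function(dataset, snp_id, carrier = "major_carrier",
                      exposure, threshold = NULL) {
  stopifnot(inherits(dataset, "cohort"))
  if (!snp_id %in% dataset$snps$snp_id) stop("SNP not in dataset: ", snp_id)
  if (!exposure %in% names(dataset$subjects))
    stop("exposure covariate not in dataset: ", exposure)
  s <- dataset$snps[dataset$snps$snp_id == snp_id, ]
  d <- dataset$subjects[[snp_id]]

  rule <- carrier
  if (nchar(carrier) == 1) {
    if (carrier == s$allele_counted) rule <- "minor_carrier"
    else if (carrier == s$allele_major) rule <- "major_carrier"
    else stop("allele ", carrier, " is not an allele of ", snp_id)
  }
  rule <- match.arg(rule, c("minor_carrier", "minor_hom", "major_carrier",
                            "major_hom"))
  gflag <- switch(rule,
    minor_carrier = d >= 1L, minor_hom = d == 2L,
    major_carrier = d <= 1L, major_hom = d == 0L)
  glabel <- switch(rule,
    minor_carrier = paste0(s$allele_counted, " carrier"),
    minor_hom = paste0(s$allele_counted, s$allele_counted, " homozygote"),
    major_carrier = paste0(s$allele_major, " carrier"),
    major_hom = paste0(s$allele_major, s$allele_major, " homozygote"))

  ev <- dataset$subjects[[exposure]]
  if (is.logical(ev)) {
    eflag <- ev
    elabel <- exposure
  } else {
    if (is.null(threshold))
      stop("numeric exposure ", exposure, " requires a threshold")
    eflag <- as.numeric(ev) >= threshold
    elabel <- sprintf("%s >= %g", exposure, threshold)
  }
  keep <- !is.na(gflag) & !is.na(eflag)
  gflag <- gflag[keep]; eflag <- eflag[keep]
  st <- dataset$subjects$status[keep]
  cell <- function(g, e, grp) sum(gflag == g & eflag == e & st == grp)
  counts <- rbind(g1e1 = c(cell(TRUE, TRUE, "case"), cell(TRUE, TRUE, "control")),
                  g1e0 = c(cell(TRUE, FALSE, "case"), cell(TRUE, FALSE, "control")),
                  g0e1 = c(cell(FALSE, TRUE, "case"), cell(FALSE, TRUE, "control")),
                  g0e0 = c(cell(FALSE, FALSE, "case"), cell(FALSE, FALSE, "control")))
  colnames(counts) <- c("case", "control")
  if (sum(counts["g1e1", ] + counts["g0e1", ]) == 0 ||
      sum(counts["g1e0", ] + counts["g0e0", ]) == 0)
    warning("degenerate exposure: one exposure stratum is empty", call. = FALSE)
  if (all(counts["g0e0", ] == 0))
    stop("empty reference cell (non-carrier, unexposed); ",
         "interaction measures need a zero_policy upstream or a different contrast")
  structure(list(counts = counts,
                 labels = list(snp_id = snp_id, genotype = glabel,
                               exposure = elabel),
                 n_excluded = sum(!keep)),
            class = "four_by_two")
}

#' @export
print.four_by_two <- function(x, ...) {
  cat(sprintf("4x2 table: %s (%s) x %s  [reference: non-carrier, unexposed]\n",
              x$labels$snp_id, x$labels$genotype, x$labels$exposure))
  print(x$counts)
  if (x$n_excluded > 0) cat(x$n_excluded, "subject(s) excluded (missing data)\n")
  invisible(x)
}

## log-OR covariance for the three exposure/genotype classes vs the shared
## reference cell; cells may carry a Haldane correction already.
lnor_cov <- function(counts) {
  v <- function(r) 1 / counts[r, "case"] + 1 / counts[r, "control"]
  ref <- v("g0e0")
  m <- matrix(ref, 3, 3)
  diag(m) <- c(v("g1e1"), v("g1e0"), v("g0e1")) + ref
  dimnames(m) <- list(c("or11", "or10", "or01"), c("or11", "or10", "or01"))
  m
}

#' Additive and multiplicative interaction measures from a 4x2 table
#'
#' Computes the three odds ratios against the common double-reference cell
#' (`OR01` exposure only, `OR10` genotype only, `OR11` joint) and the
#' interaction measures
#' `RERI = OR11 - OR10 - OR01 + 1`, `AP = RERI / OR11`,
#' `SI = (OR11 - 1) / ((OR01 - 1) + (OR10 - 1))`, and
#' `SIM = OR11 / (OR01 * OR10)`.
#'
#' The SI interval is Zou's MOVER construction (method of variance
#' estimates recovery), combining the individual Woolf log-OR limits with
#' the shared-reference-cell correlation; RERI and AP default to the
#' Hosmer-Lemeshow delta method, with MOVER and seeded bootstrap options.
#' The SIM interval comes from `ln SIM = lnOR11 - lnOR01 - lnOR10` with the
#' full covariance of the three log-ORs.
#'
#' @param table a [build_4x2()] object, or a 4x2 counts matrix in the same
#'   row/column layout.
#' @param ci_method_additive `"delta"` (default), `"mover"`, or
#'   `"bootstrap"` for the RERI and AP intervals.
#' @param alpha synergy is declared when the additive-interaction p-value is
#'   below `alpha` (default 0.025, a Bonferroni-corrected threshold).
#' @param conf confidence level for all intervals (default 0.95).
#' @param n_boot,seed bootstrap control (used when any bootstrap interval is
#'   requested; resamples the case and control margins as multinomials).
#' @return A `gxe_measures` object with components `or01`, `or10`, `or11`
#'   ([odds_ratio()] results), `reri`, `ap`, `si`, `sim` (each a list with
#'   `estimate`, `ci`, and for RERI/SIM a p-value), `p_additive`,
#'   `p_multiplicative`, `synergy`, `flags`.
#' @export
interaction_measures <- function(table, ci_method_additive = c("delta", "mover",
                                                               "bootstrap"),
                                 alpha = 0.025, conf = 0.95, n_boot = 2000L,
                                 seed = NULL) {
  ci_method_additive <- match.arg(ci_method_additive)
  counts <- if (inherits(table, "four_by_two")) table$counts else table
  stopifnot(is.matrix(counts), nrow(counts) == 4, ncol(counts) == 2)
  if (is.null(rownames(counts)))
    rownames(counts) <- c("g1e1", "g1e0", "g0e1", "g0e0")
  if (all(counts["g0e0", ] == 0)) stop("empty reference cell")
  flags <- character(0)
  w <- counts
  if (any(counts == 0)) {
    w <- counts + 0.5
    flags <- c(flags, "haldane: 0.5 added to all 8 cells (zero cell present)")
  }
  or_for <- function(row, lab)
    odds_ratio(w[row, "case"], w["g0e0", "case"], w[row, "control"],
               w["g0e0", "control"], zero_policy = "error", conf = conf,
               contrast = lab)
  or11 <- or_for("g1e1", "joint"); or10 <- or_for("g1e0", "genotype_only")
  or01 <- or_for("g0e1", "exposure_only")
  o11 <- or11$or; o10 <- or10$or; o01 <- or01$or

  V <- lnor_cov(w)
  z <- stats::qnorm(1 - (1 - conf) / 2)

  reri_hat <- o11 - o10 - o01 + 1
  ap_hat <- reri_hat / o11
  sim_hat <- o11 / (o01 * o10)
  si_denom <- (o01 - 1) + (o10 - 1)
  si_hat <- if (abs(si_denom) < 1e-300) NA_real_ else (o11 - 1) / si_denom
  if (is.na(si_hat) || abs(si_denom) < 1e-12)
    flags <- c(flags, "SI undefined: (OR01 - 1) + (OR10 - 1) is zero")
  if (o01 < 1 || o10 < 1)
    flags <- c(flags, "SI interpretability: OR01 and OR10 not both > 1")

  ## delta-method variances on the measure scale
  g_reri <- c(o11, -o10, -o01)
  var_reri <- drop(t(g_reri) %*% V %*% g_reri)
  g_ap <- c((o10 + o01 - 1) / o11, -o10 / o11, -o01 / o11)
  var_ap <- drop(t(g_ap) %*% V %*% g_ap)
  g_sim <- c(1, -1, -1)
  var_lnsim <- drop(t(g_sim) %*% V %*% g_sim)

  p_add <- 2 * stats::pnorm(-abs(reri_hat) / sqrt(var_reri))
  p_mult <- 2 * stats::pnorm(-abs(log(sim_hat)) / sqrt(var_lnsim))

  ## individual OR limits and correlations for MOVER
  l <- c(or11$ci_low, or10$ci_low, or01$ci_low)
  u <- c(or11$ci_high, or10$ci_high, or01$ci_high)
  o <- c(o11, o10, o01)
  R <- stats::cov2cor(V)

  mover_reri <- function() {
    t12 <- 2 * R[1, 2] * (o[1] - l[1]) * (u[2] - o[2])
    t13 <- 2 * R[1, 3] * (o[1] - l[1]) * (u[3] - o[3])
    t23 <- 2 * R[2, 3] * (u[2] - o[2]) * (u[3] - o[3])
    lo <- reri_hat - sqrt(max(0, (o[1] - l[1])^2 + (u[2] - o[2])^2 +
                                (u[3] - o[3])^2 - t12 - t13 + t23))
    t12 <- 2 * R[1, 2] * (u[1] - o[1]) * (o[2] - l[2])
    t13 <- 2 * R[1, 3] * (u[1] - o[1]) * (o[3] - l[3])
    t23 <- 2 * R[2, 3] * (o[2] - l[2]) * (o[3] - l[3])
    hi <- reri_hat + sqrt(max(0, (u[1] - o[1])^2 + (o[2] - l[2])^2 +
                                (o[3] - l[3])^2 - t12 - t13 + t23))
    c(lo, hi)
  }

  ## MOVER interval for a sum x + y with correlation r
  mover_sum <- function(xh, lx, ux, yh, ly, uy, r) {
    lo <- xh + yh - sqrt(max(0, (xh - lx)^2 + (yh - ly)^2 +
                               2 * r * (xh - lx) * (yh - ly)))
    hi <- xh + yh + sqrt(max(0, (ux - xh)^2 + (uy - yh)^2 +
                               2 * r * (ux - xh) * (uy - yh)))
    c(lo, hi)
  }
  ## Donner-Zou MOVER-R interval for a ratio t1/t2 with correlation r
  ## between the numerator and denominator estimates
  mover_ratio <- function(t1, l1, u1, t2, l2, u2, r = 0) {
    dl <- u2 * (2 * t2 - u2); dh <- l2 * (2 * t2 - l2)
    kl <- t1 * t2 - r * (t1 - l1) * (u2 - t2)
    ku <- t1 * t2 - r * (u1 - t1) * (t2 - l2)
    lo <- if (dl <= 0) NA_real_ else
      (kl - sqrt(max(0, kl^2 - l1 * u2 * (2 * t1 - l1) * (2 * t2 - u2)))) / dl
    hi <- if (dh <= 0) NA_real_ else
      (ku + sqrt(max(0, ku^2 - u1 * l2 * (2 * t1 - u1) * (2 * t2 - l2)))) / dh
    c(lo, hi)
  }

  ## correlation between OR11 and the sum OR01 + OR10 (delta method on the
  ## OR scale; shared reference cell drives the covariance)
  cor_num_denom <- local({
    c_ij <- function(i, j) o[i] * o[j] * V[i, j]
    v1 <- o[1]^2 * V[1, 1]
    v2 <- o[3]^2 * V[3, 3] + o[2]^2 * V[2, 2] + 2 * o[2] * o[3] * V[2, 3]
    cv <- c_ij(1, 3) + c_ij(1, 2)
    cv / sqrt(v1 * v2)
  })

  si_ci <- c(NA_real_, NA_real_)
  if (!is.na(si_hat)) {
    den_ci <- mover_sum(o[3] - 1, l[3] - 1, u[3] - 1,
                        o[2] - 1, l[2] - 1, u[2] - 1, R[2, 3])
    si_ci <- mover_ratio(o[1] - 1, l[1] - 1, u[1] - 1,
                         si_denom, den_ci[1], den_ci[2], r = cor_num_denom)
    if (any(is.na(si_ci)))
      flags <- c(flags, "SI MOVER interval unstable (denominator CI spans 0)")
  }

  boot_q <- NULL
  if (ci_method_additive == "bootstrap") {
    boot_q <- boot_measures(counts, n_boot = n_boot, conf = conf, seed = seed)
  }
  reri_ci <- switch(ci_method_additive,
    delta = reri_hat + c(-z, z) * sqrt(var_reri),
    mover = mover_reri(),
    bootstrap = boot_q$reri)
  ap_ci <- switch(ci_method_additive,
    delta = ap_hat + c(-z, z) * sqrt(var_ap),
    mover = { num_ci <- mover_sum(o[3], l[3], u[3], o[2] - 1, l[2] - 1,
                                  u[2] - 1, R[2, 3])
              rr <- mover_ratio(o[3] + o[2] - 1, num_ci[1], num_ci[2],
                                o[1], l[1], u[1], r = cor_num_denom)
              c(1 - rr[2], 1 - rr[1]) },
    bootstrap = boot_q$ap)
  ap_ci[2] <- min(ap_ci[2], 1)
  sim_ci <- exp(log(sim_hat) + c(-z, z) * sqrt(var_lnsim))

  structure(list(
    or01 = or01, or10 = or10, or11 = or11,
    reri = list(estimate = reri_hat, ci = reri_ci, se = sqrt(var_reri),
                p_value = p_add),
    ap = list(estimate = ap_hat, ci = ap_ci, se = sqrt(var_ap)),
    si = list(estimate = si_hat, ci = si_ci, method = "mover"),
    sim = list(estimate = sim_hat, ci = sim_ci, se_log = sqrt(var_lnsim),
               p_value = p_mult),
    p_additive = p_add, p_multiplicative = p_mult,
    synergy = isTRUE(p_add < alpha && reri_hat > 0),
    alpha = alpha, conf = conf, ci_method_additive = ci_method_additive,
    counts = counts, flags = flags,
    labels = if (inherits(table, "four_by_two")) table$labels else NULL),
    class = "gxe_measures")
}

## percentile bootstrap over the case and control multinomial margins
boot_measures <- function(counts, n_boot = 2000L, conf = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nc <- sum(counts[, "case"]); nk <- sum(counts[, "control"])
  pc <- counts[, "case"] / nc; pk <- counts[, "control"] / nk
  cs <- stats::rmultinom(n_boot, nc, pc)
  ks <- stats::rmultinom(n_boot, nk, pk)
  stat <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("reri", "ap", "si", "sim")))
  for (b in seq_len(n_boot)) {
    w <- cbind(case = cs[, b], control = ks[, b])
    rownames(w) <- rownames(counts)
    if (any(w == 0)) w <- w + 0.5
    orx <- function(r) (w[r, "case"] * w["g0e0", "control"]) /
      (w["g0e0", "case"] * w[r, "control"])
    o11 <- orx("g1e1"); o10 <- orx("g1e0"); o01 <- orx("g0e1")
    stat[b, "reri"] <- o11 - o10 - o01 + 1
    stat[b, "ap"] <- stat[b, "reri"] / o11
    den <- (o01 - 1) + (o10 - 1)
    stat[b, "si"] <- if (abs(den) < 1e-12) NA_real_ else (o11 - 1) / den
    stat[b, "sim"] <- o11 / (o01 * o10)
  }
  pr <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  list(reri = unname(stats::quantile(stat[, "reri"], pr, na.rm = TRUE)),
       ap = unname(stats::quantile(stat[, "ap"], pr, na.rm = TRUE)),
       si = unname(stats::quantile(stat[, "si"], pr, na.rm = TRUE)),
       sim = unname(stats::quantile(stat[, "sim"], pr, na.rm = TRUE)))
}

#' Bootstrap confidence interval for the synergy index
#'
#' Seeded percentile bootstrap over the case/control multinomial margins of
#' a 4x2 table; the cross-check companion to the MOVER SI interval.
#'
#' @inheritParams interaction_measures
#' @return Length-2 numeric vector (lower, upper).
#' @export
si_bootstrap_ci <- function(table, n_boot = 2000L, conf = 0.95, seed = NULL) {
  counts <- if (inherits(table, "four_by_two")) table$counts else table
  boot_measures(counts, n_boot = n_boot, conf = conf, seed = seed)$si
}

#' @export
print.gxe_measures <- function(x, digits = 2, ...) {
  if (!is.null(x$labels))
    cat(sprintf("Gene-environment interaction: %s (%s) x %s\n",
                x$labels$snp_id, x$labels$genotype, x$labels$exposure))
  fmt <- function(o) sprintf("%.*f (%.*f-%.*f)", digits, o$or, digits,
                             o$ci_low, digits, o$ci_high)
  cat("  OR01 (exposure only) =", fmt(x$or01), "\n")
  cat("  OR10 (genotype only) =", fmt(x$or10), "\n")
  cat("  OR11 (joint)         =", fmt(x$or11), "\n")
  m <- function(v) sprintf("%.*f (%.*f, %.*f)", digits, v$estimate, digits,
                           v$ci[1], digits, v$ci[2])
  cat("  RERI =", m(x$reri), sprintf(" p = %.3g\n", x$reri$p_value))
  cat("  AP   =", m(x$ap), "\n")
  cat("  SI   =", if (is.na(x$si$estimate)) "undefined" else m(x$si), "\n")
  cat("  SIM  =", m(x$sim), sprintf(" p = %.3g\n", x$sim$p_value))
  cat(sprintf("  synergy at alpha = %g: %s\n", x$alpha,
              if (x$synergy) "YES" else "no"))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Scan SNP-exposure pairs for additive and multiplicative synergy
#'
#' Evaluates [interaction_measures()] for every combination of the listed
#' SNP carrier contrasts and exposures, ranks by RERI, and applies a
#' Bonferroni-corrected significance verdict across the scan.
#'
#' @param dataset a [cohort()] object.
#' @param snps SNPs to scan (default: all in the dataset).
#' @param exposures named list defining exposures: a numeric element is a
#'   threshold on that covariate (exposed means `>= threshold`); a `NULL`
#'   element marks a logical covariate used as is.
#' @param carrier carrier rule applied to every SNP (see [build_4x2()]), or
#'   a named vector of per-SNP rules.
#' @param alpha per-test significance threshold after Bonferroni correction
#'   (default 0.025).
#' @return A `gxe_scan` data.frame, one row per evaluated pair, ranked by
#'   decreasing RERI, with the interaction measures, delta-method CIs,
#'   p-values, Bonferroni-adjusted p, and synergy verdict. Constant or
#'   degenerate exposures are skipped with a warning.
#' @export
interaction_scan <- function(dataset, snps = NULL, exposures,
                             carrier = "major_carrier", alpha = 0.025) {
  stopifnot(inherits(dataset, "cohort"))
  snps <- snps %||% dataset$snps$snp_id
  cols <- c("snp_id", "genotype", "exposure", "or01", "or10", "or11", "reri",
            "reri_low", "reri_high", "ap", "si", "sim", "p_additive",
            "p_multiplicative", "p_bonferroni", "synergy")
  empty <- stats::setNames(
    data.frame(character(), character(), character(), numeric(), numeric(),
               numeric(), numeric(), numeric(), numeric(), numeric(),
               numeric(), numeric(), numeric(), numeric(), numeric(),
               logical(), stringsAsFactors = FALSE), cols)
  if (!length(exposures)) {
    class(empty) <- c("gxe_scan", "data.frame")
    return(empty)
  }
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    stop("exposures must be a named list")
  rows <- list()
  for (s in snps) {
    rule <- if (length(carrier) > 1 || !is.null(names(carrier)))
      carrier[[s]] else carrier
    for (e in names(exposures)) {
      ev <- dataset$subjects[[e]]
      if (is.null(ev)) stop("exposure covariate not in dataset: ", e)
      thr <- exposures[[e]]
      flag <- if (is.logical(ev)) ev else if (!is.null(thr)) ev >= thr else
        stop("numeric exposure ", e, " requires a threshold")
      if (length(unique(flag[!is.na(flag)])) < 2) {
        warning("exposure ", e, " is constant; skipped", call. = FALSE)
        next
      }
      tb <- try(build_4x2(dataset, s, carrier = rule, exposure = e,
                          threshold = thr), silent = TRUE)
      if (inherits(tb, "try-error")) {
        warning("skipping ", s, " x ", e, ": ",
                attr(tb, "condition")$message, call. = FALSE)
        next
      }
      mm <- interaction_measures(tb, alpha = alpha)
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = s, genotype = tb$labels$genotype, exposure = tb$labels$exposure,
        or01 = mm$or01$or, or10 = mm$or10$or, or11 = mm$or11$or,
        reri = mm$reri$estimate, reri_low = mm$reri$ci[1],
        reri_high = mm$reri$ci[2], ap = mm$ap$estimate, si = mm$si$estimate,
        sim = mm$sim$estimate, p_additive = mm$p_additive,
        p_multiplicative = mm$p_multiplicative, p_bonferroni = NA_real_,
        synergy = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    class(empty) <- c("gxe_scan", "data.frame")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p_additive, method = "bonferroni")
  out$synergy <- out$p_additive < alpha & out$reri > 0
  out <- out[order(-out$reri), ]
  rownames(out) <- NULL
  class(out) <- c("gxe_scan", "data.frame")
  out
}

#' @export
print.gxe_scan <- function(x, digits = 2, ...) {
  if (!nrow(x)) { cat("Empty interaction scan.\n"); return(invisible(x)) }
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits + 1)
  print(y, row.names = FALSE)
  invisible(x)
}
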