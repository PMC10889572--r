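#' Odds ratio from a 2x2 case-control table
#'
#' Cross-product odds ratio with Woolf (log-normal) confidence interval and
#' a two-sided Pearson chi-square p-value (no continuity correction). The
#' table convention is `a` = exposed cases, `b` = unexposed cases, `c` =
#' exposed controls, `d` = unexposed controls, so `OR = (a*d)/(b*c)`.
#'
#' @param a,b,c,d non-negative cell counts (or `a` may be a length-4 vector).
#' @param zero_policy what to do when a cell is zero: `"error"`,
#'   `"haldane"` (add 0.5 to every cell for estimation, flagged), or
#'   `"risk_ratio"` (report the risk ratio `[a/(a+c)]/[b/(b+d)]` with a
#'   log-RR interval instead, flagged).
#' @param conf confidence level (default 0.95).
#' @param contrast label carried into the result.
#'
#' @return An `odds_ratio_result`: list with `or`, `ci_low`, `ci_high`,
#'   `p_value`, `chi2`, `contrast`, `estimator` (`"cross_product"`,
#'   `"haldane"` or `"risk_ratio_fallback"`), `table`, and `conf`.
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL,
                       zero_policy = c("haldane", "error", "risk_ratio"),
                       conf = 0.95, contrast = "custom") {
  zero_policy <- match.arg(zero_policy)
  if (is.null(b)) { stopifnot(length(a) == 4); d <- a[4]; c <- a[3]; b <- a[2]; a <- a[1] }
  cells <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
             d = as.numeric(d))
  a <- cells[["a"]]; b <- cells[["b"]]; c <- cells[["c"]]; d <- cells[["d"]]
  stopifnot(all(cells >= 0))
  if (sum(cells) == 0) stop("empty 2x2 table")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ## p-value always from the uncorrected Pearson chi-square on the raw table
  n <- sum(cells)
  marg <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- if (marg == 0) NA_real_ else n * (a * d - b * c)^2 / marg
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, 1, lower.tail = FALSE)

  has_zero <- any(cells == 0)
  estimator <- "cross_product"
  w <- cells
  if (has_zero) {
    if (zero_policy == "error") {
      stop("zero cell(s) in 2x2 table (", paste(names(cells)[cells == 0], collapse = ", "),
           "); choose zero_policy = \"haldane\" or \"risk_ratio\"")
    } else if (zero_policy == "haldane") {
      w <- cells + 0.5
      estimator <- "haldane"
    } else {
      rr <- (a / (a + c)) / (b / (b + d))
      se <- sqrt(1 / a - 1 / (a + c) + 1 / b - 1 / (b + d))
      ci <- exp(log(rr) + c(-z, z) * se)
      return(structure(list(or = rr, ci_low = ci[1], ci_high = ci[2],
                            p_value = p, chi2 = chi2, contrast = contrast,
                            estimator = "risk_ratio_fallback", table = cells,
                            conf = conf), class = "odds_ratio_result"))
    }
  }
  or <- (w[["a"]] * w[["d"]]) / (w[["b"]] * w[["c"]])
  se <- sqrt(sum(1 / w))
  ci <- exp(log(or) + c(-z, z) * se)
  structure(list(or = or, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 chi2 = chi2, contrast = contrast, estimator = estimator,
                 table = cells, conf = conf),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, digits = 2, ...) {
  lab <- if (x$estimator == "risk_ratio_fallback") "RR" else "OR"
  cat(sprintf("%s [%s] = %.*f (%g%% CI %.*f-%.*f), p = %.3g%s\n", lab,
              x$contrast, digits, x$or, 100 * x$conf, digits, x$ci_low,
              digits, x$ci_high, x$p_value,
              if (x$estimator == "haldane") "  [Haldane 0.5 correction]" else ""))
  invisible(x)
}

#' Inheritance-model association contrasts for one SNP
#'
#' Builds the standard case-control contrasts from genotype counts:
#' dominant (major-allele homozygotes vs heterozygotes + minor-allele
#' homozygotes), additive (heterozygotes vs major homozygotes), recessive
#' in both orientations (minor homozygotes vs the rest, and the carrier
#' orientation), and the allele-level odds ratio in both orientations.
#'
#' @param counts a [genotype_counts()] object (or list with `case`,
#'   `control`, `alleles`, `snp_id` in the same layout).
#' @inheritParams odds_ratio
#' @return A `contrast_table` data.frame with one row per contrast:
#'   `snp_id`, `contrast`, `label`, `a`, `b`, `c`, `d`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `estimator`.
#' @export
model_contrasts <- function(counts, zero_policy = "haldane", conf = 0.95) {
  stopifnot(inherits(counts, "genotype_counts"))
  cs <- counts$case; ct <- counts$control
  if (sum(cs) == 0 || sum(ct) == 0) stop("both groups must be non-empty")
  al <- counts$alleles
  g <- c(paste0(al[1], al[1]), paste0(al[1], al[2]), paste0(al[2], al[2]))
  ac <- counts$allele_counts
  spec <- list(
    list("dominant", sprintf("%s vs %s+%s", g[1], g[2], g[3]),
         cs[[1]], cs[[2]] + cs[[3]], ct[[1]], ct[[2]] + ct[[3]]),
    list("additive", sprintf("%s vs %s", g[2], g[1]),
         cs[[2]], cs[[1]], ct[[2]], ct[[1]]),
    list("recessive", sprintf("%s vs %s+%s", g[3], g[2], g[1]),
         cs[[3]], cs[[1]] + cs[[2]], ct[[3]], ct[[1]] + ct[[2]]),
    list("carrier", sprintf("%s+%s vs %s", g[2], g[1], g[3]),
         cs[[1]] + cs[[2]], cs[[3]], ct[[1]] + ct[[2]], ct[[3]]),
    list("allele_major", sprintf("allele %s", al[1]),
         ac["case", 1], ac["case", 2], ac["control", 1], ac["control", 2]),
    list("allele_minor", sprintf("allele %s", al[2]),
         ac["case", 2], ac["case", 1], ac["control", 2], ac["control", 1]))
  rows <- lapply(spec, function(s) {
    o <- odds_ratio(s[[3]], s[[4]], s[[5]], s[[6]], zero_policy = zero_policy,
                    conf = conf, contrast = s[[1]])
    data.frame(snp_id = counts$snp_id, contrast = s[[1]], label = s[[2]],
               a = s[[3]], b = s[[4]], c = s[[5]], d = s[[6]],
               or = o$or, ci_low = o$ci_low, ci_high = o$ci_high,
               p_value = o$p_value, estimator = o$estimator,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' @export
print.contrast_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y$or <- round(y$or, digits); y$ci_low <- round(y$ci_low, digits)
  y$ci_high <- round(y$ci_high, digits); y$p_value <- signif(y$p_value, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Post-hoc power of the two-proportion z-test
#'
#' Approximate power of the two-sided pooled two-proportion z-test at the
#' observed proportions and group sizes, one plausible reading of post-hoc
#' power statements accompanying case-control odds ratios.
#'
#' @param x either a length-4 2x2 table `c(a, b, c, d)` (`a` exposed cases,
#'   `b` unexposed cases, `c` exposed controls, `d` unexposed controls; the
#'   compared proportions are then `a/(a+b)` vs `c/(c+d)`), or the first
#'   proportion `p1`.
#' @param p2,n1,n2 when `x` is a proportion: the second proportion and the
#'   two group sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in percent.
#' @export
posthoc_power <- function(x, p2 = NULL, n1 = NULL, n2 = NULL, alpha = 0.05) {
  if (length(x) == 4 && is.null(p2)) {
    a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
    p1 <- a / (a + b); p2 <- c / (c + d); n1 <- a + b; n2 <- c + d
  } else p1 <- x
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 > 0, n2 > 0)
  if (p1 %in% c(0, 1) && p2 %in% c(0, 1) && p1 == p2)
    stop("degenerate proportions: power undefined")
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))   # null (pooled) SE
  s1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) # alternative SE
  if (s1 == 0) stop("degenerate proportions: zero variance under the alternative")
  z <- stats::qnorm(1 - alpha / 2)
  delta <- p1 - p2
  pow <- stats::pnorm((delta - z * s0) / s1) + stats::pnorm((-delta - z * s0) / s1)
  100 * pow
}
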