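#' Hardy-Weinberg equilibrium test
#'
#' Tests one genotype distribution (major-homozygote, heterozygote,
#' minor-homozygote counts) against Hardy-Weinberg expectations
#' `n*p^2, 2*n*p*q, n*q^2`, where `p` is the major-allele frequency
#' estimated from the allele counts.
#'
#' @param counts either a numeric vector `c(major_hom, het, minor_hom)` or a
#'   [genotype_counts()] object (see `group`).
#' @param method `"chi2"` (1-df Pearson goodness of fit, default) or
#'   `"exact"` (full enumeration of heterozygote counts conditional on
#'   allele counts, mid-free two-sided probability-mass test).
#' @param group when `counts` is a `genotype_counts` object, which group to
#'   test (`"control"` by default, the conventional HWE reference).
#'
#' @return An `hwe_test` object: list with `chi2`, `p_value`, `df`,
#'   `observed`, `expected`, `p_allele` (major-allele frequency),
#'   `method`, and `monomorphic` flag. A monomorphic SNP returns
#'   `chi2 = 0`, `p = 1`, flagged.
#' @export
hwe_test <- function(counts, method = c("chi2", "exact"), group = "control") {
  method <- match.arg(method)
  if (inherits(counts, "genotype_counts")) counts <- counts[[group]]
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  names(counts) <- c("major_hom", "het", "minor_hom")
  p <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  q <- 1 - p
  expected <- n * c(major_hom = p^2, het = 2 * p * q, minor_hom = q^2)
  mono <- p %in% c(0, 1)
  if (mono) {
    return(structure(list(chi2 = 0, p_value = 1, df = 1L, observed = counts,
                          expected = expected, p_allele = p, method = method,
                          monomorphic = TRUE), class = "hwe_test"))
  }
  if (method == "chi2") {
    chi2 <- sum((counts - expected)^2 / expected)
    pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    pv <- hwe_exact_p(counts[[2]], counts[[1]], counts[[3]])
    chi2 <- sum((counts - expected)^2 / expected)
  }
  structure(list(chi2 = chi2, p_value = pv, df = 1L, observed = counts,
                 expected = expected, p_allele = p, method = method,
                 monomorphic = FALSE), class = "hwe_test")
}

## Exact HWE p-value by enumerating heterozygote counts conditional on the
## rare-allele count (Wigginton-style), summing probabilities <= that of the
## observed configuration.
hwe_exact_p <- function(n_het, n_hom_major, n_hom_minor) {
  n <- n_het + n_hom_major + n_hom_minor
  n_rare <- 2 * min(n_hom_major, n_hom_minor) + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  ## log P(het = h | n, n_rare) up to a constant
  lp <- vapply(hets, function(h) {
    r_hom <- (n_rare - h) / 2
    c_hom <- n - h - r_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(r_hom + 1) - lgamma(c_hom + 1) +
      h * log(2)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg %s test: chi2 = %.4f (df = %d), p = %.4g\n",
              x$method, x$chi2, x$df, x$p_value))
  cat(sprintf("  major-allele frequency p = %.4f%s\n", x$p_allele,
              if (x$monomorphic) "  [monomorphic]" else ""))
  m <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(m)
  invisible(x)
}
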