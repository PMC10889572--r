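## Haplotypes over L biallelic SNPs are 0/1 vectors (0 = major allele,
## 1 = counted allele), indexed 1..2^L in binary order (SNP 1 = lowest bit).

hap_index <- function(bits) 1L + as.integer(bits %*% 2^(seq_along(bits) - 1L))

hap_label <- function(idx, alleles) {
  ## alleles: list of c(major, counted) per SNP
  L <- length(alleles)
  vapply(idx, function(i) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(L)]
    paste(mapply(function(a, b) a[b + 1L], alleles, bits), collapse = "-")
  }, "")
}

## All unordered haplotype pairs compatible with one multilocus genotype
## (dosage vector over L SNPs). Returns a matrix with columns h1, h2, mult
## (2 for heterozygous pairs, 1 for homozygous).
compatible_pairs <- function(g) {
  L <- length(g)
  het <- which(g == 1L)
  base <- integer(L)
  base[g == 2L] <- 1L
  if (!length(het)) {
    h <- hap_index(base)
    return(matrix(c(h, h, 1L), 1, 3, dimnames = list(NULL, c("h1", "h2", "mult"))))
  }
  k <- length(het)
  n_assign <- 2L^(k - 1L)
  out <- matrix(0L, n_assign, 3, dimnames = list(NULL, c("h1", "h2", "mult")))
  for (i in seq_len(n_assign)) {
    bits <- as.integer(intToBits(i - 1L))[seq_len(max(k - 1L, 1L))]
    h1 <- base; h2 <- base
    h1[het[1]] <- 0L; h2[het[1]] <- 1L   # fix first het site to break symmetry
    if (k > 1) {
      h1[het[-1]] <- bits[seq_len(k - 1L)]
      h2[het[-1]] <- 1L - bits[seq_len(k - 1L)]
    }
    out[i, ] <- c(hap_index(h1), hap_index(h2), 2L)
  }
  out
}

dosage_matrix <- function(dataset, snp_ids) {
  if (is.matrix(dataset)) {
    m <- dataset
    if (is.null(colnames(m))) colnames(m) <- snp_ids
    return(m[, snp_ids, drop = FALSE])
  }
  stopifnot(inherits(dataset, "cohort"))
  missing_snp <- setdiff(snp_ids, dataset$snps$snp_id)
  if (length(missing_snp)) stop("SNP(s) not in dataset: ",
                                paste(missing_snp, collapse = ", "))
  as.matrix(dataset$subjects[snp_ids])
}

snp_allele_list <- function(dataset, snp_ids) {
  if (!inherits(dataset, "cohort"))
    return(lapply(snp_ids, function(s) c("0", "1")))
  lapply(snp_ids, function(s) {
    r <- dataset$snps[dataset$snps$snp_id == s, ]
    c(r$allele_major, r$allele_counted)
  })
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Expectation-maximisation over diplotype expansions: each multi-site
#' heterozygote contributes fractional weights to its compatible haplotype
#' pairs in proportion to the current frequency products (random-mating
#' assumption); the M-step re-estimates frequencies from the expected
#' haplotype counts. Initialisation is the product of marginal allele
#' frequencies (deterministic). Subjects with a missing call at any listed
#' SNP are excluded.
#'
#' @param dataset a [cohort()] object, or a dosage matrix (subjects x SNPs,
#'   values 0/1/2/NA).
#' @param snp_ids SNPs to phase (>= 2, <= 10).
#' @param tol convergence tolerance on the maximum absolute frequency change
#'   per iteration (default 1e-10).
#' @param max_iter iteration cap (default 1000); hitting it flags
#'   `converged = FALSE`.
#' @return A `haplo_em` object: list with `haplotypes` (allele-string
#'   labels), `frequencies`, `log_likelihood`, `loglik_trace`,
#'   `n_iterations`, `converged`, `n_subjects`, `snp_ids`. Frequencies below
#'   1e-6 are truncated to zero and the vector renormalised at output.
#' @export
em_haplotypes <- function(dataset, snp_ids, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(snp_ids) >= 2, length(snp_ids) <= 10)
  m <- dosage_matrix(dataset, snp_ids)
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) stop("no subjects with complete genotypes at the listed SNPs")
  L <- length(snp_ids)
  nh <- 2L^L

  ## collapse to unique genotype patterns
  key <- apply(m, 1, paste, collapse = ",")
  tab <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  wts <- as.vector(tab)
  pairs <- lapply(seq_len(nrow(pats)), function(i) compatible_pairs(pats[i, ]))

  ## init: product of marginal counted-allele frequencies
  pmar <- colMeans(m) / 2
  f <- vapply(seq_len(nh), function(h) {
    bits <- as.integer(intToBits(h - 1L))[seq_len(L)]
    prod(ifelse(bits == 1L, pmar, 1 - pmar))
  }, 0)
  f <- f / sum(f)

  n2 <- 2 * nrow(m)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    cnt <- numeric(nh)
    ll <- 0
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      lik <- p[, "mult"] * f[p[, "h1"]] * f[p[, "h2"]]
      s <- sum(lik)
      if (s <= 0) { # pattern has zero likelihood under current f; spread evenly
        w <- rep(1 / nrow(p), nrow(p))
        ll <- -Inf
      } else {
        w <- lik / s
        ll <- ll + wts[i] * log(s)
      }
      add <- wts[i] * w
      for (j in seq_len(nrow(p))) {
        cnt[p[j, "h1"]] <- cnt[p[j, "h1"]] + add[j]
        cnt[p[j, "h2"]] <- cnt[p[j, "h2"]] + add[j]
      }
    }
    if (is.finite(ll) && ll < ll_prev - 1e-8)
      stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
    ll_trace <- c(ll_trace, ll)
    f_new <- cnt / n2
    delta <- max(abs(f_new - f))
    f <- f_new
    ll_prev <- ll
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  f[f < 1e-6] <- 0
  f <- f / sum(f)
  alleles <- snp_allele_list(dataset, snp_ids)
  structure(list(haplotypes = hap_label(seq_len(nh), alleles),
                 frequencies = f, log_likelihood = ll_prev,
                 loglik_trace = ll_trace, n_iterations = it,
                 converged = converged, n_subjects = nrow(m),
                 snp_ids = snp_ids), class = "haplo_em")
}

#' @export
print.haplo_em <- function(x, ...) {
  cat("EM haplotype estimate over", paste(x$snp_ids, collapse = ", "),
      sprintf("(%d subjects)\n", x$n_subjects))
  ord <- order(x$frequencies, decreasing = TRUE)
  keep <- x$frequencies[ord] > 0
  df <- data.frame(haplotype = x$haplotypes[ord][keep],
                   frequency = round(x$frequencies[ord][keep], 4))
  print(df, row.names = FALSE)
  cat(sprintf("log-likelihood %.4f after %d iteration(s)%s\n", x$log_likelihood,
              x$n_iterations, if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

## D, D', r2 from the four two-SNP haplotype frequencies (pAB, order
## (major,major), (counted,major), (major,counted), (counted,counted) in
## binary index order; "A"/"B" below denote the counted alleles).
ld_from_freq <- function(f) {
  ## f indexed: 1 = 00, 2 = 10, 3 = 01, 4 = 11 (SNP1 low bit)
  pA <- f[2] + f[4]          # counted allele, SNP 1
  pB <- f[3] + f[4]          # counted allele, SNP 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic SNP: LD undefined")
  D <- f[4] - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  Dp <- if (Dmax == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(D = D, D_prime = min(Dp, 1), r2 = min(r2, 1), pA = pA, pB = pB)
}

#' Pairwise linkage disequilibrium (D' and r^2)
#'
#' Estimates the four haplotype frequencies for one SNP pair by EM and
#' derives `D = pAB - pA*pB`, the normalised `D'`, and the squared allelic
#' correlation `r^2`. The `D'` confidence interval is a seeded
#' nonparametric bootstrap over subjects (percentile interval; the default
#' 90% level matches the 5%/95% one-sided bounds used in Gabriel-style
#' block calling).
#'
#' @param dataset a [cohort()] object, dosage matrix, or a fitted
#'   [em_haplotypes()] object restricted to 2 SNPs (no CI in that case).
#' @param snp_ids the SNP pair.
#' @param n_boot bootstrap resamples for the `D'` CI (default 1000; 0
#'   disables).
#' @param conf CI level (default 0.90).
#' @param seed optional RNG seed for the bootstrap.
#' @return An `ld_result`: list with `D`, `D_prime`, `r2`, `D_prime_ci`,
#'   `conf`, `snp_ids`, `n_subjects`.
#' @export
ld_measures <- function(dataset, snp_ids = NULL, n_boot = 1000L, conf = 0.90,
                        seed = NULL) {
  if (inherits(dataset, "haplo_em")) {
    stopifnot(length(dataset$snp_ids) == 2)
    ld <- ld_from_freq(dataset$frequencies)
    return(structure(c(ld[c("D", "D_prime", "r2")],
                       list(D_prime_ci = c(NA_real_, NA_real_), conf = conf,
                            snp_ids = dataset$snp_ids,
                            n_subjects = dataset$n_subjects)),
                     class = "ld_result"))
  }
  stopifnot(length(snp_ids) == 2)
  m <- dosage_matrix(dataset, snp_ids)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  est <- em_haplotypes(m, snp_ids)
  ld <- ld_from_freq(est$frequencies)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(m)
    dp <- vapply(seq_len(n_boot), function(b) {
      mb <- m[sample.int(n, n, replace = TRUE), , drop = FALSE]
      eb <- try(em_haplotypes(mb, snp_ids), silent = TRUE)
      if (inherits(eb, "try-error")) return(NA_real_)
      ldb <- try(ld_from_freq(eb$frequencies), silent = TRUE)
      if (inherits(ldb, "try-error")) NA_real_ else ldb$D_prime
    }, 0)
    dp <- dp[!is.na(dp)]
    if (length(dp))
      ci <- unname(stats::quantile(dp, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(c(ld[c("D", "D_prime", "r2")],
              list(D_prime_ci = ci, conf = conf, snp_ids = snp_ids,
                   n_subjects = nrow(m))), class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD %s - %s (n = %d): D = %.4f, D' = %.3f, r2 = %.3f\n",
              x$snp_ids[1], x$snp_ids[2], x$n_subjects, x$D, x$D_prime, x$r2))
  if (!is.na(x$D_prime_ci[1]))
    cat(sprintf("  D' %g%% bootstrap CI: (%.3f, %.3f)\n", 100 * x$conf,
                x$D_prime_ci[1], x$D_prime_ci[2]))
  invisible(x)
}

#' Gabriel-style haplotype block detection
#'
#' Classifies every SNP pair from its bootstrap `D'` confidence bounds
#' (strong LD: upper bound >= 0.98 and lower bound >= 0.70; strong
#' recombination: upper bound < 0.90; otherwise inconclusive) and accepts a
#' contiguous candidate block when at least 95% of its informative pairs
#' are in strong LD. Maximal non-overlapping blocks are reported, longest
#' first.
#'
#' @param dataset a [cohort()] object (SNP positions required).
#' @param snp_ids SNPs to consider (default: all), ordered by position.
#' @param n_boot,seed bootstrap control passed to [ld_measures()].
#' @return A `block_partition`: list with `blocks` (list of SNP-id vectors),
#'   `pairs` (data.frame of pairwise `D'`, CI, class), `snp_ids` in
#'   position order.
#' @export
gabriel_blocks <- function(dataset, snp_ids = NULL, n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(dataset, "cohort"))
  snp_ids <- snp_ids %||% dataset$snps$snp_id
  if (length(snp_ids) < 2) stop("at least 2 SNPs required for block detection")
  info <- dataset$snps[match(snp_ids, dataset$snps$snp_id), ]
  if (any(is.na(info$position)))
    stop("missing position(s) for: ",
         paste(info$snp_id[is.na(info$position)], collapse = ", "))
  ord <- order(info$position)
  snp_ids <- snp_ids[ord]
  L <- length(snp_ids)
  if (!is.null(seed)) set.seed(seed)
  pairs <- list()
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    ld <- ld_measures(dataset, c(snp_ids[i], snp_ids[j]), n_boot = n_boot)
    cl <- if (is.na(ld$D_prime_ci[2])) "inconclusive"
          else if (ld$D_prime_ci[2] >= 0.98 && ld$D_prime_ci[1] >= 0.70) "strong_LD"
          else if (ld$D_prime_ci[2] < 0.90) "recombination"
          else "inconclusive"
    pairs[[length(pairs) + 1]] <-
      data.frame(snp1 = snp_ids[i], snp2 = snp_ids[j], i = i, j = j,
                 D_prime = ld$D_prime, r2 = ld$r2,
                 ci_low = ld$D_prime_ci[1], ci_high = ld$D_prime_ci[2],
                 class = cl, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)

  cand <- list()
  for (len in L:2) for (start in seq_len(L - len + 1)) {
    i0 <- start; j0 <- start + len - 1
    sel <- pairs$i >= i0 & pairs$j <= j0
    informative <- sum(pairs$class[sel] != "inconclusive")
    strong <- sum(pairs$class[sel] == "strong_LD")
    if (informative > 0 && strong / informative >= 0.95)
      cand[[length(cand) + 1]] <- c(i0, j0)
  }
  blocks <- list()
  taken <- rep(FALSE, L)
  for (b in cand) {
    if (any(taken[b[1]:b[2]])) next
    taken[b[1]:b[2]] <- TRUE
    blocks[[length(blocks) + 1]] <- snp_ids[b[1]:b[2]]
  }
  if (length(blocks))
    blocks <- blocks[order(vapply(blocks, function(b)
      match(b[1], snp_ids), 0))]
  structure(list(blocks = blocks, pairs = pairs, snp_ids = snp_ids),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Pairwise LD classification:\n")
  y <- x$pairs[c("snp1", "snp2", "D_prime", "r2", "ci_low", "ci_high", "class")]
  y[3:6] <- lapply(y[3:6], round, 3)
  print(y, row.names = FALSE)
  if (!length(x$blocks)) cat("No haplotype blocks detected.\n")
  else for (b in x$blocks) cat("Block:", paste(b, collapse = " - "), "\n")
  invisible(x)
}
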