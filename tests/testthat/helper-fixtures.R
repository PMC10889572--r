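## Shared builders for small in-code fixtures.

## A minimal two-SNP cohort with covariates and survival follow-up.
make_small_cohort <- function() {
  subj <- data.frame(
    subject_id = sprintf("s%02d", 1:8),
    status = c("case", "case", "case", "case", "control", "control",
               "control", "control"),
    rs1 = c(0L, 1L, 2L, NA, 0L, 1L, 1L, 2L),
    rs2 = c(0L, 0L, 1L, 1L, 0L, 2L, NA, 1L),
    tc = c(5.5, 4.2, 6.0, 5.0, 4.8, 5.2, 3.9, 4.4),
    smoking = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    time = c(2.5, 4.2, 7.0, 1.1, NA, NA, NA, NA),
    event = c(TRUE, FALSE, TRUE, FALSE, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = c("rs1", "rs2"),
                     allele_major = c("C", "A"), allele_counted = c("T", "G"),
                     chromosome = "15", position = c(100L, 9100L),
                     stringsAsFactors = FALSE)
  cohort(subj, snps)
}

## Random cohort for round-trip properties (genotypes with missingness,
## numeric + logical covariates, survival on cases).
make_random_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  status <- sample(c("case", "control"), n, replace = TRUE)
  subj <- data.frame(
    subject_id = sprintf("r%03d", seq_len(n)),
    status = status,
    snpA = sample(c(0:2, NA), n, replace = TRUE),
    snpB = sample(c(0:2, NA), n, replace = TRUE),
    tc = round(stats::rlnorm(n, log(5), 0.2), 3),
    smoking = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
  subj$time <- ifelse(status == "case", round(stats::rexp(n, 0.1), 3), NA)
  subj$event <- ifelse(status == "case", stats::runif(n) < 0.5, NA)
  snps <- data.frame(snp_id = c("snpA", "snpB"),
                     allele_major = c("G", "T"), allele_counted = c("A", "C"),
                     chromosome = c("1", "1"), position = c(500L, 1500L),
                     stringsAsFactors = FALSE)
  cohort(subj, snps)
}

## Build a cohort holding only genotype dosages for two SNPs (LD/EM tests).
cohort_from_dosages <- function(m, snp_ids = c("s1", "s2"),
                                positions = c(1000L, 2000L)) {
  n <- nrow(m)
  subj <- data.frame(subject_id = sprintf("x%04d", seq_len(n)),
                     status = rep(c("case", "control"), length.out = n),
                     stringsAsFactors = FALSE)
  for (i in seq_along(snp_ids)) subj[[snp_ids[i]]] <- as.integer(m[, i])
  snps <- data.frame(snp_id = snp_ids,
                     allele_major = rep(c("A", "C"), length.out = length(snp_ids)),
                     allele_counted = rep(c("G", "T"), length.out = length(snp_ids)),
                     chromosome = "1", position = positions,
                     stringsAsFactors = FALSE)
  cohort(subj, snps)
}

## Draw n two-SNP dosage rows from a 4-haplotype pool (binary index order).
draw_diplotypes <- function(n, pool) {
  h1 <- sample.int(4L, n, replace = TRUE, prob = pool)
  h2 <- sample.int(4L, n, replace = TRUE, prob = pool)
  bit <- function(h, k) as.integer(bitwAnd(h - 1L, k) > 0L)
  cbind(bit(h1, 1L) + bit(h2, 1L), bit(h1, 2L) + bit(h2, 2L))
}

## Independent brute-force maximiser of the two-SNP haplotype multinomial
## likelihood over a frequency grid (coarse pass, then top-point refinement
## down to 1e-4 resolution). Oracle for the EM estimates.
grid_em_oracle <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  key <- paste(m[, 1], m[, 2], sep = ",")
  tab <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ","), as.integer))
  wts <- as.vector(tab)
  ## compatible haplotype pairs per pattern (index order 00,10,01,11)
  pair_list <- lapply(seq_len(nrow(pats)), function(i) {
    g <- pats[i, ]
    het <- which(g == 1L)
    base <- c(0L, 0L); base[g == 2L] <- 1L
    idx <- function(b) 1L + b[1] + 2L * b[2]
    if (length(het) == 0) cbind(idx(base), idx(base), 1)
    else if (length(het) == 1) {
      b1 <- base; b2 <- base; b1[het] <- 0L; b2[het] <- 1L
      cbind(idx(b1), idx(b2), 2)
    } else rbind(c(idx(c(0L, 0L)), idx(c(1L, 1L)), 2),
                 c(idx(c(0L, 1L)), idx(c(1L, 0L)), 2))
  })
  loglik <- function(fm) { # fm: npts x 4
    ll <- rep(0, nrow(fm))
    for (i in seq_along(pair_list)) {
      p <- pair_list[[i]]
      pr <- rep(0, nrow(fm))
      for (j in seq_len(nrow(p)))
        pr <- pr + p[j, 3] * fm[, p[j, 1]] * fm[, p[j, 2]]
      ll <- ll + wts[i] * log(pmax(pr, 1e-300))
    }
    ll
  }
  simplex_grid <- function(lo, hi, step) {
    s <- lapply(1:3, function(i) seq(max(0, lo[i]), min(1, hi[i]), by = step))
    g <- as.matrix(expand.grid(s[[1]], s[[2]], s[[3]]))
    f4 <- 1 - rowSums(g)
    keep <- f4 >= -1e-12
    cbind(g[keep, , drop = FALSE], pmax(f4[keep], 0))
  }
  fm <- simplex_grid(c(0, 0, 0), c(1, 1, 1), 0.02)
  ll <- loglik(fm)
  best <- fm[order(ll, decreasing = TRUE)[seq_len(min(10, nrow(fm)))], ,
             drop = FALSE]
  for (step in c(2e-3, 1e-4)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(best)), function(i)
      simplex_grid(best[i, 1:3] - 15 * step, best[i, 1:3] + 15 * step, step)))
    ll <- loglik(cand)
    best <- cand[order(ll, decreasing = TRUE)[seq_len(min(5, nrow(cand)))], ,
                 drop = FALSE]
  }
  best[1, ]
}

## Exact odds-ratio 4x2 count tables for worked interaction examples:
## reference odds fixed at 0.5 (10 cases / 20 controls).
table_with_ors <- function(or01, or10, or11, scale = 20) {
  w <- rbind(g1e1 = c(or11 * 0.5 * scale, scale),
             g1e0 = c(or10 * 0.5 * scale, scale),
             g0e1 = c(or01 * 0.5 * scale, scale),
             g0e0 = c(0.5 * scale, scale))
  colnames(w) <- c("case", "control")
  w
}
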