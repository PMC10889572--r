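#' Construct a cohort dataset
#'
#' A `cohort` bundles a subject-level table (case/control status, genotype
#' dosages, covariates, optional survival follow-up) with the SNP annotation
#' needed to interpret the genotype columns. Genotypes are stored as dosages
#' of the *counted* allele (0, 1, 2 or `NA`); by convention the counted
#' allele is the minor allele in the combined sample.
#'
#' @param subjects data.frame with columns `subject_id` (unique character),
#'   `status` (`"case"` or `"control"`), one integer dosage column per SNP
#'   (named by `snp_id`), any number of numeric/logical covariate columns,
#'   and optionally `time` (years) and `event` (logical) for cases.
#' @param snps data.frame with columns `snp_id`, `allele_major`,
#'   `allele_counted` (single-character nucleotides, distinct), and
#'   optionally `chromosome` and `position` (1-based bp).
#'
#' @return An object of class `cohort`: a list with elements `subjects`
#'   and `snps`.
#'
#' @details Survival follow-up is only meaningful for cases (controls are
#'   unfollowed blood donors); non-missing `time`/`event` on a control is an
#'   error. Missing genotype calls are `NA`, distinct from dosage 0.
#'
#' @examples
#' subj <- data.frame(subject_id = c("s1", "s2"), status = c("case", "control"),
#'                    rs1 = c(1L, 0L))
#' snps <- data.frame(snp_id = "rs1", allele_major = "C", allele_counted = "T")
#' cohort(subj, snps)
#' @export
cohort <- function(subjects, snps) {
  stopifnot(is.data.frame(subjects), is.data.frame(snps))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  req <- c("snp_id", "allele_major", "allele_counted")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(snps$snp_id))
    stop("duplicate snp_id in snp table: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  bad <- snps$allele_major == snps$allele_counted
  if (any(bad))
    stop("allele_major equals allele_counted for SNP ",
         paste(snps$snp_id[bad], collapse = ", "))
  if (!"chromosome" %in% names(snps)) snps$chromosome <- NA_character_
  if (!"position" %in% names(snps)) snps$position <- NA_integer_

  if (!all(c("subject_id", "status") %in% names(subjects)))
    stop("subjects must have columns subject_id and status")
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  bad_status <- setdiff(unique(subjects$status), c("case", "control"))
  if (length(bad_status))
    stop("invalid status value(s): ", paste(sQuote(bad_status), collapse = ", "),
         "; accepted tokens are \"case\" and \"control\"")
  missing_cols <- setdiff(snps$snp_id, names(subjects))
  if (length(missing_cols))
    stop("genotype column(s) absent from subjects: ",
         paste(missing_cols, collapse = ", "))
  for (s in snps$snp_id) {
    d <- subjects[[s]]
    if (!all(is.na(d) | d %in% 0:2))
      stop("dosage values for ", s, " must be 0, 1, 2 or NA")
    subjects[[s]] <- as.integer(d)
  }
  has_time <- "time" %in% names(subjects)
  has_event <- "event" %in% names(subjects)
  if (has_time != has_event)
    stop("survival columns time and event must be supplied together")
  if (has_time) {
    t <- subjects$time
    if (any(!is.na(t) & t < 0)) stop("survival time must be >= 0")
    ctrl <- subjects$status == "control"
    if (any(ctrl & (!is.na(t) | !is.na(subjects$event))))
      stop("survival follow-up present for control subject(s): controls are not followed")
    if (any(!is.na(t) & is.na(subjects$event)) || any(is.na(t) & !is.na(subjects$event)))
      stop("time and event must be jointly present or jointly missing per subject")
    subjects$event <- as.logical(subjects$event)
    subjects$time <- as.numeric(subjects$time)
  }
  structure(list(subjects = subjects, snps = snps), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ns <- table(factor(x$subjects$status, levels = c("case", "control")))
  cat("Cohort dataset:", nrow(x$subjects), "subjects (",
      ns[["case"]], "cases /", ns[["control"]], "controls ),",
      nrow(x$snps), "SNP(s)\n")
  for (i in seq_len(nrow(x$snps))) {
    s <- x$snps[i, ]
    miss <- sum(is.na(x$subjects[[s$snp_id]]))
    cat(sprintf("  %s  %s>%s (counted %s)  missing calls: %d\n", s$snp_id,
                s$allele_major, s$allele_counted, s$allele_counted, miss))
  }
  cov <- setdiff(names(x$subjects),
                 c("subject_id", "status", "time", "event", x$snps$snp_id))
  if (length(cov)) cat("  covariates:", paste(cov, collapse = ", "), "\n")
  if ("time" %in% names(x$subjects))
    cat("  survival follow-up on", sum(!is.na(x$subjects$time)), "cases\n")
  invisible(x)
}

## ---- delimited format ------------------------------------------------------

## Header metadata lines, one per SNP, written before the column header:
##   #snp id=rs1994016 alleles=C/T counted=T chrom=15 pos=78963975
## Genotypes are written as unordered allele pairs ("C/T"); missing is NA.

format_snp_meta <- function(s) {
  out <- sprintf("#snp id=%s alleles=%s/%s counted=%s", s$snp_id,
                 s$allele_major, s$allele_counted, s$allele_counted)
  if (!is.na(s$chromosome)) out <- paste0(out, " chrom=", s$chromosome)
  if (!is.na(s$position)) out <- paste0(out, " pos=", s$position)
  out
}

parse_snp_meta <- function(lines) {
  out <- lapply(lines, function(l) {
    body <- sub("^#snp\\s+", "", l)
    kv <- strsplit(strsplit(body, "\\s+")[[1]], "=")
    vals <- vapply(kv, `[`, "", 2)
    names(vals) <- vapply(kv, `[`, "", 1)
    al <- strsplit(vals[["alleles"]], "/", fixed = TRUE)[[1]]
    counted <- vals[["counted"]]
    data.frame(snp_id = vals[["id"]],
               allele_major = setdiff(al, counted)[1],
               allele_counted = counted,
               chromosome = if ("chrom" %in% names(vals)) vals[["chrom"]] else NA_character_,
               position = if ("pos" %in% names(vals)) as.integer(vals[["pos"]]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Dosage from an "A/B" pair (unordered, phase ignored) against a counted
## allele; unknown tokens -> NA. Integer-looking tokens pass through as dosage.
pair_to_dosage <- function(x, major, counted) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  is_int <- grepl("^[012]$", x)
  out[is_int] <- as.integer(x[is_int])
  pair <- grepl("^[ACGTacgt][/|][ACGTacgt]$", x)
  foreign_pairs <- 0L
  if (any(pair)) {
    a1 <- toupper(substr(x[pair], 1, 1))
    a2 <- toupper(substr(x[pair], 3, 3))
    ok <- (a1 %in% c(major, counted)) & (a2 %in% c(major, counted))
    d <- (a1 == counted) + (a2 == counted)
    d[!ok] <- NA_integer_
    out[pair] <- d
    foreign_pairs <- sum(!ok)
  }
  known <- is_int | pair | is.na(x) | x %in% c("", "NA", "./.", ".|.", ".")
  attr(out, "n_unknown") <- sum(!known) + foreign_pairs
  out
}

sniff_sep <- function(path) {
  l <- readLines(path, n = 50L, warn = FALSE)
  l <- l[!startsWith(l, "#")]
  if (!length(l)) stop("no header line found in ", path)
  if (lengths(regmatches(l[1], gregexpr("\t", l[1]))) > 0) "\t" else ","
}

#' Read a cohort dataset
#'
#' Reads the canonical delimited cohort format (UTF-8, comma- or
#' tab-separated, sniffed; `NA` missing token; optional `#snp` metadata
#' lines declaring alleles and positions) or a VCF file paired with a
#' phenotype table.
#'
#' @param path file to read (delimited cohort file, or VCF when
#'   `format = "vcf"`).
#' @param format `"delimited"` (default) or `"vcf"`.
#' @param phenotype for `format = "vcf"`: path to a delimited phenotype file
#'   with columns `subject_id`, `status`, covariates, optional
#'   `time`/`event`, keyed by the VCF sample names.
#' @param snps optional SNP annotation data.frame (as in [cohort()]) used
#'   when the delimited file carries no `#snp` metadata. If neither is
#'   available, alleles are inferred from the genotype pairs and the counted
#'   allele is the minor allele in the combined sample (ties broken
#'   lexicographically).
#'
#' @return A [cohort()] object. Unrecognised genotype tokens are converted
#'   to missing with a warning giving the count per SNP.
#' @export
read_cohort <- function(path, format = c("delimited", "vcf"), phenotype = NULL,
                        snps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_cohort_vcf(path, phenotype))

  all_lines <- readLines(path, warn = FALSE)
  meta <- all_lines[startsWith(all_lines, "#snp")]
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  if (!all(c("subject_id", "status") %in% names(df)))
    stop("malformed header: required columns subject_id and status not found in ", path)
  df$subject_id <- as.character(df$subject_id)

  if (length(meta)) {
    snp_tab <- parse_snp_meta(meta)
  } else if (!is.null(snps)) {
    snp_tab <- as.data.frame(snps, stringsAsFactors = FALSE)
  } else {
    snp_tab <- infer_snp_table(df)
  }
  miss_col <- setdiff(snp_tab$snp_id, names(df))
  if (length(miss_col))
    stop("malformed header: declared SNP column(s) missing: ",
         paste(miss_col, collapse = ", "))
  for (i in seq_len(nrow(snp_tab))) {
    s <- snp_tab[i, ]
    d <- pair_to_dosage(as.character(df[[s$snp_id]]), s$allele_major, s$allele_counted)
    nun <- attr(d, "n_unknown")
    if (!is.null(nun) && nun > 0)
      warning(nun, " unrecognised genotype token(s) at ", s$snp_id,
              " set to missing", call. = FALSE)
    df[[s$snp_id]] <- as.integer(d)
  }
  if ("event" %in% names(df) && !is.logical(df$event))
    df$event <- as.logical(df$event)
  cohort(df, snp_tab)
}

## Infer per-SNP alleles and the counted (minor) allele from raw "A/B" columns.
infer_snp_table <- function(df) {
  skip <- c("subject_id", "status", "time", "event")
  cand <- setdiff(names(df), skip)
  rows <- list()
  for (col in cand) {
    x <- as.character(df[[col]])
    pr <- grepl("^[ACGTacgt][/|][ACGTacgt]$", x)
    if (!any(pr)) next
    al <- toupper(c(substr(x[pr], 1, 1), substr(x[pr], 3, 3)))
    tab <- sort(table(al))
    alleles <- names(tab)
    if (length(alleles) == 1) alleles <- c(alleles, alleles) # monomorphic column
    if (length(alleles) > 2)
      stop("non-biallelic genotype column ", col, ": alleles ",
           paste(names(tab), collapse = ", "))
    counts <- as.vector(tab)
    minor <- if (counts[1] == counts[2]) sort(alleles)[1] else alleles[1]
    major <- setdiff(alleles, minor)[1]
    if (is.na(major)) major <- minor # degenerate; caught by cohort()
    rows[[col]] <- data.frame(snp_id = col, allele_major = major,
                              allele_counted = minor,
                              chromosome = NA_character_, position = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no genotype columns recognised and no snp metadata given")
  do.call(rbind, rows)
}

read_cohort_vcf <- function(path, phenotype) {
  if (is.null(phenotype))
    stop("VCF import requires a phenotype file (subject_id, status, ...)")
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package vcfR is required for VCF import")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.null(dim(fix))) as.data.frame(t(fix), stringsAsFactors = FALSE)
         else as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi))
    stop("non-biallelic SNP record(s) in VCF: ",
         paste(sprintf("%s:%s (%s)", fix$CHROM[multi], fix$POS[multi],
                       ifelse(is.na(fix$ID[multi]), ".", fix$ID[multi])),
               collapse = "; "))
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, names(gt)))
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  })
  ph_sep <- sniff_sep(phenotype)
  ph <- utils::read.table(phenotype, header = TRUE, sep = ph_sep,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  ph$subject_id <- as.character(ph$subject_id)
  samp <- colnames(gt)
  missing_ph <- setdiff(samp, ph$subject_id)
  if (length(missing_ph))
    stop("VCF sample(s) absent from phenotype file: ",
         paste(missing_ph, collapse = ", "))
  ph <- ph[match(samp, ph$subject_id), , drop = FALSE]
  for (i in seq_along(ids)) ph[[ids[i]]] <- as.integer(dos[i, ])
  ## ALT is the counted allele per VCF GT semantics
  snp_tab <- data.frame(snp_id = ids, allele_major = fix$REF,
                        allele_counted = fix$ALT, chromosome = fix$CHROM,
                        position = as.integer(fix$POS), stringsAsFactors = FALSE)
  if ("event" %in% names(ph) && !is.logical(ph$event))
    ph$event <- as.logical(ph$event)
  cohort(ph, snp_tab)
}

#' Write a cohort dataset to the canonical delimited format
#'
#' Tab-separated, UTF-8, with one `#snp` metadata line per SNP so that
#' [read_cohort()] round-trips the dataset field-for-field, including
#' missing genotype calls and survival records.
#'
#' @param dataset a [cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(dataset, path) {
  stopifnot(inherits(dataset, "cohort"))
  df <- dataset$subjects
  for (i in seq_len(nrow(dataset$snps))) {
    s <- dataset$snps[i, ]
    d <- df[[s$snp_id]]
    g <- c(paste0(s$allele_major, "/", s$allele_major),
           paste0(s$allele_major, "/", s$allele_counted),
           paste0(s$allele_counted, "/", s$allele_counted))[d + 1L]
    df[[s$snp_id]] <- ifelse(is.na(d), NA_character_, g)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(dataset$snps)))
    writeLines(format_snp_meta(dataset$snps[i, ]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Genotype and allele counts for one SNP
#'
#' Tabulates major-homozygote, heterozygote and minor-homozygote counts in
#' cases and controls for a single SNP, excluding subjects with a missing
#' call at that SNP (pairwise-complete deletion), together with the derived
#' allele counts (2 x homozygotes + heterozygotes).
#'
#' @param dataset a [cohort()] object.
#' @param snp_id SNP identifier present in `dataset$snps`.
#' @return A `genotype_counts` object: list with `snp_id`, `alleles`
#'   (major, counted), `case` and `control` (named integer vectors
#'   `major_hom`, `het`, `minor_hom`), and `allele_counts` (2x2 matrix,
#'   rows case/control, columns major/counted allele).
#' @export
genotype_counts <- function(dataset, snp_id) {
  stopifnot(inherits(dataset, "cohort"))
  if (!snp_id %in% dataset$snps$snp_id) stop("SNP not in dataset: ", snp_id)
  s <- dataset$snps[dataset$snps$snp_id == snp_id, ]
  d <- dataset$subjects[[snp_id]]
  st <- dataset$subjects$status
  count3 <- function(x) {
    x <- x[!is.na(x)]
    c(major_hom = sum(x == 0L), het = sum(x == 1L), minor_hom = sum(x == 2L))
  }
  cs <- count3(d[st == "case"])
  ct <- count3(d[st == "control"])
  if (sum(cs) + sum(ct) == 0)
    warning("all genotype calls missing at ", snp_id, call. = FALSE)
  genotype_counts_obj(snp_id, c(s$allele_major, s$allele_counted), cs, ct)
}

genotype_counts_obj <- function(snp_id, alleles, case, control) {
  ac <- rbind(case = c(2 * case[["major_hom"]] + case[["het"]],
                       2 * case[["minor_hom"]] + case[["het"]]),
              control = c(2 * control[["major_hom"]] + control[["het"]],
                          2 * control[["minor_hom"]] + control[["het"]]))
  colnames(ac) <- alleles
  structure(list(snp_id = snp_id, alleles = alleles,
                 case = case, control = control, allele_counts = ac),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("Genotype counts for", x$snp_id, " (counted allele:", x$alleles[2], ")\n")
  m <- rbind(case = x$case, control = x$control)
  gl <- c(paste0(x$alleles[1], x$alleles[1]), paste0(x$alleles[1], x$alleles[2]),
          paste0(x$alleles[2], x$alleles[2]))
  colnames(m) <- gl
  print(m)
  cat("Allele counts:\n")
  print(x$allele_counts)
  invisible(x)
}

## Covariate columns of a cohort (everything that is not id/status/genotype/survival)
covariate_names <- function(dataset) {
  setdiff(names(dataset$subjects),
          c("subject_id", "status", "time", "event", dataset$snps$snp_id))
}
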