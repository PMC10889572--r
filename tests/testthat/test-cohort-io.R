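test_that("allele pairs are encoded as counted-allele dosages", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#snp id=rs1 alleles=C/T counted=T",
               "subject_id\tstatus\trs1",
               "a\tcase\tC/C", "b\tcase\tC/T", "c\tcontrol\tT/T"), f)
  d <- read_cohort(f)
  expect_identical(d$subjects$rs1, c(0L, 1L, 2L))
})

test_that("alleles and counted allele are inferred without metadata", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,status,rs9",
               "a,case,C/C", "b,case,C/T", "c,control,C/C", "d,control,C/T"), f)
  d <- read_cohort(f)
  ## T is rarer in the combined sample -> counted
  expect_equal(d$snps$allele_counted, "T")
  expect_identical(d$subjects$rs9, c(0L, 1L, 0L, 1L))
})

test_that("invalid status tokens are rejected with the offending value", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#snp id=rs1 alleles=C/T counted=T",
               "subject_id\tstatus\trs1", "a\tpatient\tC/C"), f)
  expect_error(read_cohort(f), "patient")
  expect_error(read_cohort(f), "case")
})

test_that("duplicate subject ids and unknown genotype tokens are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#snp id=rs1 alleles=C/T counted=T",
               "subject_id\tstatus\trs1",
               "a\tcase\tC/C", "a\tcontrol\tC/T"), f)
  expect_error(read_cohort(f), "duplicate subject_id")
  writeLines(c("#snp id=rs1 alleles=C/T counted=T",
               "subject_id\tstatus\trs1",
               "a\tcase\tC/C", "b\tcontrol\tXX", "c\tcontrol\tG/G"), f)
  expect_warning(d <- read_cohort(f), "2 unrecognised")
  expect_identical(d$subjects$rs1, c(0L, NA, NA))
})

test_that("delimited round-trip reproduces datasets field-for-field", {
  for (seed in 1:3) {
    d <- make_random_cohort(n = 30, seed = seed)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_cohort(d, f)
    d2 <- read_cohort(f)
    expect_equal(d2$snps, d$snps)
    expect_equal(d2$subjects, d$subjects, tolerance = 1e-12)
  }
})

test_that("round-trip preserves missing genotypes and survival records", {
  d <- make_small_cohort()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(d, f)
  d2 <- read_cohort(f)
  expect_identical(d2$subjects$rs1[4], NA_integer_)  # missing, not 0
  expect_equal(d2$subjects$time[1], 2.5)
  expect_true(d2$subjects$event[1])
  expect_identical(d2$subjects$event[5], NA)
})

test_that("survival follow-up on controls is rejected", {
  subj <- data.frame(subject_id = c("a", "b"), status = c("case", "control"),
                     rs1 = c(0L, 1L), time = c(1, 2), event = c(TRUE, FALSE))
  snps <- data.frame(snp_id = "rs1", allele_major = "C", allele_counted = "T")
  expect_error(cohort(subj, snps), "controls are not followed")
})

test_that("genotype_counts matches the study fixture and direct counting", {
  fx <- cad_study_counts()$rs1994016
  expect_equal(unname(fx$case), c(85, 104, 28))
  expect_equal(unname(fx$control), c(84, 101, 47))
  expect_equal(unname(fx$allele_counts["case", ]), c(274, 160))
  expect_equal(unname(fx$allele_counts["control", ]), c(269, 195))

  d <- make_small_cohort()
  gc <- genotype_counts(d, "rs1")
  ## case dosages 0,1,2,NA; control 0,1,1,2
  expect_equal(unname(gc$case), c(1, 1, 1))
  expect_equal(unname(gc$control), c(1, 2, 1))
  expect_equal(sum(gc$allele_counts["control", ]), 2 * sum(gc$control))
})

test_that("counts sum to non-missing n and all-missing yields a warning", {
  d <- make_random_cohort(n = 25, seed = 9)
  gc <- genotype_counts(d, "snpA")
  expect_equal(sum(gc$case) + sum(gc$control),
               sum(!is.na(d$subjects$snpA)))
  d$subjects$snpA[] <- NA_integer_
  expect_warning(gc0 <- genotype_counts(d, "snpA"), "all genotype calls missing")
  expect_equal(sum(gc0$case) + sum(gc0$control), 0)
  expect_error(genotype_counts(d, "nope"), "not in dataset")
})

test_that("VCF import equals delimited import of the same genotype matrix", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "15\t100\trs1\tC\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "15\t900\trs2\tA\tG\t.\tPASS\t.\tGT\t0/1\t./.\t0/0"), vcf)
  ph <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\ttc",
               "s1\tcase\t5.1", "s2\tcase\t4.0", "s3\tcontrol\t6.2"), ph)
  dv <- read_cohort(vcf, format = "vcf", phenotype = ph)
  expect_identical(dv$subjects$rs1, c(0L, 1L, 2L))
  expect_identical(dv$subjects$rs2, c(1L, NA, 0L))
  expect_equal(dv$snps$allele_counted, c("T", "G"))

  del <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#snp id=rs1 alleles=C/T counted=T chrom=15 pos=100",
               "#snp id=rs2 alleles=A/G counted=G chrom=15 pos=900",
               "subject_id\tstatus\ttc\trs1\trs2",
               "s1\tcase\t5.1\tC/C\tA/G",
               "s2\tcase\t4.0\tC/T\tNA",
               "s3\tcontrol\t6.2\tT/T\tA/A"), del)
  dd <- read_cohort(del)
  expect_identical(dv$subjects[c("rs1", "rs2")], dd$subjects[c("rs1", "rs2")])
})

test_that("multi-allelic VCF records are rejected with record context", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "15\t100\trs1\tC\tT,G\t.\tPASS\t.\tGT\t0/1"), vcf)
  ph <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus", "s1\tcase"), ph)
  expect_error(read_cohort(vcf, format = "vcf", phenotype = ph),
               "non-biallelic.*15:100", perl = TRUE)
})
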