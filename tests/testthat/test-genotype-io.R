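# Genotype containers, readers, encoding, filtering and imputation.

test_that("TSV round-trip is value-identical including the missing mask", {
  fx <- make_tsv_fixture()
  gm <- read_genotypes(fx$path, format = "tsv")
  expect_equal(dim(gm), c(3L, 4L))
  expect_identical(gm$values, fx$gm$values)
  expect_identical(gm$missing, fx$gm$missing)
  expect_identical(gm$sample_ids, fx$gm$sample_ids)
  # second round trip
  p2 <- tempfile(fileext = ".tsv")
  write_genotypes(gm, p2)
  expect_identical(readLines(p2), readLines(fx$path))
})

test_that("genotype_matrix validates codes, shapes and identifiers", {
  expect_error(genotype_matrix(matrix(c(0, 1, 3, 2), 2)), "0, 1 or 2")
  expect_error(genotype_matrix(matrix(0:1, 1, 2)), "at least 2")
  expect_error(genotype_matrix(matrix(rep(1, 4), 2), sample_ids = c("a", "a")),
               "unique")
  expect_warning(genotype_matrix(matrix(rep(c(0, 1, 2), 4), 4, 3)), "m << n")
})

test_that("VCF parsing maps GT to minor-allele dosage and skips non-SNP records", {
  gm <- read_genotypes(make_vcf_fixture(), format = "vcf")
  expect_equal(attr(gm, "skipped"), 1)          # the indel
  expect_equal(dim(gm), c(3L, 4L))
  # rs1: ALT G ties REF A 3:3 -> minor is lexicographic "A" -> flipped
  expect_equal(unname(gm$values[, "rs1"]), c(1, 0, 2))
  expect_true(gm$locus_meta$flipped[gm$locus_ids == "rs1"])
  # rs2: 0|0, 0/1, ./. -> ALT T is minor, dosages kept; half/full missing masked
  expect_equal(unname(gm$values[, "rs2"]), c(0, 1, NA))
  expect_true(gm$missing[3, "rs2"])
  # rs4: ALT C carried 5/6 -> major; codes flipped to count T
  expect_equal(unname(gm$values[, "rs4"]), c(0, 0, 1))
  # rs5: half call "0/." is missing
  expect_equal(unname(gm$values[, "rs5"]), c(NA, 0, 1))
})

test_that("traw parsing transposes, re-checks the COUNTED allele and flags flips", {
  gm <- read_genotypes(make_traw_fixture(), format = "traw")
  expect_equal(gm$sample_ids, c("s1", "s2", "s3"))
  expect_equal(unname(gm$values[, "snp1"]), c(0, 1, 2))   # tie: COUNTED=A minor
  expect_false(gm$locus_meta$flipped[1])
  expect_equal(unname(gm$values[, "snp2"]), c(0, 0, 1))   # COUNTED=T is major
  expect_true(gm$locus_meta$flipped[2])
  expect_equal(unname(gm$values[, "snp3"]), c(0, NA, 1))
})

test_that("minor allele is the cohort-rarer allele with lexicographic tie-break", {
  expect_equal(as.character(minor_allele(c(A = 150, G = 50))), "G")
  expect_equal(as.character(minor_allele(c(T = 10, C = 10))), "C")
  expect_true(attr(minor_allele(c(A = 10, G = 0)), "monomorphic"))
})

test_that("additive encoding conserves the minor-allele count", {
  set.seed(42)
  dosage <- matrix(rbinom(200, 2, runif(20, 0.1, 0.9)[rep(1:20, each = 10)]),
                   nrow = 10)
  enc <- encode_additive(dosage, counted = rep("A", 20), other = rep("G", 20))
  # sum of codes at each locus equals the total count of the minor allele
  cnt_counted <- colSums(dosage)
  n_tot <- 2 * nrow(dosage)
  expected <- ifelse(enc$flipped, n_tot - cnt_counted, cnt_counted)
  expect_equal(unname(colSums(enc$codes)), unname(expected))
  # every minor allele frequency is <= 0.5
  expect_true(all(colMeans(enc$codes) / 2 <= 0.5 + 1e-12))
})

test_that("Hardy-Weinberg chi-square matches hand-computed tables", {
  # (AA, Aa, aa) = (25, 50, 25): exact equilibrium
  G <- matrix(c(rep(0, 25), rep(1, 50), rep(2, 25)), ncol = 1)
  gm <- suppressWarnings(genotype_matrix(cbind(G, G),
                        sample_ids = paste0("s", 1:100),
                        locus_ids = c("a", "b")))
  hw <- hwe_test(gm)
  expect_equal(hw$chisq, c(0, 0))
  expect_equal(hw$p_value, c(1, 1))
  # (50, 0, 50): complete heterozygote deficit, chi-square = n = 100
  G2 <- matrix(c(rep(0, 50), rep(2, 50)), ncol = 1)
  gm2 <- suppressWarnings(genotype_matrix(cbind(G2, G2),
                         sample_ids = paste0("s", 1:100),
                         locus_ids = c("a", "b")))
  hw2 <- hwe_test(gm2)
  expect_equal(hw2$chisq, c(100, 100))
  expect_lt(hw2$p_value[1], 1e-20)
})

test_that("HWE p-values are uniform on equilibrium data", {
  set.seed(5)
  G <- matrix(rbinom(300 * 10000, 2, 0.3), 300, 10000)
  pv <- hwe_test(genotype_matrix(G))$p_value
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("locus filters apply in fixed order and account for every removal", {
  set.seed(21)
  n <- 200
  loci <- cbind(
    hwe_ok   = rbinom(n, 2, 0.3),
    hwe_ok2  = rbinom(n, 2, 0.4),
    mono     = rep(0, n),
    rare     = c(rep(1, 1), rep(0, n - 1)),            # MAF = 0.0025
    hwe_bad  = c(rep(0, n / 2), rep(2, n / 2)),        # no heterozygotes
    missing  = c(rep(NA, 150), rbinom(n - 150, 2, 0.4)))
  gm <- suppressWarnings(genotype_matrix(loci))
  res <- filter_loci(gm, maf_min = 0.01, hwe_alpha = 1e-6, missing_max = 0.1)
  rpt <- res$report
  expect_equal(rpt$n_input, 6)
  expect_equal(rpt$n_removed_missing, 1)
  expect_equal(rpt$n_removed_monomorphic, 1)
  expect_equal(rpt$n_removed_maf, 1)
  expect_equal(rpt$n_removed_hwe, 1)
  expect_equal(rpt$n_output, 2)
  expect_equal(res$genotypes$locus_ids, c("hwe_ok", "hwe_ok2"))
  expect_equal(rpt$n_input,
               rpt$n_output + rpt$n_removed_missing + rpt$n_removed_monomorphic +
                 rpt$n_removed_maf + rpt$n_removed_hwe)
  # disabling thresholds removes only monomorphic loci
  res0 <- filter_loci(gm, maf_min = 0, hwe_alpha = 0, missing_max = 1)
  expect_equal(res0$report$n_removed_monomorphic, 1)
  expect_equal(res0$report$n_output, 5)
  expect_error(filter_loci(suppressWarnings(
    genotype_matrix(cbind(rep(0, 10), rep(2, 10)))), 0, 0, 1),
    "no loci survive")
})

test_that("mean imputation fills by locus mean and preserves provenance", {
  gm <- suppressWarnings(genotype_matrix(matrix(c(0, 2, NA,
                                 1, 1, NA,
                                 0, 1, 2), nrow = 3),
                        sample_ids = c("a", "b", "c"),
                        locus_ids = c("x", "y", "z")))
  # locus x: (0,2,NA) -> 1; locus y: (1,1,NA)... (matrix is column-major)
  imp <- impute_missing(gm)
  expect_equal(unname(imp$values[3, "x"]), 1)      # mean of 0 and 2
  expect_true(imp$imputed)
  expect_identical(imp$missing, gm$missing)
  # untouched matrix returned unchanged
  full <- genotype_matrix(matrix(rep(c(0, 1, 2), 3), 3, 3))
  expect_identical(impute_missing(full), full)
  # fully missing locus is an error
  gm_bad <- suppressWarnings(genotype_matrix(matrix(c(0, 1, 2, NA, NA, NA), 3, 2)))
  expect_error(impute_missing(gm_bad), "filter")
})

test_that("label tables attach by sample id with header auto-detection", {
  p <- tempfile()
  writeLines(c("sample_id\tpopulation", "s1\tCEU", "s2\tYRI", "s3\tCEU"), p)
  lab <- read_labels(p)
  expect_equal(unname(lab["s2"]), "YRI")
  p2 <- tempfile()
  writeLines(c("s1\tCEU", "s2\tYRI", "s3\tCEU"), p2)   # headerless
  expect_equal(read_labels(p2), lab)
  fx <- make_tsv_fixture()
  gm <- read_genotypes(fx$path, labels = p)
  expect_equal(gm$population, c("CEU", "YRI", "CEU"))
})
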