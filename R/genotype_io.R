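# Reading, encoding, filtering and imputing SNP genotype matrices.
# The in-memory model is `genotype_matrix`: samples as rows, loci as columns,
# additive minor-allele codes {0, 1, 2} with an explicit missingness mask.

#' Construct a genotype matrix
#'
#' Container for additively encoded SNP genotypes: an `m x n` matrix of
#' minor-allele counts (`m` samples, `n` loci), a missingness mask, sample
#' and locus identifiers, optional per-locus metadata (chromosome, 1-based
#' position, major/minor alleles) and optional per-sample population labels.
#'
#' @param values Numeric `m x n` matrix; non-missing entries must be in
#'   `{0, 1, 2}` unless `imputed = TRUE` (imputation makes entries real).
#'   `NA` entries are taken as missing.
#' @param sample_ids,locus_ids Unique identifier vectors (defaults taken
#'   from dimnames, or generated).
#' @param locus_meta Optional data.frame of per-locus records.
#' @param population Optional character vector of per-sample labels.
#' @param imputed Logical; `TRUE` after mean imputation.
#' @return An object of class `genotype_matrix` with elements `values`,
#'   `missing` (logical mask), `sample_ids`, `locus_ids`, `locus_meta`,
#'   `population`, `imputed`.
#' @export
genotype_matrix <- function(values, sample_ids = NULL, locus_ids = NULL,
                            locus_meta = NULL, population = NULL,
                            imputed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  m <- nrow(values); n <- ncol(values)
  if (m < 2 || n < 2) stop("need at least 2 samples and 2 loci")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%0*d", nchar(m), seq_len(m))
  if (is.null(locus_ids)) locus_ids <- colnames(values)
  if (is.null(locus_ids)) locus_ids <- sprintf("locus%0*d", nchar(n), seq_len(n))
  sample_ids <- as.character(sample_ids); locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != m || length(locus_ids) != n)
    stop("identifier length does not match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("sample IDs must be unique")
  if (anyDuplicated(locus_ids)) stop("locus IDs must be unique")
  dimnames(values) <- list(sample_ids, locus_ids)
  miss <- is.na(values)
  ok <- values[!miss]
  if (!imputed && length(ok) && !all(ok %in% c(0, 1, 2)))
    stop("non-missing genotype codes must be 0, 1 or 2")
  if (!is.null(population)) {
    population <- as.character(population)
    if (length(population) != m) stop("population labels must match sample count")
  }
  if (m > n)
    warning("more samples than loci (m > n); the method expects m << n",
            call. = FALSE)
  structure(list(values = values, missing = miss, sample_ids = sample_ids,
                 locus_ids = locus_ids, locus_meta = locus_meta,
                 population = population, imputed = imputed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.2f%% missing%s%s)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$missing),
              if (x$imputed) ", mean-imputed" else "",
              if (!is.null(x$population))
                sprintf("; %d populations", length(unique(x$population))) else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Determine the minor allele from allele tallies
#'
#' The minor allele is the rarer of the two alleles in the loaded cohort;
#' exact ties are broken toward the lexicographically smaller allele label,
#' so the encoding is deterministic.
#'
#' @param counts Named numeric vector of length 2: observed haploid counts
#'   per allele label.
#' @return The minor allele label (character scalar); attribute
#'   `"monomorphic"` is `TRUE` when one count is zero.
#' @export
#' @examples
#' minor_allele(c(A = 150, G = 50))   # "G"
#' minor_allele(c(T = 10, C = 10))    # "C" (tie -> lexicographic)
minor_allele <- function(counts) {
  if (length(counts) != 2 || is.null(names(counts)))
    stop("counts must be a named vector of two allele tallies")
  o <- order(counts, names(counts))  # rarest first; ties by label
  structure(names(counts)[o[1]], monomorphic = any(counts == 0))
}

#' Re-encode a dosage matrix to minor-allele counts
#'
#' Given genotypes expressed as counts of a designated allele per locus
#' (e.g. the VCF ALT allele or the PLINK COUNTED allele), determines the
#' cohort minor allele at each locus and flips codes (`2 - x`) wherever the
#' counted allele is in fact the major one.
#'
#' @param dosage `m x n` matrix of counts (0/1/2, `NA` missing) of
#'   `counted` at each locus.
#' @param counted,other Character vectors (length `n`) of allele labels;
#'   `counted` is the allele the input dosages count.
#' @return List with `codes` (minor-allele counts), `minor`, `major`,
#'   `flipped` (logical, per locus) and `monomorphic` (logical, per locus).
#' @export
encode_additive <- function(dosage, counted, other) {
  dosage <- as.matrix(dosage)
  n <- ncol(dosage)
  if (length(counted) != n || length(other) != n)
    stop("allele label vectors must match locus count")
  nonmiss <- colSums(!is.na(dosage))
  cnt_counted <- colSums(dosage, na.rm = TRUE)
  cnt_other <- 2 * nonmiss - cnt_counted
  minor <- character(n); flipped <- logical(n); mono <- logical(n)
  for (j in seq_len(n)) {
    tall <- setNames(c(cnt_counted[j], cnt_other[j]),
                     c(counted[j], other[j]))
    ma <- minor_allele(tall)
    minor[j] <- ma
    mono[j] <- attr(ma, "monomorphic")
    flipped[j] <- !identical(as.character(ma), as.character(counted[j]))
  }
  codes <- dosage
  if (any(flipped)) codes[, flipped] <- 2 - codes[, flipped, drop = FALSE]
  major <- ifelse(minor == counted, other, counted)
  list(codes = codes, minor = minor, major = major,
       flipped = flipped, monomorphic = mono)
}

#' Read genotypes from TSV, VCF or PLINK traw
#'
#' All three dialects are loaded into the same [genotype_matrix()] model.
#'
#' * `tsv`: header row of locus IDs, first column the sample ID, cells in
#'   `{0, 1, 2, NA}` (codes are taken as already minor-allele oriented).
#' * `vcf`: VCF v4.x; only biallelic SNP records (single-base REF and ALT)
#'   are used, others are skipped and counted in attribute `"skipped"` of the
#'   result.  Diploid GT fields are parsed with either `/` or `|`
#'   separators; any half or full missing call (`./.`, `0/.` ...) is masked.
#'   ALT dosages are re-oriented to the cohort minor allele via
#'   [encode_additive()].
#' * `traw`: PLINK transposed raw; the six leading columns
#'   (CHR, SNP, (C)M, POS, COUNTED, ALT) are recognised, loci are rows and
#'   are transposed to sample-major orientation.  COUNTED-allele dosages are
#'   re-checked against the cohort minor allele and flipped where needed
#'   (flips recorded in `locus_meta$flipped`).
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"vcf"`, `"traw"`.
#' @param labels Optional path to a two-column sample/population table (see
#'   [read_labels()]).
#' @return A [genotype_matrix()].  All-missing samples or loci are retained
#'   but reported via a warning.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf", "traw"),
                           labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  gm <- switch(format,
    tsv = .read_tsv_genotypes(path),
    vcf = .read_vcf_genotypes(path),
    traw = .read_traw_genotypes(path))
  empty_s <- rowSums(!gm$missing) == 0
  empty_l <- colSums(!gm$missing) == 0
  if (any(empty_s))
    warning(sum(empty_s), " sample(s) entirely missing: ",
            paste(head(gm$sample_ids[empty_s]), collapse = ", "), call. = FALSE)
  if (any(empty_l))
    warning(sum(empty_l), " locus/loci entirely missing", call. = FALSE)
  if (!is.null(labels)) gm <- attach_labels(gm, read_labels(labels))
  gm
}

.read_tsv_genotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(dt) < 3) stop("TSV genotype table needs a sample-ID column and >= 2 loci")
  ids <- as.character(dt[[1]])
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  bad <- !is.na(vals) & !(vals %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(rowSums(bad) > 0)[1]
    stop("invalid genotype code(s) at data line ", idx, " of ", path)
  }
  genotype_matrix(vals, sample_ids = ids, locus_ids = colnames(dt)[-1])
}

.read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!biallelic_snp)
  if (!any(biallelic_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic_snp, , drop = FALSE]
  fix <- fix[biallelic_snp, , drop = FALSE]
  # dosage of the ALT allele; any "." haplotype masks the call
  dose <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(a == "1")
    }, 0)
  }
  gt[is.na(gt)] <- "./."
  dosage <- t(apply(gt, 1, dose))          # loci x samples
  dosage <- t(dosage)                      # samples x loci
  ids <- colnames(gt)
  loci <- fix[, "ID"]
  loci[is.na(loci) | loci == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(loci) | loci == "."]
  enc <- encode_additive(dosage, counted = alt[biallelic_snp],
                         other = ref[biallelic_snp])
  meta <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = alt[biallelic_snp],
                     minor = enc$minor, major = enc$major,
                     flipped = enc$flipped, stringsAsFactors = FALSE)
  gm <- genotype_matrix(enc$codes, sample_ids = ids, locus_ids = loci,
                        locus_meta = meta)
  attr(gm, "skipped") <- n_skipped
  gm
}

.read_traw_genotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  need <- c("CHR", "SNP", "POS", "COUNTED", "ALT")
  if (!all(need %in% colnames(dt)))
    stop("not a PLINK traw table (missing ", paste(setdiff(need, colnames(dt)), collapse = ", "), ")")
  lead <- which(colnames(dt) %in% c(need, "(C)M", "CM"))
  samp_cols <- setdiff(seq_len(ncol(dt)), lead)
  dosage <- t(as.matrix(dt[, samp_cols, drop = FALSE]))  # samples x loci
  storage.mode(dosage) <- "double"
  enc <- encode_additive(dosage, counted = as.character(dt$COUNTED),
                         other = as.character(dt$ALT))
  meta <- data.frame(chrom = dt$CHR, pos = dt$POS,
                     counted = dt$COUNTED, alt = dt$ALT,
                     minor = enc$minor, major = enc$major,
                     flipped = enc$flipped, stringsAsFactors = FALSE)
  genotype_matrix(enc$codes, sample_ids = colnames(dt)[samp_cols],
                  locus_ids = as.character(dt$SNP), locus_meta = meta)
}

#' Write a genotype matrix as TSV
#'
#' The package's plain-text dialect: header of locus IDs, first column
#' `sample_id`, cells in `{0, 1, 2, NA}`.  Reading it back with
#' [read_genotypes()] is value-identical, including the missingness mask.
#'
#' @param gm A [genotype_matrix()] (unimputed).
#' @param path Output file.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (gm$imputed) stop("write the unimputed matrix; imputed values are not codes")
  df <- data.frame(sample_id = gm$sample_ids,
                   gm$values, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a sample-to-population label table
#'
#' Two-column delimited table (sample ID, population).  A header row is
#' auto-detected: if the first row matches common header names
#' (`sample`/`sample_id`/`id`, `population`/`pop`/`label`) it is dropped.
#'
#' @param path Input file.
#' @return Named character vector of populations, names are sample IDs.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(dt) < 2) stop("labels file needs two columns (sample, population)")
  first <- tolower(as.character(unlist(dt[1, 1:2])))
  if (first[1] %in% c("sample", "sample_id", "id", "iid") ||
      first[2] %in% c("population", "pop", "label", "group"))
    dt <- dt[-1, , drop = FALSE]
  setNames(as.character(dt[[2]]), as.character(dt[[1]]))
}

#' Attach population labels to a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param labels Named character vector as returned by [read_labels()].
#' @return The genotype matrix with `population` filled (NA for samples
#'   absent from the table, with a warning).
#' @export
attach_labels <- function(gm, labels) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pop <- unname(labels[gm$sample_ids])
  if (anyNA(pop))
    warning(sum(is.na(pop)), " sample(s) without a population label", call. = FALSE)
  gm$population <- pop
  gm
}

#' Hardy-Weinberg chi-square test per locus
#'
#' Pearson chi-square with 1 degree of freedom (no continuity correction)
#' comparing observed genotype counts at each locus with the
#' Hardy-Weinberg expectations `(1-p)^2, 2p(1-p), p^2` at the observed
#' minor-allele frequency.
#'
#' @param gm A [genotype_matrix()] (unimputed).
#' @return Data frame with columns `chisq`, `p_value`, `maf`, `n` per locus.
#' @export
hwe_test <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (gm$imputed) stop("Hardy-Weinberg test needs raw genotype codes")
  v <- gm$values
  n0 <- colSums(v == 0, na.rm = TRUE)
  n1 <- colSums(v == 1, na.rm = TRUE)
  n2 <- colSums(v == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)          # minor-allele frequency
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chisq <- numeric(length(n))
  for (j in seq_along(n)) {
    obs <- c(n0[j], n1[j], n2[j]); ex <- c(e0[j], e1[j], e2[j])
    keep <- ex > 0
    chisq[j] <- sum((obs[keep] - ex[keep])^2 / ex[keep])
  }
  data.frame(locus = gm$locus_ids, chisq = chisq,
             p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
             maf = pmin(p, 1 - p), n = n, row.names = NULL)
}

#' Filter loci by missingness, monomorphism, MAF and Hardy-Weinberg
#'
#' Removal rules are applied in a fixed order so report counts are
#' reproducible, each locus counted once under the first rule it fails:
#' missing fraction above `missing_max`, then monomorphic loci, then
#' minor-allele frequency below `maf_min`, then Hardy-Weinberg chi-square
#' p-value below `hwe_alpha`.
#'
#' @param gm A [genotype_matrix()] (unimputed).
#' @param maf_min Minimum minor-allele frequency, in `[0, 0.5]`.
#' @param hwe_alpha Remove loci with HWE p-value below this; `0` disables.
#' @param missing_max Maximum tolerated missing fraction per locus.
#' @return List with `genotypes` (the filtered matrix) and `report`
#'   (class `filter_report`: input/output counts, per-rule removals,
#'   thresholds).  An empty result is an error.
#' @export
filter_loci <- function(gm, maf_min = 0.01, hwe_alpha = 1e-6,
                        missing_max = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (gm$imputed) stop("filter before imputation")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (hwe_alpha < 0 || hwe_alpha > 1) stop("hwe_alpha must be in [0, 1]")
  if (missing_max < 0 || missing_max > 1) stop("missing_max must be in [0, 1]")
  n_in <- ncol(gm$values)
  alive <- rep(TRUE, n_in)

  miss_frac <- colMeans(gm$missing)
  fail_miss <- alive & miss_frac > missing_max
  alive <- alive & !fail_miss

  hw <- hwe_test(gm)
  mono <- alive & (hw$maf == 0 | hw$n == 0)
  alive <- alive & !mono

  fail_maf <- alive & hw$maf < maf_min
  alive <- alive & !fail_maf

  fail_hwe <- alive & hwe_alpha > 0 & hw$p_value < hwe_alpha
  alive <- alive & !fail_hwe

  if (!any(alive)) stop("no loci survive filters")
  # the m >> n advisory was already raised (if due) when gm was built
  out <- withCallingHandlers(
    genotype_matrix(gm$values[, alive, drop = FALSE],
                         sample_ids = gm$sample_ids,
                         locus_ids = gm$locus_ids[alive],
                         locus_meta = if (!is.null(gm$locus_meta))
                           gm$locus_meta[alive, , drop = FALSE] else NULL,
                         population = gm$population),
    warning = function(w) {
      if (grepl("m << n", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  report <- structure(list(
    n_input = n_in, n_output = sum(alive),
    n_removed_missing = sum(fail_miss),
    n_removed_monomorphic = sum(mono),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    thresholds = c(maf_min = maf_min, hwe_alpha = hwe_alpha,
                   missing_max = missing_max)), class = "filter_report")
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("locus filter: %d in -> %d out\n",
                     "  removed: %d missingness, %d monomorphic, %d MAF, %d HWE\n",
                     "  thresholds: maf_min=%g, hwe_alpha=%g, missing_max=%g\n"),
              x$n_input, x$n_output, x$n_removed_missing,
              x$n_removed_monomorphic, x$n_removed_maf, x$n_removed_hwe,
              x$thresholds["maf_min"], x$thresholds["hwe_alpha"],
              x$thresholds["missing_max"]))
  invisible(x)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing entry by the locus mean over non-missing samples
#' (entries become real-valued); the original missingness mask is kept for
#' provenance.  A matrix with no missing entries is returned unchanged.
#'
#' @param gm A [genotype_matrix()].
#' @return The imputed genotype matrix (`imputed = TRUE` when any entry was
#'   filled).
#' @export
impute_missing <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!any(gm$missing)) return(gm)
  if (any(colSums(!gm$missing) == 0))
    stop("fully-missing locus; filter loci before imputing")
  v <- gm$values
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(gm$missing, arr.ind = TRUE)
  v[idx] <- mu[idx[, 2]]
  out <- genotype_matrix(v, sample_ids = gm$sample_ids,
                         locus_ids = gm$locus_ids, locus_meta = gm$locus_meta,
                         population = gm$population, imputed = TRUE)
  out$missing <- gm$missing
  out
}
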