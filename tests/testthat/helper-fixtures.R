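# Fixture builders: small genotype files written programmatically.

make_tsv_fixture <- function(path = tempfile(fileext = ".tsv")) {
  gm <- genotype_matrix(
    matrix(c(0, 1, 2, NA,
             2, 1, 0, 1,
             1, NA, 2, 0), nrow = 3, byrow = TRUE),
    sample_ids = c("s1", "s2", "s3"),
    locus_ids = c("l1", "l2", "l3", "l4"))
  write_genotypes(gm, path)
  list(gm = gm, path = path)
}

make_vcf_fixture <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1/1", "0/0"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0|0", "0/1", "./."), collapse = "\t"),
    paste(c("1", "300", "rs3", "G", "GA", ".", "PASS", ".", "GT",
            "0/1", "0/0", "0/0"), collapse = "\t"),  # indel: skipped
    paste(c("1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
            "1/1", "1/1", "0/1"), collapse = "\t"),  # ALT is major: flipped
    paste(c("1", "500", "rs5", "A", "C", ".", "PASS", ".", "GT",
            "0/.", "0/0", "0/1"), collapse = "\t"))  # half call: missing
  writeLines(lines, path)
  path
}

make_traw_fixture <- function(path = tempfile(fileext = ".traw")) {
  lines <- c(
    paste(c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT",
            "s1", "s2", "s3"), collapse = "\t"),
    paste(c("1", "snp1", "0", "100", "A", "G", "0", "1", "2"), collapse = "\t"),
    paste(c("1", "snp2", "0", "200", "T", "C", "2", "2", "1"), collapse = "\t"),
    paste(c("1", "snp3", "0", "300", "G", "A", "0", "NA", "1"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Embedding with prescribed loadings on one axis (for separation tests):
# two clusters of loadings jittered around given centers.
make_loading_embedding <- function(centers, n_each = 20, lambda1 = 4,
                                   noise = 0.02, seed = 1) {
  set.seed(seed)
  U1 <- unlist(lapply(centers, function(m) m + rnorm(n_each, sd = noise)))
  U1 <- pmin(pmax(U1, -0.999), 0.999)
  m <- length(U1)
  U <- cbind(U1, rep(0.1, m))
  dec <- structure(list(
    U = U, singular_values = sqrt(c(lambda1, 1) * 999),
    Vt = NULL, eigenvalues = c(lambda1, 1),
    null_components = c(FALSE, FALSE), n_samples = m, n_loci = 1000,
    sample_ids = paste0("s", seq_len(m)),
    population = rep(paste0("grp", seq_along(centers)), each = n_each)),
    class = "pca_decomposition")
  make_embedding(dec, axes = c(1, 2))
}
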