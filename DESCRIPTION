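Package: mipca
Title: Mutual-Information Rescaling of Principal Component Maps for
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Principal component analysis for SNP genotype matrices with an
    information-theoretic rescaling of the resulting maps.  Correlation-based
    PC coordinates are transformed through the signed mutual-information
    function r(rho) = -sgn(rho) * log(1 - rho^2) / 2, so that distances along
    each axis are expressed in information units (nats or bits) while order
    relationships are preserved.  Includes a SmartPCA-style standardization
    and SVD engine, closed-form mutual information for the bivariate Gaussian
    and Student-t families, a Kraskov nearest-neighbour estimator, cluster
    separability diagnostics with the critical-correlation gate test, readers
    for delimited, VCF and PLINK traw genotype tables, and a Balding-Nichols
    population simulator for fully offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    ggplot2,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
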