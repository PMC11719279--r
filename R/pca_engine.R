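# SmartPCA-style standardization and SVD of the genotype matrix.
# Samples are rows; the m x m correlation matrix C = Z Z^T / (n - 1) is
# diagonalized through the thin SVD Z = U S V^T, and the loadings matrix of
# sample-component correlations satisfies M = cor(Z, P^T) = U exactly.

#' Row-standardize a genotype (or general feature) matrix
#'
#' Centers and scales so that `Z Z^T / (n - 1)` is a correlation matrix.
#' In the default `"row"` mode each sample row is centered by its ordinary
#' mean and divided by its sample standard deviation (denominator `n - 1`),
#' the convention under which the left singular vectors of `Z` are exactly
#' the sample-component correlations.  `"snp"` mode centers and scales per
#' column instead, for comparability with column-standardized runs of other
#' tools; the correlation identity between samples then no longer holds
#' exactly.
#'
#' @param x A mean-imputed [genotype_matrix()] or any numeric matrix with
#'   samples as rows (no missing values).
#' @param center_mode `"row"` (default) or `"snp"`.
#' @param strict Error on zero-variance rows instead of dropping them.
#' @return An object of class `standardized_genotypes`: `Z` (the
#'   standardized matrix), `row_means`, `row_sds`, `dropped_rows` (IDs of
#'   zero-variance rows), `center_mode`, `population`.
#' @export
#' @examples
#' standardize_genotypes(rbind(a = c(0, 1, 2), b = c(2, 1, 0)))
standardize_genotypes <- function(x, center_mode = c("row", "snp"),
                                  strict = FALSE) {
  center_mode <- match.arg(center_mode)
  pop <- NULL
  if (inherits(x, "genotype_matrix")) {
    if (any(is.na(x$values)))
      stop("missing entries present; impute_missing() first")
    pop <- x$population
    g <- x$values
  } else {
    g <- as.matrix(x)
    if (anyNA(g)) stop("missing entries present")
  }
  if (is.null(rownames(g))) rownames(g) <- paste0("s", seq_len(nrow(g)))
  if (center_mode == "snp") {
    sds <- apply(g, 2, sd)
    keep <- sds > 0
    Z <- scale(g[, keep, drop = FALSE])
    attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
    return(structure(list(Z = unclass(Z), row_means = rowMeans(g),
                          row_sds = apply(g, 1, sd),
                          dropped_rows = character(0),
                          center_mode = center_mode, population = pop),
                     class = "standardized_genotypes"))
  }
  mu <- rowMeans(g)
  sds <- apply(g, 1, sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    if (strict) stop("zero-variance sample row(s): ",
                     paste(rownames(g)[zero], collapse = ", "))
    warning("dropping ", sum(zero), " zero-variance sample row(s)",
            call. = FALSE)
  }
  keep <- !zero
  Z <- (g[keep, , drop = FALSE] - mu[keep]) / sds[keep]
  structure(list(Z = Z, row_means = mu[keep], row_sds = sds[keep],
                 dropped_rows = rownames(g)[zero],
                 center_mode = center_mode,
                 population = if (!is.null(pop)) pop[keep] else NULL),
            class = "standardized_genotypes")
}

#' @export
print.standardized_genotypes <- function(x, ...) {
  cat(sprintf("standardized_genotypes: %d x %d (%s-centered, %d dropped)\n",
              nrow(x$Z), ncol(x$Z), x$center_mode, length(x$dropped_rows)))
  invisible(x)
}

.get_Z <- function(x) {
  if (inherits(x, "standardized_genotypes")) x$Z
  else stop("expected a standardized_genotypes object; run standardize_genotypes()")
}

#' Sample-sample correlation matrix
#'
#' `C = Z Z^T / (n - 1)`: symmetric, positive semi-definite, unit diagonal,
#' with entries the pairwise Pearson correlations between sample rows.
#'
#' @param z A `standardized_genotypes` object (row mode).
#' @return The `m x m` correlation matrix.
#' @export
correlation_matrix <- function(z) {
  Z <- .get_Z(z)
  tcrossprod(Z) / (ncol(Z) - 1)
}

#' SVD-based principal component decomposition
#'
#' Thin singular value decomposition `Z = U S V^T` of the standardized
#' matrix, with eigenvalues of the correlation matrix
#' `lambda_j = S_j^2 / (n - 1)` (so `sum(lambda) = m` at full rank).  The
#' sign of each `U` column is fixed so its largest-magnitude entry is
#' positive, making maps reproducible across SVD implementations.
#' Components with `lambda < 1e-12 * lambda_1` are flagged null; their
#' correlations are undefined and treated as zero downstream.
#'
#' @param z A `standardized_genotypes` object.
#' @param k Number of components, or `"full"` for `min(m, n)`.
#' @return An object of class `pca_decomposition`: `U` (`m x r`
#'   orthonormal), `singular_values`, `Vt` (`r-by-n`, half-orthonormal rows),
#'   `eigenvalues`, `null_components` (logical), `n_samples`, `n_loci`,
#'   `sample_ids`, `population`.
#' @export
pca_decompose <- function(z, k = "full") {
  Z <- .get_Z(z)
  m <- nrow(Z); n <- ncol(Z)
  r_max <- min(m, n)
  if (identical(k, "full")) k <- r_max
  k <- as.integer(k)
  if (k < 1 || k > r_max) stop("k must be in [1, min(m, n)] = [1, ", r_max, "]")
  sv <- svd(Z, nu = k, nv = k)
  U <- sv$u; d <- sv$d[seq_len(k)]
  Vt <- t(sv$v)
  # deterministic sign: largest-|entry| of each loading column positive
  for (j in seq_len(k)) {
    s <- sign(U[which.max(abs(U[, j])), j])
    if (s < 0) { U[, j] <- -U[, j]; Vt[j, ] <- -Vt[j, ] }
  }
  lambda <- d^2 / (n - 1)
  rownames(U) <- rownames(Z)
  structure(list(U = U, singular_values = d, Vt = Vt, eigenvalues = lambda,
                 null_components = lambda < 1e-12 * lambda[1],
                 n_samples = m, n_loci = n, sample_ids = rownames(Z),
                 population = z$population),
            class = "pca_decomposition")
}

#' @export
print.pca_decomposition <- function(x, ...) {
  cat(sprintf("pca_decomposition: %d samples, %d loci, %d components\n",
              x$n_samples, x$n_loci, length(x$eigenvalues)))
  ve <- x$eigenvalues / x$n_samples
  k <- min(5, length(ve))
  cat("  lambda:", paste(sprintf("%.4g", x$eigenvalues[seq_len(k)]), collapse = ", "),
      if (length(ve) > k) "..." else "", "\n")
  invisible(x)
}

#' Component score rows P = U^T Z
#'
#' The mutually orthogonal principal component rows (`r-by-n`); their
#' covariance matrix is diagonal.
#'
#' @param decomp A `pca_decomposition`.
#' @param z The `standardized_genotypes` it came from.
#' @return `r-by-n` matrix of component scores.
#' @export
component_scores <- function(decomp, z) {
  Z <- .get_Z(z)
  if (ncol(Z) != decomp$n_loci || nrow(Z) != decomp$n_samples)
    stop("decomposition does not match the standardized matrix")
  crossprod(decomp$U, Z)
}

#' Sample-component correlation loadings (M = U)
#'
#' Computes the loadings matrix
#' `M = cor(Z, P^T) = [cov(Z, Z^T)]^{-1/2} cov(Z, P^T) [cov(P, P^T)]^{-1/2}`
#' directly from `Z` and the component rows `P = U^T Z` — the whitened
#' cross-covariance between samples and components, i.e. the correlation
#' matrix in its matrix normalization — and verifies the analytic identity
#' `M = U` to the stated tolerance.  (The entrywise Pearson correlation of
#' sample row `i` with component row `j` is `sqrt(lambda_j) * U_ij`; the
#' whitened normalization removes the `sqrt(lambda_j)` factor, which is
#' what makes the loadings a common correlation scale across axes.)  The
#' returned entries lie in `[-1, 1]` and are the values the information
#' rescaling acts on.  Null components (zero eigenvalue) have undefined
#' correlations; their column is set to 0 and flagged in attribute
#' `"null_components"`.
#'
#' The inverse square root of `cov(Z, Z^T)` is taken by an eigendecomposition
#' independent of the SVD path, so the check exercises the whole
#' normalization chain.
#'
#' @param decomp A `pca_decomposition`.
#' @param z The matching `standardized_genotypes`.
#' @param tol Verification tolerance for `max |M - U|`.
#' @return `m x r` loadings matrix with attribute `null_components`.
#' @export
correlation_loadings <- function(decomp, z, tol = 1e-8) {
  Z <- .get_Z(z)
  P <- component_scores(decomp, z)
  n1 <- ncol(Z) - 1
  C <- tcrossprod(Z) / n1                     # cov(Z, Z^T)
  eC <- eigen(C, symmetric = TRUE)
  pos <- eC$values > 1e-12 * eC$values[1]
  # pseudo inverse square root on the positive eigenspace
  Cinv_sqrt <- eC$vectors[, pos, drop = FALSE] %*%
    (t(eC$vectors[, pos, drop = FALSE]) / sqrt(eC$values[pos]))
  covZP <- tcrossprod(Z, P) / n1              # cov(Z, P^T), m x r
  dP <- diag(tcrossprod(P) / n1)              # cov(P, P^T) is diagonal
  nullc <- decomp$null_components
  M <- matrix(0, nrow(Z), nrow(P), dimnames = list(rownames(Z), NULL))
  ok <- !nullc & dP > 0
  M[, ok] <- (Cinv_sqrt %*% covZP[, ok, drop = FALSE]) %*%
    diag(1 / sqrt(dP[ok]), sum(ok))
  dev <- max(abs(M[, ok, drop = FALSE] - decomp$U[, ok, drop = FALSE]))
  if (dev > tol)
    stop(sprintf("internal consistency failure: max|cor(Z, P^T) - U| = %.3g > %g (normalization bug)",
                 dev, tol))
  attr(M, "null_components") <- nullc
  M
}

#' Conventional PC map coordinates
#'
#' Coordinate of sample `i` on axis `j` is `U_ij * sqrt(lambda_j)` — the
#' correlation with the component weighted by the axis scale (the standard
#' PC score up to the `n - 1` convention).  `scale = "singular"` gives the
#' `S`-scaled variant `U_ij * S_j` instead.
#'
#' @param decomp A `pca_decomposition`.
#' @param axes Integer vector of distinct component indices.
#' @param scale `"sqrt_lambda"` (default) or `"singular"`.
#' @return `m x length(axes)` coordinate matrix (columns named `PC<j>`).
#' @export
pc_coordinates <- function(decomp, axes = c(1, 2),
                           scale = c("sqrt_lambda", "singular")) {
  scale <- match.arg(scale)
  axes <- as.integer(axes)
  if (anyDuplicated(axes)) stop("axes must be distinct")
  if (any(axes < 1 | axes > length(decomp$eigenvalues)))
    stop("axis index out of range")
  w <- switch(scale,
              sqrt_lambda = sqrt(decomp$eigenvalues[axes]),
              singular = decomp$singular_values[axes])
  w[decomp$null_components[axes]] <- 0
  out <- decomp$U[, axes, drop = FALSE] %*% diag(w, length(axes))
  dimnames(out) <- list(decomp$sample_ids, paste0("PC", axes))
  out
}

#' Eigenvalue / variance-explained report
#'
#' @param decomp A `pca_decomposition`.
#' @param path Optional TSV output path.
#' @return Data frame with component index, eigenvalue, proportion of
#'   variance and cumulative proportion (total variance equals the number
#'   of samples under row standardization).
#' @export
eigenvalue_report <- function(decomp, path = NULL) {
  lam <- decomp$eigenvalues
  df <- data.frame(component = seq_along(lam), lambda = lam,
                   proportion = lam / decomp$n_samples,
                   cumulative = cumsum(lam) / decomp$n_samples)
  if (!is.null(path))
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  df
}
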