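# Standardization, the SVD engine and the M = U identity.

test_that("row standardization reproduces the 2x3 hand example", {
  G <- rbind(a = c(0, 1, 2), b = c(2, 1, 0))
  z <- standardize_genotypes(G)
  expect_equal(unname(z$Z), rbind(c(-1, 0, 1), c(1, 0, -1)))
  expect_equal(unname(z$row_means), c(1, 1))
  expect_equal(unname(z$row_sds), c(1, 1))
  C <- correlation_matrix(z)
  expect_equal(unname(C), rbind(c(1, -1), c(-1, 1)))
})

test_that("every retained standardized row has mean 0 and sd 1", {
  set.seed(13)
  G <- matrix(rbinom(30 * 400, 2, 0.3), 30, 400)
  z <- standardize_genotypes(genotype_matrix(G))
  expect_lt(max(abs(rowMeans(z$Z))), 1e-12)
  expect_lt(max(abs(apply(z$Z, 1, sd) - 1)), 1e-10)
  C <- correlation_matrix(z)
  expect_equal(unname(diag(C)), rep(1, nrow(C)))
  expect_true(all(abs(C) <= 1 + 1e-12))
  expect_equal(C, t(C))
})

test_that("constant rows are dropped (or rejected in strict mode)", {
  G <- rbind(a = c(0, 1, 2, 1), b = c(2, 1, 0, 1), c = c(1, 1, 1, 1))
  expect_warning(z <- standardize_genotypes(G), "zero-variance")
  expect_equal(z$dropped_rows, "c")
  expect_equal(nrow(z$Z), 2)
  expect_error(standardize_genotypes(G, strict = TRUE), "zero-variance")
})

test_that("correlation matrix equals brute-force pairwise Pearson correlations", {
  set.seed(3)
  G <- matrix(rnorm(6 * 200), 6, 200)
  z <- standardize_genotypes(G)
  C <- correlation_matrix(z)
  expect_equal(unname(C), unname(cor(t(G))), tolerance = 1e-12)
})

test_that("the 2x3 example has eigenvalues {2, 0} and a single nonzero singular value", {
  z <- standardize_genotypes(rbind(c(0, 1, 2), c(2, 1, 0)))
  dec <- pca_decompose(z, k = "full")
  expect_equal(dec$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(dec$null_components, c(FALSE, TRUE))
  expect_equal(abs(unname(dec$U[, 1])), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("SVD path matches the eigendecomposition oracle and reconstructs Z", {
  set.seed(17)
  sizes <- list(c(8, 60), c(20, 500), c(50, 2000))
  for (sz in sizes) {
    G <- matrix(rnorm(sz[1] * sz[2]), sz[1], sz[2])
    z <- standardize_genotypes(G)
    dec <- pca_decompose(z, k = "full")
    ev <- eigen_oracle(z$Z)$values
    expect_equal(dec$eigenvalues, pmax(ev, 0), tolerance = 1e-8)
    # reconstruction
    Zr <- dec$U %*% diag(dec$singular_values) %*% dec$Vt
    expect_lt(norm(Zr - z$Z, "F") / norm(z$Z, "F"), 1e-8)
    # U orthonormal; V half-orthonormal with VtV far from identity (m << n)
    expect_equal(crossprod(dec$U), diag(sz[1]), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(tcrossprod(dec$Vt), diag(sz[1]), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # eigen-equation C u = lambda u
    C <- correlation_matrix(z)
    expect_lt(max(abs(C %*% dec$U - dec$U %*% diag(dec$eigenvalues))), 1e-8)
    # trace identity: sum(lambda) = m at full rank
    expect_equal(sum(dec$eigenvalues), sz[1], tolerance = 1e-8)
  }
})

test_that("component score rows are orthogonal with diagonal covariance", {
  set.seed(23)
  z <- standardize_genotypes(matrix(rnorm(12 * 300), 12, 300))
  dec <- pca_decompose(z)
  P <- component_scores(dec, z)
  D <- tcrossprod(P) / (ncol(P) - 1)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-8)
  expect_equal(diag(D), dec$eigenvalues, tolerance = 1e-10)
})

test_that("whitened correlation loadings equal the left singular vectors", {
  set.seed(29)
  for (i in 1:3) {
    z <- standardize_genotypes(matrix(rnorm(20 * 500), 20, 500))
    dec <- pca_decompose(z)
    M <- correlation_loadings(dec, z)
    expect_lt(max(abs(M - dec$U)), 1e-8)
    expect_true(all(abs(M) <= 1 + 1e-10))
  }
  # 2x3 hand example: |M| entries are 1/sqrt(2) on the nonzero component,
  # zero on the null component
  z2 <- standardize_genotypes(rbind(c(0, 1, 2), c(2, 1, 0)))
  dec2 <- pca_decompose(z2)
  M2 <- correlation_loadings(dec2, z2)
  expect_equal(abs(unname(M2[, 1])), c(1, 1) / sqrt(2), tolerance = 1e-10)
  expect_equal(unname(M2[, 2]), c(0, 0))
  expect_true(attr(M2, "null_components")[2])
})

test_that("sample permutation permutes loadings rows identically", {
  set.seed(31)
  G <- matrix(rbinom(10 * 400, 2, 0.25), 10, 400,
              dimnames = list(paste0("s", 1:10), NULL))
  z1 <- standardize_genotypes(G)
  perm <- sample(10)
  z2 <- standardize_genotypes(G[perm, ])
  d1 <- pca_decompose(z1, k = 4)
  d2 <- pca_decompose(z2, k = 4)
  expect_equal(d2$eigenvalues, d1$eigenvalues, tolerance = 1e-10)
  expect_equal(unname(d2$U), unname(d1$U[perm, ]), tolerance = 1e-8)
})

test_that("conventional coordinates are U*sqrt(lambda), center at zero, and respect axis rules", {
  set.seed(37)
  z <- standardize_genotypes(matrix(rnorm(15 * 300), 15, 300))
  dec <- pca_decompose(z)
  xy <- pc_coordinates(dec, axes = c(1, 2))
  expect_equal(unname(xy),
               unname(dec$U[, 1:2] %*% diag(sqrt(dec$eigenvalues[1:2]))))
  # under snp (column) centering, scores sum to zero across samples
  zc <- standardize_genotypes(matrix(rnorm(15 * 300), 15, 300),
                              center_mode = "snp")
  xc <- pc_coordinates(pca_decompose(zc, k = 5), axes = c(1, 2))
  expect_lt(max(abs(colSums(xc))), 1e-8)
  # the S-scaled variant differs by exactly sqrt(n - 1)
  xs <- pc_coordinates(dec, axes = c(1, 2), scale = "singular")
  expect_equal(unname(xs), unname(xy * sqrt(ncol(z$Z) - 1)), tolerance = 1e-10)
  expect_error(pc_coordinates(dec, axes = c(1, 1)), "distinct")
  expect_error(pc_coordinates(dec, axes = c(1, 99)), "out of range")
  # zero-eigenvalue axis maps to the origin
  z2 <- standardize_genotypes(rbind(c(0, 1, 2), c(2, 1, 0)))
  d2 <- pca_decompose(z2)
  expect_equal(unname(pc_coordinates(d2, axes = 2)[, 1]), c(0, 0))
})

test_that("distinct principal components of Gaussian data share no mutual information", {
  set.seed(41)
  n <- 5000
  A <- matrix(c(1, 0.6, 0.3, 0.1,
                0, 1, 0.5, 0.2,
                0, 0, 1, 0.4,
                0, 0, 0, 1), 4, 4, byrow = TRUE)
  X <- A %*% matrix(rnorm(4 * n), 4, n)    # 4 correlated variables
  z <- standardize_genotypes(X)
  dec <- pca_decompose(z)
  P <- component_scores(dec, z)
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(empirical_mi(P[i, ], P[j, ]), 0.02)
})
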