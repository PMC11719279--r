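# Synthetic genotype data with known population structure (Balding-Nichols
# model), bivariate Gaussian/Student-t samplers for information-theoretic
# validation, a Hudson-type FST estimator and the segregating-sites
# harmonic-sum utility.

# Deterministic per-locus seed stream: locus subsets are reproducible
# regardless of how many loci are drawn in one call.
.locus_seed <- function(seed, locus) {
  as.integer((as.numeric(seed) * 1000003 + locus * 7919) %% 2147483647)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' For each locus an ancestral allele frequency `p` is drawn uniformly from
#' `ancestral_maf_range`; each population `k` then receives a frequency
#' `p_k ~ Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k)` — mean `p`,
#' variance `F_k p (1 - p)` — and diploid genotypes are Binomial(2, p_k)
#' counts of that allele.  `F` is interpretable as the fixation index FST
#' between each population and the ancestral pool.  Missingness is applied
#' uniformly at random.  One root seed drives deterministic per-locus
#' streams, so the first `L` loci of a longer simulation equal a shorter
#' simulation of `L` loci.
#'
#' @param n_pops Number of populations (>= 1).
#' @param n_per_pop Samples per population (recycled to `n_pops`).
#' @param n_loci Number of loci.
#' @param fst Per-population divergence in `(0, 1)` (recycled).
#' @param ancestral_maf_range Interval within `(0, 0.5]` for the ancestral
#'   allele frequency; default `c(0.05, 0.5)` mimics the common-variant
#'   spectrum of genotyping arrays.
#' @param missing_rate Probability an entry is masked, in `[0, 1)`.
#' @param seed Integer root seed.
#' @return A [genotype_matrix()] with population labels `pop1..popK`;
#'   attribute `"true_freqs"` holds the `n_pops x n_loci` per-population
#'   allele frequencies.
#' @export
#' @examples
#' gm <- simulate_balding_nichols(n_pops = 2, n_per_pop = 10, n_loci = 100,
#'                                fst = 0.1, seed = 1)
simulate_balding_nichols <- function(n_pops = 3, n_per_pop = 50,
                                     n_loci = 2000, fst = 0.1,
                                     ancestral_maf_range = c(0.05, 0.5),
                                     missing_rate = 0, seed = 1) {
  if (n_pops < 1) stop("n_pops must be >= 1")
  n_per_pop <- rep_len(n_per_pop, n_pops)
  if (any(n_per_pop < 1)) stop("n_per_pop must be positive")
  if (sum(n_per_pop) < 2) stop("need at least 2 samples in total")
  if (n_loci < 2) stop("need at least 2 loci")
  fst <- rep_len(fst, n_pops)
  if (any(fst <= 0 | fst >= 1)) stop("fst must lie in (0, 1)")
  r <- ancestral_maf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2])
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  m <- sum(n_per_pop)
  pop_of <- rep(paste0("pop", seq_len(n_pops)), n_per_pop)
  G <- matrix(NA_real_, m, n_loci)
  freqs <- matrix(NA_real_, n_pops, n_loci)
  a <- (1 - fst) / fst
  for (l in seq_len(n_loci)) {
    .with_seed(.locus_seed(seed, l), {
      p <- runif(1, r[1], r[2])
      pk <- rbeta(n_pops, p * a, (1 - p) * a)
      freqs[, l] <- pk
      g <- rbinom(m, size = 2, prob = rep(pk, n_per_pop))
      if (missing_rate > 0)
        g[runif(m) < missing_rate] <- NA_integer_
      G[, l] <- g
    })
  }
  gm <- genotype_matrix(G,
    sample_ids = paste0(pop_of, "_", unlist(lapply(n_per_pop, seq_len))),
    locus_ids = sprintf("L%0*d", nchar(n_loci), seq_len(n_loci)),
    population = pop_of)
  attr(gm, "true_freqs") <- freqs
  gm
}

#' Simulate a correlated bivariate Gaussian or Student-t sample
#'
#' Gaussian pairs come from the Cholesky factor of the 2x2 correlation
#' matrix; Student-t pairs divide a Gaussian pair by the same
#' `sqrt(chisq_alpha / alpha)` draw, giving the elliptical bivariate t with
#' tail parameter `alpha` and the same copula correlation structure.
#'
#' @param n Number of draws.
#' @param rho Correlation in `(-1, 1)`.
#' @param alpha `"gaussian"` (default) or a positive tail parameter.
#' @param seed Optional integer seed (the global RNG state is restored).
#' @return List with numeric vectors `x` and `y`.
#' @export
simulate_bivariate <- function(n, rho, alpha = "gaussian", seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (n < 1) stop("n must be positive")
  gauss <- identical(alpha, "gaussian")
  if (!gauss && (!is.numeric(alpha) || alpha <= 0))
    stop("alpha must be 'gaussian' or a positive number")
  draw <- function() {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    if (!gauss) {
      s <- sqrt(rchisq(n, df = alpha) / alpha)
      z1 <- z1 / s; z2 <- z2 / s
    }
    list(x = z1, y = z2)
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Hudson-type FST estimate from genotype data
#'
#' Ratio-of-averages Hudson estimator: per locus and population pair,
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`, with `p` the sample allele frequency
#' and `n` the number of sampled alleles; numerators and denominators are
#' summed over loci (and over pairs for more than two populations) before
#' the ratio is taken.
#'
#' @param gm A [genotype_matrix()] with population labels (or pass
#'   `labels`).
#' @param labels Optional per-sample label vector overriding
#'   `gm$population`.
#' @return The FST estimate (scalar).
#' @references Bhatia et al. (2013) Genome Research 23:1514-1521.
#' @export
hudson_fst <- function(gm, labels = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  lab <- if (!is.null(labels)) as.character(labels) else gm$population
  if (is.null(lab)) stop("population labels required")
  pops <- unique(lab)
  if (length(pops) < 2) stop("need at least two populations")
  v <- gm$values
  v[gm$missing] <- NA
  freq_n <- lapply(pops, function(p) {
    rows <- v[lab == p, , drop = FALSE]
    nal <- 2 * colSums(!is.na(rows))
    list(p = colSums(rows, na.rm = TRUE) / nal, n = nal)
  })
  num <- 0; den <- 0
  for (i in seq_along(pops)[-length(pops)]) for (j in seq((i + 1), length(pops))) {
    p1 <- freq_n[[i]]$p; n1 <- freq_n[[i]]$n
    p2 <- freq_n[[j]]$p; n2 <- freq_n[[j]]$n
    ok <- n1 >= 4 & n2 >= 4 & is.finite(p1) & is.finite(p2)
    nl <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    dl <- p1 * (1 - p2) + p2 * (1 - p1)
    num <- num + sum(nl[ok]); den <- den + sum(dl[ok])
  }
  if (den <= 0) stop("degenerate data: zero between-population heterozygosity")
  num / den
}

#' Expected number of segregating sites
#'
#' `4 * Ne * mu * sum_{k=1}^{N} 1/k`: the classical harmonic-sum scaling of
#' the expected count of polymorphic sites with effective population size
#' `Ne`, mutation rate `mu` and sample size `N`.  The sum runs over
#' `k = 1..N` exactly as stated (the common coalescent convention sums to
#' `N - 1`; at large `N` the two differ by `4*Ne*mu/N`).  Growth in `N` is
#' approximately logarithmic — the information-rescaled map separates
#' populations by surviving branching events, whose count scales the same
#' way.
#'
#' @param Ne Effective population size (> 0).
#' @param mu Per-site mutation rate (> 0).
#' @param N Sample size (positive integer).
#' @return Expected segregating-site count.
#' @export
#' @examples
#' expected_segregating_sites(1000, 1e-5, 10)
expected_segregating_sites <- function(Ne, mu, N) {
  if (Ne <= 0 || mu <= 0) stop("Ne and mu must be positive")
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("N must be a positive integer")
  4 * Ne * mu * sum(1 / seq_len(N))
}
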