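# Closed-form and empirical mutual information, and the signed rescaling
# function applied to every correlation-based map coordinate.

.clamp_rho <- function(rho, strict = FALSE, slack = 1e-10) {
  bad <- abs(rho) > 1 + slack
  if (any(bad, na.rm = TRUE))
    stop("correlation outside [-1, 1]: ", paste(head(rho[bad]), collapse = ", "))
  at_one <- abs(rho) >= 1 - 1e-12
  if (any(at_one, na.rm = TRUE)) {
    if (strict)
      stop("|rho| = 1 encountered in strict mode (infinite mutual information)")
    warning("|rho| >= 1 - 1e-12 clamped to finite value; ",
            "duplicated samples give rho = 1 and infinite information",
            call. = FALSE)
    rho[at_one] <- sign(rho[at_one]) * (1 - 1e-12)
  }
  rho
}

#' Mutual information of a bivariate Gaussian
#'
#' For a jointly Gaussian pair with correlation `rho` the mutual information
#' is `-log(1 - rho^2) / 2`.  It is even in `rho`, zero only at independence,
#' strictly increasing in `|rho|` and divergent as `|rho| -> 1`.
#'
#' @param rho Correlation(s) in `(-1, 1)`.  Values with `|rho| >= 1 - 1e-12`
#'   are clamped to `1 - 1e-12` with a warning unless `strict = TRUE`;
#'   `|rho| > 1` is always an error.
#' @param base Information unit, `"nats"` (default) or `"bits"`.
#' @param strict Raise an error instead of clamping at `|rho| = 1`.
#' @return Numeric vector of non-negative information values in `base`.
#' @seealso [signed_rescale()], [student_t_mi()], [empirical_mi()]
#' @export
#' @examples
#' gaussian_mi(0.5)           # 0.1438410 nats
#' gaussian_mi(0.5, "bits")
gaussian_mi <- function(rho, base = "nats", strict = FALSE) {
  base <- .check_base(base)
  rho <- .clamp_rho(rho, strict = strict)
  # log(1 - rho^2) = log1p(-rho) + log1p(rho), accurate near |rho| = 1
  mi <- -0.5 * (log1p(-rho) + log1p(rho))
  convert_information(mi, "nats", base)
}

#' Signed information rescaling of a correlation
#'
#' The map transform at the core of the package:
#' `r(rho) = -sgn(rho) * log(1 - rho^2) / 2`, i.e. the Gaussian mutual
#' information carrying the correlation's sign.  It is odd, fixes 0, and is
#' strictly increasing on `[-1, 1]`, so it preserves order along a map axis
#' while re-expressing distances in information units.
#'
#' @inheritParams gaussian_mi
#' @return Numeric vector of signed information values in `base`;
#'   `sign(signed_rescale(rho)) == sign(rho)` and
#'   `abs(signed_rescale(rho)) == gaussian_mi(rho)`.
#' @export
#' @examples
#' signed_rescale(c(-0.5, 0, 0.5))
signed_rescale <- function(rho, base = "nats", strict = FALSE) {
  sign(rho) * gaussian_mi(rho, base = base, strict = strict)
}

# Harmonic number of (possibly fractional, possibly negative) argument,
# H_x = digamma(x + 1) + Euler-Mascheroni constant.
.harmonic <- function(x) digamma(x + 1) - digamma(1)

#' Student-t mutual-information correction term
#'
#' The additive term by which the mutual information of a bivariate Student-t
#' pair with tail parameter `alpha` exceeds the Gaussian value at the same
#' correlation:
#' `lambda_alpha = -2/alpha + log(alpha) + 2*pi*(alpha+1)*csc(pi*alpha)
#'  + 2*log(B(alpha/2, 1/2)) - (alpha+1)*H(-alpha/2)
#'  + (alpha+1)*H(-alpha/2 - 1/2) - 1 - log(2*pi)`,
#' with `H` the harmonic number of fractional argument and `B` the beta
#' function.  It equals the mutual information of an uncorrelated Student-t
#' pair (a heavy-tailed pair is dependent even at `rho = 0`) and vanishes in
#' the Gaussian limit `alpha -> Inf`.
#'
#' The cosecant term and the harmonic-number difference have exactly
#' cancelling poles at integer `alpha`:
#' `2*pi*(alpha+1)*csc(pi*alpha) + (alpha+1)*(H(-alpha/2-1/2) - H(-alpha/2))`
#' equals `(alpha+1)*(digamma((alpha+1)/2) - digamma(alpha/2))` by the
#' digamma reflection formula.  The default `method = "grouped"` evaluates
#' that pole-free grouping, which is finite and stable for every
#' `alpha > 0`; `method = "printed"` evaluates the literal expression above,
#' taking the numerical limit (average of `alpha +- 1e-6`) at integer
#' `alpha` where the individual terms diverge.
#'
#' @param alpha Positive tail parameter (degrees of freedom); vectorised.
#' @param method `"grouped"` (default, pole-free) or `"printed"` (literal
#'   expression with limit evaluation at integer `alpha`).
#' @return Mutual information of the uncorrelated bivariate Student-t, in
#'   nats; non-negative and decreasing in `alpha`.
#' @seealso [student_t_mi()]
#' @export
#' @examples
#' lambda_alpha(3)
#' lambda_alpha(c(5, 10, 50, 1e3))  # decay toward the Gaussian limit
lambda_alpha <- function(alpha, method = c("grouped", "printed")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive and finite")
  if (method == "grouped") return(.lambda_grouped(alpha))
  vapply(alpha, function(a) {
    if (abs(a - round(a)) < 1e-9) {
      # csc(pi*alpha) and the harmonic terms have simple poles at integer
      # alpha that cancel in the sum; take the symmetric numerical limit.
      # The offset trades the O(delta^2) limit error against the
      # 1/delta amplification of digamma argument rounding near the pole;
      # 1e-4 keeps both below ~1e-7.
      mean(c(.lambda_printed(a - 1e-4), .lambda_printed(a + 1e-4)))
    } else .lambda_printed(a)
  }, 0)
}

.lambda_grouped <- function(a) {
  -2 / a + log(a) + 2 * lbeta(a / 2, 0.5) +
    (a + 1) * (digamma((a + 1) / 2) - digamma(a / 2)) - 1 - log(2 * pi)
}

.lambda_printed <- function(a) {
  # sinpi does exact argument reduction: essential near the csc poles
  -2 / a + log(a) + 2 * pi * (a + 1) / sinpi(a) + 2 * lbeta(a / 2, 0.5) -
    (a + 1) * .harmonic(-a / 2) + (a + 1) * .harmonic(-a / 2 - 0.5) -
    1 - log(2 * pi)
}

#' Mutual information of a bivariate Student-t
#'
#' `-log(1 - rho^2)/2 + lambda_alpha(alpha)`: the Gaussian term plus the
#' tail-dependence correction.  Unlike the Gaussian case, `rho = 0` does not
#' mean independence; the correction is independent of `rho` and converges
#' to zero as `alpha -> Inf`.
#'
#' @inheritParams gaussian_mi
#' @inheritParams lambda_alpha
#' @return Non-negative information value(s) in `base`.
#' @export
#' @examples
#' student_t_mi(0.5, alpha = 3)
#' student_t_mi(0.5, alpha = 1e6)  # ~ gaussian_mi(0.5)
student_t_mi <- function(rho, alpha, base = "nats", strict = FALSE,
                         method = c("grouped", "printed")) {
  base <- .check_base(base)
  mi <- gaussian_mi(rho, base = "nats", strict = strict) +
    lambda_alpha(alpha, method = method)
  convert_information(mi, "nats", base)
}

#' Empirical mutual information of two samples
#'
#' Nonparametric estimate of the mutual information between two real-valued
#' samples, used to validate that distinct principal components of Gaussian
#' data carry (near) zero mutual information.
#'
#' `method = "knn"` is the Kraskov-Stoegbauer-Grassberger nearest-neighbour
#' estimator (their first variant):
#' `I = digamma(k) + digamma(n) - mean(digamma(nx+1) + digamma(ny+1))`,
#' with marginal neighbour counts taken strictly inside the max-norm distance
#' to each point's k-th neighbour.  A vanishing tie-breaking jitter is added
#' when duplicate values are present (deterministic given `jitter_seed`).
#' `method = "binned"` is the histogram plug-in estimator on
#' Freedman-Diaconis grids with the Miller-Madow bias correction.
#'
#' @param x,y Numeric vectors of equal length (at least 50).
#' @param method `"knn"` (default) or `"binned"`.
#' @param k Number of neighbours for `"knn"` (default 3).
#' @param bins Number of bins per margin for `"binned"`; `NULL` (default)
#'   chooses by the Freedman-Diaconis rule.
#' @param base Information unit of the returned estimate.
#' @param jitter_seed Seed for the duplicate-breaking jitter (knn only).
#' @return A single non-negative estimate.  Slightly negative raw estimates
#'   (possible for both estimators) are clipped to zero, with the raw value
#'   kept in attribute `"raw"` and `attr(, "clipped")` set.
#' @references Kraskov, Stoegbauer and Grassberger (2004) Phys. Rev. E 69,
#'   066138.
#' @export
#' @examples
#' xy <- simulate_bivariate(2000, rho = 0.6, seed = 1)
#' empirical_mi(xy$x, xy$y)          # near -log(1 - 0.36)/2 = 0.223
empirical_mi <- function(x, y, method = c("knn", "binned"), k = 3L,
                         bins = NULL, base = "nats", jitter_seed = 1L) {
  method <- match.arg(method)
  base <- .check_base(base)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 50) stop("need at least 50 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has undefined mutual information")
  est <- if (method == "knn") {
    if (k < 1 || k >= n) stop("k must be in [1, n - 1]")
    # MI is invariant under marginal scaling; equalizing the scales avoids
    # the max-norm neighbourhood degenerating into slabs when the two
    # margins live on very different scales
    xx <- (x - mean(x)) / sd(x)
    yy <- (y - mean(y)) / sd(y)
    if (anyDuplicated(xx) || anyDuplicated(yy)) {
      # KSG assumes continuous data; break ties with a vanishing jitter
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(jitter_seed)
      xx <- xx + rnorm(n, sd = sd(xx) * 1e-10)
      yy <- yy + rnorm(n, sd = sd(yy) * 1e-10)
      if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
        rm(".Random.seed", envir = globalenv())
    }
    cnt <- ksg_counts(as.numeric(xx), as.numeric(yy), as.integer(k))
    digamma(k) + digamma(n) - mean(digamma(cnt$nx + 1) + digamma(cnt$ny + 1))
  } else {
    .binned_mi(x, y, bins)
  }
  out <- max(est, 0)
  attr(out, "raw") <- est
  attr(out, "clipped") <- est < 0
  convert_information(out, "nats", base)
}

.fd_bins <- function(v) {
  iqr <- stats::IQR(v)
  if (iqr == 0) return(min(10L, max(2L, length(unique(v)))))
  h <- 2 * iqr / length(v)^(1 / 3)
  max(2L, min(512L, ceiling(diff(range(v)) / h)))
}

.binned_mi <- function(x, y, bins = NULL) {
  bx <- if (is.null(bins)) .fd_bins(x) else as.integer(bins)
  by <- if (is.null(bins)) .fd_bins(y) else as.integer(bins)
  n <- length(x)
  cx <- cut(x, breaks = bx, include.lowest = TRUE)
  cy <- cut(y, breaks = by, include.lowest = TRUE)
  joint <- table(cx, cy) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  plug <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  # Miller-Madow: entropy bias (K-1)/(2n) per table, combined for I = Hx+Hy-Hxy
  kx <- sum(px > 0); ky <- sum(py > 0); kxy <- sum(nz)
  plug + ((kx - 1) + (ky - 1) - (kxy - 1)) / (2 * n)
}

#' Binned entropy of one sample
#'
#' Histogram entropy of `x` (Freedman-Diaconis bins unless `bins` is
#' given) with the Miller-Madow bias correction `(K - 1) / (2n)`, in
#' `base`.  When `y` duplicates `x` exactly, [empirical_mi()] with
#' `method = "binned"` equals this value (perfect dependence: the mutual
#' information saturates at the entropy of the common margin).
#'
#' @inheritParams empirical_mi
#' @export
binned_entropy <- function(x, bins = NULL, base = "nats") {
  base <- .check_base(base)
  b <- if (is.null(bins)) .fd_bins(x) else as.integer(bins)
  p <- table(cut(x, breaks = b, include.lowest = TRUE)) / length(x)
  p <- p[p > 0]
  h <- -sum(p * log(p)) + (length(p) - 1) / (2 * length(x))
  convert_information(h, "nats", base)
}

# Bivariate standard-normal MI integrand f * log(f / (fx * fy)); zero where
# the density underflows.
.mi_integrand <- function(x, y, rho) {
  den <- exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
    (2 * pi * sqrt(1 - rho^2))
  v <- den * log(den / (stats::dnorm(x) * stats::dnorm(y)))
  v[!is.finite(v)] <- 0
  v
}

# Nested adaptive quadrature of the MI integrand over x in [xlo, xhi].
.mi_quad <- function(rho, xlo, xhi, lim = 9, tol = 1e-11) {
  outer_f <- function(xv) vapply(xv, function(x)
    integrate(function(y) .mi_integrand(x, y, rho), -lim, lim,
              rel.tol = tol, abs.tol = tol * 0.1,
              subdivisions = 400L)$value, 0)
  integrate(outer_f, xlo, xhi, rel.tol = tol, abs.tol = tol * 0.1,
            subdivisions = 400L)$value
}

#' Additivity of mutual information across a partition
#'
#' Mutual information is an integral against the joint density, so it is
#' additive over any partition of the domain (unlike correlation).  This
#' check integrates the bivariate-Gaussian MI integrand separately over
#' `{x < c}` and `{x >= c}` by adaptive quadrature and compares the sum of
#' the parts with the full integral (and with the closed form).
#'
#' @param rho Correlation in `(-1, 1)`.
#' @param partition_point The cut point `c` on the x margin.
#' @param lim Truncation half-width of the quadrature domain (standard
#'   deviations; the neglected tail mass is below 1e-17 at the default 9).
#' @return A list with `parts` (the two partial integrals), `sum_of_parts`,
#'   `whole` (independently integrated full domain), `closed_form`
#'   (`gaussian_mi(rho)`) and `discrepancy` (`|sum_of_parts - whole|`).
#' @export
#' @examples
#' mi_additivity_check(0.5, 0)
mi_additivity_check <- function(rho, partition_point = 0, lim = 9) {
  if (length(rho) != 1 || !is.finite(rho) || abs(rho) >= 1)
    stop("rho must be a single value in (-1, 1)")
  cpt <- partition_point
  if (!is.finite(cpt)) stop("partition_point must be finite")
  lo <- min(-lim, cpt - 1); hi <- max(lim, cpt + 1)
  left <- .mi_quad(rho, lo, cpt, lim = lim)
  right <- .mi_quad(rho, cpt, hi, lim = lim)
  whole <- .mi_quad(rho, lo, hi, lim = lim)
  list(parts = c(left = left, right = right),
       sum_of_parts = left + right,
       whole = whole,
       closed_form = gaussian_mi(rho),
       discrepancy = abs(left + right - whole))
}
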