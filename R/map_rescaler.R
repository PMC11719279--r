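# Conversion of a PCA decomposition into paired conventional and
# information-rescaled map coordinates: M' = r(U), coordinates r(rho)*sqrt(lambda).

#' Rescale a correlation-loadings table into signed information
#'
#' Entrywise application of [signed_rescale()] to a matrix of correlations
#' (typically the `M = U` loadings).  The transform is odd and strictly
#' monotone, so each column's ranks are preserved exactly while distances
#' become information-valued.
#'
#' @param M Numeric matrix (or vector) of correlations; entries must lie in
#'   `[-1, 1]` up to a `1e-10` numerical slack, otherwise the input is not a
#'   correlation table and an error is raised.  Entries within `1e-12` of
#'   `+-1` are clamped (with a warning) to keep coordinates finite.
#' @param base Information unit of the result.
#' @return Matrix of the same shape; attribute `"n_clamped"` counts clamped
#'   entries.
#' @export
#' @examples
#' rescale_loadings(matrix(c(0, 0.5, -0.5, 0.9), 2))
rescale_loadings <- function(M, base = "nats") {
  base <- .check_base(base)
  v <- as.numeric(M)
  if (any(!is.finite(v))) stop("non-finite entries in loadings")
  if (any(abs(v) > 1 + 1e-10))
    stop("entries outside [-1, 1]: input is not a correlation table")
  n_clamped <- sum(abs(v) >= 1 - 1e-12)
  out <- signed_rescale(pmin(pmax(v, -1), 1), base = base)
  if (is.matrix(M)) out <- matrix(out, nrow(M), ncol(M), dimnames = dimnames(M))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Build paired conventional and information-rescaled map coordinates
#'
#' For the chosen component axes, the conventional coordinate of sample `i`
#' on axis `j` is `U_ij * sqrt(lambda_j)` and the rescaled coordinate is
#' `r(U_ij) * sqrt(lambda_j)` with `r` the signed information rescaling —
#' each sample's own correlation with the component is transformed, which
#' stretches the map nonuniformly along each axis (strongly correlated
#' samples move outward, weakly correlated ones pull in) while preserving
#' the per-axis ordering exactly.
#'
#' @param decomp A `pca_decomposition`.
#' @param axes Component indices (distinct, non-empty).
#' @param base Information unit of the rescaled coordinates (the
#'   conventional coordinates are unit-free and unaffected).
#' @param weight `"sqrt_lambda"` (default, the `r(rho) * sqrt(lambda)` map
#'   coordinate) or `"none"` (pure `r(rho)`, information units comparable
#'   across axes).
#' @return An object of class `mi_embedding`: `sample_ids`, `axes`,
#'   `conventional` and `rescaled` (`m x length(axes)` matrices),
#'   `eigenvalues` (of the chosen axes), `loadings` (the `U` columns used),
#'   `base`, `weight`, `population`.
#' @export
make_embedding <- function(decomp, axes = c(1, 2), base = "nats",
                           weight = c("sqrt_lambda", "none")) {
  stopifnot(inherits(decomp, "pca_decomposition"))
  weight <- match.arg(weight)
  base <- .check_base(base)
  axes <- as.integer(axes)
  if (length(axes) == 0) stop("axes must be non-empty")
  if (anyDuplicated(axes)) stop("axes must be distinct")
  if (any(axes < 1 | axes > length(decomp$eigenvalues)))
    stop("axis index out of range")
  lam <- decomp$eigenvalues[axes]
  nullax <- decomp$null_components[axes]
  if (any(nullax)) {
    warning("axis with zero eigenvalue: coordinates set to 0", call. = FALSE)
    lam[nullax] <- 0
  }
  U <- decomp$U[, axes, drop = FALSE]
  U[, nullax] <- 0
  w <- if (weight == "sqrt_lambda") sqrt(lam) else as.numeric(!nullax)
  conv <- sweep(U, 2, sqrt(lam), `*`)
  resc <- sweep(rescale_loadings(U, base = base), 2, w, `*`)
  attr(resc, "n_clamped") <- NULL
  cn <- paste0("PC", axes)
  dimnames(conv) <- dimnames(resc) <- list(decomp$sample_ids, cn)
  structure(list(sample_ids = decomp$sample_ids, axes = axes,
                 conventional = conv, rescaled = resc,
                 eigenvalues = lam, loadings = U, base = base,
                 weight = weight, population = decomp$population),
            class = "mi_embedding")
}

#' @export
print.mi_embedding <- function(x, ...) {
  cat(sprintf("mi_embedding: %d samples on axes %s (%s%s)\n",
              length(x$sample_ids), paste(x$axes, collapse = ", "), x$base,
              if (x$weight == "none") ", unweighted" else ""))
  invisible(x)
}

#' Change the information unit of an embedding
#'
#' Rescaled coordinates are multiplied by exactly `1/log(2)` going from
#' nats to bits (conventional coordinates are unchanged).
#'
#' @param emb An `mi_embedding`.
#' @param base Target unit.
#' @export
set_embedding_base <- function(emb, base) {
  stopifnot(inherits(emb, "mi_embedding"))
  base <- .check_base(base)
  emb$rescaled <- convert_information(emb$rescaled, emb$base, base)
  emb$base <- base
  emb
}

#' Write an embedding as TSV
#'
#' Columns `sample_id`, `population`, then per axis `PC<j>_conv` and
#' `PC<j>_mi`.  Values are written with 17 significant digits, so
#' [read_embedding()] round-trips losslessly.
#'
#' @param emb An `mi_embedding`.
#' @param path Output file.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "mi_embedding"))
  if (length(emb$axes) == 0) stop("empty axis list")
  df <- data.frame(sample_id = emb$sample_ids,
                   population = if (is.null(emb$population)) NA_character_
                                else emb$population)
  for (i in seq_along(emb$axes)) {
    df[[paste0("PC", emb$axes[i], "_conv")]] <-
      sprintf("%.17g", emb$conventional[, i])
    df[[paste0("PC", emb$axes[i], "_mi")]] <-
      sprintf("%.17g", emb$rescaled[, i])
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  # trailer comment lines carry the metadata needed to rebuild the object
  cat(sprintf("# axes=%s base=%s weight=%s eigenvalues=%s\n",
              paste(emb$axes, collapse = ","), emb$base, emb$weight,
              paste(sprintf("%.17g", emb$eigenvalues), collapse = ",")),
      file = path, append = TRUE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path Input TSV.
#' @return An `mi_embedding` (loadings reconstructed from the conventional
#'   coordinates where the eigenvalue is nonzero).
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  meta_line <- grep("^# axes=", lines, value = TRUE)
  if (length(meta_line) != 1) stop("not an embedding file (metadata line missing)")
  kv <- regmatches(meta_line, gregexpr("[a-z]+=[^ ]+", meta_line))[[1]]
  meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  axes <- as.integer(strsplit(meta[["axes"]], ",")[[1]])
  lam <- as.numeric(strsplit(meta[["eigenvalues"]], ",")[[1]])
  df <- data.table::fread(text = lines[!startsWith(lines, "#")],
                          sep = "\t", header = TRUE, data.table = FALSE)
  conv <- as.matrix(df[, paste0("PC", axes, "_conv"), drop = FALSE])
  resc <- as.matrix(df[, paste0("PC", axes, "_mi"), drop = FALSE])
  cn <- paste0("PC", axes)
  colnames(conv) <- colnames(resc) <- cn
  rownames(conv) <- rownames(resc) <- df$sample_id
  U <- sweep(conv, 2, ifelse(lam > 0, sqrt(lam), 1), `/`)
  pop <- if (all(is.na(df$population))) NULL else as.character(df$population)
  structure(list(sample_ids = as.character(df$sample_id), axes = axes,
                 conventional = conv, rescaled = resc, eigenvalues = lam,
                 loadings = U, base = meta[["base"]],
                 weight = meta[["weight"]], population = pop),
            class = "mi_embedding")
}

#' Two-panel map plot (conventional vs information-rescaled)
#'
#' Side-by-side scatter of the first two embedding axes, colored by
#' population label when present.  Requires ggplot2 (optional dependency);
#' never needed by the computational pipeline.
#'
#' @param emb An `mi_embedding` with at least two axes.
#' @param path Optional output file (PNG/SVG/PDF by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_embedding <- function(emb, path = NULL) {
  stopifnot(inherits(emb, "mi_embedding"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_embedding needs the ggplot2 package")
  if (length(emb$axes) < 2) stop("need at least two axes to plot")
  mk <- function(mat, panel) data.frame(
    x = mat[, 1], y = mat[, 2], panel = panel,
    population = if (is.null(emb$population)) "all" else emb$population)
  df <- rbind(mk(emb$conventional, "conventional"),
              mk(emb$rescaled, sprintf("rescaled (%s)", emb$base)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$population)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = paste0("PC", emb$axes[1]), y = paste0("PC", emb$axes[2])) +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 9, height = 4.2, dpi = 150)
  invisible(p)
}
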