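# Principal coordinate analysis (metric multidimensional scaling) via
# Gower double-centering and eigendecomposition.

#' Principal coordinate analysis of a distance matrix
#'
#' Double-centers the squared distances, B = -1/2 J D^2 J with
#' J = I - 11'/n, and eigendecomposes B. Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues; the percent
#' of variation explained by each axis is 100 * lambda_i / sum of positive
#' lambda. Negative eigenvalues (possible for non-Euclidean
#' dissimilarities) are dropped from both the axes and the
#' explained-variance denominator; their count is reported.
#'
#' @param d a `dist` object or square symmetric matrix with zero diagonal,
#'   over at least 3 samples.
#' @return an object of class `pcoa_ordination`: list with `coordinates`
#'   (samples x axes), `explained` (percent per axis, non-increasing),
#'   `eigenvalues` (all, decreasing) and `negative` (count of negative
#'   eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8) ||
      any(abs(diag(m)) > 1e-12) || any(m < 0))
    stop("'d' must be a symmetric non-negative distance matrix with zero diagonal")
  n <- nrow(m)
  if (n < 3) stop("PCoA needs at least 3 samples")
  centered <- scale(m^2, center = TRUE, scale = FALSE)
  b <- -0.5 * t(scale(t(centered), center = TRUE, scale = FALSE))
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  neg <- sum(eig$values < -tol)
  lambda <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda),
                                                      nrow = length(lambda))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 explained = 100 * lambda / sum(lambda),
                 eigenvalues = eig$values,
                 negative = neg),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("Principal coordinate analysis:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "positive axes\n")
  k <- min(3, length(x$explained))
  cat("  explained (%):",
      paste(sprintf("%s %.2f", colnames(x$coordinates)[seq_len(k)],
                    x$explained[seq_len(k)]), collapse = ", "), "\n")
  if (x$negative > 0)
    cat("  negative eigenvalues dropped:", x$negative, "\n")
  invisible(x)
}
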