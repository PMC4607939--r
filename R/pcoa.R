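# Gower-centered inner-product matrix of a distance matrix:
# G = C (-0.5 D^2) C with C = I - 11'/n. trace(G) equals
# (1/n) * sum_{i<j} d_ij^2, the total sum of squares all the
# distance-based partitions in this package work with.
#' @keywords internal
#' @noRd
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm
  (G + t(G)) / 2
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: the Gower-centered
#' matrix of `-d^2/2` is eigendecomposed, axes are ordered by decreasing
#' eigenvalue, and coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues. Negative eigenvalues, which arise for
#' semimetric dissimilarities such as Bray-Curtis, are reported unchanged;
#' by default they are excluded from the `proportion_explained`
#' denominator (no correction is applied).
#'
#' @param D symmetric distance matrix (n >= 3) with sample IDs.
#' @return List with `coordinates` (n x k matrix, k = number of positive
#'   eigenvalues), `eigenvalues` (all n, descending) and
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(D) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  assert_that(n >= 3, "PCoA needs at least 3 samples")
  e <- eigen(gower_center(D), symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(D), paste0("PCo", seq_along(pos)))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values[pos] / sum(e$values[pos]))
}
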