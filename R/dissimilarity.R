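#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical
#' composition, 1 for disjoint taxa. The abundance-based workhorse metric
#' for community comparison; similarity used downstream is uniformly
#' `1 - dissimilarity`.
#'
#' @param x,y nonnegative numeric vectors of equal length, each with at
#'   least one positive entry.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  assert_that(length(x) == length(y), "vectors differ in length")
  assert_that(all(x >= 0) && all(y >= 0), "abundances must be nonnegative")
  assert_that(sum(x) > 0 && sum(y) > 0, "all-zero abundance vector")
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

#' Sorensen dissimilarity between two samples
#'
#' Incidence-based companion to [bray_curtis()]: vectors are binarized at
#' count > 0 and `1 - 2|A intersect B| / (|A| + |B|)` is returned.
#'
#' @inheritParams bray_curtis
#' @return Dissimilarity in \[0, 1\].
#' @export
sorensen <- function(x, y) {
  assert_that(length(x) == length(y), "vectors differ in length")
  a <- x > 0; b <- y > 0
  assert_that(any(a) && any(b), "empty sample")
  1 - 2 * sum(a & b) / (sum(a) + sum(b))
}

#' Pairwise distance matrix for a community table
#'
#' Computes all pairwise Bray-Curtis or Sorensen dissimilarities between
#' samples, returning a validated square symmetric matrix keyed by sample
#' IDs (zero diagonal, values in \[0, 1\]).
#'
#' @param table a `community_table` with at least 2 samples.
#' @param metric `"bray_curtis"` (abundance-based, default) or
#'   `"sorensen"` (incidence-based).
#' @return Square symmetric numeric matrix of dissimilarities.
#' @export
distance_matrix <- function(table, metric = c("bray_curtis", "sorensen")) {
  stopifnot(inherits(table, "community_table"))
  metric <- match.arg(metric)
  assert_that(n_samples(table) >= 2, "need at least 2 samples")
  tot <- colSums(table$counts)
  assert_that(all(tot > 0), paste0("all-zero sample(s): ",
              paste(table$sample_ids[tot == 0], collapse = ", ")))
  x <- t(table$counts)
  d <- if (metric == "bray_curtis") vegan::vegdist(x, method = "bray")
       else vegan::vegdist(x, method = "bray", binary = TRUE)
  validate_distance_matrix(as.matrix(d))
}

#' Per-sample alpha diversity
#'
#' Richness (taxa with count > 0), Shannon index H' (natural log, over
#' positive proportions) and Pielou evenness J = H'/ln(richness), with
#' J defined as 1 for single-taxon samples.
#'
#' @param table a `community_table` (counts or proportions).
#' @param base logarithm base for H' (default `exp(1)`).
#' @return data.frame with `sample_id`, `richness`, `shannon`, `evenness`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "community_table"))
  tot <- colSums(table$counts)
  assert_that(all(tot > 0), "empty sample")
  res <- apply(table$counts, 2, function(v) {
    p <- v[v > 0] / sum(v)
    h <- -sum(p * log(p, base = base))
    s <- length(p)
    c(richness = s, shannon = h,
      evenness = if (s == 1) 1 else h / log(s, base = base))
  })
  data.frame(sample_id = colnames(table$counts), t(res),
             row.names = NULL, stringsAsFactors = FALSE)
}
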