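#' Analysis of similarity (ANOSIM)
#'
#' Rank-based contrast of between-group versus within-group
#' dissimilarities: `R = (mean_between_rank - mean_within_rank) /
#' (n(n-1)/4)`, in \[-1, 1\]; R near 1 means groups are strongly
#' separated, near 0 means no separation. Ties receive average ranks.
#' Significance by free permutation of group labels (+1 convention).
#'
#' @param D symmetric distance matrix with sample IDs.
#' @param grouping factor/character of group labels, one per sample of `D`
#'   (same order), with at least 2 groups of at least 2 samples.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return List with `R`, `p`, `n_perm`, `seed`.
#' @export
anosim <- function(D, grouping, n_perm = 999, seed = NULL) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  assert_that(length(grouping) == n, "one group label per sample required")
  grouping <- as.factor(grouping)
  tab <- table(grouping)
  assert_that(length(tab) >= 2, "need at least 2 groups")
  assert_that(all(tab >= 2), paste0("singleton group(s): ",
              paste(names(tab)[tab < 2], collapse = ", ")))
  assert_that(n_perm >= 99, "`n_perm` must be at least 99")

  lower <- lower.tri(D)
  r <- matrix(0, n, n)
  r[lower] <- rank(D[lower])  # average ranks for ties
  r <- r + t(r)
  denom <- n * (n - 1) / 4

  stat <- function(g) {
    within <- outer(g, g, "==")[lower]
    (mean(r[lower][!within]) - mean(r[lower][within])) / denom
  }
  R_obs <- stat(grouping)
  R_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    stat(grouping[sample.int(n)]), numeric(1)))
  list(R = R_obs, p = perm_pvalue(R_obs, R_perm), n_perm = n_perm, seed = seed)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Pearson or Spearman) between the lower triangles of two
#' distance matrices over the same samples; significance by jointly
#' permuting the rows and columns of the second matrix (+1 convention,
#' one-sided on positive association).
#'
#' @param D1,D2 symmetric distance matrices over the same sample IDs
#'   (same order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return List with `r`, `p`, `method`, `n_perm`, `seed`.
#' @export
mantel <- function(D1, D2, method = c("pearson", "spearman"),
                   n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  D1 <- validate_distance_matrix(D1)
  D2 <- validate_distance_matrix(D2)
  assert_that(identical(dim(D1), dim(D2)) &&
                identical(rownames(D1), rownames(D2)),
              "D1 and D2 must cover the same samples in the same order")
  assert_that(n_perm >= 99, "`n_perm` must be at least 99")
  lower <- lower.tri(D1)
  v1 <- D1[lower]
  r_obs <- stats::cor(v1, D2[lower], method = method)
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(D2))
    stats::cor(v1, D2[idx, idx][lower], method = method)
  }, numeric(1)))
  list(r = r_obs, p = perm_pvalue(r_obs, r_perm), method = method,
       n_perm = n_perm, seed = seed)
}
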