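#' Pairwise similarity versus time lag within a group
#'
#' For every unordered pair of samples in `group` with a positive lag,
#' emits the time interval in days and the community similarity
#' `1 - d_ij`. Lag-0 pairs (replicates at the same day) are returned
#' separately: they cannot enter a log-log regression but do enter
#' within-group similarity summaries.
#'
#' @param D symmetric distance matrix with sample IDs.
#' @param meta data.frame with `sample_id`, `site` and `day` columns.
#' @param group site label selecting the samples; `NULL` uses them all.
#' @return List with `pairs` (data.frame: sample_i, sample_j, lag_days,
#'   similarity; lag > 0) and `lag0` (same layout, lag = 0).
#' @export
similarity_lag_pairs <- function(D, meta, group = NULL) {
  D <- validate_distance_matrix(D)
  meta <- align_samples(meta, rownames(D))
  assert_that(all(c("day") %in% names(meta)), "`meta` needs a `day` column")
  ids <- rownames(D)
  if (!is.null(group)) {
    assert_that("site" %in% names(meta), "`meta` needs a `site` column")
    keep <- meta$site == group
    assert_that(sum(keep) >= 2, "fewer than 2 samples in group")
    ids <- ids[keep]; meta <- meta[keep, , drop = FALSE]
    D <- D[ids, ids, drop = FALSE]
  }
  assert_that(length(unique(meta$day)) >= 2,
              "group has a single time point; no lags to form")
  n <- length(ids)
  ij <- which(lower.tri(D), arr.ind = TRUE)
  lag <- abs(meta$day[ij[, 1]] - meta$day[ij[, 2]])
  res <- data.frame(sample_i = ids[ij[, 2]], sample_j = ids[ij[, 1]],
                    lag_days = lag, similarity = 1 - D[ij],
                    stringsAsFactors = FALSE)
  list(pairs = res[res$lag_days > 0, , drop = FALSE],
       lag0 = res[res$lag_days == 0, , drop = FALSE])
}

# OLS of log10(similarity) on log10(lag) after optional mean-per-lag
# aggregation; shared by the fit and all its resampling tests.
#' @keywords internal
#' @noRd
.tdr_slope <- function(lag, sim, aggregation) {
  if (aggregation == "mean-per-lag") {
    sim <- tapply(sim, lag, mean)
    lag <- as.numeric(names(sim))
    sim <- as.numeric(sim)
  }
  usable <- sim > 0
  lag <- lag[usable]; sim <- sim[usable]
  if (length(unique(lag)) < 3) return(NULL)
  x <- log10(lag); y <- log10(sim)
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(intercept = fit$coefficients[[1]], slope = fit$coefficients[[2]],
       r_squared = r2, n_points = length(y), dropped = sum(!usable))
}

#' Fit the time-decay-of-similarity relationship (TDR)
#'
#' Ordinary least squares of `log10(similarity)` on `log10(lag)`. With
#' the default `"mean-per-lag"` aggregation, similarities are first
#' averaged within each distinct lag, so the regression runs on one mean
#' point per time interval; `"all-pairs"` regresses on every pair. The
#' turnover rate is `w = -slope` (positive for decaying similarity).
#' Lags whose (aggregated) similarity is not positive are dropped with a
#' warning, since their logarithm is undefined; at least 3 usable
#' distinct lags are required.
#'
#' @param pairs data.frame with `lag_days` and `similarity` columns, as
#'   produced by [similarity_lag_pairs()]`$pairs`.
#' @param aggregation `"mean-per-lag"` (default) or `"all-pairs"`.
#' @return Object of class `tdr_fit`: list with `slope`, `intercept`,
#'   `w = -slope`, `r_squared`, `n_points`, `aggregation`.
#' @export
tdr_fit <- function(pairs, aggregation = c("mean-per-lag", "all-pairs")) {
  aggregation <- match.arg(aggregation)
  assert_that(is.data.frame(pairs) &&
                all(c("lag_days", "similarity") %in% names(pairs)),
              "`pairs` needs `lag_days` and `similarity` columns")
  assert_that(all(pairs$lag_days > 0), "lag-0 pairs cannot enter the TDR fit")
  fit <- .tdr_slope(pairs$lag_days, pairs$similarity, aggregation)
  assert_that(!is.null(fit),
              "fewer than 3 distinct lags with positive similarity")
  if (fit$dropped > 0)
    warning(fit$dropped, " lag point(s) with nonpositive similarity dropped")
  structure(list(slope = fit$slope, intercept = fit$intercept,
                 w = -fit$slope, r_squared = fit$r_squared,
                 n_points = fit$n_points, aggregation = aggregation),
            class = "tdr_fit")
}

#' @export
print.tdr_fit <- function(x, ...) {
  cat(sprintf("TDR fit (%s): w = %.4f, intercept = %.4f, R2 = %.3f (%d points)\n",
              x$aggregation, x$w, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Test the TDR slope against zero
#'
#' Primary inference is a permutation test: similarity values are
#' shuffled across lags `n_boot` times, the regression is refit, and the
#' two-sided p-value is the fraction of permuted |slopes| at least as
#' large as the observed (+1 convention). A bootstrap distribution of
#' the slope — resampling *samples* (not pairs) with replacement and
#' recomputing the pairs — is reported alongside with a percentile CI,
#' together with a one-sample t test of the random-pairing null slopes
#' against the observed slope (`t_test_p`), a secondary diagnostic.
#'
#' @param fit a [tdr_fit()] object.
#' @param pairs the pair table the fit was derived from.
#' @param n_boot permutations/bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param D,meta optional distance matrix and metadata; when both are
#'   supplied the sample-level bootstrap is computed (otherwise only the
#'   permutation test is run).
#' @param group site label passed to [similarity_lag_pairs()] for the
#'   bootstrap.
#' @return List with `p` (permutation p-value), `perm_slopes`,
#'   `t_test_p`, and, when `D`/`meta` are given, `boot_slopes`, `boot_ci`
#'   (2.5/97.5 percentiles), `n_boot`, `seed`.
#' @export
slope_test_zero <- function(fit, pairs, n_boot = 1000, seed = NULL,
                            D = NULL, meta = NULL, group = NULL) {
  stopifnot(inherits(fit, "tdr_fit"))
  assert_that(n_boot >= 100, "`n_boot` must be at least 100")
  seeds <- derive_seeds(if (is.null(seed)) sample.int(2^30, 1) else seed, 2L)

  perm_slopes <- with_seed(seeds[1], vapply(seq_len(n_boot), function(i) {
    f <- .tdr_slope(pairs$lag_days, sample(pairs$similarity), fit$aggregation)
    if (is.null(f)) NA_real_ else f$slope
  }, numeric(1)))
  perm_slopes <- perm_slopes[!is.na(perm_slopes)]
  p <- perm_pvalue(fit$slope, perm_slopes, tail = "two.sided")
  tt_p <- tryCatch(stats::t.test(perm_slopes, mu = fit$slope)$p.value,
                   error = function(e) NA_real_)  # degenerate null slopes

  out <- list(p = p, perm_slopes = perm_slopes, t_test_p = tt_p,
              n_boot = n_boot, seed = seed)

  if (!is.null(D) && !is.null(meta)) {
    D <- validate_distance_matrix(D)
    meta_al <- align_samples(meta, rownames(D))
    ids <- rownames(D)
    if (!is.null(group)) ids <- ids[meta_al$site == group]
    boot <- with_seed(seeds[2], vapply(seq_len(n_boot), function(i) {
      take <- sample(ids, length(ids), replace = TRUE)
      take <- unique(take)  # duplicates add only lag-0 / self pairs
      if (length(take) < 3) return(NA_real_)
      meta_take <- meta_al[match(take, rownames(D)), , drop = FALSE]
      if (length(unique(meta_take$day)) < 3) return(NA_real_)
      sub <- similarity_lag_pairs(D[take, take, drop = FALSE], meta_take)
      f <- .tdr_slope(sub$pairs$lag_days, sub$pairs$similarity,
                      fit$aggregation)
      if (is.null(f)) NA_real_ else f$slope
    }, numeric(1)))
    boot <- boot[!is.na(boot)]
    out$boot_slopes <- boot
    out$boot_ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)
  }
  out
}

#' Compare turnover rates between two groups
#'
#' Observed difference `delta_w = w_A - w_B`. The null distribution is
#' built by permuting group membership at the *sample* level: samples
#' are randomly reassigned to the two groups (keeping group sizes),
#' pairs are recomputed within each permuted group, and both slopes are
#' refit. Two-sided p with the +1 convention.
#'
#' @param D symmetric distance matrix covering both groups.
#' @param meta data.frame with `sample_id`, `site`, `day`.
#' @param group_a,group_b the two site labels to compare.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param aggregation passed to the slope computation.
#' @return List with `delta_w`, `w_a`, `w_b`, `p`, `n_perm`, `seed`.
#' @export
compare_slopes <- function(D, meta, group_a, group_b, n_perm = 1000,
                           seed = NULL,
                           aggregation = c("mean-per-lag", "all-pairs")) {
  aggregation <- match.arg(aggregation)
  D <- validate_distance_matrix(D)
  meta <- align_samples(meta, rownames(D))
  ids <- rownames(D)
  in_a <- meta$site == group_a
  in_b <- meta$site == group_b
  assert_that(sum(in_a) >= 4 && sum(in_b) >= 4,
              "each group needs at least 4 samples")
  both <- ids[in_a | in_b]
  days <- meta$day[match(both, ids)]
  is_a <- in_a[match(both, ids)]
  Dsub <- D[both, both, drop = FALSE]

  slope_of <- function(members) {
    sub <- Dsub[members, members, drop = FALSE]
    ij <- which(lower.tri(sub), arr.ind = TRUE)
    d <- days[match(rownames(sub), both)]
    lag <- abs(d[ij[, 1]] - d[ij[, 2]])
    sim <- 1 - sub[ij]
    pos <- lag > 0
    f <- .tdr_slope(lag[pos], sim[pos], aggregation)
    if (is.null(f)) NA_real_ else f$slope
  }
  s_a <- slope_of(both[is_a]); s_b <- slope_of(both[!is_a])
  assert_that(!is.na(s_a) && !is.na(s_b),
              "degenerate group: fewer than 3 usable lags")
  delta_obs <- (-s_a) - (-s_b)

  delta_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lab <- sample(is_a)
    pa <- slope_of(both[lab]); pb <- slope_of(both[!lab])
    if (is.na(pa) || is.na(pb)) NA_real_ else (-pa) - (-pb)
  }, numeric(1)))
  delta_perm <- delta_perm[!is.na(delta_perm)]
  list(delta_w = delta_obs, w_a = -s_a, w_b = -s_b,
       p = perm_pvalue(delta_obs, delta_perm, tail = "two.sided"),
       n_perm = n_perm, seed = seed)
}

#' Within-group community similarity summaries and contrast
#'
#' Pools all within-group pairwise similarities (every lag, including
#' lag 0) and reports mean, SD and pair count per group. When exactly two
#' groups are given, a permutation test on the difference of group mean
#' similarities (relabelling samples, +1 convention, two-sided) is
#' included.
#'
#' @param D symmetric distance matrix.
#' @param meta data.frame with `sample_id` and `site`.
#' @param groups site labels to summarize (default: all present).
#' @param n_perm permutations for the two-group contrast.
#' @param seed integer seed.
#' @return List with `summary` (data.frame: group, mean, sd, n_pairs)
#'   and, for two groups, `delta_mean` and `p`.
#' @export
within_group_similarity <- function(D, meta, groups = NULL, n_perm = 999,
                                    seed = NULL) {
  D <- validate_distance_matrix(D)
  meta <- align_samples(meta, rownames(D))
  if (is.null(groups)) groups <- unique(meta$site)
  ids <- rownames(D)
  sims_of <- function(members) {
    sub <- D[members, members, drop = FALSE]
    1 - sub[lower.tri(sub)]
  }
  summ <- do.call(rbind, lapply(groups, function(g) {
    members <- ids[meta$site == g]
    assert_that(length(members) >= 2, paste0("singleton group: ", g))
    s <- sims_of(members)
    data.frame(group = g, mean = mean(s), sd = stats::sd(s),
               n_pairs = length(s), stringsAsFactors = FALSE)
  }))
  out <- list(summary = summ)
  if (length(groups) == 2) {
    members <- ids[meta$site %in% groups]
    lab <- meta$site[match(members, ids)] == groups[1]
    delta_obs <- mean(sims_of(members[lab])) - mean(sims_of(members[!lab]))
    delta_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      pl <- sample(lab)
      mean(sims_of(members[pl])) - mean(sims_of(members[!pl]))
    }, numeric(1)))
    out$delta_mean <- delta_obs
    out$p <- perm_pvalue(delta_obs, delta_perm, tail = "two.sided")
  }
  out
}
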