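#' Null-model randomizations of a community table
#'
#' Generates randomized community tables defining the stochastic
#' expectation against which deterministic assembly is measured. Each
#' randomization preserves, per sample, (a) the observed richness and
#' (b) the observed total count and abundance values: taxon identities
#' are drawn without replacement from the regional pool with probability
#' proportional to each taxon's occurrence frequency across samples
#' (Raup-Crick-style, extended to abundances), and the sample's observed
#' positive abundance values are randomly permuted across the drawn taxa.
#' An unweighted-draw variant (`weighting = "uniform"`) is provided for
#' sensitivity analyses.
#'
#' @param table a `community_table` of counts.
#' @param n_null number of randomizations (>= 100).
#' @param seed integer seed; randomizations are independent given it.
#' @param weighting `"occurrence"` (default) or `"uniform"` taxon draws.
#' @return List of `n_null` count matrices (same dimnames as the input).
#' @export
null_communities <- function(table, n_null, seed = NULL,
                             weighting = c("occurrence", "uniform")) {
  stopifnot(inherits(table, "community_table"))
  weighting <- match.arg(weighting)
  assert_that(n_null >= 100, "`n_null` must be at least 100")
  counts <- table$counts
  K <- nrow(counts)
  freq <- rowSums(counts > 0)
  pool <- which(freq > 0)
  w <- if (weighting == "occurrence") freq[pool] else rep(1, length(pool))
  rich <- colSums(counts > 0)
  assert_that(all(rich <= length(pool)),
              "sample richness exceeds the regional pool")
  abund <- lapply(seq_len(ncol(counts)),
                  function(j) counts[counts[, j] > 0, j])
  with_seed(seed, lapply(seq_len(n_null), function(b) {
    m <- matrix(0L, K, ncol(counts), dimnames = dimnames(counts))
    for (j in seq_len(ncol(counts))) {
      r <- rich[j]
      taxa <- if (r == length(pool)) pool
              else pool[sample.int(length(pool), r, prob = w)]
      vals <- abund[[j]]
      m[taxa, j] <- as.integer(vals[sample.int(length(vals))])
    }
    m
  }))
}

#' Partition community assembly into deterministic and stochastic shares
#'
#' For each within-group sample pair, compares the observed similarity
#' `s_obs = 1 - d_obs` with the mean similarity of the same pair across
#' `n_null` null-model randomizations. The per-pair determinism fraction
#' is `(s_obs - s_null_mean) / s_obs`: positive values mean the pair is
#' more similar than expected by chance (deterministic convergence),
#' negative values deterministic divergence.
#'
#' Two group aggregations are reported, because they answer different
#' questions:
#' * **truncated** (`determinism_pct`): `100 * mean(pmax(fraction, 0))`,
#'   counting only convergent excess similarity (nonnegative by
#'   construction); the matching `stochasticity_pct` is
#'   `100 * mean(pmin(s_null_mean/s_obs, 1))`, so the two need not sum
#'   to 100.
#' * **symmetric** (`determinism_pct_sym`): `100 * mean(fraction)`
#'   untruncated, with `stochasticity_pct_sym = 100 - determinism_pct_sym`;
#'   this is the unbiased-under-the-null summary used for calibration.
#'
#' @param table a `community_table` of counts (the observed table).
#' @param D_obs distance matrix of the observed table (same metric used
#'   on the null tables).
#' @param pairs data.frame with `sample_i`, `sample_j` columns naming the
#'   within-group pairs to evaluate (e.g. from [similarity_lag_pairs()]);
#'   an optional `group` column yields per-group summaries.
#' @param n_null randomizations (>= 100).
#' @param seed integer seed.
#' @param metric distance metric for the null tables.
#' @param weighting passed to [null_communities()].
#' @return Object of class `null_partition`: list with `pair_table`
#'   (per-pair s_obs, s_null_mean, s_null_sd, determinism_fraction),
#'   `summary` (per-group determinism_pct, stochasticity_pct,
#'   determinism_pct_sym, stochasticity_pct_sym, n_pairs, mc_se),
#'   `n_null`, `seed`.
#' @export
partition_assembly <- function(table, D_obs, pairs, n_null = 999,
                               seed = NULL,
                               metric = c("bray_curtis", "sorensen"),
                               weighting = c("occurrence", "uniform")) {
  stopifnot(inherits(table, "community_table"))
  metric <- match.arg(metric)
  weighting <- match.arg(weighting)
  D_obs <- validate_distance_matrix(D_obs)
  assert_that(all(c("sample_i", "sample_j") %in% names(pairs)),
              "`pairs` needs sample_i / sample_j columns")
  ids <- rownames(D_obs)
  assert_that(all(c(pairs$sample_i, pairs$sample_j) %in% ids),
              "pair samples missing from D_obs")

  i_idx <- match(pairs$sample_i, ids)
  j_idx <- match(pairs$sample_j, ids)
  s_obs <- 1 - D_obs[cbind(i_idx, j_idx)]
  usable <- s_obs > 0
  if (any(!usable))
    warning(sum(!usable), " pair(s) with zero observed similarity excluded")

  nulls <- null_communities(table, n_null, seed = seed, weighting = weighting)
  # accumulate per-pair null similarities across randomizations
  s_sum <- numeric(nrow(pairs)); s_sqsum <- numeric(nrow(pairs))
  col_i <- match(pairs$sample_i, table$sample_ids)
  col_j <- match(pairs$sample_j, table$sample_ids)
  for (m in nulls) {
    dn <- as.matrix(vegan::vegdist(t(m), method = "bray",
                                   binary = (metric == "sorensen")))
    sn <- 1 - dn[cbind(col_i, col_j)]
    s_sum <- s_sum + sn
    s_sqsum <- s_sqsum + sn^2
  }
  s_null_mean <- s_sum / n_null
  s_null_sd <- sqrt(pmax(0, s_sqsum / n_null - s_null_mean^2) *
                      n_null / (n_null - 1))

  frac <- ifelse(usable, (s_obs - s_null_mean) / s_obs, NA_real_)
  pair_table <- data.frame(
    sample_i = pairs$sample_i, sample_j = pairs$sample_j,
    s_obs = s_obs, s_null_mean = s_null_mean, s_null_sd = s_null_sd,
    determinism_fraction = frac, stringsAsFactors = FALSE)
  if ("group" %in% names(pairs)) pair_table$group <- pairs$group

  grp <- if ("group" %in% names(pairs)) pairs$group else rep("all", nrow(pairs))
  summary <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), grp),
                                   function(rows) {
    f <- frac[rows]; f <- f[!is.na(f)]
    so <- s_obs[rows]; sn <- s_null_mean[rows]
    stoch <- pmin(sn[so > 0] / so[so > 0], 1)
    data.frame(
      group = grp[rows[1]],
      determinism_pct = 100 * mean(pmax(f, 0)),
      stochasticity_pct = 100 * mean(stoch),
      determinism_pct_sym = 100 * mean(f),
      stochasticity_pct_sym = 100 - 100 * mean(f),
      n_pairs = length(f),
      mc_se = 100 * stats::sd(f) / sqrt(length(f)),
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(pair_table = pair_table, summary = summary,
                 n_null = n_null, seed = seed, metric = metric,
                 weighting = weighting),
            class = "null_partition")
}

#' @export
print.null_partition <- function(x, ...) {
  cat("Null-model assembly partition (", x$n_null, " randomizations, ",
      x$metric, " similarity)\n", sep = "")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Contrast determinism between two partitions
#'
#' Percentage increase in the (truncated) determinism share of partition
#' A over partition B: `100 * (det_A - det_B) / det_B`, computed overall
#' and for every group label present in both partitions (e.g. seasons).
#'
#' @param part_a,part_b `null_partition` objects (e.g. disturbed site vs
#'   control).
#' @return List with `pct_increase` (overall, from the pooled per-pair
#'   fractions) and `by_group` (data.frame: group, det_a, det_b,
#'   pct_increase).
#' @export
determinism_contrast <- function(part_a, part_b) {
  stopifnot(inherits(part_a, "null_partition"),
            inherits(part_b, "null_partition"))
  det_of <- function(p) {
    f <- p$pair_table$determinism_fraction
    100 * mean(pmax(f[!is.na(f)], 0))
  }
  da <- det_of(part_a); db <- det_of(part_b)
  assert_that(db > 0, "reference partition has zero determinism share")
  shared <- intersect(part_a$summary$group, part_b$summary$group)
  by_group <- do.call(rbind, lapply(shared, function(g) {
    a <- part_a$summary$determinism_pct[part_a$summary$group == g]
    b <- part_b$summary$determinism_pct[part_b$summary$group == g]
    data.frame(group = g, det_a = a, det_b = b,
               pct_increase = if (b > 0) 100 * (a - b) / b else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pct_increase = 100 * (da - db) / db, by_group = by_group)
}
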