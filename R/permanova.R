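# Enumerate all permutations of 1..n (n! rows). Used for exact permutation
# p-values on small designs.
#' @keywords internal
#' @noRd
all_permutations <- function(n) {
  assert_that(n <= 8, "complete enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# Hat (projection) matrix of a design matrix, via QR for rank safety.
#' @keywords internal
#' @noRd
hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix,
#' `SS_total = (1/n) * sum_{i<j} d_ij^2`, among the terms of a model
#' formula via projections of the Gower-centered matrix (sequential,
#' Type-I sums of squares in formula order). Pseudo-F per term is the
#' term mean square over the residual mean square; significance comes
#' from free permutation of sample labels, with the +1 convention
#' (observed statistic counted in numerator and denominator) for sampled
#' permutations, or from complete enumeration of all `n!` relabellings
#' when `permutations = "exact"`.
#'
#' @param D symmetric distance matrix with sample IDs.
#' @param data data.frame of factors/covariates; either rownames or a
#'   `sample_id` column must match the IDs of `D`.
#' @param formula right-hand-side formula over columns of `data`, e.g.
#'   `~ day * site`. Interactions follow the usual formula syntax.
#' @param n_perm number of permutations (>= 99) when sampling.
#' @param seed integer seed for the permutation stream.
#' @param permutations `"sample"` (Monte-Carlo, default) or `"exact"`
#'   (all `n!` permutations; limited to n <= 8).
#' @return Object of class `permanova`: list with `aov_tab` (per-term df,
#'   SS, pseudo-F, R2, p, plus Residual and Total rows), `n_perm`, `seed`.
#' @export
permanova <- function(D, data, formula, n_perm = 999, seed = NULL,
                      permutations = c("sample", "exact")) {
  permutations <- match.arg(permutations)
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  data <- align_samples(data, rownames(D))
  if (permutations == "sample")
    assert_that(n_perm >= 99, "`n_perm` must be at least 99")

  G <- gower_center(D)
  ss_total <- sum(diag(G))

  trm <- stats::terms(formula, data = data)
  labels <- attr(trm, "term.labels")
  assert_that(length(labels) >= 1, "formula has no terms")
  for (v in all.vars(formula)) {
    vals <- data[[v]]
    if (is.character(vals) || is.factor(vals))
      assert_that(length(unique(vals)) >= 2,
                  paste0("term '", v, "' has fewer than 2 levels"))
  }

  # cumulative hat matrices: intercept, then one more term at a time
  hats <- vector("list", length(labels) + 1L)
  ranks <- integer(length(labels) + 1L)
  X <- matrix(1, n, 1)
  hats[[1]] <- hat_matrix(X); ranks[1] <- 1L
  for (k in seq_along(labels)) {
    f_k <- stats::reformulate(labels[seq_len(k)])
    X <- stats::model.matrix(f_k, data = data)
    hats[[k + 1]] <- hat_matrix(X)
    ranks[k + 1] <- qr(X)$rank
  }
  df_term <- diff(ranks)
  assert_that(all(df_term > 0),
              "confounded terms: design is singular for some term")
  df_res <- n - ranks[length(ranks)]
  assert_that(df_res > 0, "no residual degrees of freedom")

  ss_from_G <- function(Gp) {
    cum <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- diff(cum)
    ss_res <- sum(diag(Gp)) - cum[length(cum)]
    list(ss = ss, ss_res = ss_res)
  }
  obs <- ss_from_G(G)
  f_obs <- (obs$ss / df_term) / (obs$ss_res / df_res)

  if (permutations == "exact") {
    perms <- all_permutations(n)
    f_perm <- matrix(0, nrow(perms), length(labels))
    for (i in seq_len(nrow(perms))) {
      Gp <- G[perms[i, ], perms[i, ]]
      pr <- ss_from_G(Gp)
      f_perm[i, ] <- (pr$ss / df_term) / (pr$ss_res / df_res)
    }
    # identity permutation is one of the n!; p = share at least as extreme
    # (relative tolerance absorbs rounding noise among tied permutations)
    tol <- 1e-8 * pmax(1, abs(f_obs))
    p <- colMeans(sweep(f_perm, 2, f_obs - tol, ">="))
    n_perm_used <- nrow(perms)
  } else {
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        Gp <- G[idx, idx]
        pr <- ss_from_G(Gp)
        (pr$ss / df_term) / (pr$ss_res / df_res)
      }, numeric(length(labels)))
    })
    f_perm <- matrix(f_perm, ncol = n_perm)
    p <- vapply(seq_along(labels), function(k)
      perm_pvalue(f_obs[k], f_perm[k, ]), numeric(1))
    n_perm_used <- n_perm
  }

  aov_tab <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(df_term, df_res, n - 1L),
    ss = c(obs$ss, obs$ss_res, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  structure(list(aov_tab = aov_tab, n_perm = n_perm_used, seed = seed,
                 permutations = permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_perm, "permutations)\n")
  print(x$aov_tab, digits = 4, row.names = FALSE)
  invisible(x)
}

# Align a metadata/env data.frame to the sample order of a distance matrix.
#' @keywords internal
#' @noRd
align_samples <- function(data, ids) {
  assert_that(is.data.frame(data), "`data` must be a data.frame")
  if ("sample_id" %in% names(data)) {
    assert_that(all(ids %in% data$sample_id),
                "samples in D missing from `data`")
    data <- data[match(ids, data$sample_id), , drop = FALSE]
  } else if (!is.null(rownames(data)) && all(ids %in% rownames(data))) {
    data <- data[ids, , drop = FALSE]
  } else {
    assert_that(nrow(data) == length(ids),
                "`data` rows cannot be matched to samples of D")
  }
  rownames(data) <- ids
  data
}
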