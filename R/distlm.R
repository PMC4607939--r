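#' Distance-based linear model with marginal tests and forward selection
#'
#' Relates a community distance matrix to numeric environmental
#' variables through the same trace-form sum-of-squares machinery as
#' [permanova()]. Two tables are produced, mirroring the usual DistLM
#' report:
#'
#' * **marginal**: each variable fitted alone — pseudo-F, permutation p,
#'   and % variation `100 * SS_var / SS_total`;
#' * **sequential**: forward selection — at each step every remaining
#'   variable's conditional SS gain (given the variables already in the
#'   model) and conditional permutation p are computed, and the variable
#'   with the largest gain among those with `p <= selection_alpha` is
#'   added; selection stops when no candidate qualifies, and the stop
#'   reason is recorded.
#'
#' Constant (zero-variance) variables are excluded with a warning.
#' Permutation p-values use free permutation of sample labels of the
#' Gower-centered matrix with the +1 convention.
#'
#' @param D symmetric distance matrix with sample IDs.
#' @param env data.frame of numeric variables; rownames or a `sample_id`
#'   column must match `D`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @param selection_alpha significance level a candidate's conditional
#'   test must meet to enter the model (default 0.05).
#' @return Object of class `distlm`: list with `marginal` (data.frame:
#'   variable, pseudo_F, p, pct_variation), `sequential` (data.frame:
#'   variable, pseudo_F, p, pct_added, pct_cumulative), `stop_reason`,
#'   `excluded` (zero-variance variables), `n_perm`, `seed`.
#' @export
distlm <- function(D, env, n_perm = 999, seed = NULL,
                   selection_alpha = 0.05) {
  D <- validate_distance_matrix(D)
  n <- nrow(D)
  env <- align_samples(env, rownames(D))
  env <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
  assert_that(all(vapply(env, is.numeric, logical(1))),
              "all environmental variables must be numeric")
  assert_that(n_perm >= 99, "`n_perm` must be at least 99")

  sds <- vapply(env, stats::sd, numeric(1))
  excluded <- names(env)[sds == 0 | is.na(sds)]
  if (length(excluded)) {
    warning("excluding zero-variance variable(s): ",
            paste(excluded, collapse = ", "))
    env <- env[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  vars <- names(env)
  assert_that(length(vars) >= 1, "no usable environmental variables")

  G <- gower_center(D)
  ss_total <- sum(diag(G))
  seeds <- derive_seeds(if (is.null(seed)) sample.int(2^30, 1) else seed, 2L)
  perm_idx <- with_seed(seeds[1],
                        replicate(n_perm, sample.int(n), simplify = FALSE))

  hat_for <- function(v) hat_matrix(cbind(1, as.matrix(env[v])))

  # -- marginal tests -------------------------------------------------
  marginal <- do.call(rbind, lapply(vars, function(v) {
    H <- hat_for(v)
    # trace(H G); the intercept contributes 0 because G is doubly centered
    ss <- sum(H * G)
    f_obs <- ss / ((ss_total - ss) / (n - 2))
    f_perm <- vapply(perm_idx, function(idx) {
      Gp <- G[idx, idx]
      ssp <- sum(H * Gp)
      ssp / ((ss_total - ssp) / (n - 2))
    }, numeric(1))
    data.frame(variable = v, pseudo_F = f_obs, p = perm_pvalue(f_obs, f_perm),
               pct_variation = 100 * ss / ss_total, stringsAsFactors = FALSE)
  }))
  marginal <- marginal[order(-marginal$pct_variation), ]
  rownames(marginal) <- NULL

  # -- forward selection ----------------------------------------------
  selected <- character(0)
  seq_rows <- list()
  stop_reason <- NULL
  perm_idx2 <- with_seed(seeds[2],
                         replicate(n_perm, sample.int(n), simplify = FALSE))
  repeat {
    remaining <- setdiff(vars, selected)
    if (!length(remaining)) {
      stop_reason <- "all variables entered the model"
      break
    }
    H_sel <- if (length(selected)) hat_for(selected)
             else hat_matrix(matrix(1, n, 1))
    ss_sel <- sum(H_sel * G)
    p_sel <- length(selected)
    cand <- lapply(remaining, function(v) {
      H_new <- hat_for(c(selected, v))
      gain <- sum(H_new * G) - ss_sel
      df_res <- n - p_sel - 2
      f_obs <- gain / ((ss_total - ss_sel - gain) / df_res)
      f_perm <- vapply(perm_idx2, function(idx) {
        Gp <- G[idx, idx]
        g <- sum(H_new * Gp) - sum(H_sel * Gp)
        g / ((sum(diag(Gp)) - sum(H_sel * Gp) - g) / df_res)
      }, numeric(1))
      list(v = v, gain = gain, f = f_obs, p = perm_pvalue(f_obs, f_perm))
    })
    ok <- Filter(function(c) c$p <= selection_alpha && c$gain > 0, cand)
    if (!length(ok)) {
      stop_reason <- paste0(
        "stopped: no remaining variable improved the model at the ",
        "conditional test (alpha = ", selection_alpha, ")")
      break
    }
    best <- ok[[which.max(vapply(ok, `[[`, numeric(1), "gain"))]]
    selected <- c(selected, best$v)
    seq_rows[[length(seq_rows) + 1L]] <- data.frame(
      variable = best$v, pseudo_F = best$f, p = best$p,
      pct_added = 100 * best$gain / ss_total,
      pct_cumulative = 100 * (ss_sel + best$gain) / ss_total,
      stringsAsFactors = FALSE)
  }
  sequential <- if (length(seq_rows)) do.call(rbind, seq_rows)
                else data.frame(variable = character(0), pseudo_F = numeric(0),
                                p = numeric(0), pct_added = numeric(0),
                                pct_cumulative = numeric(0))
  structure(list(marginal = marginal, sequential = sequential,
                 stop_reason = stop_reason, excluded = excluded,
                 n_perm = n_perm, seed = seed),
            class = "distlm")
}

#' @export
print.distlm <- function(x, ...) {
  cat("Distance-based linear model (", x$n_perm, " permutations)\n", sep = "")
  cat("Marginal tests:\n")
  print(x$marginal, digits = 4, row.names = FALSE)
  cat("Sequential forward selection:\n")
  if (nrow(x$sequential)) print(x$sequential, digits = 4, row.names = FALSE)
  else cat("  (no variable selected)\n")
  cat(x$stop_reason, "\n")
  invisible(x)
}
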