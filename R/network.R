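#' Correlation matrix over core-OTU abundance profiles
#'
#' Pairwise Pearson (or Spearman) correlation of per-OTU abundance
#' profiles across samples, after a log(x + 1) transform of relative
#' abundances (a log-pseudocount variant is available). Zero-variance
#' OTUs are excluded with a warning, since their correlation is
#' undefined.
#'
#' @param core_table a `community_table` (typically post [core_otus()])
#'   with at least 4 samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"log1p"` (default, `log(relative abundance + 1)`),
#'   `"log_pseudo"` (`log(relative abundance + pseudocount)`, pseudocount
#'   = half the smallest nonzero proportion), or `"none"`.
#' @return Symmetric correlation matrix with unit diagonal, OTU IDs as
#'   dimnames.
#' @export
correlation_matrix <- function(core_table,
                               method = c("pearson", "spearman"),
                               transform = c("log1p", "log_pseudo", "none")) {
  stopifnot(inherits(core_table, "community_table"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  assert_that(n_samples(core_table) >= 4, "need at least 4 samples")
  rel <- relative_abundance(core_table)$counts
  x <- switch(transform,
              log1p = log1p(rel),
              log_pseudo = log(rel + min(rel[rel > 0]) / 2),
              none = rel)
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance OTU(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x), method = method)
  diag(r) <- 1
  r
}

# Unfold a sorted eigenvalue spectrum: fit a smooth low-order polynomial
# to the empirical cumulative spectral density and map eigenvalues
# through it, so spacings of the unfolded spectrum have unit mean
# density. Degenerate (tied) eigenvalues are collapsed first.
#' @keywords internal
#' @noRd
.unfold_spacings <- function(ev, degree = 5L, tol = 1e-8) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > tol)]  # drop degenerate copies
  n <- length(ev)
  if (n < 20) return(NULL)
  cum <- seq_len(n) / n
  deg <- min(degree, n - 2L)
  fit <- stats::lm(cum ~ poly(ev, deg))
  unfolded <- n * stats::fitted(fit)
  sp <- diff(sort(unfolded))
  sp <- sp[sp >= 0]
  if (!length(sp) || mean(sp) <= 0) return(NULL)
  sp / mean(sp)
}

# Chi-square goodness of fit of spacings to the Poisson form exp(-s),
# using equal-probability bins under Exp(1); bin count ceiling(sqrt(m)).
#' @keywords internal
#' @noRd
.poisson_gof_p <- function(spacings) {
  m <- length(spacings)
  if (m < 10) return(NA_real_)
  k <- max(3L, ceiling(sqrt(m)))
  edges <- stats::qexp(seq(0, 1, length.out = k + 1))
  edges[k + 1] <- Inf
  obs <- tabulate(findInterval(spacings, edges,
                               rightmost.closed = TRUE, left.open = TRUE) + 0L,
                  nbins = k)
  expd <- rep(m / k, k)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
}

#' Random-matrix-theory threshold selection
#'
#' Scans candidate similarity thresholds: at each `st` the correlation
#' matrix is hard-thresholded (`|r| < st` zeroed), its eigenvalue
#' spectrum is unfolded via a polynomial fit to the cumulative spectral
#' density, and the nearest-neighbour spacing distribution (NNSD) is
#' tested against the Poisson form `exp(-s)` by a chi-square test on
#' equal-probability bins (bin count `ceiling(sqrt(#spacings))`). The
#' chosen threshold is the smallest `st` whose NNSD is
#' Poisson-consistent (p > `alpha`) — the RMT signature of modular,
#' noise-free structure — while the unthresholded spectrum is not.
#'
#' @param corr symmetric correlation matrix (>= 30 OTUs for a meaningful
#'   spectrum).
#' @param scan candidate thresholds (default `seq(0.30, 0.99, 0.01)`).
#' @param alpha Poisson-consistency level (default 0.05).
#' @return List with `st` (chosen threshold or `NA` on failure),
#'   `diagnostics` (data.frame: st, p_poisson, n_spacings),
#'   `p_unthresholded`, `converged`.
#' @export
rmt_threshold <- function(corr, scan = seq(0.30, 0.99, by = 0.01),
                          alpha = 0.05) {
  assert_that(is.matrix(corr) && nrow(corr) == ncol(corr),
              "`corr` must be square")
  assert_that(nrow(corr) >= 30,
              "need at least 30 OTUs for a meaningful spectrum")
  p_of <- function(m) {
    sp <- .unfold_spacings(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (is.null(sp)) NA_real_ else .poisson_gof_p(sp)
  }
  p0 <- p_of(corr)
  diag_rows <- lapply(scan, function(st) {
    m <- corr
    m[abs(m) < st] <- 0
    sp <- .unfold_spacings(eigen(m, symmetric = TRUE,
                                 only.values = TRUE)$values)
    data.frame(st = st,
               p_poisson = if (is.null(sp)) NA_real_ else .poisson_gof_p(sp),
               n_spacings = if (is.null(sp)) 0L else length(sp))
  })
  diagnostics <- do.call(rbind, diag_rows)
  ok <- which(!is.na(diagnostics$p_poisson) & diagnostics$p_poisson > alpha)
  st <- if (length(ok)) diagnostics$st[min(ok)] else NA_real_
  list(st = st, diagnostics = diagnostics, p_unthresholded = p0,
       converged = !is.na(st))
}

#' Build a co-occurrence network at a similarity threshold
#'
#' Keeps every OTU pair with `|r| >= st` as a signed, undirected edge.
#' Isolated OTUs are dropped from the network, so the reported size is
#' the connected network size.
#'
#' @param corr symmetric correlation matrix with OTU dimnames.
#' @param st similarity threshold in (0, 1).
#' @return Object of class `eco_network`: list with `nodes`, `edges`
#'   (data.frame: otu_a, otu_b, r, sign), `st` and the `igraph` graph.
#' @export
build_network <- function(corr, st) {
  assert_that(st > 0 && st < 1, "`st` must be in (0, 1)")
  assert_that(!is.null(rownames(corr)), "`corr` needs OTU dimnames")
  m <- corr
  diag(m) <- 0
  ij <- which(abs(m) >= st & upper.tri(m), arr.ind = TRUE)
  assert_that(nrow(ij) > 0, paste0("no edges at st = ", st))
  edges <- data.frame(otu_a = rownames(m)[ij[, 1]],
                      otu_b = colnames(m)[ij[, 2]],
                      r = m[ij], sign = sign(m[ij]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("otu_a", "otu_b")],
                                     directed = FALSE)
  igraph::E(g)$r <- edges$r
  igraph::E(g)$sign <- edges$sign
  structure(list(nodes = igraph::V(g)$name, edges = edges, st = st,
                 graph = g),
            class = "eco_network")
}

#' Topology metrics of a co-occurrence network
#'
#' Reports the standard descriptors: number of nodes and links, average
#' degree `avgK = 2L/n`, average clustering coefficient (nodes of degree
#' < 2 contribute 0), average geodesic distance GD (mean shortest path
#' over connected pairs within components), modularity M of the
#' fast-greedy agglomerative partition, the R-squared of the
#' log-frequency versus log-degree least-squares line (power-law fit),
#' and the positive-edge fraction.
#'
#' @param net an `eco_network`.
#' @return List of metrics plus `modules`, the node-to-module membership.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "eco_network"))
  g <- net$graph
  n <- igraph::vcount(g); L <- igraph::ecount(g)
  assert_that(L >= 1, "empty network")
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0  # degree < 2 contributes 0
  gd <- igraph::mean_distance(g, unconnected = TRUE)
  fg <- igraph::cluster_fast_greedy(g)
  deg <- igraph::degree(g)
  tab <- table(deg[deg > 0])
  powerlaw_r2 <- if (length(tab) >= 3) {
    x <- log(as.numeric(names(tab))); y <- log(as.numeric(tab))
    summary(stats::lm(y ~ x))$r.squared
  } else NA_real_
  list(n_nodes = n, n_links = L, avgK = 2 * L / n, avgCC = mean(cc),
       GD = gd, modularity = igraph::modularity(fg),
       n_modules = length(fg), powerlaw_r2 = powerlaw_r2,
       positive_edge_fraction = positive_edge_fraction(net),
       modules = stats::setNames(igraph::membership(fg), igraph::V(g)$name))
}

#' Fraction of positive edges
#'
#' @param net an `eco_network`.
#' @return `count(sign > 0) / L`.
#' @export
positive_edge_fraction <- function(net) {
  stopifnot(inherits(net, "eco_network"))
  mean(net$edges$sign > 0)
}

# Degree-preserving randomization by repeated double-edge swaps:
# pick two edges (a-b, c-d), rewire to (a-d, c-b), rejecting swaps that
# would create self-loops or multi-edges. Runs until `target_success`
# successful swaps (or an attempt cap for rigid graphs).
#' @keywords internal
#' @noRd
.rewire_edges <- function(edges, target_success, max_attempts) {
  L <- nrow(edges)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(L)) assign(key(edges[i, 1], edges[i, 2]), TRUE, present)
  succ <- 0L; att <- 0L
  while (succ < target_success && att < max_attempts) {
    att <- att + 1L
    pick <- sample.int(L, 2L)
    a <- edges[pick[1], 1]; b <- edges[pick[1], 2]
    c_ <- edges[pick[2], 1]; d <- edges[pick[2], 2]
    if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == d || c_ == b) next                       # self-loop
    if (length(unique(c(a, b, c_, d))) < 4 &&
        (a == c_ || b == d)) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (exists(k1, present) || exists(k2, present) || k1 == k2) next
    rm(list = c(key(a, b), key(c_, d)), envir = present)
    assign(k1, TRUE, present); assign(k2, TRUE, present)
    edges[pick[1], ] <- c(a, d); edges[pick[2], ] <- c(c_, b)
    succ <- succ + 1L
  }
  list(edges = edges, successes = succ)
}

#' Degree-preserving random-network baseline
#'
#' Generates `n_rand` randomized versions of the network by repeated
#' double-edge swaps (targeting at least `10 * L` successful swaps per
#' replicate, rejecting self-loops and multi-edges), which preserve the
#' exact degree sequence, and recomputes average path length, average
#' clustering coefficient and fast-greedy modularity on each. Graphs too
#' rigid to rewire (e.g. cliques) simply return themselves, giving a
#' degenerate (zero-SD) baseline, which is reported.
#'
#' @param net an `eco_network` with at least 2 edges.
#' @param n_rand number of randomized networks (default 100).
#' @param seed integer seed.
#' @param swaps_per_edge target successful swaps per edge (default 10).
#' @return List with `GD`, `avgCC`, `modularity` (each `c(mean, sd)`),
#'   `swap_successes` (per replicate) and `n_rand`.
#' @export
random_baseline <- function(net, n_rand = 100, seed = NULL,
                            swaps_per_edge = 10) {
  stopifnot(inherits(net, "eco_network"))
  L <- nrow(net$edges)
  assert_that(L >= 2, "need at least 2 edges to rewire")
  em <- cbind(match(net$edges$otu_a, net$nodes),
              match(net$edges$otu_b, net$nodes))
  target <- ceiling(swaps_per_edge * L)
  cap <- 200L * target
  res <- with_seed(seed, lapply(seq_len(n_rand), function(i) {
    rw <- .rewire_edges(em, target, cap)
    g <- igraph::graph_from_edgelist(rw$edges, directed = FALSE)
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[is.na(cc)] <- 0
    c(GD = igraph::mean_distance(g, unconnected = TRUE),
      avgCC = mean(cc),
      modularity = igraph::modularity(igraph::cluster_fast_greedy(g)),
      successes = rw$successes)
  }))
  m <- do.call(rbind, res)
  stat <- function(col) c(mean = mean(m[, col]), sd = stats::sd(m[, col]))
  out <- list(GD = stat("GD"), avgCC = stat("avgCC"),
              modularity = stat("modularity"),
              swap_successes = m[, "successes"], n_rand = n_rand)
  if (any(m[, "successes"] < target))
    out$note <- "some replicates reached fewer swaps than targeted (rigid graph)"
  out
}
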