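test_that("PCoA reproduces planar geometry exactly", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  res <- pcoa(euclid_dm(sq))
  ev <- sort(res$eigenvalues, decreasing = TRUE)
  expect_lt(abs(ev[1] - 1), 1e-8)
  expect_lt(abs(ev[2] - 1), 1e-8)
  expect_true(all(abs(ev[3:4]) < 1e-8))
  # three collinear points: one positive axis
  line <- pcoa(euclid_dm(c(0, 1, 2)))
  expect_equal(sum(line$eigenvalues > 1e-8), 1)
  # equidistant points: n-1 equal eigenvalues (regular simplex)
  n <- 5
  Deq <- matrix(1, n, n); diag(Deq) <- 0
  dimnames(Deq) <- list(paste0("s", 1:n), paste0("s", 1:n))
  ev_eq <- pcoa(Deq)$eigenvalues
  expect_equal(ev_eq[1:(n - 1)], rep(ev_eq[1], n - 1), tolerance = 1e-10)
})

test_that("PCoA recovers Euclidean coordinates up to rotation", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  res <- pcoa(euclid_dm(X))
  expect_lt(procrustes_residual(X, res$coordinates), 1e-8)
  # and agrees with classical MDS
  cmd <- cmdscale(dist(X), k = 3, eig = TRUE)
  expect_equal(sort(res$eigenvalues, decreasing = TRUE)[1:3],
               cmd$eig[1:3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PERMANOVA reproduces the enumerable two-group oracle", {
  fx <- permanova_fixture()
  res <- permanova(fx$D, fx$meta, ~ g, permutations = "exact")
  tab <- res$aov_tab
  expect_equal(tab$ss[tab$term == "g"], 100)
  expect_equal(tab$ss[tab$term == "Total"], 101)
  expect_equal(tab$pseudo_F[tab$term == "g"], 200)
  expect_equal(tab$R2[tab$term == "g"], 100 / 101)
  expect_equal(tab$p[tab$term == "g"], 1 / 3)  # 8 of the 24 relabellings
  expect_equal(sum(tab$R2[tab$term != "Total"]), 1)
})

test_that("PERMANOVA agrees with an independent implementation", {
  set.seed(5)
  m <- matrix(rpois(8 * 24, 6), 8, dimnames = list(paste0("o", 1:8),
                                                   paste0("s", 1:24)))
  ct <- community_table(m)
  D <- distance_matrix(ct)
  md <- data.frame(sample_id = colnames(m),
                   f = rep(c("a", "b"), each = 12),
                   t = rep(c("x", "y", "z"), 8))
  mine <- permanova(D, md, ~ f * t, n_perm = 99, seed = 1)$aov_tab
  ref <- vegan::adonis2(as.dist(D) ~ f * t, data = md, permutations = 99,
                        by = "terms")
  expect_equal(mine$ss[1:4], ref$SumOfSqs[1:4], tolerance = 1e-10)
  expect_equal(mine$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$R2[1:4], ref$R2[1:4], tolerance = 1e-10)
})

test_that("PERMANOVA on 1-D Euclidean data equals classical one-way ANOVA", {
  set.seed(6)
  for (i in 1:5) {
    y <- rnorm(12)
    g <- factor(rep(c("a", "b"), each = 6))
    res <- permanova(euclid_dm(y), data.frame(g = g), ~ g, n_perm = 99,
                     seed = i)
    f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(res$aov_tab$pseudo_F[1], f_classic, tolerance = 1e-10)
  }
})

test_that("sampled permutation p matches exact enumeration within binomial error", {
  set.seed(7)
  y <- c(0.1, 0.9, 1.4, 3.1, 3.3, 4.0)
  md <- data.frame(g = rep(c("a", "b"), each = 3))
  D <- euclid_dm(y)
  p_exact <- permanova(D, md, ~ g, permutations = "exact")$aov_tab$p[1]
  p_samp <- permanova(D, md, ~ g, n_perm = 999, seed = 8)$aov_tab$p[1]
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_samp - p_exact), 3 * se + 2 / 999)
})

test_that("identical groups give near-zero R2 and confounding is caught", {
  m <- cbind(a = c(5, 1), b = c(1, 5), a2 = c(5, 1), b2 = c(1, 5))
  rownames(m) <- c("o1", "o2")
  D <- distance_matrix(community_table(m))
  md <- data.frame(g = c("g1", "g1", "g2", "g2"))  # each group = {a, b}
  res <- permanova(D, md, ~ g, n_perm = 99, seed = 1)
  expect_lt(res$aov_tab$R2[1], 1e-10)
  md2 <- data.frame(g = c("g1", "g1", "g2", "g2"),
                    h = c("u", "u", "v", "v"))
  expect_error(permanova(D, md2, ~ g + h, n_perm = 99, seed = 1),
               "confounded|levels")
})

test_that("ANOSIM matches vegan and its closed-form extremes", {
  # perfectly separated groups: R = 1
  D <- euclid_dm(c(0, 0.1, 0.2, 10, 10.1, 10.2))
  g <- rep(c("a", "b"), each = 3)
  expect_equal(anosim(D, g, n_perm = 99, seed = 1)$R, 1)
  # agreement with vegan on noisy data
  set.seed(8)
  m <- matrix(rpois(6 * 16, 5), 6, dimnames = list(paste0("o", 1:6),
                                                   paste0("s", 1:16)))
  D2 <- distance_matrix(community_table(m))
  g2 <- rep(c("a", "b"), 8)
  mine <- anosim(D2, g2, n_perm = 99, seed = 2)
  ref <- vegan::anosim(as.dist(D2), g2, permutations = 99)
  expect_equal(mine$R, unname(ref$statistic), tolerance = 1e-12)
  expect_error(anosim(D, c("a", "a", "a", "a", "a", "b"), 99), "singleton")
})

test_that("Mantel handles identity, affine maps and vegan agreement", {
  set.seed(9)
  D1 <- euclid_dm(matrix(rnorm(24), 8))
  expect_equal(mantel(D1, D1, n_perm = 99, seed = 1)$r, 1)
  D2 <- 0.3 + 2 * D1; diag(D2) <- 0
  expect_equal(mantel(D1, D2, n_perm = 99, seed = 1)$r, 1)
  D3 <- euclid_dm(matrix(rnorm(24), 8))
  mine <- mantel(D1, D3, n_perm = 99, seed = 3)
  ref <- vegan::mantel(as.dist(D1), as.dist(D3), permutations = 99)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  sp <- mantel(D1, D3, method = "spearman", n_perm = 99, seed = 3)
  refs <- vegan::mantel(as.dist(D1), as.dist(D3), method = "spearman",
                        permutations = 99)
  expect_equal(sp$r, unname(refs$statistic), tolerance = 1e-12)
})

test_that("DistLM marginal test saturates on its own variable", {
  set.seed(10)
  y <- rnorm(20)
  res <- distlm(euclid_dm(y), data.frame(y = y), n_perm = 99, seed = 1)
  expect_equal(res$marginal$pct_variation, 100, tolerance = 1e-6)
})

test_that("DistLM on orthogonal variables: conditional equals marginal, sums to 100", {
  n <- 16
  x1 <- scale(stats::poly(1:n, 2)[, 1], scale = FALSE)[, 1]
  x2 <- scale(stats::poly(1:n, 2)[, 2], scale = FALSE)[, 1]  # orthogonal
  X <- cbind(x1 = 3 * x1, x2 = x2)
  res <- distlm(euclid_dm(X), as.data.frame(X), n_perm = 99, seed = 2,
                selection_alpha = 1)
  expect_equal(sum(res$marginal$pct_variation), 100, tolerance = 1e-6)
  expect_equal(max(res$sequential$pct_cumulative), 100, tolerance = 1e-6)
  seq_shares <- res$sequential$pct_added[order(res$sequential$variable)]
  marg_shares <- res$marginal$pct_variation[order(res$marginal$variable)]
  expect_equal(seq_shares, marg_shares, tolerance = 1e-6)
})

test_that("DistLM stops immediately on pure noise and drops constants", {
  set.seed(11)
  D <- euclid_dm(rnorm(20))
  env <- data.frame(junk = rnorm(20), flat = rep(1, 20))
  expect_warning(res <- distlm(D, env, n_perm = 199, seed = 4), "zero-variance")
  expect_identical(res$excluded, "flat")
  expect_equal(nrow(res$sequential), 0)
  expect_match(res$stop_reason, "no remaining variable")
})
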