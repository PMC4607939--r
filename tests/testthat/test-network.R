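test_that("correlation matrix honours duplicated and mirrored profiles", {
  set.seed(30)
  base <- matrix(rpois(5 * 20, 20) + 1, 5,
                 dimnames = list(paste0("o", 1:5), paste0("s", 1:20)))
  m <- rbind(base, dup = base[1, ])
  rownames(m)[6] <- "dup"
  corr <- correlation_matrix(community_table(m), transform = "none")
  expect_equal(corr["o1", "dup"], 1, tolerance = 1e-12)
  expect_error(correlation_matrix(community_table(base[, 1:3])), "4 samples")
  # zero-variance OTU (constant proportion: equal column totals) excluded
  m2 <- rbind(o1 = c(10L, 20L, 30L, 40L), o2 = c(40L, 30L, 20L, 10L),
              flat = rep(5L, 4))
  colnames(m2) <- paste0("s", 1:4)
  ct2 <- community_table(m2)
  expect_warning(c2 <- correlation_matrix(ct2, transform = "none"),
                 "zero-variance")
  expect_false("flat" %in% rownames(c2))
})

test_that("network construction thresholds and signs edges", {
  k3 <- matrix(0.95, 3, 3); diag(k3) <- 1
  dimnames(k3) <- list(letters[1:3], letters[1:3])
  net <- build_network(k3, 0.9)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes, letters[1:3])
  # negative correlations keep their sign
  mneg <- k3; mneg["a", "b"] <- mneg["b", "a"] <- -0.95
  netn <- build_network(mneg, 0.9)
  expect_equal(netn$edges$sign[netn$edges$otu_a == "a" &
                                 netn$edges$otu_b == "b"], -1)
  expect_error(build_network(k3, 0.99), "no edges")
  expect_error(build_network(k3, 1.2), "0, 1")
})

test_that("edge sets are nested in the threshold", {
  set.seed(31)
  tb <- generate_blocked_taxa(40, 60, 3, 6, 0.8, seed = 1)
  corr <- correlation_matrix(tb)
  edges_at <- function(st) {
    net <- try(build_network(corr, st), silent = TRUE)
    if (inherits(net, "try-error")) character(0)
    else paste(net$edges$otu_a, net$edges$otu_b)
  }
  e1 <- edges_at(0.5); e2 <- edges_at(0.7); e3 <- edges_at(0.9)
  expect_true(all(e2 %in% e1))
  expect_true(all(e3 %in% e2))
})

test_that("topology metrics match closed forms", {
  k3 <- matrix(0.95, 3, 3); diag(k3) <- 1
  dimnames(k3) <- list(letters[1:3], letters[1:3])
  t3 <- topology(build_network(k3, 0.9))
  expect_equal(t3$avgK, 2); expect_equal(t3$avgCC, 1); expect_equal(t3$GD, 1)
  # star S4: hub plus 4 leaves
  s4 <- matrix(0, 5, 5); s4[1, 2:5] <- s4[2:5, 1] <- 0.95; diag(s4) <- 1
  dimnames(s4) <- list(letters[1:5], letters[1:5])
  t4 <- topology(build_network(s4, 0.9))
  expect_equal(t4$avgCC, 0)
  expect_equal(t4$GD, 1.6)  # (4*1 + 6*2) / 10 pairs
  expect_equal(t4$avgK, 8 / 5)
})

test_that("fast-greedy modularity matches hand-computed partitions", {
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- 0.95; m[5:8, 5:8] <- 0.95
  m[4, 5] <- m[5, 4] <- 0.95; diag(m) <- 1
  dimnames(m) <- list(letters[1:8], letters[1:8])
  tb <- topology(build_network(m, 0.9))
  expect_equal(tb$modularity, 12 / 13 - 1 / 2, tolerance = 1e-12)
  expect_equal(tb$n_modules, 2)
  # disconnected pair of triangles: M = 0.5 for the component partition
  m2 <- matrix(0, 6, 6); m2[1:3, 1:3] <- 0.95; m2[4:6, 4:6] <- 0.95
  diag(m2) <- 1; dimnames(m2) <- list(letters[1:6], letters[1:6])
  t6 <- topology(build_network(m2, 0.9))
  expect_gte(t6$modularity, 0.5 - 1e-12)
})

test_that("positive edge fraction counts signs", {
  m <- matrix(0, 9, 9)
  for (i in 1:8) m[i, i + 1] <- m[i + 1, i] <- 0.95
  m[1, 2] <- m[2, 1] <- -0.95  # one negative of 8
  diag(m) <- 1; dimnames(m) <- list(letters[1:9], letters[1:9])
  net <- build_network(m, 0.9)
  expect_equal(positive_edge_fraction(net), 7 / 8)
  expect_equal(positive_edge_fraction(net),
               1 - mean(net$edges$sign < 0))
})

test_that("degree-preserving rewiring keeps every degree sequence", {
  set.seed(32)
  tb <- generate_blocked_taxa(30, 80, 3, 6, 0.85, seed = 2)
  corr <- correlation_matrix(tb)
  net <- build_network(corr, 0.6)
  em <- cbind(match(net$edges$otu_a, net$nodes),
              match(net$edges$otu_b, net$nodes))
  deg_obs <- tabulate(em, nbins = length(net$nodes))
  set.seed(33)
  for (i in 1:10) {
    rw <- microtempo:::.rewire_edges(em, 10 * nrow(em), 2000 * nrow(em))
    expect_identical(tabulate(rw$edges, nbins = length(net$nodes)), deg_obs)
    expect_gt(rw$successes, 0)
  }
  base <- random_baseline(net, n_rand = 20, seed = 3)
  expect_true(all(base$swap_successes > 0))
  expect_true(all(is.finite(base$GD)))
  # a clique cannot be rewired: identical metrics, zero SD
  k4 <- matrix(0.95, 4, 4); diag(k4) <- 1
  dimnames(k4) <- list(letters[1:4], letters[1:4])
  cl <- random_baseline(build_network(k4, 0.9), n_rand = 10, seed = 4)
  expect_equal(unname(cl$GD["sd"]), 0)
  expect_equal(unname(cl$avgCC["mean"]), 1)
})

test_that("modular graphs lose modularity under rewiring", {
  corr <- planted_corr_table(n_otus = 60, n_samples = 200, n_blocks = 5,
                             block_size = 10, block_rho = 0.9)$corr
  net <- build_network(corr, 0.6)
  top <- topology(net)
  base <- random_baseline(net, n_rand = 30, seed = 5)
  expect_lt(unname(base$modularity["mean"]), top$modularity)
})

test_that("RMT threshold separates planted blocks from background", {
  fx <- planted_corr_table()
  rt <- rmt_threshold(fx$corr)
  expect_true(rt$converged)
  within_r <- mean(abs(fx$corr[1:8, 1:8][upper.tri(diag(8))]))
  bg_idx <- which(fx$blocks == 0)
  bg_r <- mean(abs(fx$corr[bg_idx, bg_idx][upper.tri(diag(length(bg_idx)))]))
  expect_gt(rt$st, bg_r)
  expect_lt(rt$st, within_r)
  net <- build_network(fx$corr, rt$st)
  comp <- igraph::components(net$graph)
  recovered <- lapply(split(names(comp$membership), comp$membership), sort)
  planted <- lapply(split(fx$table$otu_ids[fx$blocks > 0],
                          fx$blocks[fx$blocks > 0]), sort)
  expect_setequal(unname(vapply(recovered, paste, "", collapse = ",")),
                  unname(vapply(planted, paste, "", collapse = ",")))
})

test_that("RMT scan reports failure on an identity matrix", {
  id <- diag(40); dimnames(id) <- list(paste0("o", 1:40), paste0("o", 1:40))
  rt <- rmt_threshold(id)
  expect_false(rt$converged)
  expect_true(is.na(rt$st))
  expect_error(build_network(id, 0.5), "no edges")
  small <- diag(10); dimnames(small) <- list(letters[1:10], letters[1:10])
  expect_error(rmt_threshold(small), "at least 30")
})
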