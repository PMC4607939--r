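turnover_fixture <- function() {
  # 2 sites x 3 days x 2 replicates with known geometry
  days <- c(1, 6, 60)
  meta <- expand.grid(site = c("A", "B"), day = days, rep = 1:2,
                      stringsAsFactors = FALSE)
  meta$sample_id <- with(meta, paste0(site, "_d", day, "_r", rep))
  set.seed(20)
  m <- matrix(rpois(30 * nrow(meta), 10), 30,
              dimnames = list(paste0("o", 1:30), meta$sample_id))
  list(D = distance_matrix(community_table(m)), meta = meta)
}

test_that("lag pairs are counted and computed correctly", {
  fx <- turnover_fixture()
  pr <- similarity_lag_pairs(fx$D, fx$meta, group = "A")
  # 6 samples: 15 pairs = 12 cross-time + 3 lag-0
  expect_equal(nrow(pr$pairs), 12)
  expect_equal(nrow(pr$lag0), 3)
  expect_setequal(unique(pr$pairs$lag_days), c(5, 54, 59))
  expect_true(all(pr$pairs$similarity >= 0 & pr$pairs$similarity <= 1))
  # identical samples at a positive lag have similarity 1
  m <- cbind(a = c(3, 1), b = c(3, 1)); rownames(m) <- c("o1", "o2")
  D <- distance_matrix(community_table(m))
  meta <- data.frame(sample_id = c("a", "b"), day = c(1, 6))
  expect_equal(similarity_lag_pairs(D, meta)$pairs$similarity, 1)
  expect_error(similarity_lag_pairs(D, data.frame(sample_id = c("a", "b"),
                                                  day = c(3, 3))),
               "single time point")
})

test_that("an exact power law is recovered to machine precision", {
  lags <- c(5, 54, 59, 88, 142, 147)
  pairs <- data.frame(lag_days = lags, similarity = 0.5 * lags^(-0.1))
  fit <- tdr_fit(pairs)
  expect_equal(fit$slope, -0.1, tolerance = 1e-10)
  expect_equal(fit$w, 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, log10(0.5), tolerance = 1e-10)
  # constant similarity: zero slope
  flat <- data.frame(lag_days = lags, similarity = rep(0.4, 6))
  expect_equal(tdr_fit(flat)$w, 0)
})

test_that("mean-per-lag aggregation averages before regressing", {
  pairs <- data.frame(lag_days = c(5, 5, 50, 50, 500, 500),
                      similarity = c(0.6, 0.8, 0.5, 0.7, 0.4, 0.6))
  fit <- tdr_fit(pairs)
  by_hand <- lm(log10(c(0.7, 0.6, 0.5)) ~ log10(c(5, 50, 500)))
  expect_equal(fit$slope, unname(coef(by_hand)[2]), tolerance = 1e-12)
  # all-pairs mode uses every point
  fit2 <- tdr_fit(pairs, aggregation = "all-pairs")
  expect_equal(fit2$n_points, 6)
})

test_that("the slope is invariant to rescaling the lags", {
  pairs <- data.frame(lag_days = c(2, 11, 29, 53),
                      similarity = c(0.7, 0.55, 0.5, 0.42))
  f1 <- tdr_fit(pairs)
  pairs2 <- transform(pairs, lag_days = lag_days * 7)
  f2 <- tdr_fit(pairs2)
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(f1$intercept, f2$intercept)))
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(tdr_fit(data.frame(lag_days = c(1, 2), similarity = c(1, 1))),
               "3 distinct lags")
  expect_error(tdr_fit(data.frame(lag_days = c(0, 1, 2, 3),
                                  similarity = rep(0.5, 4))), "lag-0")
  expect_warning(
    tdr_fit(data.frame(lag_days = c(1, 2, 3, 4),
                       similarity = c(0.5, 0.4, 0, 0.3))), "dropped")
})

test_that("zero-slope test behaves at the extremes", {
  lags <- c(5, 54, 59, 88, 142, 147)
  flat <- data.frame(lag_days = rep(lags, each = 2),
                     similarity = rep(0.4, 12))
  fit <- tdr_fit(flat)
  res <- slope_test_zero(fit, flat, n_boot = 199, seed = 1)
  expect_gt(res$p, 0.99)  # every permutation ties the zero slope
  steep <- data.frame(lag_days = lags, similarity = 0.5 * lags^(-0.4))
  fit2 <- tdr_fit(steep)
  res2 <- slope_test_zero(fit2, steep, n_boot = 199, seed = 1)
  expect_equal(res2$p, 1 / 200)  # grid minimum
  expect_error(slope_test_zero(fit2, steep, n_boot = 50), "at least 100")
})

test_that("sample-level bootstrap produces a usable slope distribution", {
  ds <- generate_dataset(sim_config(n_otus_pool = 150,
                                    reads_per_sample = 600, seed = 5))
  D <- distance_matrix(ds$table)
  pr <- similarity_lag_pairs(D, ds$meta, group = "control")
  fit <- tdr_fit(pr$pairs)
  res <- slope_test_zero(fit, pr$pairs, n_boot = 100, seed = 2,
                         D = D, meta = ds$meta, group = "control")
  expect_gt(length(res$boot_slopes), 50)
  expect_lt(res$boot_ci[1], res$boot_ci[2])
  expect_true(is.finite(res$t_test_p))
})

test_that("turnover rate ordering follows the generating process", {
  ok <- vapply(1:10, function(s) {
    w_of <- function(theta) {
      ds <- generate_dataset(sim_config(n_otus_pool = 200,
                                        reads_per_sample = 1000,
                                        turnover_theta = theta, seed = s))
      D <- distance_matrix(ds$table)
      tdr_fit(similarity_lag_pairs(D, ds$meta, group = "control")$pairs)$w
    }
    w_of(0.008) > w_of(0.002)
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("compare_slopes is null for identical groups and detects contrast", {
  fx <- turnover_fixture()
  # identical distance structure between the two site labels: delta near 0
  ds <- generate_dataset(sim_config(n_otus_pool = 150,
                                    reads_per_sample = 600, seed = 9))
  D <- distance_matrix(ds$table)
  res <- compare_slopes(D, ds$meta, "control", "farm", n_perm = 199, seed = 1)
  expect_equal(res$delta_w, res$w_a - res$w_b)
  expect_true(res$p > 0.001)
})

test_that("within-group similarity summarises pairs and contrasts groups", {
  m <- cbind(a1 = c(4, 4), a2 = c(4, 4), a3 = c(4, 4), a4 = c(4, 4),
             b1 = c(9, 1), b2 = c(1, 9))
  rownames(m) <- c("o1", "o2")
  D <- distance_matrix(community_table(m))
  meta <- data.frame(sample_id = colnames(m),
                     site = c(rep("A", 4), rep("B", 2)))
  res <- within_group_similarity(D, meta, n_perm = 99, seed = 1)
  a_row <- res$summary[res$summary$group == "A", ]
  expect_equal(a_row$mean, 1)   # identical samples
  expect_equal(a_row$sd, 0)
  expect_equal(a_row$n_pairs, 6)  # choose(4, 2)
  expect_equal(res$summary$n_pairs[res$summary$group == "B"], 1)
  expect_true(res$p <= 1 && res$p >= 1 / 100)
})
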