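#' Configuration for the synthetic community generator
#'
#' Bundles and validates the parameters of the simulation model used to
#' validate every downstream statistic against a known ground truth. The
#' defaults emulate a seasonal coastal sampling design: 2 sites x 6 time
#' points x 4 replicates, an even depth of 3870 reads per sample, and
#' sampling days 1, 6, 60, 66, 148, 153 (pairs of cruises within three
#' seasons, so both ~5-day and ~2-season lags are represented).
#'
#' The community model: each taxon has a lognormal base abundance; on top
#' of it a discrete-time Ornstein-Uhlenbeck (mean-reverting Gaussian)
#' process on log abundance, independent per site, makes composition
#' temporally autocorrelated so that expected between-time similarity
#' decays with lag at a rate set by `turnover_theta`. Environmental
#' filtering multiplies sampling probabilities by
#' `exp(-filter_strength * (optimum - environment)^2)` on one latent
#' seasonal axis; `filter_strength = 0` is neutral. A site effect adds a
#' site-specific taxon preference of magnitude `site_effect`; with
#' `filter_strength = 0` and `site_effect = 0` the two sites are
#' exchangeable draws from one process. Observed counts are multinomial
#' draws of `reads_per_sample` reads; replicates are independent draws at
#' the same time point.
#'
#' @param n_otus_pool taxa in the regional pool (default 500).
#' @param n_sites,n_timepoints,n_replicates design dimensions (2, 6, 4).
#' @param reads_per_sample fixed sequencing depth (3870).
#' @param sampling_days strictly increasing integer days, one per time point.
#' @param turnover_theta mean-reversion rate of the latent process per day;
#'   larger values mean faster compositional turnover (default 0.002,
#'   which yields turnover rates and within-site similarities on the
#'   scale reported for coastal bacterioplankton time series).
#' @param latent_sd stationary standard deviation of the OU fluctuation on
#'   log abundance (default 1.5).
#' @param replicate_sd standard deviation of independent per-sample
#'   lognormal noise on log abundance (default 1.5), representing local
#'   patchiness among replicate water samples; it lowers similarity at
#'   every lag without altering the log-log decay slope.
#' @param base_sd standard deviation of lognormal base log abundances
#'   (default 1.5).
#' @param filter_strength weight of environmental matching (0 = neutral).
#' @param site_effect magnitude of site-specific taxon preferences.
#' @param n_corr_blocks,block_size,block_rho planted taxon-correlation
#'   blocks injected into the table (0 blocks by default); see
#'   [generate_blocked_taxa()] for the block model.
#' @param seed master seed; all child streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_otus_pool = 500L, n_sites = 2L, n_timepoints = 6L,
                       n_replicates = 4L, reads_per_sample = 3870L,
                       sampling_days = c(1L, 6L, 60L, 66L, 148L, 153L),
                       turnover_theta = 0.002, latent_sd = 1.5, base_sd = 1.5,
                       replicate_sd = 1.5,
                       filter_strength = 0, site_effect = 0,
                       n_corr_blocks = 0L, block_size = 0L, block_rho = 0,
                       seed = 1L) {
  dims <- c(n_otus_pool = n_otus_pool, n_sites = n_sites,
            n_timepoints = n_timepoints, n_replicates = n_replicates,
            reads_per_sample = reads_per_sample)
  assert_that(all(dims == round(dims)) && all(dims >= 1),
              "design dimensions must be positive integers")
  assert_that(length(sampling_days) == n_timepoints,
              "`sampling_days` must have one entry per time point")
  assert_that(all(sampling_days > 0) && all(diff(sampling_days) > 0),
              "`sampling_days` must be strictly increasing positive days")
  assert_that(turnover_theta >= 0, "`turnover_theta` must be nonnegative")
  assert_that(filter_strength >= 0, "`filter_strength` must be nonnegative")
  assert_that(site_effect >= 0, "`site_effect` must be nonnegative")
  assert_that(block_rho >= 0 && block_rho <= 1, "`block_rho` must be in [0,1]")
  assert_that(n_corr_blocks * block_size <= n_otus_pool,
              "correlation blocks exceed the taxon pool")
  structure(list(
    n_otus_pool = as.integer(n_otus_pool), n_sites = as.integer(n_sites),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    reads_per_sample = as.integer(reads_per_sample),
    sampling_days = as.integer(sampling_days),
    turnover_theta = turnover_theta, latent_sd = latent_sd, base_sd = base_sd,
    replicate_sd = replicate_sd,
    filter_strength = filter_strength, site_effect = site_effect,
    n_corr_blocks = as.integer(n_corr_blocks),
    block_size = as.integer(block_size), block_rho = block_rho,
    seed = as.integer(seed)), class = "sim_config")
}

# Stationary discrete-time OU path sampled at irregular days.
# Returns a n_taxa x n_times matrix with N(0, sd^2) marginals and
# corr(z_t, z_{t+dt}) = exp(-theta * dt).
#' @keywords internal
#' @noRd
.ou_path <- function(n_taxa, days, theta, sd) {
  z <- matrix(0, n_taxa, length(days))
  z[, 1] <- stats::rnorm(n_taxa, 0, sd)
  if (length(days) > 1) for (i in 2:length(days)) {
    rho <- exp(-theta * (days[i] - days[i - 1]))
    z[, i] <- z[, i - 1] * rho + stats::rnorm(n_taxa, 0, sd * sqrt(1 - rho^2))
  }
  z
}

# Seasonal latent environmental axis: a declining temperature-like trend,
# standardized over the sampled days.
#' @keywords internal
#' @noRd
.latent_env <- function(days) {
  e <- 28 - 0.12 * days
  if (length(days) < 2 || stats::sd(e) == 0) return(rep(0, length(days)))
  as.numeric(scale(e))
}

#' Generate a synthetic community dataset with known ground truth
#'
#' Draws an OTU count table, a sample metadata frame and an environmental
#' table from the model described in [sim_config()]. Every stochastic
#' ingredient is derived from `config$seed`, so the same configuration
#' reproduces bit-identical tables.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{table}{`community_table` of counts; every column sums to
#'       `reads_per_sample`.}
#'     \item{meta}{data.frame with `sample_id`, `site`, `season`, `day`,
#'       `replicate` (one row per sample).}
#'     \item{env}{data.frame of per-sample environmental variables:
#'       `temperature` (a deterministic function of the latent seasonal
#'       axis), `do` and `chla` (noisy correlates), `din` (site-shifted
#'       nutrient) and `noise` (pure noise).}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  seeds <- derive_seeds(cf$seed, 6L)
  K <- cf$n_otus_pool
  days <- cf$sampling_days
  env_axis <- .latent_env(days)

  base <- with_seed(seeds[1], stats::rnorm(K, 0, cf$base_sd))
  optima <- with_seed(seeds[2], stats::runif(K, min(env_axis) - 0.5,
                                             max(env_axis) + 0.5))
  site_pref <- with_seed(seeds[3],
                         matrix(stats::rnorm(K * cf$n_sites), K, cf$n_sites))
  ou <- with_seed(seeds[4], lapply(seq_len(cf$n_sites), function(s)
    .ou_path(K, days, cf$turnover_theta, cf$latent_sd)))

  site_names <- if (cf$n_sites == 2) c("control", "farm")
                else paste0("site", seq_len(cf$n_sites))
  otu_ids <- sprintf("OTU_%04d", seq_len(K))

  n_samp <- cf$n_sites * cf$n_timepoints * cf$n_replicates
  counts <- matrix(0L, K, n_samp)
  sample_id <- character(n_samp)
  meta_site <- character(n_samp); meta_day <- integer(n_samp)
  meta_rep <- integer(n_samp)

  j <- 0L
  counts_draw <- with_seed(seeds[5], {
    for (s in seq_len(cf$n_sites)) for (t in seq_len(cf$n_timepoints)) {
      lat <- base + cf$site_effect * site_pref[, s] + ou[[s]][, t]
      if (cf$filter_strength > 0)
        lat <- lat - cf$filter_strength * (optima - env_axis[t])^2
      p <- exp(lat - max(lat))
      p <- p / sum(p)
      for (r in seq_len(cf$n_replicates)) {
        j <- j + 1L
        p_r <- p * exp(stats::rnorm(K, 0, cf$replicate_sd))
        p_r <- p_r / sum(p_r)
        counts[, j] <- stats::rmultinom(1, cf$reads_per_sample, p_r)[, 1]
        sample_id[j] <- paste0(site_names[s], "_d", days[t], "_r", r)
        meta_site[j] <- site_names[s]; meta_day[j] <- days[t]; meta_rep[j] <- r
      }
    }
    counts
  })
  dimnames(counts_draw) <- list(otu_ids, sample_id)

  season <- cut(meta_day, breaks = c(-Inf, 30, 120, Inf),
                labels = c("summer", "autumn", "winter"))
  meta <- data.frame(sample_id = sample_id, site = meta_site,
                     season = as.character(season), day = meta_day,
                     replicate = meta_rep, stringsAsFactors = FALSE)

  env <- with_seed(seeds[6], {
    e <- env_axis[match(meta_day, days)]
    site_idx <- match(meta_site, site_names) - 1
    data.frame(
      sample_id = sample_id,
      temperature = 28 - 0.12 * meta_day,          # exactly the latent axis
      do = 8 - 1.2 * e + stats::rnorm(n_samp, 0, 0.3),
      din = 5 + 2 * cf$site_effect * site_idx + stats::rnorm(n_samp, 0, 0.5),
      chla = pmax(0.1, 2 + 0.8 * e + stats::rnorm(n_samp, 0, 0.6)),
      noise = stats::rnorm(n_samp),
      stringsAsFactors = FALSE)
  })

  list(table = community_table(counts_draw), meta = meta, env = env)
}

#' Generate a community table with planted taxon-correlation blocks
#'
#' Builds a taxa-by-samples table in which `n_blocks` disjoint groups of
#' `block_size` taxa share a common latent factor: each block taxon's
#' per-sample value is `sqrt(rho) * factor + sqrt(1 - rho) * noise`, so
#' the expected within-block pairwise correlation is `block_rho`, while
#' between-block and background correlations are 0. Latent values are
#' mapped affinely to nonnegative integer abundances, preserving the
#' correlation structure, which makes this the standard fixture for
#' testing correlation-network recovery.
#'
#' @param n_otus total taxa (blocks plus independent background taxa).
#' @param n_samples number of samples (columns).
#' @param n_blocks,block_size planted block layout;
#'   `n_blocks * block_size <= n_otus`.
#' @param block_rho target within-block correlation in \[0, 1\].
#' @param seed integer seed.
#' @param base_mean,base_sd affine map from latent N(0,1) values to
#'   abundances (`round(base_mean + base_sd * z)`, floored at 0).
#' @return A `community_table`; attribute `"block"` is an integer vector
#'   giving each OTU's block id (0 = background).
#' @export
generate_blocked_taxa <- function(n_otus, n_samples, n_blocks, block_size,
                                  block_rho, seed = 1L,
                                  base_mean = 100, base_sd = 15) {
  assert_that(block_rho >= 0 && block_rho <= 1, "`block_rho` must be in [0,1]")
  assert_that(n_blocks * block_size <= n_otus,
              "n_blocks * block_size exceeds n_otus")
  z <- with_seed(seed, {
    lat <- matrix(stats::rnorm(n_otus * n_samples), n_otus, n_samples)
    if (n_blocks > 0 && block_size > 0) {
      fac <- matrix(stats::rnorm(n_blocks * n_samples), n_blocks, n_samples)
      for (b in seq_len(n_blocks)) {
        rows <- ((b - 1) * block_size + 1):(b * block_size)
        lat[rows, ] <- sqrt(block_rho) * matrix(fac[b, ], block_size,
                                                n_samples, byrow = TRUE) +
          sqrt(1 - block_rho) * lat[rows, ]
      }
    }
    lat
  })
  counts <- pmax(round(base_mean + base_sd * z), 0)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sprintf("OTU_%04d", seq_len(n_otus)),
                           sprintf("S%03d", seq_len(n_samples)))
  block <- integer(n_otus)
  if (n_blocks > 0 && block_size > 0)
    block[seq_len(n_blocks * block_size)] <- rep(seq_len(n_blocks),
                                                 each = block_size)
  out <- community_table(counts)
  attr(out, "block") <- block
  out
}
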