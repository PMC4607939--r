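#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles inputs, metric, resampling effort and seeds for [run_all()].
#' A run is fully determined by its configuration: re-running the same
#' config reproduces byte-identical numeric outputs.
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` when reading
#'   from files.
#' @param table_path,meta_path,env_path input files (classic OTU table and
#'   TSVs) used when `sim` is `NULL`.
#' @param metric distance metric for all downstream statistics.
#' @param rarefy_depth even depth to rarefy to, or `NULL` to skip (the
#'   simulator already emits even-depth tables).
#' @param n_perm permutations for PERMANOVA/ANOSIM/DistLM and the
#'   within-group contrast.
#' @param n_boot TDR permutation/bootstrap replicates.
#' @param n_null null-model randomizations for the assembly partition.
#' @param network_scan candidate thresholds for [rmt_threshold()].
#' @param network_st manual similarity threshold overriding the RMT scan
#'   (`NULL` = automatic).
#' @param core_min_prevalence prevalence cutoff for core OTUs.
#' @param seed master seed; every stage derives its own stream from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), table_path = NULL,
                       meta_path = NULL, env_path = NULL,
                       metric = c("bray_curtis", "sorensen"),
                       rarefy_depth = NULL, n_perm = 999, n_boot = 999,
                       n_null = 999, network_scan = seq(0.5, 0.95, 0.01),
                       network_st = NULL, core_min_prevalence = 0.5,
                       seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(sim))
    assert_that(!is.null(table_path) && !is.null(meta_path),
                "either `sim` or input paths must be given")
  structure(list(sim = sim, table_path = table_path, meta_path = meta_path,
                 env_path = env_path, metric = metric,
                 rarefy_depth = rarefy_depth, n_perm = n_perm,
                 n_boot = n_boot, n_null = n_null,
                 network_scan = network_scan, network_st = network_st,
                 core_min_prevalence = core_min_prevalence,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @keywords internal
#' @noRd
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full temporal-community analysis
#'
#' Orchestrates the pipeline: simulate or ingest tables, optionally
#' rarefy, compute distance matrices, PCoA, PERMANOVA (`~ day * site`),
#' ANOSIM, DistLM on the environmental table, per-site time-decay fits
#' with slope tests and the between-site slope comparison, within-group
#' similarity, per-site null-model assembly partitions with the
#' site contrast, per-site core-OTU co-occurrence networks (RMT-chosen
#' threshold, topology, degree-preserving baselines) and the dominant-
#' taxa screen. Tabular outputs are TSV, summaries JSON; a manifest
#' records seeds and the emitted files, and stage runtimes go to a
#' separate `runtime.log` so numeric outputs stay run-to-run identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with all in-memory results and
#'   `manifest`.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 10L)
  t0 <- proc.time()[["elapsed"]]
  stage_log <- character(0)
  tick <- function(stage) {
    stage_log <<- c(stage_log,
                    sprintf("%s\t%.2fs", stage, proc.time()[["elapsed"]] - t0))
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$sim)) {
    ds <- generate_dataset(config$sim)
    table <- ds$table; meta <- ds$meta; env <- ds$env
  } else {
    table <- read_otu_table(config$table_path)
    meta <- utils::read.delim(config$meta_path, stringsAsFactors = FALSE)
    env <- if (!is.null(config$env_path))
      utils::read.delim(config$env_path, stringsAsFactors = FALSE) else NULL
  }
  if (!is.null(config$rarefy_depth))
    table <- rarefy(table, config$rarefy_depth, seed = seeds[1])
  write_otu_table(table, file.path(out_dir, "otu_table.tsv"))
  .write_tsv(meta, file.path(out_dir, "metadata.tsv"))
  if (!is.null(env)) .write_tsv(env, file.path(out_dir, "environment.tsv"))
  tick("inputs")

  # --- distances and ordination --------------------------------------
  D <- distance_matrix(table, metric = config$metric)
  write_distance_matrix(D, file.path(out_dir, "distance_matrix.tsv"))
  ord <- pcoa(D)
  .write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates, check.names = FALSE),
             file.path(out_dir, "pcoa_coordinates.tsv"))
  .write_tsv(data.frame(axis = seq_along(ord$eigenvalues),
                        eigenvalue = ord$eigenvalues),
             file.path(out_dir, "pcoa_eigenvalues.tsv"))
  tick("ordination")

  # --- PERMANOVA / ANOSIM / DistLM -----------------------------------
  meta_f <- meta
  meta_f$day_f <- factor(meta_f$day)
  perm <- permanova(D, meta_f, ~ day_f * site, n_perm = config$n_perm,
                    seed = seeds[2])
  .write_tsv(perm$aov_tab, file.path(out_dir, "permanova.tsv"))
  ano <- anosim(D, meta$site[match(rownames(D), meta$sample_id)],
                n_perm = config$n_perm, seed = seeds[3])
  dlm <- NULL
  if (!is.null(env)) {
    dlm <- distlm(D, env, n_perm = config$n_perm, seed = seeds[4])
    .write_tsv(dlm$marginal, file.path(out_dir, "distlm_marginal.tsv"))
    .write_tsv(dlm$sequential, file.path(out_dir, "distlm_sequential.tsv"))
  }
  tick("multivariate")

  # --- turnover -------------------------------------------------------
  sites <- unique(meta$site)
  tdr <- lapply(sites, function(s) {
    pr <- similarity_lag_pairs(D, meta, group = s)
    fit <- tdr_fit(pr$pairs)
    test <- slope_test_zero(fit, pr$pairs, n_boot = config$n_boot,
                            seed = seeds[5], D = D, meta = meta, group = s)
    .write_tsv(pr$pairs, file.path(out_dir, paste0("tdr_pairs_", s, ".tsv")))
    list(site = s, fit = fit, test = test)
  })
  names(tdr) <- sites
  cmp <- if (length(sites) == 2)
    compare_slopes(D, meta, sites[1], sites[2], n_perm = config$n_boot,
                   seed = seeds[6]) else NULL
  wgs <- within_group_similarity(D, meta, groups = sites,
                                 n_perm = config$n_perm, seed = seeds[7])
  .write_tsv(wgs$summary, file.path(out_dir, "within_group_similarity.tsv"))
  tick("turnover")

  # --- assembly -------------------------------------------------------
  parts <- lapply(sites, function(s) {
    members <- meta$sample_id[meta$site == s]
    sub <- community_table(table$counts[, members, drop = FALSE],
                           taxonomy = table$taxonomy)
    Dsub <- D[members, members, drop = FALSE]
    ij <- which(lower.tri(Dsub), arr.ind = TRUE)
    season <- meta$season[match(members, meta$sample_id)]
    pairs <- data.frame(sample_i = members[ij[, 2]],
                        sample_j = members[ij[, 1]],
                        stringsAsFactors = FALSE)
    # a pair belongs to a season only when both samples share it
    pairs$group <- ifelse(season[ij[, 1]] == season[ij[, 2]],
                          season[ij[, 1]], "cross-season")
    partition_assembly(sub, Dsub, pairs, n_null = config$n_null,
                       seed = seeds[8], metric = config$metric)
  })
  names(parts) <- sites
  for (s in sites)
    .write_tsv(parts[[s]]$summary,
               file.path(out_dir, paste0("assembly_summary_", s, ".tsv")))
  contrast <- if (length(sites) == 2)
    determinism_contrast(parts[[2]], parts[[1]]) else NULL
  tick("assembly")

  # --- networks -------------------------------------------------------
  nets <- lapply(sites, function(s) {
    members <- meta$sample_id[meta$site == s]
    sub <- community_table(table$counts[, members, drop = FALSE])
    core <- core_otus(sub, config$core_min_prevalence)
    corr <- correlation_matrix(core)
    st <- config$network_st
    rmt <- NULL
    if (is.null(st)) {
      rmt <- rmt_threshold(corr, scan = config$network_scan)
      st <- rmt$st
    }
    if (is.na(st) || max(abs(corr[upper.tri(corr)])) < st)
      return(list(site = s, core_n = n_otus(core), st = st, failed = TRUE,
                  rmt = rmt))
    net <- build_network(corr, st)
    top <- topology(net)
    base <- if (nrow(net$edges) >= 2)
      random_baseline(net, n_rand = 100, seed = seeds[9]) else NULL
    .write_tsv(net$edges, file.path(out_dir, paste0("network_edges_", s, ".tsv")))
    list(site = s, core_n = n_otus(core), st = st, rmt = rmt,
         network = net, topology = top, baseline = base, failed = FALSE)
  })
  names(nets) <- sites
  tick("networks")

  # --- dominant taxa --------------------------------------------------
  dom <- dominant_taxa(table)
  .write_tsv(data.frame(taxon = as.character(dom),
                        mean_rel_abundance = attr(dom, "mean_abundance")),
             file.path(out_dir, "dominant_taxa.tsv"))
  alpha <- alpha_diversity(table)
  .write_tsv(alpha, file.path(out_dir, "alpha_diversity.tsv"))
  tick("tables")

  # --- summary + manifest --------------------------------------------
  summary <- list(
    metric = config$metric,
    anosim = ano[c("R", "p")],
    permanova = perm$aov_tab,
    turnover = lapply(tdr, function(x)
      list(site = x$site, w = x$fit$w, intercept = x$fit$intercept,
           r_squared = x$fit$r_squared, p_slope_zero = x$test$p,
           t_test_p = x$test$t_test_p)),
    slope_comparison = cmp[c("delta_w", "w_a", "w_b", "p")],
    within_group_similarity = wgs,
    assembly = lapply(parts, `[[`, "summary"),
    determinism_contrast = contrast,
    networks = lapply(nets, function(x) {
      out <- x[c("site", "core_n", "st", "failed")]
      if (!isTRUE(x$failed)) out <- c(out, x$topology[
        c("n_nodes", "n_links", "avgK", "avgCC", "GD", "modularity",
          "n_modules", "powerlaw_r2", "positive_edge_fraction")],
        list(random_GD = x$baseline$GD, random_avgCC = x$baseline$avgCC,
             random_modularity = x$baseline$modularity))
      out
    }),
    dominant_taxa = as.character(dom))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    seed = config$seed, derived_seeds = seeds,
    n_perm = config$n_perm, n_boot = config$n_boot, n_null = config$n_null,
    files = sort(setdiff(list.files(out_dir),
                         c("manifest.json", "runtime.log"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(stage_log, file.path(out_dir, "runtime.log"))
  invisible(list(table = table, meta = meta, env = env, D = D, pcoa = ord,
                 permanova = perm, anosim = ano, distlm = dlm, tdr = tdr,
                 slope_comparison = cmp, within_group_similarity = wgs,
                 assembly = parts, determinism_contrast = contrast,
                 networks = nets, dominant_taxa = dom, summary = summary,
                 manifest = manifest))
}
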