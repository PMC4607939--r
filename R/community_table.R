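#' Community table construction and accessors
#'
#' A `community_table` holds an OTUs-by-samples abundance matrix together
#' with optional taxonomy lineages, the container consumed by every
#' downstream statistic in the package. Rows are taxa (OTUs), columns are
#' samples; entries are nonnegative counts, or proportions after
#' [relative_abundance()].
#'
#' @param counts numeric matrix, OTUs in rows and samples in columns, with
#'   unique rownames (OTU IDs) and colnames (sample IDs).
#' @param taxonomy optional named character vector mapping OTU IDs to
#'   semicolon-separated ranked lineages (`k__...;p__...;...;g__...`).
#' @return An object of class `community_table`: a list with elements
#'   `counts`, `otu_ids`, `sample_ids` and `taxonomy` (possibly `NULL`).
#' @examples
#' m <- matrix(c(5, 3, 2, 0, 1, 4), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
#' ct <- community_table(m)
#' n_samples(ct)
#' @export
community_table <- function(counts, taxonomy = NULL) {
  assert_that(is.matrix(counts) && is.numeric(counts),
              "`counts` must be a numeric matrix (OTUs x samples)")
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "`counts` needs OTU rownames and sample colnames")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate OTU IDs")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate sample IDs")
  assert_that(all(counts >= 0) && !anyNA(counts),
              "counts must be nonnegative and non-missing")
  if (!is.null(taxonomy)) {
    assert_that(is.character(taxonomy) && !is.null(names(taxonomy)),
                "`taxonomy` must be a named character vector")
    missing <- setdiff(rownames(counts), names(taxonomy))
    assert_that(length(missing) == 0,
                paste0("taxonomy missing for OTUs: ",
                       paste(utils::head(missing, 5), collapse = ", ")))
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(
    list(counts = counts, otu_ids = rownames(counts),
         sample_ids = colnames(counts), taxonomy = taxonomy),
    class = "community_table"
  )
}

#' @rdname community_table
#' @param x a `community_table`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname community_table
#' @export
n_otus <- function(x) length(x$otu_ids)

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", n_otus(x), "OTUs x", n_samples(x), "samples\n")
  cat("  taxonomy:", if (is.null(x$taxonomy)) "absent" else "present", "\n")
  tot <- colSums(x$counts)
  cat("  per-sample totals:", paste(format(range(tot)), collapse = " - "), "\n")
  invisible(x)
}

#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads uniformly without replacement down to a
#' common depth, the standard correction for unequal sequencing effort
#' before diversity and dissimilarity comparisons. Samples whose total is
#' below `depth` are dropped (with a message naming them). All-zero OTU
#' rows arising from the subsampling are retained unless `prune = TRUE`.
#'
#' @param table a `community_table` of integer counts.
#' @param depth target reads per sample (positive integer).
#' @param seed integer seed controlling the subsample; same seed, same table.
#' @param prune drop OTUs with all-zero rows afterwards? Default `FALSE`.
#' @return A rarefied `community_table`; attribute `"dropped_samples"`
#'   records samples below depth.
#' @export
rarefy <- function(table, depth, seed = NULL, prune = FALSE) {
  stopifnot(inherits(table, "community_table"))
  assert_that(length(depth) == 1 && depth >= 1 && depth == round(depth),
              "`depth` must be a positive integer")
  counts <- table$counts
  assert_that(all(counts == round(counts)),
              "rarefaction needs integer counts")
  tot <- colSums(counts)
  keep <- tot >= depth
  assert_that(any(keep), "all samples are below the rarefaction depth")
  dropped <- colnames(counts)[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  sub <- counts[, keep, drop = FALSE]
  # rrarefy's "smallest count" heuristic warning is noise for valid counts
  rare <- with_seed(seed, withCallingHandlers(
    t(vegan::rrarefy(t(sub), depth)),
    warning = function(w) {
      if (grepl("smallest count", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  dimnames(rare) <- dimnames(sub)
  if (prune) rare <- rare[rowSums(rare) > 0, , drop = FALSE]
  out <- community_table(rare, taxonomy = table$taxonomy[rownames(rare)])
  attr(out, "dropped_samples") <- dropped
  out
}

#' Convert counts to relative abundance
#'
#' @param table a `community_table` with positive column sums.
#' @return A `community_table` of proportions; every column sums to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "community_table"))
  tot <- colSums(table$counts)
  assert_that(all(tot > 0), paste0("zero-sum sample(s): ",
              paste(table$sample_ids[tot == 0], collapse = ", ")))
  community_table(sweep(table$counts, 2, tot, "/"), taxonomy = table$taxonomy)
}

# Parse "k__Bacteria;p__...;...": position in the lineage gives the rank.
.rank_index <- c(kingdom = 1L, phylum = 2L, class = 3L, order = 4L,
                 family = 5L, genus = 6L, species = 7L)

#' Aggregate a community table at a taxonomic rank
#'
#' Sums OTU rows sharing the same label at the requested rank of their
#' semicolon-separated lineage. OTUs whose lineage is missing, truncated
#' before the rank, or empty at the rank are pooled into `"Unassigned"`.
#' Column (sample) totals are conserved exactly.
#'
#' @param table a `community_table` with taxonomy.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A `community_table` with one row per rank label (no taxonomy).
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "community_table"))
  assert_that(!is.null(table$taxonomy), "table has no taxonomy map")
  rank <- match.arg(rank, names(.rank_index))
  idx <- .rank_index[[rank]]
  labels <- vapply(strsplit(table$taxonomy, ";", fixed = TRUE), function(parts) {
    if (length(parts) < idx) return("Unassigned")
    lab <- trimws(parts[idx])
    # bare rank prefixes like "f__" carry no assignment
    if (lab == "" || grepl("^[a-z]__$", lab)) "Unassigned" else lab
  }, character(1))
  agg <- rowsum(table$counts, group = labels)
  community_table(as.matrix(agg))
}

#' Dominant taxa by mean relative abundance
#'
#' Returns the taxa whose mean relative abundance across all samples is
#' strictly greater than `threshold`, the screen used to pick out the
#' handful of families that carry most of a community's signal.
#'
#' @param table a `community_table`; converted to relative abundance
#'   internally if columns do not already sum to 1.
#' @param threshold proportion in (0, 1); default 0.01 (i.e. > 1%).
#' @param group optional factor/character of length `n_samples(table)`;
#'   when given, a taxon qualifies if its mean exceeds the threshold in
#'   any group.
#' @return Character vector of taxon IDs, sorted by decreasing overall mean;
#'   attribute `"mean_abundance"` carries the means.
#' @export
dominant_taxa <- function(table, threshold = 0.01, group = NULL) {
  stopifnot(inherits(table, "community_table"))
  assert_that(threshold > 0 && threshold < 1, "`threshold` must be in (0,1)")
  tot <- colSums(table$counts)
  rel <- if (all(abs(tot - 1) < 1e-9)) table else relative_abundance(table)
  means <- rowMeans(rel$counts)
  if (is.null(group)) {
    hit <- means > threshold
  } else {
    assert_that(length(group) == n_samples(table),
                "`group` must have one entry per sample")
    gm <- vapply(split(seq_along(group), group),
                 function(j) rowMeans(rel$counts[, j, drop = FALSE]),
                 numeric(n_otus(table)))
    hit <- apply(gm > threshold, 1, any)
  }
  ids <- names(sort(means[hit], decreasing = TRUE))
  structure(ids, mean_abundance = means[ids])
}

#' Core OTUs by prevalence
#'
#' Retains OTUs detected (count > 0) in strictly more than
#' `min_prevalence` of the samples — the "core" community used for
#' co-occurrence network construction.
#'
#' @param table a `community_table`.
#' @param min_prevalence prevalence fraction in \[0, 1); default 0.5,
#'   i.e. present in more than half the samples.
#' @return A `community_table` restricted to the core OTUs.
#' @export
core_otus <- function(table, min_prevalence = 0.5) {
  stopifnot(inherits(table, "community_table"))
  assert_that(min_prevalence >= 0 && min_prevalence < 1,
              "`min_prevalence` must be in [0, 1)")
  prev <- rowMeans(table$counts > 0)
  keep <- prev > min_prevalence
  assert_that(any(keep), "no OTU exceeds the prevalence cutoff")
  community_table(table$counts[keep, , drop = FALSE],
                  taxonomy = table$taxonomy[keep])
}
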