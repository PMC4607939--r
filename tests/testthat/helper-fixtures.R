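# Shared fixtures, built in code at test time.

# tiny community table with taxonomy
tiny_table <- function() {
  m <- matrix(c(5L, 3L, 2L,
                0L, 1L, 4L,
                2L, 2L, 2L), nrow = 3, byrow = FALSE,
              dimnames = list(c("otu1", "otu2", "otu3"),
                              c("s1", "s2", "s3")))
  tax <- c(otu1 = "k__Bacteria;p__Bacteroidetes;c__Flavobacteriia;o__Flavobacteriales;f__Flavobacteriaceae;g__Polaribacter",
           otu2 = "k__Bacteria;p__Bacteroidetes;c__Flavobacteriia;o__Flavobacteriales;f__Flavobacteriaceae;g__Tenacibaculum",
           otu3 = "k__Bacteria;p__Proteobacteria;c__Alphaproteobacteria")
  community_table(m, taxonomy = tax)
}

# Euclidean distance matrix from a coordinate matrix, with IDs
euclid_dm <- function(x, ids = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(x)))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(ids, ids)
  d
}

# the 4-point 1-D two-group PERMANOVA oracle fixture
permanova_fixture <- function() {
  list(D = euclid_dm(c(0, 1, 10, 11)),
       meta = data.frame(sample_id = paste0("s", 1:4),
                         g = c("a", "a", "b", "b")))
}

# Procrustes residual after optimal translation/rotation/reflection
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  k <- min(ncol(Xc), ncol(Yc))
  Xc <- Xc[, 1:k, drop = FALSE]; Yc <- Yc[, 1:k, drop = FALSE]
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sum((Xc - Yc %*% R)^2)
}

# correlation matrix with planted blocks of high correlation on a noisy
# moderate background, built directly (valid for thresholding machinery)
planted_corr_table <- function(n_otus = 100, n_samples = 400, n_blocks = 6,
                               block_size = 8, block_rho = 0.9, seed = 3) {
  tb <- generate_blocked_taxa(n_otus, n_samples, n_blocks, block_size,
                              block_rho, seed = seed)
  list(table = tb, corr = correlation_matrix(tb),
       blocks = attr(tb, "block"))
}
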