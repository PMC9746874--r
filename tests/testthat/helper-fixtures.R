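# Small programmatic fixtures shared across test files.

# dense integer matrix with ids, coerced through the package validator
small_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  as_count_matrix(m)
}

# write a minimal 10x v2 triplet directory; entries is a data.frame/matrix
# with columns (row, col, value), 1-based
write_mtx_fixture <- function(dir, n_genes, n_cells, entries,
                              gene_file = "genes.tsv", gzip = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- as.matrix(entries)
  lines <- c("%%MatrixMarket matrix coordinate integer general",
             paste(n_genes, n_cells, nrow(entries)),
             if (nrow(entries) > 0)
               apply(entries, 1, paste, collapse = " "))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  gf <- file.path(dir, gene_file)
  con <- if (gzip) gzfile(gf) else file(gf)
  writeLines(paste0("G", seq_len(n_genes), "\tsym", seq_len(n_genes)), con)
  close(con)
  writeLines(paste0("BC", seq_len(n_cells)), file.path(dir, "barcodes.tsv"))
  dir
}

# exchangeable random count matrix for null-structure tests
random_counts <- function(n_genes, n_cells, seed, lambda_shape = 1,
                          lambda_mean = 0.5) {
  set.seed(seed)
  lam <- rgamma(n_genes, shape = lambda_shape,
                rate = lambda_shape / lambda_mean)
  m <- matrix(rpois(n_genes * n_cells, lam), n_genes, n_cells)
  small_counts(m, sprintf("g%04d", seq_len(n_genes)),
               sprintf("c%04d", seq_len(n_cells)))
}

ks_uniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(c(s - (seq_len(n) - 1) / n, s - seq_len(n) / n)))
}
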