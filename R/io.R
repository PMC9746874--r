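#' Validate a gene-by-cell count matrix
#'
#' Coerces to a sparse `dgCMatrix` with genes as rows and checks the count
#' invariants: non-negative integral entries and unique, non-empty gene and
#' cell identifiers in the dimnames.
#'
#' @param x A base matrix or `Matrix` with rownames (genes) and colnames
#'   (cells), or coercible to one.
#' @return A validated `dgCMatrix`, genes x cells.
#' @export
as_count_matrix <- function(x) {
  m <- if (is(x, "sparseMatrix")) {
    as(as(x, "CsparseMatrix"), "generalMatrix")
  } else {
    as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "generalMatrix")
  }
  if (!is(m, "dMatrix")) m <- as(m, "dMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  v <- m@x
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(v != round(v))) stop("counts must be integral")
  m
}

.open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else file(path)
}

.read_id_column <- function(path, what) {
  con <- .open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) == 0) stop("empty ", what, " file: ", path)
  ids <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  ids
}

.find_10x_file <- function(dir, candidates, what) {
  for (nm in candidates) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  stop("missing ", what, " file in ", dir,
       " (looked for: ", paste(candidates, collapse = ", "), ")")
}

#' Read a 10x Genomics Matrix Market count directory
#'
#' Reads the triplet matrix plus gene/feature and barcode id files from a
#' 10x-style directory, accepting both the v2 layout (`genes.tsv`) and the
#' v3 layout (`features.tsv.gz`), gzipped or not. The result always has
#' genes as rows, regardless of on-disk orientation, which is detected by
#' matching the matrix dimensions against the id files.
#'
#' @param path Directory containing `matrix.mtx[.gz]`, `genes.tsv` /
#'   `features.tsv[.gz]`, and `barcodes.tsv[.gz]`.
#' @return A genes x cells `dgCMatrix` with ids as dimnames.
#' @export
read_counts_mtx <- function(path) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  mtx <- .find_10x_file(path, c("matrix.mtx", "matrix.mtx.gz"), "matrix")
  gf <- .find_10x_file(
    path, c("genes.tsv", "genes.tsv.gz", "features.tsv", "features.tsv.gz"),
    "genes/features")
  bf <- .find_10x_file(path, c("barcodes.tsv", "barcodes.tsv.gz"), "barcodes")
  m <- Matrix::readMM(mtx)
  genes <- .read_id_column(gf, "gene")
  cells <- .read_id_column(bf, "barcode")
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    # canonical 10x orientation
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither ", length(genes), " genes x ",
         length(cells), " cells nor the transpose")
  }
  dimnames(m) <- list(genes, cells)
  as_count_matrix(m)
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a dense delimited count table
#'
#' Reads a CSV/TSV with a header row and ids in the first column. Genes may
#' be on rows (default) or columns; the result always has genes as rows.
#'
#' @param path Delimited text file.
#' @param genes_in `"rows"` or `"columns"`.
#' @return A genes x cells `dgCMatrix`.
#' @export
read_counts_table <- function(path, genes_in = c("rows", "columns")) {
  genes_in <- match.arg(genes_in)
  sep <- .sniff_sep(path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- ids
  if (genes_in == "columns") m <- t(m)
  as_count_matrix(m)
}

#' Read per-cell group labels
#'
#' Reads a two-column TSV (cell_id, group) mapping each cell to group 1 or
#' 2. Cells of `cell_ids` absent from the file are dropped with a warning;
#' labelled cells absent from `cell_ids` are ignored.
#'
#' @param path Two-column TSV, no header required (a `cell_id` header line
#'   is skipped if present).
#' @param cell_ids Cell ids of the count matrix to align against.
#' @return Named integer vector of 1/2 labels over the retained cells.
#' @export
read_group_labels <- function(path, cell_ids) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group label file needs two columns: ", path)
  if (tolower(df[1, 1]) %in% c("cell_id", "cell", "barcode"))
    df <- df[-1, , drop = FALSE]
  labs <- df[[2]]
  names(labs) <- as.character(df[[1]])
  keep <- cell_ids[cell_ids %in% names(labs)]
  if (length(keep) < length(cell_ids))
    warning(length(cell_ids) - length(keep),
            " cells have no group label and were dropped")
  out <- as.integer(labs[keep])
  if (!all(out %in% c(1L, 2L))) stop("group labels must be 1 or 2")
  names(out) <- keep
  out
}

#' Write a 10x-style Matrix Market count directory
#'
#' @param counts Genes x cells count matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a HEART result table to TSV
#'
#' Columns: gene_id, m1, m2, L1, L2, L3, Q, p, q, is_de. Numeric columns
#' are written with 15 significant digits so that a round-trip read
#' reproduces the values to at least 12 significant digits.
#'
#' @param results A `heart_result` object or its `$table` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_heart_results <- function(results, path) {
  tab <- if (inherits(results, "heart_result")) results$table else results
  cols <- c("gene_id", "m1", "m2", "L1", "L2", "L3", "Q", "p", "q", "is_de")
  if (!all(cols %in% names(tab)))
    stop("result table is missing columns: ",
         paste(setdiff(cols, names(tab)), collapse = ", "))
  out <- tab[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x)
    format(x, digits = 15, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a HEART result table written by [write_heart_results()]
#'
#' @param path TSV file.
#' @return Data frame with the standard result columns.
#' @export
read_heart_results <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_de <- as.logical(df$is_de)
  df
}
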