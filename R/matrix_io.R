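#' Sparse UMI count matrices
#'
#' A count matrix is represented as a `Matrix::dgCMatrix` of non-negative
#' integer UMI counts with genes in rows (rownames = gene ids) and barcodes
#' in columns (colnames = barcode ids). Gene symbols, when present in the
#' feature annotation, travel in the `"gene_symbols"` attribute; they are
#' used only for mitochondrial filtering and may duplicate, whereas gene
#' ids must be unique.
#'
#' @name count-matrix
NULL

# Validate the count-matrix contract; returns the matrix invisibly.
validate_count_matrix <- function(m) {
  if (!is(m, "sparseMatrix")) stop("count matrix must be a sparse Matrix", call. = FALSE)
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("count matrix entries must be non-negative integers", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must carry gene ids (rownames) and barcode ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("gene ids must be unique", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("barcode ids must be unique", call. = FALSE)
  invisible(m)
}

# Construct a validated dgCMatrix count matrix from parts.
make_count_matrix <- function(counts, gene_ids, barcode_ids, gene_symbols = NULL) {
  m <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(gene_ids, barcode_ids)
  if (!is.null(gene_symbols)) attr(m, "gene_symbols") <- gene_symbols
  validate_count_matrix(m)
  m
}

# Find <stem>{,.gz} inside dir; NULL when absent.
find_mtx_file <- function(dir, stems) {
  for (s in stems) {
    for (f in c(s, paste0(s, ".gz"))) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
  }
  NULL
}

# readMM() cannot read gzipped files directly; inflate to a temp file first.
ungzip_to_temp <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  out <- tempfile(fileext = ".mtx")
  inc <- gzfile(path, "rb")
  on.exit(close(inc), add = TRUE)
  outc <- file(out, "wb")
  on.exit(close(outc), add = TRUE)
  repeat {
    chunk <- readBin(inc, raw(), 1048576L)
    if (!length(chunk)) break
    writeBin(chunk, outc)
  }
  out
}

#' Read a 10x-style sparse count matrix
#'
#' Reads the MatrixMarket triplet format used by droplet scRNA-seq pipelines:
#' a directory holding `matrix.mtx`, `barcodes.tsv` and `features.tsv` (or
#' the legacy two-column `genes.tsv`), each optionally gzipped. MTX indices
#' are 1-based on disk and converted to R's indexing on read.
#'
#' @param path directory containing the three files.
#' @return a sparse gene-by-barcode count matrix (see [count-matrix]).
#' @export
#' @examples
#' d <- tempfile(); dir.create(d)
#' m <- make_demo_matrix()
#' write_10x_mtx(m, d)
#' m2 <- read_10x_mtx(d)
#' all.equal(as.matrix(m), as.matrix(m2))
read_10x_mtx <- function(path) {
  if (!dir.exists(path)) stop("input directory not found: ", path, call. = FALSE)
  mtx <- find_mtx_file(path, "matrix.mtx")
  bcf <- find_mtx_file(path, "barcodes.tsv")
  ftf <- find_mtx_file(path, c("features.tsv", "genes.tsv"))
  if (is.null(mtx) || is.null(bcf) || is.null(ftf)) {
    stop("directory must contain matrix.mtx, barcodes.tsv and features.tsv/genes.tsv",
         call. = FALSE)
  }
  counts <- Matrix::readMM(ungzip_to_temp(mtx))
  barcodes <- readLines(bcf)
  feat <- read.delim(ftf, header = FALSE, colClasses = "character")
  if (nrow(feat) != nrow(counts)) {
    stop(sprintf("feature annotation has %d rows but matrix declares %d genes",
                 nrow(feat), nrow(counts)), call. = FALSE)
  }
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("barcodes file has %d lines but matrix declares %d columns",
                 length(barcodes), ncol(counts)), call. = FALSE)
  }
  symbols <- if (ncol(feat) >= 2L) feat[[2L]] else feat[[1L]]
  make_count_matrix(counts, feat[[1L]], barcodes, gene_symbols = symbols)
}

#' Write a count matrix in 10x triplet format
#'
#' Writes `matrix.mtx`, `barcodes.tsv` and `features.tsv` into `path`
#' (created if needed) such that [read_10x_mtx()] reproduces the input
#' exactly. Indices are written 1-based per the MatrixMarket convention.
#'
#' @param m count matrix.
#' @param path output directory.
#' @param gzip write gzipped files.
#' @return invisibly, the output directory.
#' @export
write_10x_mtx <- function(m, path, gzip = FALSE) {
  validate_count_matrix(m)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE)) {
    stop("cannot create output directory: ", path, call. = FALSE)
  }
  ext <- if (gzip) ".gz" else ""
  tmp <- tempfile(fileext = ".mtx")
  Matrix::writeMM(m, tmp)
  mtx_out <- file.path(path, paste0("matrix.mtx", ext))
  if (gzip) {
    inc <- file(tmp, "rb"); outc <- gzfile(mtx_out, "wb")
    writeBin(readBin(inc, raw(), file.size(tmp)), outc)
    close(inc); close(outc)
  } else {
    file.copy(tmp, mtx_out, overwrite = TRUE)
  }
  con <- if (gzip) gzfile(file.path(path, paste0("barcodes.tsv", ext)), "w") else
    file.path(path, "barcodes.tsv")
  writeLines(colnames(m), con)
  if (inherits(con, "connection")) close(con)
  symbols <- attr(m, "gene_symbols") %||% rownames(m)
  feat <- data.frame(rownames(m), symbols, "Gene Expression")
  con <- if (gzip) gzfile(file.path(path, paste0("features.tsv", ext)), "w") else
    file.path(path, "features.tsv")
  write.table(feat, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (inherits(con, "connection")) close(con)
  invisible(path)
}

#' Drop all-zero genes and barcodes
#'
#' Removes genes with zero counts across all barcodes and barcodes with zero
#' counts across all genes. Always run before background estimation so the
#' ambient profile is defined over expressed genes only.
#'
#' @param m count matrix.
#' @return the filtered count matrix; errors if nothing is left.
#' @export
drop_empty <- function(m) {
  validate_count_matrix(m)
  keep_g <- Matrix::rowSums(m) > 0
  keep_b <- Matrix::colSums(m) > 0
  if (!any(keep_g) || !any(keep_b)) {
    stop("matrix is entirely zero: nothing to analyze", call. = FALSE)
  }
  out <- m[keep_g, keep_b, drop = FALSE]
  sym <- attr(m, "gene_symbols")
  if (!is.null(sym)) attr(out, "gene_symbols") <- sym[keep_g]
  out
}

#' Per-barcode total UMI counts
#'
#' @param m count matrix.
#' @return named integer-valued vector of column sums.
#' @export
barcode_totals <- function(m) {
  validate_count_matrix(m)
  Matrix::colSums(m)
}

#' A tiny deterministic demo matrix
#'
#' Four genes by four barcodes, used in examples.
#' @return a small count matrix.
#' @export
make_demo_matrix <- function() {
  counts <- Matrix::sparseMatrix(
    i = c(1L, 2L, 3L, 1L, 4L, 2L),
    j = c(1L, 1L, 2L, 3L, 3L, 4L),
    x = c(5, 3, 2, 1, 4, 7),
    dims = c(4L, 4L)
  )
  make_count_matrix(counts, paste0("gene", 1:4), paste0("bc", 1:4))
}
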