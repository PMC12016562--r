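#' Write / read an expression matrix as TSV
#'
#' Genes-by-samples matrix with gene ids in the first column (`gene_id`)
#' and sample ids as the header.
#'
#' @param x matrix with dimnames.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read an expression matrix as MTX triplets
#'
#' MatrixMarket sparse triplet file with `features.tsv` / `barcodes.tsv`
#' sidecars (gene rows, sample/cell columns), the layout single-cell tools
#' exchange.
#'
#' @param x matrix with dimnames.
#' @param dir directory for `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return `dir` / the dense matrix.
#' @export
write_expression_mtx <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(x), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "features.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(dir) {
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv"))
    if (!file.exists(file.path(dir, f)))
      stop2("read_expression_mtx: missing ", file.path(dir, f))
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}

#' Write / read window counts as TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `gene_id`,
#' `strand`, `widx`, `count`; the library size is stored on a
#' `# library_size=` header line.
#'
#' @param x a [window_counts()] object.
#' @param path file path.
#' @return `path` / the `window_counts` object.
#' @export
write_window_counts <- function(x, path) {
  stopifnot(inherits(x, "window_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# library_size=%.0f", x$library_size), con)
  df <- cbind(x$windows, count = x$counts)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_counts
#' @export
read_window_counts <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# library_size=", first))
    stop2("read_window_counts: missing '# library_size=' header in ", path)
  lib <- as.numeric(sub("^# library_size=", "", first))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  window_counts(df[, setdiff(names(df), "count"), drop = FALSE],
                df$count, lib)
}

#' Write / read a transcript annotation as TSV
#'
#' @param annotation a [gen_annotation()]-style table.
#' @param path file path.
#' @return `path` / the table.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read position probability matrices
#'
#' Plain-text blocks: a `>motif_id` header followed by four tab-separated
#' rows labeled A, C, G, U (one column per motif position).
#'
#' @param ppms named list of 4-by-L matrices.
#' @param path file path.
#' @return `path` / the named list.
#' @export
write_ppms <- function(ppms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- names(ppms) %||% paste0("motif_", seq_along(ppms))
  for (i in seq_along(ppms)) {
    writeLines(paste0(">", ids[i]), con)
    p <- ppms[[i]]
    for (b in c("A", "C", "G", "U"))
      writeLines(paste(c(b, format(p[b, ], digits = 15)), collapse = "\t"),
                 con)
  }
  invisible(path)
}

#' @rdname write_ppms
#' @export
read_ppms <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop2("read_ppms: no '>' headers in ", path)
  ppms <- lapply(heads, function(h) {
    rows <- lines[(h + 1):(h + 4)]
    m <- t(vapply(rows, function(r) {
      parts <- strsplit(r, "\t")[[1]]
      as.numeric(parts[-1])
    }, numeric(length(strsplit(rows[1], "\t")[[1]]) - 1)))
    rownames(m) <- vapply(rows, function(r) strsplit(r, "\t")[[1]][1],
                          character(1))
    m[c("A", "C", "G", "U"), , drop = FALSE]
  })
  names(ppms) <- sub("^>", "", lines[heads])
  ppms
}

#' Read a regulator gene list (one id per line)
#' @param path file path.
#' @return Character vector.
#' @export
read_regulators <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (!length(x)) stop2("read_regulators: empty regulator list")
  x
}

#' Read a two-column ortholog mapping table (TSV, source then target)
#' @param path file path.
#' @param header whether the file has a header line.
#' @return Data frame with columns `source`, `target`.
#' @export
read_mapping <- function(path, header = TRUE) {
  df <- read.table(path, header = header, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop2("read_mapping: need two columns")
  setNames(df[, 1:2], c("source", "target"))
}

#' Write / read an m6A peak/site matrix as TSV
#'
#' Rows are `gene:start-end` site ids (first column `site_id`), columns
#' are samples or cells.
#'
#' @param x sites-by-samples matrix.
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_m6a_matrix <- function(x, path) {
  df <- data.frame(site_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_m6a_matrix
#' @export
read_m6a_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write called peaks as BED6
#'
#' `chrom start end name score strand` with `name = gene:start-end` and
#' `score = round(100 * mean winscore)` capped at 1000.
#'
#' @param peaks peak table from [call_merge_split()].
#' @param levels optional peaks-by-samples level matrix from
#'   [peak_levels()]; its across-sample mean feeds the score column.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, levels = NULL, path) {
  score <- if (is.null(levels)) rep(0, nrow(peaks)) else
    pmin(1000, round(100 * rowMeans(as.matrix(levels))))
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                    score, peaks$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
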