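#' Drop rows/columns with too many missing values
#'
#' m6A site-by-sample matrices are typically NA-rich; rows and then columns
#' whose missing fraction strictly exceeds `max_frac` are removed. Both
#' fractions are computed on the original matrix (a single pass:
#' row-then-column order with original percentages is deterministic and
#' symmetric to document, but the result is not in general a fixed point of
#' the rule).
#'
#' @param x numeric matrix, possibly with NAs.
#' @param max_frac maximum tolerated missing fraction (strict `>` drops; a
#'   row or column at exactly the threshold is retained).
#' @return List with `x` (the reduced matrix), `dropped_rows`,
#'   `dropped_cols` (character vectors of ids, positional ids when dimnames
#'   are absent).
#' @export
filter_missing <- function(x, max_frac = 0.10) {
  x <- as.matrix(x)
  if (length(x) == 0) stop2("filter_missing: empty matrix")
  rn <- rownames(x) %||% paste0("row", seq_len(nrow(x)))
  cn <- colnames(x) %||% paste0("col", seq_len(ncol(x)))
  row_frac <- rowMeans(is.na(x))
  col_frac <- colMeans(is.na(x))
  keep_r <- row_frac <= max_frac
  keep_c <- col_frac <= max_frac
  if (!any(keep_r) || !any(keep_c))
    stop2("filter_missing: every row or every column exceeds the missing-value threshold")
  list(x = x[keep_r, keep_c, drop = FALSE],
       dropped_rows = rn[!keep_r], dropped_cols = cn[!keep_c])
}

#' Single-cell QC configuration
#'
#' Thresholds for cell- and gene-level quality control of raw scRNA-seq
#' count matrices: cells are kept when the number of detected genes and the
#' total count fall strictly inside their bounds and the mitochondrial
#' percentage is strictly below `max_pct_mito`; genes expressed in fewer
#' than `min_cells_per_gene` cells are then removed.
#'
#' @param min_features,max_features bounds on detected genes per cell
#'   (kept when strictly greater / strictly smaller).
#' @param min_counts,max_counts bounds on total counts per cell.
#' @param max_pct_mito mitochondrial percentage upper bound (percent).
#' @param min_cells_per_gene minimum cells expressing a gene.
#' @param min_genes_per_cell minimum detected genes (cells expressing fewer
#'   are excluded); redundant with `min_features` at the defaults but kept
#'   as an independent knob.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_features = 200L, max_features = 4000L,
                      min_counts = 200L, max_counts = 20000L,
                      max_pct_mito = 25, min_cells_per_gene = 3L,
                      min_genes_per_cell = 200L) {
  cfg <- list(min_features = min_features, max_features = max_features,
              min_counts = min_counts, max_counts = max_counts,
              max_pct_mito = max_pct_mito,
              min_cells_per_gene = min_cells_per_gene,
              min_genes_per_cell = min_genes_per_cell)
  if (cfg$min_features >= cfg$max_features ||
      cfg$min_counts >= cfg$max_counts)
    stop2("qc_config: each min must be smaller than its max")
  structure(cfg, class = "qc_config")
}

#' Quality-control filtering of a raw count matrix
#'
#' @param counts genes-by-cells matrix of nonnegative integer counts.
#' @param mito_genes character vector of mitochondrial gene ids; defaults
#'   to rownames starting with `MT-` (case-insensitive).
#' @param cfg a [qc_config()].
#' @return List with `x` (filtered matrix), `removed_cells`,
#'   `removed_genes`.
#' @export
qc_filter_cells <- function(counts, mito_genes = NULL, cfg = qc_config()) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop2("qc_filter_cells: counts must be nonnegative integers")
  if (is.null(mito_genes))
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE,
                       value = TRUE)
  n_feat <- colSums(counts > 0)
  n_count <- colSums(counts)
  mito <- intersect(mito_genes, rownames(counts))
  pct_mito <- if (length(mito))
    100 * colSums(counts[mito, , drop = FALSE]) / pmax(n_count, 1)
  else rep(0, ncol(counts))
  keep_cell <- n_feat > cfg$min_features & n_feat < cfg$max_features &
    n_count > cfg$min_counts & n_count < cfg$max_counts &
    pct_mito < cfg$max_pct_mito &
    n_feat >= cfg$min_genes_per_cell
  if (!any(keep_cell)) stop2("qc_filter_cells: no cell passes QC")
  x <- counts[, keep_cell, drop = FALSE]
  keep_gene <- rowSums(x > 0) >= cfg$min_cells_per_gene
  if (!any(keep_gene)) stop2("qc_filter_cells: no gene passes QC")
  list(x = x[keep_gene, , drop = FALSE],
       removed_cells = colnames(counts)[!keep_cell] %||% which(!keep_cell),
       removed_genes = rownames(x)[!keep_gene] %||% which(!keep_gene))
}

#' Library-size normalization with log transform
#'
#' Per cell: counts are scaled to `scale_factor` total (10,000 by default)
#' and natural-log transformed with a pseudo-count of one
#' (`log1p(count / cell_total * scale_factor)`), the standard log-normalize
#' scheme for scRNA-seq.
#'
#' @param counts genes-by-cells matrix of nonnegative values.
#' @param scale_factor per-cell total after scaling.
#' @return Matrix of the same shape.
#' @export
normalize_expression <- function(counts, scale_factor = 1e4) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop2("normalize_expression: negative counts")
  totals <- colSums(counts)
  if (any(totals == 0)) stop2("normalize_expression: cell with zero total counts")
  log1p(sweep(counts, 2, totals, "/") * scale_factor)
}

#' Assemble the trans feature matrix
#'
#' Restricts an expression matrix to an ordered regulator panel, giving a
#' cells-by-regulators predictor matrix. Regulators absent from the
#' expression matrix become all-zero columns flagged in the feature
#' manifest (scRNA-seq panels routinely lack genes; the manifest keeps the
#' imputation auditable).
#'
#' @param expr genes-by-cells expression matrix with gene rownames.
#' @param regulators character vector of regulator gene ids (unique,
#'   nonempty); column order of the result.
#' @return Numeric matrix (cells x regulators) with a `manifest` attribute:
#'   data frame of `feature`, `type`, `imputed`.
#' @export
build_trans_features <- function(expr, regulators) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop2("build_trans_features: expr needs gene rownames")
  regulators <- as.character(regulators)
  if (length(regulators) == 0 || anyDuplicated(regulators))
    stop2("build_trans_features: regulators must be unique and nonempty")
  present <- regulators %in% rownames(expr)
  if (!any(present))
    stop2("build_trans_features: none of the regulators found in expr")
  out <- matrix(0, nrow = ncol(expr), ncol = length(regulators),
                dimnames = list(colnames(expr), regulators))
  out[, regulators[present]] <- t(expr[regulators[present], , drop = FALSE])
  attr(out, "manifest") <- data.frame(feature = regulators, type = "trans",
                                      imputed = !present,
                                      stringsAsFactors = FALSE)
  out
}

#' Feature manifest of a feature matrix
#' @param x a feature matrix built by [build_trans_features()] or
#'   [build_cis_features()].
#' @return The manifest data frame, or NULL.
#' @export
feature_manifest <- function(x) attr(x, "manifest")

scan_ppm <- function(ppm, seq_chars, floor = 1e-6) {
  L <- ncol(ppm)
  n <- length(seq_chars)
  if (n < L) return(-Inf)
  lp <- log(pmax(ppm, floor)) - log(0.25)
  best <- -Inf
  for (off in 0:(n - L)) {
    s <- 0
    for (j in seq_len(L)) s <- s + lp[seq_chars[off + j], j]
    if (s > best) best <- s
  }
  best
}

#' Assemble cis sequence features
#'
#' Two representations of the cis channel:
#' * `flatten`: each site's own PPM is unrolled row-major (A row, then C,
#'   G, U) into a 4L vector — constant per site, informative only for
#'   models fitted across sites;
#' * `score`: each site sequence is scanned by every motif PPM and the
#'   maximum log-likelihood-ratio score against a uniform background is
#'   recorded, giving one feature per motif (42 with the default panel).
#'
#' @param ppms list of PPMs: per-site PPMs in `flatten` mode (all the same
#'   width), the motif panel in `score` mode.
#' @param mode `"flatten"` or `"score"`.
#' @param sequences character vector of site RNA sequences (ACGU; T read as
#'   U), required in `score` mode.
#' @param prob_floor probability floor applied before taking logs in score
#'   mode (one-hot PPM columns would otherwise give -Inf on any mismatch).
#' @return Sites-by-features matrix with a `manifest` attribute.
#' @export
build_cis_features <- function(ppms, mode = c("flatten", "score"),
                               sequences = NULL, prob_floor = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(is.list(ppms), length(ppms) > 0)
  bases <- c("A", "C", "G", "U")
  if (mode == "flatten") {
    Ls <- vapply(ppms, ncol, integer(1))
    if (length(unique(Ls)) != 1)
      stop2("build_cis_features: ragged PPM lengths in flatten mode")
    L <- Ls[[1]]
    out <- t(vapply(ppms, function(p) as.vector(t(p[bases, , drop = FALSE])),
                    numeric(4 * L)))
    colnames(out) <- paste0(rep(bases, each = L), rep(seq_len(L), 4))
    rownames(out) <- names(ppms)
    manifest <- data.frame(feature = colnames(out), type = "cis_flat",
                           imputed = FALSE, stringsAsFactors = FALSE)
  } else {
    if (is.null(sequences))
      stop2("build_cis_features: sequences required in score mode")
    chars <- lapply(toupper(sequences), function(s) {
      v <- chartr("T", "U", strsplit(s, "")[[1]])
      if (!all(v %in% bases))
        stop2("build_cis_features: sequence contains non-ACGU characters")
      v
    })
    motif_ids <- names(ppms) %||% paste0("motif_", seq_along(ppms))
    out <- vapply(ppms, function(p)
      vapply(chars, function(sc) scan_ppm(p, sc, prob_floor), numeric(1)),
      numeric(length(chars)))
    out <- matrix(out, nrow = length(chars),
                  dimnames = list(names(sequences), motif_ids))
    manifest <- data.frame(feature = motif_ids, type = "cis_score",
                           imputed = FALSE, stringsAsFactors = FALSE)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Reconstruct a PPM from its flattened cis feature vector
#' @param v length-4L vector from [build_cis_features()] flatten mode.
#' @return 4-by-L PPM with rownames A, C, G, U.
#' @export
unflatten_ppm <- function(v) {
  if (length(v) %% 4 != 0) stop2("unflatten_ppm: length not divisible by 4")
  matrix(v, nrow = 4, byrow = TRUE,
         dimnames = list(c("A", "C", "G", "U"), NULL))
}

#' Map expression rows to ortholog gene ids
#'
#' Converts gene ids of an expression matrix to a target species via a
#' two-column mapping (at most many-to-one source-to-target). Unmapped
#' genes are dropped and reported; multiple sources hitting one target are
#' aggregated (sum by default — counts are additive — or max). Optionally
#' the mapped matrix is log1p-harmonized, the transformation used when
#' comparing expression across species.
#'
#' @param expr genes-by-samples matrix with gene rownames.
#' @param mapping data frame whose first two columns are source and target
#'   ids.
#' @param aggregate `"sum"` or `"max"` for duplicated targets.
#' @param harmonize apply `log1p` after aggregation.
#' @return List with `x` (mapped matrix), `dropped_genes`,
#'   `n_aggregated` (number of target ids formed from >1 source).
#' @export
map_orthologs <- function(expr, mapping, aggregate = c("sum", "max"),
                          harmonize = TRUE) {
  aggregate <- match.arg(aggregate)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop2("map_orthologs: expr needs gene rownames")
  if (!is.data.frame(mapping) || ncol(mapping) < 2 || nrow(mapping) == 0)
    stop2("map_orthologs: mapping must be a nonempty two-column table")
  src <- as.character(mapping[[1]]); tgt <- as.character(mapping[[2]])
  if (anyDuplicated(src))
    stop2("map_orthologs: mapping must be at most many-to-one (duplicate source ids)")
  hit <- rownames(expr) %in% src
  if (!any(hit)) stop2("map_orthologs: no expression gene maps")
  x <- expr[hit, , drop = FALSE]
  targets <- tgt[match(rownames(x), src)]
  agg_fun <- if (aggregate == "sum") colSums else
    function(m) apply(m, 2, max)
  groups <- split(seq_len(nrow(x)), targets)
  out <- t(vapply(groups, function(i) agg_fun(x[i, , drop = FALSE]),
                  numeric(ncol(x))))
  colnames(out) <- colnames(expr)
  if (harmonize) out <- log1p(out)
  list(x = out,
       dropped_genes = rownames(expr)[!hit],
       n_aggregated = sum(vapply(groups, length, integer(1)) > 1))
}
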