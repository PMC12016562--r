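#' Quantification configuration
#'
#' Settings of the winscore m6A quantification: the sliding-window grid, the
#' enrichment cutoff (windows are called when winscore is strictly greater
#' than the cutoff), the pseudo-count added to every window RPKM in both
#' libraries before the ratio, the maximum number of windows a merged peak
#' may span before it is split, and the statistic summarizing member-window
#' winscores into a peak level.
#'
#' With the defaults (window 100 bp, step 50 bp), five consecutive sliding
#' windows span 300 bp, so the split rule caps peaks at 300 bp.
#'
#' @param window_size window width in bases.
#' @param step offset between consecutive window starts, at most
#'   `window_size`.
#' @param winscore_cutoff enrichment-fraction cutoff (strict `>`).
#' @param pseudo_rpkm pseudo-count added to IP and input RPKM.
#' @param max_windows_per_peak maximum member windows per peak after
#'   splitting.
#' @param gene_median_norm if TRUE, adjusted RPKMs are divided by their
#'   within-gene median before the ratio (the original winscore variant).
#' @param peak_level_stat `"mean"` or `"max"` of member-window winscores.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(window_size = 100L, step = 50L, winscore_cutoff = 2,
                         pseudo_rpkm = 1, max_windows_per_peak = 5L,
                         gene_median_norm = FALSE,
                         peak_level_stat = c("mean", "max")) {
  peak_level_stat <- match.arg(peak_level_stat)
  cfg <- list(window_size = as.integer(window_size), step = as.integer(step),
              winscore_cutoff = winscore_cutoff, pseudo_rpkm = pseudo_rpkm,
              max_windows_per_peak = as.integer(max_windows_per_peak),
              gene_median_norm = isTRUE(gene_median_norm),
              peak_level_stat = peak_level_stat)
  if (!is_count(cfg$window_size) || !is_count(cfg$step))
    stop2("quant_config: window_size and step must be positive integers")
  if (cfg$step > cfg$window_size)
    stop2("quant_config: step must not exceed window_size")
  if (!is_number(cfg$winscore_cutoff) || cfg$winscore_cutoff <= 0)
    stop2("quant_config: winscore_cutoff must be positive")
  if (cfg$max_windows_per_peak < 1L)
    stop2("quant_config: max_windows_per_peak must be at least 1")
  structure(cfg, class = "quant_config")
}

#' Build the sliding-window grid over transcripts
#'
#' Per transcript, full windows start at offsets 0, step, 2*step, ...; if
#' the last full window ends short of the transcript end, one trailing
#' partial window at the next offset is kept when it is at least `step`
#' wide. Transcripts shorter than the window size yield a single partial
#' window covering the whole transcript. Coordinates are 0-based half-open.
#'
#' @param annotation data frame with at least `transcript_id`, `gene_id`,
#'   `strand`, `length`.
#' @param cfg a [quant_config()].
#' @return Data frame of windows: `chrom` (transcript id), `start`, `end`,
#'   `gene_id`, `strand`, `widx` (1-based index along the transcript grid).
#'   Rows are ordered by transcript then position.
#' @export
make_windows <- function(annotation, cfg = quant_config()) {
  stopifnot(is.data.frame(annotation))
  if (nrow(annotation) == 0) stop2("make_windows: empty annotation")
  need <- c("transcript_id", "gene_id", "strand", "length")
  if (!all(need %in% names(annotation)))
    stop2("make_windows: annotation must have columns ",
          paste(need, collapse = ", "))
  w <- cfg$window_size; s <- cfg$step
  if (any(annotation$length < s))
    stop2("make_windows: transcript shorter than the step size")
  pieces <- lapply(seq_len(nrow(annotation)), function(i) {
    len <- annotation$length[i]
    if (len >= w) {
      starts <- seq.int(0L, len - w, by = s)
      ends <- starts + w
      if (ends[length(ends)] < len) {
        cand <- starts[length(starts)] + s
        if (len - cand >= s) {
          starts <- c(starts, cand)
          ends <- c(ends, len)
        }
      }
    } else {
      starts <- 0L
      ends <- len
    }
    data.frame(chrom = annotation$transcript_id[i],
               start = as.integer(starts), end = as.integer(ends),
               gene_id = annotation$gene_id[i],
               strand = annotation$strand[i],
               widx = seq_along(starts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Window count table
#'
#' Pairs a window grid with per-window read counts and the library's total
#' mapped reads.
#'
#' @param windows a window grid from [make_windows()] (or a data frame with
#'   the same columns).
#' @param counts nonnegative integer vector, one count per window.
#' @param library_size total mapped reads of the library.
#' @return A list of class `window_counts`.
#' @export
window_counts <- function(windows, counts, library_size) {
  stopifnot(is.data.frame(windows))
  counts <- as.numeric(counts)
  if (length(counts) != nrow(windows))
    stop2("window_counts: counts must align 1:1 with windows")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop2("window_counts: counts must be nonnegative integers")
  if (!is_number(library_size) || library_size <= 0)
    stop2("window_counts: library_size must be positive")
  if (length(counts) && library_size < max(counts))
    stop2("window_counts: library_size smaller than a window count")
  structure(list(windows = windows, counts = counts,
                 library_size = as.numeric(library_size)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts: ", nrow(x$windows), " windows over ",
      length(unique(x$windows$chrom)), " transcripts; library size ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM_w = count_w / ((width_w / 1000) * (library_size / 1e6))`.
#'
#' @param x a [window_counts()] object.
#' @return Numeric vector aligned with the window grid.
#' @export
rpkm <- function(x) {
  stopifnot(inherits(x, "window_counts"))
  width <- x$windows$end - x$windows$start
  if (any(width <= 0)) stop2("rpkm: zero-width window")
  x$counts / ((width / 1000) * (x$library_size / 1e6))
}

#' Window enrichment score (winscore)
#'
#' The enrichment fraction of a window: IP over input RPKM after adding a
#' pseudo-count to both (low-coverage windows otherwise produce unstable
#' ratios). With `gene_median_norm`, each library's adjusted RPKM is first
#' divided by its within-gene median, the normalization of the original
#' winscore definition.
#'
#' @param ip_rpkm,input_rpkm per-window RPKM vectors on the same grid.
#' @param cfg a [quant_config()].
#' @param gene_id per-window gene assignment; required when
#'   `gene_median_norm` is TRUE.
#' @return Per-window winscore vector.
#' @export
winscore <- function(ip_rpkm, input_rpkm, cfg = quant_config(),
                     gene_id = NULL) {
  if (length(ip_rpkm) != length(input_rpkm))
    stop2("winscore: IP and input vectors are misaligned")
  a_ip <- ip_rpkm + cfg$pseudo_rpkm
  a_in <- input_rpkm + cfg$pseudo_rpkm
  if (cfg$gene_median_norm) {
    if (is.null(gene_id) || length(gene_id) != length(ip_rpkm))
      stop2("winscore: gene_id required for gene-median normalization")
    med_ip <- stats::ave(a_ip, gene_id, FUN = median)
    med_in <- stats::ave(a_in, gene_id, FUN = median)
    a_ip <- a_ip / med_ip
    a_in <- a_in / med_in
  }
  a_ip / a_in
}

#' Call, merge and split m6A peaks
#'
#' Windows whose winscore strictly exceeds the cutoff are grouped into
#' maximal runs of consecutive windows within the same gene (merging), and
#' runs spanning more than `max_windows_per_peak` windows are chunked
#' greedily left-to-right into pieces of at most that many windows
#' (splitting), so a run of k significant windows yields ceiling(k / max)
#' peaks.
#'
#' @param windows window grid from [make_windows()].
#' @param winscores per-window winscore vector on that grid.
#' @param cfg a [quant_config()].
#' @return Data frame of peaks: `peak_id` (`gene:start-end`), `chrom`,
#'   `gene_id`, `strand`, `start`, `end`, `n_windows`, and `win_from` /
#'   `win_to` (row indices into `windows`). Empty input gives zero rows.
#' @export
call_merge_split <- function(windows, winscores, cfg = quant_config()) {
  stopifnot(is.data.frame(windows))
  if (length(winscores) != nrow(windows))
    stop2("call_merge_split: winscores misaligned with the window grid")
  empty <- data.frame(peak_id = character(), chrom = character(),
                      gene_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), win_from = integer(),
                      win_to = integer(), stringsAsFactors = FALSE)
  sig <- which(winscores > cfg$winscore_cutoff)
  if (length(sig) == 0) return(empty)
  # maximal runs: consecutive rows of the grid within one transcript/gene
  consec <- c(FALSE, diff(sig) == 1L &
                windows$chrom[sig[-1]] == windows$chrom[sig[-length(sig)]] &
                windows$widx[sig[-1]] == windows$widx[sig[-length(sig)]] + 1L)
  run_id <- cumsum(!consec)
  mx <- cfg$max_windows_per_peak
  rows <- lapply(split(sig, run_id), function(run) {
    n <- length(run)
    from <- seq.int(1L, n, by = mx)
    to <- pmin(from + mx - 1L, n)
    data.frame(win_from = run[from], win_to = run[to])
  })
  chunks <- do.call(rbind, rows)
  out <- data.frame(
    peak_id = NA_character_,
    chrom = windows$chrom[chunks$win_from],
    gene_id = windows$gene_id[chunks$win_from],
    strand = windows$strand[chunks$win_from],
    start = windows$start[chunks$win_from],
    end = windows$end[chunks$win_to],
    n_windows = chunks$win_to - chunks$win_from + 1L,
    win_from = chunks$win_from, win_to = chunks$win_to,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$peak_id <- make.unique(sprintf("%s:%d-%d", out$gene_id, out$start,
                                     out$end))
  rownames(out) <- NULL
  out
}

#' Summarize member-window winscores into peak levels
#'
#' @param peaks peak table from [call_merge_split()].
#' @param winscores per-window winscore vector, or a windows-by-samples
#'   matrix, on the grid the peaks were called from.
#' @param cfg a [quant_config()]; `peak_level_stat` selects mean or max.
#' @return Peaks-by-samples m6A level matrix with `peak_id` rownames.
#' @export
peak_levels <- function(peaks, winscores, cfg = quant_config()) {
  ws <- as.matrix(winscores)
  if (nrow(peaks) && max(peaks$win_to) > nrow(ws))
    stop2("peak_levels: peak references a window outside the winscore grid")
  stat <- if (cfg$peak_level_stat == "max") max else mean
  out <- matrix(NA_real_, nrow = nrow(peaks), ncol = ncol(ws),
                dimnames = list(peaks$peak_id,
                                colnames(ws) %||% paste0("S", seq_len(ncol(ws)))))
  for (i in seq_len(nrow(peaks))) {
    block <- ws[peaks$win_from[i]:peaks$win_to[i], , drop = FALSE]
    out[i, ] <- apply(block, 2, stat)
  }
  out
}

#' Quantile-normalize a TPM (or any expression) matrix
#'
#' Forces every column to share the same distribution: each value is
#' replaced by the mean of the values of its rank across columns, with ties
#' resolved by average rank. After normalization the sorted values of every
#' column are identical.
#'
#' @param x numeric matrix, samples in columns, nonnegative values.
#' @return Matrix of the same shape and dimnames.
#' @export
tpm_quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE))
    stop2("tpm_quantile_normalize: negative values")
  if (ncol(x) < 2) {
    warning("tpm_quantile_normalize: fewer than 2 columns; returning input")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

parse_site_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop2("malformed site id(s): ", paste(head(ids[bad], 3), collapse = ", "))
  data.frame(id = ids,
             gene_id = vapply(m, `[`, character(1), 2L),
             start = as.integer(vapply(m, `[`, character(1), 3L)),
             end = as.integer(vapply(m, `[`, character(1), 4L)),
             stringsAsFactors = FALSE)
}

#' Match peak rows between two m6A matrices
#'
#' Pairs rows of two peak/site matrices whose `gene:start-end` identifiers
#' refer to the same gene and whose spans overlap (reciprocally by at least
#' `min_overlap_frac` of each span). Matching is greedy by overlap length,
#' each row used at most once, ties broken by row order for determinism.
#'
#' @param a,b m6A matrices (or their rowname character vectors) with
#'   `gene:start-end` row identifiers.
#' @param min_overlap_frac required reciprocal overlap fraction; 0 accepts
#'   any overlap within the same gene.
#' @return Data frame with `id_a`, `id_b`, `overlap` (bases).
#' @export
match_windows <- function(a, b, min_overlap_frac = 0) {
  ids_a <- if (is.character(a)) a else rownames(a)
  ids_b <- if (is.character(b)) b else rownames(b)
  pa <- parse_site_ids(ids_a)
  pb <- parse_site_ids(ids_b)
  cand <- merge(cbind(pa, row_a = seq_len(nrow(pa))),
                cbind(pb, row_b = seq_len(nrow(pb))),
                by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(cand) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      overlap = integer(), stringsAsFactors = FALSE))
  cand$overlap <- pmax(0L, pmin(cand$end_a, cand$end_b) -
                         pmax(cand$start_a, cand$start_b))
  keep <- cand$overlap > 0
  if (min_overlap_frac > 0) {
    keep <- keep &
      cand$overlap >= min_overlap_frac * (cand$end_a - cand$start_a) &
      cand$overlap >= min_overlap_frac * (cand$end_b - cand$start_b)
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$row_a, cand$row_b), , drop = FALSE]
  used_a <- logical(length(ids_a)); used_b <- logical(length(ids_b))
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ra <- cand$row_a[i]; rb <- cand$row_b[i]
    if (!used_a[ra] && !used_b[rb]) {
      take[i] <- TRUE
      used_a[ra] <- TRUE; used_b[rb] <- TRUE
    }
  }
  sel <- cand[take, , drop = FALSE]
  sel <- sel[order(sel$row_a), , drop = FALSE]
  data.frame(id_a = sel$id_a, id_b = sel$id_b, overlap = sel$overlap,
             stringsAsFactors = FALSE)
}

#' Quantify m6A peak levels from paired IP/input window counts
#'
#' Full winscore quantification: per-sample winscores on a shared window
#' grid, peak calling on the across-sample mean winscore (a single
#' reference grid keeps peak identities comparable across samples), then
#' per-sample peak levels.
#'
#' @param ip,input a [window_counts()] object or a list of them (one per
#'   sample) on identical window grids.
#' @param cfg a [quant_config()].
#' @return List with `windows`, `winscores` (windows x samples), `peaks`,
#'   and `levels` (an m6A peaks-by-samples matrix).
#' @export
quantify_m6a <- function(ip, input, cfg = quant_config()) {
  as_list <- function(x) if (inherits(x, "window_counts")) list(x) else x
  ip <- as_list(ip); input <- as_list(input)
  if (length(ip) != length(input))
    stop2("quantify_m6a: need matching numbers of IP and input libraries")
  grid <- ip[[1]]$windows
  ws <- vapply(seq_along(ip), function(i) {
    if (!identical(ip[[i]]$windows[, c("chrom", "start", "end")],
                   grid[, c("chrom", "start", "end")]) ||
        !identical(input[[i]]$windows[, c("chrom", "start", "end")],
                   grid[, c("chrom", "start", "end")]))
      stop2("quantify_m6a: sample ", i, " is not on the shared window grid")
    winscore(rpkm(ip[[i]]), rpkm(input[[i]]), cfg, gene_id = grid$gene_id)
  }, numeric(nrow(grid)))
  ws <- matrix(ws, nrow = nrow(grid),
               dimnames = list(NULL, names(ip) %||% paste0("S", seq_along(ip))))
  ref <- rowMeans(ws)
  peaks <- call_merge_split(grid, ref, cfg)
  levels <- peak_levels(peaks, ws, cfg)
  list(windows = grid, winscores = ws, peaks = peaks, levels = levels)
}
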