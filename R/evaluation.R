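#' Evaluation configuration
#'
#' @param tolerance absolute prediction-error tolerance defining the binary
#'   accuracy label (a pair is "accurate" when `|pred - true| <= tolerance`;
#'   default 0.5, on the model's target scale).
#' @param n_permutations draws of the permutation null.
#' @param correlation_method `"pearson"` (default; figures report R) or
#'   `"spearman"`.
#' @param n_resample number of randomly re-paired (true, predicted) draws
#'   appended as the negative-enriched pool in [auroc_tolerance()];
#'   defaults to the number of observed pairs.
#' @param seed integer seed.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(tolerance = 0.5, n_permutations = 1000L,
                        correlation_method = c("pearson", "spearman"),
                        n_resample = NULL, seed = 1L) {
  correlation_method <- match.arg(correlation_method)
  if (!is_number(tolerance) || tolerance <= 0)
    stop2("eval_config: tolerance must be positive")
  if (!is_count(n_permutations))
    stop2("eval_config: n_permutations must be a positive integer")
  structure(list(tolerance = tolerance,
                 n_permutations = as.integer(n_permutations),
                 correlation_method = correlation_method,
                 n_resample = n_resample, seed = as.integer(seed)),
            class = "eval_config")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE / SST` of predictions against truths (NA pairs dropped).
#' Can be negative when predictions are worse than the mean predictor.
#'
#' @param y_true,y_pred aligned numeric vectors.
#' @return A single real number, at most 1.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop2("r_squared: misaligned vectors")
  ok <- is.finite(y_true) & is.finite(y_pred)
  y <- y_true[ok]; p <- y_pred[ok]
  if (length(y) < 2) stop2("r_squared: need at least 2 finite pairs")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop2("r_squared: zero variance in y_true")
  1 - sum((y - p)^2) / sst
}

#' Tolerance-rule accuracy labels
#'
#' Label 1 when the absolute difference between the predicted and true m6A
#' value is no more than the tolerance (inclusive boundary), 0 otherwise.
#'
#' @param y_true,y_pred aligned numeric vectors.
#' @param cfg an [eval_config()] (supplies the tolerance).
#' @return Integer vector of 0/1 labels.
#' @export
tolerance_labels <- function(y_true, y_pred, cfg = eval_config()) {
  if (length(y_true) != length(y_pred))
    stop2("tolerance_labels: misaligned vectors")
  as.integer(abs(y_pred - y_true) <= cfg$tolerance)
}

#' Rank-statistic AUROC with ROC curve points
#'
#' The area under the ROC curve computed as the Mann-Whitney rank statistic
#' (probability that a positive outscores a negative, ties counted half),
#' plus the curve's (FPR, TPR) points over all score thresholds.
#'
#' @param scores continuous scores, larger = more positive.
#' @param labels 0/1 labels aligned with `scores`; both classes required.
#' @return List with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop2("roc_auc: misaligned vectors")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop2("roc_auc: AUROC undefined, labels contain a single class")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr)))
}

#' Tolerance-label AUROC on a negative-enriched pair pool
#'
#' Builds an evaluation pool from the observed (true, predicted) pairs plus
#' `n_resample` randomly re-paired draws (seeded; random re-pairings are
#' mostly inaccurate, enriching the negative class so both label classes
#' exist). Every pooled pair is labeled by the tolerance rule and scored by
#' the negated absolute error, and the AUROC of the scores against the
#' labels is returned with the curve points.
#'
#' Because the label is a threshold of the score, the observed AUROC is
#' close to 1 whenever both classes are present; it is informative only
#' against its permutation null (labels shuffled against scores give 0.5).
#' See the methods vignette.
#'
#' @param y_true,y_pred aligned numeric vectors.
#' @param cfg an [eval_config()].
#' @return List with `auc`, `curve`, `labels`, `scores`.
#' @export
auroc_tolerance <- function(y_true, y_pred, cfg = eval_config()) {
  if (length(y_true) != length(y_pred))
    stop2("auroc_tolerance: misaligned vectors")
  n <- length(y_true)
  m <- cfg$n_resample %||% n
  withr::with_seed(cfg$seed + 21L, {
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n, m, replace = TRUE)
    list(i, j)
  }) -> idx
  pool_true <- c(y_true, y_true[idx[[1]]])
  pool_pred <- c(y_pred, y_pred[idx[[2]]])
  labels <- tolerance_labels(pool_true, pool_pred, cfg)
  scores <- -abs(pool_pred - pool_true)
  if (length(unique(labels)) < 2)
    stop2("auroc_tolerance: AUROC undefined, pooled labels are single-class")
  out <- roc_auc(scores, labels)
  out$labels <- labels
  out$scores <- scores
  out
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity of binary labels. When `predicted`
#' is a numeric score vector, the maximum balanced accuracy over all ROC
#' thresholds is returned (the operating point a threshold-free comparison
#' uses).
#'
#' @param truth 0/1 true labels (both classes required).
#' @param predicted 0/1 predicted labels, or numeric scores.
#' @return A real in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  truth <- as.integer(truth)
  if (length(truth) != length(predicted))
    stop2("balanced_accuracy: misaligned vectors")
  if (length(unique(truth)) < 2)
    stop2("balanced_accuracy: truth contains a single class")
  if (is.numeric(predicted) && !all(predicted %in% c(0, 1))) {
    roc <- roc_auc(predicted, truth)
    return(max((roc$curve$tpr + 1 - roc$curve$fpr) / 2))
  }
  predicted <- as.integer(predicted)
  sens <- sum(truth == 1 & predicted == 1) / sum(truth == 1)
  spec <- sum(truth == 0 & predicted == 0) / sum(truth == 0)
  (sens + spec) / 2
}

#' Permutation null of an evaluation metric
#'
#' Recomputes a metric after shuffling the pairing between truths and
#' predictions `n_permutations` times (seeded) and returns the null
#' distribution together with the one-sided empirical p-value with the +1
#' correction, `p = (1 + #(null >= observed)) / (1 + n_permutations)`.
#' Permutations on which the metric is not computable are recorded as
#' missing and reported.
#'
#' @param metric function of `(y_true, y_pred)` returning a single number
#'   (e.g. [r_squared()], or a correlation wrapper).
#' @param y_true,y_pred aligned numeric vectors.
#' @param cfg an [eval_config()].
#' @return List with `observed`, `null` (numeric vector, NAs for failed
#'   draws), `p`, `n_failed`.
#' @export
permutation_null <- function(metric, y_true, y_pred, cfg = eval_config()) {
  observed <- metric(y_true, y_pred)
  null <- withr::with_seed(cfg$seed + 31L, {
    vapply(seq_len(cfg$n_permutations), function(b) {
      perm <- sample.int(length(y_pred))
      tryCatch(metric(y_true, y_pred[perm]), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- !is.na(null)
  p <- (1 + sum(null[ok] >= observed)) / (1 + sum(ok))
  list(observed = observed, null = null, p = p, n_failed = sum(!ok))
}

#' Correlation with significance
#'
#' Pearson (default) or Spearman correlation with a two-sided p-value,
#' after pairwise deletion of missing values.
#'
#' @param a,b aligned numeric vectors.
#' @param cfg an [eval_config()].
#' @return List with `r`, `p`, `n` (complete pairs used).
#' @export
correlate <- function(a, b, cfg = eval_config()) {
  if (length(a) != length(b)) stop2("correlate: misaligned vectors")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop2("correlate: need at least 3 complete pairs")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
    stop2("correlate: zero variance")
  ct <- cor.test(a[ok], b[ok], method = cfg$correlation_method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Metagene distribution of m6A peaks
#'
#' Maps each peak midpoint to its transcript region (5'UTR, CDS, 3'UTR in
#' transcript coordinates), rescales the position to `[0, 1)` within the
#' region, and bins it (`bins` per region, default 10, giving a 30-bin
#' density over the standardized transcript model). The vector is
#' normalized to sum 1; peaks on transcripts lacking region annotation are
#' skipped and counted.
#'
#' @param peaks peak table with `chrom` (transcript id), `start`, `end`.
#' @param annotation table with `transcript_id`, `utr5_len`, `cds_len`,
#'   `utr3_len`.
#' @param bins bins per region.
#' @return List with `density` (length `3 * bins`, named
#'   `utr5_1..utr3_bins`), `counts` (raw bin counts), `n_mapped`,
#'   `n_skipped`.
#' @export
metagene_profile <- function(peaks, annotation, bins = 10L) {
  stopifnot(is.data.frame(peaks), is.data.frame(annotation))
  need <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(annotation)))
    stop2("metagene_profile: annotation must have columns ",
          paste(need, collapse = ", "))
  ann <- annotation[!duplicated(annotation$transcript_id), , drop = FALSE]
  rownames(ann) <- ann$transcript_id
  counts <- setNames(numeric(3 * bins),
                     paste0(rep(c("utr5", "cds", "utr3"), each = bins),
                            "_", rep(seq_len(bins), 3)))
  skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    tx <- as.character(peaks$chrom[i])
    if (!tx %in% rownames(ann)) { skipped <- skipped + 1L; next }
    u5 <- ann[tx, "utr5_len"]; cd <- ann[tx, "cds_len"]; u3 <- ann[tx, "utr3_len"]
    mid <- (peaks$start[i] + peaks$end[i]) / 2
    if (!is.finite(mid) || mid < 0 || mid >= u5 + cd + u3) {
      skipped <- skipped + 1L; next
    }
    if (mid < u5) { region <- 0L; frac <- mid / u5 }
    else if (mid < u5 + cd) { region <- 1L; frac <- (mid - u5) / cd }
    else { region <- 2L; frac <- (mid - u5 - cd) / u3 }
    bin <- region * bins + min(bins - 1L, floor(frac * bins)) + 1L
    counts[bin] <- counts[bin] + 1
  }
  total <- sum(counts)
  density <- if (total > 0) counts / total else counts
  list(density = density, counts = counts,
       n_mapped = as.integer(total), n_skipped = skipped)
}

#' Evaluate predicted m6A matrices against the truth
#'
#' Per-site R-squared, tolerance-label AUROC and maximum balanced accuracy
#' (from tolerance labels vs negated-error scores on the resampled pool),
#' pooled as median and quartiles — the evaluation metrics do not follow a
#' normal distribution, so quartiles are the summary of record.
#'
#' @param truth,pred sites-by-observations matrices with matching dimnames
#'   (columns restricted to shared observations; typically the held-out
#'   test cells).
#' @param cfg an [eval_config()].
#' @return A list of class `eval_report`: `per_site` data frame (`site`,
#'   `r2`, `auroc`, `balanced_accuracy`, `n`), and `summary` (median and
#'   quartiles per metric).
#' @export
evaluate_predictions <- function(truth, pred, cfg = eval_config()) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  sites <- intersect(rownames(truth), rownames(pred))
  obs <- intersect(colnames(truth), colnames(pred))
  if (length(sites) == 0 || length(obs) == 0)
    stop2("evaluate_predictions: no shared sites/observations")
  rows <- lapply(sites, function(s) {
    yt <- truth[s, obs]; yp <- pred[s, obs]
    r2 <- tryCatch(r_squared(yt, yp), error = function(e) NA_real_)
    roc <- tryCatch(auroc_tolerance(yt, yp, cfg), error = function(e) NULL)
    au <- if (is.null(roc)) NA_real_ else roc$auc
    ba <- if (is.null(roc)) NA_real_ else
      tryCatch(balanced_accuracy(roc$labels, roc$scores),
               error = function(e) NA_real_)
    data.frame(site = s, r2 = r2, auroc = au, balanced_accuracy = ba,
               n = sum(is.finite(yt) & is.finite(yp)),
               stringsAsFactors = FALSE)
  })
  per_site <- do.call(rbind, rows)
  qs <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(c(q25 = NA, median = NA, q75 = NA))
    setNames(quantile(v, c(0.25, 0.5, 0.75), names = FALSE),
             c("q25", "median", "q75"))
  }
  summary <- rbind(r2 = qs(per_site$r2), auroc = qs(per_site$auroc),
                   balanced_accuracy = qs(per_site$balanced_accuracy))
  structure(list(per_site = per_site, summary = as.data.frame(summary),
                 tolerance = cfg$tolerance),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report over", nrow(x$per_site), "sites (tolerance",
      x$tolerance, ")\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report an `eval_report` from [evaluate_predictions()].
#' @param prefix file prefix; writes `<prefix>.json` and
#'   `<prefix>_per_site.tsv`.
#' @return The JSON path, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "eval_report"))
  json <- file.path(paste0(prefix, ".json"))
  jsonlite::write_json(
    list(tolerance = report$tolerance,
         summary = cbind(metric = rownames(report$summary), report$summary),
         per_site = report$per_site),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.table(report$per_site, paste0(prefix, "_per_site.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json)
}
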