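test_that("window grid: 300 bp transcript gives five 100/50 windows", {
  ann <- mk_annotation(300L)
  win <- make_windows(ann, quant_config())
  expect_equal(nrow(win), 5)
  expect_equal(win$start, c(0, 50, 100, 150, 200))
  expect_equal(win$end, c(100, 150, 200, 250, 300))
  expect_equal(min(win$start), 0)
  expect_equal(max(win$end), 300)
})

test_that("window grid edge cases: short transcripts and partial tails", {
  expect_equal(nrow(make_windows(mk_annotation(100L), quant_config())), 1)
  # 70 bp: shorter than the window but at least one step wide
  w70 <- make_windows(mk_annotation(70L, utr5 = 10L, utr3 = 10L))
  expect_equal(c(w70$start, w70$end), c(0, 70))
  # 120 bp: one full window plus a partial tail window
  w120 <- make_windows(mk_annotation(120L))
  expect_equal(w120$start, c(0, 50))
  expect_equal(w120$end, c(100, 120))
  expect_error(make_windows(mk_annotation(30L, utr5 = 5L, utr3 = 5L)),
               "shorter than the step")
})

test_that("windows are sorted and overlap successors by window - step", {
  cfg <- quant_config(window_size = 100, step = 40)
  win <- make_windows(mk_annotation(c(500L, 777L)), cfg)
  for (tx in unique(win$chrom)) {
    w <- win[win$chrom == tx, ]
    expect_true(all(diff(w$start) > 0))
    full <- which(w$end - w$start == 100)
    full <- full[full < nrow(w)]
    expect_true(all(w$end[full] - w$start[full + 1] == 100 - 40))
  }
})

test_that("rpkm matches the definition and its scaling laws", {
  ann <- mk_annotation(300L)
  win <- make_windows(ann)
  wc <- window_counts(win, c(10, 0, 5, 2, 7), 1e6)
  r <- rpkm(wc)
  expect_equal(r[1], 10 / (0.1 * 1))  # count 10, 100 bp, 1e6 reads -> 100
  expect_equal(r[2], 0)
  wc2 <- window_counts(win, c(10, 0, 5, 2, 7), 2e6)
  expect_equal(rpkm(wc2), r / 2)
  # linear in counts, invariant under joint scaling of counts and library
  wc3 <- window_counts(win, 3 * c(10, 0, 5, 2, 7), 3e6)
  expect_equal(rpkm(wc3), r)
})

test_that("winscore is the pseudo-count-adjusted RPKM ratio", {
  expect_equal(winscore(9, 4), (9 + 1) / (4 + 1))
  expect_equal(winscore(9, 4), 2.0)  # boundary value, not called at cutoff 2
  x <- runif(20, 0, 50)
  expect_equal(winscore(x, x), rep(1, 20))
  # monotone: increasing in IP, decreasing in input
  expect_true(all(diff(winscore(1:10, rep(5, 10))) > 0))
  expect_true(all(diff(winscore(rep(5, 10), 1:10)) < 0))
  expect_error(winscore(1:3, 1:4), "misaligned")
})

test_that("gene-median normalization divides adjusted RPKM by gene medians", {
  cfg <- quant_config(gene_median_norm = TRUE)
  ip <- c(9, 1, 1); input <- c(4, 4, 4)
  gene <- c("g1", "g1", "g1")
  # adjusted ip = (10,2,2), median 2; adjusted input = (5,5,5), median 5
  expect_equal(winscore(ip, input, cfg, gene_id = gene),
               (c(10, 2, 2) / 2) / (c(5, 5, 5) / 5))
  expect_error(winscore(ip, input, cfg), "gene_id")
})

test_that("peak calling merges runs and splits them greedily", {
  ann <- mk_annotation(1600L)
  win <- make_windows(ann)  # 31 windows
  ws <- rep(1, nrow(win))
  ws[3:14] <- 3  # 12 consecutive significant windows
  peaks <- call_merge_split(win, ws, quant_config())
  expect_equal(nrow(peaks), 3)  # ceiling(12 / 5)
  expect_equal(peaks$n_windows, c(5, 5, 2))
  # exactly five significant windows are not split
  ws5 <- rep(1, nrow(win)); ws5[3:7] <- 3
  expect_equal(call_merge_split(win, ws5, quant_config())$n_windows, 5)
  # one isolated window
  ws1 <- rep(1, nrow(win)); ws1[10] <- 3
  p1 <- call_merge_split(win, ws1, quant_config())
  expect_equal(nrow(p1), 1)
  expect_equal(p1$n_windows, 1)
  expect_equal(p1$start, win$start[10])
  # empty input
  expect_equal(nrow(call_merge_split(win, rep(1, nrow(win)), quant_config())),
               0)
})

test_that("peaks partition the significant windows and never cross genes", {
  ann <- mk_annotation(c(700L, 900L, 400L))
  win <- make_windows(ann)
  set.seed(14)
  for (rep_i in 1:20) {
    ws <- runif(nrow(win), 0, 4)
    peaks <- call_merge_split(win, ws, quant_config())
    covered <- unlist(lapply(seq_len(nrow(peaks)), function(i)
      peaks$win_from[i]:peaks$win_to[i]))
    expect_setequal(covered, which(ws > 2))
    expect_equal(anyDuplicated(covered), 0)
    expect_true(all(peaks$n_windows <= 5))
    expect_true(all(win$chrom[peaks$win_from] == win$chrom[peaks$win_to]))
  }
})

test_that("peak levels summarize member windows by mean or max", {
  ann <- mk_annotation(300L)
  win <- make_windows(ann)
  ws <- c(3, 5, 1, 1, 1)
  peaks <- call_merge_split(win, ws, quant_config())
  expect_equal(nrow(peaks), 1)  # windows 1-2 merge into a single peak
  lv_mean <- peak_levels(peaks, ws, quant_config())
  expect_equal(unname(lv_mean[1, 1]), 4)
  lv_max <- peak_levels(peaks, ws, quant_config(peak_level_stat = "max"))
  expect_equal(unname(lv_max[1, 1]), 5)
  # matrix shape: peaks x samples, single-window peak equals its winscore
  wsm <- cbind(S1 = ws, S2 = ws * 2)
  lv <- peak_levels(peaks, wsm, quant_config())
  expect_equal(dim(lv), c(1L, 2L))
  ws_iso <- c(1, 1, 1, 3, 1)
  p_iso <- call_merge_split(win, ws_iso, quant_config())
  expect_equal(unname(peak_levels(p_iso, ws_iso, quant_config())[1, 1]), 3)
})

test_that("quantile normalization equalizes column distributions exactly", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- tpm_quantile_normalize(x)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))
  set.seed(8)
  y <- matrix(rexp(400), ncol = 4)
  qy <- tpm_quantile_normalize(y)
  for (j in 2:4)
    expect_equal(sort(qy[, j]), sort(qy[, 1]), tolerance = 1e-12)
  expect_equal(diff(range(colMeans(qy))), 0, tolerance = 1e-12)
  # identical columns pass through unchanged
  z <- cbind(y[, 1], y[, 1])
  expect_equal(unname(tpm_quantile_normalize(z)), unname(z))
  expect_warning(tpm_quantile_normalize(y[, 1, drop = FALSE]), "2 columns")
})

test_that("matched windows pair rows by gene and maximal overlap", {
  ids <- c("G1:100-300", "G2:0-200", "G3:500-700")
  m <- match_windows(ids, ids)
  expect_equal(nrow(m), 3)
  expect_identical(m$id_a, m$id_b)
  # disjoint genes
  expect_equal(nrow(match_windows("G1:0-100", "G9:0-100")), 0)
  # two A peaks overlap one B peak: the larger overlap wins
  a <- c("G1:100-200", "G1:180-400")
  b <- "G1:150-400"
  m2 <- match_windows(a, b)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$id_a, "G1:180-400")  # overlap 220 beats 50
  expect_error(match_windows("nonsense", b), "malformed")
  # reciprocal fraction screens out slivers
  m3 <- match_windows("G1:0-1000", "G1:990-1000", min_overlap_frac = 0.5)
  expect_equal(nrow(m3), 0)
})

test_that("quantify_m6a runs the full chain and checks grid alignment", {
  cfg <- sim_config(n_cells = 10, n_sites = 8, seed = 17, seq_depth = 1e6)
  ann <- gen_annotation(cfg, n_transcripts = 8)
  spans <- plant_sites(ann, cfg)
  counts <- gen_window_counts(ann, spans, cfg)
  q <- quantify_m6a(counts$ip, counts$input)
  expect_gt(nrow(q$peaks), 0)
  expect_equal(nrow(q$levels), nrow(q$peaks))
  expect_true(all(is.finite(q$levels)))
  # all planted sites should be recovered by a matched peak
  m <- match_windows(spans$site_id, q$levels)
  expect_equal(nrow(m), nrow(spans))
  # mismatched grids are refused
  ann3 <- gen_annotation(cfg, n_transcripts = 3, seed = 99)
  other <- gen_window_counts(ann3, plant_sites(ann3, cfg), cfg)
  expect_error(quantify_m6a(counts$ip, other$input), "shared window grid")
})

test_that("window count tables validate their invariants", {
  win <- make_windows(mk_annotation(300L))
  expect_error(window_counts(win, 1:3, 100), "align")
  expect_error(window_counts(win, c(1, 2, 3, 4, -1), 100), "nonnegative")
  expect_error(window_counts(win, c(1, 2, 3, 4, 200), 100), "library_size")
})
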