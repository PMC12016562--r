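test_that("r_squared matches hand computations and edge rules", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_equal(r_squared(1:10, 1:10), 1)
  y <- c(4, 8, 6, 2)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(r_squared(1:3, 1:4), "misaligned")
})

test_that("tolerance labels implement the inclusive 0.5 rule", {
  cfg <- eval_config()
  expect_identical(tolerance_labels(0, 0.5, cfg), 1L)  # boundary inclusive
  expect_identical(tolerance_labels(c(0, 0, 0), c(0.4, 0.6, -0.5), cfg),
                   c(1L, 0L, 1L))
  expect_identical(tolerance_labels(1:5, 1:5, cfg), rep(1L, 5))
  # hand enumeration on random pairs
  withr::with_seed(20, {
    y <- rnorm(100); p <- y + rnorm(100, 0, 0.7)
  })
  oracle <- vapply(seq_along(y),
                   function(i) if (abs(p[i] - y[i]) <= 0.5) 1L else 0L,
                   integer(1))
  expect_identical(tolerance_labels(y, p, cfg), oracle)
})

test_that("rank AUROC equals the all-pairs brute force exactly", {
  withr::with_seed(21, {
    for (rep_i in 1:10) {
      n <- sample(10:50, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(rnorm(n), 1)  # rounding forces ties
      expect_equal(roc_auc(scores, labels)$auc,
                   auc_bruteforce(scores, labels))
    }
  })
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4)), "single class")
})

test_that("rank AUROC agrees with the pROC reference implementation", {
  withr::with_seed(22, {
    scores <- rnorm(80)
    labels <- rbinom(80, 1, plogis(scores))
  })
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                        predictor = scores,
                                        levels = c(0, 1), direction = "<",
                                        quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random labels give chance-level AUROC", {
  withr::with_seed(23, {
    scores <- rnorm(1000)
    labels <- sample(0:1, 1000, replace = TRUE)
  })
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("tolerance AUROC builds a seeded negative-enriched pool", {
  withr::with_seed(24, {
    y <- rnorm(300, 3, 1.5)
    p <- y + rnorm(300, 0, 0.2)  # accurate predictions
  })
  cfg <- eval_config(seed = 5)
  roc <- auroc_tolerance(y, p, cfg)
  expect_length(roc$labels, 600)  # observed pairs + resampled pool
  expect_true(all(c(0, 1) %in% roc$labels))
  # deterministic under the seed
  expect_identical(roc$auc, auroc_tolerance(y, p, cfg)$auc)
  # label is a threshold of the score, so observed AUROC is ~1 by design
  expect_gt(roc$auc, 0.99)
  # ... and collapses to chance when labels are shuffled against scores
  null <- permutation_null(function(l, s) roc_auc(s, l)$auc,
                           roc$labels, roc$scores,
                           eval_config(n_permutations = 200, seed = 6))
  expect_lt(abs(median(null$null) - 0.5), 0.05)
  # constant perfect predictions leave a single class -> undefined
  expect_error(auroc_tolerance(rep(1, 50), rep(1, 50), cfg), "single-class")
})

test_that("balanced accuracy matches the confusion-matrix formula", {
  # TP = 4, FN = 1, TN = 3, FP = 2 -> (0.8 + 0.6) / 2 = 0.7
  truth <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 1, 0, 1, 1, 0, 0, 0)
  expect_equal(balanced_accuracy(truth, pred), 0.7)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(truth, rep(1, 10)), 0.5)
  expect_error(balanced_accuracy(rep(1, 4), c(1, 0, 1, 0)), "single class")
  # score input: best threshold of a separable score vector gives 1
  expect_equal(balanced_accuracy(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
})

test_that("permutation nulls are centered, seeded and +1-corrected", {
  withr::with_seed(25, {
    y <- rnorm(400)
    p <- y + rnorm(400, 0, 0.3)  # strong signal
  })
  corr_metric <- function(a, b) correlate(a, b)$r
  cfg <- eval_config(n_permutations = 200, seed = 7)
  pn <- permutation_null(corr_metric, y, p, cfg)
  expect_equal(pn$p, 1 / 201)  # observed beats every draw
  expect_lt(abs(mean(pn$null)), 3 / sqrt(400 * 200 / 2))
  pn2 <- permutation_null(corr_metric, y, p, cfg)
  expect_identical(pn$null, pn2$null)
  expect_equal(pn$n_failed, 0)
})

test_that("correlation wrapper handles signs, nulls and guards", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(correlate(a, a)$r, 1)
  expect_equal(correlate(a, -a)$r, -1)
  withr::with_seed(26, {
    u <- rnorm(5000); v <- rnorm(5000)
  })
  expect_lt(abs(correlate(u, v)$r), 0.05)
  expect_gt(correlate(u, v)$p, 1e-4)
  sp <- correlate(a, a^3, eval_config(correlation_method = "spearman"))
  expect_equal(sp$r, 1)  # monotone transform
  expect_error(correlate(c(1, 2), c(1, 2)), "3 complete pairs")
  expect_error(correlate(rep(1, 5), a), "zero variance")
})

test_that("metagene bins follow the 10-per-region coordinate arithmetic", {
  ann <- data.frame(transcript_id = "TX1", utr5_len = 100, cds_len = 1000,
                    utr3_len = 400)
  # peak midpoint at the CDS midpoint -> bin 16 (CDS bins are 11-20)
  peaks <- data.frame(chrom = "TX1", start = 550, end = 650)
  prof <- metagene_profile(peaks, ann)
  expect_length(prof$density, 30)
  expect_equal(sum(prof$density), 1)
  expect_equal(unname(which(prof$density > 0)), 16)
  # analytic positions across all three regions
  mk <- function(mid) data.frame(chrom = "TX1", start = mid - 1, end = mid + 1)
  expect_equal(unname(which(metagene_profile(mk(5), ann)$density > 0)), 1)
  expect_equal(unname(which(metagene_profile(mk(95), ann)$density > 0)), 10)
  expect_equal(unname(which(metagene_profile(mk(105), ann)$density > 0)), 11)
  expect_equal(unname(which(metagene_profile(mk(1101), ann)$density > 0)), 21)
  expect_equal(unname(which(metagene_profile(mk(1460), ann)$density > 0)), 30)
  # no peaks -> zero vector; unknown transcripts skipped and counted
  empty <- metagene_profile(peaks[0, ], ann)
  expect_equal(sum(empty$density), 0)
  sk <- metagene_profile(data.frame(chrom = c("TX1", "ghost"),
                                    start = c(550, 0), end = c(650, 10)),
                         ann)
  expect_equal(sk$n_skipped, 1)
  expect_equal(sk$n_mapped, 1)
})

test_that("evaluation reports summarize per-site metrics by quartiles", {
  withr::with_seed(27, {
    truth <- matrix(rnorm(20 * 60, 3), 20, 60,
                    dimnames = list(paste0("s", 1:20), paste0("c", 1:60)))
    pred <- truth + matrix(rnorm(20 * 60, 0, 0.3), 20, 60,
                           dimnames = dimnames(truth))
  })
  rep <- evaluate_predictions(truth, pred, eval_config(seed = 9))
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep$per_site), 20)
  expect_true(all(rep$per_site$auroc >= 0 & rep$per_site$auroc <= 1,
                  na.rm = TRUE))
  expect_true(all(rep$per_site$r2 <= 1, na.rm = TRUE))
  expect_identical(rownames(rep$summary),
                   c("r2", "auroc", "balanced_accuracy"))
  expect_true(all(rep$summary$q25 <= rep$summary$median &
                    rep$summary$median <= rep$summary$q75, na.rm = TRUE))
  out <- file.path(tempdir(), "eval_test")
  write_eval_report(rep, out)
  expect_true(file.exists(paste0(out, ".json")))
  js <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(js$tolerance, 0.5)
  unlink(paste0(out, c(".json", "_per_site.tsv")))
})
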