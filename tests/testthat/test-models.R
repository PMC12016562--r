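make_linear_data <- function(n = 200, p = 10, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rlnorm(n * p, 1, 1), n, p,
                dimnames = list(sprintf("cell_%03d", 1:n), paste0("R", 1:p)))
    beta <- c(1.5, -1, 0.5, rep(0, p - 3))
    y <- 3 + log1p(X) %*% beta + rnorm(n, 0, noise)
  })
  list(X = log1p(X), y = drop(y), beta = beta)
}

test_that("train/test split is a seeded 70/30 partition", {
  cfg <- train_config(seed = 4)
  s <- split_train_test(10, cfg)
  expect_length(s$train, 7)
  expect_length(s$test, 3)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_identical(s, split_train_test(10, cfg))
  s2 <- split_train_test(paste0("c", 1:100), cfg)
  expect_length(s2$train, 70)
  expect_error(split_train_test(3, cfg), "at least 4")
})

test_that("grid search evaluates the full grid and picks the CV winner", {
  d <- make_linear_data(n = 500, p = 20, noise = 0.1, seed = 2)
  cfg <- train_config(seed = 2)
  # single-candidate grid is returned untouched
  one <- grid_search(model_spec("knn", grid = list(k = 7)), d$X, d$y, cfg)
  expect_equal(one$best, list(k = 7))
  # table bookkeeping: grid size x folds rows
  gs <- grid_search(model_spec("knn", grid = list(k = c(3, 5, 10))),
                    d$X, d$y, cfg)
  expect_equal(nrow(gs$scores), 3 * 5)
  expect_true(gs$best$k %in% c(3, 5, 10))
  # planted linear data: lr cross-validates essentially perfectly
  lr <- grid_search(model_spec("lr"), d$X, d$y, cfg)
  expect_gte(lr$best_mean_r2, 0.9)
})

test_that("all five regressor families fit and predict finite values", {
  d <- make_linear_data(n = 120, p = 5, noise = 0.2, seed = 3)
  y <- matrix(d$y, 1, 120, dimnames = list("s1", rownames(d$X)))
  for (fam in c("rf", "knn", "svr_poly", "lr", "linear_svr")) {
    spec <- model_spec(fam, grid = list())
    fit <- fit_scm6a(spec, d$X, y, train_config(seed = 3))
    pred <- predict(fit, d$X)
    expect_equal(dim(pred), c(1L, 120L))
    expect_true(all(is.finite(pred)), info = fam)
  }
})

test_that("noise-free linear data is interpolated exactly by lr", {
  d <- make_linear_data(n = 150, p = 8, noise = 0, seed = 5)
  y <- matrix(d$y, 1, 150, dimnames = list("s1", rownames(d$X)))
  fit <- fit_scm6a(model_spec("lr"), d$X, y, train_config(seed = 5))
  pred <- predict(fit, d$X)
  expect_equal(unname(pred[1, ]), unname(d$y), tolerance = 1e-6)
  expect_equal(r_squared(d$y[fit$split$test_idx],
                         pred[1, fit$split$test_idx]), 1, tolerance = 1e-6)
})

test_that("constant targets degrade gracefully to a constant predictor", {
  d <- make_linear_data(n = 60, p = 4, seed = 6)
  y <- matrix(2.2, 1, 60, dimnames = list("s1", rownames(d$X)))
  fit <- fit_scm6a(model_spec("lr"), d$X, y, train_config(seed = 6))
  pred <- predict(fit, d$X * 5)
  expect_equal(unname(pred[1, ]), rep(2.2, 60), tolerance = 1e-8)
  expect_error(r_squared(y[1, ], pred[1, ]), "zero variance")
})

test_that("fits are deterministic under a fixed seed", {
  d <- make_linear_data(n = 150, p = 6, noise = 0.3, seed = 7)
  y <- matrix(d$y + rev(d$y), 1, 150, dimnames = list("s1", rownames(d$X)))
  spec <- model_spec("rf", grid = list(num.trees = 100), seed = 99)
  f1 <- fit_scm6a(spec, d$X, y, train_config(seed = 7))
  f2 <- fit_scm6a(spec, d$X, y, train_config(seed = 7))
  expect_identical(predict(f1, d$X), predict(f2, d$X))
})

test_that("per-site and global modes cover identical site ids", {
  withr::with_seed(10, {
    X <- matrix(rlnorm(100 * 6), 100, 6,
                dimnames = list(paste0("c", 1:100), paste0("R", 1:6)))
    y <- matrix(rnorm(5 * 100, 3), 5, 100,
                dimnames = list(paste0("G", 1:5, ":0-100"), paste0("c", 1:100)))
    cis <- matrix(runif(5 * 4), 5, 4, dimnames = list(rownames(y), NULL))
  })
  ps <- fit_scm6a(model_spec("lr"), X, y, train_config(seed = 10))
  gl <- fit_scm6a(model_spec("lr"), X, y,
                  train_config(mode = "global", seed = 10), cis = cis)
  pp <- predict(ps, X); pg <- predict(gl, X)
  expect_identical(rownames(pp), rownames(pg))
  expect_identical(dim(pp), dim(pg))
  expect_error(fit_scm6a(model_spec("lr"), X, y,
                         train_config(mode = "global", seed = 1)),
               "cis")
})

test_that("log2 target transform round-trips predictions to the raw scale", {
  d <- make_linear_data(n = 120, p = 5, noise = 0, seed = 11)
  y <- matrix(pmax(d$y, 0), 1, 120, dimnames = list("s1", rownames(d$X)))
  fit <- fit_scm6a(model_spec("knn", grid = list(k = 1)), d$X, y,
                   train_config(target_transform = "log2", seed = 11))
  pred <- predict(fit, d$X)
  tr <- fit$split$train_idx
  expect_equal(unname(pred[1, tr]), unname(y[1, tr]), tolerance = 1e-8)
})

test_that("sites with all-missing training targets are skipped, reported", {
  d <- make_linear_data(n = 80, p = 5, noise = 0.1, seed = 12)
  y <- rbind(s1 = d$y, s2 = NA_real_)
  colnames(y) <- rownames(d$X)
  fit <- fit_scm6a(model_spec("lr"), d$X, y, train_config(seed = 12))
  expect_identical(fit$skipped_sites, "s2")
  expect_identical(fit$site_ids, "s1")
})

test_that("manifest mismatches are errors; extra columns warn", {
  d <- make_linear_data(n = 80, p = 5, noise = 0.1, seed = 13)
  y <- matrix(d$y, 1, 80, dimnames = list("s1", rownames(d$X)))
  fit <- fit_scm6a(model_spec("lr"), d$X, y, train_config(seed = 13))
  expect_error(predict(fit, d$X[, 1:3]), "lacks manifest columns")
  extra <- cbind(d$X, junk = 1)
  expect_warning(p2 <- predict(fit, extra), "ignoring")
  expect_equal(p2, predict(fit, d$X))
})

test_that("model bundles round-trip on disk and reject tampering", {
  d <- make_linear_data(n = 80, p = 5, noise = 0.1, seed = 14)
  y <- matrix(d$y, 1, 80, dimnames = list("s1", rownames(d$X)))
  fit <- fit_scm6a(model_spec("rf", grid = list(num.trees = 50)), d$X, y,
                   train_config(seed = 14))
  dir <- file.path(tempdir(), "bundle_test")
  save_models(fit, dir)
  back <- load_models(dir)
  expect_identical(predict(back, d$X), predict(fit, d$X))
  # tampered feature manifest is refused
  writeLines(c("R1", "R2", "hacked", "R4", "R5"),
             file.path(dir, "features.txt"))
  expect_error(load_models(dir), "hash mismatch")
  expect_error(load_models(file.path(tempdir(), "no_such_bundle")),
               "missing file")
  unlink(dir, recursive = TRUE)
})

test_that("refitting on permuted targets destroys test R-squared", {
  withr::with_seed(15, {
    X <- matrix(rlnorm(200 * 20, 1, 1), 200, 20,
                dimnames = list(paste0("c", 1:200), paste0("R", 1:20)))
    B <- matrix(0, 50, 20)
    for (s in 1:50)
      B[s, sample(20, 3)] <- sample(c(-1, 1), 3, TRUE) * runif(3, 0.5, 1.5)
    y <- 3 + B %*% t(log1p(X)) + matrix(rnorm(50 * 200, 0, 0.05), 50)
    dimnames(y) <- list(paste0("site", 1:50), rownames(X))
    y_shuf <- t(apply(y, 1, sample))
    colnames(y_shuf) <- colnames(y)
  })
  feats <- log1p(X)
  cfg <- train_config(seed = 15)
  fit <- fit_scm6a(model_spec("lr"), feats, y_shuf, cfg)
  pred <- predict(fit, feats)
  te <- fit$split$test_idx
  r2 <- vapply(seq_len(50), function(s)
    r_squared(y_shuf[s, te], pred[s, te]), numeric(1))
  expect_lte(median(r2), 0.05)
  # while the intact pairing fits well
  fit0 <- fit_scm6a(model_spec("lr"), feats, y, cfg)
  pred0 <- predict(fit0, feats)
  r20 <- vapply(seq_len(50), function(s)
    r_squared(y[s, te], pred0[s, te]), numeric(1))
  expect_gt(median(r20), 0.9)
})
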