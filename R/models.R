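MODEL_FAMILIES <- c("rf", "knn", "svr_poly", "lr", "linear_svr")
MODEL_FORMAT_VERSION <- "1.0"

#' Default hyperparameter grids
#'
#' Candidate grids searched by cross-validation for each regressor family.
#' Linear regression has no tunable hyperparameters. All grids are
#' overridable through [model_spec()].
#'
#' @param family one of `rf`, `knn`, `svr_poly`, `lr`, `linear_svr`.
#' @return Named list of candidate value vectors.
#' @export
default_grid <- function(family) {
  switch(family,
         rf = list(num.trees = c(100, 300, 500), max.depth = c(0, 10, 20)),
         knn = list(k = c(3, 5, 10)),
         svr_poly = list(degree = c(2, 3), cost = c(0.1, 1, 10)),
         linear_svr = list(cost = c(0.1, 1, 10)),
         lr = list(),
         stop2("unknown model family: ", family))
}

#' Model specification
#'
#' Selects one of the five regressor families mapping features to per-site
#' m6A levels — random forest (`rf`), k-nearest neighbours (`knn`),
#' polynomial-kernel support vector regression (`svr_poly`), linear
#' regression (`lr`), linear support vector regression (`linear_svr`) —
#' together with its hyperparameter grid and a seed for the stochastic
#' stages.
#'
#' @param family regressor family.
#' @param grid named list of candidate hyperparameter values; exhaustively
#'   crossed during [grid_search()].
#' @param seed integer seed threaded into stochastic fits.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("rf", "knn", "svr_poly", "lr", "linear_svr"),
                       grid = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  stopifnot(is.list(grid))
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

#' Training configuration
#'
#' @param train_fraction fraction of observations randomly allocated to the
#'   training set (default 0.70; the remainder is the held-out test set).
#' @param cv_folds folds of the cross-validation used for hyperparameter
#'   selection (default 5).
#' @param mode `"per_site"` (one regressor per m6A site on trans features)
#'   or `"global"` (one pooled regressor over site-by-observation rows with
#'   trans features joined to per-site cis features).
#' @param target_transform `"identity"` or `"log2"` (fits on `log2(y + 1)`,
#'   predictions returned on the original scale).
#' @param per_site_grid if TRUE, the hyperparameter grid is searched
#'   separately for every site; by default it is searched once on a
#'   reference site and the winning parameters are shared.
#' @param seed integer seed for the split and fold assignment.
#' @return A list of class `train_config`.
#' @export
train_config <- function(train_fraction = 0.70, cv_folds = 5L,
                         mode = c("per_site", "global"),
                         target_transform = c("identity", "log2"),
                         per_site_grid = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  target_transform <- match.arg(target_transform)
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop2("train_config: train_fraction must lie strictly between 0 and 1")
  if (!is_count(cv_folds) || cv_folds < 2)
    stop2("train_config: cv_folds must be an integer >= 2")
  structure(list(train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), mode = mode,
                 target_transform = target_transform,
                 per_site_grid = isTRUE(per_site_grid),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split observations into training and test sets
#'
#' Random, seeded, disjoint and exhaustive split; the training set has
#' `round(train_fraction * n)` observations.
#'
#' @param obs observation ids (character vector) or a single count `n`.
#' @param cfg a [train_config()].
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(obs, cfg = train_config()) {
  ids <- if (length(obs) == 1 && is.numeric(obs)) seq_len(obs) else obs
  n <- length(ids)
  if (n < 4) stop2("split_train_test: need at least 4 observations")
  n_train <- round(cfg$train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  tr <- withr::with_seed(cfg$seed, sort(sample.int(n, n_train)))
  list(train = ids[tr], test = ids[-tr])
}

apply_transform <- function(y, transform) {
  if (transform == "log2") log2(y + 1) else y
}

invert_transform <- function(p, transform) {
  if (transform == "log2") pmax(2^p - 1, 0) else p
}

fit_regressor <- function(family, x, y, params = list(), seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- switch(family,
    rf = ranger::ranger(x = x, y = y,
                        num.trees = params$num.trees %||% 300,
                        max.depth = params$max.depth %||% 0,
                        # regression-forest convention (p/3), which handles
                        # sparse signals much better than sqrt(p)
                        mtry = params$mtry %||% max(1, floor(ncol(x) / 3)),
                        importance = "impurity",
                        seed = seed, num.threads = 1),
    knn = caret::knnreg(x, y, k = params$k %||% 5),
    svr_poly = e1071::svm(x = x, y = y, type = "eps-regression",
                          kernel = "polynomial",
                          degree = params$degree %||% 3,
                          cost = params$cost %||% 1, scale = FALSE),
    linear_svr = e1071::svm(x = x, y = y, type = "eps-regression",
                            kernel = "linear",
                            cost = params$cost %||% 1, scale = FALSE),
    lr = {
      f <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
      cf <- f$coefficients
      cf[is.na(cf)] <- 0
      list(coef = cf)
    },
    stop2("unknown model family: ", family))
  structure(list(family = family, fit = fit, features = colnames(x)),
            class = "scm6a_regressor")
}

predict_regressor <- function(m, x) {
  x <- as.matrix(x)[, m$features, drop = FALSE]
  switch(m$family,
         rf = predict(m$fit, data = x, num.threads = 1)$predictions,
         knn = as.numeric(predict(m$fit, x)),
         svr_poly = ,
         linear_svr = as.numeric(predict(m$fit, x)),
         lr = drop(cbind(1, x) %*% m$fit$coef))
}

expand_candidates <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  g <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every hyperparameter candidate by k-fold cross-validated mean
#' R-squared and returns the winner (ties broken by first-in-grid order).
#' Fold assignment and every stochastic fit are seeded, so repeated calls
#' are identical.
#'
#' @param spec a [model_spec()].
#' @param X observations-by-features matrix.
#' @param y numeric response aligned with `X` rows.
#' @param cfg a [train_config()]; supplies `cv_folds` and the seed.
#' @return List with `best` (named hyperparameter list), `best_mean_r2`,
#'   and `scores`, a data frame with one row per candidate-fold pair.
#' @export
grid_search <- function(spec, X, y, cfg = train_config()) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop2("grid_search: X and y are misaligned")
  if (nrow(X) < cfg$cv_folds)
    stop2("grid_search: fewer observations than cv_folds")
  candidates <- expand_candidates(spec$grid)
  folds <- withr::with_seed(cfg$seed + 11L,
    sample(rep_len(seq_len(cfg$cv_folds), nrow(X))))
  rows <- list()
  means <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    r2 <- numeric(cfg$cv_folds)
    for (k in seq_len(cfg$cv_folds)) {
      hold <- folds == k
      m <- fit_regressor(spec$family, X[!hold, , drop = FALSE], y[!hold],
                         candidates[[ci]], seed = spec$seed)
      pred <- predict_regressor(m, X[hold, , drop = FALSE])
      r2[k] <- if (sd(y[hold]) == 0) NA_real_ else r_squared(y[hold], pred)
    }
    means[ci] <- mean(r2)
    rows[[ci]] <- data.frame(candidate = ci,
                             params = vapply(list(candidates[[ci]]),
                                             function(p) paste(
                                               names(p), unlist(p),
                                               sep = "=", collapse = ","),
                                             character(1)),
                             fold = seq_len(cfg$cv_folds), r2 = r2,
                             stringsAsFactors = FALSE)
  }
  if (all(!is.finite(means)))
    stop2("grid_search: no candidate produced a finite CV score")
  means[!is.finite(means)] <- -Inf
  best <- which.max(means)
  list(best = candidates[[best]], best_mean_r2 = means[best],
       scores = do.call(rbind, rows))
}

#' Fit the per-site (or global) m6A regression models
#'
#' Splits observations 70/30 (seeded), selects hyperparameters by grid
#' search with k-fold cross-validation on the training set, and fits the
#' chosen regressor. In `per_site` mode one regressor is fitted per m6A
#' site on the trans features; in `global` mode one pooled regressor is
#' fitted on site-by-observation rows whose features are the observation's
#' trans features joined with the site's cis features. Unless
#' `per_site_grid` is set, the grid is searched once on the first site with
#' complete training targets and the winning parameters are shared across
#' sites.
#'
#' @param spec a [model_spec()].
#' @param X observations(cells)-by-features trans feature matrix.
#' @param y sites-by-observations matrix of m6A levels (may contain NAs;
#'   sites with no usable training target are skipped and reported).
#' @param cfg a [train_config()].
#' @param cis sites-by-features cis feature matrix, required in `global`
#'   mode, rows aligned with `y`.
#' @return A `SiteModelSet`: fitted regressor(s), chosen hyperparameters,
#'   feature manifest, split ids, target transform and seeds.
#' @export
fit_scm6a <- function(spec, X, y, cfg = train_config(), cis = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "train_config"))
  X <- as.matrix(X)
  y <- as.matrix(y)
  if (ncol(y) != nrow(X))
    stop2("fit_scm6a: y must be sites x observations with columns matching X rows")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  site_ids <- rownames(y) %||% paste0("site_", seq_len(nrow(y)))
  obs_ids <- rownames(X) %||% paste0("obs_", seq_len(nrow(X)))
  split <- split_train_test(seq_len(nrow(X)), cfg)
  yt <- apply_transform(y, cfg$target_transform)
  candidates <- expand_candidates(spec$grid)

  if (cfg$mode == "per_site") {
    usable <- rowSums(!is.na(yt[, split$train, drop = FALSE])) > 0
    skipped <- site_ids[!usable]
    if (!any(usable)) stop2("fit_scm6a: every site has all-missing training targets")
    shared_params <- NULL
    grid_scores <- NULL
    if (!cfg$per_site_grid && length(candidates) > 1) {
      ref <- which(rowSums(is.na(yt[, split$train, drop = FALSE])) == 0)[1]
      if (is.na(ref)) ref <- which(usable)[1]
      keep <- split$train[!is.na(yt[ref, split$train])]
      gs <- grid_search(spec, X[keep, , drop = FALSE], yt[ref, keep], cfg)
      shared_params <- gs$best
      grid_scores <- gs$scores
    } else if (length(candidates) == 1) {
      shared_params <- candidates[[1]]
    }
    models <- vector("list", sum(usable))
    names(models) <- site_ids[usable]
    for (s in which(usable)) {
      keep <- split$train[!is.na(yt[s, split$train])]
      if (length(keep) < cfg$cv_folds)
        stop2("fit_scm6a: site ", site_ids[s], " has fewer than cv_folds (",
              cfg$cv_folds, ") training observations")
      params <- shared_params
      if (is.null(params)) {
        gs <- grid_search(spec, X[keep, , drop = FALSE], yt[s, keep], cfg)
        params <- gs$best
      }
      models[[site_ids[s]]] <- fit_regressor(spec$family,
                                             X[keep, , drop = FALSE],
                                             yt[s, keep], params,
                                             seed = spec$seed)
    }
    out <- list(mode = "per_site", family = spec$family,
                models = models, params = shared_params,
                grid_scores = grid_scores, cis = NULL)
  } else {
    if (is.null(cis))
      stop2("fit_scm6a: global mode requires a cis feature matrix")
    cis <- as.matrix(cis)
    if (nrow(cis) != nrow(y))
      stop2("fit_scm6a: cis rows must align with y sites")
    if (is.null(colnames(cis))) colnames(cis) <- paste0("c", seq_len(ncol(cis)))
    rownames(cis) <- site_ids
    skipped <- character()
    tr <- split$train
    big_x <- do.call(rbind, lapply(seq_len(nrow(y)), function(s)
      cbind(X[tr, , drop = FALSE],
            matrix(cis[s, ], nrow = length(tr), ncol = ncol(cis),
                   byrow = TRUE, dimnames = list(NULL, colnames(cis))))))
    big_y <- as.vector(t(yt[, tr, drop = FALSE]))
    ok <- !is.na(big_y)
    if (!any(ok)) stop2("fit_scm6a: all training targets missing")
    params <- if (length(candidates) > 1) {
      gs <- grid_search(spec, big_x[ok, , drop = FALSE], big_y[ok], cfg)
      gs$best
    } else candidates[[1]]
    model <- fit_regressor(spec$family, big_x[ok, , drop = FALSE],
                           big_y[ok], params, seed = spec$seed)
    out <- list(mode = "global", family = spec$family,
                models = list(global = model), params = params,
                grid_scores = NULL, cis = cis)
  }
  out$site_ids <- if (cfg$mode == "per_site") names(out$models) else site_ids
  out$skipped_sites <- skipped
  out$manifest <- colnames(X)
  out$target_transform <- cfg$target_transform
  out$seed <- spec$seed
  out$split <- list(train = obs_ids[split$train], test = obs_ids[split$test],
                    train_idx = split$train, test_idx = split$test)
  out$version <- MODEL_FORMAT_VERSION
  class(out) <- "SiteModelSet"
  out
}

#' @export
print.SiteModelSet <- function(x, ...) {
  cat("SiteModelSet (", x$mode, ", family ", x$family, "): ",
      length(x$site_ids), " sites, ", length(x$manifest),
      " trans features, target transform ", x$target_transform, "\n",
      sep = "")
  invisible(x)
}

check_manifest <- function(object, features) {
  have <- colnames(features)
  missing <- setdiff(object$manifest, have)
  if (length(missing))
    stop2("predict: feature matrix lacks manifest columns: ",
          paste(head(missing, 5), collapse = ", "))
  extra <- setdiff(have, object$manifest)
  if (length(extra))
    warning("predict: ignoring ", length(extra),
            " feature columns absent from the model manifest")
  features[, object$manifest, drop = FALSE]
}

#' Predict per-site m6A levels for new observations
#'
#' Applies a fitted `SiteModelSet` to a (cells-by-features) trans feature
#' matrix and returns a sites-by-cells m6A matrix on the original target
#' scale. The feature manifest is enforced: missing columns are an error,
#' extra columns are dropped with a warning.
#'
#' @param object a `SiteModelSet` from [fit_scm6a()].
#' @param features observations-by-features matrix.
#' @param ... unused.
#' @return Sites-by-observations numeric matrix.
#' @export
predict.SiteModelSet <- function(object, features, ...) {
  features <- check_manifest(object, as.matrix(features))
  obs_ids <- rownames(features) %||% paste0("obs_", seq_len(nrow(features)))
  n_sites <- length(object$site_ids)
  pred <- matrix(NA_real_, nrow = n_sites, ncol = nrow(features),
                 dimnames = list(object$site_ids, obs_ids))
  if (object$mode == "per_site") {
    for (s in seq_len(n_sites))
      pred[s, ] <- predict_regressor(object$models[[s]], features)
  } else {
    cis <- object$cis
    for (s in seq_len(n_sites)) {
      xs <- cbind(features,
                  matrix(cis[s, ], nrow = nrow(features), ncol = ncol(cis),
                         byrow = TRUE, dimnames = list(NULL, colnames(cis))))
      pred[s, ] <- predict_regressor(object$models$global, xs)
    }
  }
  invert_transform(pred, object$target_transform)
}

#' Save a fitted model set to a directory bundle
#'
#' The bundle holds a JSON manifest (family, mode, hyperparameters, feature
#' list checksum, target transform, seed, format version), the feature list
#' as plain text, and the serialized regressors.
#'
#' @param models a `SiteModelSet`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "SiteModelSet"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  feat_file <- file.path(path, "features.txt")
  writeLines(models$manifest, feat_file)
  manifest <- list(format_version = models$version, family = models$family,
                   mode = models$mode, params = models$params,
                   target_transform = models$target_transform,
                   seed = models$seed, n_sites = length(models$site_ids),
                   features_md5 = unname(tools::md5sum(feat_file)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(models, file.path(path, "models.rds"))
  invisible(path)
}

#' Load a model bundle written by [save_models()]
#'
#' Refuses bundles with a mismatched format version or a feature manifest
#' whose checksum does not match the stored hash.
#'
#' @param path bundle directory.
#' @return The `SiteModelSet`.
#' @export
load_models <- function(path) {
  for (f in c("manifest.json", "features.txt", "models.rds")) {
    if (!file.exists(file.path(path, f)))
      stop2("load_models: missing file ", file.path(path, f))
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  if (!identical(manifest$format_version, MODEL_FORMAT_VERSION))
    stop2("load_models: format version mismatch (bundle ",
          manifest$format_version, ", supported ", MODEL_FORMAT_VERSION, ")")
  md5 <- unname(tools::md5sum(file.path(path, "features.txt")))
  if (!identical(md5, manifest$features_md5))
    stop2("load_models: feature manifest hash mismatch; refusing to load")
  models <- readRDS(file.path(path, "models.rds"))
  feats <- readLines(file.path(path, "features.txt"))
  if (!identical(feats, models$manifest))
    stop2("load_models: feature manifest does not match the stored models")
  models
}
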