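PIPELINE_STAGES <- c("simulate", "quantify", "build-features", "train",
                     "predict", "evaluate", "metagene")

section_builders <- function() {
  list(sim = sim_config, quant = quant_config, train = train_config,
       eval = eval_config, qc = qc_config)
}

#' Pipeline run configuration
#'
#' Merges the per-stage configurations into one serializable object. Every
#' stage consumes only its own section; unknown sections or keys are
#' rejected so config typos fail loudly instead of silently using
#' defaults.
#'
#' @param seed master seed; section seeds default to it.
#' @param sim,quant,train,eval,qc named lists of arguments for
#'   [sim_config()], [quant_config()], [train_config()], [eval_config()],
#'   [qc_config()].
#' @param model named list: `family` (one of the five regressors) and
#'   optionally `grid`.
#' @param features named list: `transform` (`"log1p"`, the default, or
#'   `"identity"`) applied to the trans feature matrix.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = list(), quant = list(),
                       train = list(), eval = list(), qc = list(),
                       model = list(), features = list()) {
  builders <- section_builders()
  sections <- list(sim = sim, quant = quant, train = train, eval = eval,
                   qc = qc)
  cfg <- list(seed = as.integer(seed))
  for (nm in names(sections)) {
    sec <- sections[[nm]]
    allowed <- names(formals(builders[[nm]]))
    unknown <- setdiff(names(sec), allowed)
    if (length(unknown))
      stop2("run_config: unknown key(s) in `", nm, "`: ",
            paste(unknown, collapse = ", "))
    if ("seed" %in% allowed && is.null(sec$seed)) sec$seed <- seed
    cfg[[nm]] <- do.call(builders[[nm]], sec)
  }
  unknown <- setdiff(names(model), c("family", "grid"))
  if (length(unknown))
    stop2("run_config: unknown key(s) in `model`: ",
          paste(unknown, collapse = ", "))
  cfg$model <- list(family = model$family %||% "rf", grid = model$grid)
  if (!cfg$model$family %in% MODEL_FAMILIES)
    stop2("run_config: model family must be one of ",
          paste(MODEL_FAMILIES, collapse = ", "))
  unknown <- setdiff(names(features), "transform")
  if (length(unknown))
    stop2("run_config: unknown key(s) in `features`: ",
          paste(unknown, collapse = ", "))
  cfg$features <- list(transform = features$transform %||% "log1p")
  if (!cfg$features$transform %in% c("log1p", "identity"))
    stop2("run_config: features$transform must be log1p or identity")
  structure(cfg, class = "run_config")
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Save / load a run configuration (YAML)
#'
#' `load_run_config(save_run_config(cfg))` reproduces `cfg` exactly (the
#' round-trip re-validates through [run_config()]).
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `path` / the `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(strip_classes(cfg), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop2("load_run_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("seed", "sim", "quant", "train", "eval", "qc", "model",
             "features")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop2("load_run_config: unknown section(s): ",
          paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

config_md5 <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip_classes(cfg), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

need_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop2("run_pipeline: stage `", stage, "` needs `", path,
          "`; run the `", produced_by, "` stage first or provide the file")
  path
}

stage_msg <- function(stage, t0) {
  message(sprintf("[scm6a] %-14s %6.1fs", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the end-to-end pipeline
#'
#' Wires the stages simulate -> quantify -> build-features -> train ->
#' predict -> evaluate (-> metagene) through plain-file artifacts in
#' `out_dir` (TSV/BED/JSON only, inspectable and reusable across tools).
#' Each stage reads only files, so any stage can be re-run or fed external
#' data in the same formats. A run manifest (config hash, seed, package
#' version, stages) is written alongside; rerunning with an identical
#' config reproduces identical artifacts.
#'
#' @param config a [run_config()].
#' @param stages subset of
#'   `c("simulate", "quantify", "build-features", "train", "predict",
#'   "evaluate", "metagene")`.
#' @param out_dir artifact directory (created if needed).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config = run_config(), stages = PIPELINE_STAGES,
                         out_dir = "scm6a_run") {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  art <- list(expression = p("expression.tsv"), truth = p("m6a_truth.tsv"),
              annotation = p("annotation.tsv"), spans = p("spans.tsv"),
              ip = p("ip_counts.tsv"), input = p("input_counts.tsv"),
              ppms = p("ppms.txt"), regulators = p("regulators.txt"),
              peaks = p("peaks.bed"), winscore = p("m6a_winscore.tsv"),
              features = p("features.tsv"), models = p("models"),
              pred = p("m6a_pred.tsv"), eval = p("eval"),
              metagene = p("metagene.tsv"), manifest = p("run_manifest.json"))

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    sim <- simulate_dataset(config$sim, config$quant,
                            fold_from_levels = TRUE)
    write_expression_tsv(t(sim$expr), art$expression)  # genes x cells on disk
    write_m6a_matrix(sim$m6a, art$truth)
    write_annotation(sim$annotation, art$annotation)
    write.table(sim$spans, art$spans, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_window_counts(sim$counts$ip, art$ip)
    write_window_counts(sim$counts$input, art$input)
    write_ppms(sim$ppms, art$ppms)
    writeLines(colnames(sim$expr), art$regulators)
    stage_msg("simulate", t0)
  }

  if ("quantify" %in% stages) {
    t0 <- proc.time()[3]
    ip <- read_window_counts(need_artifact(art$ip, "quantify", "simulate"))
    input <- read_window_counts(need_artifact(art$input, "quantify",
                                              "simulate"))
    q <- quantify_m6a(ip, input, config$quant)
    write_peaks_bed(q$peaks, q$levels, art$peaks)
    write_m6a_matrix(q$levels, art$winscore)
    stage_msg("quantify", t0)
  }

  if ("build-features" %in% stages) {
    t0 <- proc.time()[3]
    expr <- read_expression_tsv(need_artifact(art$expression,
                                              "build-features", "simulate"))
    regulators <- read_regulators(need_artifact(art$regulators,
                                                "build-features", "simulate"))
    feats <- build_trans_features(expr, regulators)
    if (config$features$transform == "log1p") feats[] <- log1p(feats)
    write_expression_tsv(t(feats), art$features)  # features x cells on disk
    stage_msg("build-features", t0)
  }

  read_features <- function(stage) {
    t(read_expression_tsv(need_artifact(art$features, stage,
                                        "build-features")))
  }

  if ("train" %in% stages) {
    t0 <- proc.time()[3]
    feats <- read_features("train")
    truth <- read_m6a_matrix(need_artifact(art$truth, "train", "simulate"))
    spec <- model_spec(config$model$family, grid = config$model$grid,
                       seed = config$seed)
    models <- fit_scm6a(spec, feats, truth, config$train)
    save_models(models, art$models)
    stage_msg("train", t0)
  }

  if ("predict" %in% stages) {
    t0 <- proc.time()[3]
    need_artifact(file.path(art$models, "manifest.json"), "predict", "train")
    models <- load_models(art$models)
    feats <- read_features("predict")
    pred <- predict(models, feats)
    write_m6a_matrix(pred, art$pred)
    stage_msg("predict", t0)
  }

  if ("evaluate" %in% stages) {
    t0 <- proc.time()[3]
    truth <- read_m6a_matrix(need_artifact(art$truth, "evaluate", "simulate"))
    pred <- read_m6a_matrix(need_artifact(art$pred, "evaluate", "predict"))
    need_artifact(file.path(art$models, "manifest.json"), "evaluate", "train")
    models <- load_models(art$models)
    test_cells <- intersect(models$split$test, colnames(pred))
    report <- evaluate_predictions(truth[, test_cells, drop = FALSE],
                                   pred[, test_cells, drop = FALSE],
                                   config$eval)
    write_eval_report(report, art$eval)
    stage_msg("evaluate", t0)
  }

  if ("metagene" %in% stages) {
    t0 <- proc.time()[3]
    ann <- read_annotation(need_artifact(art$annotation, "metagene",
                                         "simulate"))
    bed <- read.table(need_artifact(art$peaks, "metagene", "quantify"),
                      sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("chrom", "start", "end", "name",
                                    "score", "strand"))
    prof <- metagene_profile(bed, ann)
    write.table(data.frame(bin = names(prof$density),
                           count = as.numeric(prof$counts),
                           density = as.numeric(prof$density)),
                art$metagene, sep = "\t", quote = FALSE, row.names = FALSE)
    stage_msg("metagene", t0)
  }

  jsonlite::write_json(list(package = "scm6a",
                            version = as.character(utils::packageVersion("scm6a")),
                            config_md5 = config_md5(config),
                            seed = config$seed,
                            stages = stages),
                       art$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(art)
}
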