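#' Configuration for an end-to-end link-prediction run
#'
#' Feature-set presets map to the three standard configurations:
#' `"I"` = path counts over the similarity-free catalog subset (29 columns),
#' `"II"` = path counts over the full catalog (51 columns),
#' `"III"` = path counts plus random-walk normalization over the full
#' catalog (102 columns). `"custom"` uses `measures` as given on the full
#' catalog.
#'
#' @param network path to an edge-list TSV, or a `hetnet`.
#' @param labels path to a labeled-pairs TSV, or a data.frame
#'   (`compound_id`, `protein_id`, `label`).
#' @param catalog path to a catalog YAML, or a `metapath_catalog`; default
#'   is the packaged 51-entry catalog.
#' @param feature_set `"I"`, `"II"`, `"III"` or `"custom"`.
#' @param measures measures for `feature_set = "custom"`.
#' @param model a [model_spec()].
#' @param ratio train:test split ratio (default 2:1).
#' @param seed master seed; stage seeds are derived from it and logged.
#' @param out_dir output directory for the run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(network, labels, catalog = NULL,
                       feature_set = c("III", "II", "I", "custom"),
                       measures = c("PC", "RW"), model = model_spec("rf"),
                       ratio = c(2, 1), seed = 1L, out_dir = tempfile("run")) {
  feature_set <- match.arg(feature_set)
  structure(list(network = network, labels = labels, catalog = catalog,
                 feature_set = feature_set, measures = measures,
                 model = model, ratio = ratio, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full link-prediction pipeline
#'
#' Stages: leakage guard (positive links removed from the network) ->
#' feature extraction -> stratified train/test split -> model training ->
#' evaluation -> feature importance. Outputs (feature table, evaluation
#' report, importance report, manifest with derived seeds and config hash)
#' are written under `config$out_dir`; re-running the same config reproduces
#' identical metrics.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `split`, `model`, `evaluation`,
#'   `importance`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  schema <- default_schema()
  net <- stage("network", {
    if (inherits(config$network, "hetnet")) config$network
    else read_edge_list(config$network, schema)
  })
  labels <- stage("labels", {
    lp <- if (is.data.frame(config$labels)) config$labels
          else read_pairs(config$labels)
    stopifnot(all(c("compound_id", "protein_id", "label") %in% names(lp)))
    lp
  })
  catalog <- stage("catalog", {
    if (is.null(config$catalog)) default_catalog(net$schema)
    else if (inherits(config$catalog, "metapath_catalog")) config$catalog
    else parse_catalog(config$catalog, net$schema)
  })
  fs <- switch(config$feature_set,
    I = list(catalog = similarity_free(catalog, net$schema), measures = "PC"),
    II = list(catalog = catalog, measures = "PC"),
    III = list(catalog = catalog, measures = c("PC", "RW")),
    custom = list(catalog = catalog, measures = config$measures))

  guarded <- stage("guard", leakage_guard(net, labels))
  features <- stage("features",
                    extract_features(guarded, fs$catalog, labels, fs$measures))
  split_seed <- derive_seed(config$seed, 101L)
  split <- stage("split", split_dataset(features, config$ratio, split_seed))

  spec <- config$model
  spec$seed <- derive_seed(config$seed, 102L)
  model <- stage("train", train_model(split$train, split$train$label, spec))
  evaluation <- stage("evaluate",
                      evaluate_model(model, split$test, split$test$label))
  importance <- stage("importance", {
    if (config$model$algorithm == "rf") {
      fit <- model$model
      data.frame(feature = fit$feature_names, oob_mda = unname(fit$mda),
                 mdg = unname(fit$mdg), stringsAsFactors = FALSE)
    } else {
      permutation_importance(model, split$test, split$test$label,
                             n_repeats = 3L,
                             seed = derive_seed(config$seed, 103L))
    }
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("metapathDTI")),
    feature_set = config$feature_set,
    measures = fs$measures,
    n_feature_columns = length(feature_columns(features)),
    feature_columns = feature_columns(features),
    algorithm = config$model$algorithm,
    chosen_params = model$params[setdiff(names(model$params),
                                         c("oob_grid", "cv_f1"))],
    seed = config$seed,
    derived_seeds = list(split = split_seed, train = spec$seed),
    catalog_hash = config_hash(vapply(fs$catalog, metapath_key, "")),
    schema_hash = config_hash(net$schema$edge_specs$id),
    n_train = nrow(split$train), n_test = nrow(split$test),
    metrics = list(f1 = evaluation$f1, auc_roc = evaluation$auc_roc,
                   auc_pr = evaluation$auc_pr, bedroc = evaluation$bedroc)
  )
  write_feature_table(features, file.path(config$out_dir, "features.tsv"))
  utils::write.table(importance, file.path(config$out_dir, "importance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(split = split, model = model, evaluation = evaluation,
                 importance = importance, manifest = manifest,
                 out_dir = config$out_dir))
}

# stable content hash without extra dependencies: FNV-1a over the serialized
# character representation
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
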