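# Pipeline entry point chaining generation, feature extraction, training
# and evaluation, with a manifest for replayability. The command-line
# wrapper in inst/cli/convboost parses flags into the same config list.

#' Run one pipeline stage
#'
#' Stages: `"synth"` (write a synthetic FASTA + labels CSV), `"extract"`
#' (peptides -> feature CSV), `"train"` (feature CSV -> model bundle),
#' `"cv"` (feature CSV -> per-fold metrics CSV), `"test"` (train + test
#' feature CSVs -> metrics CSV), `"predict"` (model bundle + FASTA ->
#' predictions CSV). Every run writes `manifest.json` (config, seed,
#' package version) into the output directory. All stage randomness
#' derives from the single `seed`.
#'
#' @param stage Stage name.
#' @param config Named list of stage options: `input`, `labels`, `train`,
#'   `test`, `model`, `out_dir`, `fc_name`, `variant`, `n_cpp`,
#'   `n_noncpp`, `separation`, `tune`, `seed`.
#' @return The stage's main result, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(stage = c("synth", "extract", "train", "cv",
                                   "test", "predict"),
                         config = list()) {
  stage <- rlang::arg_match(stage)
  cfg <- utils::modifyList(list(
    out_dir = ".", fc_name = "FC-STR", variant = "+NOHo",
    n_cpp = 300L, n_noncpp = 300L, separation = "strong",
    tune = FALSE, seed = 1L), config)
  if (!cfg$fc_name %in% c("FC-SEQ", "FC-STR", "FC-SEQ-STR", "FC-Kendall")) {
    rlang::abort(sprintf(
      "Invalid feature composition '%s'; valid names: FC-SEQ, FC-STR, FC-SEQ-STR, FC-Kendall.",
      cfg$fc_name))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(key) {
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]])) {
      rlang::abort(sprintf("Missing input for --%s: %s", key,
                           cfg[[key]] %||% "(not given)"))
    }
    cfg[[key]]
  }
  read_features <- function(path) {
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  }
  result <- switch(stage,
    synth = {
      peps <- generate_peptides(generator_config(
        n_cpp = cfg$n_cpp, n_noncpp = cfg$n_noncpp,
        separation = cfg$separation, seed = cfg$seed))
      write_fasta(peps, file.path(cfg$out_dir, "peptides.fasta"))
      utils::write.csv(peps[, c("id", "label")],
                       file.path(cfg$out_dir, "labels.csv"),
                       row.names = FALSE)
      peps
    },
    extract = {
      peps <- read_fasta(need("input"))
      if (!is.null(cfg$labels)) {
        lab <- utils::read.csv(cfg$labels)
        peps <- dplyr::left_join(peps, lab, by = "id")
      }
      peps <- preprocess_peptides(peps, quiet = TRUE)
      feats <- extract_features(peps, cfg$fc_name, cfg$variant)
      utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                       row.names = FALSE)
      feats
    },
    train = {
      feats <- read_features(need("input"))
      spec <- convboost_spec(cfg$fc_name, cfg$variant, tune = cfg$tune)
      model <- fit_convboost(feats, spec, seed = cfg$seed)
      save_convboost(model, file.path(cfg$out_dir, "model"))
      model
    },
    cv = {
      feats <- read_features(need("input"))
      spec <- convboost_spec(cfg$fc_name, cfg$variant, tune = cfg$tune)
      cv <- ten_fold_cv(feats, spec, seed = cfg$seed)
      out <- dplyr::bind_rows(
        cv$folds,
        dplyr::bind_cols(tibble::tibble(fold = NA_integer_),
                         tibble::tibble(TP = NA_integer_, FP = NA_integer_,
                                        TN = NA_integer_, FN = NA_integer_),
                         cv$summary))
      utils::write.csv(out, file.path(cfg$out_dir, "cv_metrics.csv"),
                       row.names = FALSE)
      cv
    },
    test = {
      tr <- read_features(need("train"))
      te <- read_features(need("test"))
      spec <- convboost_spec(cfg$fc_name, cfg$variant, tune = cfg$tune)
      res <- independent_test(tr, te, spec, seed = cfg$seed)
      utils::write.csv(dplyr::bind_cols(res$counts, res$metrics),
                       file.path(cfg$out_dir, "test_metrics.csv"),
                       row.names = FALSE)
      res
    },
    predict = {
      model <- load_convboost(need("model"))
      peps <- read_fasta(need("input"))
      pr <- predict(model, peps)
      utils::write.csv(pr, file.path(cfg$out_dir, "predictions.csv"),
                       row.names = FALSE)
      pr
    })
  manifest <- list(stage = stage, config = cfg,
                   package_version = as.character(utils::packageVersion("convboost")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
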