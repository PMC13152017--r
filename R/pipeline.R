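#' @title End-to-end pipeline with lock-box discipline
#' @description Orchestrates the preregistration-shaped workflow: feature
#'   extraction, stratified splitting with a frozen hashed manifest, model
#'   training on the Train split, and evaluation on the Validation split.
#'   The Test (lock-box) split is evaluated only when `unlock = TRUE` is
#'   passed explicitly, and every unlock is recorded in the append-only run
#'   log — the procedural lock-box discipline, enforced in software.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param output_dir directory for artifacts (created if needed).
#' @param seed master seed for every stage.
#' @param synth a [synth_config()] to generate the input cohort, or `NULL`
#'   when `keypoint_paths`/`cohort_path` point at files on disk.
#' @param keypoint_paths character vector of keypoint files (one per
#'   subject), used when `synth` is `NULL`.
#' @param cohort_path cohort CSV path, used when `synth` is `NULL`.
#' @param preprocess a [preprocess_config()].
#' @param features a [features_config()].
#' @param fractions split fractions (train, val, test).
#' @param unlock evaluate the Test (lock-box) split (default `FALSE`).
#' @return list of class `kin_run_config`.
#' @export
run_config <- function(output_dir, seed = 1L, synth = NULL,
                       keypoint_paths = NULL, cohort_path = NULL,
                       preprocess = preprocess_config(),
                       features = features_config(),
                       fractions = c(train = 0.70, val = 0.10, test = 0.20),
                       unlock = FALSE) {
  assert_that(!is.null(synth) || (!is.null(keypoint_paths) && !is.null(cohort_path)),
              "run_config: provide either a synth config or input paths")
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 synth = synth, keypoint_paths = keypoint_paths,
                 cohort_path = cohort_path, preprocess = preprocess,
                 features = features, fractions = fractions,
                 unlock = isTRUE(unlock)),
            class = "kin_run_config")
}

log_event <- function(log, stage, ...) {
  log$events[[length(log$events) + 1L]] <-
    c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      list(...))
  log
}

file_sha256 <- function(path) digest::digest(path, algo = "sha256", file = TRUE)

#' Run the full pipeline
#'
#' Stages: input (generate or load) -> preprocess/normalize/extract
#' features -> stratified split (manifest frozen + hashed) -> train on the
#' Train split -> evaluate on Val -> optionally, with `unlock`, evaluate on
#' the Test (lock-box) split. All artifacts are written under
#' `config$output_dir` and hashed into the run log. Deterministic given the
#' seed.
#'
#' @param config a [run_config()].
#' @return list of class `kin_run` with `feature_table`, `manifest`,
#'   `model`, `val_report`, `test_report` (`NULL` unless unlocked) and
#'   `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kin_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = config$seed, events = list(),
              config_hash = sha256_of(as.character(canonical_json(
                list(seed = config$seed, fractions = as.list(config$fractions),
                     preprocess = config$preprocess,
                     unlock = config$unlock)))))
  log <- log_event(log, "start")

  # ---- input + features
  if (!is.null(config$synth)) {
    cohort <- generate_cohort(config$synth)
    feats <- cohort_feature_table(cohort, preprocess = config$preprocess,
                                  features_cfg = config$features)
    strata <- cohort$cohort[, "sex", drop = FALSE]
  } else {
    records <- read_cohort(config$cohort_path)
    raws <- lapply(config$keypoint_paths, read_keypoints)
    labels <- stats::setNames(records$label, records$subject_id)
    feats <- cohort_feature_table(raws, labels = labels,
                                  preprocess = config$preprocess,
                                  features_cfg = config$features)
    strata <- if ("sex" %in% names(records)) {
      records[match(feats$subject_id, records$subject_id), "sex", drop = FALSE]
    } else NULL
  }
  feat_path <- file.path(config$output_dir, "features.csv")
  write_feature_table(feats, feat_path)
  log <- log_event(log, "features", file = feat_path,
                   hash = file_sha256(feat_path), n = nrow(feats))

  # ---- split
  trainable <- feats$label %in% c("FM_plus", "FM_minus")
  manifest <- stratified_split(feats$subject_id[trainable],
                               feats$label[trainable],
                               strata = if (!is.null(strata))
                                 strata[trainable, , drop = FALSE] else NULL,
                               fractions = config$fractions,
                               seed = config$seed)
  man_path <- file.path(config$output_dir, "split_manifest.json")
  freeze_manifest(manifest, man_path)
  log <- log_event(log, "split", file = man_path, hash = manifest$hash)

  # ---- train
  tr <- feats[feats$subject_id %in% manifest$splits$train, ]
  model <- train(tr, tr$label, train_config(seed = config$seed))
  log <- log_event(log, "train",
                   chosen = model$meta$chosen$kind %||% "automl",
                   internal_cv_ba = model$meta$internal_cv_ba_best)

  evaluate_split <- function(split_name) {
    ev <- feats[feats$subject_id %in% manifest$splits[[split_name]], ]
    sc <- predict_scores(model, ev)
    roc <- roc_auc(sc)
    pr <- pr_auc(sc)
    op <- youden_threshold(roc$curve)
    list(split = split_name, n = nrow(ev),
         roc_auc = roc$auc, pr_auc = pr$auc,
         youden = op[c("threshold", "tpr", "fpr", "j")])
  }

  val_report <- evaluate_split("val")
  val_path <- file.path(config$output_dir, "val_report.json")
  writeLines(as.character(canonical_json(val_report)), val_path)
  log <- log_event(log, "evaluate_val", file = val_path,
                   hash = file_sha256(val_path), roc_auc = val_report$roc_auc)

  test_report <- NULL
  if (config$unlock) {
    log <- log_event(log, "lockbox_unlock",
                     note = "Test (lock-box) split accessed by explicit unlock")
    test_report <- evaluate_split("test")
    test_path <- file.path(config$output_dir, "test_report.json")
    writeLines(as.character(canonical_json(test_report)), test_path)
    log <- log_event(log, "evaluate_test", file = test_path,
                     hash = file_sha256(test_path),
                     roc_auc = test_report$roc_auc)
  }

  log <- log_event(log, "done")
  log_path <- file.path(config$output_dir, "run_log.json")
  writeLines(as.character(jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA,
                                           null = "null")), log_path)
  structure(list(feature_table = feats, manifest = manifest, model = model,
                 val_report = val_report, test_report = test_report,
                 log = log),
            class = "kin_run")
}

#' Evaluate a trained model on one split of a frozen manifest
#'
#' Stand-alone evaluation honoring the lock-box guard: asking for the
#' `"test"` split without `unlock = TRUE` is refused. Every unlock is
#' recorded on the returned report (`unlock_event`).
#'
#' @param model a `kin_model`.
#' @param feats feature table covering the manifest's subjects.
#' @param manifest a `kin_manifest` (or path to a frozen one, verified
#'   before use).
#' @param split `"train"`, `"val"` or `"test"`.
#' @param unlock explicit consent to touch the lock-box split.
#' @return list with `roc_auc`, `pr_auc`, `youden` operating point, `n`,
#'   and `unlock_event` (logical).
#' @export
evaluate_on_split <- function(model, feats, manifest, split = "val",
                              unlock = FALSE) {
  if (is.character(manifest)) manifest <- verify_manifest(manifest)
  if (identical(split, "test") && !isTRUE(unlock)) {
    stop("evaluate_on_split: the Test (lock-box) split is sealed; pass ",
         "unlock = TRUE to evaluate it exactly once under your preregistered ",
         "plan", call. = FALSE)
  }
  ev <- feats[feats$subject_id %in% manifest$splits[[split]], ]
  sc <- predict_scores(model, ev)
  roc <- roc_auc(sc)
  list(split = split, n = nrow(ev), roc_auc = roc$auc,
       pr_auc = pr_auc(sc)$auc,
       youden = youden_threshold(roc$curve),
       unlock_event = identical(split, "test"))
}

#' Minimal command-line interface
#'
#' Subcommands: `synth` (generate a cohort of keypoint JSON files plus a
#' cohort CSV), `run` (full pipeline on a synthetic cohort; add `--unlock`
#' to evaluate the lock-box split). Arguments: `--out DIR`, `--n N`,
#' `--seed S`, `--prevalence P`, `--effect E`, `--unlock`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's result.
#' @export
kin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: kinfant <synth|run> --out DIR [--n N] [--seed S]",
        "[--prevalence P] [--effect E] [--unlock]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- function(name, default) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  out <- opt("out", "kinfant_out")
  n <- as.integer(opt("n", "50"))
  seed <- as.integer(opt("seed", "1"))
  prevalence <- as.numeric(opt("prevalence", "0.11"))
  effect <- as.numeric(opt("effect", "1"))
  unlock <- "--unlock" %in% args
  cfg <- synth_config(n_subjects = n, prevalence = prevalence,
                      effect_size = effect, seed = seed)
  if (cmd == "synth") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cohort <- generate_cohort(cfg)
    for (s in cohort$subjects) {
      write_keypoints(s$raw, file.path(out, paste0(s$raw$subject_id, ".json")))
    }
    utils::write.csv(cohort$cohort, file.path(out, "cohort.csv"),
                     row.names = FALSE)
    writeLines(as.character(jsonlite::toJSON(cohort$truth, digits = NA)),
               file.path(out, "ground_truth.json"))
    cat(sprintf("wrote %d subjects to %s\n", n, out))
    return(invisible(cohort))
  }
  if (cmd == "run") {
    res <- run_pipeline(run_config(output_dir = out, seed = seed,
                                   synth = cfg, unlock = unlock))
    cat(sprintf("val ROC-AUC %.3f%s\n", res$val_report$roc_auc,
                if (unlock) sprintf(", test ROC-AUC %.3f",
                                    res$test_report$roc_auc) else ""))
    return(invisible(res))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
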