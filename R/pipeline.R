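# End-to-end pipeline orchestration:
# augment -> extract (two extractors) -> select per extractor -> fuse ->
# evaluate classifier presets, with per-stage seed fan-out, logging and a
# config echo sufficient to reproduce a run bit-identically.

#' Pipeline configuration
#'
#' @param seed Global seed; per-stage seeds are derived from it by a
#'   documented stage-name hash (see [derive_stage_seed()]), so stages can
#'   be re-run independently.
#' @param out_dir Run directory (created); default a fresh temporary
#'   directory.
#' @param image_dir Optional class-per-folder PNG directory. When `NULL`,
#'   synthetic lesion images are generated from `synthetic_args`.
#' @param synthetic_args Arguments for [synthetic_images()] when no
#'   `image_dir` is given.
#' @param augment,select Stage toggles; both on by default.
#' @param augment_repeats Repeats for [augment_images()].
#' @param extractor_grids Two grid sizes for the built-in extractor, one
#'   per feature branch; default `c(3, 5)`.
#' @param mfo Arguments for [mfo_config()] used by selection.
#' @param fitness Arguments for [fitness_spec()].
#' @param classifiers Preset ids to evaluate on the fused table.
#' @param protocol List with `holdout_fraction` and `cv_folds` for
#'   [evaluate_classifier()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL, image_dir = NULL,
                            synthetic_args = list(),
                            augment = TRUE, augment_repeats = 1L,
                            select = TRUE,
                            extractor_grids = c(3L, 5L),
                            mfo = list(n_moths = 20, max_iterations = 50),
                            fitness = list(),
                            classifiers = c("f_knn", "q_svm"),
                            protocol = list(holdout_fraction = 0.2,
                                            cv_folds = 10)) {
  stopifnot(length(extractor_grids) == 2)
  if (!is.null(image_dir) && !dir.exists(image_dir)) {
    stop("image_dir does not exist: ", image_dir, call. = FALSE)
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 image_dir = image_dir, synthetic_args = synthetic_args,
                 augment = augment, augment_repeats = augment_repeats,
                 select = select, extractor_grids = as.integer(extractor_grids),
                 mfo = mfo, fitness = fitness,
                 classifiers = classifiers, protocol = protocol),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

#' Derive a per-stage seed from the global seed
#'
#' `(seed * 1009 + sum of the stage name's character codes) mod (2^31 - 1)`
#' — deterministic, documented, and stable across sessions, so any stage
#' can be re-run on its own with the same stream it saw inside the full
#' pipeline.
#'
#' @param seed Global integer seed.
#' @param stage Stage name string.
#' @export
derive_stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003 * 1009 +
                sum(utf8ToInt(stage))) %% 2147483647)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  writeLines(msg, con)
  invisible(msg)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order — augment, extract (two feature
#' branches), select per branch, fuse, evaluate every requested classifier
#' preset — writing feature tables, selection JSONs, metric reports, a
#' manifest, a timestamped log and a config echo into the run directory.
#' Identical configs (including seed) reproduce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run directory (`dir`), the per-branch
#'   selections, the fused table, and a tibble of evaluation summaries
#'   (`results`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$out_dir %||% tempfile("mothflame_run_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(dir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  stage <- "start"
  tryCatch({
    log_line(logcon, "pipeline start, seed ", config$seed)

    stage <- "load_images"
    images <- if (!is.null(config$image_dir)) {
      read_image_dir(config$image_dir)
    } else {
      do.call(synthetic_images,
              utils::modifyList(list(seed = derive_stage_seed(config$seed,
                                                              "images")),
                                config$synthetic_args))
    }
    log_line(logcon, length(images), " images loaded")

    if (isTRUE(config$augment)) {
      stage <- "augment"
      images <- augment_images(images, repeats = config$augment_repeats)
      log_line(logcon, "augmented to ", length(images), " images")
    }
    utils::write.csv(augmentation_manifest(images),
                     file.path(dir, "manifest.csv"), row.names = FALSE)

    stage <- "extract"
    branches <- purrr::map(config$extractor_grids, function(g) {
      tbl <- extract_features(images, grid = g)
      write_feature_table(tbl, file.path(dir, sprintf("features_g%d.csv", g)))
      tbl
    })
    log_line(logcon, "extracted branch widths: ",
             paste(purrr::map_int(branches, ~ ncol(.x) - 1L), collapse = ", "))

    selections <- NULL
    if (isTRUE(config$select)) {
      stage <- "select"
      selections <- purrr::imap(branches, function(tbl, i) {
        sseed <- derive_stage_seed(config$seed, paste0("select", i))
        cfg <- do.call(mfo_config,
                       utils::modifyList(config$mfo, list(seed = sseed)))
        fs <- do.call(fitness_spec,
                      utils::modifyList(config$fitness, list(seed = sseed)))
        sel <- select_features(tbl, config = cfg, spec = fs)
        write_selection_json(sel, file.path(dir,
                                            sprintf("selection_%d.json", i)))
        sel
      })
      branches <- purrr::map2(branches, selections, function(tbl, sel) {
        dplyr::select(tbl, dplyr::all_of(c(sel$selected, "label")))
      })
      log_line(logcon, "selected widths: ",
               paste(purrr::map_int(selections, "n_selected"), collapse = ", "))
    }

    stage <- "fuse"
    fused <- fuse_features(branches[[1]], branches[[2]])
    write_fused_features(fused, file.path(dir, "fused.csv"))
    log_line(logcon, "fused width: ", ncol(fused) - 1L)

    stage <- "evaluate"
    eseed <- derive_stage_seed(config$seed, "evaluate")
    evals <- purrr::map(config$classifiers, function(p) {
      evaluate_classifier(fused, classifier_spec(p, seed = eseed),
                          holdout_fraction = config$protocol$holdout_fraction,
                          cv_folds = config$protocol$cv_folds, seed = eseed)
    })
    results <- purrr::map_dfr(evals, glance)
    write_feature_table(report_table(evals), file.path(dir, "report.csv"))
    jsonlite::write_json(results, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(logcon, "evaluation done: ",
             paste(sprintf("%s=%.1f", results$preset,
                           results$holdout_accuracy), collapse = ", "))

    stage <- "echo"
    echo <- unclass(config)
    echo$out_dir <- NULL
    yaml::write_yaml(echo, file.path(dir, "config_echo.yaml"))
    log_line(logcon, "pipeline complete")
    invisible(list(dir = dir, selections = selections, fused = fused,
                   results = results, evaluations = evals))
  }, error = function(e) {
    log_line(logcon, "FAILED at stage '", stage, "': ", conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
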