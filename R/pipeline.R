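#' @importFrom utils write.csv read.csv modifyList
NULL

pipeline_defaults <- function() {
  list(cohort = list(), model_task = "std3D",
       selection = list(k = 25, delta = 0.5),
       bootstrap = list(n_samples = 1000, seed = 1, threshold = 0.5),
       max_order = 10, tol = 0.005, out_dir = "mprad_run")
}

#' Read a pipeline configuration
#'
#' Accepts a list, a JSON file or a YAML file; unspecified fields take the
#' pipeline defaults (paper-scale bootstrap of 1000 samples, std3D task,
#' k = 25, delta = 0.5, orders 1..10).
#'
#' @param config list or path to a `.json` / `.yaml` / `.yml` file.
#' @return Complete configuration list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_config(pipeline_defaults(), config)
}

# like modifyList, but an explicit NULL in `cfg` overrides the default
# (needed e.g. for cohort$dce_times = NULL, "no DCE series")
merge_config <- function(def, cfg) {
  for (nm in names(cfg)) {
    if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]])) &&
        is.list(def[[nm]]))
      def[[nm]] <- merge_config(def[[nm]], cfg[[nm]])
    else
      def[nm] <- list(cfg[[nm]])
  }
  def
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[mprad %s] %s", format(Sys.time(), "%H:%M:%S"),
                              sprintf(fmt, ...)))
}

#' Run the full radiomic pipeline
#'
#' Config-driven orchestration: simulate the cohort, fit parameter maps,
#' extract the task's feature table, reduce the features, build and finalize
#' the logistic models, and write a run directory containing every artifact
#' plus a manifest with content hashes. Identical config (including seeds)
#' reproduces identical manifest hashes; with `resume = TRUE` existing
#' upstream artifacts are reused instead of recomputed.
#'
#' @param config list / JSON / YAML, see [read_pipeline_config()].
#' @param resume reuse existing stage outputs when present.
#' @param quiet suppress stage log messages.
#' @return Invisibly, the manifest (named list of file md5 hashes); artifacts
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$out_dir, f)
  task <- match.arg(cfg$model_task, c("std3D", "adv3D", "adv2D"))

  cohort <- stage("simulate", {
    f <- pth("cohort.rds")
    if (resume && file.exists(f)) readRDS(f) else {
      log_stage(quiet, "simulating cohort")
      co <- generate_cohort(do.call(cohort_spec, cfg$cohort))
      saveRDS(co, f)
      write.csv(co$truth, pth("truth.csv"), row.names = FALSE)
      manifest <- do.call(rbind, lapply(co$segmentations, function(s)
        data.frame(voi_id = s$voi_id, subject_id = s$subject_id,
                   label = s$label, roi_dim = s$roi_dim,
                   n_voxels = sum(s$mask$data))))
      write.csv(manifest, pth("segmentations.csv"), row.names = FALSE)
      co
    }
  })

  cohort <- stage("fit-maps", {
    f <- pth("cohort_maps.rds")
    if (resume && file.exists(f)) readRDS(f) else {
      log_stage(quiet, "fitting parameter maps")
      maps <- model_map_catalog(task)
      co <- compute_cohort_maps(cohort, maps = maps)
      saveRDS(co, f)
      co
    }
  })

  feats <- stage("extract-features", {
    f <- pth(sprintf("features_%s.csv", task))
    if (resume && file.exists(f)) read_feature_table(f, task) else {
      log_stage(quiet, "extracting %s features", task)
      ft <- extract_feature_table(cohort, task)
      write.csv(ft, f, row.names = FALSE)
      ft
    }
  })

  boot <- iabr_control(n_samples = cfg$bootstrap$n_samples,
                       seed = cfg$bootstrap$seed,
                       threshold = cfg$bootstrap$threshold)
  model <- stage("model", {
    log_stage(quiet, "reducing features and building models (B = %d)",
              boot$n_samples)
    radiomic_model(feats, k = cfg$selection$k, delta = cfg$selection$delta,
                   max_order = cfg$max_order, control = boot, tol = cfg$tol)
  })

  stage("report", {
    write.csv(cbind(rank = model$reduced$rank,
                    split_feature_key(model$reduced$feature),
                    gain = model$reduced$gain),
              pth(sprintf("reduced_%s.csv", task)), row.names = FALSE)
    write.csv(performance_table(model$models),
              pth(sprintf("performance_%s.csv", task)), row.names = FALSE)
    jsonlite::write_json(
      list(task = task, best_order = model$best_order,
           features = model$final$features,
           coefficients = as.list(model$final$coefficients),
           auc632 = model$final$auc632, sens632 = model$final$sens632,
           spec632 = model$final$spec632),
      pth(sprintf("model_%s.json", task)), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    saveRDS(model, pth(sprintf("model_%s.rds", task)))
  })

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  names(manifest) <- files
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage(quiet, "done: %s", cfg$out_dir)
  invisible(manifest)
}

# "T2W.first.mean" -> map / order / statistic columns (Table-1-like layout)
split_feature_key <- function(keys) {
  parts <- strsplit(keys, ".", fixed = TRUE)
  data.frame(map = vapply(parts, `[`, "", 1),
             order = vapply(parts, `[`, "", 2),
             statistic = vapply(parts, `[`, "", 3))
}

#' Read a persisted feature table
#'
#' @param path CSV written by [run_pipeline()] (or `write.csv` of an
#'   `mprad_features` table).
#' @param model the task the table belongs to.
#' @return `mprad_features` data frame.
#' @export
read_feature_table <- function(path, model = NULL) {
  tab <- read.csv(path, check.names = FALSE)
  structure(tab, model = model,
            feature_cols = setdiff(names(tab),
                                   c("voi_id", "subject_id", "label")),
            class = c("mprad_features", "data.frame"))
}
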