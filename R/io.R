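#' Write a feature table as CSV
#'
#' UTF-8 CSV with '.' decimal separator; missing cells are written as empty
#' strings so the round trip preserves missingness flags exactly.
#'
#' @param table data.frame with `sample_id` and `line` columns.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path (empty cells become `NA`).
#' @param expected_columns optional column whitelist; any column in the file
#'   not listed (besides `sample_id` and `line`) raises a schema error
#'   naming it.
#' @return data.frame with `line` as factor and numeric parameter columns.
#' @export
read_feature_table <- function(path, expected_columns = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", check.names = FALSE)
  for (req in c("sample_id", "line"))
    if (!req %in% names(tab))
      stop("feature table is missing required column '", req, "'")
  if (!is.null(expected_columns)) {
    unknown <- setdiff(names(tab), c("sample_id", "line", expected_columns))
    if (length(unknown))
      stop("unknown column(s) in feature table: ",
           paste(unknown, collapse = ", "))
  }
  tab$line <- factor(tab$line)
  for (cl in setdiff(names(tab), c("sample_id", "line"))) {
    v <- tab[[cl]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v)))
        stop("column '", cl, "' contains non-numeric values")
      v <- vn
    }
    tab[[cl]] <- v
  }
  tab
}

#' Write a grayscale image or mask as ASCII PGM (P2)
#'
#' Plain-text portable graymap: grey values survive the round trip exactly.
#' Masks use `maxval = 1`, 12-bit marker images `maxval = 4095`.
#'
#' @param pixels numeric/logical matrix (rows = y).
#' @param path output path.
#' @param maxval maximum grey value declared in the header.
#' @export
write_pgm <- function(pixels, path, maxval = 4095) {
  m <- round(as.matrix(pixels) * 1)
  if (any(m < 0) || any(m > maxval)) stop("pixel values outside [0, maxval]")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ASCII PGM (P2) image
#' @param path PGM file path.
#' @return integer matrix with attribute `maxval`.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(toks) < 4 || toks[1] != "P2")
    stop("'", path, "' is not an ASCII PGM (P2) file")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h)
    stop("PGM pixel count mismatch in '", path, "'")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  attr(m, "maxval") <- maxval
  m
}

#' Write an uptake volume as text raw grid + JSON sidecar
#'
#' `<prefix>.txt` holds the voxel values in column-major order, one per
#' line; `<prefix>.json` records dims, voxel size and injection metadata.
#'
#' @param volume an [uptake_volume()].
#' @param prefix path prefix (without extension).
#' @export
write_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "uptake_volume"))
  meta <- list(dims = dim(volume$voxels), voxel_size = volume$voxel_size,
               injected_activity = volume$injected_activity,
               body_weight = volume$body_weight,
               sample_id = volume$sample_id)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(format(as.vector(volume$voxels), digits = 17, trim = TRUE,
                    scientific = FALSE),
             paste0(prefix, ".txt"))
  invisible(prefix)
}

#' Read an uptake volume written by [write_volume()]
#' @param prefix path prefix.
#' @return an [uptake_volume()].
#' @export
read_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(paste0(prefix, ".txt")))
  if (length(vals) != prod(meta$dims))
    stop("voxel count does not match sidecar dims for '", prefix, "'")
  uptake_volume(array(vals, dim = meta$dims), voxel_size = meta$voxel_size,
                injected_activity = meta$injected_activity,
                body_weight = meta$body_weight,
                sample_id = meta$sample_id %||% "sample")
}

#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end synthetic run: the study-shaped
#' cohort (14 lines, 72 tumors, 35 columns), stratified 75/25 splits, and
#' reduced repeat/tree counts so the full pipeline (including the exhaustive
#' subset sweep) completes in minutes. The study's headline settings were
#' 1000 repeats and 20000 trees; raise `n_repeats`/`n_trees` for a
#' full-fidelity run.
#'
#' @param seed master seed for the run.
#' @return named list; see field names in the source.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(seed = seed, n_lines = 14, n_per_line = NULL,
       n_repeats = 50, train_fraction = 0.75, stratify = TRUE,
       n_trees = 1000, n_trees_sweep = 100, sweep_repeats = 20,
       k_range = 1:8, correlation_method = "spearman",
       ihc_bin_width = 25, pet_bin_width = 0.5, rescale_ref = 1000)
}

read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' Run the full synthetic characterization pipeline
#'
#' simulate -> variance decomposition -> classification -> importance ->
#' subset sweep -> paired model comparison, writing the result bundle and a
#' run manifest to `outdir`:
#' `cohort.csv`, `heterogeneity.csv` (per-column within/total ratios),
#' `accuracy.csv` (per-model OOB and CV accuracy as in a classifier
#' performance table), `importance.csv`, `sweep.csv`, `comparison.json` and
#' `manifest.json` (config snapshot, seeds, file digests, timing). Reruns
#' with identical config produce byte-identical CSV/JSON outputs.
#'
#' @param config list from [default_pipeline_config()] (or a subset of its
#'   fields to override).
#' @param outdir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = "xenomark-run") {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  # stage 1: simulate the cohort
  spec <- if (cfg$n_lines == 14)
    study_cohort_spec(n_per_line = cfg$n_per_line, seed = cfg$seed)
  else  # non-default line counts: generic balanced cohort, IHC params only
    cohort_spec(n_lines = cfg$n_lines, n_per_line = cfg$n_per_line %||% 5,
                parameter_specs = lapply(ihc_parameter_names(), function(nm)
                  parameter_spec(nm, var_between = 0.7, var_within = 0.3)),
                seed = cfg$seed)
  cohort <- generate_cohort(spec)
  write_feature_table(cohort$table, file.path(outdir, "cohort.csv"))

  # stage 2: heterogeneity (within/total) per column + correlations
  het <- heterogeneity_table(cohort$table)
  utils::write.csv(het, file.path(outdir, "heterogeneity.csv"),
                   row.names = FALSE)

  # stage 3: classification on the imputed table under shared splits
  imp_tab <- median_impute(cohort$table)
  param_cols <- intersect(c(ihc_parameter_names(), pet_parameter_names()),
                          names(imp_tab))
  feat_cols <- intersect(c(ihc_feature_names(), pet_feature_names()),
                         names(imp_tab))
  if (length(feat_cols) == 0) feat_cols <- NULL
  scheme <- make_cv_scheme(imp_tab$line, n_repeats = cfg$n_repeats,
                           train_fraction = cfg$train_fraction,
                           stratify = cfg$stratify, seed = cfg$seed + 1L)
  models <- list(parameters = param_cols)
  if (!is.null(feat_cols))
    models$parameters_plus_features <- c(param_cols, feat_cols)
  acc_rows <- list()
  results <- list()
  for (nm in names(models)) {
    oob <- fit_forest(imp_tab, models[[nm]], n_trees = cfg$n_trees,
                      seed = cfg$seed + 2L)$oob_accuracy
    res <- evaluate_model(imp_tab, models[[nm]], scheme,
                          n_trees = cfg$n_trees, seed = cfg$seed + 3L,
                          model_name = nm)
    results[[nm]] <- res
    acc_rows[[nm]] <- data.frame(model = nm, n_columns = length(models[[nm]]),
                                 oob_accuracy = oob, cv_mean = res$mean,
                                 cv_sd = res$sd)
  }
  utils::write.csv(do.call(rbind, acc_rows),
                   file.path(outdir, "accuracy.csv"), row.names = FALSE)

  # stage 4: importance of the parameters model
  imp <- parameter_importance(imp_tab, param_cols, n_trees = cfg$n_trees,
                              seed = cfg$seed + 4L)
  utils::write.csv(imp, file.path(outdir, "importance.csv"),
                   row.names = FALSE)

  # stage 5: exhaustive IHC-subset sweep on a reduced scheme
  ihc_cols <- intersect(ihc_parameter_names(), names(imp_tab))
  sweep_scheme <- make_cv_scheme(imp_tab$line,
                                 n_repeats = cfg$sweep_repeats,
                                 train_fraction = cfg$train_fraction,
                                 stratify = cfg$stratify,
                                 seed = cfg$seed + 5L)
  k_range <- cfg$k_range[cfg$k_range <= length(ihc_cols) - 1]
  sw <- subset_sweep(imp_tab, ihc_cols, k_range = k_range,
                     scheme = sweep_scheme, n_trees = cfg$n_trees_sweep,
                     seed = cfg$seed + 6L)
  utils::write.csv(sw$by_k, file.path(outdir, "sweep.csv"),
                   row.names = FALSE)

  # stage 6: paired comparison of the two headline models
  if (length(results) >= 2) {
    cmp <- compare_models(results[[2]], results[[1]])
    jsonlite::write_json(
      list(a = results[[2]]$model_name, b = results[[1]]$model_name,
           mean_difference = cmp$mean_difference, ci95 = cmp$ci95,
           p_value = cmp$p_value, test = cmp$test,
           degenerate = cmp$degenerate),
      file.path(outdir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  }

  files <- c("cohort.csv", "heterogeneity.csv", "accuracy.csv",
             "importance.csv", "sweep.csv", "comparison.json")
  files <- files[file.exists(file.path(outdir, files))]
  digests <- tools::md5sum(file.path(outdir, files))
  names(digests) <- files
  manifest <- list(config = cfg,
                   files = as.list(digests),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
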