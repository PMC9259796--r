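# Tabular I/O in one dialect throughout: TSV (comma also accepted on read)
# with a header row; matrices carry a `sample_id` first column; floats are
# serialized at 10 significant digits.

#' Write / read an omics matrix as TSV
#'
#' Rows are samples; the first column is `sample_id`, the remaining columns
#' are feature ids. [read_omics_matrix()] sniffs tab vs comma delimiters
#' from the header, rejects duplicate sample ids and reports the coordinates
#' of any non-numeric cell.
#'
#' @param m an [omics_matrix()].
#' @param path file path.
#' @return `read_omics_matrix` returns an [omics_matrix()];
#'   `write_omics_matrix` returns `path` invisibly.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m$values),
                   apply(m$values, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_omics_matrix
#' @param kind omics kind tag to attach on read.
#' @export
read_omics_matrix <- function(path, kind) {
  sep <- sniff_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   colClasses = "character", quote = "")
  if (names(df)[1] != "sample_id") stopf("first column must be 'sample_id'")
  ids <- df$sample_id
  if (anyDuplicated(ids)) stopf("duplicate sample ids in %s", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("non-numeric cell at row %d (sample '%s'), column '%s' in %s",
            bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]], path)
  }
  dimnames(num) <- list(ids, colnames(vals))
  omics_matrix(num, kind)
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Write / read a clinical table
#'
#' Columns `sample_id`, `time`, `event`; tab- or comma-delimited on read.
#'
#' @param clinical a [clinical_table()].
#' @param path file path.
#' @export
write_clinical <- function(clinical, path) {
  out <- data.frame(sample_id = clinical$sample_id,
                    time = format_num(clinical$time),
                    event = clinical$event, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- read.table(path, header = TRUE, sep = sniff_sep(path),
                   check.names = FALSE)
  clinical_table(df$sample_id, df$time, df$event)
}

#' Write an omics stack with its provenance sidecar
#'
#' The stack matrix goes to `stack.tsv` (columns named
#' `<kind>:<feature_id>`) and the provenance map to `columns.tsv` (column
#' index, kind, feature id) under `dir`.
#'
#' @param stack an `omics_stack`.
#' @param dir output directory (created if needed).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- stack$values
  colnames(v) <- paste(stack$provenance$kind, stack$provenance$feature_id,
                       sep = ":")
  df <- data.frame(sample_id = rownames(v), apply(v, 2, format_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "stack.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(stack$provenance, file.path(dir, "columns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  prov <- read.table(file.path(dir, "columns.tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  df <- read.table(file.path(dir, "stack.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  colnames(v) <- paste(prov$kind, prov$feature_id, sep = ":")
  structure(list(values = v, provenance = prov), class = "omics_stack")
}

#' Write a Kaplan-Meier curve as TSV
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param path file path.
#' @export
write_km_curve <- function(curve, path) {
  out <- data.frame(time = format_num(curve$time), n_risk = curve$n_risk,
                    n_event = curve$n_event,
                    survival = format_num(curve$survival),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / load a lasso signature
#'
#' A YAML header (kind, intercept, lambda, threshold, training scaling) in
#' `#`-prefixed lines, followed by a TSV body (`feature_id`, `coefficient`).
#'
#' @param sig a `lasso_signature`.
#' @param path file path.
#' @export
write_signature <- function(sig, path) {
  hdr <- yaml::as.yaml(precision = 12, list(
    omics_kind = sig$omics_kind,
    intercept = sig$intercept,
    lambda = sig$lambda,
    decision_threshold = sig$decision_threshold,
    training_min = as.list(stats::setNames(sig$training_scaling$min,
                                           sig$training_scaling$feature_id)),
    training_max = as.list(stats::setNames(sig$training_scaling$max,
                                           sig$training_scaling$feature_id))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(hdr, "\n")[[1]]), con)
  writeLines("feature_id\tcoefficient", con)
  if (length(sig$feature_ids) > 0)
    writeLines(paste(sig$feature_ids, format_num(sig$coefficients),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr_lines <- sub("^# ?", "", lines[startsWith(lines, "#")])
  meta <- yaml::yaml.load(paste(hdr_lines, collapse = "\n"))
  body <- lines[!startsWith(lines, "#")]
  df <- if (length(body) > 1)
    read.table(text = body, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  else data.frame(feature_id = character(0), coefficient = numeric(0))
  structure(list(omics_kind = meta$omics_kind,
                 feature_ids = df$feature_id,
                 coefficients = df$coefficient,
                 intercept = meta$intercept,
                 lambda = meta$lambda,
                 decision_threshold = meta$decision_threshold,
                 training_scaling = data.frame(
                   feature_id = names(meta$training_min),
                   min = unlist(meta$training_min, use.names = FALSE),
                   max = unlist(meta$training_max, use.names = FALSE),
                   stringsAsFactors = FALSE)),
            class = "lasso_signature")
}

#' Write a synthetic dataset to a directory
#'
#' One TSV per omics block, `clinical.tsv`, `truth.tsv` (true subgroup
#' labels; informative feature lists as comma-joined columns) and the
#' generator config echoed as `config.yaml`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ds$omics))
    write_omics_matrix(ds$omics[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_clinical(ds$clinical, file.path(dir, "clinical.tsv"))
  truth <- data.frame(sample_id = names(ds$true_labels),
                      true_label = unname(ds$true_labels),
                      stringsAsFactors = FALSE)
  for (nm in names(ds$truth))
    truth[[paste0("informative_", nm)]] <-
      c(paste(ds$truth[[nm]], collapse = ","),
        rep("", nrow(truth) - 1))
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- unclass(ds$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Pipeline configuration
#'
#' Either simulate-mode (give a [synth_config()]) or file-mode (give named
#' `omics_paths` mapping kind to TSV path plus `clinical_path`).
#'
#' @param synth a [synth_config()], or `NULL` for file mode.
#' @param omics_paths named character vector (names = omics kinds).
#' @param clinical_path clinical TSV path.
#' @param grid optional list of [ae_config()]s (default: the canonical
#'   eight-model grid seeded from `seed`).
#' @param alpha,k,folds,n_restarts see [ae_subtype()].
#' @param seed global seed.
#' @param out_dir run output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, omics_paths = NULL,
                            clinical_path = NULL, grid = NULL, alpha = 0.05,
                            k = 2, folds = 10, n_restarts = 20, seed = 1,
                            out_dir) {
  if (is.null(synth)) {
    if (is.null(omics_paths) || is.null(clinical_path))
      stopf("file mode needs `omics_paths` and `clinical_path`")
    missing <- c(omics_paths, clinical_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing) > 0)
      stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
  }
  structure(list(synth = synth, omics_paths = omics_paths,
                 clinical_path = clinical_path, grid = grid, alpha = alpha,
                 k = k, folds = folds, n_restarts = n_restarts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' The bundled demonstration configuration
#'
#' Simulate-mode config over the default synthetic conditions (400 samples,
#' five 200-feature blocks with 20 informative features each at effect 1.0,
#' hazard ratio 3, 30% censoring) with the canonical eight-model grid.
#'
#' @param out_dir run output directory.
#' @param seed global seed.
#' @export
demo_config <- function(out_dir, seed = 1) {
  pipeline_config(synth = synth_config(seed = sub_seed(seed, "synth")),
                  seed = seed, out_dir = out_dir)
}

#' Run the complete workflow and write a run directory
#'
#' Simulates or reads the inputs, fits [ae_subtype()], and writes
#' `grid_report.tsv`, `cv_report.tsv`, `assignment.tsv`, per-subgroup KM
#' curves, per-omics signature files and a machine-readable `manifest.json`
#' (config, seeds, package version, output inventory). The run is a pure
#' function of (input files, config, seed): reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return The fitted `ae_subtype` object, invisibly, with attribute
#'   `"out_dir"`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$synth)) {
    ds <- generate_dataset(config$synth)
    omics <- ds$omics
    clinical <- ds$clinical
    write_dataset(ds, file.path(config$out_dir, "inputs"))
  } else {
    omics <- lapply(names(config$omics_paths), function(kind)
      read_omics_matrix(config$omics_paths[[kind]], kind))
    clinical <- read_clinical(config$clinical_path)
  }
  fit <- ae_subtype(omics, clinical, grid = config$grid,
                    alpha = config$alpha, k = config$k, folds = config$folds,
                    n_restarts = config$n_restarts, seed = config$seed)
  write_run(fit, config)
  invisible(structure(fit, out_dir = config$out_dir))
}

write_run <- function(fit, config) {
  out <- config$out_dir
  rep <- fit$grid_report
  rep$rmse <- format_num(rep$rmse)
  write.table(rep, file.path(out, "grid_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cvr <- do.call(rbind, lapply(fit$cv_reports[!vapply(fit$cv_reports, is.null,
                                                      logical(1))],
    function(r) data.frame(model_id = r$model_id,
                           deep_features = r$n_deep_features_selected,
                           mean_cindex = format_num(r$mean_cindex),
                           sd_cindex = format_num(r$sd_cindex),
                           stringsAsFactors = FALSE)))
  write.table(cvr, file.path(out, "cv_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = fit$assignment$sample_ids,
                         subgroup = fit$assignment$label,
                         stringsAsFactors = FALSE),
              file.path(out, "assignment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cl <- align_clinical(fit$clinical, fit$assignment$sample_ids)
  write_km_curve(km_estimate(cl, fit$assignment$label == "S1"),
                 file.path(out, "km_S1.tsv"))
  write_km_curve(km_estimate(cl, fit$assignment$label == "S2"),
                 file.path(out, "km_S2.tsv"))
  sig_files <- character(0)
  if (!is.null(fit$signatures)) {
    dir.create(file.path(out, "signatures"), showWarnings = FALSE)
    for (k in names(fit$signatures)) {
      f <- file.path(out, "signatures", paste0("signature_", k, ".tsv"))
      write_signature(fit$signatures[[k]], f)
      sig_files <- c(sig_files, f)
    }
  }
  manifest <- list(
    package = "aesubtype",
    version = as.character(utils::packageVersion("aesubtype")),
    seed = config$seed,
    mode = if (is.null(config$synth)) "files" else "simulate",
    config = manifest_config(config),
    best_model = fit$best_model_id,
    logrank_p = fit$logrank$p,
    outputs = basename(c("grid_report.tsv", "cv_report.tsv",
                         "assignment.tsv", "km_S1.tsv", "km_S2.tsv",
                         sig_files)),
    models = fit$grid_report$ae_models)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

manifest_config <- function(config) {
  c(list(alpha = config$alpha, k = config$k, folds = config$folds,
         n_restarts = config$n_restarts),
    if (!is.null(config$synth)) list(synth = unclass(config$synth))
    else list(omics_paths = as.list(config$omics_paths),
              clinical_path = config$clinical_path))
}
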