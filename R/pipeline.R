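#' Read and normalize a run configuration
#'
#' Configurations drive the end-to-end analysis commands [run_franz()],
#' [run_fit()] and [run_validate()]. YAML and JSON are equivalent (chosen by
#' file extension); a named list is accepted directly. Missing fields take
#' defaults that reproduce the standard procedure: 7 cross-validation
#' groups, 20 response permutations, permutation intercept limits 0.4
#' (R-squared) and 0.05 (Q-squared).
#'
#' @param config path to a YAML/JSON file, or a named list. Recognized
#'   fields: `dataset` (CSV path), `response` (column name, default
#'   "P_app"), `ncomp` (fixed component count; `NULL` lets cross-validation
#'   choose), `ncomp_max` (default 5), `n_folds` (default 7),
#'   `n_permutations` (default 20), `intercept_limits` (default 0.4, 0.05),
#'   `exclude` (compound ids), `seed` (default 1), `split_seed` (external
#'   validation; defaults to `seed`), `permeation` (long CSV path),
#'   `geometry` (path or list), `output_dir` (default ".").
#' @return A classed `run_config` list with all defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::fromJSON(config)
  }
  stopifnot(is.list(config))
  defaults <- list(dataset = NULL, response = "P_app", ncomp = NULL,
                   ncomp_max = 5L, n_folds = 7L, n_permutations = 20L,
                   intercept_limits = c(0.4, 0.05), exclude = character(),
                   seed = 1L, split_seed = NULL, permeation = NULL,
                   geometry = NULL, output_dir = ".")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(defaults, config)
  if (is.null(out$split_seed)) out$split_seed <- out$seed
  out$intercept_limits <- as.numeric(unlist(out$intercept_limits))
  out$exclude <- as.character(unlist(out$exclude))
  structure(out, class = "run_config")
}

write_manifest <- function(config, outputs, out_dir) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  manifest <- list(config = jsonlite::fromJSON(cfg_json),
                   config_md5 = unname(tools::md5sum(tmp)),
                   outputs = outputs,
                   package_version =
                     as.character(utils::packageVersion("plsperm")),
                   r_version = R.version.string)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

load_config_dataset <- function(config) {
  if (is.null(config$dataset))
    stop("config field 'dataset' is required for this command", call. = FALSE)
  ds <- read_dataset(config$dataset, config$response)
  exclude_observations(ds$table, ds$response, config$exclude)
}

#' Reduce Franz-cell input to permeability summaries
#'
#' Reads the long-format permeation CSV and geometry named in the config,
#' reduces every compound x replicate series to its steady-state flux and
#' apparent permeability, aggregates replicates per compound, and writes
#' `permeation_replicates.csv`, `permeation_aggregated.csv` and a manifest
#' into the output directory.
#'
#' @param config a [read_run_config()] input (path or list).
#' @return Invisibly, a list with `replicates` and `aggregated` data.frames.
#' @export
run_franz <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$permeation) || is.null(config$geometry))
    stop("config fields 'permeation' and 'geometry' are required; see ",
         "?read_run_config for the expected layout", call. = FALSE)
  series <- read_permeation(config$permeation, config$geometry)
  summaries <- lapply(series, summarize_permeation)
  reps <- permeation_table(summaries)
  agg <- do.call(rbind, lapply(split(summaries,
                                     vapply(summaries, `[[`, "", "compound")),
                               function(group) {
    a <- aggregate_replicates(group)
    data.frame(compound = a$compound, n_replicates = a$n,
               mean_P_app_cm_h = a$mean_P_app, sd_P_app_cm_h = a$sd_P_app,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(config$output_dir, "permeation_replicates.csv")
  f2 <- file.path(config$output_dir, "permeation_aggregated.csv")
  utils::write.csv(reps, f1, row.names = FALSE)
  utils::write.csv(agg, f2, row.names = FALSE)
  write_manifest(config, c(f1, f2), config$output_dir)
  invisible(list(replicates = reps, aggregated = agg))
}

#' Fit and report a QSPR PLS model from a config
#'
#' Loads the dataset, applies configured exclusions, picks the component
#' count by cross-validation unless `ncomp` is fixed, fits the model, and
#' writes `model.json`, `vip.csv`, `wc_coordinates.csv` (2+ components),
#' `observed_vs_predicted.csv` and a manifest.
#'
#' @param config a [read_run_config()] input.
#' @return Invisibly, the fitted [fit_pls()] model.
#' @export
run_fit <- function(config) {
  config <- read_run_config(config)
  ds <- load_config_dataset(config)
  ncomp <- config$ncomp
  if (is.null(ncomp)) {
    cv <- cross_validate(ds$table, ds$response, ncomp_max = config$ncomp_max,
                         n_folds = config$n_folds)
    ncomp <- max(cv$recommended_ncomp, 1L)
  }
  model <- pls_qspr(ds$table, ds$response, ncomp = ncomp)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(config$output_dir,
                       c("model.json", "vip.csv", "observed_vs_predicted.csv"))
  pls_to_json(model, outputs[1L])
  utils::write.csv(vip(model), outputs[2L], row.names = FALSE)
  utils::write.csv(observed_vs_predicted(model), outputs[3L],
                   row.names = FALSE)
  if (model$ncomp >= 2L) {
    f <- file.path(config$output_dir, "wc_coordinates.csv")
    utils::write.csv(wc_coordinates(model), f, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  if (length(config$exclude))
    message("excluded observation(s): ", paste(config$exclude,
                                               collapse = ", "))
  write_manifest(config, outputs, config$output_dir)
  invisible(model)
}

#' Run the full validation suite from a config
#'
#' Cross-validation (PRESS/Q-squared per component and recommended size),
#' response-permutation validation with intercept limits, and external
#' two-half swap validation. Writes `cv.csv`, `permutation_points.csv`,
#' `validation_report.json` and a manifest.
#'
#' @param config a [read_run_config()] input.
#' @return Invisibly, a list with elements `cv`, `permutation`, `external`.
#' @export
run_validate <- function(config) {
  config <- read_run_config(config)
  ds <- load_config_dataset(config)
  cv <- cross_validate(ds$table, ds$response, ncomp_max = config$ncomp_max,
                       n_folds = config$n_folds)
  ncomp <- config$ncomp %||% max(cv$recommended_ncomp, 1L)
  perm <- permutation_validation(ds$table, ds$response, ncomp = ncomp,
                                 n_permutations = config$n_permutations,
                                 n_folds = config$n_folds,
                                 intercept_limits = config$intercept_limits,
                                 seed = config$seed)
  ext <- external_swap_validation(ds$table, ds$response, ncomp = ncomp,
                                  seed = config$split_seed)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  cv_tab <- data.frame(component = seq_len(cv$ncomp_max), PRESS = cv$PRESS,
                       Q2 = cv$Q2, Q2_cum = cv$Q2_cum,
                       significant = cv$significant)
  outputs <- file.path(config$output_dir,
                       c("cv.csv", "permutation_points.csv",
                         "validation_report.json"))
  utils::write.csv(cv_tab, outputs[1L], row.names = FALSE)
  utils::write.csv(perm$points, outputs[2L], row.names = FALSE)
  validation_report_json(cv, perm, ext, outputs[3L])
  write_manifest(config, outputs, config$output_dir)
  invisible(list(cv = cv, permutation = perm, external = ext))
}
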