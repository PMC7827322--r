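# Readers, writers and run configuration: plain CSV/JSON/YAML interfaces so
# every fit is reproducible from its emitted metadata alone.

config_defaults <- function() {
  list(q = 4L, b = 100L, split_fraction = 0.5, seed = 1L,
       quantile_scope = "full", beta_signs = NULL,
       select = "aic", nlambda = 100L, lambda_min_ratio = 0.001,
       gamma = 3, gamma_outer = 3, tol = 1e-8, max_iterations = 500L,
       alpha = 0.05)
}

#' Build or load a run configuration
#'
#' Defaults follow the study design: quartile scoring (`q = 4`), 100
#' bootstraps, a 50/50 split, penalty selection by AIC. Unknown keys and
#' invalid values are rejected.
#'
#' @param ... Named overrides of the default fields.
#' @return A named list of class `"gwqs_config"`.
#' @export
gwqs_config <- function(...) {
  override <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, override, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "gwqs_config")
}

validate_config <- function(cfg) {
  if (cfg$q < 2) abort("config field `q`: must be >= 2")
  if (cfg$b < 1) abort("config field `b`: must be >= 1")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    abort("config field `split_fraction`: must be in (0, 1)")
  }
  if (!cfg$quantile_scope %in% c("full", "train")) {
    abort("config field `quantile_scope`: must be \"full\" or \"train\"")
  }
  if (!cfg$select %in% c("aic", "cv")) {
    abort("config field `select`: must be \"aic\" or \"cv\"")
  }
  if (cfg$lambda_min_ratio <= 0 || cfg$lambda_min_ratio >= 1) {
    abort("config field `lambda_min_ratio`: must be in (0, 1)")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; keys absent from
#'   the file take the defaults of [gwqs_config()].
#' @return A `"gwqs_config"`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  do.call(gwqs_config, raw)
}

#' Write a run configuration
#'
#' @param cfg A `"gwqs_config"`.
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  payload <- unclass(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' Read an exposure dataset, group map and outcome
#'
#' @param data_path CSV with one column per component plus outcome (and
#'   covariate) columns; header row required.
#' @param groups_path Group map: a CSV with `component`,`group` columns or
#'   a JSON object of `{"group": ["component", ...]}` arrays.
#' @param outcome Name of the binary outcome column.
#' @param covariates Optional covariate column names.
#' @return A list: `data` (tibble with complete rows only; the count of
#'   dropped incomplete rows is reported), `groups`
#'   (a [group_structure()]), `outcome`, `covariates`.
#' @export
read_dataset <- function(data_path, groups_path, outcome = "y",
                         covariates = NULL) {
  if (!file.exists(data_path)) abort(paste0("data file not found: ", data_path))
  if (!file.exists(groups_path)) {
    abort(paste0("group map not found: ", groups_path))
  }
  data <- tibble::as_tibble(utils::read.csv(data_path,
                                            check.names = FALSE))
  groups <- if (grepl("\\.json$", groups_path, ignore.case = TRUE)) {
    group_structure(jsonlite::read_json(groups_path, simplifyVector = TRUE))
  } else {
    group_structure(utils::read.csv(groups_path))
  }
  needed <- c(groups$component, outcome, covariates)
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("columns missing from data: ",
                 paste(missing, collapse = ", ")))
  }
  data <- data[needed]
  complete <- stats::complete.cases(data)
  if (any(!complete)) {
    warn(paste0("dropped ", sum(!complete), " rows with missing values"))
    data <- data[complete, , drop = FALSE]
  }
  yv <- data[[outcome]]
  if (!all(yv %in% c(0, 1))) {
    abort(paste0("outcome column `", outcome, "` must be coded 0/1"))
  }
  group_structure(groups, data[groups$component])
  list(data = data, groups = groups, outcome = outcome,
       covariates = covariates)
}

#' Write fit results as CSV with a JSON manifest
#'
#' Writes the validation coefficient table (`results.csv`: term, estimate,
#' SE, OR, CI bounds, p-value), the averaged weights (`weights.csv`:
#' group, component, weight) and a `manifest.json` listing every file with
#' its MD5 checksum plus the fit configuration, so the run is reproducible
#' from the metadata alone.
#'
#' @param fit A `"gwqs_fit"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(fit, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  res <- tidy(fit)
  names(res) <- c("term", "estimate", "SE", "OR", "CI_low", "CI_high",
                  "p_value")
  res_path <- file.path(out_dir, "results.csv")
  utils::write.csv(format_sig(res), res_path, row.names = FALSE,
                   quote = FALSE)
  w_path <- file.path(out_dir, "weights.csv")
  utils::write.csv(format_sig(fit$weights), w_path, row.names = FALSE,
                   quote = FALSE)
  files <- c(res_path, w_path)
  manifest <- list(
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    config = fit$config,
    n_converged = fit$diagnostics$n_converged,
    package_version = as.character(utils::packageVersion("gwqsr")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

format_sig <- function(df, digits = 6) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) signif(col, digits) else col
  })
  df
}

#' Write the simulation-study summary tables as CSV
#'
#' One CSV per summary (effects, power, sensitivity/specificity, AIC) plus
#' the combined long-format replicate table.
#'
#' @param study A `"simulation_study"`.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_study <- function(study, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tables <- list(
    effects = summarize_effects(study),
    power = summarize_power(study),
    classification = summarize_classification(study),
    aic = summarize_aic(study),
    replicates = study$replicates)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(format_sig(tables[[nm]]), p, row.names = FALSE,
                     quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
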