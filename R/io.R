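# CSV schemas: column name -> type ("c" character, "d" double). All files are
# UTF-8, comma-separated, "." decimal, header row, empty cell = missing.
cohort_schemas <- function() {
  list(
    sites = c(site_id = "c", aridity_index = "d", mat = "d", map = "d",
              longitude = "d"),
    samples = c(sample_id = "c", site_id = "c", depth = "c", moisture = "c",
                ph = "d", cec = "d", ca = "d", mg = "d", sic = "d", soc = "d",
                oc_pom = "d", oc_maom = "d", oc_fe = "d", oc_ca = "d",
                sir_resp = "d", basal_resp = "d",
                delta13c_soc = "d", delta13c_sic = "d"),
    incubation = c(sample_id = "c", temperature_C = "d", duration_h = "d",
                   co2_initial_ppm = "d", co2_final_ppm = "d",
                   delta13c_headspace_permil = "d"),
    truth = c(sample_id = "c", site_id = "c", depth = "c", moisture = "c",
              true_q10_soc = "d", true_q10_sic = "d", true_k_soc = "d",
              true_k_sic = "d", true_b_soc = "d", true_b_sic = "d",
              true_f_sic_20C = "d")
  )
}

# internal <-> on-disk column names for the incubation table
incubation_disk_names <- c(
  temperature = "temperature_C", duration = "duration_h",
  co2_initial = "co2_initial_ppm", co2_final = "co2_final_ppm",
  delta13c_headspace = "delta13c_headspace_permil")

#' Write a cohort to CSV files
#'
#' Writes `sites.csv`, `samples.csv`, `incubation.csv` and `truth.csv` into
#' `dir` using the documented schemas. Ground truth lives in its own file so
#' the analysis-facing tables look like real study inputs.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inc <- cohort$incubation
  names(inc) <- ifelse(names(inc) %in% names(incubation_disk_names),
                       incubation_disk_names[names(inc)], names(inc))
  sam <- cohort$samples[names(cohort_schemas()$samples)]
  readr::write_csv(cohort$sites, file.path(dir, "sites.csv"))
  readr::write_csv(sam, file.path(dir, "samples.csv"))
  readr::write_csv(inc, file.path(dir, "incubation.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read and validate a cohort directory
#'
#' Loads `sites.csv`, `samples.csv`, `incubation.csv` (and `truth.csv` when
#' present), checking that every declared column exists with the declared
#' type, that numeric cells parse, and that sample identifiers are unique.
#' Errors name the offending file and column.
#'
#' @param dir Directory containing the CSV files.
#' @return A list of validated tibbles (`sites`, `samples`, `incubation`,
#'   and `truth` if available).
#' @export
read_tables <- function(dir) {
  schemas <- cohort_schemas()
  out <- list()
  for (tab in c("sites", "samples", "incubation")) {
    out[[tab]] <- read_one_table(file.path(dir, paste0(tab, ".csv")),
                                 schemas[[tab]], tab)
  }
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- read_one_table(truth_path, schemas$truth, "truth")
  }
  if (anyDuplicated(out$samples$sample_id)) {
    stop("duplicate sample_id in samples.csv")
  }
  if (nrow(out$incubation) == 0) stop("no incubation records")
  names(out$incubation) <- ifelse(
    names(out$incubation) %in% incubation_disk_names,
    names(incubation_disk_names)[match(names(out$incubation),
                                       incubation_disk_names)],
    names(out$incubation))
  message(sprintf("read %d sites, %d samples, %d incubation records",
                  nrow(out$sites), nrow(out$samples), nrow(out$incubation)))
  out
}

read_one_table <- function(path, schema, label) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s.csv: missing column(s) %s", label,
                 paste(missing_cols, collapse = ", ")))
  }
  for (cn in names(schema)) {
    if (schema[[cn]] == "d") {
      vals <- df[[cn]]
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & vals != "" & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("%s.csv: non-numeric value '%s' in column %s, row %d",
                     label, vals[bad[1]], cn, bad[1]))
      }
      df[[cn]] <- parsed
    }
  }
  df
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, then chains flux computation, isotope
#' partitioning, temperature-response fitting, gradient statistics, the path
#' models for both responses, and the upscaling arithmetic. Writes all output
#' CSVs plus a JSON summary when `out_dir` is given. With a fixed seed the
#' whole run is deterministic.
#'
#' @param config A [cohort_config()].
#' @param cohort Optional pre-loaded cohort (list of tables); when `NULL`,
#'   one is generated from `config`.
#' @param out_dir Optional output directory.
#' @return A list with every stage's tables and a `summary` list.
#' @export
run_all <- function(config = cohort_config(), cohort = NULL, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(cohort)) cohort <- stage("simulate", generate_cohort(config))
  emissions <- stage("flux", compute_fluxes(cohort$incubation, config$protocol))
  partition <- stage("partition",
                     partition_all(emissions, cohort$samples,
                                   config$end_members))
  q10 <- stage("q10", fit_q10_all(partition, cohort$samples))
  gradient <- stage("gradient", aridity_gradient(q10, cohort$sites))
  whc_levels <- intersect(c("WHC20", "WHC40", "WHC60"),
                          unique(cohort$samples$moisture))
  if (length(whc_levels) >= 2) {
    ttests <- stage("ttests", moisture_tests(q10))
  } else {
    message("fewer than two WHC levels present; paired-test stage skipped")
    ttests <- NULL
  }
  correlations <- stage("correlations",
                        dplyr::bind_rows(lapply(unique(cohort$samples$depth),
    function(dp) {
      ct <- q10_correlations(q10, cohort$samples, cohort$sites, dp)
      ct$depth <- dp
      ct
    })))
  paths <- stage("pathmodel", lapply(c("q10_soc", "q10_sic"), function(resp) {
    run_path_analysis(q10, cohort$samples, cohort$sites, response = resp)
  }))
  names(paths) <- c("q10_soc", "q10_sic")
  upscale <- stage("upscaling", run_upscaling())

  summary <- list(
    seed = config$seed,
    n_sites = nrow(cohort$sites),
    n_samples = nrow(cohort$samples),
    n_incubation = nrow(cohort$incubation),
    qc_pass_rate = mean(q10$qc_pass),
    package_version = as.character(utils::packageVersion("dryq10"))
  )
  if (!is.null(cohort$truth)) {
    tr <- dplyr::inner_join(
      q10[q10$source %in% c("SOC", "SIC") & q10$qc_pass,
          c("sample_id", "source", "q10")],
      cohort$truth, by = "sample_id")
    truth_q10 <- ifelse(tr$source == "SOC", tr$true_q10_soc, tr$true_q10_sic)
    summary$max_abs_q10_error <- max(abs(tr$q10 - truth_q10))
  }
  result <- list(cohort = cohort, emissions = emissions,
                 partition = partition, q10 = q10, gradient = gradient,
                 ttests = ttests, correlations = correlations, paths = paths,
                 upscaling = upscale, summary = summary)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, out_dir)
    readr::write_csv(partition, file.path(out_dir, "partition.csv"))
    readr::write_csv(q10, file.path(out_dir, "q10.csv"))
    readr::write_csv(gradient, file.path(out_dir, "gradient.csv"))
    if (!is.null(ttests)) {
      readr::write_csv(ttests, file.path(out_dir, "ttests.csv"))
    }
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    effects <- dplyr::bind_rows(lapply(names(paths), function(nm) {
      ef <- paths[[nm]]$effects
      ef$response <- nm
      ef
    }))
    readr::write_csv(effects, file.path(out_dir, "effects.csv"))
    jsonlite::write_json(
      c(summary, upscale[setdiff(names(upscale), "constants")]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Write a run configuration to YAML
#'
#' @param config A [cohort_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$protocol <- unclass(cfg$protocol)
  cfg$end_members <- unclass(cfg$end_members)
  # named vectors must become maps, or YAML drops the depth names
  for (nm in c("sic_contribution_20C", "r_soc_20C")) {
    cfg[[nm]] <- as.list(cfg[[nm]])
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; the result round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file written by [write_run_config()].
#' @return A [cohort_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$protocol)) {
    cfg$protocol <- do.call(incubation_protocol, cfg$protocol)
  }
  if (!is.null(cfg$end_members)) {
    cfg$end_members <- do.call(end_members_config, cfg$end_members)
  }
  for (nm in c("sic_contribution_20C", "r_soc_20C")) {
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  do.call(cohort_config, cfg)
}
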