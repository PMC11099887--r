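# Workflow entry points tying the modules together. These functions back
# the command-line script (exec/lipidccs) but are equally usable from R.

#' Workflow configuration
#'
#' Collects input paths (or in-memory tables), thresholds and the seed for
#' the workflow runners. All thresholds default to the reference workflow's
#' stated values: 5 ppm mass accuracy, detection in 2 dilutions, 0.1 min
#' coelution tolerance, 1% CCS RSD, 3-6 standards per function, at most
#' 100 functions per group, slope band 0.8-1.2 and minimum r-squared 0.99.
#'
#' @param library Path to a library CSV, a [ccs_library], or `NULL` for
#'   the packaged reference library.
#' @param measured Path to a measured-CCS CSV or a data frame.
#' @param observations Path to an observation CSV or a data frame.
#' @param out Output directory.
#' @param seed Integer seed (recorded in every output header).
#' @param mode `"mean"` or `"per_file"` (see [fit_ccs_correction()]).
#' @param ppm_max,min_detections,rt_tol,rsd_max Curation thresholds.
#' @param k_min,k_max,cap,slope_band,r2_min Correction-ensemble settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(library = NULL, measured = NULL, observations = NULL,
                       out = "lipidccs_out", seed = 1,
                       mode = c("mean", "per_file"),
                       ppm_max = 5, min_detections = 2, rt_tol = 0.1,
                       rsd_max = 1, k_min = 3, k_max = 6, cap = 100,
                       slope_band = c(0.8, 1.2), r2_min = 0.99) {
  mode <- match.arg(mode)
  if (ppm_max <= 0 || min_detections < 1 || rt_tol <= 0 || rsd_max <= 0 ||
      k_min < 2 || k_max < k_min || cap < 1 || r2_min < 0 || r2_min > 1)
    stop("threshold out of its documented range", call. = FALSE)
  stopifnot(length(slope_band) == 2, slope_band[1] < slope_band[2])
  structure(list(library = library, measured = measured,
                 observations = observations, out = out,
                 seed = as.integer(seed), mode = mode, ppm_max = ppm_max,
                 min_detections = min_detections, rt_tol = rt_tol,
                 rsd_max = rsd_max, k_min = k_min, k_max = k_max, cap = cap,
                 slope_band = slope_band, r2_min = r2_min),
            class = "run_config")
}

#' Read a workflow configuration from a YAML file
#'
#' Keys match the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(run_config)))
  if (length(bad))
    .schema_stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# 32-bit FNV-1a over the deparsed thresholds: a short reproducible
# fingerprint of the configuration for output headers
.config_hash <- function(config) {
  x <- config[setdiff(names(config), c("library", "measured",
                                       "observations", "out"))]
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^32
  sprintf("%08x", as.integer(h %% 2^31))
}

.output_header <- function(config) {
  c(paste0("lipidccs ", as.character(utils::packageVersion("lipidccs"))),
    paste0("config_hash: ", .config_hash(config)),
    paste0("seed: ", config$seed))
}

.load_library <- function(config) {
  if (is.null(config$library)) return(default_ccs_library())
  if (inherits(config$library, "ccs_library")) return(config$library)
  read_ccs_library(config$library)
}

.load_table <- function(x, reader, what) {
  if (is.null(x)) .schema_stop("no ", what, " input given")
  if (is.data.frame(x)) return(x)
  reader(x)
}

#' Run the bias-monitoring stage
#'
#' Matches measured CCS values against the reference library and writes
#' the matched-pair table, the unmatched report and the grouped bias
#' summaries (including polarity-level rollups) to the output directory.
#'
#' @param config A [run_config()] with `measured` set.
#' @return Invisibly, a list with `pairs`, `unmatched` and `summary`.
#' @export
run_monitor <- function(config) {
  stopifnot(inherits(config, "run_config"))
  library <- .load_library(config)
  measured <- validate_measured(.load_table(config$measured, read_measured,
                                            "measured-CCS"))
  if (config$mode == "mean") measured <- aggregate_measured(measured)
  m <- match_to_library(measured, library)
  if (!nrow(m$pairs)) warning("no measured ion matched the library",
                              call. = FALSE)
  s <- summarize_bias(m$pairs)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  hdr <- .output_header(config)
  .write_csv_with_header(m$pairs, file.path(config$out, "matched_pairs.csv"),
                         hdr)
  .write_csv_with_header(m$unmatched, file.path(config$out, "unmatched.csv"),
                         hdr)
  .write_csv_with_header(s, file.path(config$out, "bias_summary.csv"), hdr)
  invisible(list(pairs = m$pairs, unmatched = m$unmatched, summary = s))
}

#' Run the correction stage
#'
#' Monitors first (see [run_monitor()]), then fits the class- and
#' adduct-specific correction ensembles on the labeled standards and
#' corrects all measured lipids of the covered groups irrespective of
#' labeling status. Writes the function table, the corrected-CCS tables
#' (point estimates and the full per-function ensemble), and before/after
#' bias tables per group and per function.
#'
#' @param config A [run_config()] with `measured` set.
#' @return Invisibly, a list with the fitted `model`
#'   (a [fit_ccs_correction()] object), the `monitor` results, the group
#'   summary and the corrected table.
#' @export
run_correct <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mon <- run_monitor(config)
  model <- fit_ccs_correction(mon$pairs, min_lipids = 3,
                              k_min = config$k_min, k_max = config$k_max,
                              cap = config$cap, seed = config$seed,
                              slope_band = config$slope_band,
                              r2_min = config$r2_min,
                              mode = if (config$mode == "per_file")
                                "per_file" else "mean")
  fns <- coef(model)
  if (any(fns$flagged))
    message(sum(fns$flagged), " correction function(s) flagged by the ",
            "quality rule (slope outside [",
            paste(config$slope_band, collapse = ", "), "] or r2 < ",
            config$r2_min, ")")

  # correct every measured lipid of a covered group, labeled or not
  measured <- validate_measured(.load_table(config$measured, read_measured,
                                            "measured-CCS"))
  if (config$mode == "mean") measured <- aggregate_measured(measured)
  parsed <- .parse_lipid_names(measured$lipid_name)
  measured$lipid_class <- parsed$lipid_class
  measured$ccs_corrected <- predict(model, measured)
  corrected <- measured[!is.na(measured$ccs_corrected), , drop = FALSE]

  smry <- summary(model)
  hdr <- .output_header(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  .write_csv_with_header(fns,
                         file.path(config$out, "correction_functions.csv"),
                         hdr)
  .write_csv_with_header(corrected,
                         file.path(config$out, "corrected_ccs.csv"), hdr)
  ens <- predict(model, corrected, ensemble = TRUE)
  ens$lipid_name <- corrected$lipid_name[ens$row]
  ens$label <- corrected$label[ens$row]
  .write_csv_with_header(ens,
                         file.path(config$out, "corrected_ccs_ensemble.csv"),
                         hdr)
  .write_csv_with_header(smry$groups,
                         file.path(config$out, "bias_before_after.csv"), hdr)
  .write_csv_with_header(smry$per_function,
                         file.path(config$out, "per_function_bias.csv"), hdr)
  invisible(list(model = model, monitor = mon, summary = smry$groups,
                 corrected = corrected))
}

#' Run the library-curation stage
#'
#' Applies the four-criterion curation pipeline to a dilution-series
#' observation table and writes the curated library, the rejection report,
#' the ECN-violation report and the library summary.
#'
#' @param config A [run_config()] with `observations` set.
#' @return Invisibly, a list with `library`, `rejections`,
#'   `ecn_violations` and `summary`.
#' @export
run_curate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  obs <- .load_table(config$observations, function(p) {
    if (!file.exists(p)) .schema_stop("observation file not found: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE, comment.char = "#")
  }, "observation")
  res <- curate_library(obs, ppm_max = config$ppm_max,
                        min_detections = config$min_detections,
                        rt_tol = config$rt_tol, rsd_max = config$rsd_max)
  ecn <- ecn_trend_report(res$library)
  s <- library_summary(res$library)
  hdr <- .output_header(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_ccs_library(res$library,
                    file.path(config$out, "curated_library.csv"), hdr)
  .write_csv_with_header(res$rejections,
                         file.path(config$out, "rejections.csv"), hdr)
  .write_csv_with_header(ecn, file.path(config$out, "ecn_violations.csv"),
                         hdr)
  sdf <- data.frame(n_entries = s$n_entries, n_species = s$n_species,
                    n_classes = s$n_classes, n_adducts = s$n_adducts,
                    mz_min = s$mz_range[1], mz_max = s$mz_range[2],
                    dtccs_min = s$dtccs_range[1],
                    dtccs_max = s$dtccs_range[2])
  .write_csv_with_header(sdf, file.path(config$out, "library_summary.csv"),
                         hdr)
  invisible(list(library = res$library, rejections = res$rejections,
                 ecn_violations = ecn, summary = s))
}

#' Run the simulation stage
#'
#' Generates a synthetic data set ([simulate_ccs_dataset()]) and writes
#' its three CSV files to the output directory.
#'
#' @param config A [run_config()]; its `seed` is passed to the generator.
#' @param sim_cfg Optional [sim_config()] (its seed is overridden by
#'   `config$seed`).
#' @return Invisibly, the `ccs_simulation`.
#' @export
run_simulate <- function(config, sim_cfg = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed)
  else sim_cfg$seed <- config$seed
  sim <- simulate_ccs_dataset(sim_cfg)
  write_sim_dataset(sim, config$out, .output_header(config))
  invisible(sim)
}
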