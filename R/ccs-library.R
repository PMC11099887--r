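# Reference DT-CCS(N2) library: data model, CSV I/O, curation, ECN checks.

.LIBRARY_COLS <- c("lipid_name", "lipid_class", "carbons", "double_bonds",
                   "isomer", "adduct", "polarity", "label", "mz_theoretical",
                   "dtccs_n2", "ccs_rsd_pct", "n_detections")

.OBSERVATION_COLS <- c("file_id", "dilution_id", "lipid_name", "adduct",
                       "polarity", "label", "mz_measured", "mz_theoretical",
                       "rt_min", "ccs")

.schema_stop <- function(...) {
  stop(errorCondition(paste0(...), class = c("lipidccs_schema_error", "error")))
}

.validation_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lipidccs_validation_error", "error")))
}

.check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .schema_stop(what, " is missing column(s): ",
                 paste(missing, collapse = ", "))
  invisible(df)
}

#' Construct a curated CCS reference library
#'
#' Wraps a validated entry table together with a provenance string. One row
#' per (lipid species, adduct); the shipped reference values are drift-tube
#' CCS in nitrogen for uniformly 13C-labeled lipids.
#'
#' @param entries Data frame with columns
#'   `lipid_name, lipid_class, carbons, double_bonds, isomer, adduct,
#'   polarity, label, mz_theoretical, dtccs_n2, ccs_rsd_pct, n_detections`.
#' @param provenance Free-text description of the source and the curation
#'   thresholds used.
#' @return An object of class `ccs_library`.
#' @export
ccs_library <- function(entries, provenance = "unspecified") {
  .check_columns(entries, .LIBRARY_COLS, "library table")
  entries <- entries[, .LIBRARY_COLS]
  entries$lipid_name <- as.character(entries$lipid_name)
  entries$adduct <- .normalize_adduct(as.character(entries$adduct))

  if (nrow(entries)) {
    # canonical names must round-trip through the parser
    parsed <- .parse_lipid_names(entries$lipid_name)
    canon <- mapply(function(cl, cb, db, iso)
      format_lipid_name(list(lipid_class = cl, carbons = cb,
                             double_bonds = db, isomer = iso)),
      parsed$lipid_class, parsed$carbons, parsed$double_bonds, parsed$isomer)
    bad <- entries$lipid_name != canon
    if (any(bad))
      .validation_stop("non-canonical lipid name(s): ",
                       paste(unique(entries$lipid_name[bad]), collapse = ", "))
    entries$lipid_class <- parsed$lipid_class
    entries$carbons <- parsed$carbons
    entries$double_bonds <- parsed$double_bonds
    entries$isomer <- parsed$isomer

    pol <- adduct_polarity(entries$adduct)
    if (any(entries$polarity != pol))
      .validation_stop("polarity inconsistent with adduct for: ",
                       paste(unique(entries$lipid_name[entries$polarity != pol]),
                             collapse = ", "))
    if (any(!is.finite(entries$dtccs_n2) | entries$dtccs_n2 <= 0))
      .validation_stop("non-positive reference CCS value(s)")
    if (any(!is.finite(entries$mz_theoretical) | entries$mz_theoretical <= 0))
      .validation_stop("non-positive theoretical m/z value(s)")
    if (any(entries$ccs_rsd_pct >= 1))
      .validation_stop("CCS RSD >= 1% violates the curation criterion for: ",
                       paste(entries$lipid_name[entries$ccs_rsd_pct >= 1],
                             collapse = ", "))
    if (any(entries$n_detections < 2))
      .validation_stop("entries with fewer than 2 detections present")
    key <- paste(entries$lipid_name, entries$adduct)
    if (anyDuplicated(key))
      .validation_stop("duplicate (species, adduct) key(s): ",
                       paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  structure(list(entries = entries, provenance = provenance),
            class = "ccs_library")
}

#' @export
print.ccs_library <- function(x, ...) {
  s <- library_summary(x)
  cat("<ccs_library> ", s$n_entries, " entries, ", s$n_species, " species, ",
      s$n_classes, " classes, ", s$n_adducts, " adduct types\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a CCS reference library from CSV
#'
#' Comma-separated, UTF-8, period decimal separator; lines starting with
#' `#` (reproducibility headers written by the workflow functions) are
#' skipped. All library invariants are checked on load.
#'
#' @param path Path to the library CSV.
#' @param provenance Optional provenance override; defaults to the path.
#' @return A [ccs_library] object.
#' @export
read_ccs_library <- function(path, provenance = path) {
  if (!file.exists(path)) .schema_stop("library file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  ccs_library(df, provenance = provenance)
}

#' Packaged synthetic reference library
#'
#' Loads the reference library shipped with the package:
#' `extdata/u13c_dtccs_library_synthetic.csv`, a fully synthetic stand-in
#' that reproduces the composition of the published drift-tube CCS library
#' for uniformly 13C-labeled yeast lipids (377 entries for 162 species
#' across 15 lipid classes and 5 adduct types, m/z 318.3501-966.9794,
#' CCS 189.4-327.1 A^2) with class-wise ECN-consistent values. The CCS and
#' m/z values themselves are constructed, not measured.
#'
#' @return A [ccs_library] object.
#' @export
default_ccs_library <- function() {
  path <- system.file("extdata", "u13c_dtccs_library_synthetic.csv",
                      package = "lipidccs", mustWork = TRUE)
  read_ccs_library(path, provenance = "packaged synthetic reference library")
}

#' Write a library to CSV
#'
#' @param library A [ccs_library].
#' @param path Output path.
#' @param header Optional character vector of header lines (written with a
#'   leading `# `).
#' @return `path`, invisibly.
#' @export
write_ccs_library <- function(library, path, header = NULL) {
  stopifnot(inherits(library, "ccs_library"))
  .write_csv_with_header(library$entries, path, header)
}

.write_csv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate an observation table
#'
#' @param observations Data frame of replicate observations across a
#'   dilution series (see package README for the column schema).
#' @return The observation data frame, normalized, invisibly usable.
#' @export
validate_observations <- function(observations) {
  .check_columns(observations, .OBSERVATION_COLS, "observation table")
  observations$adduct <- .normalize_adduct(as.character(observations$adduct))
  observations$lipid_name <- as.character(observations$lipid_name)
  if (nrow(observations)) {
    if (any(!is.finite(observations$ccs) | observations$ccs <= 0))
      .validation_stop("non-positive CCS in observations")
    if (any(observations$rt_min < 0))
      .validation_stop("negative retention time in observations")
    pol <- adduct_polarity(observations$adduct)
    if (any(observations$polarity != pol))
      .validation_stop("observation polarity inconsistent with adduct")
  }
  observations
}

#' Curate a reference library from replicate observations
#'
#' Applies the four curation criteria, in order, to each (species, adduct)
#' group of a dilution-series observation table:
#' \enumerate{
#'   \item mass accuracy: every replicate within `ppm_max` (inclusive);
#'   \item detection in at least `min_detections` distinct dilutions;
#'   \item coelution of adducts: the group's mean retention time must lie
#'     within `rt_tol` minutes of the median retention time over all adduct
#'     groups of the same species (across both polarities);
#'   \item CCS repeatability: relative standard deviation strictly below
#'     `rsd_max` percent.
#' }
#' A rejected group is reported with the first criterion it fails. Retained
#' groups become library entries with the reference CCS set to the
#' arithmetic mean over replicates.
#'
#' @param observations Observation data frame (see
#'   [validate_observations()]).
#' @param ppm_max Maximum absolute mass error in ppm (default 5, inclusive).
#' @param min_detections Minimum number of distinct dilutions (default 2).
#' @param rt_tol Coelution tolerance in minutes (default 0.1).
#' @param rsd_max CCS RSD threshold in percent (default 1, exclusive).
#' @param provenance Provenance string stored in the curated library.
#' @return A list with elements `library` (a [ccs_library]) and
#'   `rejections` (data frame `lipid_name, adduct, reason` with reasons in
#'   `mass_accuracy`, `min_detections`, `coelution`, `ccs_rsd`).
#' @export
curate_library <- function(observations, ppm_max = 5, min_detections = 2,
                           rt_tol = 0.1, rsd_max = 1,
                           provenance = NULL) {
  observations <- validate_observations(observations)
  if (is.null(provenance))
    provenance <- sprintf(
      "curated: ppm<=%g, dilutions>=%d, |dRT|<=%g min, RSD<%g%%",
      ppm_max, min_detections, rt_tol, rsd_max)

  empty_rej <- data.frame(lipid_name = character(), adduct = character(),
                          reason = character(), stringsAsFactors = FALSE)
  if (!nrow(observations)) {
    lib <- ccs_library(.empty_library_entries(), provenance = provenance)
    return(list(library = lib, rejections = empty_rej))
  }

  key <- paste(observations$lipid_name, observations$adduct, sep = "\r")
  groups <- split(seq_len(nrow(observations)), key)

  per_group <- lapply(groups, function(i) {
    g <- observations[i, ]
    data.frame(
      lipid_name = g$lipid_name[1],
      adduct = g$adduct[1],
      polarity = g$polarity[1],
      label = g$label[1],
      mz_theoretical = g$mz_theoretical[1],
      max_abs_ppm = max(abs(ppm_error(g$mz_measured, g$mz_theoretical))),
      n_dilutions = length(unique(g$dilution_id)),
      rt_mean = mean(g$rt_min),
      ccs_mean = mean(g$ccs),
      ccs_rsd = if (nrow(g) > 1) stats::sd(g$ccs) / mean(g$ccs) * 100 else 0,
      stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, per_group)
  rownames(stats_df) <- NULL

  # coelution: per species, deviation of each adduct group's mean RT from
  # the median over that species' adduct groups (pooled across polarities)
  med_rt <- tapply(stats_df$rt_mean, stats_df$lipid_name, stats::median)
  stats_df$rt_dev <- abs(stats_df$rt_mean -
                           med_rt[stats_df$lipid_name])

  reason <- rep(NA_character_, nrow(stats_df))
  reason[is.na(reason) & stats_df$max_abs_ppm > ppm_max] <- "mass_accuracy"
  reason[is.na(reason) & stats_df$n_dilutions < min_detections] <- "min_detections"
  reason[is.na(reason) & stats_df$rt_dev > rt_tol] <- "coelution"
  reason[is.na(reason) & stats_df$ccs_rsd >= rsd_max] <- "ccs_rsd"

  keep <- is.na(reason)
  rejections <- data.frame(lipid_name = stats_df$lipid_name[!keep],
                           adduct = stats_df$adduct[!keep],
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  if (!any(keep)) {
    lib <- ccs_library(.empty_library_entries(), provenance = provenance)
    return(list(library = lib, rejections = rejections))
  }

  kept <- stats_df[keep, ]
  parsed <- .parse_lipid_names(kept$lipid_name)
  entries <- data.frame(
    lipid_name = kept$lipid_name,
    lipid_class = parsed$lipid_class,
    carbons = parsed$carbons,
    double_bonds = parsed$double_bonds,
    isomer = parsed$isomer,
    adduct = kept$adduct,
    polarity = kept$polarity,
    label = kept$label,
    mz_theoretical = kept$mz_theoretical,
    dtccs_n2 = kept$ccs_mean,
    ccs_rsd_pct = kept$ccs_rsd,
    n_detections = kept$n_dilutions,
    stringsAsFactors = FALSE)
  entries <- entries[order(entries$lipid_class, entries$carbons,
                           entries$double_bonds, entries$lipid_name,
                           entries$adduct), ]
  rownames(entries) <- NULL
  list(library = ccs_library(entries, provenance = provenance),
       rejections = rejections)
}

.empty_library_entries <- function() {
  data.frame(lipid_name = character(), lipid_class = character(),
             carbons = integer(), double_bonds = integer(),
             isomer = integer(), adduct = character(),
             polarity = character(), label = character(),
             mz_theoretical = numeric(), dtccs_n2 = numeric(),
             ccs_rsd_pct = numeric(), n_detections = integer(),
             stringsAsFactors = FALSE)
}

#' Check ECN-trend consistency of one class-adduct group
#'
#' Within a lipid class and adduct, a longer total fatty acyl chain should
#' give a larger CCS and more double bonds a smaller CCS (the equivalent
#' carbon number ordering transferred from retention time to the CCS
#' dimension). Returns every ordered entry pair violating this.
#'
#' @param library A [ccs_library].
#' @param lipid_class,adduct Group to check.
#' @return Data frame with one row per violating pair: `name_1, name_2,
#'   ccs_1, ccs_2, kind` (`chain_length` or `unsaturation`). Zero rows means
#'   the group is consistent.
#' @export
ecn_trend_validate <- function(library, lipid_class, adduct) {
  stopifnot(inherits(library, "ccs_library"))
  e <- library$entries
  adduct <- .normalize_adduct(adduct)
  e <- e[e$lipid_class == lipid_class & e$adduct == adduct, ]
  out <- data.frame(name_1 = character(), name_2 = character(),
                    ccs_1 = numeric(), ccs_2 = numeric(),
                    kind = character(), stringsAsFactors = FALSE)
  n <- nrow(e)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_db <- e$double_bonds[i] == e$double_bonds[j]
      same_c <- e$carbons[i] == e$carbons[j]
      if (same_db && e$carbons[i] < e$carbons[j] &&
          e$dtccs_n2[i] >= e$dtccs_n2[j]) {
        out <- rbind(out, data.frame(
          name_1 = e$lipid_name[i], name_2 = e$lipid_name[j],
          ccs_1 = e$dtccs_n2[i], ccs_2 = e$dtccs_n2[j],
          kind = "chain_length", stringsAsFactors = FALSE))
      }
      if (same_c && e$double_bonds[i] < e$double_bonds[j] &&
          e$dtccs_n2[i] <= e$dtccs_n2[j]) {
        out <- rbind(out, data.frame(
          name_1 = e$lipid_name[i], name_2 = e$lipid_name[j],
          ccs_1 = e$dtccs_n2[i], ccs_2 = e$dtccs_n2[j],
          kind = "unsaturation", stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' ECN-trend report over all class-adduct groups
#'
#' @param library A [ccs_library].
#' @return Data frame of all violating pairs across groups, with
#'   `lipid_class` and `adduct` columns prepended; zero rows if the whole
#'   library is ECN-consistent.
#' @export
ecn_trend_report <- function(library) {
  stopifnot(inherits(library, "ccs_library"))
  e <- library$entries
  groups <- unique(e[, c("lipid_class", "adduct")])
  out <- NULL
  for (k in seq_len(nrow(groups))) {
    v <- ecn_trend_validate(library, groups$lipid_class[k], groups$adduct[k])
    if (nrow(v)) {
      v <- cbind(lipid_class = groups$lipid_class[k],
                 adduct = groups$adduct[k], v)
      out <- rbind(out, v)
    }
  }
  if (is.null(out))
    out <- data.frame(lipid_class = character(), adduct = character(),
                      name_1 = character(), name_2 = character(),
                      ccs_1 = numeric(), ccs_2 = numeric(),
                      kind = character(), stringsAsFactors = FALSE)
  out
}

#' Summarize library composition
#'
#' @param library A [ccs_library].
#' @return An object of class `ccs_library_summary`: entry count, distinct
#'   species / class / adduct counts, and m/z and CCS ranges (`NA` for an
#'   empty library).
#' @export
library_summary <- function(library) {
  stopifnot(inherits(library, "ccs_library"))
  e <- library$entries
  s <- list(
    n_entries = nrow(e),
    n_species = length(unique(e$lipid_name)),
    n_classes = length(unique(e$lipid_class)),
    n_adducts = length(unique(e$adduct)),
    mz_range = if (nrow(e)) range(e$mz_theoretical) else c(NA_real_, NA_real_),
    dtccs_range = if (nrow(e)) range(e$dtccs_n2) else c(NA_real_, NA_real_))
  structure(s, class = "ccs_library_summary")
}

#' @export
print.ccs_library_summary <- function(x, ...) {
  cat("CCS reference library summary\n")
  cat(sprintf("  entries:  %d\n  species:  %d\n  classes:  %d\n  adducts:  %d\n",
              x$n_entries, x$n_species, x$n_classes, x$n_adducts))
  if (x$n_entries) {
    cat(sprintf("  m/z:      %.4f - %.4f\n", x$mz_range[1], x$mz_range[2]))
    cat(sprintf("  CCS (A^2): %.1f - %.1f\n",
                x$dtccs_range[1], x$dtccs_range[2]))
  }
  invisible(x)
}
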