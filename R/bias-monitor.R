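# Matching measured CCS values to the reference library; percent-bias
# computation and grouped summaries.

.MEASURED_COLS <- c("file_id", "lipid_name", "adduct", "polarity", "label",
                    "mz_measured", "rt_min", "ccs_measured")

#' Validate a measured-CCS table
#'
#' The measured table is a targeted export: one row per observed
#' lipid-adduct ion per data file, with the externally calibrated CCS (for
#' example a trapped-ion-mobility CCS). `label` is `"U13C"` for uniformly
#' 13C-labeled ions and `"12C"` for unlabeled ones; labeling is a column,
#' not part of the species name, because the same species identity exists
#' in both forms.
#'
#' @param measured Data frame with columns
#'   `file_id, lipid_name, adduct, polarity, label, mz_measured, rt_min,
#'   ccs_measured`.
#' @return The normalized data frame.
#' @export
validate_measured <- function(measured) {
  .check_columns(measured, .MEASURED_COLS, "measured-CCS table")
  measured$adduct <- .normalize_adduct(as.character(measured$adduct))
  measured$lipid_name <- as.character(measured$lipid_name)
  if (nrow(measured)) {
    if (any(!is.finite(measured$ccs_measured) | measured$ccs_measured <= 0))
      .validation_stop("non-positive measured CCS")
    pol <- adduct_polarity(measured$adduct)
    if (any(measured$polarity != pol))
      .validation_stop("measured polarity inconsistent with adduct")
    if (!all(measured$label %in% c("U13C", "12C")))
      .validation_stop("label must be 'U13C' or '12C'")
  }
  measured
}

#' Read a measured-CCS table from CSV
#'
#' @param path Path to the CSV (lines starting with `#` are skipped).
#' @return Validated measured data frame.
#' @export
read_measured <- function(path) {
  if (!file.exists(path)) .schema_stop("measured file not found: ", path)
  validate_measured(utils::read.csv(path, stringsAsFactors = FALSE,
                                    comment.char = "#"))
}

#' Average measured CCS across files
#'
#' Collapses a measured table to one row per (species, adduct, label) ion
#' with the mean measured CCS, m/z and retention time over all files. This
#' is the "mean mode" granularity used when an experiment's files are
#' summarized before bias assessment; with a single input file it is the
#' identity (up to the `file_id` value).
#'
#' @param measured Validated measured data frame.
#' @return Measured data frame with `file_id = "<mean>"`.
#' @export
aggregate_measured <- function(measured) {
  measured <- validate_measured(measured)
  if (!nrow(measured)) return(measured)
  key <- paste(measured$lipid_name, measured$adduct, measured$label,
               sep = "\r")
  idx <- split(seq_len(nrow(measured)), key)
  rows <- lapply(idx, function(i) {
    g <- measured[i, ]
    data.frame(file_id = "<mean>", lipid_name = g$lipid_name[1],
               adduct = g$adduct[1], polarity = g$polarity[1],
               label = g$label[1], mz_measured = mean(g$mz_measured),
               rt_min = mean(g$rt_min), ccs_measured = mean(g$ccs_measured),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lipid_name, out$adduct, out$label), ]
}

#' Percent CCS bias of a measured value against a reference
#'
#' @param ccs_measured,ccs_reference Positive CCS values in the same units.
#' @return `(measured - reference) / reference * 100`; positive means the
#'   instrument reads larger than the reference.
#' @export
#' @examples
#' ccs_bias_percent(252.5, 250)
ccs_bias_percent <- function(ccs_measured, ccs_reference) {
  if (any(ccs_measured <= 0) || any(ccs_reference <= 0))
    stop("CCS values must be positive", call. = FALSE)
  (ccs_measured - ccs_reference) / ccs_reference * 100
}

#' Match measured ions to the reference library
#'
#' Labeled (`U13C`) measured ions are matched to library entries on the
#' exact (canonical species name including isomer index, adduct) key.
#' Unlabeled ions are never matched (the library holds labeled lipids);
#' they are carried separately for correction application. A labeled ion
#' whose name lacks an isomer index while the library holds more than one
#' isomer of that class/carbons/double-bonds/adduct is excluded as
#' ambiguous rather than guessed.
#'
#' @param measured Measured data frame (see [validate_measured()]).
#' @param library A [ccs_library].
#' @return List with `pairs` (matched rows joined with reference columns
#'   `mz_theoretical`, `dtccs_n2` and computed `bias_pct`) and `unmatched`
#'   (labeled ions not matched, with a `reason` of `not_in_library` or
#'   `ambiguous_isomer`).
#' @export
match_to_library <- function(measured, library) {
  measured <- validate_measured(measured)
  stopifnot(inherits(library, "ccs_library"))
  e <- library$entries

  lab <- measured[measured$label == "U13C", , drop = FALSE]
  ref_key <- paste(e$lipid_name, e$adduct, sep = "\r")
  meas_key <- paste(lab$lipid_name, lab$adduct, sep = "\r")
  hit <- match(meas_key, ref_key)

  # ambiguity: no exact hit, no isomer index on the measured name, but the
  # library holds >1 isomer of the same species backbone for that adduct
  ambiguous <- rep(FALSE, nrow(lab))
  if (nrow(lab)) {
    parsed <- .parse_lipid_names(lab$lipid_name)
    backbone_key <- paste(e$lipid_class, e$carbons, e$double_bonds, e$adduct,
                          sep = "\r")
    n_iso <- table(backbone_key)
    meas_backbone <- paste(parsed$lipid_class, parsed$carbons,
                           parsed$double_bonds, lab$adduct, sep = "\r")
    ambiguous <- is.na(hit) & is.na(parsed$isomer) &
      !is.na(match(meas_backbone, names(n_iso))) &
      as.vector(n_iso[meas_backbone]) > 1
    ambiguous[is.na(ambiguous)] <- FALSE
  }

  ok <- !is.na(hit)
  pairs <- cbind(lab[ok, , drop = FALSE],
                 e[hit[ok], c("lipid_class", "carbons", "double_bonds",
                              "isomer", "mz_theoretical", "dtccs_n2"),
                   drop = FALSE])
  rownames(pairs) <- NULL
  if (nrow(pairs)) {
    pairs$bias_pct <- ccs_bias_percent(pairs$ccs_measured, pairs$dtccs_n2)
  } else {
    pairs$bias_pct <- numeric(0)
  }

  unmatched <- lab[!ok, c("file_id", "lipid_name", "adduct", "polarity"),
                   drop = FALSE]
  unmatched$reason <- ifelse(ambiguous[!ok], "ambiguous_isomer",
                             "not_in_library")
  rownames(unmatched) <- NULL
  list(pairs = pairs, unmatched = unmatched)
}

#' Grouped CCS-bias summaries
#'
#' Summarizes matched-pair biases per (lipid class, adduct, polarity)
#' group and, when `modes = TRUE`, adds mode-level rollups over all matched
#' ions of each ionization polarity (each matched ion weighted equally).
#'
#' @param pairs Matched pairs from [match_to_library()].
#' @param modes Add polarity-level rollup rows (default `TRUE`).
#' @return Data frame with columns `lipid_class, adduct, polarity, n,
#'   mean_bias, mean_abs_bias, min_bias, max_bias`; rollup rows carry
#'   `lipid_class = adduct = "<all>"`. Empty input gives zero rows.
#' @export
summarize_bias <- function(pairs, modes = TRUE) {
  empty <- data.frame(lipid_class = character(), adduct = character(),
                      polarity = character(), n = integer(),
                      mean_bias = numeric(), mean_abs_bias = numeric(),
                      min_bias = numeric(), max_bias = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  stat_row <- function(cls, add, pol, b) {
    data.frame(lipid_class = cls, adduct = add, polarity = pol,
               n = length(b), mean_bias = mean(b),
               mean_abs_bias = mean(abs(b)),
               min_bias = min(b), max_bias = max(b),
               stringsAsFactors = FALSE)
  }
  key <- paste(pairs$lipid_class, pairs$adduct, sep = "\r")
  idx <- split(seq_len(nrow(pairs)), key)
  out <- do.call(rbind, lapply(idx, function(i)
    stat_row(pairs$lipid_class[i[1]], pairs$adduct[i[1]],
             pairs$polarity[i[1]], pairs$bias_pct[i])))
  out <- out[order(out$lipid_class, out$adduct), ]
  if (modes) {
    for (pol in unique(pairs$polarity)) {
      b <- pairs$bias_pct[pairs$polarity == pol]
      out <- rbind(out, stat_row("<all>", "<all>", pol, b))
    }
  }
  rownames(out) <- NULL
  out
}
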