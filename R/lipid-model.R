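# Species-level lipid nomenclature, adduct arithmetic and small mass utilities.

#' Supported lipid classes
#'
#' Lipid class abbreviations recognised by [parse_lipid_name()]: AcCa
#' (acylcarnitine), Cer (ceramide), Co (coenzyme), DG (diacylglycerol),
#' HexCer (hexosylceramide), LPC (lysophosphatidylcholine), LPE
#' (lysophosphatidylethanolamine), PA (phosphatidic acid), PC
#' (phosphatidylcholine), PE (phosphatidylethanolamine), PG
#' (phosphatidylglycerol), PI (phosphatidylinositol), PS
#' (phosphatidylserine), SPH (sphingoid base), TG (triacylglycerol).
#'
#' @return Character vector of class abbreviations.
#' @export
lipid_classes <- function() {
  c("AcCa", "Cer", "Co", "DG", "HexCer", "LPC", "LPE", "PA",
    "PC", "PE", "PG", "PI", "PS", "SPH", "TG")
}

# charge-carrier mass changes (Da) for the five singly charged adducts
.ADDUCTS <- data.frame(
  adduct     = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
  polarity   = c("positive", "positive", "positive", "negative", "negative"),
  mass_delta = c(1.007276, 18.033823, 22.989218, -1.007276, 44.998201),
  stringsAsFactors = FALSE
)

#' Supported adducts
#'
#' The five singly charged adduct types covered by the reference library,
#' with ionization polarity and the fixed charge-carrier mass change.
#'
#' @return A data frame with columns `adduct`, `polarity` and `mass_delta`
#'   (Da, signed).
#' @export
#' @examples
#' adduct_table()
adduct_table <- function() .ADDUCTS

.normalize_adduct <- function(adduct) {
  # tolerate the typographic minus and embedded spaces ("[M - H]-")
  a <- gsub("−", "-", adduct)
  a <- gsub("[[:space:]]+", "", a)
  a
}

.adduct_row <- function(adduct) {
  a <- .normalize_adduct(adduct)
  i <- match(a, .ADDUCTS$adduct)
  if (anyNA(i)) {
    stop("unknown adduct: ", paste(unique(adduct[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  .ADDUCTS[i, , drop = FALSE]
}

#' Polarity of an adduct
#'
#' @param adduct Adduct name, e.g. `"[M+H]+"`.
#' @return `"positive"` or `"negative"` (vectorized).
#' @export
adduct_polarity <- function(adduct) .adduct_row(adduct)$polarity

#' Parse a species-level lipid name
#'
#' Parses names of the form `"PC 34:2"` or `"TG 48:2 (2)"`: class
#' abbreviation, total fatty acyl carbons, total double bonds, and an
#' optional isomer index in parentheses giving the chromatographic elution
#' order when one species resolves into several isomers.
#'
#' @param name Non-empty character scalar.
#' @return An object of class `lipid_species`: a list with elements
#'   `lipid_class`, `carbons`, `double_bonds`, `isomer` (`NA_integer_` when
#'   absent).
#' @seealso [format_lipid_name()] for the inverse.
#' @export
#' @examples
#' parse_lipid_name("PC 34:2")
#' parse_lipid_name("TG 48:2 (2)")
parse_lipid_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a non-empty character scalar", call. = FALSE)
  m <- regmatches(name, regexec(
    "^([A-Za-z]+) ([0-9]+):([0-9]+)(?: \\(([0-9]+)\\))?$", name))[[1]]
  if (length(m) == 0L)
    stop("malformed lipid name: '", name, "'", call. = FALSE)
  cls <- m[2]
  if (!cls %in% lipid_classes())
    stop("unknown lipid class '", cls, "' in '", name, "'", call. = FALSE)
  isomer <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  if (!is.na(isomer) && isomer < 1L)
    stop("isomer index must be a positive integer in '", name, "'",
         call. = FALSE)
  structure(
    list(lipid_class = cls,
         carbons = as.integer(m[3]),
         double_bonds = as.integer(m[4]),
         isomer = isomer),
    class = "lipid_species")
}

#' Format a lipid species back to its canonical name
#'
#' @param species A `lipid_species` object or a list with fields
#'   `lipid_class`, `carbons`, `double_bonds` and optionally `isomer`.
#' @return Canonical species name, e.g. `"TG 48:2 (2)"`.
#' @export
format_lipid_name <- function(species) {
  base <- sprintf("%s %d:%d", species$lipid_class,
                  as.integer(species$carbons), as.integer(species$double_bonds))
  iso <- species$isomer
  if (!is.null(iso) && length(iso) == 1L && !is.na(iso))
    base <- sprintf("%s (%d)", base, as.integer(iso))
  base
}

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species> ", format_lipid_name(x), "\n", sep = "")
  invisible(x)
}

# vectorized parse into a data.frame; used by the table-level readers
.parse_lipid_names <- function(names) {
  parts <- lapply(names, parse_lipid_name)
  data.frame(
    lipid_class  = vapply(parts, `[[`, "", "lipid_class"),
    carbons      = vapply(parts, `[[`, 0L, "carbons"),
    double_bonds = vapply(parts, `[[`, 0L, "double_bonds"),
    isomer       = vapply(parts, `[[`, NA_integer_, "isomer"),
    stringsAsFactors = FALSE)
}

#' m/z of a singly charged adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (> 0).
#' @param adduct Adduct name (see [adduct_table()]).
#' @return m/z = neutral mass + charge-carrier mass change.
#' @export
#' @examples
#' adduct_mz(760.5851, "[M+H]+")
adduct_mz <- function(neutral_mass, adduct) {
  if (any(!is.finite(neutral_mass)) || any(neutral_mass <= 0))
    stop("'neutral_mass' must be positive", call. = FALSE)
  neutral_mass + .adduct_row(adduct)$mass_delta
}

# 13C - 12C mass difference, Da
.C13_SHIFT <- 13.0033548 - 12

#' Mass shift of a uniformly 13C-labeled molecule
#'
#' For uniform labeling every carbon is 13C, so the shift is the carbon
#' count times the 13C-12C mass difference (1.0033548 Da).
#'
#' @param n_carbons Non-negative integer carbon count.
#' @return Mass shift in Da.
#' @export
#' @examples
#' u13c_mass_shift(42)
u13c_mass_shift <- function(n_carbons) {
  if (any(!is.finite(n_carbons)) || any(n_carbons < 0))
    stop("'n_carbons' must be non-negative", call. = FALSE)
  n_carbons * .C13_SHIFT
}

#' Mass error in parts per million
#'
#' @param measured_mz,theoretical_mz m/z values; `theoretical_mz` must be
#'   positive.
#' @return Signed ppm error, `(measured - theoretical) / theoretical * 1e6`.
#'   Filters use the absolute value.
#' @export
ppm_error <- function(measured_mz, theoretical_mz) {
  if (any(!is.finite(theoretical_mz)) || any(theoretical_mz <= 0))
    stop("'theoretical_mz' must be positive", call. = FALSE)
  (measured_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Apparent CCS shift between isotopologues from reduced-mass considerations
#'
#' In drift-tube theory the measured mobility depends on the ion-gas reduced
#' mass mu = m * M / (m + M). Two isotopologues of identical structure then
#' show a small apparent relative CCS difference of
#' `sqrt(mu_heavy / mu_light) - 1` when CCS values are computed with the
#' respective exact masses but a common mobility. This is a diagnostic for
#' the small systematic offset seen between unlabeled and uniformly
#' 13C-labeled lipids; it is not a correction.
#'
#' @param m_light,m_heavy Ion masses in Da, `m_heavy >= m_light > 0`.
#' @param gas_mass Buffer gas mass in Da (N2 = 28.0134).
#' @return Non-negative fractional shift (0 when masses are equal).
#' @export
#' @examples
#' isotopologue_apparent_shift(760.59, 802.73, 28.0134)
isotopologue_apparent_shift <- function(m_light, m_heavy, gas_mass = 28.0134) {
  if (any(m_light <= 0) || any(m_heavy <= 0) || any(gas_mass <= 0))
    stop("masses must be positive", call. = FALSE)
  if (any(m_heavy < m_light))
    stop("'m_heavy' must be >= 'm_light'", call. = FALSE)
  mu_l <- m_light * gas_mass / (m_light + gas_mass)
  mu_h <- m_heavy * gas_mass / (m_heavy + gas_mass)
  sqrt(mu_h / mu_l) - 1
}
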