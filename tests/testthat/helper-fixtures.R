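# In-code fixtures shared across the test files.

# small hand-built monotone library: one class-adduct group of PCs with
# CCS = 200 + 2*carbons - 1*double_bonds, plus a TG isomer duo
toy_library_entries <- function() {
  pc <- expand.grid(carbons = c(30, 32, 34, 36), double_bonds = 0:2)
  pc <- data.frame(
    lipid_name = sprintf("PC %d:%d", pc$carbons, pc$double_bonds),
    lipid_class = "PC", carbons = pc$carbons,
    double_bonds = pc$double_bonds, isomer = NA_integer_,
    adduct = "[M+H]+", polarity = "positive", label = "U13C",
    mz_theoretical = 700 + 14 * (pc$carbons - 30) - 2 * pc$double_bonds,
    dtccs_n2 = 200 + 2 * pc$carbons - 1 * pc$double_bonds,
    ccs_rsd_pct = 0.3, n_detections = 3, stringsAsFactors = FALSE)
  tg <- data.frame(
    lipid_name = c("TG 48:2 (1)", "TG 48:2 (2)"),
    lipid_class = "TG", carbons = 48, double_bonds = 2, isomer = 1:2,
    adduct = "[M+NH4]+", polarity = "positive", label = "U13C",
    mz_theoretical = c(820.7, 820.7), dtccs_n2 = c(300.1, 301.4),
    ccs_rsd_pct = 0.2, n_detections = 2, stringsAsFactors = FALSE)
  rbind(pc, tg)
}

toy_library <- function() ccs_library(toy_library_entries(), "toy")

# measured table derived from a library by an affine map plus optional noise
measured_from_library <- function(lib, slope = 1, intercept = 0,
                                  noise_sd = 0, label = "U13C",
                                  file_id = "f1", seed = NULL) {
  e <- lib$entries
  ccs <- (e$dtccs_n2 - intercept) / slope
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ccs <- ccs * (1 + rnorm(length(ccs), 0, noise_sd / 100))
  }
  data.frame(file_id = file_id, lipid_name = e$lipid_name,
             adduct = e$adduct, polarity = e$polarity, label = label,
             mz_measured = e$mz_theoretical, rt_min = 5,
             ccs_measured = ccs, stringsAsFactors = FALSE)
}

# observation-table builder for curation tests
obs_rows <- function(name, adduct, ccs, dilutions = 1:3, rt = 5,
                     mz_theoretical = 700, mz_measured = mz_theoretical) {
  n <- length(dilutions)
  data.frame(file_id = sprintf("run%d", dilutions),
             dilution_id = sprintf("D%d", dilutions),
             lipid_name = name, adduct = adduct,
             polarity = adduct_polarity(adduct), label = "U13C",
             mz_measured = rep_len(mz_measured, n),
             mz_theoretical = mz_theoretical,
             rt_min = rep_len(rt, n), ccs = rep_len(ccs, n),
             stringsAsFactors = FALSE)
}

# independent OLS oracle: closed-form normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- n * sum(x^2) - sum(x)^2
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / sxx
  intercept <- (sum(y) - slope * sum(x)) / n
  c(slope = slope, intercept = intercept)
}
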