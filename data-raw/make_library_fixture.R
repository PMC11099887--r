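# Builds inst/extdata/u13c_dtccs_library_synthetic.csv: a fully synthetic
# stand-in reference library for uniformly 13C-labeled yeast lipids. The
# composition is fixed by design (377 entries, 162 species, 15 classes, 5
# adduct types; m/z 318.3501-966.9794; CCS 189.4-327.1 A^2; 10 classes with
# >= 3 species in at least one adduct) and the values follow a class-wise
# monotone ECN model. Deterministic; run from the package root:
#   Rscript data-raw/make_library_fixture.R

ADDUCTS <- data.frame(
  adduct = c("[M+H]+", "[M+NH4]+", "[M+Na]+", "[M-H]-", "[M+HCOO]-"),
  polarity = c("positive", "positive", "positive", "negative", "negative"),
  mass_delta = c(1.007276, 18.033823, 22.989218, -1.007276, 44.998201),
  stringsAsFactors = FALSE)
C13 <- 1.0033548
ADDUCT_CCS <- c("[M+H]+" = 0, "[M+NH4]+" = 2, "[M+Na]+" = 1,
                "[M-H]-" = -1.5, "[M+HCOO]-" = 3.5)

# per-class parameters: unlabeled neutral-mass anchor at (anchor_carbons,
# anchor_db), headgroup carbons (for the uniform-13C shift), and raw ECN
# coefficients for CCS
P <- list(
  #        anchor     aC aDB head  base  inc  dec
  PC     = c(757.5622, 34, 2, 8, 214.2, 2.0, 1.1),
  PE     = c(715.5152, 34, 2, 5, 208.0, 2.0, 1.1),
  TG     = c(858.7464, 52, 2, 3, 208.0, 2.2, 1.0),
  DG     = c(592.5067, 34, 2, 3, 210.0, 1.9, 1.0),
  Cer    = c(565.5434, 36, 1, 0, 212.0, 2.05, 0.9),
  HexCer = c(787.6534, 40, 1, 6, 220.0, 2.0, 0.9),
  LPC    = c(495.3325, 16, 0, 8, 196.0, 2.1, 1.0),
  PA     = c(672.4730, 34, 2, 3, 204.0, 2.0, 1.1),
  PI     = c(834.5258, 34, 2, 9, 209.0, 2.0, 1.1),
  PS     = c(759.5051, 34, 2, 6, 207.0, 2.0, 1.1),
  AcCa   = c(399.3349, 16, 0, 7, 202.0, 2.1, 0.9),
  Co     = c(794.6213, 54, 10, 0, 239.0, 1.5, 1.0),
  LPE    = c(479.3012, 18, 1, 5, 188.0, 2.1, 1.0),
  PG     = c(748.5254, 34, 1, 6, 206.0, 2.0, 1.1),
  SPH    = c(299.2824, 18, 1, 0, 152.0, 2.1, 0.8))

grid <- function(cls, carbons, db, isomer = NA_integer_)
  expand.grid(lipid_class = cls, carbons = carbons, double_bonds = db,
              isomer = isomer, stringsAsFactors = FALSE)

species <- rbind(
  grid("PC", c(30, 32, 34, 36, 38), 0:4),
  grid("PE", c(32, 34, 36, 38), 0:4), grid("PE", 30, 0:1),
  grid("TG", c(42, 44, 46, 48, 50, 52), 0:3)[
    !(rep(c(42, 44, 46, 48, 50, 52), 4) == 48 &
        rep(0:3, each = 6) == 2) &
    !(rep(c(42, 44, 46, 48, 50, 52), 4) == 50 &
        rep(0:3, each = 6) == 3), ],
  grid("TG", 48, 2, 1), grid("TG", 48, 2, 2),
  grid("TG", 50, 3, 1), grid("TG", 50, 3, 2),
  grid("TG", 40, 0:2), grid("TG", 54, 1),
  grid("DG", c(32, 34, 36), 0:3),
  grid("Cer", c(34, 36, 40, 42), 1:3),
  grid("HexCer", c(34, 40, 42, 44), 1:2),
  grid("LPC", 16:18, 0:1),
  grid("PA", c(32, 34, 36), 0:3),
  grid("PI", c(32, 34, 36), 0:3), grid("PI", 38, 2:3),
  grid("PS", c(34, 36, 38), 0:3),
  grid("AcCa", 16, 0), grid("AcCa", 18, 1),
  grid("Co", 54, 10),
  grid("LPE", 18, 0:1),
  grid("PG", 34, 1), grid("PG", 36, 2),
  grid("SPH", 18, 0:1))

class_adducts <- list(
  PC = c("[M+H]+", "[M+Na]+", "[M+HCOO]-"),
  PE = c("[M+H]+", "[M+Na]+", "[M-H]-"),
  TG = c("[M+NH4]+", "[M+Na]+"),
  DG = c("[M+NH4]+", "[M+Na]+"),
  Cer = c("[M+H]+", "[M+HCOO]-"),
  HexCer = c("[M+H]+", "[M+HCOO]-"),
  LPC = c("[M+H]+", "[M+Na]+", "[M+HCOO]-"),
  PA = c("[M-H]-", "[M+Na]+"),
  PI = c("[M-H]-", "[M+NH4]+"),
  PS = c("[M-H]-", "[M+H]+"),
  AcCa = c("[M+H]+", "[M+Na]+"),
  Co = c("[M+H]+", "[M+NH4]+"),
  LPE = c("[M+H]+", "[M-H]-"),
  PG = c("[M-H]-", "[M+NH4]+"),
  SPH = c("[M+H]+", "[M+Na]+"))

rows <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
  s <- species[i, ]
  cbind(s[rep(1, length(class_adducts[[s$lipid_class]])), ],
        adduct = class_adducts[[s$lipid_class]], stringsAsFactors = FALSE)
}))
rownames(rows) <- NULL

p <- do.call(rbind, P)[rows$lipid_class, ]
neutral_labeled <- p[, 1] + 14.01565 * (rows$carbons - p[, 2]) -
  2.01565 * (rows$double_bonds - p[, 3]) + C13 * (rows$carbons + p[, 4])
# pinned heaviest species: TG 54:1 with [M+Na]+ at the library maximum m/z
neutral_labeled[rows$lipid_class == "TG" & rows$carbons == 54] <-
  966.9794 - 22.989218
ai <- match(rows$adduct, ADDUCTS$adduct)
mz <- neutral_labeled + ADDUCTS$mass_delta[ai]

ccs_raw <- p[, 5] + p[, 6] * rows$carbons - p[, 7] * rows$double_bonds +
  unname(ADDUCT_CCS[rows$adduct]) +
  ifelse(!is.na(rows$isomer) & rows$isomer == 2, 0.6, 0)
scale <- (327.1 - 189.4) / diff(range(ccs_raw))
ccs <- 189.4 + (ccs_raw - min(ccs_raw)) * scale

name <- sprintf("%s %d:%d", rows$lipid_class, rows$carbons,
                rows$double_bonds)
name <- ifelse(is.na(rows$isomer), name,
               sprintf("%s (%d)", name, rows$isomer))

i <- seq_len(nrow(rows))
out <- data.frame(
  lipid_name = name, lipid_class = rows$lipid_class,
  carbons = rows$carbons, double_bonds = rows$double_bonds,
  isomer = rows$isomer, adduct = rows$adduct,
  polarity = ADDUCTS$polarity[ai], label = "U13C",
  mz_theoretical = sprintf("%.4f", mz),
  dtccs_n2 = sprintf("%.1f", ccs),
  ccs_rsd_pct = sprintf("%.2f", 0.1 + 0.8 * ((i * 37) %% 97) / 97),
  n_detections = 2L + (i %% 4L),
  stringsAsFactors = FALSE)
out <- out[order(out$lipid_class, out$carbons, out$double_bonds,
                 out$lipid_name, out$adduct), ]

# composition checks
stopifnot(nrow(out) == 377,
          length(unique(out$lipid_name)) == 162,
          length(unique(out$lipid_class)) == 15,
          length(unique(out$adduct)) == 5,
          !anyDuplicated(paste(out$lipid_name, out$adduct)),
          min(as.numeric(out$mz_theoretical)) == 318.3501,
          max(as.numeric(out$mz_theoretical)) == 966.9794,
          min(as.numeric(out$dtccs_n2)) == 189.4,
          max(as.numeric(out$dtccs_n2)) == 327.1)
# classes with >= 3 species sharing an adduct must be exactly the 10
# covered by the correction procedure
tab <- table(out$lipid_class, out$adduct)
eligible <- sort(rownames(tab)[apply(tab >= 3, 1, any)])
stopifnot(identical(eligible, sort(c("Cer", "DG", "HexCer", "LPC", "PA",
                                     "PC", "PE", "PI", "PS", "TG"))))
# ECN monotonicity within every class-adduct group
for (key in unique(paste(out$lipid_class, out$adduct, sep = "\r"))) {
  g <- out[paste(out$lipid_class, out$adduct, sep = "\r") == key, ]
  g$ccs <- as.numeric(g$dtccs_n2)
  for (a in seq_len(nrow(g))) for (b in seq_len(nrow(g))) {
    if (a == b) next
    if (g$double_bonds[a] == g$double_bonds[b] &&
        g$carbons[a] < g$carbons[b])
      stopifnot(g$ccs[a] < g$ccs[b])
    if (g$carbons[a] == g$carbons[b] &&
        g$double_bonds[a] < g$double_bonds[b])
      stopifnot(g$ccs[a] > g$ccs[b])
  }
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.csv(out, "inst/extdata/u13c_dtccs_library_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("wrote", nrow(out), "entries\n")
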