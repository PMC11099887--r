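# The command-line script (exec/lipidccs) is a thin wrapper over these
# runner functions; the workflow behavior is tested here directly.

local_sim_files <- function(seed = 21, ...) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_ccs_dataset(sim_config(seed = seed, ...))
  write_sim_dataset(sim, d)
  list(dir = d, sim = sim,
       library = file.path(d, "library.csv"),
       observations = file.path(d, "observations.csv"),
       measured = file.path(d, "measured.csv"))
}

test_that("run_monitor writes summaries that match brute-force recomputation", {
  fx <- local_sim_files()
  out <- file.path(fx$dir, "mon")
  cfg <- run_config(library = fx$library, measured = fx$measured, out = out,
                    seed = 21)
  res <- run_monitor(cfg)
  expect_true(all(file.exists(file.path(out, c("matched_pairs.csv",
                                               "unmatched.csv",
                                               "bias_summary.csv")))))
  written <- read.csv(file.path(out, "bias_summary.csv"), comment.char = "#")
  expect_equal(nrow(written), nrow(res$summary))
  k <- which(written$lipid_class == "PC" & written$adduct == "[M+H]+")
  b <- res$pairs$bias_pct[res$pairs$lipid_class == "PC" &
                            res$pairs$adduct == "[M+H]+"]
  expect_equal(written$mean_bias[k], mean(b), tolerance = 1e-8)
  expect_equal(written$n[k], length(b))
})

test_that("empty measured input warns and writes empty outputs", {
  fx <- local_sim_files()
  empty <- read_measured(fx$measured)[0, ]
  out <- file.path(fx$dir, "empty")
  cfg <- run_config(library = fx$library, measured = empty, out = out)
  expect_warning(run_monitor(cfg), "no measured ion")
  expect_equal(nrow(read.csv(file.path(out, "matched_pairs.csv"),
                             comment.char = "#")), 0)
})

test_that("run_correct covers all simulated classes and approaches zero bias", {
  fx <- local_sim_files(seed = 22)
  out <- file.path(fx$dir, "cor")
  cfg <- run_config(library = fx$library, measured = fx$measured, out = out,
                    seed = 22)
  res <- run_correct(cfg)
  expect_equal(sort(unique(res$summary$lipid_class)),
               sort(unique(fx$sim$truth$ions$lipid_class)))
  expect_lt(mean(abs(res$summary$mean_bias_after)),
            mean(abs(res$summary$mean_bias_before)))
  expect_lt(mean(res$summary$mean_abs_bias_after), 0.12)
  # corrected table includes unlabeled lipids of covered groups
  expect_setequal(unique(res$corrected$label), c("U13C", "12C"))
  expect_true(all(file.exists(file.path(out, c(
    "correction_functions.csv", "corrected_ccs.csv",
    "corrected_ccs_ensemble.csv", "bias_before_after.csv",
    "per_function_bias.csv")))))
})

test_that("a group of exactly three standards yields a single function", {
  fx <- local_sim_files(seed = 23, classes = "PC", n_per_group = 3)
  out <- file.path(fx$dir, "one")
  cfg <- run_config(library = fx$library, measured = fx$measured, out = out,
                    seed = 23)
  res <- run_correct(cfg)
  fns <- coef(res$model)
  expect_equal(as.vector(table(paste(fns$lipid_class, fns$adduct))),
               rep(1L, 3))
})

test_that("a planted outlier standard flags the subsets containing it", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 1.0, intercept = 0)
  # one badly measured standard drags its subsets' fits off slope 1
  bad <- meas$lipid_name == "PC 36:2"
  meas$ccs_measured[bad] <- meas$ccs_measured[bad] * 1.2
  model <- fit_ccs_correction(match_to_library(meas, lib)$pairs, seed = 2)
  fns <- coef(model)
  has_outlier <- grepl("PC 36:2", fns$subset_ids, fixed = TRUE)
  expect_true(all(fns$flagged[has_outlier]))
  expect_false(any(fns$flagged[!has_outlier]))
})

test_that("eligibility failure raises its dedicated condition class", {
  lib <- toy_library()
  meas <- measured_from_library(lib)
  meas <- meas[meas$lipid_name %in% c("PC 30:0", "PC 32:0"), ]
  cfg <- run_config(library = lib, measured = meas, out = tempfile())
  expect_error(suppressWarnings(run_correct(cfg)),
               class = "lipidccs_eligibility_error")
})

test_that("schema failures raise their dedicated condition class", {
  cfg <- run_config(measured = tempfile(), out = tempfile())
  expect_error(run_monitor(cfg), class = "lipidccs_schema_error")
  bad <- data.frame(x = 1)
  cfg2 <- run_config(measured = bad, out = tempfile())
  expect_error(run_monitor(cfg2), class = "lipidccs_schema_error")
  expect_error(run_config(ppm_max = -5), "range")
})

test_that("per-file and mean modes coincide for single-file input", {
  fx <- local_sim_files(seed = 24, n_files = 1, classes = c("PC", "TG"))
  out1 <- file.path(fx$dir, "m1"); out2 <- file.path(fx$dir, "m2")
  r_mean <- run_correct(run_config(library = fx$library,
                                   measured = fx$measured, out = out1,
                                   seed = 24, mode = "mean"))
  r_file <- run_correct(run_config(library = fx$library,
                                   measured = fx$measured, out = out2,
                                   seed = 24, mode = "per_file"))
  f1 <- coef(r_mean$model); f2 <- coef(r_file$model)
  expect_equal(f1[, c("slope", "intercept", "r_squared")],
               f2[, c("slope", "intercept", "r_squared")])
  expect_equal(sort(r_mean$corrected$ccs_corrected),
               sort(r_file$corrected$ccs_corrected))
})

test_that("run_curate on simulated violations reproduces the truth labels", {
  fx <- local_sim_files(seed = 25,
                        violations = list(high_ppm = 2, single_dilution = 1,
                                          non_coeluting = 1, high_rsd = 1))
  out <- file.path(fx$dir, "cur")
  cfg <- run_config(observations = fx$observations, out = out, seed = 25)
  res <- run_curate(cfg)
  truth <- fx$sim$truth$violations
  expect_equal(nrow(res$rejections), nrow(truth))
  expect_equal(res$summary$n_entries, nrow(fx$sim$truth$ions))
  expect_equal(nrow(res$ecn_violations), 0)
  expect_true(all(file.exists(file.path(out, c(
    "curated_library.csv", "rejections.csv", "ecn_violations.csv",
    "library_summary.csv")))))
  # rerunning on the curated library's observations leaves it unchanged
  obs <- read.csv(fx$observations, comment.char = "#")
  kept <- paste(obs$lipid_name, obs$adduct) %in%
    paste(res$library$entries$lipid_name, res$library$entries$adduct)
  res2 <- curate_library(obs[kept, ])
  expect_equal(res2$library$entries, res$library$entries, tolerance = 1e-8)
})

test_that("outputs carry a reproducibility header with version and seed", {
  fx <- local_sim_files(seed = 26, classes = "PC")
  out <- file.path(fx$dir, "hdr")
  cfg <- run_config(library = fx$library, measured = fx$measured, out = out,
                    seed = 26)
  run_monitor(cfg)
  head3 <- readLines(file.path(out, "bias_summary.csv"), n = 3)
  expect_match(head3[1], "^# lipidccs ")
  expect_match(head3[2], "^# config_hash: [0-9a-f]+$")
  expect_match(head3[3], "^# seed: 26$")
  # identical config -> identical header; different seed -> different header
  cfg2 <- run_config(library = fx$library, measured = fx$measured,
                     out = file.path(fx$dir, "hdr2"), seed = 27)
  run_monitor(cfg2)
  expect_false(identical(head3[3],
                         readLines(file.path(fx$dir, "hdr2",
                                             "bias_summary.csv"), n = 3)[3]))
})

test_that("YAML configuration files round-trip through read_run_config", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 11", "ppm_max: 4", "mode: per_file",
               "out: somewhere"), p)
  cfg <- read_run_config(p)
  expect_equal(cfg$seed, 11L)
  expect_equal(cfg$ppm_max, 4)
  expect_equal(cfg$mode, "per_file")
  writeLines(c("seed: 1", "bogus_key: 2"), p)
  expect_error(read_run_config(p), "unknown configuration key",
               class = "lipidccs_schema_error")
})
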