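test_that("group eligibility requires three labeled standards", {
  lib <- toy_library()
  pairs <- match_to_library(measured_from_library(lib), lib)$pairs
  g <- eligible_groups(pairs)
  # 12 PC standards qualify; the 2-isomer TG group does not
  expect_equal(g$lipid_class, "PC")
  expect_equal(g$n_available, 12)
  expect_equal(nrow(eligible_groups(pairs[pairs$lipid_class == "TG", ])), 0)
  g3 <- eligible_groups(pairs[pairs$lipid_name %in%
                                c("PC 30:0", "PC 32:0", "PC 34:0"), ])
  expect_equal(g3$n_available, 3)
  expect_equal(nrow(eligible_groups(pairs[0, ])), 0)
})

test_that("subset ensembles have the exact combinatorial size", {
  expect_equal(length(enumerate_subsets(letters[1:3])), 1)
  expect_equal(enumerate_subsets(letters[1:3])[[1]], c("a", "b", "c"))
  expect_equal(length(enumerate_subsets(letters[1:6])), 42)
  expect_equal(length(enumerate_subsets(letters[1:10])), 100)
  # ensemble size = min(cap, sum_k C(n, k)) for a spread of n
  for (n in c(3, 4, 5, 6, 7, 8, 12)) {
    total <- sum(choose(n, 3:min(6, n)))
    expect_equal(length(enumerate_subsets(seq_len(n), cap = 100)),
                 min(100, total))
  }
  expect_error(enumerate_subsets(letters[1:2]),
               class = "lipidccs_eligibility_error")
})

test_that("sampled subsets are distinct, size-bounded and seed-deterministic", {
  ids <- sprintf("L%02d", 1:10)  # 792 candidate subsets, capped at 100
  s1 <- enumerate_subsets(ids, seed = 5)
  s2 <- enumerate_subsets(ids, seed = 5)
  expect_identical(s1, s2)
  sizes <- lengths(s1)
  expect_true(all(sizes >= 3 & sizes <= 6))
  keys <- vapply(s1, paste, "", collapse = "|")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(unlist(s1) %in% ids))
  # a different seed gives a different draw
  s3 <- enumerate_subsets(ids, seed = 6)
  expect_false(identical(vapply(s3, paste, "", collapse = "|"), keys))
  # small-n enumeration covers every subset exactly once
  all4 <- enumerate_subsets(letters[1:4])
  expect_equal(length(all4), choose(4, 3) + 1)
})

test_that("an exact affine relationship is recovered perfectly", {
  pts <- data.frame(lipid_name = c("PC 30:0", "PC 32:0", "PC 34:0"),
                    ccs_measured = c(250, 255, 262),
                    dtccs_n2 = 1.02 * c(250, 255, 262) - 3)
  fit <- fit_correction(pts)
  expect_equal(fit$slope, 1.02, tolerance = 1e-12)
  expect_equal(fit$intercept, -3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$n_points, 3)
})

test_that("degenerate and out-of-range subsets are rejected", {
  pts <- data.frame(lipid_name = sprintf("PC %d:0", c(30, 32, 34)),
                    ccs_measured = c(250, 250, 250),
                    dtccs_n2 = c(251, 252, 253))
  expect_error(fit_correction(pts), class = "lipidccs_degenerate_fit")
  expect_error(fit_correction(pts[1:2, ]), "between")
  expect_error(fit_correction(pts[rep(1, 7), ]), "between")
})

test_that("fitted coefficients match the normal-equations oracle", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(3:6, 1)
    x <- 200 + runif(n, 0, 100)
    y <- runif(1, 0.9, 1.1) * x + runif(1, -5, 5) + rnorm(n, 0, 0.5)
    pts <- data.frame(lipid_name = sprintf("PC %d:0", seq_len(n) * 2 + 28),
                      ccs_measured = x, dtccs_n2 = y)
    fit <- fit_correction(pts)
    oracle <- ols_oracle(x, y)
    expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-9)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-9)
  }
})

test_that("applying a function is a plug-in affine map", {
  ident <- list(slope = 1, intercept = 0)
  expect_equal(apply_correction(ident, c(200, 250.5)), c(200, 250.5))
  expect_equal(apply_correction(list(slope = 1.02, intercept = -3), 250), 252)
  # positive slope preserves the CCS ordering of any two ions
  fn <- list(slope = 1.07, intercept = -12)
  x <- runif(50, 150, 350)
  expect_equal(order(apply_correction(fn, x)), order(x))
  expect_error(apply_correction(ident, -1), "positive")
})

test_that("the quality rule flags the poor-slope functions", {
  fns <- data.frame(slope = c(2.42, 0.46, 0.01, 1.00, 1.19),
                    r_squared = c(1, 1, 1, 1, 0.995),
                    flagged = FALSE)
  out <- flag_poor_functions(fns)
  expect_equal(out$flagged, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # r-squared alone can flag
  out2 <- flag_poor_functions(data.frame(slope = 1, r_squared = 0.9,
                                         flagged = FALSE))
  expect_true(out2$flagged)
})

test_that("ensembles on exact affine groups give identically zero bias", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 1.01, intercept = -2)
  pairs <- match_to_library(meas, lib)$pairs
  model <- fit_ccs_correction(pairs, seed = 3)
  fns <- coef(model)
  expect_true(all(abs(fns$slope - 1.01) < 1e-9))
  expect_true(all(abs(fns$intercept - (-2)) < 1e-9))
  expect_true(all(abs(model$after$bias_after) < 1e-9))
  expect_false(any(fns$flagged))
  # identity data with identity fits: before = after = 0
  ident <- fit_ccs_correction(match_to_library(measured_from_library(lib),
                                               lib)$pairs, seed = 3)
  expect_true(all(abs(ident$points$bias_before) < 1e-12))
  expect_true(all(abs(ident$after$bias_after) < 1e-9))
})

test_that("mean signed fitting residual of every function is zero", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 0.99, intercept = 1,
                                noise_sd = 0.3, seed = 13)
  model <- fit_ccs_correction(match_to_library(meas, lib)$pairs, seed = 13)
  r <- residuals(model)
  by_fn <- tapply(r$residual, r$function_index, mean)
  expect_true(all(abs(by_fn) < 1e-9))
})

test_that("ensemble coefficients are unbiased on noisy synthetic groups", {
  # reference = s * measured + b + noise: the model the fit assumes, under
  # which OLS coefficients are exactly unbiased
  set.seed(29)
  e <- toy_library_entries()[1:12, ]
  true_s <- 1.03; true_b <- -4
  slopes <- numeric(); ints <- numeric()
  for (r in 1:40) {
    x <- e$dtccs_n2
    pairs <- data.frame(
      file_id = "f1", lipid_name = e$lipid_name, adduct = e$adduct,
      polarity = e$polarity, label = "U13C",
      mz_measured = e$mz_theoretical, rt_min = 5, ccs_measured = x,
      lipid_class = e$lipid_class, carbons = e$carbons,
      double_bonds = e$double_bonds, isomer = e$isomer,
      mz_theoretical = e$mz_theoretical,
      dtccs_n2 = true_s * x + true_b + rnorm(12, 0, 0.002 * x),
      stringsAsFactors = FALSE)
    pairs$bias_pct <- ccs_bias_percent(pairs$ccs_measured, pairs$dtccs_n2)
    model <- fit_ccs_correction(pairs, seed = r, r2_min = 0)
    fns <- coef(model)
    slopes <- c(slopes, mean(fns$slope)); ints <- c(ints, mean(fns$intercept))
  }
  expect_lt(abs(mean(slopes) - true_s), 2 * sd(slopes) / sqrt(length(slopes)))
  expect_lt(abs(mean(ints) - true_b), 2 * sd(ints) / sqrt(length(ints)))
})

test_that("predictor-side noise attenuates slopes by the dilution factor", {
  # when the 0.2% noise sits on the measured (predictor) side, OLS slopes
  # shrink by about Var(x)/(Var(x) + sigma^2) — regression dilution; the
  # effect at this noise level is small but systematic
  set.seed(31)
  lib <- toy_library()
  slopes <- numeric()
  true_s <- 1.03; true_b <- -4
  for (r in 1:30) {
    meas <- measured_from_library(lib, slope = true_s, intercept = true_b,
                                  noise_sd = 0.2)
    fns <- coef(fit_ccs_correction(match_to_library(meas, lib)$pairs,
                                   seed = r, r2_min = 0))
    slopes <- c(slopes, mean(fns$slope))
  }
  # dilution factor from the design: true predictor values and noise scale
  x_true <- (toy_library_entries()$dtccs_n2[1:12] - true_b) / true_s
  lambda <- var(x_true) / (var(x_true) + mean(0.002 * x_true)^2)
  expect_lt(mean(slopes), true_s)           # attenuation is toward zero
  expect_equal(mean(slopes), true_s * lambda, tolerance = 0.01)
})

test_that("after-bias stays within the noise-derived standard-error bound", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 1.01, intercept = -2,
                                noise_sd = 0.2, seed = 17)
  model <- fit_ccs_correction(match_to_library(meas, lib)$pairs, seed = 17,
                              r2_min = 0)
  s <- summary(model)
  pf <- s$per_function
  # |mean after-bias| of each function stays within ~3 SE of the 0.2% noise
  expect_true(all(abs(pf$mean_bias_after) <= 3 * 0.2 / sqrt(12) + 0.1))
})

test_that("prediction returns medians over non-flagged functions", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 1.02, intercept = -3)
  model <- fit_ccs_correction(match_to_library(meas, lib)$pairs, seed = 1)
  nd <- data.frame(lipid_class = c("PC", "TG"), adduct = c("[M+H]+", "[M+NH4]+"),
                   ccs_measured = c(250, 300))
  p <- predict(model, nd)
  expect_equal(p[1], 1.02 * 250 - 3, tolerance = 1e-9)
  expect_true(is.na(p[2]))  # TG group was not eligible
  ens <- predict(model, nd, ensemble = TRUE)
  expect_equal(unique(ens$lipid_class), "PC")
  expect_equal(nrow(ens), nrow(coef(model)))
  # hand-check the median against the function table
  fns <- coef(model)
  expect_equal(p[1], median(fns$slope * 250 + fns$intercept))
})

test_that("refitting with identical inputs and seed reproduces the model", {
  lib <- toy_library()
  meas <- measured_from_library(lib, slope = 0.995, intercept = 2,
                                noise_sd = 0.2, seed = 23)
  pairs <- match_to_library(meas, lib)$pairs
  m1 <- fit_ccs_correction(pairs, seed = 9)
  m2 <- fit_ccs_correction(pairs, seed = 9)
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$after, m2$after)
})
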