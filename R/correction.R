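# Lipid class- and adduct-specific linear CCS correction ensembles.
#
# The model: for each lipid class-adduct combination with at least three
# labeled internal standards, up to `cap` distinct subsets of 3-6 standards
# are drawn and an ordinary least-squares line
#     reference CCS = slope * measured CCS + intercept
# is fitted per subset. Correction of any lipid in the group (labeled or
# not) is a direct plug-in of its measured CCS into each non-flagged
# function; the point estimate is the median across functions.

.degenerate_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lipidccs_degenerate_fit", "error")))
}

.eligibility_stop <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lipidccs_eligibility_error", "error")))
}

#' Class-adduct groups eligible for correction
#'
#' A group qualifies when at least `min_lipids` distinct labeled lipid
#' species are matched to the library for that class-adduct combination.
#'
#' @param pairs Matched pairs from [match_to_library()].
#' @param min_lipids Minimum number of labeled standards (default 3).
#' @return Data frame `lipid_class, adduct, polarity, n_available`, one row
#'   per eligible group.
#' @export
eligible_groups <- function(pairs, min_lipids = 3) {
  empty <- data.frame(lipid_class = character(), adduct = character(),
                      polarity = character(), n_available = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(pairs) || !nrow(pairs)) return(empty)
  key <- paste(pairs$lipid_class, pairs$adduct, sep = "\r")
  idx <- split(seq_len(nrow(pairs)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(lipid_class = pairs$lipid_class[i[1]],
               adduct = pairs$adduct[i[1]],
               polarity = pairs$polarity[i[1]],
               n_available = length(unique(pairs$lipid_name[i])),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_available >= min_lipids, , drop = FALSE]
  out <- out[order(out$lipid_class, out$adduct), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# number of k-subsets of n for k in k_min..min(k_max, n)
.subset_counts <- function(n, k_min, k_max) {
  ks <- seq.int(k_min, min(k_max, n))
  stats::setNames(choose(n, ks), ks)
}

# lexicographic unranking of the rank-r (0-based) k-combination of 1..n
.unrank_combination <- function(r, n, k) {
  out <- integer(k)
  x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_ <- choose(n - x, k - i)
      if (r < c_) break
      r <- r - c_
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out
}

# run `expr` under a private RNG stream seeded with `seed`
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Enumerate or sample distinct standard subsets
#'
#' All subsets of `ids` with size between `k_min` and `min(k_max,
#' length(ids))` are eligible. When their total count is at most `cap`
#' every subset is returned (sizes ascending, lexicographic within size);
#' otherwise exactly `cap` subsets are drawn uniformly at random without
#' replacement from the pooled collection, deterministically for a fixed
#' `seed` (combinadic unranking of sampled ranks, so the full collection is
#' never materialized).
#'
#' @param ids Vector of at least 3 distinct identifiers.
#' @param k_min,k_max Subset size bounds (defaults 3 and 6).
#' @param cap Maximum ensemble size (default 100).
#' @param seed Integer seed for the subset draw.
#' @return List of subsets (vectors of elements of `ids`).
#' @export
#' @examples
#' length(enumerate_subsets(letters[1:6]))  # choose(6,3)+...+choose(6,6) = 42
enumerate_subsets <- function(ids, k_min = 3, k_max = 6, cap = 100, seed = 1) {
  ids <- sort(unique(as.character(ids)))
  n <- length(ids)
  if (n < k_min)
    .eligibility_stop("need at least ", k_min, " distinct ids, got ", n)
  counts <- .subset_counts(n, k_min, k_max)
  total <- sum(counts)
  ks <- as.integer(names(counts))
  if (total <= cap) {
    subs <- list()
    for (k in ks) {
      subs <- c(subs, utils::combn(ids, k, simplify = FALSE))
    }
    return(subs)
  }
  ranks <- sort(.with_seed(seed, sample.int(total, cap)))  # 1-based pooled ranks
  offsets <- cumsum(c(0, counts))
  lapply(ranks, function(r) {
    size_idx <- findInterval(r - 1L, offsets, rightmost.closed = FALSE)
    k <- ks[size_idx]
    local_rank <- (r - 1L) - offsets[size_idx]
    ids[.unrank_combination(local_rank, n, k)]
  })
}

#' Fit one linear correction function
#'
#' Ordinary least squares of the reference CCS (response) on the measured
#' CCS (predictor) over one subset of labeled standards, so that applying
#' the function is a direct plug-in of a measured value.
#'
#' @param subset_pairs Matched pairs (3-6 rows, one per standard) with
#'   columns `ccs_measured`, `dtccs_n2` and `lipid_name`.
#' @param k_min,k_max Allowed point-count bounds.
#' @return List with `slope`, `intercept`, `r_squared`, `n_points`,
#'   `subset_ids`.
#' @export
fit_correction <- function(subset_pairs, k_min = 3, k_max = 6) {
  n <- nrow(subset_pairs)
  if (is.null(n) || n < k_min || n > k_max)
    stop("subset must contain between ", k_min, " and ", k_max,
         " standards, got ", n, call. = FALSE)
  x <- subset_pairs$ccs_measured
  y <- subset_pairs$dtccs_n2
  if (diff(range(x)) == 0)
    .degenerate_stop("all measured CCS values identical; cannot fit")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), y)
  coefs <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
  list(slope = unname(coefs["slope"]),
       intercept = unname(coefs["intercept"]),
       r_squared = r2,
       n_points = n,
       subset_ids = sort(subset_pairs$lipid_name))
}

#' Apply a correction function to measured CCS values
#'
#' @param fn A fitted function (list or one-row data frame with `slope`
#'   and `intercept`).
#' @param ccs_measured Positive measured CCS value(s).
#' @return Corrected CCS, `slope * ccs_measured + intercept`.
#' @export
apply_correction <- function(fn, ccs_measured) {
  if (any(ccs_measured <= 0))
    stop("'ccs_measured' must be positive", call. = FALSE)
  fn$slope * ccs_measured + fn$intercept
}

#' Flag poorly behaved correction functions
#'
#' A function is flagged when its slope falls outside `slope_band` or its
#' r-squared is below `r2_min`. Flagged functions are excluded from point
#' estimates but retained in all reports.
#'
#' @param fns Function table (as in `coef()` of a fitted
#'   [fit_ccs_correction()] model).
#' @param slope_band Length-2 numeric interval (default `c(0.8, 1.2)`).
#' @param r2_min Minimum r-squared (default 0.99).
#' @return `fns` with its `flagged` column updated.
#' @export
flag_poor_functions <- function(fns, slope_band = c(0.8, 1.2),
                                r2_min = 0.99) {
  stopifnot(length(slope_band) == 2, slope_band[1] < slope_band[2])
  fns$flagged <- fns$slope < slope_band[1] | fns$slope > slope_band[2] |
    fns$r_squared < r2_min
  fns
}

#' Fit class- and adduct-specific CCS correction ensembles
#'
#' The central fitting function. For every eligible lipid class-adduct
#' group (>= `min_lipids` labeled standards matched to the reference
#' library) it draws up to `cap` distinct subsets of `k_min`-`k_max`
#' standards ([enumerate_subsets()]), fits one ordinary least-squares
#' correction line per subset ([fit_correction()]), flags poorly behaved
#' functions ([flag_poor_functions()]), and evaluates the percent CCS bias
#' of every standard before and after correction under every function.
#'
#' Fitting granularity: with `mode = "mean"` (default) measured CCS values
#' are first averaged across files per ion, mirroring a summary over an
#' experiment's files; `mode = "per_file"` fits on per-file values and
#' requires the input to contain a single `file_id` (run each file
#' separately for per-file ensembles).
#'
#' @param pairs Matched pairs from [match_to_library()].
#' @param min_lipids Minimum standards per group (default 3).
#' @param k_min,k_max Subset size bounds (defaults 3 and 6).
#' @param cap Maximum number of functions per group (default 100).
#' @param seed Integer seed for subset sampling (recorded in the object).
#' @param slope_band,r2_min Quality rule, see [flag_poor_functions()].
#' @param mode `"mean"` or `"per_file"`.
#' @return An object of class `ccs_correction` with components `functions`
#'   (one row per fitted function), `points` (the per-ion fitting points
#'   with before-correction bias), `after` (long table of per-standard,
#'   per-function after-correction biases), `groups`, and `settings`.
#'   Methods: [print][print.ccs_correction], [summary][summary.ccs_correction],
#'   [coef][coef.ccs_correction], [predict][predict.ccs_correction],
#'   [plot][plot.ccs_correction], [residuals][residuals.ccs_correction].
#' @export
fit_ccs_correction <- function(pairs, min_lipids = 3, k_min = 3, k_max = 6,
                               cap = 100, seed = 1,
                               slope_band = c(0.8, 1.2), r2_min = 0.99,
                               mode = c("mean", "per_file")) {
  mode <- match.arg(mode)
  if (is.null(pairs) || !nrow(pairs))
    .eligibility_stop("no matched pairs; nothing to fit")
  if (mode == "mean") {
    points <- .aggregate_pairs(pairs)
  } else {
    if (length(unique(pairs$file_id)) > 1)
      stop("mode 'per_file' expects a single file_id; ",
           "split the input by file and fit each separately", call. = FALSE)
    points <- pairs
  }
  points$bias_before <- ccs_bias_percent(points$ccs_measured, points$dtccs_n2)

  groups <- eligible_groups(points, min_lipids = min_lipids)
  if (!nrow(groups))
    .eligibility_stop("no lipid class-adduct group has >= ", min_lipids,
                      " labeled standards")

  fn_rows <- list()
  after_rows <- list()
  for (g in seq_len(nrow(groups))) {
    cls <- groups$lipid_class[g]
    add <- groups$adduct[g]
    gp <- points[points$lipid_class == cls & points$adduct == add, ,
                 drop = FALSE]
    subsets <- enumerate_subsets(unique(gp$lipid_name), k_min = k_min,
                                 k_max = k_max, cap = cap, seed = seed)
    for (f in seq_along(subsets)) {
      sp <- gp[gp$lipid_name %in% subsets[[f]], , drop = FALSE]
      fit <- fit_correction(sp, k_min = k_min, k_max = k_max)
      fn_rows[[length(fn_rows) + 1L]] <- data.frame(
        lipid_class = cls, adduct = add, function_index = f,
        n_points = fit$n_points,
        subset_ids = paste(fit$subset_ids, collapse = "; "),
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, flagged = FALSE,
        stringsAsFactors = FALSE)
      after_rows[[length(after_rows) + 1L]] <- data.frame(
        lipid_class = cls, adduct = add, function_index = f,
        lipid_name = gp$lipid_name,
        in_subset = gp$lipid_name %in% subsets[[f]],
        bias_after = ccs_bias_percent(apply_correction(fit, gp$ccs_measured),
                                      gp$dtccs_n2),
        stringsAsFactors = FALSE)
    }
  }
  fns <- flag_poor_functions(do.call(rbind, fn_rows),
                             slope_band = slope_band, r2_min = r2_min)
  rownames(fns) <- NULL
  after <- do.call(rbind, after_rows)
  rownames(after) <- NULL

  structure(list(
    functions = fns,
    points = points,
    after = after,
    groups = groups,
    settings = list(min_lipids = min_lipids, k_min = k_min, k_max = k_max,
                    cap = cap, seed = seed, slope_band = slope_band,
                    r2_min = r2_min, mode = mode)),
    class = "ccs_correction")
}

# mean measured CCS per ion across files (pairs variant of
# aggregate_measured; reference columns are constant within an ion)
.aggregate_pairs <- function(pairs) {
  key <- paste(pairs$lipid_name, pairs$adduct, sep = "\r")
  idx <- split(seq_len(nrow(pairs)), key)
  rows <- lapply(idx, function(i) {
    g <- pairs[i, ]
    g$ccs_measured[1] <- mean(g$ccs_measured)
    g$mz_measured[1] <- mean(g$mz_measured)
    g$rt_min[1] <- mean(g$rt_min)
    g$file_id[1] <- "<mean>"
    g[1, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lipid_class, out$adduct, out$lipid_name), ]
  rownames(out) <- NULL
  out
}

#' @export
print.ccs_correction <- function(x, ...) {
  cat("<ccs_correction> ", nrow(x$groups),
      " lipid class-adduct group(s), ", nrow(x$functions),
      " correction function(s), ", sum(x$functions$flagged), " flagged\n",
      sep = "")
  cat("subset sizes ", x$settings$k_min, "-", x$settings$k_max,
      ", cap ", x$settings$cap, ", seed ", x$settings$seed,
      ", mode '", x$settings$mode, "'\n", sep = "")
  invisible(x)
}

#' Coefficients of a fitted correction ensemble
#'
#' @param object A `ccs_correction` model.
#' @param ... Unused.
#' @return The function table: one row per correction function with group,
#'   `function_index`, subset members, `slope`, `intercept`, `r_squared`
#'   and `flagged`.
#' @export
coef.ccs_correction <- function(object, ...) object$functions

#' Per-standard, per-function bias distributions
#'
#' @param object A `ccs_correction` model.
#' @param fns Optionally re-flagged function table (defaults to the fitted
#'   one); used by [flag_poor_functions()] workflows.
#' @return Long data frame of after-correction biases (`bias_after`, %)
#'   per standard per function, with `in_subset` marking standards used in
#'   that function's fit.
#' @export
correction_bias_distribution <- function(object, fns = NULL) {
  stopifnot(inherits(object, "ccs_correction"))
  object$after
}

#' Summary of a fitted correction ensemble
#'
#' Per lipid class-adduct group: number of standards and functions, mean
#' signed and mean absolute percent bias before correction, and the same
#' after correction using the median corrected value across non-flagged
#' functions per standard (flagged functions are excluded from point
#' estimates but remain in `coef()` and the distributions).
#'
#' @param object A `ccs_correction` model.
#' @param ... Unused.
#' @return An object of class `summary.ccs_correction` wrapping the group
#'   table (`$groups`) and the per-function mean after-bias table
#'   (`$per_function`).
#' @export
summary.ccs_correction <- function(object, ...) {
  fns <- object$functions
  after <- object$after
  pts <- object$points

  per_function <- do.call(rbind, lapply(seq_len(nrow(fns)), function(i) {
    sel <- after$lipid_class == fns$lipid_class[i] &
      after$adduct == fns$adduct[i] &
      after$function_index == fns$function_index[i]
    data.frame(lipid_class = fns$lipid_class[i], adduct = fns$adduct[i],
               function_index = fns$function_index[i],
               flagged = fns$flagged[i],
               mean_bias_after = mean(after$bias_after[sel]),
               mean_abs_bias_after = mean(abs(after$bias_after[sel])),
               stringsAsFactors = FALSE)
  }))

  groups <- object$groups
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    cls <- groups$lipid_class[g]; add <- groups$adduct[g]
    before <- pts$bias_before[pts$lipid_class == cls & pts$adduct == add]
    est <- .point_estimates(object, cls, add)
    data.frame(lipid_class = cls, adduct = add,
               n_standards = groups$n_available[g],
               n_functions = sum(fns$lipid_class == cls & fns$adduct == add),
               n_flagged = sum(fns$flagged[fns$lipid_class == cls &
                                             fns$adduct == add]),
               mean_bias_before = mean(before),
               mean_abs_bias_before = mean(abs(before)),
               mean_bias_after = mean(est$bias_after),
               mean_abs_bias_after = mean(abs(est$bias_after)),
               stringsAsFactors = FALSE)
  })
  structure(list(groups = do.call(rbind, rows), per_function = per_function,
                 settings = object$settings),
            class = "summary.ccs_correction")
}

# median corrected value (and its bias) per standard across non-flagged
# functions of one group
.point_estimates <- function(object, cls, add) {
  fns <- object$functions
  keep <- !fns$flagged & fns$lipid_class == cls & fns$adduct == add
  fns <- fns[keep, , drop = FALSE]
  pts <- object$points
  pts <- pts[pts$lipid_class == cls & pts$adduct == add, , drop = FALSE]
  if (!nrow(fns)) {
    pts$ccs_corrected <- NA_real_
    pts$bias_after <- NA_real_
    return(pts)
  }
  corrected <- vapply(seq_len(nrow(pts)), function(i) {
    stats::median(fns$slope * pts$ccs_measured[i] + fns$intercept)
  }, 0)
  pts$ccs_corrected <- corrected
  pts$bias_after <- ccs_bias_percent(corrected, pts$dtccs_n2)
  pts
}

#' @export
print.summary.ccs_correction <- function(x, ...) {
  cat("CCS correction summary (bias in %, before -> after):\n")
  g <- x$groups
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-7s %-10s n=%2d fns=%3d (%d flagged)  mean |bias| %.3f -> %.3f\n",
                g$lipid_class[i], g$adduct[i], g$n_standards[i],
                g$n_functions[i], g$n_flagged[i],
                g$mean_abs_bias_before[i], g$mean_abs_bias_after[i]))
  }
  invisible(x)
}

#' Correct measured CCS values with a fitted ensemble
#'
#' Applies each group's non-flagged correction functions to new measured
#' CCS values. Correction applies to every lipid of a covered class-adduct
#' combination irrespective of its labeling status.
#'
#' @param object A `ccs_correction` model.
#' @param newdata Data frame with columns `lipid_class`, `adduct` and
#'   `ccs_measured` (e.g. a validated measured table augmented with
#'   `lipid_class`, or matched pairs).
#' @param ensemble Return the full per-function table instead of point
#'   estimates (default `FALSE`).
#' @param ... Unused.
#' @return With `ensemble = FALSE`, a numeric vector of corrected CCS
#'   point estimates (median over the group's non-flagged functions; `NA`
#'   for rows whose group has no usable function). With `ensemble = TRUE`,
#'   a long data frame `row, lipid_class, adduct, function_index,
#'   ccs_corrected`.
#' @export
predict.ccs_correction <- function(object, newdata, ensemble = FALSE, ...) {
  .check_columns(newdata, c("lipid_class", "adduct", "ccs_measured"),
                 "newdata")
  newdata$adduct <- .normalize_adduct(as.character(newdata$adduct))
  fns <- object$functions
  if (!ensemble) {
    vapply(seq_len(nrow(newdata)), function(i) {
      keep <- !fns$flagged & fns$lipid_class == newdata$lipid_class[i] &
        fns$adduct == newdata$adduct[i]
      if (!any(keep)) return(NA_real_)
      stats::median(fns$slope[keep] * newdata$ccs_measured[i] +
                      fns$intercept[keep])
    }, 0)
  } else {
    out <- lapply(seq_len(nrow(newdata)), function(i) {
      keep <- fns$lipid_class == newdata$lipid_class[i] &
        fns$adduct == newdata$adduct[i]
      if (!any(keep)) return(NULL)
      data.frame(row = i, lipid_class = newdata$lipid_class[i],
                 adduct = newdata$adduct[i],
                 function_index = fns$function_index[keep],
                 flagged = fns$flagged[keep],
                 ccs_corrected = fns$slope[keep] * newdata$ccs_measured[i] +
                   fns$intercept[keep],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
      out <- data.frame(row = integer(), lipid_class = character(),
                        adduct = character(), function_index = integer(),
                        flagged = logical(), ccs_corrected = numeric(),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  }
}

#' Fitting residuals of each correction function
#'
#' @param object A `ccs_correction` model.
#' @param ... Unused.
#' @return Long data frame of residuals (reference minus fitted CCS, in
#'   A^2) of each function over its own fitting subset; the mean residual
#'   per function is zero up to numerical tolerance (an OLS identity).
#' @export
residuals.ccs_correction <- function(object, ...) {
  fns <- object$functions
  after <- object$after
  pts <- object$points
  rows <- lapply(seq_len(nrow(fns)), function(i) {
    sub <- strsplit(fns$subset_ids[i], "; ", fixed = TRUE)[[1]]
    sp <- pts[pts$lipid_class == fns$lipid_class[i] &
                pts$adduct == fns$adduct[i] &
                pts$lipid_name %in% sub, , drop = FALSE]
    data.frame(lipid_class = fns$lipid_class[i], adduct = fns$adduct[i],
               function_index = fns$function_index[i],
               lipid_name = sp$lipid_name,
               residual = sp$dtccs_n2 -
                 (fns$slope[i] * sp$ccs_measured + fns$intercept[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot before/after bias distributions per group
#'
#' One panel per lipid class-adduct group: the before-correction biases of
#' the standards next to the distribution of after-correction biases over
#' all non-flagged functions.
#'
#' @param x A `ccs_correction` model.
#' @param max_groups Plot at most this many groups (default 6).
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.ccs_correction <- function(x, max_groups = 6, ...) {
  g <- x$groups
  n <- min(nrow(g), max_groups)
  old <- graphics::par(mfrow = c(ceiling(n / 2), min(n, 2)))
  on.exit(graphics::par(old))
  fns <- x$functions
  for (i in seq_len(n)) {
    cls <- g$lipid_class[i]; add <- g$adduct[i]
    before <- x$points$bias_before[x$points$lipid_class == cls &
                                     x$points$adduct == add]
    keep_f <- fns$function_index[!fns$flagged & fns$lipid_class == cls &
                                   fns$adduct == add]
    sel <- x$after$lipid_class == cls & x$after$adduct == add &
      x$after$function_index %in% keep_f
    graphics::boxplot(list(before = before, after = x$after$bias_after[sel]),
                      ylab = "CCS bias (%)", main = paste(cls, add), ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
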