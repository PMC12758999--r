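#' @title OSL dosimeter calibration
#' @description Optically stimulated luminescence dosimeters report raw
#'   photomultiplier counts; a modality-specific calibration converts counts
#'   to absorbed dose. The calibration factor (cGy per count) is the mean of
#'   per-point delivered-dose / mean-count ratios across the calibration
#'   exposures; count-to-dose conversion additionally applies multiplicative
#'   beam-quality, linearity, angle and fading corrections.
#' @name osl-calibration
NULL

.modalities <- c("planning_ct", "cbct", "rt")

#' Replicate statistics of repeated OSL readings
#'
#' @param counts numeric vector of positive replicate counts.
#' @return list with `mean`, `sd` (sample, n-1 denominator; 0 for a single
#'   reading) and `cv` (coefficient of variation, sd/mean).
#' @examples
#' replicate_stats(c(101, 99, 100))
#' @export
replicate_stats <- function(counts) {
  if (length(counts) == 0L) stop("no replicate counts supplied")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts <= 0)) stop("counts must be positive")
  m <- mean(counts)
  s <- if (length(counts) > 1L) stats::sd(counts) else 0
  list(mean = m, sd = s, cv = s / m)
}

#' A single calibration exposure
#'
#' @param delivered_dose_cgy delivered reference dose in cGy (> 0).
#' @param count_mean mean of the replicate counts (> 0).
#' @param count_sd sample standard deviation of the replicates (>= 0).
#' @param n_replicates number of replicate dosimeters read.
#' @return list of class `calibration_point`.
#' @export
calibration_point <- function(delivered_dose_cgy, count_mean, count_sd = 0,
                              n_replicates = 1L) {
  if (delivered_dose_cgy <= 0) stop("delivered dose must be positive")
  if (count_mean <= 0) stop("count mean must be positive")
  if (count_sd < 0) stop("count sd must be nonnegative")
  if (count_sd / count_mean >= 1)
    stop("replicate CV must be below 1; check the counts")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(
    list(delivered_dose_cgy = delivered_dose_cgy, count_mean = count_mean,
         count_sd = count_sd, n_replicates = as.integer(n_replicates)),
    class = "calibration_point"
  )
}

#' Multiplicative reading correction factors
#'
#' Beam-quality, linearity, angle and fading corrections applied on top of
#' the calibration factor; all default to 1.
#'
#' @param beam_quality,linearity,angle,fading positive scalars.
#' @return list of class `correction_factors`.
#' @export
correction_factors <- function(beam_quality = 1, linearity = 1, angle = 1,
                               fading = 1) {
  f <- c(beam_quality = beam_quality, linearity = linearity,
         angle = angle, fading = fading)
  if (any(!is.finite(f)) || any(f <= 0))
    stop("all correction factors must be positive")
  structure(as.list(f), class = "correction_factors")
}

#' Build a modality-specific calibration curve
#'
#' The calibration factor is the mean over points of the delivered-dose /
#' mean-count ratio (`method = "ratio"`, the default). A least-squares
#' slope through the origin of dose on counts is available for comparison
#' (`method = "slope"`). The relative uncertainty of the factor is the
#' standard deviation of the per-point ratios divided by their mean
#' (0 for a single point).
#'
#' @param points list of [calibration_point]s (at least one).
#' @param modality `"planning_ct"`, `"cbct"` or `"rt"`.
#' @param corrections a [correction_factors].
#' @param method `"ratio"` or `"slope"`.
#' @return list of class `calibration_curve` with `factor_cgy_per_count`,
#'   `inverse_counts_per_cgy` (exact reciprocal), `factor_uncertainty`
#'   (relative), `corrections`, `modality`, `method` and the input `points`.
#' @examples
#' pt <- calibration_point(100, 1e6)
#' build_calibration(list(pt), "cbct")
#' @export
build_calibration <- function(points, modality = .modalities,
                              corrections = correction_factors(),
                              method = c("ratio", "slope")) {
  modality <- match.arg(modality)
  method <- match.arg(method)
  if (inherits(points, "calibration_point")) points <- list(points)
  if (length(points) == 0L) stop("at least one calibration point required")
  stopifnot(all(vapply(points, inherits, logical(1), "calibration_point")),
            inherits(corrections, "correction_factors"))
  doses <- vapply(points, `[[`, numeric(1), "delivered_dose_cgy")
  counts <- vapply(points, `[[`, numeric(1), "count_mean")
  ratios <- doses / counts
  factor <- switch(method,
    ratio = mean(ratios),
    slope = sum(doses * counts) / sum(counts^2)
  )
  rel_u <- if (length(ratios) > 1L) stats::sd(ratios) / mean(ratios) else 0
  structure(
    list(modality = modality, factor_cgy_per_count = factor,
         inverse_counts_per_cgy = 1 / factor,
         corrections = corrections, factor_uncertainty = rel_u,
         method = method, points = points),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve [%s, %s]: %.6g cGy/count (%.6g counts/cGy), rel. u = %.3g, %d point(s)\n",
    x$modality, x$method, x$factor_cgy_per_count, x$inverse_counts_per_cgy,
    x$factor_uncertainty, length(x$points)))
  invisible(x)
}

#' A raw OSL reading
#'
#' @param raw_counts raw counts read from the dosimeter (>= background).
#' @param background_counts background counts (default 0).
#' @param modality the modality the dosimeter was exposed in.
#' @return list of class `osl_reading`.
#' @export
osl_reading <- function(raw_counts, background_counts = 0,
                        modality = .modalities) {
  modality <- match.arg(modality)
  if (background_counts < 0) stop("background counts must be nonnegative")
  if (raw_counts < background_counts)
    stop("raw counts must be at least the background counts")
  structure(list(raw_counts = raw_counts,
                 background_counts = background_counts,
                 modality = modality),
            class = "osl_reading")
}

#' Convert an OSL reading to absorbed dose
#'
#' dose(cGy) = (raw - background) * factor * beam_quality * linearity *
#' angle * fading. The reading's modality must match the curve's.
#'
#' @param reading an [osl_reading], or a plain numeric count value (taken as
#'   background-free counts in the curve's modality).
#' @param curve a [calibration_curve].
#' @return a [dose_value] in cGy.
#' @export
counts_to_dose <- function(reading, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.numeric(reading))
    reading <- osl_reading(reading, 0, curve$modality)
  stopifnot(inherits(reading, "osl_reading"))
  if (reading$modality != curve$modality)
    stop("configuration error: reading modality '", reading$modality,
         "' does not match curve modality '", curve$modality, "'")
  co <- curve$corrections
  net <- reading$raw_counts - reading$background_counts
  dose_cgy <- net * curve$factor_cgy_per_count *
    co$beam_quality * co$linearity * co$angle * co$fading
  dose_value(dose_cgy, "cGy")
}

#' Combine relative measurement uncertainties
#'
#' Quadrature combines component relative standard deviations as
#' `sqrt(sum s_k^2)`. The Monte-Carlo method perturbs each multiplicative
#' factor independently as `N(1, s_k)`, forms their product over `n` seeded
#' draws and reports the empirical relative standard deviation of the
#' product; for small components the two agree closely.
#'
#' @param components named numeric vector of relative standard deviations
#'   (>= 0), one per uncertainty source.
#' @param method `"quadrature"` or `"monte_carlo"`.
#' @param n number of Monte-Carlo draws.
#' @param seed RNG seed for the Monte-Carlo method (recorded in the output).
#' @return list of class `uncertainty_budget` with `components`, `method`,
#'   `combined_relative_sd` and (for Monte-Carlo) `n` and `seed`.
#' @examples
#' propagate_uncertainty(c(calibration = 0.03, reading = 0.04))
#' @export
propagate_uncertainty <- function(components,
                                  method = c("quadrature", "monte_carlo"),
                                  n = 1e5, seed = 20260101L) {
  method <- match.arg(method)
  if (length(components) == 0L) stop("no uncertainty components supplied")
  if (!is.numeric(components) || any(!is.finite(components)) ||
      any(components < 0))
    stop("relative standard deviations must be nonnegative numbers")
  if (is.null(names(components)))
    names(components) <- paste0("component_", seq_along(components))
  combined <- if (method == "quadrature") {
    sqrt(sum(components^2))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draws <- vapply(components, function(s) stats::rnorm(n, 1, s),
                    numeric(n))
    prod_draws <- apply(draws, 1L, prod)
    stats::sd(prod_draws) / mean(prod_draws)
  }
  structure(
    list(components = components, method = method,
         combined_relative_sd = combined,
         n = if (method == "monte_carlo") n else NA_integer_,
         seed = if (method == "monte_carlo") seed else NA_integer_),
    class = "uncertainty_budget"
  )
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget (%s): combined relative sd %.4g\n",
              x$method, x$combined_relative_sd))
  for (nm in names(x$components))
    cat(sprintf("  %-20s %.4g\n", nm, x$components[[nm]]))
  invisible(x)
}

#' Bleaching verification of dosimeters before reuse
#'
#' After optical bleaching a dosimeter should carry no residual signal; a
#' reading whose background-corrected counts exceed the threshold fails the
#' check (inclusive at the boundary: counts equal to the threshold pass).
#'
#' @param readings list of [osl_reading]s (or a numeric vector of net
#'   counts).
#' @param threshold_counts positive count threshold; see
#'   [zero_check_threshold()] to derive it from the reader sensitivity.
#' @return logical vector, `TRUE` where the reading passes.
#' @export
zero_check <- function(readings, threshold_counts) {
  if (threshold_counts <= 0) stop("threshold must be positive")
  net <- if (is.numeric(readings)) readings else
    vapply(readings, function(r) r$raw_counts - r$background_counts,
           numeric(1))
  net <= threshold_counts
}

#' Count threshold equivalent to the reader sensitivity
#'
#' Converts a dose sensitivity (default 0.7 mGy, the detection limit of the
#' reading system) through a calibration curve into the corresponding count
#' threshold for [zero_check()].
#'
#' @param curve a [calibration_curve].
#' @param sensitivity_mgy dose sensitivity in mGy.
#' @return count threshold (numeric).
#' @export
zero_check_threshold <- function(curve, sensitivity_mgy = 0.7) {
  stopifnot(inherits(curve, "calibration_curve"))
  sens_cgy <- dose_gy(sensitivity_mgy, "mGy") / .dose_units[["cGy"]]
  sens_cgy * curve$inverse_counts_per_cgy
}

#' Read calibration points from CSV
#'
#' Expects columns `modality,delivered_dose_cgy,count_mean,count_sd,
#' n_replicates`.
#'
#' @param path CSV file path.
#' @return named list (by modality) of lists of [calibration_point]s.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "delivered_dose_cgy", "count_mean", "count_sd",
            "n_replicates")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$modality), function(g) {
    lapply(seq_len(nrow(g)), function(i) {
      calibration_point(g$delivered_dose_cgy[i], g$count_mean[i],
                        g$count_sd[i], g$n_replicates[i])
    })
  })
}

#' Export / import a calibration curve as JSON
#'
#' @param curve a [calibration_curve].
#' @param path output (or input) JSON path.
#' @return `write_calibration_json()` returns `path` invisibly;
#'   `read_calibration_json()` returns a [calibration_curve].
#' @export
write_calibration_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(
    modality = curve$modality,
    method = curve$method,
    factor_cgy_per_count = curve$factor_cgy_per_count,
    inverse_counts_per_cgy = curve$inverse_counts_per_cgy,
    factor_uncertainty = curve$factor_uncertainty,
    corrections = unclass(curve$corrections),
    points = lapply(curve$points, unclass)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- lapply(obj$points, function(p) {
    calibration_point(p$delivered_dose_cgy, p$count_mean, p$count_sd,
                      p$n_replicates)
  })
  co <- do.call(correction_factors, obj$corrections)
  build_calibration(pts, modality = obj$modality, corrections = co,
                    method = obj$method)
}

# save/restore .Random.seed so seeded internals do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
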