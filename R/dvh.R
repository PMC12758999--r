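#' @title Dose-volume histograms
#' @description A DVH is stored as strictly increasing bin doses (Gy) with a
#'   volume fraction per bin, in either differential form (fraction of organ
#'   volume in each dose bin; fractions sum to 1) or cumulative form (fraction
#'   of volume receiving at least each bin dose; non-increasing, starting
#'   at 1). Bin doses of a differential DVH are bin-center doses; cumulative
#'   volumes use the inclusive "receiving >= dose" convention.
#' @name dvh
NULL

.dvh_sum_tol <- 1e-9

#' Construct a dose-volume histogram
#'
#' @param dose_gy strictly increasing numeric vector of bin doses in Gy.
#' @param volume volume fractions in \[0, 1\], one per bin.
#' @param organ organ label.
#' @param form `"differential"` or `"cumulative"`.
#' @return an object of class `dvh`.
#' @examples
#' dvh(c(10, 30), c(0.5, 0.5), organ = "heart")
#' @export
dvh <- function(dose_gy, volume, organ = NA_character_,
                form = c("differential", "cumulative")) {
  form <- match.arg(form)
  if (length(dose_gy) == 0L) stop("empty DVH: at least one bin required")
  if (length(dose_gy) != length(volume))
    stop("dose and volume vectors must have the same length")
  if (any(!is.finite(dose_gy)) || any(!is.finite(volume)))
    stop("DVH bins must be finite")
  if (any(dose_gy < 0)) stop("bin doses must be nonnegative")
  if (any(diff(dose_gy) <= 0)) stop("bin doses must be strictly increasing")
  if (any(volume < -.dvh_sum_tol) || any(volume > 1 + .dvh_sum_tol))
    stop("volume fractions must lie in [0, 1]")
  volume <- pmin(pmax(volume, 0), 1)
  if (form == "differential") {
    if (abs(sum(volume) - 1) > .dvh_sum_tol)
      stop("differential DVH volume fractions must sum to 1 (tolerance 1e-9)")
  } else {
    if (any(diff(volume) > .dvh_sum_tol))
      stop("cumulative DVH volume fractions must be non-increasing in dose")
    if (abs(volume[1L] - 1) > .dvh_sum_tol)
      stop("cumulative DVH must start at volume fraction 1")
  }
  structure(
    list(organ = as.character(organ), dose_gy = as.numeric(dose_gy),
         volume = as.numeric(volume), form = form),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("DVH (%s) organ=%s, %d bins, dose %.4g-%.4g Gy\n",
              x$form, x$organ, length(x$dose_gy),
              min(x$dose_gy), max(x$dose_gy)))
  invisible(x)
}

#' Convert a DVH between differential and cumulative form
#'
#' The conversion is lossless on the shared bin doses: the cumulative volume
#' at bin i is the sum of differential fractions at bins >= i, and the
#' inverse is the first difference. Converting to the form the DVH is
#' already in returns it unchanged.
#'
#' @param x a [dvh].
#' @param target_form `"differential"` or `"cumulative"`.
#' @return a [dvh] in the requested form.
#' @export
convert_dvh <- function(x, target_form = c("differential", "cumulative")) {
  target_form <- match.arg(target_form)
  stopifnot(inherits(x, "dvh"))
  if (x$form == target_form) return(x)
  if (target_form == "cumulative") {
    cum <- rev(cumsum(rev(x$volume)))
    dvh(x$dose_gy, cum, organ = x$organ, form = "cumulative")
  } else {
    n <- length(x$volume)
    diffv <- c(x$volume[-n] - x$volume[-1L], x$volume[n])
    dvh(x$dose_gy, diffv, organ = x$organ, form = "differential")
  }
}

#' Summary dose metrics of a DVH
#'
#' Computes Dmax (highest bin dose with nonzero volume), Dmean (volume-
#' weighted mean dose) and Vx values (percent of organ volume receiving at
#' least each threshold dose; inclusive at the threshold).
#'
#' @param x a [dvh] in either form.
#' @param thresholds_gy numeric vector of Vx threshold doses in Gy
#'   (e.g. `c(20, 30, 45)` for V20/V30/V45).
#' @return a list of class `plan_metrics` with elements `organ`, `dmax_gy`,
#'   `dmean_gy` and `vx` (named percent-volume vector).
#' @examples
#' d <- dvh(c(10, 25), c(0.75, 0.25))
#' dvh_metrics(d, thresholds_gy = 20)
#' @export
dvh_metrics <- function(x, thresholds_gy = numeric()) {
  stopifnot(inherits(x, "dvh"))
  d <- convert_dvh(x, "differential")
  nz <- d$volume > .dvh_sum_tol
  if (!any(nz)) stop("DVH has no bin with nonzero volume")
  dmax <- max(d$dose_gy[nz])
  dmean <- sum(d$volume * d$dose_gy)
  vx <- vapply(thresholds_gy, function(thr) {
    100 * sum(d$volume[d$dose_gy >= thr])
  }, numeric(1))
  names(vx) <- if (length(thresholds_gy))
    paste0("V", format(thresholds_gy, trim = TRUE)) else character()
  structure(list(organ = d$organ, dmax_gy = dmax, dmean_gy = dmean, vx = vx),
            class = "plan_metrics")
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat(sprintf("Plan metrics organ=%s: Dmax %.3f Gy, Dmean %.3f Gy\n",
              x$organ, x$dmax_gy, x$dmean_gy))
  if (length(x$vx))
    cat(paste(sprintf("  %s = %.2f%%", names(x$vx), x$vx), collapse = "\n"), "\n")
  invisible(x)
}

#' Equieffective dose in 2 Gy fractions (EQD2) transform of a DVH
#'
#' Rescales each bin dose D, delivered in `n_fractions` equal fractions,
#' to the linear-quadratic equieffective total dose in 2 Gy fractions:
#' D * (D/n + alpha/beta) / (2 + alpha/beta). Volume fractions are
#' unchanged. This correction is opt-in; the pipeline never applies it
#' unless asked.
#'
#' @param x a [dvh].
#' @param alpha_beta_gy tissue alpha/beta ratio in Gy (> 0).
#' @param n_fractions number of fractions the DVH doses were delivered in.
#' @return a [dvh] with transformed bin doses.
#' @export
eqd2_transform <- function(x, alpha_beta_gy, n_fractions) {
  stopifnot(inherits(x, "dvh"))
  if (!is.numeric(alpha_beta_gy) || length(alpha_beta_gy) != 1L ||
      alpha_beta_gy <= 0)
    stop("alpha/beta must be a single positive value in Gy")
  if (n_fractions < 1 || n_fractions != round(n_fractions))
    stop("n_fractions must be a positive integer")
  d2 <- x$dose_gy * (x$dose_gy / n_fractions + alpha_beta_gy) /
    (2 + alpha_beta_gy)
  dvh(d2, x$volume, organ = x$organ, form = x$form)
}

#' Read DVHs from CSV
#'
#' Expects columns `organ,dose_gy,volume_fraction,form`; one file may hold
#' several organs (UTF-8, dot decimal separator).
#'
#' @param path CSV file path.
#' @return named list of [dvh] objects, one per organ.
#' @export
read_dvh_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "dose_gy", "volume_fraction", "form")
  if (!all(need %in% names(df)))
    stop("DVH CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$organ), function(g) {
    form <- unique(g$form)
    if (length(form) != 1L)
      stop("organ '", g$organ[1L], "' mixes DVH forms in one file")
    g <- g[order(g$dose_gy), ]
    dvh(g$dose_gy, g$volume_fraction, organ = g$organ[1L], form = form)
  })
  out[unique(df$organ)]
}

#' Write DVHs to CSV
#'
#' @param dvhs a [dvh] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path) {
  if (inherits(dvhs, "dvh")) dvhs <- list(dvhs)
  rows <- do.call(rbind, lapply(dvhs, function(d) {
    data.frame(organ = d$organ, dose_gy = d$dose_gy,
               volume_fraction = d$volume, form = d$form)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
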