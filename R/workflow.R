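#' @title Imaging-dose accounting across the radiotherapy pathway
#' @description Ledger of per-organ absorbed doses over the treatment
#'   workflow: one planning CT plus `n` repeated CBCT position-verification
#'   acquisitions, compared against the prescribed therapeutic dose. Doses
#'   are carried at full precision; report-time rounding (mGy to the nearest
#'   integer, percents to two decimals) is applied only by the formatting
#'   helpers.
#' @name workflow-accounting
NULL

#' Treatment prescription
#'
#' @param craniospinal_gy craniospinal prescription dose in Gy.
#' @param craniospinal_fractions number of fractions for the craniospinal
#'   course.
#' @param boost_gy boost dose in Gy (0 for none).
#' @param boost_fractions number of boost fractions.
#' @return list of class `prescription`; `total_with_boost_gy` is the sum.
#' @examples
#' prescription()  # 36 Gy / 20 fx craniospinal + 18 Gy / 10 fx boost
#' @export
prescription <- function(craniospinal_gy = 36, craniospinal_fractions = 20L,
                         boost_gy = 18, boost_fractions = 10L) {
  if (craniospinal_gy <= 0) stop("craniospinal dose must be positive")
  if (boost_gy < 0) stop("boost dose must be nonnegative")
  if (craniospinal_fractions < 1) stop("fractions must be >= 1")
  structure(
    list(craniospinal_gy = craniospinal_gy,
         craniospinal_fractions = as.integer(craniospinal_fractions),
         boost_gy = boost_gy, boost_fractions = as.integer(boost_fractions),
         total_with_boost_gy = craniospinal_gy + boost_gy),
    class = "prescription"
  )
}

#' Cumulative imaging dose for one organ
#'
#' total = (CT dose, if included) + n_cbct * per-acquisition CBCT dose.
#' Per-acquisition CBCT uncertainties are treated as independent and
#' combined in quadrature: `sqrt(u_ct^2 + n * u_cbct^2)`.
#'
#' @param ct_dose_mgy planning-CT organ dose, mGy.
#' @param cbct_dose_mgy organ dose per CBCT acquisition, mGy.
#' @param n_cbct number of CBCT acquisitions (>= 0).
#' @param include_ct include the planning-CT contribution?
#' @param ct_u_mgy,cbct_u_mgy one-sigma uncertainties, mGy.
#' @return list with `total_mgy` and `uncertainty_mgy`.
#' @examples
#' cumulative_imaging_dose(4.92, 5.720, n_cbct = 15, include_ct = FALSE)
#' @export
cumulative_imaging_dose <- function(ct_dose_mgy, cbct_dose_mgy, n_cbct,
                                    include_ct = TRUE,
                                    ct_u_mgy = 0, cbct_u_mgy = 0) {
  if (n_cbct < 0 || n_cbct != round(n_cbct))
    stop("n_cbct must be a nonnegative integer")
  if (any(c(ct_dose_mgy, cbct_dose_mgy) < 0)) stop("doses must be nonnegative")
  if (any(c(ct_u_mgy, cbct_u_mgy) < 0))
    stop("uncertainties must be nonnegative")
  total <- (if (include_ct) ct_dose_mgy else 0) + n_cbct * cbct_dose_mgy
  u <- sqrt((if (include_ct) ct_u_mgy^2 else 0) + n_cbct * cbct_u_mgy^2)
  list(total_mgy = total, uncertainty_mgy = u)
}

#' Dose as a percentage of a reference dose
#'
#' Units are reconciled exactly before dividing; rounding happens only at
#' report time.
#'
#' @param dose a [dose_value], or numeric with `dose_unit`.
#' @param reference a [dose_value], or numeric with `reference_unit`;
#'   must be positive.
#' @param dose_unit,reference_unit units for plain-numeric inputs.
#' @return percent (numeric), `100 * dose / reference`.
#' @examples
#' relative_dose(dose_value(86, "mGy"), dose_value(36, "Gy"))  # 0.238...
#' @export
relative_dose <- function(dose, reference, dose_unit = "Gy",
                          reference_unit = "Gy") {
  d <- dose_gy(dose, dose_unit)
  r <- dose_gy(reference, reference_unit)
  if (length(r) != 1L || r <= 0)
    stop("reference dose must be a single positive value")
  100 * d / r
}

#' Read a per-organ imaging-dose table from CSV
#'
#' Expects columns `organ,n_osl,ct_dose_mgy,ct_u_mgy,cbct_dose_mgy,
#' cbct_u_mgy` (doses in mGy: one planning-CT scan and one CBCT
#' acquisition per organ).
#'
#' @param path CSV file path.
#' @return data.frame with the columns above; organ labels must be unique.
#' @export
read_organ_doses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "n_osl", "ct_dose_mgy", "ct_u_mgy", "cbct_dose_mgy",
            "cbct_u_mgy")
  if (!all(need %in% names(df)))
    stop("organ-dose CSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$organ))
    stop("duplicate organ labels in organ-dose table")
  if (any(df[c("ct_dose_mgy", "cbct_dose_mgy")] < 0))
    stop("doses must be nonnegative")
  df
}

#' Measured phantom organ doses for one planning CT and one CBCT
#'
#' Per-organ absorbed doses (mGy, with one-sigma uncertainties) measured
#' with nanoDot OSL dosimeters in a 5-year-old anthropomorphic phantom:
#' one full-body planning-CT scan and one CBCT position-verification
#' acquisition. `n_osl` is the number of dosimeter positions per organ.
#'
#' @return data.frame as from [read_organ_doses()].
#' @export
phantom_organ_doses <- function() {
  read_organ_doses(system.file("extdata", "phantom_organ_doses.csv",
                               package = "dosepath", mustWork = TRUE))
}

#' Per-organ exposure ledger across the imaging workflow
#'
#' One row per organ with the planning-CT dose, the CBCT-only cumulative
#' dose over `n_cbct` acquisitions, the combined imaging total with
#' quadrature uncertainty, and the total as a percent of the craniospinal
#' prescription and of the prescription-plus-boost. When per-technique
#' plan EUDs are supplied, matching columns `eud_<technique>_gy` and
#' `plan_pct_<technique>` are merged in (organs without a plan value get
#' `NA`, never zero).
#'
#' @param organ_doses data.frame as from [read_organ_doses()].
#' @param rx a [prescription].
#' @param n_cbct number of CBCT acquisitions over the treatment.
#' @param plans optional named list: technique -> data.frame with columns
#'   `organ` and `eud_gy`.
#' @return data.frame of class `exposure_report`, with a `summary`
#'   attribute giving the across-organ min/max of the CBCT-only totals and
#'   the maximum imaging percent of prescription.
#' @examples
#' rep <- build_exposure_report(phantom_organ_doses(), prescription(), 15)
#' attr(rep, "summary")
#' @export
build_exposure_report <- function(organ_doses, rx = prescription(),
                                  n_cbct = 15L, plans = NULL) {
  stopifnot(is.data.frame(organ_doses), inherits(rx, "prescription"))
  if (anyDuplicated(organ_doses$organ))
    stop("duplicate organ labels in organ-dose table")
  cum <- Map(cumulative_imaging_dose,
             organ_doses$ct_dose_mgy, organ_doses$cbct_dose_mgy,
             MoreArgs = list(n_cbct = n_cbct, include_ct = TRUE),
             organ_doses$ct_u_mgy, organ_doses$cbct_u_mgy)
  cbct_total <- n_cbct * organ_doses$cbct_dose_mgy
  imaging_total <- vapply(cum, `[[`, numeric(1), "total_mgy")
  imaging_u <- vapply(cum, `[[`, numeric(1), "uncertainty_mgy")
  out <- data.frame(
    organ = organ_doses$organ,
    ct_dose_mgy = organ_doses$ct_dose_mgy,
    cbct_dose_mgy = organ_doses$cbct_dose_mgy,
    n_cbct = n_cbct,
    cbct_total_mgy = cbct_total,
    imaging_total_mgy = imaging_total,
    imaging_u_mgy = imaging_u,
    pct_of_prescription = relative_dose(
      dose_value(imaging_total, "mGy"), rx$craniospinal_gy),
    pct_of_total_with_boost = relative_dose(
      dose_value(imaging_total, "mGy"), rx$total_with_boost_gy),
    stringsAsFactors = FALSE
  )
  if (!is.null(plans)) {
    for (tech in names(plans)) {
      p <- plans[[tech]]
      stopifnot(all(c("organ", "eud_gy") %in% names(p)))
      idx <- match(out$organ, p$organ)
      out[[paste0("eud_", tech, "_gy")]] <- p$eud_gy[idx]
      out[[paste0("plan_pct_", tech)]] <-
        100 * p$eud_gy[idx] / rx$craniospinal_gy
    }
  }
  attr(out, "summary") <- list(
    n_cbct = n_cbct,
    cbct_total_min = list(organ = out$organ[which.min(cbct_total)],
                          mgy = min(cbct_total)),
    cbct_total_max = list(organ = out$organ[which.max(cbct_total)],
                          mgy = max(cbct_total)),
    max_pct_of_prescription = max(out$pct_of_prescription)
  )
  class(out) <- c("exposure_report", "data.frame")
  out
}

#' @export
print.exposure_report <- function(x, ...) {
  s <- attr(x, "summary")
  print.data.frame(format_exposure_report(x), ...)
  cat(sprintf(
    "CBCT-only totals over %d acquisitions: %s-%s mGy (%s to %s); max imaging dose %.2f%% of prescription\n",
    s$n_cbct, round(s$cbct_total_min$mgy), round(s$cbct_total_max$mgy),
    s$cbct_total_min$organ, s$cbct_total_max$organ,
    s$max_pct_of_prescription))
  invisible(x)
}

#' Report-time rounding of an exposure report
#'
#' mGy columns round to the nearest integer and percent columns to two
#' decimals; the underlying report keeps full precision.
#'
#' @param report an `exposure_report`.
#' @return a plain data.frame with rounded display values.
#' @export
format_exposure_report <- function(report) {
  out <- as.data.frame(report)
  mgy_cols <- grep("_mgy$", names(out), value = TRUE)
  mgy_cols <- setdiff(mgy_cols, c("ct_dose_mgy", "cbct_dose_mgy"))
  for (cc in mgy_cols) out[[cc]] <- round(out[[cc]])
  for (cc in grep("^(pct_|plan_pct_)", names(out), value = TRUE))
    out[[cc]] <- round(out[[cc]], 2)
  out
}

#' Organ-by-technique EUD and NTCP comparison matrices
#'
#' Builds organ x technique matrices of EUD (Gy) and NTCP (%) from a long
#' table of per-plan EUDs, plus per-organ deltas and ratios against a
#' reference technique. Organs missing a value for some technique yield
#' `NA` cells (flagged with a message).
#'
#' @param eud_long data.frame with columns `organ`, `technique`, `eud_gy`.
#' @param params named list of [organ_ntcp_params] keyed by organ (e.g.
#'   from [read_ntcp_params()]); organs without parameters get `NA` NTCP.
#' @param reference technique name used for deltas/ratios (default: first).
#' @return list of class `technique_comparison`: matrices `eud_gy` and
#'   `ntcp_pct`, `delta_eud_gy` and `ratio_eud` vs the reference, and
#'   `reference`.
#' @examples
#' long <- data.frame(organ = "heart", technique = c("3dcrt", "vmat"),
#'                    eud_gy = c(16, 6.6))
#' p <- list(heart = fit_ntcp_params(c(16, 6.6), c(0.30, 0.004), "heart"))
#' compare_techniques(long, p, reference = "3dcrt")
#' @export
compare_techniques <- function(eud_long, params = list(), reference = NULL) {
  stopifnot(is.data.frame(eud_long),
            all(c("organ", "technique", "eud_gy") %in% names(eud_long)))
  if (nrow(eud_long) == 0L) stop("empty technique table")
  organs <- unique(eud_long$organ)
  techs <- unique(eud_long$technique)
  if (is.null(reference)) reference <- techs[1L]
  if (!reference %in% techs)
    stop("reference technique '", reference, "' not present")
  eud <- matrix(NA_real_, length(organs), length(techs),
                dimnames = list(organs, techs))
  eud[cbind(match(eud_long$organ, organs),
            match(eud_long$technique, techs))] <- eud_long$eud_gy
  if (anyNA(eud))
    message(sum(is.na(eud)), " missing organ/technique cell(s) left as NA")
  ntcp <- eud
  for (og in organs) {
    p <- params[[og]]
    for (tc in techs) {
      e <- eud[og, tc]
      ntcp[og, tc] <- if (is.null(p) || is.na(e)) NA_real_ else
        compute_ntcp(e, p)$ntcp_pct
    }
  }
  structure(
    list(eud_gy = eud, ntcp_pct = ntcp,
         delta_eud_gy = eud - eud[, reference],
         ratio_eud = eud / eud[, reference],
         reference = reference),
    class = "technique_comparison"
  )
}

#' @export
print.technique_comparison <- function(x, ...) {
  cat("EUD (Gy) by organ and technique:\n")
  print(round(x$eud_gy, 2))
  cat("NTCP (%) by organ and technique:\n")
  print(round(x$ntcp_pct, 2))
  cat("Reference technique:", x$reference, "\n")
  invisible(x)
}
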