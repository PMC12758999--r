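#' @title End-to-end pipeline orchestration
#' @description Runs the full chain — OSL calibration, organ-dose
#'   accounting, DVH-based EUD/NTCP, technique comparison — on synthetic or
#'   supplied inputs, writing CSV/JSON reports plus a run manifest that
#'   records every input, seed and parameter needed to reproduce the run.
#' @name pipeline
NULL

#' Run the full low-dose analysis pipeline
#'
#' Stages, in order: (1) calibration — simulate replicate counts at several
#' dose levels per modality and build the modality calibration curves;
#' (2) organ-dose table — simulate (or load) the per-organ CT/CBCT dose
#' table and convert it into the cumulative exposure ledger for the
#' configured number of CBCT acquisitions and prescription; (3) plan
#' radiobiology — generate the per-organ, per-technique DVHs, compute EUD
#' and NTCP per cell; (4) comparison — assemble the organ x technique
#' matrices. All outputs are deterministic given `config$seed`: rerunning
#' with the same config gives byte-identical CSVs.
#'
#' On any stage failure the partially written outputs are removed and the
#' error is re-thrown with a stage tag.
#'
#' @param config a [study_config()] (or a YAML path readable by
#'   [read_study_config()]).
#' @param output_dir directory for the report bundle (created if missing).
#' @param organ_doses optional data.frame as from [read_organ_doses()];
#'   when supplied it replaces the simulated organ-dose table.
#' @param ntcp_params named list of [organ_ntcp_params]; defaults to the
#'   packaged parameter file.
#' @param reference reference technique for deltas (default: first
#'   technique found).
#' @return invisibly, a list with `curves`, `organ_doses`, `exposure`,
#'   `eud_long`, `comparison`, and `files` (paths written).
#' @examples
#' \donttest{
#' out <- run_pipeline(study_config(seed = 7), output_dir = tempfile())
#' attr(out$exposure, "summary")$max_pct_of_prescription
#' }
#' @export
run_pipeline <- function(config, output_dir,
                         organ_doses = NULL,
                         ntcp_params = read_ntcp_params(default_ntcp_params_path()),
                         reference = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  stage <- "setup"
  tryCatch({
    set.seed(config$seed)

    stage <- "calibration"
    cal_doses_cgy <- list(planning_ct = c(500, 1500, 2868, 5000, 7077),
                          cbct = c(1, 2, 5, 10, 14),
                          rt = c(50, 100, 200))
    curves <- lapply(names(config$true_factors), function(mod) {
      pts <- lapply(cal_doses_cgy[[mod]], function(d) {
        counts <- generate_osl_counts(d, config$true_factors[[mod]],
                                      cv = config$count_cv, n_replicates = 5L)
        st <- replicate_stats(counts)
        calibration_point(d, st$mean, st$sd, length(counts))
      })
      build_calibration(pts, modality = mod)
    })
    names(curves) <- names(config$true_factors)
    for (mod in names(curves))
      write_calibration_json(curves[[mod]],
                             emit(file.path(output_dir,
                                            paste0("calibration_", mod, ".json"))))

    stage <- "dose-accounting"
    if (is.null(organ_doses))
      organ_doses <- generate_organ_dose_table(config$organs)
    utils::write.csv(organ_doses,
                     emit(file.path(output_dir, "organ_doses.csv")),
                     row.names = FALSE, quote = FALSE)
    exposure <- build_exposure_report(organ_doses, config$rx, config$n_cbct)
    utils::write.csv(format_exposure_report(exposure),
                     emit(file.path(output_dir, "exposure_report.csv")),
                     row.names = FALSE, quote = FALSE)

    stage <- "radiobiology"
    eud_long <- do.call(rbind, lapply(names(config$dvh_families), function(og) {
      fams <- config$dvh_families[[og]]
      do.call(rbind, lapply(names(fams), function(tech) {
        f <- fams[[tech]]
        d <- generate_dvh(f$dmean_gy, f$dmax_gy, f$steepness, f$n_bins,
                          organ = og)
        a_used <- if (!is.null(ntcp_params[[og]])) ntcp_params[[og]]$a else 1
        data.frame(organ = og, technique = tech,
                   eud_gy = compute_eud(d, a_used)$eud_gy,
                   a = a_used, stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(eud_long, emit(file.path(output_dir, "eud_long.csv")),
                     row.names = FALSE, quote = FALSE)

    stage <- "comparison"
    comparison <- compare_techniques(eud_long, ntcp_params,
                                     reference = reference)
    mat_files <- render_matrices(comparison, output_dir)
    written <- c(written, mat_files)

    stage <- "manifest"
    manifest <- list(
      package = "dosepath",
      version = as.character(utils::packageVersion("dosepath")),
      seed = config$seed,
      n_cbct = config$n_cbct,
      prescription = unclass(config$rx),
      organs = config$organs,
      true_factors = config$true_factors,
      count_cv = config$count_cv,
      dvh_families = config$dvh_families,
      ntcp_params = lapply(ntcp_params, unclass),
      reference_technique = comparison$reference,
      files = c(basename(written), "manifest.json")
    )
    jsonlite::write_json(manifest,
                         emit(file.path(output_dir, "manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(curves = curves, organ_doses = organ_doses,
                   exposure = exposure, eud_long = eud_long,
                   comparison = comparison, files = written))
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage [", stage, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Write comparison matrices to long-format CSV (and optional heat maps)
#'
#' Emits one long-format CSV `organ,technique,metric,value` covering the
#' EUD (Gy) and NTCP (%) matrices, plus wide per-metric CSVs. When
#' `heatmap = TRUE` and the pheatmap package is available, PNG heat maps
#' are written alongside.
#'
#' @param comparison a `technique_comparison` from [compare_techniques()].
#' @param output_dir output directory (created if missing).
#' @param heatmap also render PNG heat maps?
#' @return character vector of file paths written.
#' @export
render_matrices <- function(comparison, output_dir, heatmap = FALSE) {
  stopifnot(inherits(comparison, "technique_comparison"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  long <- do.call(rbind, lapply(
    c(eud_gy = "eud_gy", ntcp_pct = "ntcp_pct"),
    function(metric) {
      m <- comparison[[metric]]
      data.frame(organ = rep(rownames(m), ncol(m)),
                 technique = rep(colnames(m), each = nrow(m)),
                 metric = metric,
                 value = as.vector(m), stringsAsFactors = FALSE)
    }))
  # keep input organ order, techniques varying fastest within organ
  long <- long[order(match(long$organ, rownames(comparison$eud_gy)),
                     match(long$technique, colnames(comparison$eud_gy)),
                     long$metric), ]
  files <- file.path(output_dir, "comparison_long.csv")
  utils::write.csv(long, files[1L], row.names = FALSE, quote = FALSE)
  for (metric in c("eud_gy", "ntcp_pct")) {
    p <- file.path(output_dir, paste0(metric, "_matrix.csv"))
    utils::write.csv(as.data.frame(comparison[[metric]]), p,
                     row.names = TRUE, quote = FALSE)
    files <- c(files, p)
  }
  if (heatmap && requireNamespace("pheatmap", quietly = TRUE)) {
    for (metric in c("eud_gy", "ntcp_pct")) {
      m <- comparison[[metric]]
      if (all(is.finite(m))) {
        p <- file.path(output_dir, paste0(metric, "_heatmap.png"))
        grDevices::png(p, width = 720, height = 480)
        pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                           display_numbers = TRUE)
        grDevices::dev.off()
        files <- c(files, p)
      }
    }
  }
  files
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror the arguments of [study_config()]; `rx` is a
#' mapping with the [prescription()] fields.
#'
#' @param path YAML file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  rx <- if (is.null(y$rx)) prescription() else do.call(prescription, y$rx)
  args <- y[setdiff(names(y), "rx")]
  args$rx <- rx
  do.call(study_config, args)
}
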