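#' Validate a run configuration
#'
#' Parses a JSON configuration (file path or literal text), fills
#' defaults, and range-checks every safety-gated field with unit-explicit
#' messages: the prescription must lie in 43.2-50.4 Gy and the PTV margin
#' in 0.3-1.0 cm. The validated configuration is echoed into the plan
#' provenance by [run_pipeline()].
#'
#' @param config JSON text, a file path, or an R list.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(config) {
  raw <- if (is.list(config)) {
    config
  } else if (length(config) == 1L && file.exists(config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    jsonlite::fromJSON(paste(config, collapse = "\n"),
                       simplifyVector = TRUE)
  }
  def <- list(technique = "fourfield", rx = 45, ptv_margin_mm = 5,
              aperture_margin_mm = 7,
              itv_margins = list(anterior = 10, posterior = 10,
                                 superior = 10, inferior = 10,
                                 left = 5, right = 5),
              preset = "default", fif = list(), engine = list(),
              fourfield = list(), phantom = list(),
              suppress_exterior = FALSE, exterior_level = 0.70,
              structures_dir = NULL, out_dir = "planout", seed = 1L)
  cfg <- utils::modifyList(def, raw)
  if (!cfg$technique %in% c("fourfield", "crt3d"))
    stop("technique must be 'fourfield' or 'crt3d', got '", cfg$technique, "'")
  if (!is.numeric(cfg$rx) || cfg$rx < RX_RANGE[1] || cfg$rx > RX_RANGE[2])
    stop(sprintf(
      "rx = %s Gy is outside the accepted prescription range 43.2-50.4 Gy",
      format(cfg$rx)))
  if (!is.numeric(cfg$ptv_margin_mm) ||
      cfg$ptv_margin_mm < PTV_MARGIN_RANGE[1] ||
      cfg$ptv_margin_mm > PTV_MARGIN_RANGE[2])
    stop(sprintf(
      "ptv_margin = %s mm is outside the accepted range 0.3-1.0 cm",
      format(cfg$ptv_margin_mm)))
  if (cfg$aperture_margin_mm < 0)
    stop("aperture_margin must be >= 0 mm")
  im <- cfg$itv_margins
  cfg$itv_margins <- margin_spec(im$anterior, im$posterior, im$superior,
                                 im$inferior, im$left, im$right)
  cfg$fif <- do.call(fif_config, cfg$fif)
  cfg$engine <- do.call(engine_params, cfg$engine)
  cfg$fourfield <- do.call(fourfield_params, cfg$fourfield)
  if (is.null(cfg$structures_dir)) {
    ph <- cfg$phantom
    ph$random_seed <- if (is.null(ph$random_seed)) cfg$seed else
      ph$random_seed
    cfg$phantom <- do.call(phantom_spec, ph)
  }
  if (!is.null(cfg$structures_dir) && !dir.exists(cfg$structures_dir))
    stop("structures_dir does not exist: ", cfg$structures_dir)
  structure(cfg, class = "run_config")
}

#' Run the full planning pipeline
#'
#' phantom-or-load, plan assembly, FIF hot-spot reduction, optional
#' exterior-dose suppression, and constraint evaluation. Writes the plan
#' JSON, dose NIfTI, DVH CSV, constraint report (JSON + text), FIF
#' iteration trace CSV, and a provenance manifest with every parameter.
#' Hard landmark failures propagate as errors; FIF non-convergence is a
#' recorded warning status.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return Invisibly, a list with the `result` (`rt_plan_result`), the
#'   constraint `report`, and the written `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- Sys.time()
  stage <- function(nm, expr) {
    t <- system.time(v <- force(expr))["elapsed"]
    message(sprintf("[pelviplan] %-12s %6.1f s", nm, t))
    v
  }
  structures <- stage("structures", {
    if (!is.null(config$structures_dir))
      read_structure_set(config$structures_dir)
    else generate_phantom(config$phantom)
  })
  result <- stage("assemble", {
    if (config$technique == "fourfield")
      assemble_fourfield(structures, rx = config$rx,
                         params = config$fourfield, engine = config$engine)
    else
      assemble_crt3d(structures, rx = config$rx,
                     itv_margins = config$itv_margins,
                     ptv_margin_mm = config$ptv_margin_mm,
                     aperture_margin_mm = config$aperture_margin_mm,
                     preset = config$preset, engine = config$engine)
  })
  result <- stage("fif", fif_reduce(result, config$fif))
  if (isTRUE(config$suppress_exterior))
    result <- stage("exterior",
                    suppress_exterior_dose(result, config$exterior_level,
                                           config$fif))
  report <- stage("evaluate",
                  embrace_report(result$dose, structures, config$rx))

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(plan = file.path(out, "plan.json"),
                dose = file.path(out, "dose.nii"),
                dvh = file.path(out, "dvh.csv"),
                report_json = file.path(out, "report.json"),
                report_txt = file.path(out, "report.txt"),
                trace = file.path(out, "fif_trace.csv"),
                manifest = file.path(out, "manifest.json"))
  write_plan_json(result$plan, paths$plan)
  write_nifti(result$dose, paths$dose, result$geometry)
  dvh_names <- intersect(c("bladder", "rectum", "bowel_space", "spinal_cord",
                           "femur_l", "femur_r"), names(structures$masks))
  dvhs <- lapply(dvh_names, function(nm)
    compute_dvh(result$dose, structures$masks[[nm]], 0.5, result$geometry,
                structure = nm))
  tgt <- result$plan$normalization$target_structure
  dvhs <- c(dvhs, list(compute_dvh(result$dose, result$targets[[tgt]], 0.5,
                                   result$geometry, structure = tgt)))
  write_dvh_csv(dvhs, paths$dvh)
  jsonlite::write_json(as.data.frame(report), paths$report_json,
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(report)), paths$report_txt)
  if (!is.null(result$fif$trace))
    utils::write.csv(result$fif$trace, paths$trace, row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pelviplan")),
    config = rapply(unclass(config), unclass, how = "replace"),
    fif_status = result$fif$status, fif_iterations = result$fif$iterations,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(list(result = result, report = report, paths = paths))
}
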