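#' Run the end-to-end multi-technique analysis
#'
#' Orchestrates the full characterization workflow over whichever
#' modalities are supplied: static light scattering (aggregation number),
#' SAXS (sphere radius, pair-distance distribution), dynamic light
#' scattering (hydrodynamic radius) and diffusional sizing (association
#' constant, onset concentration). A cross-modality consistency section
#' compares the sphere radius with the hydrodynamic radii and derives the
#' protein volume fraction from (N, R). Failing stages are reported and
#' skipped, not fatal.
#'
#' @param inputs Named list of file paths; any subset of `dls`, `sls`
#'   (CSV, see [read_table()]), `saxs` (text, see [read_saxs()]), `mds`
#'   (CSV). At least one must be present.
#' @param config Configuration list, see [default_config()].
#' @param output_dir Optional directory; when given, the effective config
#'   (YAML) and a machine-readable JSON summary are written there.
#' @param aggregation_number Used for the volume-fraction estimate when no
#'   SLS input is supplied.
#' @return A list of class `os_report` with one element per analyzed
#'   modality, a `consistency` section and `failures`.
#' @export
run_pipeline <- function(inputs, config = default_config(),
                         output_dir = NULL, aggregation_number = NULL) {
  stopifnot(is.list(inputs))
  known <- intersect(names(inputs), c("dls", "sls", "saxs", "mds"))
  if (length(known) == 0L)
    stop("`inputs` must name at least one of dls, sls, saxs, mds")
  obj <- config_objects(config)
  report <- list()
  failures <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (!is.null(inputs$sls)) {
    report$sls <- run_stage("sls", {
      df <- read_table(inputs$sls, "sls")
      analyze_sls(df, obj$protein, obj$calib, config$sls$wavelength_nm)
    })
  }
  if (!is.null(inputs$dls)) {
    report$dls <- run_stage("dls", {
      df <- read_table(inputs$dls, "dls")
      hydrodynamic_radius(df, obj$solvent, config$dls$wavelength_nm)
    })
  }
  if (!is.null(inputs$saxs)) {
    report$saxs <- run_stage("saxs", {
      curve <- read_saxs(inputs$saxs)
      fit <- fit_sphere(curve, q_max = config$saxs$q_max)
      pddf <- estimate_pddf(curve, d_max = config$saxs$d_max,
                            n_points = config$saxs$n_points)
      list(fit = fit, pddf = pddf)
    })
  }
  if (!is.null(inputs$mds)) {
    report$mds <- run_stage("mds", {
      df <- read_table(inputs$mds, "mds")
      analyze_mds(df, obj$assoc,
                  calibration_range = config$association$calibration_range)
    })
  }

  # cross-modality consistency
  N <- if (!is.null(report$sls)) round(mean(report$sls$by_day$N_raw)) else
    aggregation_number
  consistency <- list()
  if (!is.null(report$saxs) && !is.null(N)) {
    consistency$volume_fraction <-
      volume_fraction(N, obj$protein, report$saxs$fit$radius)
  }
  radii <- c(
    dls_r_h = if (!is.null(report$dls)) report$dls$r_h_nm else NA_real_,
    sphere_radius = if (!is.null(report$saxs)) report$saxs$fit$radius else NA_real_,
    mds_oligomer_r_h = if (!is.null(report$mds)) obj$assoc$r_h_oligomer else NA_real_
  )
  consistency$radii_nm <- radii[is.finite(radii)]
  report$consistency <- consistency
  report$failures <- failures

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(output_dir, "config.yaml"))
    jsonlite::write_json(report_summary(report),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "os_report"
  report
}

# flatten a report into plain named numbers for the JSON summary
report_summary <- function(report) {
  out <- list()
  if (!is.null(report$sls))
    out$sls <- list(by_day = report$sls$by_day)
  if (!is.null(report$dls))
    out$dls <- list(r_h_nm = report$dls$r_h_nm,
                    diffusion_m2_s = report$dls$diffusion)
  if (!is.null(report$saxs))
    out$saxs <- list(radius_nm = report$saxs$fit$radius,
                     forward_intensity = report$saxs$fit$forward_intensity,
                     internal_background = report$saxs$fit$internal_background,
                     pddf_d_max_nm = report$saxs$pddf$d_max)
  if (!is.null(report$mds))
    out$mds <- list(log10K = report$mds$fit$log10K,
                    identifiable = report$mds$fit$identifiable,
                    onset_nM = report$mds$onset$c_agg_nM,
                    high_plateau_nm = report$mds$high_plateau$mean,
                    low_plateau_nm = report$mds$low_plateau$mean)
  out$consistency <- report$consistency
  if (length(report$failures)) out$failures <- report$failures
  out
}

#' @export
print.os_report <- function(x, ...) {
  cat("Multi-technique self-assembly analysis report\n")
  if (!is.null(x$sls)) {
    cat("  SLS aggregation number by day:\n")
    print(x$sls$by_day, row.names = FALSE)
  }
  if (!is.null(x$dls))
    cat(sprintf("  DLS hydrodynamic radius: %.2f nm\n", x$dls$r_h_nm))
  if (!is.null(x$saxs))
    cat(sprintf("  SAXS sphere radius: %.2f nm (d_max = %.1f nm)\n",
                x$saxs$fit$radius, x$saxs$pddf$d_max))
  if (!is.null(x$mds))
    cat(sprintf("  MDS: log10K = %.2f, onset = %.2f nM, plateaus %.2f / %.2f nm\n",
                x$mds$fit$log10K, x$mds$onset$c_agg_nM,
                x$mds$low_plateau$mean, x$mds$high_plateau$mean))
  if (!is.null(x$consistency$volume_fraction))
    cat(sprintf("  Protein volume fraction in assembly: %.2f\n",
                x$consistency$volume_fraction))
  if (length(x$failures))
    cat("  Failed stages:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
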