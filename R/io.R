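## Plain-text table readers/writers and YAML configuration.

# schema registry: mandatory columns per table kind
.os_schemas <- list(
  dls = c("angle_deg", "lag_s", "g2"),
  sls = c("angle_deg", "I_sample", "I_buffer", "I_toluene", "conc_uM"),
  mds = c("conc_nM_nominal", "replicate", "r_h_nm", "intensity"),
  decay_fits = c("angle_deg", "q_nm_inv", "beta", "gamma_s_inv", "residual_rms"),
  pddf = c("r_nm", "p_normalized")
)

#' Read a typed CSV table
#'
#' Reads one of the package's CSV table kinds, checking the header against
#' the schema. Unknown columns are preserved; a missing mandatory column
#' raises an error naming it; unparseable numeric entries raise an error
#' with the offending line number.
#'
#' @param path Path to a CSV file.
#' @param schema_id One of `"dls"`, `"sls"`, `"mds"`, `"decay_fits"`,
#'   `"pddf"`.
#' @return A data frame.
#' @export
read_table <- function(path, schema_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- .os_schemas[[schema_id]]
  if (is.null(schema)) stop("unknown schema id: ", schema_id)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols))
    stop(sprintf("missing mandatory column(s) in %s: %s",
                 path, paste(missing_cols, collapse = ", ")))
  numeric_cols <- setdiff(schema, c("day"))
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad))
      stop(sprintf("unparseable numeric in column `%s` of %s at line %d",
                   col, path, bad[1] + 1L))
    df[[col]] <- vals
  }
  df
}

#' Write a typed CSV table
#'
#' @param df A data frame whose columns include the schema's mandatory
#'   ones.
#' @param path Output path.
#' @param schema_id Table kind, see [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema_id) {
  schema <- .os_schemas[[schema_id]]
  if (is.null(schema)) stop("unknown schema id: ", schema_id)
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols))
    stop("data frame lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 1-D SAXS curve from a text file
#'
#' Accepts the common 2- or 3-column `q I [sigma]` layout, whitespace- or
#' comma-separated, with `#`-prefixed comment lines. q may be supplied in
#' 1/nm or 1/angstrom; angstrom values are multiplied by 10 on read so the
#' package works in 1/nm throughout.
#'
#' @param path Path to the file.
#' @param qunit `"nm"` (default) or `"angstrom"`.
#' @return A data frame with columns `q` (1/nm), `intensity` and, when
#'   present, `sigma`.
#' @export
read_saxs <- function(path, qunit = c("nm", "angstrom")) {
  qunit <- match.arg(qunit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  txt <- gsub(",", " ", lines)
  df <- utils::read.table(text = txt, header = FALSE)
  if (ncol(df) < 2) stop("SAXS file must have at least 2 columns (q, I)")
  out <- data.frame(q = df[[1]], intensity = df[[2]])
  if (ncol(df) >= 3) out$sigma <- df[[3]]
  if (qunit == "angstrom") out$q <- out$q * 10
  if (any(diff(out$q) <= 0)) stop("q must be strictly increasing")
  out
}

#' Write a SAXS curve as 3-column text
#'
#' @param curve Data frame with `q`, `intensity`, optionally `sigma`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs <- function(curve, path) {
  cols <- c("q", "intensity", if (!is.null(curve$sigma)) "sigma")
  utils::write.table(curve[cols], path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Solvent, protein and calibration defaults plus stage parameters, as a
#' plain nested list suitable for YAML round-tripping.
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    solvent = list(temperature = 298.15, viscosity = 8.872e-4,
                   refractive_index = 1.33),
    protein = list(monomer_molar_mass = 20000,
                   refractive_index_increment = 0.185,
                   mass_density = 1.4),
    calibration = list(rayleigh_toluene = 1.148e-5, n_buffer = 1.33,
                       n_toluene = 1.49),
    dls = list(wavelength_nm = 660),
    sls = list(wavelength_nm = 660),
    saxs = list(q_max = 2.5, d_max = 13, n_points = 101),
    association = list(subunits_per_oligomer = 9, monomers_per_subunit = 2,
                       r_h_subunit = 5, r_h_oligomer = 7,
                       calibration_range = c(1000, 8000)),
    seed = 1
  )
}

#' Read / write a run configuration
#'
#' YAML files holding overrides of [default_config()]; unspecified keys
#' keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return For `read_config`, the merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# build typed parameter objects from a config list
config_objects <- function(config) {
  list(
    solvent = do.call(solvent_conditions, config$solvent),
    protein = do.call(protein_params, config$protein),
    calib = do.call(calibration_constants, config$calibration),
    assoc = association_params(
      assoc_constant = 1e-4,
      subunits_per_oligomer = config$association$subunits_per_oligomer,
      monomers_per_subunit = config$association$monomers_per_subunit,
      r_h_subunit = config$association$r_h_subunit,
      r_h_oligomer = config$association$r_h_oligomer)
  )
}
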