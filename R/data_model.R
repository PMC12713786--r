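#' Tabular data model: schemas and loaders
#'
#' All pipeline inputs are comma-separated UTF-8 tables with a mandatory
#' header row and "." decimals. Absent values are empty cells (never 0 or a
#' sentinel). One row is one entry at the study x species x particle
#' granularity; any aggregation happens downstream, never in the loader.
#'
#' Toxicity table columns (`toxicity_schema()`): `entry_id`, `study_id`,
#' `species_label`, `taxon_group` (plant/invertebrate/bacteria/fungi),
#' `endpoint_name`, `endpoint_category` (A/B/C), `descriptor_kind`
#' (HONEC/NOEC/LOEC), `noec_value`, `loec_value`, `honec_value`,
#' `exposure_days`, `concentration_unit` (nb_per_kg_dw/mg_per_kg_dw), and
#' particle columns `particle_shape` (sphere/fiber/film),
#' `particle_diameter_um`, `particle_length_um`, `particle_thickness_um`,
#' `particle_density_g_cm3`, `particle_polymer`, `particle_size_basis`.
#'
#' Exposure table columns (`exposure_schema()`): `sample_id`, `study_id`,
#' `site_id`, `concentration_nb_per_kg_dw`.
#'
#' @name data_model
NULL

TAXON_GROUPS <- c("plant", "invertebrate", "bacteria", "fungi")
ENDPOINT_CATEGORIES <- c("A", "B", "C")
DESCRIPTOR_KINDS <- c("HONEC", "NOEC", "LOEC")
CONCENTRATION_UNITS <- c("nb_per_kg_dw", "mg_per_kg_dw")
MATRICES <- c("sludge", "sas", "control")

#' @rdname data_model
#' @export
toxicity_schema <- function() {
  c("entry_id", "study_id", "species_label", "taxon_group", "endpoint_name",
    "endpoint_category", "descriptor_kind", "noec_value", "loec_value",
    "honec_value", "exposure_days", "concentration_unit", "particle_shape",
    "particle_diameter_um", "particle_length_um", "particle_thickness_um",
    "particle_density_g_cm3", "particle_polymer", "particle_size_basis")
}

#' @rdname data_model
#' @export
exposure_schema <- function() {
  c("sample_id", "study_id", "site_id", "concentration_nb_per_kg_dw")
}

# Validate one toxicity row; returns character(0) when clean.
validate_toxicity_row <- function(row) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  chk(nzchar(row$entry_id %||% ""), "entry_id is empty")
  chk(nzchar(row$species_label %||% ""), "species_label is empty")
  chk(row$taxon_group %in% TAXON_GROUPS,
      sprintf("taxon_group '%s' not one of %s", row$taxon_group,
              paste(TAXON_GROUPS, collapse = "/")))
  chk(row$endpoint_category %in% ENDPOINT_CATEGORIES,
      sprintf("endpoint_category '%s' not one of A/B/C", row$endpoint_category))
  chk(row$descriptor_kind %in% DESCRIPTOR_KINDS,
      sprintf("descriptor_kind '%s' not one of HONEC/NOEC/LOEC",
              row$descriptor_kind))
  chk(row$concentration_unit %in% CONCENTRATION_UNITS,
      sprintf("concentration_unit '%s' unknown", row$concentration_unit))
  vals <- c(noec = row$noec_value, loec = row$loec_value,
            honec = row$honec_value)
  chk(any(!is.na(vals)), "no descriptor value present (NOEC/LOEC/HONEC all absent)")
  for (nm in names(vals)) {
    if (!is.na(vals[[nm]])) chk(vals[[nm]] > 0,
                                sprintf("%s_value must be > 0", nm))
  }
  if (!is.na(row$noec_value) && !is.na(row$loec_value)) {
    chk(row$noec_value < row$loec_value,
        sprintf("NOEC (%g) must be < LOEC (%g)", row$noec_value, row$loec_value))
  }
  chk(is.finite(row$exposure_days) && row$exposure_days > 5,
      sprintf("exposure_days (%s) must be > 5 (chronic inclusion criterion)",
              format(row$exposure_days)))
  if (identical(row$concentration_unit, "mg_per_kg_dw")) {
    chk(!is.na(row$particle_shape) && nzchar(row$particle_shape),
        "mg/kg entries need a particle_shape for number conversion")
  }
  problems
}

#' Load and validate a toxicity-entry table
#'
#' @param path CSV file path.
#' @param on_error `"stop"` (default) aborts listing every bad row;
#'   `"keep"` returns the accepted rows with the rejected rows and reasons
#'   attached as `attr(, "rejected")`, so no row is ever silently dropped.
#' @return a data.frame of validated entries (class `mp_toxicity`), row
#'   order preserved.
#' @export
load_toxicity_table <- function(path, on_error = c("stop", "keep")) {
  on_error <- match.arg(on_error)
  df <- read_mp_csv(path, toxicity_schema())
  num_cols <- c("noec_value", "loec_value", "honec_value", "exposure_days",
                "particle_diameter_um", "particle_length_um",
                "particle_thickness_um", "particle_density_g_cm3")
  df <- coerce_numeric_cols(df, num_cols, path)
  reasons <- vapply(seq_len(nrow(df)), function(i)
    paste(validate_toxicity_row(as.list(df[i, ])), collapse = "; "),
    character(1))
  bad <- nzchar(reasons)
  if (any(bad) && on_error == "stop") {
    stop_mp("invalid toxicity rows in '%s':\n%s", path,
            paste(sprintf("  row %d (entry_id=%s): %s", which(bad),
                          df$entry_id[bad], reasons[bad]), collapse = "\n"),
            class = "mp_validation_error")
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mp_toxicity", "data.frame")
  if (any(bad)) {
    attr(out, "rejected") <- data.frame(row = which(bad),
                                        entry_id = df$entry_id[bad],
                                        reason = reasons[bad],
                                        stringsAsFactors = FALSE)
  }
  out
}

#' Load an exposure-concentration table
#'
#' Concentrations are particle counts per kg dry weight. Exact zeros (below
#' detection) are floored to half the smallest positive value in the table,
#' with a warning, so that strictly-positive families (log-normal,
#' log-logistic, Burr) stay applicable to the same vector as Weibull/gamma.
#'
#' @param path CSV file path.
#' @param matrix one of `"sludge"`, `"sas"`, `"control"`; every sample is
#'   tagged with it.
#' @param floor_zeros logical; apply the zero floor (default TRUE).
#' @return data.frame (class `mp_exposure`) with columns `sample_id`,
#'   `study_id`, `site_id`, `matrix`, `concentration`.
#' @export
load_exposure_table <- function(path, matrix, floor_zeros = TRUE) {
  if (!matrix %in% MATRICES) {
    stop_mp("unknown matrix '%s' (expected %s)", matrix,
            paste(MATRICES, collapse = "/"), class = "mp_config_error")
  }
  df <- read_mp_csv(path, exposure_schema())
  df <- coerce_numeric_cols(df, "concentration_nb_per_kg_dw", path)
  bad <- is.na(df$concentration_nb_per_kg_dw) |
    df$concentration_nb_per_kg_dw < 0
  if (any(bad)) {
    stop_mp("invalid concentrations in '%s' at row(s) %s (must be >= 0)",
            path, paste(which(bad), collapse = ", "),
            class = "mp_validation_error")
  }
  conc <- df$concentration_nb_per_kg_dw
  if (floor_zeros && any(conc == 0)) {
    floor_val <- min(conc[conc > 0]) / 2
    warning(sprintf("%d zero concentration(s) in '%s' floored to %g (half the smallest positive value)",
                    sum(conc == 0), path, floor_val), call. = FALSE)
    conc[conc == 0] <- floor_val
  }
  out <- data.frame(sample_id = df$sample_id, study_id = df$study_id,
                    site_id = df$site_id, matrix = matrix,
                    concentration = conc, stringsAsFactors = FALSE)
  class(out) <- c("mp_exposure", "data.frame")
  out
}

read_mp_csv <- function(path, schema) {
  if (!file.exists(path)) {
    stop_mp("file not found: '%s'", path, class = "mp_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "",
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(schema, names(df))
  if (length(missing_cols)) {
    stop_mp("'%s' is missing required column(s): %s", path,
            paste(missing_cols, collapse = ", "), class = "mp_schema_error")
  }
  df[schema]
}

coerce_numeric_cols <- function(df, cols, path) {
  for (cl in cols) {
    raw <- df[[cl]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad)) {
      stop_mp("column '%s' of '%s': non-numeric value '%s' at row %d",
              cl, path, raw[which(bad)[1]], which(bad)[1],
              class = "mp_parse_error")
    }
    df[[cl]] <- num
  }
  df
}

#' Write result tables plus a machine-readable run summary
#'
#' Writes one CSV per named table and a `run_summary.json` capturing the
#' seed, configuration and package version, then returns a manifest.
#' Re-running with identical inputs and seed reproduces the numeric columns
#' byte for byte (numbers are serialized with `format(..., digits = 15)`).
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param config run configuration list recorded in the summary.
#' @param seed seed recorded in the summary.
#' @return invisible data.frame manifest (name, path).
#' @export
write_results <- function(tables = list(), out_dir, config = list(),
                          seed = NA_integer_) {
  stopifnot(is.list(tables))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_mp("cannot create output directory '%s'", out_dir,
                     class = "mp_io_error")
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop_mp("output directory '%s' is not writable", out_dir,
            class = "mp_io_error")
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    tb <- as.data.frame(tables[[nm]])
    for (cl in names(tb)) {
      if (is.numeric(tb[[cl]])) tb[[cl]] <- format(tb[[cl]], digits = 15,
                                                   trim = TRUE,
                                                   scientific = FALSE)
    }
    utils::write.csv(tb, p, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    paths[nm] <- p
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(
    list(seed = seed, config = config,
         package_version = as.character(utils::packageVersion("mpsoilrisk")),
         r_version = R.version.string,
         tables = as.list(paths)),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  manifest <- data.frame(name = c(names(paths), "run_summary"),
                         path = c(unname(paths), summary_path),
                         stringsAsFactors = FALSE)
  invisible(manifest)
}

#' Round-trip writers for the input schemas
#'
#' `write_toxicity_table()` / `write_exposure_table()` serialize tables in
#' the exact loader schemas, so write-then-load reproduces every field.
#'
#' @param df table to write (toxicity entries or exposure samples).
#' @param path destination CSV.
#' @export
write_toxicity_table <- function(df, path) {
  stopifnot(all(toxicity_schema() %in% names(df)))
  utils::write.csv(fmt_full_precision(df[toxicity_schema()]), path,
                   row.names = FALSE, quote = TRUE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_toxicity_table
#' @export
write_exposure_table <- function(df, path) {
  out <- data.frame(sample_id = df$sample_id, study_id = df$study_id,
                    site_id = df$site_id,
                    concentration_nb_per_kg_dw =
                      df$concentration_nb_per_kg_dw %||% df$concentration)
  utils::write.csv(fmt_full_precision(out), path, row.names = FALSE,
                   quote = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

# 17 significant digits keep doubles exact across a write/load round trip
fmt_full_precision <- function(df) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) {
      v <- df[[cl]]
      df[[cl]] <- ifelse(is.na(v), NA_character_,
                         formatC(v, digits = 17, format = "g"))
    }
  }
  df
}
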