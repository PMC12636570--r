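# Table readers/writers and schema validation ----------------------------

# read a delimited table, auto-detecting comma vs tab from the header
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    stop(sprintf("%s is empty", path), call. = FALSE)
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and validate a delimited table against a column schema
#'
#' @param path CSV or TSV file with a header row.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numbers with no missing
#'   values; errors name the first offending row and column.
#' @return A tibble of the validated records.
#' @export
read_table_checked <- function(path, required, numeric_cols = character()) {
  df <- read_delim_auto(path)
  if (nrow(df) == 0L) {
    stop(sprintf("%s contains a header but no records", path), call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("%s: non-numeric value in column `%s`, row %d",
                   path, col, bad), call. = FALSE)
    }
    df[[col]] <- v
  }
  tibble::as_tibble(df)
}

#' Read a long-format growth plate CSV
#'
#' Expected columns: `well_id`, `row`, `col`, `time_hr`, `nuclei_count`.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_plate_csv <- function(path) {
  read_table_checked(
    path,
    required = c("well_id", "row", "col", "time_hr", "nuclei_count"),
    numeric_cols = c("row", "col", "time_hr", "nuclei_count")
  )
}

#' Read a flux-growth table (CSV or TSV)
#'
#' Expected columns: `organism`, `condition`, `growth_rate_per_hr`, and
#' any of the byproduct/oxygen columns `lactate`, `ethanol`, `acetate`,
#' `o2` (umol (mg protein)^-1 hr^-1); missing byproduct columns are
#' treated as zero flux.
#'
#' @param path File path.
#' @return Validated tibble with all four flux columns present.
#' @export
read_flux_table <- function(path) {
  df <- read_table_checked(
    path,
    required = c("organism", "condition", "growth_rate_per_hr"),
    numeric_cols = c("growth_rate_per_hr", "lactate", "ethanol", "acetate",
                     "o2")
  )
  for (col in c("lactate", "ethanol", "acetate", "o2")) {
    if (!col %in% names(df)) df[[col]] <- 0
  }
  df
}

#' Read a Seahorse-style trace CSV
#'
#' Expected columns: `well`, `phase`, `measurement_index`, `value`.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_seahorse_csv <- function(path) {
  read_table_checked(
    path,
    required = c("well", "phase", "measurement_index", "value"),
    numeric_cols = c("measurement_index", "value")
  )
}

#' Read a cell-line descriptor table CSV
#'
#' Expected columns: `cell_line`, `volume_fl`, `protein_per_volume`
#' (mg/fL).
#'
#' @param path File path.
#' @return Named list of [cell_descriptor()] objects keyed by cell line.
#' @export
read_descriptor_csv <- function(path) {
  df <- read_table_checked(
    path,
    required = c("cell_line", "volume_fl", "protein_per_volume"),
    numeric_cols = c("volume_fl", "protein_per_volume")
  )
  out <- lapply(seq_len(nrow(df)), function(i) {
    cell_descriptor(df$cell_line[i], df$volume_fl[i], df$protein_per_volume[i])
  })
  names(out) <- df$cell_line
  out
}

#' Write a fitted ATP-growth line (with CIs) as JSON
#'
#' @param fit A [line_fit][fit_line], typically from [bootstrap_fit()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_line_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "line_fit"))
  payload <- fit[c("slope", "intercept", "pearson_r", "r_squared", "p_value",
                   "n", "slope_ci", "intercept_ci", "n_boot", "seed")]
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a prediction band as a CSV table
#'
#' Columns: `growth_rate`, `fit`, `lower`, `upper`.
#'
#' @param band A [prediction_band()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_band_csv <- function(band, path) {
  stopifnot(inherits(band, "prediction_band"))
  write.csv(as.data.frame(band), path, row.names = FALSE)
  invisible(path)
}
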