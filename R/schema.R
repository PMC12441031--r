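#' Feature schema for tabular regression inputs
#'
#' A feature schema fixes the names and order of the input features. The
#' order matters: the shuffle window used to build self-supervised views
#' slides over features in schema order, so two tables are only comparable
#' under the same schema.
#'
#' @param feature_names Character vector of unique feature names.
#' @return An object of class `feature_schema` with elements
#'   `feature_names` and `L` (the total feature count).
#' @seealso [mangrove_schema()] for the default 22-feature schema.
#' @export
feature_schema <- function(feature_names) {
  feature_names <- as.character(feature_names)
  if (length(feature_names) < 3L) {
    stop("a feature schema needs at least 3 features", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  structure(
    list(feature_names = feature_names, L = length(feature_names)),
    class = "feature_schema"
  )
}

#' The default 22-feature mangrove biomass schema
#'
#' Seven Landsat-8 band features (coastal aerosol through the two
#' short-wave infrared bands), six vegetation indices (NDVI, RVI, DVI,
#' SAVI, EVI, GNDVI), eight GLCM texture statistics (variance,
#' homogeneity, contrast, heterogeneity, entropy, angular second moment,
#' correlation, mean) and one topographic factor, in that order. This is
#' the feature inventory used for Kandelia mangrove aboveground-biomass
#' plots; the shuffle window indexes features in this order.
#'
#' @return A `feature_schema` with `L = 22`.
#' @export
#' @examples
#' mangrove_schema()$feature_names
mangrove_schema <- function() {
  feature_schema(c(
    # Landsat-8 band values
    "coastal", "blue", "green", "red", "nir", "swir1", "swir2",
    # vegetation indices
    "NDVI", "RVI", "DVI", "SAVI", "EVI", "GNDVI",
    # GLCM texture statistics
    "VAR", "HOM", "CON", "HET", "ENT", "ASM", "COR", "MEA",
    # topographic factor from the DEM
    "TOF"
  ))
}

#' Read a feature schema from a YAML file
#'
#' The file holds a `feature_names` key with the ordered list of names,
#' so the tool generalizes beyond the default 22-feature inventory:
#'
#' ```yaml
#' feature_names: [band1, band2, NDVI, elevation]
#' ```
#'
#' @param path Path to a YAML schema file.
#' @return A [feature_schema()].
#' @export
read_feature_schema <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$feature_names)) {
    stop("schema file must define `feature_names`", call. = FALSE)
  }
  feature_schema(unlist(spec$feature_names))
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> L =", x$L, "features\n")
  cat(" ", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a feature table from CSV
#'
#' The CSV must have a header row containing every schema feature name
#' (extra columns are allowed and preserved: `sample_id` and `biomass`
#' are recognised). Rows are returned in file order.
#'
#' @param path Path to a CSV file with one sample per row.
#' @param schema A [feature_schema()]; defaults to [mangrove_schema()].
#' @return A tibble with a `sample_id` column, the schema feature columns
#'   in schema order, and a `biomass` column when present in the file.
#' @export
read_feature_table <- function(path, schema = mangrove_schema()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(schema$feature_names, names(tbl))
  if (length(missing) > 0L) {
    stop("feature table is missing schema column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in schema$feature_names) {
    if (!is.numeric(tbl[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[nm]]))) &
                     !is.na(tbl[[nm]]))
      stop("non-numeric value in column '", nm, "' (row ",
           if (length(bad)) bad[1L] else "?", ")", call. = FALSE)
    }
  }
  if (!"sample_id" %in% names(tbl)) {
    tbl$sample_id <- paste0("s", seq_len(nrow(tbl)))
  }
  keep <- c("sample_id", schema$feature_names,
            intersect("biomass", names(tbl)))
  out <- tbl[, keep]
  validate_feature_table(out, schema)
  out
}

#' Write a feature table to CSV
#'
#' @param data A feature table (tibble with schema columns and optionally
#'   `sample_id` / `biomass`).
#' @param path Output CSV path.
#' @param schema A [feature_schema()] used to order the feature columns.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, schema = mangrove_schema()) {
  validate_feature_table(data, schema)
  keep <- c(intersect("sample_id", names(data)), schema$feature_names,
            intersect("biomass", names(data)))
  readr::write_csv(data[, keep], path, progress = FALSE)
  invisible(path)
}

#' Validate a feature table against a schema
#'
#' Checks that every schema feature column is present, numeric and finite,
#' and that `biomass` (when present) is finite and positive.
#'
#' @inheritParams write_feature_table
#' @return `data`, invisibly.
#' @export
validate_feature_table <- function(data, schema = mangrove_schema()) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 1L) stop("feature table has no rows", call. = FALSE)
  missing <- setdiff(schema$feature_names, names(data))
  if (length(missing) > 0L) {
    stop("feature table is missing schema column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in schema$feature_names) {
    v <- data[[nm]]
    if (!is.numeric(v)) stop("column '", nm, "' is not numeric", call. = FALSE)
    if (!all(is.finite(v))) {
      stop("column '", nm, "' contains non-finite values", call. = FALSE)
    }
  }
  if ("biomass" %in% names(data)) {
    b <- data$biomass
    if (!all(is.finite(b)) || any(b <= 0)) {
      stop("biomass must be finite and positive", call. = FALSE)
    }
  }
  invisible(data)
}

#' Extract the feature matrix from a table
#'
#' @inheritParams write_feature_table
#' @return A numeric matrix of dimension `n x L`, columns in schema order.
#' @export
feature_matrix <- function(data, schema = mangrove_schema()) {
  validate_feature_table(data, schema)
  m <- as.matrix(data[, schema$feature_names])
  storage.mode(m) <- "double"
  rownames(m) <- if ("sample_id" %in% names(data)) data$sample_id else NULL
  m
}

#' Z-score standardization of feature columns
#'
#' Standardizes every schema feature column to mean 0 and standard
#' deviation 1. The per-feature means and standard deviations are attached
#' as the `"feature_stats"` attribute (a tibble) so that test rows can be
#' scaled with training statistics and so the transform can be inverted.
#' The target (`biomass`) is never scaled. A feature with zero spread is
#' centred and its standard deviation is treated as 1 (it standardizes to
#' a column of zeros).
#'
#' @param data A feature table.
#' @param stats Optional stats tibble (columns `feature`, `mean`, `sd`)
#'   from a previous call, e.g. fitted on the training split. When `NULL`,
#'   stats are estimated from `data` (which then needs at least 2 rows).
#' @param schema A [feature_schema()].
#' @return The table with standardized feature columns and attribute
#'   `"feature_stats"`.
#' @export
#' @examples
#' tbl <- simulate_feature_table(n = 20, seed = 1)
#' std <- standardize_features(tbl)
#' colMeans(feature_matrix(std)) # ~ 0
standardize_features <- function(data, stats = NULL,
                                 schema = mangrove_schema()) {
  validate_feature_table(data, schema)
  if (is.null(stats)) {
    if (nrow(data) < 2L) {
      stop("cannot estimate feature spread from a single row; ",
           "supply `stats` fitted on more data", call. = FALSE)
    }
    x <- feature_matrix(data, schema)
    mu <- colMeans(x)
    sd_ <- apply(x, 2L, stats::sd)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
    stats <- tibble::tibble(feature = schema$feature_names,
                            mean = unname(mu), sd = unname(sd_))
  }
  stopifnot(identical(stats$feature, schema$feature_names))
  out <- data
  for (i in seq_len(schema$L)) {
    nm <- schema$feature_names[i]
    out[[nm]] <- (data[[nm]] - stats$mean[i]) / stats$sd[i]
  }
  attr(out, "feature_stats") <- stats
  out
}

#' Invert feature standardization
#'
#' @param data A standardized feature table.
#' @param stats Stats tibble; defaults to the table's `"feature_stats"`
#'   attribute.
#' @param schema A [feature_schema()].
#' @return The table on the original feature scale.
#' @export
unstandardize_features <- function(data, stats = attr(data, "feature_stats"),
                                   schema = mangrove_schema()) {
  if (is.null(stats)) {
    stop("no standardization stats found; pass `stats`", call. = FALSE)
  }
  stopifnot(identical(stats$feature, schema$feature_names))
  out <- data
  for (i in seq_len(schema$L)) {
    nm <- schema$feature_names[i]
    out[[nm]] <- data[[nm]] * stats$sd[i] + stats$mean[i]
  }
  attr(out, "feature_stats") <- NULL
  out
}

#' Retrieve standardization stats from a table
#'
#' @param data A table produced by [standardize_features()].
#' @return A tibble with columns `feature`, `mean`, `sd`, or `NULL`.
#' @export
feature_stats <- function(data) attr(data, "feature_stats")

#' Allometric biomass from stem diameter
#'
#' Power-law allometry relating the near-ground branch trunk diameter `D`
#' of a Kandelia mangrove to its total biomass: `y = a * D^b`, with the
#' published coefficients a = 3.614 and b = 1.446 as defaults. Units of
#' the result follow the units in which the equation was calibrated and
#' are treated as opaque biomass units throughout the package.
#'
#' @param D Numeric vector of diameters, `D >= 0`.
#' @param coefficient Positive multiplier `a` (default 3.614).
#' @param exponent Positive exponent `b` (default 1.446).
#' @return Numeric vector of biomass values; strictly increasing in `D`.
#' @export
#' @examples
#' biomass_from_diameter(1)  # equals the coefficient
#' biomass_from_diameter(10) # ~ 100.9
biomass_from_diameter <- function(D, coefficient = 3.614, exponent = 1.446) {
  if (!is.numeric(D) || any(!is.finite(D))) {
    stop("D must be finite numeric", call. = FALSE)
  }
  if (any(D < 0)) stop("diameter D must be non-negative", call. = FALSE)
  if (coefficient <= 0 || exponent <= 0) {
    stop("allometric coefficient and exponent must be positive", call. = FALSE)
  }
  coefficient * D^exponent
}
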