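## Readers and writers for the plain-text exchange formats: square (or
## lower-triangle) distance matrices, species-by-assemblage abundance
## tables, trait tables with a sidecar type map, and long-format results.

#' Read a species pairwise distance matrix
#'
#' Expects a CSV/TSV file whose first row and first column are species
#' labels and whose body is square and numeric. A lower-triangle file (upper
#' body empty or absent) can be completed by symmetry with
#' `lower_triangle = TRUE`.
#'
#' @param path File path (.csv or .tsv; delimiter inferred from the
#'   extension, override with `delim`).
#' @param lower_triangle Complete an upper-empty body by reflection.
#' @param tol,symmetrize Passed to [as_fun_dist()].
#' @param delim Optional field delimiter.
#' @return A validated distance matrix.
#' @export
read_distance <- function(path, lower_triangle = FALSE, tol = 1e-10,
                          symmetrize = NULL, delim = NULL) {
  df <- read_delim_guess(path, delim)
  labs <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  m <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(body))
  bad <- which(is.na(m) & !(is.na(body) | body == ""), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    abort(sprintf("Non-numeric cell at row %d, column %d of %s.",
                  bad[1, 1], bad[1, 2] + 1, path),
          class = "funhill_error_input")
  }
  rownames(m) <- labs
  colnames(m) <- names(body)
  if (lower_triangle) {
    up <- upper.tri(m)
    if (any(!is.na(m[up]))) {
      abort("lower_triangle = TRUE but the upper triangle is not empty.",
            class = "funhill_error_input")
    }
    m[up] <- t(m)[up]
    diag(m)[is.na(diag(m))] <- 0
  }
  if (anyNA(m)) {
    abort(sprintf("Missing values in distance matrix %s.", path),
          class = "funhill_error_input")
  }
  as_fun_dist(m, tol = tol, symmetrize = symmetrize)
}

#' Read a species-by-assemblage abundance table
#'
#' Rows are species (first column holds the label), columns are assemblages
#' (header row). Absolute or relative abundances are both accepted.
#'
#' @inheritParams read_distance
#' @return A community matrix as returned by [as_community()].
#' @export
read_abundance <- function(path, delim = NULL) {
  df <- read_delim_guess(path, delim)
  as_community(as.data.frame(df))
}

#' Read a trait table with an optional sidecar type map
#'
#' The trait file has species in rows (first column the label) and traits in
#' columns. `types` may be a named vector or the path to a JSON file mapping
#' trait names to `"quantitative"`, `"categorical"` or `"binary"`.
#'
#' @inheritParams read_distance
#' @param types Named character vector or JSON file path.
#' @return A list with `traits` (data frame) and `types` (named character
#'   vector or `NULL`), ready for [gower_distance()].
#' @export
read_traits <- function(path, types = NULL, delim = NULL) {
  df <- as.data.frame(read_delim_guess(path, delim))
  if (is.character(types) && length(types) == 1 && file.exists(types)) {
    types <- unlist(jsonlite::read_json(types, simplifyVector = TRUE))
  }
  list(traits = df, types = types)
}

read_delim_guess <- function(path, delim = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "funhill_error_input")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Write results in long format
#'
#' Writes any of the package's result tibbles to CSV (as-is, full precision)
#' or JSON (records orientation). The tibbles already carry the metadata
#' needed to re-identify every number (measure/class, q, scheme, assemblage
#' or comparison).
#'
#' @param x A result tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default inferred from the extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    readr::write_csv(as.data.frame(x), path)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a distance matrix to CSV/TSV
#'
#' @param dist Distance matrix.
#' @param path Output path.
#' @param delim Field delimiter (default by extension).
#' @return `path`, invisibly.
#' @export
write_distance <- function(dist, path, delim = NULL) {
  dm <- as_fun_dist(dist)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- data.frame(species = rownames(dm), dm, check.names = FALSE)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Write a community matrix to CSV/TSV
#'
#' @param data Community matrix or data frame.
#' @inheritParams write_distance
#' @return `path`, invisibly.
#' @export
write_abundance <- function(data, path, delim = NULL) {
  z <- as_community(data, drop_empty_species = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- data.frame(species = rownames(z), z, check.names = FALSE)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}
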