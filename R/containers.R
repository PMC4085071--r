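## Input containers: species pairwise distance matrices, community abundance
## matrices and abundance vectors. All alignment between abundances and
## distances is by species label, never by position.

#' Validate and coerce a species pairwise distance matrix
#'
#' A distance matrix is a square, symmetric, nonnegative numeric matrix whose
#' row and column names are species labels. The diagonal carries intraspecific
#' distances and is zero in the usual case of no intraspecific variability;
#' nonzero diagonals are carried through every computation.
#'
#' @param x A square numeric matrix, or a data frame whose first column holds
#'   species labels and whose remaining columns form the square numeric body.
#' @param tol Relative tolerance for the symmetry check. Entries `(i, j)` and
#'   `(j, i)` differing by more than `tol` (relative to their magnitude) make
#'   the input invalid.
#' @param symmetrize If `"mean"`, an asymmetric matrix is replaced by
#'   `(x + t(x)) / 2` instead of raising an error. The default (`NULL`) treats
#'   asymmetry beyond `tol` as an error.
#'
#' @return A validated numeric matrix with identical row and column names.
#' @export
#'
#' @examples
#' d <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' as_fun_dist(d)
as_fun_dist <- function(x, tol = 1e-10, symmetrize = NULL) {
  if (is.data.frame(x)) {
    labs <- as.character(x[[1]])
    body <- as.matrix(x[, -1, drop = FALSE])
    rownames(body) <- labs
    x <- body
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("A distance matrix must be a numeric matrix.", class = "funhill_error_input")
  }
  if (nrow(x) != ncol(x)) {
    abort(sprintf("Distance matrix must be square; got %d x %d.", nrow(x), ncol(x)),
          class = "funhill_error_input")
  }
  if (is.null(rownames(x)) && is.null(colnames(x))) {
    rownames(x) <- colnames(x) <- paste0("sp", seq_len(nrow(x)))
  } else if (is.null(rownames(x))) {
    rownames(x) <- colnames(x)
  } else if (is.null(colnames(x))) {
    colnames(x) <- rownames(x)
  }
  if (!identical(rownames(x), colnames(x))) {
    abort("Row and column labels of a distance matrix must match.",
          class = "funhill_error_input")
  }
  if (anyDuplicated(rownames(x))) {
    abort("Duplicate species labels in distance matrix.", class = "funhill_error_input")
  }
  if (anyNA(x)) {
    abort("Distance matrix contains missing values.", class = "funhill_error_input")
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("Distances must be nonnegative; entry (%s, %s) is negative.",
                  rownames(x)[bad[1]], colnames(x)[bad[2]]),
          class = "funhill_error_input")
  }
  asym <- abs(x - t(x))
  scale <- pmax(abs(x), abs(t(x)), 1)
  if (any(asym > tol * scale)) {
    if (identical(symmetrize, "mean")) {
      x <- (x + t(x)) / 2
    } else {
      bad <- which(asym > tol * scale, arr.ind = TRUE)[1, ]
      bad <- c(min(bad), max(bad))
      abort(sprintf(
        "Distance matrix is asymmetric at (%s, %s): %g vs %g. Use symmetrize = \"mean\" to average.",
        rownames(x)[bad[1]], colnames(x)[bad[2]], x[bad[1], bad[2]], x[bad[2], bad[1]]),
        class = "funhill_error_asymmetry")
    }
  }
  x
}

#' Coerce community data to a species-by-assemblage abundance matrix
#'
#' Accepts the shapes community data usually arrives in and returns a plain
#' numeric matrix with species as rows (rownames) and assemblages as columns
#' (colnames). Abundances may be counts, biomass, cover or relative
#' abundances; they must be nonnegative and every assemblage must contain at
#' least one individual.
#'
#' @param x A data frame whose first column holds species labels and whose
#'   remaining columns are assemblage abundances; a numeric matrix with
#'   species rownames; or a (named) numeric vector for a single assemblage.
#' @param drop_empty_species Drop species whose total abundance is zero
#'   (default `TRUE`).
#'
#' @return A numeric S x N matrix with species and assemblage labels.
#' @export
#'
#' @examples
#' df <- data.frame(species = c("a", "b"), site1 = c(3, 1), site2 = c(0, 2))
#' as_community(df)
as_community <- function(x, drop_empty_species = TRUE) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      labs <- as.character(first)
      z <- as.matrix(x[, -1, drop = FALSE])
      rownames(z) <- labs
    } else {
      z <- as.matrix(x)
      if (is.null(rownames(z))) {
        abort("Community data frame needs a species label column or rownames.",
              class = "funhill_error_input")
      }
    }
  } else if (is.matrix(x)) {
    z <- x
  } else if (is.numeric(x)) {
    z <- matrix(x, ncol = 1, dimnames = list(names(x), "assemblage"))
  } else {
    abort("Cannot interpret community input.", class = "funhill_error_input")
  }
  if (!is.numeric(z)) {
    abort("Community abundances must be numeric.", class = "funhill_error_input")
  }
  if (is.null(rownames(z))) rownames(z) <- paste0("sp", seq_len(nrow(z)))
  if (is.null(colnames(z))) colnames(z) <- paste0("assemblage", seq_len(ncol(z)))
  if (anyDuplicated(rownames(z))) {
    abort("Duplicate species labels in community data.", class = "funhill_error_input")
  }
  if (anyNA(z)) {
    abort("Community data contain missing values.", class = "funhill_error_input")
  }
  if (any(z < 0)) {
    abort("Abundances must be nonnegative.", class = "funhill_error_input")
  }
  if (any(colSums(z) <= 0)) {
    empty <- colnames(z)[colSums(z) <= 0]
    abort(paste0("Assemblage(s) with zero total abundance: ",
                 paste(empty, collapse = ", ")),
          class = "funhill_error_input")
  }
  if (drop_empty_species && any(rowSums(z) == 0)) {
    z <- z[rowSums(z) > 0, , drop = FALSE]
  }
  z
}

## Coerce a single-assemblage abundance input to a named nonnegative vector.
as_abundance <- function(p) {
  if (is.data.frame(p)) {
    z <- as_community(p)
    if (ncol(z) != 1) {
      abort("Expected a single assemblage; got several columns.",
            class = "funhill_error_input")
    }
    p <- setNames(z[, 1], rownames(z))
  }
  if (!is.numeric(p)) {
    abort("Abundances must be numeric.", class = "funhill_error_input")
  }
  if (anyNA(p)) abort("Abundances contain missing values.", class = "funhill_error_input")
  if (any(p < 0)) abort("Abundances must be nonnegative.", class = "funhill_error_input")
  if (sum(p) <= 0) abort("At least one abundance must be positive.", class = "funhill_error_input")
  if (is.null(names(p))) names(p) <- paste0("sp", seq_along(p))
  p
}

## Normalize to relative abundances.
rel_ab <- function(p) p / sum(p)

## Align a labelled abundance vector with a distance matrix: every species in
## p must appear in the matrix; the matrix is subset and reordered to p.
align_dist <- function(p, dm) {
  missing <- setdiff(names(p), rownames(dm))
  if (length(missing)) {
    abort(paste0("Species absent from the distance matrix: ",
                 paste(missing, collapse = ", ")),
          class = "funhill_error_alignment")
  }
  dm[names(p), names(p), drop = FALSE]
}

## Align a community matrix with a distance matrix. Species in the community
## but not in the matrix are a hard error; matrix species not in the
## community are dropped with a warning.
align_community <- function(z, dm) {
  missing <- setdiff(rownames(z), rownames(dm))
  if (length(missing)) {
    abort(paste0("Species absent from the distance matrix: ",
                 paste(missing, collapse = ", ")),
          class = "funhill_error_alignment")
  }
  extra <- setdiff(rownames(dm), rownames(z))
  if (length(extra)) {
    warn(paste0("Dropping ", length(extra),
                " distance-matrix species not present in the community data."))
  }
  dm[rownames(z), rownames(z), drop = FALSE]
}

check_q <- function(q) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0)) {
    abort("The diversity order q must be a nonnegative number.",
          class = "funhill_error_domain")
  }
  q
}
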