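## Trait handling: Gower mixed-variable distances and distance-matrix
## diagnostics.

#' Gower distance matrix from a mixed trait table
#'
#' Computes the Gower coefficient of distance between species from a table
#' of quantitative, categorical and binary traits with equal (or supplied)
#' weights: `d_ij = sum_t w_t delta_t(i, j) / sum_t w_t` over the traits
#' observed for both species, where `delta` is `|x_i - x_j| / range_t` for a
#' quantitative trait and a 0/1 mismatch indicator otherwise. Distances lie
#' in `[0, 1]` with a zero diagonal. Missing trait values are handled by
#' pairwise deletion: the weight normalization uses only the traits jointly
#' observed for a pair.
#'
#' Quantitative ranges are computed over the whole supplied table. A
#' quantitative trait with zero range carries no information and is dropped
#' with a warning. Ordered factors are treated as plain categorical with a
#' warning. A species pair with no jointly observed trait has no defined
#' distance and is an error.
#'
#' @param traits A data frame whose first column holds species labels (or a
#'   data frame / matrix with species rownames); remaining columns are
#'   traits.
#' @param types Optional named character vector mapping trait names to
#'   `"quantitative"`, `"categorical"` or `"binary"`. Defaults are inferred:
#'   numeric columns are quantitative, everything else categorical.
#' @param weights Optional nonnegative trait weights (named or in column
#'   order); default equal.
#' @return A distance matrix as returned by [as_fun_dist()].
#' @export
#'
#' @examples
#' tt <- data.frame(species = c("a", "b"), height = c(0, 5), woody = c("y", "n"))
#' gower_distance(tt) # (0.5 * |0-5|/5 + 0.5 * 1) with range 5 -> 1
gower_distance <- function(traits, types = NULL, weights = NULL) {
  if (is.matrix(traits)) traits <- as.data.frame(traits)
  if (!is.data.frame(traits)) {
    abort("Trait input must be a data frame.", class = "funhill_error_input")
  }
  first <- traits[[1]]
  if (is.character(first) || is.factor(first)) {
    labs <- as.character(first)
    tt <- traits[, -1, drop = FALSE]
  } else {
    labs <- rownames(traits)
    if (is.null(labs)) {
      abort("Trait table needs a species label column or rownames.",
            class = "funhill_error_input")
    }
    tt <- traits
  }
  if (anyDuplicated(labs)) {
    abort("Duplicate species labels in trait table.", class = "funhill_error_input")
  }
  if (ncol(tt) < 1) {
    abort("At least one trait is required.", class = "funhill_error_input")
  }
  S <- length(labs)

  trait_type <- vapply(names(tt), function(nm) {
    if (!is.null(types) && nm %in% names(types)) {
      ty <- match.arg(types[[nm]], c("quantitative", "categorical", "binary", "ordinal"))
      if (ty == "ordinal") {
        warn(sprintf("Ordinal trait '%s' treated as categorical.", nm))
        ty <- "categorical"
      }
      ty
    } else if (is.ordered(tt[[nm]])) {
      warn(sprintf("Ordered factor '%s' treated as categorical.", nm))
      "categorical"
    } else if (is.numeric(tt[[nm]])) {
      "quantitative"
    } else if (is.logical(tt[[nm]])) {
      "binary"
    } else {
      "categorical"
    }
  }, character(1))

  if (is.null(weights)) {
    weights <- rep(1, ncol(tt))
  } else if (!is.null(names(weights))) {
    weights <- weights[names(tt)]
  }
  if (length(weights) != ncol(tt) || anyNA(weights) || any(weights < 0)) {
    abort("Weights must be nonnegative, one per trait.", class = "funhill_error_input")
  }

  ## Per-trait dissimilarity (S x S) and observation indicator.
  num <- matrix(0, S, S)
  den <- matrix(0, S, S)
  keep <- rep(TRUE, ncol(tt))
  for (t in seq_along(tt)) {
    xv <- tt[[t]]
    if (trait_type[t] == "quantitative") {
      x <- as.numeric(xv)
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng)) {
        abort(sprintf("Quantitative trait '%s' has no finite range.", names(tt)[t]),
              class = "funhill_error_input")
      }
      if (rng == 0) {
        warn(sprintf("Quantitative trait '%s' has zero range; dropped.", names(tt)[t]))
        keep[t] <- FALSE
        next
      }
      delta <- abs(outer(x, x, "-")) / rng
    } else {
      x <- as.character(xv)
      delta <- outer(x, x, "!=") * 1
    }
    obs <- !is.na(xv)
    joint <- outer(obs, obs, "&")
    delta[!joint] <- 0
    num <- num + weights[t] * delta
    den <- den + weights[t] * joint
  }
  if (!any(keep)) {
    abort("No usable traits remain.", class = "funhill_error_input")
  }
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] != bad[, 2], , drop = FALSE]
    if (nrow(bad)) {
      pair <- sort(bad[1, ])
      abort(sprintf("Species pair (%s, %s) has no jointly observed trait.",
                    labs[pair[1]], labs[pair[2]]),
            class = "funhill_error_input")
    }
    den[den == 0] <- 1 # species with all traits missing vs itself: distance 0
  }
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(labs, labs)
  as_fun_dist((d + t(d)) / 2) # exact symmetry against float noise
}

#' Test whether a distance matrix is ultrametric
#'
#' A matrix is ultrametric when every triple of species satisfies
#' `d(x, y) <= max(d(x, z), d(y, z))`. Trait-derived (e.g. Gower) matrices
#' generally are not, which is precisely the regime where the legacy
#' maximum-distance species equivalents misbehave.
#'
#' @param dist Distance matrix.
#' @param tol Absolute tolerance for the triple inequality.
#' @param max_violations Maximum number of violating triples to report.
#' @return `TRUE` or `FALSE`, with attribute `violations`: a tibble of up to
#'   `max_violations` violating triples (`i`, `j`, `k`, `d_ij`, `max_other`).
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' is_ultrametric(ex$case_i)  # TRUE
#' is_ultrametric(ex$case_ii) # FALSE
is_ultrametric <- function(dist, tol = 1e-8, max_violations = 10) {
  dm <- as_fun_dist(dist)
  S <- nrow(dm)
  viol <- list()
  if (S >= 3) {
    for (i in seq_len(S - 1)) {
      for (j in seq(i + 1, S)) {
        others <- setdiff(seq_len(S), c(i, j))
        m <- pmax(dm[i, others], dm[j, others])
        bad <- which(dm[i, j] > m + tol)
        for (b in bad) {
          if (length(viol) >= max_violations) break
          k <- others[b]
          viol[[length(viol) + 1]] <- tibble(
            i = rownames(dm)[i], j = rownames(dm)[j], k = rownames(dm)[k],
            d_ij = dm[i, j], max_other = m[b])
        }
      }
    }
  }
  ok <- length(viol) == 0
  attr(ok, "violations") <- if (ok) {
    tibble(i = character(), j = character(), k = character(),
           d_ij = numeric(), max_other = numeric())
  } else {
    dplyr::bind_rows(viol)
  }
  ok
}
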