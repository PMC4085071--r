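## Single-assemblage diversity measures: Hill numbers, Rao's quadratic
## entropy, FAD, functional Hill numbers and the mean/total functional
## diversities built from them, plus the legacy quadratic-entropy measures
## kept for comparison.

#' Hill number (effective number of species) of order q
#'
#' `(sum p_i^q)^(1/(1-q))` over species with positive abundance; at `q = 1`
#' the limit `exp(-sum p_i log p_i)`. Order 0 is species richness, order 1
#' the exponential of Shannon entropy, order 2 the inverse Simpson
#' concentration.
#'
#' @param p Abundance vector (any nonnegative scale; normalized internally).
#' @param q Nonnegative diversity order (scalar).
#' @return The effective number of species, between 1 and `S`.
#' @export
#'
#' @examples
#' hill_number(c(0.5, 0.25, 0.25), q = 0) # richness: 3
#' hill_number(c(0.5, 0.25, 0.25), q = 2) # inverse Simpson: 2.667
hill_number <- function(p, q) {
  p <- as_abundance(p)
  check_q(q)
  stopifnot(length(q) == 1)
  p <- rel_ab(p)
  p <- p[p > 0]
  if (q == 1) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Rao's quadratic entropy
#'
#' The abundance-weighted mean pairwise distance
#' `Q = sum_ij d_ij p_i p_j` over all ordered species pairs, i.e. the
#' expected distance between two randomly sampled individuals. Diagonal
#' (intraspecific) distances are included; a zero diagonal contributes
#' nothing.
#'
#' @inheritParams hill_number
#' @param dist Species pairwise distance matrix (see [as_fun_dist()]).
#' @return Q, in the units of the distance matrix.
#' @export
#'
#' @examples
#' d <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' quad_entropy(c(a = 1, b = 1), d) # 0.1
quad_entropy <- function(p, dist) {
  p <- rel_ab(as_abundance(p))
  dm <- align_dist(p, as_fun_dist(dist))
  drop(t(p) %*% dm %*% p)
}

#' Functional attribute diversity (FAD)
#'
#' The plain sum of pairwise distances `sum_ij d_ij` over ordered pairs of
#' the selected species (each unordered pair therefore counted twice, and
#' the diagonal included).
#'
#' @param dist Species pairwise distance matrix.
#' @param species Optional character vector of species to include; default
#'   all species in `dist`.
#' @return Total distance.
#' @export
fad <- function(dist, species = NULL) {
  dm <- as_fun_dist(dist)
  if (is.null(species)) species <- rownames(dm)
  unknown <- setdiff(species, rownames(dm))
  if (length(unknown)) {
    abort(paste0("Unknown species: ", paste(unknown, collapse = ", ")),
          class = "funhill_error_alignment")
  }
  sum(dm[species, species])
}

## Core kernel: effective number of equally abundant, equally distinct
## species given the S^2 joint-abundance matrix P (outer product of relative
## abundances, or the cross product for a pair of assemblages) and the
## matching distance matrix. Terms with zero joint abundance are excluded;
## q = 1 dispatches to its closed-form limit exactly.
fh_kernel <- function(P, dm, Q, q) {
  pos <- P > 0
  w <- dm[pos] / Q
  pp <- P[pos]
  if (q == 1) {
    exp(-0.5 * sum(w * pp * log(pp)))
  } else {
    sum(w * pp^q)^(1 / (2 * (1 - q)))
  }
}

#' Functional Hill number of order q
#'
#' The effective number of equally abundant and (functionally) equally
#' distinct species: the size of an idealized assemblage in which every one
#' of the S^2 species pairs sits at the constant distance Q (the quadratic
#' entropy of the actual assemblage) and that matches the actual assemblage's
#' q-th power sum of pair abundances weighted by distances. When all pairwise
#' distances are equal it reduces to the ordinary Hill number.
#'
#' @inheritParams quad_entropy
#' @param q Nonnegative diversity order (scalar). `q = 1` is evaluated by its
#'   closed-form limit.
#' @return Effective species count. A single-species assemblage with zero
#'   intraspecific distance returns 1 with a warning (Q = 0 leaves the
#'   measure formally undefined); several species at Q = 0 is an error.
#' @export
func_hill <- function(p, dist, q) {
  p <- rel_ab(as_abundance(p))
  check_q(q)
  stopifnot(length(q) == 1)
  dm <- align_dist(p, as_fun_dist(dist))
  Q <- drop(t(p) %*% dm %*% p)
  if (Q <= 0) {
    if (sum(p > 0) == 1) {
      warn("Single species with zero intraspecific distance: functional Hill number set to 1.")
      return(1)
    }
    abort("Quadratic entropy is zero for a multi-species assemblage; functional measures are undefined.",
          class = "funhill_error_degenerate")
  }
  fh_kernel(outer(p, p), dm, Q, q)
}

#' Functional diversity triple at one order q
#'
#' Computes, for a single assemblage, Rao's quadratic entropy `Q`, the
#' functional Hill number `D`, the mean functional diversity `MD = Q * D`
#' (effective sum of distances from one species to all others) and the total
#' functional diversity `FD = Q * D^2` (effective total distance between
#' species). At `q = 0`, `FD` equals the FAD over the species actually
#' present; with equal abundances `FD = FAD` at every order.
#'
#' @inheritParams func_hill
#' @return A one-row tibble with columns `q`, `Q`, `D`, `MD`, `FD`.
#' @export
#'
#' @examples
#' d <- matrix(0.1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' diag(d) <- 0
#' func_triple(c(a = 1, b = 1), d, q = 0)
func_triple <- function(p, dist, q) {
  p <- rel_ab(as_abundance(p))
  dm <- align_dist(p, as_fun_dist(dist))
  Q <- drop(t(p) %*% dm %*% p)
  if (Q <= 0 && sum(p > 0) == 1) {
    warn("Single species with zero intraspecific distance: D = 1, MD = FD = 0.")
    return(tibble(q = q, Q = 0, D = 1, MD = 0, FD = 0))
  }
  D <- func_hill(p, dm, q)
  tibble(q = q, Q = Q, D = D, MD = Q * D, FD = Q * D^2)
}

#' Diversity profile of one assemblage over a grid of orders
#'
#' Evaluates [func_triple()] on a grid of orders q, yielding the profiles of
#' the functional Hill number, mean functional diversity and total functional
#' diversity, together with the ordinary Hill number at each order. All
#' measures are continuous in q.
#'
#' @inheritParams func_hill
#' @param q Nonnegative, sorted vector of orders.
#' @return A tibble of class `funhill_profile` with columns `q`, `Q`, `D`,
#'   `MD`, `FD`, `hill`.
#' @export
diversity_profile <- function(p, dist, q = seq(0, 5, by = 0.05)) {
  check_q(q)
  p <- as_abundance(p)
  dm <- as_fun_dist(dist)
  out <- purrr::map_dfr(q, function(qi) func_triple(p, dm, qi))
  out$hill <- purrr::map_dbl(q, function(qi) hill_number(p, qi))
  class(out) <- c("funhill_profile", class(out))
  out
}

#' Per-assemblage functional diversity for a community table
#'
#' Applies [func_triple()] to each assemblage column of a community table,
#' over a vector of orders q. This is the data-frame-first entry point: pipe
#' a species-by-assemblage table straight in.
#'
#' @param data Community data: a data frame whose first column holds species
#'   labels and remaining columns assemblage abundances (or a matrix with
#'   species rownames).
#' @param dist Species pairwise distance matrix.
#' @param q Vector of nonnegative orders.
#' @return A tibble of class `funhill_profile` with one row per assemblage
#'   and order: columns `assemblage`, `q`, `Q`, `D`, `MD`, `FD`, `hill`.
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' func_diversity(ex$community, ex$case_i, q = c(0, 1, 2))
func_diversity <- function(data, dist, q = c(0, 1, 2)) {
  z <- as_community(data)
  dm <- align_community(z, as_fun_dist(dist))
  check_q(q)
  out <- purrr::map_dfr(colnames(z), function(k) {
    p <- setNames(z[, k], rownames(z))
    p <- p[p > 0]
    prof <- purrr::map_dfr(q, function(qi) func_triple(p, dm[names(p), names(p)], qi))
    prof$hill <- purrr::map_dbl(q, function(qi) hill_number(p, qi))
    dplyr::bind_cols(tibble(assemblage = k)[rep(1, nrow(prof)), , drop = FALSE], prof)
  })
  class(out) <- c("funhill_profile", class(out))
  out
}

#' Distance-weighted Gini-Simpson index
#'
#' `GS_D = sum_ij d_ij p_i p_j (1 - p_i p_j)`. Linked to the total
#' functional diversity of order 2 by `FD_2 = Q^2 / (Q - GS_D)`.
#'
#' @inheritParams quad_entropy
#' @return The weighted Gini-Simpson value.
#' @export
weighted_gini_simpson <- function(p, dist) {
  p <- rel_ab(as_abundance(p))
  dm <- align_dist(p, as_fun_dist(dist))
  P <- outer(p, p)
  sum(dm * P * (1 - P))
}

#' Effective number of species with maximum distance
#'
#' The legacy transformation of the quadratic entropy to species
#' equivalents, `De = 1 / (1 - Q / d_max)`, i.e. the number of equally
#' distinct species at the maximum distance `d_max` whose quadratic entropy
#' matches Q. Only meaningful for ultrametric distance matrices.
#'
#' @param Q Quadratic entropy (nonnegative, strictly below `d_max`).
#' @param d_max Maximum distance used for scaling.
#' @return De, at least 1.
#' @export
effective_max_distance <- function(Q, d_max) {
  if (Q < 0) abort("Q must be nonnegative.", class = "funhill_error_domain")
  if (Q == 0) return(1)
  if (Q >= d_max) {
    abort(sprintf("Q (%g) must be smaller than d_max (%g); De is undefined.", Q, d_max),
          class = "funhill_error_domain")
  }
  1 / (1 - Q / d_max)
}

#' Cross-assemblage functional measures for a pair of assemblages
#'
#' Extends the quadratic entropy and the functional diversities to an
#' ordered pair of assemblages: `Q_pair = sum_ij d_ij p_i1 p_j2` is the mean
#' distance between a species of the first and a species of the second
#' assemblage; `D_pair` the effective number of equally abundant, equally
#' distinct species in each assemblage at constant cross distance `Q_pair`;
#' `FD_pair = Q_pair * D_pair^2` the effective total cross distance. At
#' `q = 0`, `FD_pair` equals `FAD_pair`, the raw sum of cross distances over
#' species present in each assemblage.
#'
#' @param p1,p2 Abundance vectors of the two assemblages (labels must appear
#'   in `dist`).
#' @inheritParams func_hill
#' @return A one-row tibble with `q`, `Q_pair`, `FAD_pair`, `D_pair`,
#'   `MD_pair`, `FD_pair`.
#' @export
func_cross_pair <- function(p1, p2, dist, q) {
  p1 <- rel_ab(as_abundance(p1))
  p2 <- rel_ab(as_abundance(p2))
  check_q(q)
  stopifnot(length(q) == 1)
  dm <- as_fun_dist(dist)
  for (nm in list(names(p1), names(p2))) {
    missing <- setdiff(nm, rownames(dm))
    if (length(missing)) {
      abort(paste0("Species absent from the distance matrix: ",
                   paste(missing, collapse = ", ")),
            class = "funhill_error_alignment")
    }
  }
  d12 <- dm[names(p1), names(p2), drop = FALSE]
  Q12 <- drop(t(p1) %*% d12 %*% p2)
  fad12 <- sum(d12[p1 > 0, p2 > 0])
  if (Q12 <= 0) {
    abort("Cross-assemblage quadratic entropy is zero; pair measures are undefined.",
          class = "funhill_error_degenerate")
  }
  D <- fh_kernel(outer(p1, p2), d12, Q12, q)
  tibble(q = q, Q_pair = Q12, FAD_pair = fad12,
         D_pair = D, MD_pair = Q12 * D, FD_pair = Q12 * D^2)
}

#' Legacy quadratic-entropy differentiation measures
#'
#' The comparison measures built from Rao's quadratic entropy: the additive
#' excess `(Q_gamma - Q_alpha) / Q_gamma`, and the two normalized
#' differentiation measures obtained after transforming gamma and alpha
#' quadratic entropies to effective species numbers with the maximum
#' distance `d_max` of the pooled matrix:
#' de Bello et al.'s `(1 - alpha_e / gamma_e) / (1 - 1/N)` and Villeger et
#' al.'s `(gamma_e / alpha_e - 1) / (N - 1)`. These behave sensibly only for
#' ultrametric matrices; the package's distance-overlap measures are the
#' recommended alternative.
#'
#' Assemblages are pooled with equal weights (each column rescaled to
#' relative abundances). `Q_alpha` is the unweighted mean of the
#' within-assemblage quadratic entropies.
#'
#' @inheritParams func_diversity
#' @param d_max_scope `"pooled"` (default) takes `d_max` as the maximum entry
#'   of the full distance matrix over the community's species;
#'   `"per_assemblage"` uses, for `Q_alpha`'s transformation, the mean of the
#'   per-assemblage maxima.
#' @return A one-row tibble: `Q_gamma`, `Q_alpha`, `d_max`, `gamma_e`,
#'   `alpha_e`, `diff_additive`, `diff_debello`, `diff_villeger`.
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' legacy_differentiation(ex$community, ex$case_i)
legacy_differentiation <- function(data, dist, d_max_scope = c("pooled", "per_assemblage")) {
  d_max_scope <- match.arg(d_max_scope)
  z <- as_community(data)
  if (ncol(z) < 2) {
    abort("At least two assemblages are required.", class = "funhill_error_input")
  }
  dm <- align_community(z, as_fun_dist(dist))
  N <- ncol(z)
  zrel <- sweep(z, 2, colSums(z), "/")
  pooled <- rowSums(zrel) / N
  Q_gamma <- drop(t(pooled) %*% dm %*% pooled)
  within <- vapply(seq_len(N), function(k) {
    pk <- zrel[, k]
    drop(t(pk) %*% dm %*% pk)
  }, numeric(1))
  Q_alpha <- mean(within)
  if (Q_gamma <= 0) {
    abort("Pooled quadratic entropy is zero; differentiation is undefined.",
          class = "funhill_error_degenerate")
  }
  d_max <- max(dm)
  gamma_e <- effective_max_distance(Q_gamma, d_max)
  alpha_dmax <- if (d_max_scope == "pooled") d_max else {
    mean(vapply(seq_len(N), function(k) {
      sp <- rownames(z)[z[, k] > 0]
      max(dm[sp, sp])
    }, numeric(1)))
  }
  alpha_e <- effective_max_distance(Q_alpha, alpha_dmax)
  tibble(
    Q_gamma = Q_gamma, Q_alpha = Q_alpha, d_max = d_max,
    gamma_e = gamma_e, alpha_e = alpha_e,
    diff_additive = (Q_gamma - Q_alpha) / Q_gamma,
    diff_debello = (1 - alpha_e / gamma_e) / (1 - 1 / N),
    diff_villeger = (gamma_e / alpha_e - 1) / (N - 1)
  )
}
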