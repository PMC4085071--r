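## Normalized similarity / differentiation measures obtained by transforming
## the beta components onto [0, 1].
##
## Two families: distance-overlap measures built from the functional beta
## diversity (FD beta, range [1, N^2]) and species-overlap measures built
## from the Hill-number beta (range [1, N]). Within each family a "local"
## class takes the perspective of a pair of (or single) assemblages and a
## "regional" class the perspective of the pooled assemblage. The q = 0 and
## q = 2 members recover Sorensen/Jaccard- and Morisita-Horn-type indices.

check_beta_range <- function(beta, lo, hi, tol = 1e-9) {
  if (beta < lo - tol || beta > hi + tol) {
    abort(sprintf("beta = %g outside its admissible range [%g, %g].", beta, lo, hi),
          class = "funhill_error_domain")
  }
  min(max(beta, lo), hi)
}

#' Local distance-overlap C*_qN
#'
#' Transforms the functional beta diversity onto `[0, 1]` from the
#' perspective of a pair of local assemblages:
#' `C* = (N^(2(1-q)) - beta^(1-q)) / (N^(2(1-q)) - 1)` for `q != 1`, and
#' `1 - log(beta) / (2 log N)` at `q = 1`. The q = 0, 1, 2 members are the
#' functional Sorensen, Horn and Morisita-Horn overlaps. Equals 1 for
#' identical assemblages (beta = 1) and 0 for completely distinct ones
#' (beta = N^2).
#'
#' @param fd_beta Functional beta diversity, in `[1, N^2]`.
#' @param N Number of assemblages.
#' @param q Nonnegative order.
#' @return Similarity in `[0, 1]`.
#' @export
local_overlap <- function(fd_beta, N, q) {
  check_q(q)
  b <- check_beta_range(fd_beta, 1, N^2)
  if (q == 1) {
    1 - log(b) / (2 * log(N))
  } else {
    (N^(2 * (1 - q)) - b^(1 - q)) / (N^(2 * (1 - q)) - 1)
  }
}

#' Regional distance-overlap U*_qN
#'
#' The pooled-assemblage counterpart of [local_overlap()]:
#' `U* = ((1/beta)^(1-q) - (1/N^2)^(1-q)) / (1 - (1/N^2)^(1-q))` for
#' `q != 1`, with the same `q = 1` limit as `C*`. The q = 0 member is the
#' functional Jaccard overlap; q = 2 the functional regional overlap.
#'
#' @inheritParams local_overlap
#' @return Similarity in `[0, 1]`.
#' @export
regional_overlap <- function(fd_beta, N, q) {
  check_q(q)
  b <- check_beta_range(fd_beta, 1, N^2)
  if (q == 1) {
    1 - log(b) / (2 * log(N))
  } else {
    ((1 / b)^(1 - q) - (1 / N^2)^(1 - q)) / (1 - (1 / N^2)^(1 - q))
  }
}

#' Functional homogeneity S*_qN
#'
#' A linear function of the inverse functional beta diversity:
#' `S* = (1/beta - 1/N^2) / (1 - 1/N^2)`. As a function of beta it matches
#' the regional overlap at q = 0 and the local overlap at q = 2.
#'
#' @inheritParams local_overlap
#' @return Similarity in `[0, 1]`.
#' @export
func_homogeneity <- function(fd_beta, N) {
  b <- check_beta_range(fd_beta, 1, N^2)
  (1 / b - 1 / N^2) / (1 - 1 / N^2)
}

#' Functional turnover complement V*_qN
#'
#' One minus the relative functional distance-turnover rate:
#' `V* = (N^2 - beta) / (N^2 - 1)`. As a function of beta it matches the
#' local overlap at q = 0 and the regional overlap at q = 2.
#'
#' @inheritParams local_overlap
#' @return Similarity in `[0, 1]`.
#' @export
func_turnover_complement <- function(fd_beta, N) {
  b <- check_beta_range(fd_beta, 1, N^2)
  (N^2 - b) / (N^2 - 1)
}

#' Abundance-based overlap measures C_qN and U_qN
#'
#' The species-overlap transformations of the ordinary Hill-number beta
#' (range `[1, N]`): the local measure
#' `C_qN = (N^(1-q) - beta^(1-q)) / (N^(1-q) - 1)` generalizes Sorensen
#' (q = 0), Horn (q = 1) and Morisita-Horn (q = 2); the regional measure
#' `U_qN = (beta^(q-1) - N^(q-1)) / (1 - N^(q-1))` generalizes Jaccard at
#' q = 0. Both share the q = 1 limit `1 - log(beta) / log(N)`.
#'
#' @param hill_beta Hill-number beta diversity, in `[1, N]`.
#' @inheritParams local_overlap
#' @return A one-row tibble with columns `q`, `C`, `U`.
#' @export
abundance_overlap <- function(hill_beta, N, q) {
  check_q(q)
  b <- check_beta_range(hill_beta, 1, N)
  if (q == 1) {
    cq <- uq <- 1 - log(b) / log(N)
  } else {
    cq <- (N^(1 - q) - b^(1 - q)) / (N^(1 - q) - 1)
    uq <- (b^(q - 1) - N^(q - 1)) / (1 - N^(q - 1))
  }
  tibble(q = q, C = cq, U = uq)
}

similarity_classes <- c("local", "regional", "homogeneity", "turnover",
                        "abundance_local", "abundance_regional")

## Transform one beta value to one similarity value.
apply_class <- function(class, beta, N, q) {
  switch(class,
    local = local_overlap(beta, N, q),
    regional = regional_overlap(beta, N, q),
    homogeneity = func_homogeneity(beta, N),
    turnover = func_turnover_complement(beta, N),
    abundance_local = abundance_overlap(beta, N, q)$C,
    abundance_regional = abundance_overlap(beta, N, q)$U
  )
}

#' Similarity and differentiation profiles for a set of assemblages
#'
#' Computes, over a grid of orders q, one or more classes of normalized
#' similarity measures for the assemblages of a community table, together
#' with their one-complement differentiation values. The functional classes
#' (`"local"`, `"regional"`, `"homogeneity"`, `"turnover"`) transform the
#' functional beta diversity; the abundance classes (`"abundance_local"`,
#' `"abundance_regional"`) transform the ordinary Hill-number beta. With
#' `pairwise = TRUE` every assemblage pair is profiled separately (N = 2 in
#' each transformation); otherwise all N assemblages are compared at once.
#'
#' @inheritParams func_partition
#' @param classes Subset of `"local"`, `"regional"`, `"homogeneity"`,
#'   `"turnover"`, `"abundance_local"`, `"abundance_regional"`.
#' @param pairwise Profile each assemblage pair separately.
#' @return A tibble of class `funhill_similarity` with columns `class`,
#'   `comparison`, `N`, `q`, `beta`, `similarity`, `differentiation`.
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' func_similarity(ex$community, ex$case_ii, q = c(0, 1, 2), classes = "local")
func_similarity <- function(data, dist, q = c(0, 1, 2),
                            classes = c("local", "regional"),
                            scheme = c("relative", "absolute"),
                            pairwise = FALSE) {
  scheme <- match.arg(scheme)
  classes <- match.arg(classes, choices = similarity_classes, several.ok = TRUE)
  z <- as_community(data)
  check_q(q)
  need_dist <- any(!classes %in% c("abundance_local", "abundance_regional"))
  dm <- if (need_dist) align_community(z, as_fun_dist(dist)) else NULL

  groups <- if (pairwise) {
    pairs <- utils::combn(colnames(z), 2, simplify = FALSE)
    setNames(pairs, vapply(pairs, paste, "", collapse = " vs "))
  } else {
    stats::setNames(list(colnames(z)), paste(colnames(z), collapse = " | "))
  }

  out <- purrr::imap_dfr(groups, function(cols, label) {
    zk <- z[, cols, drop = FALSE]
    zk <- zk[rowSums(zk) > 0, , drop = FALSE]
    N <- ncol(zk)
    purrr::map_dfr(q, function(qi) {
      betas <- list()
      if (any(!classes %in% c("abundance_local", "abundance_regional"))) {
        ga <- fd_gamma_alpha(zk, dm[rownames(zk), rownames(zk)], qi, scheme)
        betas$fd <- ga$fd_gamma / ga$fd_alpha
      }
      if (any(classes %in% c("abundance_local", "abundance_regional"))) {
        ha <- hill_gamma_alpha(zk, qi, scheme)
        betas$hill <- ha$fd_gamma / ha$fd_alpha
      }
      purrr::map_dfr(classes, function(cl) {
        beta <- if (cl %in% c("abundance_local", "abundance_regional")) betas$hill else betas$fd
        s <- apply_class(cl, beta, N, qi)
        tibble(class = cl, comparison = label, N = N, q = qi,
               beta = beta, similarity = s, differentiation = 1 - s)
      })
    })
  })
  class(out) <- c("funhill_similarity", class(out))
  out
}
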