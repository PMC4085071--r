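## Gamma/alpha/beta partitioning of the functional diversity measures and of
## ordinary Hill numbers over N assemblages.
##
## The decomposition is multiplicative: beta = gamma / alpha. The alpha
## formulas follow the "effective number per assemblage (or assemblage
## pair)" definition, which keeps gamma >= alpha for every order q >= 0 and
## every distance matrix, under either pooling scheme. Q in every functional
## formula is the quadratic entropy of the POOLED assemblage.

#' Pool a community matrix over assemblages
#'
#' Returns the pooled relative abundances `z_i+ / z_++` after applying the
#' pooling scheme. Under the `"relative"` scheme (the default, matching all
#' worked examples here) each assemblage column is first rescaled to sum to
#' one, so the total is exactly `N` and assemblages are weighted equally;
#' under `"absolute"` the raw abundances are summed, weighting assemblages
#' by their size.
#'
#' @inheritParams func_diversity
#' @param scheme `"relative"` or `"absolute"`.
#' @return A tibble with columns `species` and `p` (pooled relative
#'   abundance, summing to 1).
#' @export
pool_abundances <- function(data, scheme = c("relative", "absolute")) {
  z <- scheme_matrix(as_community(data), match.arg(scheme))
  tibble(species = rownames(z), p = unname(rowSums(z) / sum(z)))
}

## Apply the pooling scheme to the raw community matrix.
scheme_matrix <- function(z, scheme) {
  if (scheme == "relative") sweep(z, 2, colSums(z), "/") else z
}

## Internal workhorse: gamma/alpha for one functional measure family at one
## order q. Returns FD gamma/alpha plus the pooled Q; D and MD components
## are derived from them (D_alpha = sqrt(FD_alpha / Q) etc.), which makes
## the identities FD_beta = D_beta^2 and D_beta = MD_beta exact.
fd_gamma_alpha <- function(z, dm, q, scheme) {
  z <- scheme_matrix(z, scheme)
  N <- ncol(z)
  a <- z / sum(z)                      # z_ik / z_++
  u <- rowSums(a)                      # z_i+ / z_++ : pooled relative abundances
  Q <- drop(t(u) %*% dm %*% u)
  if (Q <= 0) {
    abort("Pooled quadratic entropy is zero; functional decomposition is undefined.",
          class = "funhill_error_degenerate")
  }
  W <- dm / Q
  if (q == 1) {
    U <- outer(u, u)
    pos <- U > 0
    gamma <- Q * exp(-sum(W[pos] * U[pos] * log(U[pos])))
    ## sum over (i,k),(j,m): W_ij a_ik a_jm log(a_ik a_jm)
    ##   = sum_ij W_ij (v_i u_j + u_i v_j), with v_i = sum_k a_ik log a_ik
    v <- vapply(seq_len(nrow(a)), function(i) {
      ai <- a[i, ]
      ai <- ai[ai > 0]
      sum(ai * log(ai))
    }, numeric(1))
    alpha <- (Q / N^2) * exp(-(drop(t(v) %*% W %*% u) + drop(t(u) %*% W %*% v)))
  } else {
    U <- outer(u, u)
    pos <- U > 0
    gamma <- Q * sum(W[pos] * U[pos]^q)^(1 / (1 - q))
    r <- rowSums(a^q * (a > 0))        # sum over assemblages of positive terms
    alpha <- (Q / N^2) * drop(t(r) %*% W %*% r)^(1 / (1 - q))
  }
  list(Q = Q, N = N, fd_gamma = gamma, fd_alpha = alpha)
}

## Internal: Hill-number gamma/alpha at one order q.
hill_gamma_alpha <- function(z, q, scheme) {
  z <- scheme_matrix(z, scheme)
  N <- ncol(z)
  a <- z / sum(z)
  u <- rowSums(a)
  gamma <- hill_number(u, q)
  apos <- a[a > 0]
  alpha <- if (q == 1) {
    exp(-sum(apos * log(apos))) / N
  } else {
    sum(apos^q)^(1 / (1 - q)) / N
  }
  list(Q = NA_real_, N = N, fd_gamma = gamma, fd_alpha = alpha)
}

#' Partition diversity into gamma, alpha and beta components
#'
#' Multiplicative decomposition of the total functional diversity (`FD`),
#' functional Hill number (`D`), mean functional diversity (`MD`) and
#' ordinary Hill number (`Hill`) of the pooled assemblage over the N
#' assemblages of a community table. For `FD`, beta lies in `[1, N^2]` and
#' equals the effective number of completely distinct assemblage pairs; for
#' `D`, `MD` and `Hill`, beta lies in `[1, N]`. The beta components of `D`
#' and `MD` are identical and equal `sqrt(FD beta)`.
#'
#' @inheritParams func_diversity
#' @inheritParams pool_abundances
#' @param measures Subset of `c("FD", "D", "MD", "Hill")`.
#' @return An object of class `func_partition`; use [tidy()] for the long
#'   table of components and [glance()] for a one-row summary.
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' tidy(func_partition(ex$community, ex$case_i, q = c(0, 1, 2)))
func_partition <- function(data, dist, q = c(0, 1, 2),
                           scheme = c("relative", "absolute"),
                           measures = c("FD", "D", "MD", "Hill")) {
  scheme <- match.arg(scheme)
  measures <- match.arg(measures, several.ok = TRUE)
  z <- as_community(data)
  if (ncol(z) < 2) {
    abort("At least two assemblages are required for a decomposition.",
          class = "funhill_error_input")
  }
  check_q(q)
  need_dist <- any(measures != "Hill")
  dm <- if (need_dist) align_community(z, as_fun_dist(dist)) else NULL
  N <- ncol(z)

  rows <- purrr::map_dfr(q, function(qi) {
    out <- list()
    if (need_dist) {
      ga <- fd_gamma_alpha(z, dm, qi, scheme)
      fd_beta <- ga$fd_gamma / ga$fd_alpha
      if ("FD" %in% measures) {
        out <- c(out, list(tibble(measure = "FD", q = qi, scheme = scheme,
                                  gamma = ga$fd_gamma, alpha = ga$fd_alpha,
                                  beta = fd_beta, Q_pooled = ga$Q)))
      }
      d_beta <- sqrt(fd_beta)
      if ("D" %in% measures) {
        d_gamma <- sqrt(ga$fd_gamma / ga$Q)
        out <- c(out, list(tibble(measure = "D", q = qi, scheme = scheme,
                                  gamma = d_gamma, alpha = d_gamma / d_beta,
                                  beta = d_beta, Q_pooled = ga$Q)))
      }
      if ("MD" %in% measures) {
        md_gamma <- sqrt(ga$fd_gamma * ga$Q)
        out <- c(out, list(tibble(measure = "MD", q = qi, scheme = scheme,
                                  gamma = md_gamma, alpha = md_gamma / d_beta,
                                  beta = d_beta, Q_pooled = ga$Q)))
      }
    }
    if ("Hill" %in% measures) {
      ha <- hill_gamma_alpha(z, qi, scheme)
      out <- c(out, list(tibble(measure = "Hill", q = qi, scheme = scheme,
                                gamma = ha$fd_gamma, alpha = ha$fd_alpha,
                                beta = ha$fd_gamma / ha$fd_alpha,
                                Q_pooled = NA_real_)))
    }
    dplyr::bind_rows(out)
  })

  structure(
    list(components = rows, N = N, S = nrow(z), scheme = scheme,
         q = q, measures = measures,
         Q_pooled = if (need_dist) rows$Q_pooled[which(!is.na(rows$Q_pooled))[1]] else NA_real_,
         assemblages = colnames(z)),
    class = "func_partition"
  )
}

#' @export
print.func_partition <- function(x, ...) {
  cat("Functional diversity partition (", x$N, " assemblages, ", x$S,
      " species, scheme = ", x$scheme, ")\n", sep = "")
  print(x$components, ...)
  invisible(x)
}

#' Tidy a diversity partition
#'
#' @param x A `func_partition` object.
#' @param ... Unused.
#' @return A tibble with one row per measure and order: `measure`, `q`,
#'   `scheme`, `gamma`, `alpha`, `beta`, `Q_pooled`.
#' @export
tidy.func_partition <- function(x, ...) x$components

#' One-row summary of a diversity partition
#'
#' @inheritParams tidy.func_partition
#' @return A one-row tibble with `N`, `S`, `scheme` and the pooled quadratic
#'   entropy.
#' @export
glance.func_partition <- function(x, ...) {
  tibble(N = x$N, S = x$S, scheme = x$scheme,
         Q_pooled = unname(x$Q_pooled), n_orders = length(x$q))
}

#' Partition ordinary Hill numbers over assemblages
#'
#' Convenience wrapper around [func_partition()] for the abundance-only
#' decomposition: gamma is the Hill number of the pooled assemblage, alpha
#' the effective number of species per assemblage, and beta their ratio in
#' `[1, N]`.
#'
#' @inheritParams func_partition
#' @return A tibble with `measure`, `q`, `scheme`, `gamma`, `alpha`, `beta`.
#' @export
#'
#' @examples
#' z <- example1_communities()
#' hill_partition(z, q = 0)
hill_partition <- function(data, q = c(0, 1, 2), scheme = c("relative", "absolute")) {
  fit <- func_partition(data, dist = NULL, q = q, scheme = match.arg(scheme),
                        measures = "Hill")
  dplyr::select(tidy(fit), -"Q_pooled")
}

#' Functional evenness ratios
#'
#' Evenness of the functional diversity profile: the ratio of the total
#' functional diversity at order q to its order-0 value (functional
#' richness), and the same ratio on the log scale. Both equal 1 for equally
#' abundant species and are at most 1 for q > 0.
#'
#' @inheritParams func_hill
#' @param q Vector of positive orders.
#' @return A tibble with `q`, `FD`, `FD0`, `evenness` (`FD / FD0`) and
#'   `log_evenness` (`log FD / log FD0`; `NA` when `FD0 <= 1`, where the
#'   log ratio is undefined).
#' @export
func_evenness <- function(p, dist, q = c(1, 2)) {
  check_q(q)
  if (any(q <= 0)) {
    abort("Evenness ratios are defined for q > 0 only.", class = "funhill_error_domain")
  }
  p <- as_abundance(p)
  dm <- as_fun_dist(dist)
  fd0 <- func_triple(p, dm, 0)$FD
  purrr::map_dfr(q, function(qi) {
    fdq <- func_triple(p, dm, qi)$FD
    tibble(q = qi, FD = fdq, FD0 = fd0,
           evenness = fdq / fd0,
           log_evenness = if (fd0 > 1) log(fdq) / log(fd0) else NA_real_)
  })
}
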