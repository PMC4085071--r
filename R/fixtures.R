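## Generators for the worked-example inputs and for random property-test
## instances. Everything is reproducible from its arguments: the
## two-assemblage artificial layouts, the exact four-species matrices of the
## ultrametric/non-ultrametric comparison, block constructions for the
## replication principle, and seeded random communities.

#' Two-assemblage community layout with partial species overlap
#'
#' Builds the 28-species community used to study how functional distances
#' affect differentiation: two assemblages of 20 species each, sharing 12
#' species (assemblage I holds species 1-20, assemblage II species 9-28).
#' The `"equal"` variant gives every species within an assemblage relative
#' abundance 1/20. The `"heterogeneous"` variant draws within-assemblage
#' relative abundances from a lognormal species-abundance model (meanlog 0,
#' sdlog 1), normalized per assemblage.
#'
#' @param variant `"equal"` or `"heterogeneous"`.
#' @param seed Integer seed for the heterogeneous variant.
#' @return A 28 x 2 community matrix (columns sum to 1).
#' @export
example1_communities <- function(variant = c("equal", "heterogeneous"), seed = 1L) {
  variant <- match.arg(variant)
  sp <- sprintf("sp%02d", 1:28)
  z <- matrix(0, 28, 2, dimnames = list(sp, c("I", "II")))
  idx1 <- 1:20
  idx2 <- 9:28
  if (variant == "equal") {
    z[idx1, 1] <- 1 / 20
    z[idx2, 2] <- 1 / 20
  } else {
    old <- get_seed_state()
    on.exit(restore_seed_state(old), add = TRUE)
    set.seed(seed)
    a1 <- rlnorm(20)
    a2 <- rlnorm(20)
    z[idx1, 1] <- a1 / sum(a1)
    z[idx2, 2] <- a2 / sum(a2)
  }
  z
}

#' Random distance matrices for the partial-overlap layout
#'
#' Regenerates, from a seed, the two contrasting 28 x 28 distance-matrix
#' recipes used with [example1_communities()]. Type `"I"` draws every
#' off-diagonal distance from a beta(4, 4) distribution (mean 0.5), so
#' within- and pooled-assemblage distances share one distribution and the
#' alpha and gamma quadratic entropies nearly coincide. Type `"II"` draws
#' distances between the non-shared species of assemblage I (species 1-8)
#' and the non-shared species of assemblage II (species 21-28) from a
#' uniform(0.8, 1) distribution and every other off-diagonal distance from
#' uniform(0, 0.2), which pushes the gamma quadratic entropy far above
#' alpha. The published draws of these matrices came with no seed, so only
#' the distributional recipe is reproducible; exact published numbers
#' require ingesting the original matrices via [read_distance()].
#'
#' @param type `"I"` or `"II"`.
#' @param seed Integer seed.
#' @return A 28 x 28 distance matrix with zero diagonal.
#' @export
example1_matrix <- function(type = c("I", "II"), seed = 1L) {
  type <- match.arg(type)
  old <- get_seed_state()
  on.exit(restore_seed_state(old), add = TRUE)
  set.seed(seed)
  sp <- sprintf("sp%02d", 1:28)
  d <- matrix(0, 28, 28, dimnames = list(sp, sp))
  ut <- upper.tri(d)
  if (type == "I") {
    d[ut] <- rbeta(sum(ut), 4, 4)
  } else {
    d[ut] <- runif(sum(ut), 0, 0.2)
    cross <- matrix(FALSE, 28, 28)
    cross[1:8, 21:28] <- TRUE
    sel <- ut & cross
    d[sel] <- runif(sum(sel), 0.8, 1)
  }
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  as_fun_dist(d)
}

#' The four-species ultrametric / non-ultrametric example
#'
#' Two 4 x 4 distance matrices on species a, b, c, d and the matching
#' community of two completely distinct assemblages ({a, b} and {c, d},
#' species equally common within each). Within-assemblage distances are 0.1
#' (the value forced by the printed alpha quadratic entropy of 0.05 under
#' equal abundances). In the ultrametric Case I all between-assemblage
#' distances are 0.2; Case II raises d(a, c) to 0.9 and d(b, d) to 0.8,
#' which breaks ultrametricity while leaving within-assemblage structure
#' untouched.
#'
#' @return A list with elements `case_i`, `case_ii` (distance matrices) and
#'   `community` (4 x 2 matrix).
#' @export
#'
#' @examples
#' ex <- example2_fixture()
#' quad_entropy(pool_to_vector(ex$community), ex$case_i) # 0.125
example2_fixture <- function() {
  sp <- c("a", "b", "c", "d")
  ci <- matrix(0.2, 4, 4, dimnames = list(sp, sp))
  ci["a", "b"] <- ci["b", "a"] <- 0.1
  ci["c", "d"] <- ci["d", "c"] <- 0.1
  diag(ci) <- 0
  cii <- ci
  cii["a", "c"] <- cii["c", "a"] <- 0.9
  cii["b", "d"] <- cii["d", "b"] <- 0.8
  z <- matrix(0, 4, 2, dimnames = list(sp, c("I", "II")))
  z[c("a", "b"), "I"] <- 0.5
  z[c("c", "d"), "II"] <- 0.5
  list(case_i = as_fun_dist(ci), case_ii = as_fun_dist(cii), community = z)
}

#' Pooled abundance vector (equal-weight) as a named vector
#'
#' Convenience accessor: equal-weight pooled relative abundances of a
#' community matrix as a named vector, ready for the single-assemblage
#' measures.
#'
#' @inheritParams func_diversity
#' @return Named numeric vector summing to 1.
#' @export
pool_to_vector <- function(data) {
  pooled <- pool_abundances(data, scheme = "relative")
  setNames(pooled$p, pooled$species)
}

#' Replicated completely distinct assemblages
#'
#' Builds the block construction behind the replication principle: N
#' relabelled copies of a base assemblage, with a pooled distance matrix
#' whose every S x S block (within and between copies) equals the base
#' matrix. All within- and cross-assemblage quadratic entropies then
#' coincide, and pooling the N equally large copies multiplies the
#' functional Hill number and mean functional diversity by N and the total
#' functional diversity by N^2.
#'
#' @param p Base abundance vector.
#' @param dist Base distance matrix.
#' @param N Number of copies (>= 2).
#' @return A list with `community` (NS x N matrix) and `dist` (NS x NS block
#'   matrix).
#' @export
replicated_disjoint <- function(p, dist, N) {
  stopifnot(N >= 2)
  p <- rel_ab(as_abundance(p))
  dm <- align_dist(p, as_fun_dist(dist))
  S <- length(p)
  labs <- as.vector(vapply(seq_len(N), function(k) paste0(names(p), "_rep", k),
                           character(S)))
  z <- matrix(0, S * N, N, dimnames = list(labs, paste0("rep", seq_len(N))))
  for (k in seq_len(N)) z[(k - 1) * S + seq_len(S), k] <- p
  big <- matrix(0, S * N, S * N, dimnames = list(labs, labs))
  for (k in seq_len(N)) {
    for (m in seq_len(N)) {
      big[(k - 1) * S + seq_len(S), (m - 1) * S + seq_len(S)] <- dm
    }
  }
  list(community = z, dist = as_fun_dist(big))
}

#' Random community and distance matrix for property tests
#'
#' Seeded generator of valid random inputs: uniform(0, 1) off-diagonal
#' distances (symmetric, zero diagonal) and uniform abundances with a
#' controllable fraction of structural zeros (every assemblage keeps at
#' least one positive species).
#'
#' @param S Number of species (>= 2).
#' @param N Number of assemblages.
#' @param seed Integer seed.
#' @param sparsity Expected fraction of zero abundances in `[0, 1)`.
#' @return A list with `community` (S x N) and `dist` (S x S).
#' @export
random_instance <- function(S, N = 2, seed = 1L, sparsity = 0) {
  stopifnot(S >= 2, N >= 1, sparsity >= 0, sparsity < 1)
  old <- get_seed_state()
  on.exit(restore_seed_state(old), add = TRUE)
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(S))
  d <- matrix(0, S, S, dimnames = list(sp, sp))
  d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0.05, 1)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  z <- matrix(runif(S * N, 0.1, 1), S, N,
              dimnames = list(sp, paste0("A", seq_len(N))))
  if (sparsity > 0) {
    z[matrix(runif(S * N) < sparsity, S, N)] <- 0
    for (k in seq_len(N)) if (all(z[, k] == 0)) z[sample(S, 1), k] <- runif(1, 0.1, 1)
    # keep the instance a valid multi-species community
    while (sum(rowSums(z) > 0) < 2) {
      z[sample(which(rowSums(z) == 0), 1), sample(N, 1)] <- runif(1, 0.1, 1)
    }
    z <- z[rowSums(z) > 0, , drop = FALSE]
    d <- d[rownames(z), rownames(z), drop = FALSE]
  }
  list(community = z, dist = as_fun_dist(d))
}

## Save/restore the global RNG state so fixture generators do not disturb
## the caller's random stream.
get_seed_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
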