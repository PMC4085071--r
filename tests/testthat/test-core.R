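# Single-assemblage measures: Hill numbers, quadratic entropy, FAD,
# functional Hill numbers and the derived mean/total functional diversity.

test_that("hill_number matches closed forms and direct sums", {
  expect_equal(hill_number(c(0.25, 0.25, 0.25, 0.25), 2), 4)
  expect_equal(hill_number(c(0.5, 0.25, 0.25), 0), 3)
  expect_equal(hill_number(c(0.5, 0.25, 0.25), 2), 1 / 0.375, tolerance = 1e-12)
  expect_equal(hill_number(c(0.6, 0.4), 1),
               exp(-(0.6 * log(0.6) + 0.4 * log(0.4))), tolerance = 1e-12)
  # raw counts are normalized internally
  expect_equal(hill_number(c(a = 30, b = 20), 1), hill_number(c(0.6, 0.4), 1))
  expect_error(hill_number(c(-1, 2), 1), class = "funhill_error_input")
  expect_error(hill_number(c(0.5, 0.5), -1), class = "funhill_error_domain")
})

test_that("quadratic entropy is the abundance-weighted mean pairwise distance", {
  ex <- example2_fixture()
  p <- rep(0.25, 4)
  names(p) <- c("a", "b", "c", "d")
  expect_equal(quad_entropy(p, ex$case_i), 0.125)
  expect_equal(quad_entropy(p, ex$case_ii), 0.2875)
  # constant distance for ALL pairs (diagonal included) returns the constant
  expect_equal(quad_entropy(c(x = 2, y = 3), const_dist(c("x", "y"), 0.42)), 0.42)
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(quad_entropy(c(a = 0.5, b = 0.5), d2), 0.1)
  expect_error(quad_entropy(c(a = 1, zz = 1), d2), class = "funhill_error_alignment")
})

test_that("fad sums ordered pairwise distances over the selected species", {
  ex <- example2_fixture()
  expect_equal(fad(ex$case_i), 2.0)
  expect_equal(fad(ex$case_ii), 4.6)
  expect_equal(fad(ex$case_i, c("a", "b")), 0.2)
  expect_equal(fad(ex$case_i, "a"), 0)
  expect_error(fad(ex$case_i, c("a", "nope")), class = "funhill_error_alignment")
})

test_that("functional Hill number: equal abundances give S, q = 0 gives sqrt(FAD/Q)", {
  ex <- example2_fixture()
  p <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  expect_equal(func_hill(p, ex$case_i, 2), 4, tolerance = 1e-10)
  expect_equal(func_hill(p, ex$case_ii, 2), 4, tolerance = 1e-10)
  expect_equal(func_hill(p, ex$case_i, 0), sqrt(2.0 / 0.125), tolerance = 1e-10)
  # reduction: constant distances for all pairs -> ordinary Hill numbers
  p2 <- c(x = 0.6, y = 0.4)
  d <- const_dist(c("x", "y"))
  for (q in c(0, 0.5, 1, 2, 3)) {
    expect_equal(func_hill(p2, d, q), hill_number(p2, q), tolerance = 1e-9)
  }
})

test_that("degenerate quadratic entropy handled per convention", {
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_warning(out <- func_hill(c(a = 1), d1, q = 0), "zero intraspecific")
  expect_equal(out, 1)
  expect_warning(tr <- func_triple(c(a = 1), d1, 2), "zero intraspecific")
  expect_equal(tr$FD, 0)
  d2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(func_hill(c(a = 1, b = 1), d2, q = 2), class = "funhill_error_degenerate")
})

test_that("functional triple satisfies MD = Q*D and FD = Q*D^2 with q = 0 closed forms", {
  ex <- example2_fixture()
  p <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  tr <- func_triple(p, ex$case_i, 0)
  expect_equal(tr$Q, 0.125)
  expect_equal(tr$D, 4)
  expect_equal(tr$MD, 0.5)
  expect_equal(tr$FD, 2.0)
  # two species at distance 1, q = 2
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- func_triple(c(a = 1, b = 1), d, 2)
  expect_equal(tr2$FD, 2, tolerance = 1e-12)
  # equal abundances: FD = FAD at every order, for any matrix
  for (q in c(0, 0.7, 1, 2, 3.5)) {
    trq <- func_triple(p, ex$case_ii, q)
    expect_equal(trq$FD, fad(ex$case_ii), tolerance = 1e-9)
    expect_rel_equal(trq$MD, trq$Q * trq$D)
    expect_rel_equal(trq$FD, trq$Q * trq$D^2)
  }
})

test_that("vectorized measures agree with loop-sum oracles on random instances", {
  for (seed in 1:20) {
    inst <- random_instance(S = sample(2:6, 1), N = 1, seed = seed,
                            sparsity = ifelse(seed %% 2, 0, 0.3))
    p <- setNames(inst$community[, 1], rownames(inst$community))
    p <- p[p > 0]
    if (length(p) < 2) next
    d <- inst$dist[names(p), names(p), drop = FALSE]
    expect_rel_equal(quad_entropy(p, d), oracle_quad_entropy(p, d), 1e-10)
    for (q in c(0, 0.5, 1, 2, 3)) {
      expect_rel_equal(hill_number(p, q), oracle_hill(p, q), 1e-10)
      expect_rel_equal(func_hill(p, d, q), oracle_func_hill(p, d, q), 1e-10)
    }
  }
})

test_that("all measures are continuous across q = 1", {
  for (seed in 1:5) {
    inst <- random_instance(S = 5, N = 1, seed = seed)
    p <- setNames(inst$community[, 1], rownames(inst$community))
    at1 <- func_hill(p, inst$dist, 1)
    expect_lt(abs(func_hill(p, inst$dist, 1 + 1e-6) - at1), 1e-4)
    expect_lt(abs(func_hill(p, inst$dist, 1 - 1e-6) - at1), 1e-4)
    h1 <- hill_number(p, 1)
    expect_lt(abs(hill_number(p, 1 + 1e-6) - h1), 1e-4)
  }
})

test_that("adding a vanishingly rare species never decreases FD", {
  for (seed in 1:5) {
    inst <- random_instance(S = 5, N = 1, seed = seed)
    p <- setNames(inst$community[, 1], rownames(inst$community))
    d <- inst$dist
    # extend with one new species at random distances
    set.seed(seed + 100)
    dn <- cbind(rbind(d, new = runif(5, 0.05, 1)), new = c(runif(5, 0.05, 1), 0))
    dn <- (dn + t(dn)) / 2
    rownames(dn)[6] <- colnames(dn)[6] <- "new"
    pn <- c(p, new = sum(p) * 1e-12)
    for (q in c(0, 1, 2)) {
      fd_old <- func_triple(p, d, q)$FD
      fd_new <- func_triple(pn, dn, q)$FD
      expect_gte(fd_new, fd_old - 1e-9)
    }
  }
})

test_that("weighted Gini-Simpson links to order-2 functional diversity", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- c(a = 0.5, b = 0.5)
  expect_equal(weighted_gini_simpson(p, d), 0.375)
  Q <- quad_entropy(p, d)
  expect_equal(Q^2 / (Q - weighted_gini_simpson(p, d)), 2)
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(weighted_gini_simpson(c(a = 1), d1), 0)
  # identity FD_2 * (Q - GS_D) = Q^2 on random instances
  for (seed in 1:10) {
    inst <- random_instance(S = 5, N = 1, seed = seed)
    p <- setNames(inst$community[, 1], rownames(inst$community))
    Q <- quad_entropy(p, inst$dist)
    gs <- weighted_gini_simpson(p, inst$dist)
    fd2 <- func_triple(p, inst$dist, 2)$FD
    expect_rel_equal(fd2 * (Q - gs), Q^2, 1e-10)
  }
})

test_that("maximum-distance species equivalents follow the legacy transformation", {
  expect_equal(effective_max_distance(0, 0.2), 1)
  expect_equal(effective_max_distance(0.125, 0.2), 1 / (1 - 0.625))
  expect_equal(effective_max_distance(0.2875, 0.9), 1 / (1 - 0.2875 / 0.9))
  expect_error(effective_max_distance(0.3, 0.2), class = "funhill_error_domain")
})

test_that("cross-assemblage pair measures extend Q and FAD", {
  ex <- example2_fixture()
  p1 <- c(a = 0.5, b = 0.5)
  p2 <- c(c = 0.5, d = 0.5)
  cp <- func_cross_pair(p1, p2, ex$case_i, 0)
  expect_equal(cp$Q_pair, 0.2)
  expect_equal(cp$FAD_pair, 0.8)
  expect_equal(cp$FD_pair, 0.8) # q = 0: FD_pair = FAD_pair
  # same assemblage twice reproduces the ordinary quadratic entropy
  cp11 <- func_cross_pair(p1, p1, ex$case_i, 2)
  expect_equal(cp11$Q_pair, quad_entropy(p1, ex$case_i))
  expect_rel_equal(cp11$FD_pair, cp11$Q_pair * cp11$D_pair^2)
  # completely distinct assemblages: pooled FAD is the sum of the four blocks
  fad_blocks <- func_cross_pair(p1, p1, ex$case_i, 0)$FAD_pair +
    2 * cp$FAD_pair + func_cross_pair(p2, p2, ex$case_i, 0)$FAD_pair
  expect_equal(fad_blocks, fad(ex$case_i))
})

test_that("diversity profiles are continuous and ordered in q", {
  ex <- example2_fixture()
  p <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  prof <- diversity_profile(p, ex$case_i, q = c(0, 1, 2))
  expect_equal(prof$D, rep(4, 3), tolerance = 1e-9)   # equal abundances
  expect_equal(prof$FD, rep(2, 3), tolerance = 1e-9)  # FD = FAD at all q
  # Hill profile of an uneven assemblage is non-increasing in q
  p2 <- c(a = 0.7, b = 0.2, c = 0.06, d = 0.04)
  prof2 <- diversity_profile(p2, ex$case_i, q = seq(0, 4, by = 0.5))
  expect_true(all(diff(prof2$hill) <= 1e-12))
  expect_true(all(diff(prof2$FD) <= 1e-9))
})

test_that("func_diversity runs per assemblage on a community table", {
  ex <- example2_fixture()
  df <- data.frame(species = rownames(ex$community), ex$community)
  out <- func_diversity(df, ex$case_i, q = c(0, 2))
  expect_s3_class(out, "funhill_profile")
  expect_equal(nrow(out), 4)
  within <- out[out$assemblage == "I" & out$q == 0, ]
  expect_equal(within$Q, 0.05)
  expect_equal(within$FD, 0.2) # FAD of {a, b}
})
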