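# Gamma/alpha/beta partitioning of the functional measures and Hill numbers.

test_that("pooling schemes produce the documented pooled abundances", {
  z <- example1_communities()
  pooled <- pool_abundances(z, "relative")
  shared <- sprintf("sp%02d", 9:20)
  expect_equal(unique(pooled$p[pooled$species %in% shared]), 0.05)
  expect_equal(unique(pooled$p[!pooled$species %in% shared]), 0.025)
  # identical relative columns pool to either column
  z2 <- cbind(A = c(0.3, 0.7), B = c(0.3, 0.7))
  rownames(z2) <- c("x", "y")
  expect_equal(pool_abundances(z2, "relative")$p, c(0.3, 0.7))
  # absolute scheme weights by assemblage size
  z3 <- matrix(c(10, 0, 0, 30), 2, 2, dimnames = list(c("x", "y"), c("A", "B")))
  expect_equal(pool_abundances(z3, "absolute")$p, c(0.25, 0.75))
  expect_error(as_community(cbind(A = c(0, 0))), class = "funhill_error_input")
})

test_that("functional partition of the disjoint four-species community", {
  ex <- example2_fixture()
  fit <- func_partition(ex$community, ex$case_i, q = c(0, 1, 2))
  td <- tidy(fit)
  fd <- td[td$measure == "FD", ]
  expect_equal(fd$gamma, rep(2.0, 3), tolerance = 1e-9)   # pooled FAD, equal abundances
  expect_equal(fd$alpha, rep(0.5, 3), tolerance = 1e-9)   # FAD_pair / N^2 = 2.0 / 4
  expect_equal(fd$beta, rep(4, 3), tolerance = 1e-9)      # maximum N^2: completely distinct
  expect_equal(unique(fd$Q_pooled), 0.125)
  d <- td[td$measure == "D", ]
  md <- td[td$measure == "MD", ]
  expect_equal(d$beta, md$beta)
  expect_equal(d$beta^2, fd$beta, tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$N, 2)
  expect_equal(gl$Q_pooled, 0.125)
})

test_that("identical assemblages give beta = 1 and alpha = single-assemblage values", {
  inst <- random_instance(S = 6, N = 1, seed = 7)
  p <- setNames(inst$community[, 1], rownames(inst$community))
  z <- cbind(A = p, B = p, C = p)
  for (q in c(0, 1, 2)) {
    td <- tidy(func_partition(z, inst$dist, q = q))
    expect_equal(td$beta, rep(1, 4), tolerance = 1e-9)
    fd_single <- func_triple(p, inst$dist, q)$FD
    expect_rel_equal(td$alpha[td$measure == "FD"], fd_single, 1e-9)
  }
})

test_that("gamma and alpha agree with quadruple-loop oracles on random instances", {
  count <- 0
  for (seed in 1:25) {
    inst <- random_instance(S = sample(3:6, 1), N = sample(2:3, 1), seed = seed,
                            sparsity = ifelse(seed %% 2, 0.35, 0))
    for (scheme in c("relative", "absolute")) {
      for (q in c(0, 0.5, 1, 2)) {
        td <- tidy(func_partition(inst$community, inst$dist, q = q, scheme = scheme,
                                  measures = c("FD", "Hill")))
        fd <- td[td$measure == "FD", ]
        expect_rel_equal(fd$gamma, oracle_fd_gamma(inst$community, inst$dist, q, scheme), 1e-10)
        expect_rel_equal(fd$alpha, oracle_fd_alpha(inst$community, inst$dist, q, scheme), 1e-10)
        hl <- td[td$measure == "Hill", ]
        expect_rel_equal(hl$gamma, oracle_hill_gamma(inst$community, q, scheme), 1e-10)
        expect_rel_equal(hl$alpha, oracle_hill_alpha(inst$community, q, scheme), 1e-10)
        count <- count + 1
      }
    }
  }
  expect_gte(count, 100)
})

test_that("gamma >= alpha and beta stays within its range on random draws", {
  for (seed in 1:15) {
    inst <- random_instance(S = 6, N = sample(2:4, 1), seed = seed, sparsity = 0.3)
    N <- ncol(inst$community)
    for (q in c(0, 0.5, 1, 2, 5)) {
      td <- tidy(func_partition(inst$community, inst$dist, q = q))
      expect_true(all(td$gamma >= td$alpha - 1e-9))
      fd_beta <- td$beta[td$measure == "FD"]
      expect_gte(fd_beta, 1 - 1e-9); expect_lte(fd_beta, N^2 + 1e-9)
      for (m in c("D", "MD", "Hill")) {
        b <- td$beta[td$measure == m]
        expect_gte(b, 1 - 1e-9); expect_lte(b, N + 1e-9)
      }
    }
  }
})

test_that("replication principle: N disjoint copies scale D, MD by N and FD by N^2", {
  base_inst <- random_instance(S = 4, N = 1, seed = 11)
  p <- setNames(base_inst$community[, 1], rownames(base_inst$community))
  for (N in 2:4) {
    rep_inst <- replicated_disjoint(p, base_inst$dist, N)
    pooled <- pool_to_vector(rep_inst$community)
    expect_equal(quad_entropy(pooled, rep_inst$dist),
                 quad_entropy(p, base_inst$dist), tolerance = 1e-12)
    for (q in c(0, 1, 2)) {
      single <- func_triple(p, base_inst$dist, q)
      whole <- func_triple(pooled, rep_inst$dist, q)
      expect_rel_equal(whole$D, N * single$D, 1e-8)
      expect_rel_equal(whole$MD, N * single$MD, 1e-8)
      expect_rel_equal(whole$FD, N^2 * single$FD, 1e-8)
    }
  }
})

test_that("hill partition reproduces the partial-overlap layout counts", {
  z <- example1_communities()
  td <- hill_partition(z, q = c(0, 2))
  expect_equal(td$gamma[td$q == 0], 28)
  expect_equal(td$alpha[td$q == 0], 20)
  expect_equal(td$beta[td$q == 0], 1.4)
  expect_equal(td$gamma[td$q == 2], 25, tolerance = 1e-12)
  expect_equal(td$beta[td$q == 2], 1.25, tolerance = 1e-12)
  zi <- cbind(A = c(x = 1, y = 2), B = c(x = 1, y = 2))
  expect_equal(hill_partition(zi, q = 1)$beta, 1, tolerance = 1e-12)
})

test_that("columns already summing to 1 make the two schemes coincide", {
  inst <- random_instance(S = 5, N = 3, seed = 3, sparsity = 0.2)
  z <- sweep(inst$community, 2, colSums(inst$community), "/")
  for (q in c(0, 1, 2)) {
    a <- tidy(func_partition(z, inst$dist, q = q, scheme = "relative"))
    b <- tidy(func_partition(z, inst$dist, q = q, scheme = "absolute"))
    expect_equal(a$gamma, b$gamma, tolerance = 1e-12)
    expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
  }
})

test_that("functional evenness ratios behave as documented", {
  ex <- example2_fixture()
  p <- setNames(rep(0.25, 4), c("a", "b", "c", "d"))
  ev <- func_evenness(p, ex$case_i, q = c(1, 2))
  expect_equal(ev$evenness, c(1, 1), tolerance = 1e-9)
  expect_equal(ev$log_evenness, c(1, 1), tolerance = 1e-9)
  p2 <- c(a = 0.7, b = 0.2, c = 0.06, d = 0.04)
  ev2 <- func_evenness(p2, ex$case_i, q = c(1, 2))
  expect_true(all(ev2$evenness <= 1 + 1e-12))
  expect_error(func_evenness(p, ex$case_i, q = 0), class = "funhill_error_domain")
  # single species: log ratio undefined, reported as missing
  d1 <- matrix(0, 1, 1, dimnames = list("a", "a"))
  suppressWarnings(ev1 <- func_evenness(c(a = 1), d1, q = 2))
  expect_true(is.na(ev1$log_evenness))
})

test_that("species missing from the distance matrix stop the decomposition", {
  inst <- random_instance(S = 4, N = 2, seed = 5)
  dm <- inst$dist[1:3, 1:3]
  expect_error(func_partition(inst$community, dm, q = 0),
               class = "funhill_error_alignment")
  # matrix species not in the community are dropped with a warning
  big <- random_instance(S = 6, N = 1, seed = 5)$dist
  dimnames(big) <- list(c(rownames(inst$community), "x1", "x2"),
                        c(rownames(inst$community), "x1", "x2"))
  expect_warning(func_partition(inst$community, big, q = 0), "Dropping")
})
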