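# Brute-force reference implementations, written as literal loop sums so the
# vectorized package code can be checked against an independent path.

oracle_hill <- function(p, q) {
  p <- p / sum(p)
  p <- p[p > 0]
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

oracle_quad_entropy <- function(p, d) {
  p <- p / sum(p)
  Q <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      Q <- Q + d[i, j] * p[i] * p[j]
    }
  }
  Q
}

oracle_func_hill <- function(p, d, q) {
  p <- p / sum(p)
  Q <- oracle_quad_entropy(p, d)
  s <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      pp <- p[i] * p[j]
      if (pp > 0) {
        s <- s + if (q == 1) (d[i, j] / Q) * pp * log(pp) else (d[i, j] / Q) * pp^q
      }
    }
  }
  if (q == 1) exp(-0.5 * s) else s^(1 / (2 * (1 - q)))
}

# Gamma/alpha total functional diversity by literal quadruple-loop summation
# (relative pooling scheme applied first when asked).
oracle_fd_gamma <- function(z, d, q, scheme = "relative") {
  if (scheme == "relative") z <- sweep(z, 2, colSums(z), "/")
  a <- z / sum(z)
  u <- rowSums(a)
  Q <- oracle_quad_entropy(u, d) # u already sums to 1
  s <- 0
  for (i in seq_along(u)) {
    for (j in seq_along(u)) {
      uu <- u[i] * u[j]
      if (uu > 0) {
        s <- s + if (q == 1) (d[i, j] / Q) * uu * log(uu) else (d[i, j] / Q) * uu^q
      }
    }
  }
  if (q == 1) Q * exp(-s) else Q * s^(1 / (1 - q))
}

oracle_fd_alpha <- function(z, d, q, scheme = "relative") {
  if (scheme == "relative") z <- sweep(z, 2, colSums(z), "/")
  a <- z / sum(z)
  u <- rowSums(a)
  Q <- oracle_quad_entropy(u, d)
  N <- ncol(z)
  s <- 0
  for (i in seq_len(nrow(z))) {
    for (j in seq_len(nrow(z))) {
      for (k in seq_len(N)) {
        for (m in seq_len(N)) {
          t <- a[i, k] * a[j, m]
          if (t > 0) {
            s <- s + if (q == 1) (d[i, j] / Q) * t * log(t) else (d[i, j] / Q) * t^q
          }
        }
      }
    }
  }
  if (q == 1) (Q / N^2) * exp(-s) else (Q / N^2) * s^(1 / (1 - q))
}

oracle_hill_gamma <- function(z, q, scheme = "relative") {
  if (scheme == "relative") z <- sweep(z, 2, colSums(z), "/")
  oracle_hill(rowSums(z) / sum(z), q)
}

oracle_hill_alpha <- function(z, q, scheme = "relative") {
  if (scheme == "relative") z <- sweep(z, 2, colSums(z), "/")
  a <- as.vector(z / sum(z))
  a <- a[a > 0]
  N <- ncol(z)
  if (q == 1) exp(-sum(a * log(a))) / N else sum(a^q)^(1 / (1 - q)) / N
}

# A constant-distance matrix (same value for every entry, diagonal included)
# makes every functional measure collapse onto its abundance-only analogue.
const_dist <- function(labels, c = 0.3) {
  matrix(c, length(labels), length(labels), dimnames = list(labels, labels))
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
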