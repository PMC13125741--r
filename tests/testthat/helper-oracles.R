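# Independent brute-force oracles used across the test files. These share
# no code with the package internals: plain loops / expand.grid over the
# full (b, d) lattice, values grouped by rounding.

# Full enumeration of the score distribution as a data.frame of cells.
enum_cells <- function(S, M, ps, pa, beta = 1) {
  g <- expand.grid(b = 0:M, d = 0:S)
  g$p <- dbinom(g$b, M, pa) * dbinom(g$d, S, ps)
  b2 <- beta^2
  g$f <- (1 + b2) * g$d / (g$b + g$d + b2 * S)
  g
}

# Grouped pmf from enumerated cells (zero-probability cells dropped).
enum_pmf <- function(cells, digits = 12) {
  v <- round(cells$f, digits)
  agg <- aggregate(cells$p, by = list(v = v), FUN = sum)
  agg <- agg[agg$x > 0, ]
  agg[order(agg$v), ]
}

# Direct double-sum expectation of the estimated score.
enum_expectation <- function(S, M, ps, pa, beta = 1) {
  cells <- enum_cells(S, M, ps, pa, beta)
  sum(cells$p * cells$f)
}

# Minimum-tail two-sided p-value by O(K^2) enumeration.
enum_pv <- function(pmf, obs, tol = 1e-9) {
  Cu <- vapply(pmf$v, function(u) {
    min(sum(pmf$x[pmf$v <= u + tol]), sum(pmf$x[pmf$v >= u - tol]))
  }, numeric(1))
  Cobs <- min(sum(pmf$x[pmf$v <= obs + tol]), sum(pmf$x[pmf$v >= obs - tol]))
  sum(pmf$x[Cu <= Cobs + tol])
}

# Full 4-fold enumeration of the score-difference distribution.
enum_diff_pmf <- function(S, M, ps1, pa1, ps2, pa2, beta = 1, digits = 12) {
  c1 <- enum_cells(S, M, ps1, pa1, beta)
  c2 <- enum_cells(S, M, ps2, pa2, beta)
  v <- round(rep(c1$f, times = nrow(c2)) - rep(c2$f, each = nrow(c1)), digits)
  p <- rep(c1$p, times = nrow(c2)) * rep(c2$p, each = nrow(c1))
  agg <- aggregate(p, by = list(v = v), FUN = sum)
  agg <- agg[agg$x > 0, ]
  agg[order(agg$v), ]
}

# Equal-tail interval on an enumerated pmf (same one-cdf rule the package
# documents, recomputed independently).
enum_equal_tail <- function(pmf, level = 0.95) {
  a2 <- (1 - level) / 2
  cl <- cumsum(pmf$x)
  Ls <- pmf$v[cl <= a2 + 1e-12]
  c(if (length(Ls)) max(Ls) else pmf$v[1], pmf$v[cl >= 1 - a2 - 1e-12][1])
}
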