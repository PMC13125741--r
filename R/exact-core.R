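# Exact distribution machinery for the estimated F-beta score.
#
# Model: on a test set with S actual positives and M = N - S actual
# negatives, the true-positive count d ~ Binomial(S, ps) and the
# false-positive count b ~ Binomial(M, p_alpha) independently. The
# estimated score is fb = (1 + beta^2) d / (b + d + beta^2 S); p_alpha is
# calibrated so that E[fb] equals the target score induced by a
# (sensitivity, precision) pair.

# Represent beta^2 as an exact small-integer fraction num/den when beta is
# (close to) a ratio of small integers, so that score values can be grouped
# by exact rational keys. Returns NULL for effectively irrational beta.
beta2_fraction <- function(beta) {
  for (q in 1:100) {
    p <- round(beta * q)
    if (p > 0 && abs(beta * q - p) < 1e-9) {
      return(list(num = p^2, den = q^2))
    }
  }
  NULL
}

# Central window [lo, hi] of a Binomial(size, prob) holding all but ~eps of
# the mass in each tail, padded by 2 on each side.
binom_window <- function(size, prob, eps) {
  if (prob <= 0) return(c(0L, 0L))
  if (prob >= 1) return(c(size, size))
  lo <- stats::qbinom(eps, size, prob)
  hi <- stats::qbinom(eps, size, prob, lower.tail = FALSE)
  c(max(0L, lo - 2L), min(size, hi + 2L))
}

# Vectorized Euclid.
gcd_vec <- function(a, b) {
  while (any(b != 0)) {
    r <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(b != 0, b, a)
    b <- r
  }
  a
}

#' Expected estimated F-beta score under the binomial model
#'
#' Computes \eqn{E[(1+\beta^2) d / (b + d + \beta^2 S)]} for
#' `d ~ Binomial(S, ps)` and `b ~ Binomial(M, p_alpha)`, the left-hand side
#' of the calibration equation solved by [solve_p_alpha()].
#'
#' @param S Number of actual positives.
#' @param M Number of actual negatives (`N - S`).
#' @param ps Sensitivity in `[0, 1]`.
#' @param p_alpha Per-negative false-positive probability in `[0, 1]`.
#' @param beta Positive score weight.
#' @param trunc_eps Total binomial tail mass that may be ignored.
#' @return The expectation, a number in `[0, 1]`.
#' @export
expected_fbeta <- function(S, M, ps, p_alpha, beta = 1, trunc_eps = 1e-12) {
  b2 <- beta^2
  dw <- binom_window(S, ps, trunc_eps / 4)
  bw <- binom_window(M, p_alpha, trunc_eps / 4)
  d <- dw[1]:dw[2]; b <- bw[1]:bw[2]
  pd <- stats::dbinom(d, S, ps)
  pb <- stats::dbinom(b, M, p_alpha)
  f <- outer(b, d, function(b, d) (1 + b2) * d / (b + d + b2 * S))
  sum((pb %o% pd) * f)
}

#' Calibrate the false-positive rate to a target F-beta score
#'
#' Solves for the per-negative false-positive probability `p_alpha` such
#' that the expected estimated score [expected_fbeta()] equals
#' `target_fbeta`. The expectation is strictly decreasing in `p_alpha`, so
#' the root is unique; it is found by bisection to an absolute tolerance of
#' `1e-10` on the expectation.
#'
#' @inheritParams expected_fbeta
#' @param target_fbeta Target score in `(0, 1]`, typically
#'   `fbeta_score(ps, pp, beta)` for a designed precision `pp`.
#' @return The calibrated `p_alpha` in `[0, 1]`.
#'
#' @details An infeasibility error (condition class `fb_infeasible_error`)
#'   is raised when even `p_alpha = 0` leaves the expectation below the
#'   target, which happens when `S` is very small relative to the designed
#'   rates: no false-positive rate can then achieve the target score on
#'   average. Increase `S` (or `N`), or adjust the sensitivity/precision
#'   pair.
#' @examples
#' target <- fbeta_score(0.9, 0.6) # 0.72
#' solve_p_alpha(S = 20, M = 30, ps = 0.9, target_fbeta = target) # ~0.40
#' @export
solve_p_alpha <- function(S, M, ps, target_fbeta, beta = 1, trunc_eps = 1e-12) {
  stopifnot(S >= 1, M >= 0, ps >= 0, ps <= 1, beta > 0)
  if (!(target_fbeta > 0 && target_fbeta <= 1)) {
    stop_validation("target_fbeta must lie in (0, 1]")
  }
  if (M == 0) return(0)
  e0 <- expected_fbeta(S, M, ps, 0, beta, trunc_eps)
  if (target_fbeta > e0 + 1e-12) {
    stop_infeasible(sprintf(paste(
      "no p_alpha can achieve the target F-beta score %.6g:",
      "even p_alpha = 0 gives expected score %.6g.",
      "Increase S (or N), or adjust the sensitivity/precision pair."),
      target_fbeta, e0))
  }
  e1 <- expected_fbeta(S, M, ps, 1, beta, trunc_eps)
  if (target_fbeta < e1 - 1e-12) {
    stop_infeasible(sprintf(paste(
      "target F-beta score %.6g is below the expected score %.6g at",
      "p_alpha = 1; the target is not attainable at these counts."),
      target_fbeta, e1))
  }
  if (abs(e0 - target_fbeta) <= 1e-12) return(0)
  lo <- 0; hi <- 1
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    em <- expected_fbeta(S, M, ps, mid, beta, trunc_eps)
    if (abs(em - target_fbeta) <= 1e-10 && (hi - lo) < 1e-9) break
    if (em > target_fbeta) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

new_score_dist <- function(support, probs, trunc_mass, meta, diff = FALSE) {
  structure(list(support = support, probs = probs,
                 trunc_mass = trunc_mass, meta = meta),
            class = c(if (diff) "fb_diff_dist", "fb_dist"))
}

# Group (value, prob) pairs by exact rational keys kA/kB (both integer
# vectors, already reduced) or, when keys are NULL, by the value rounded to
# 12 decimals. Returns a list(support, probs) sorted by support value.
group_support <- function(value, prob, kA = NULL, kB = NULL) {
  if (is.null(kA)) {
    value <- round(value, 12)
    o <- order(value)
  } else {
    o <- order(kA, kB)
  }
  value <- value[o]; prob <- prob[o]
  if (is.null(kA)) {
    new <- c(TRUE, diff(value) > 0)
  } else {
    kA <- kA[o]; kB <- kB[o]
    new <- c(TRUE, diff(kA) != 0 | diff(kB) != 0)
  }
  grp <- cumsum(new)
  support <- value[new]
  probs <- as.vector(rowsum(prob, grp))
  o2 <- order(support)
  list(support = support[o2], probs = probs[o2])
}

#' Exact distribution of the estimated F-beta score
#'
#' Enumerates all admissible `(b, d)` pairs within central binomial windows
#' holding all but `trunc_eps` of the joint mass, groups them by the exact
#' score value `(1 + beta^2) d / (b + d + beta^2 S)`, and returns the sorted
#' support with matching probabilities. Score values are grouped by exact
#' rational keys whenever `beta` is a ratio of small integers (which covers
#' the usual `beta` of 0.5, 1, 2); ties such as
#' `2*1/(0 + 1 + 3) = 2*2/(2 + 2 + 4)` then merge exactly.
#'
#' @inheritParams expected_fbeta
#' @param max_points Cap on the number of enumerated `(b, d)` pairs; an
#'   `fb_resource_error` is raised beyond it (callers normally fall back to
#'   the normal approximation instead).
#' @return An object of class `"fb_dist"`: a list with sorted `support`,
#'   `probs`, the truncated tail mass `trunc_mass`, and `meta`.
#' @examples
#' d <- score_pmf(S = 5, M = 10, ps = 0.7, p_alpha = 0.2)
#' sum(d$probs)
#' @export
score_pmf <- function(S, M, ps, p_alpha, beta = 1, trunc_eps = 1e-12,
                      max_points = Inf) {
  stopifnot(S >= 1, M >= 0, ps >= 0, ps <= 1, p_alpha >= 0, p_alpha <= 1,
            beta > 0)
  b2 <- beta^2
  dw <- binom_window(S, ps, trunc_eps / 4)
  bw <- binom_window(M, p_alpha, trunc_eps / 4)
  d <- dw[1]:dw[2]; b <- bw[1]:bw[2]
  npairs <- length(d) * length(b)
  if (npairs > max_points) {
    stop_resource(sprintf(
      "score distribution needs %d mass points (cap %g); use the normal approximation",
      npairs, max_points))
  }
  pd <- stats::dbinom(d, S, ps)
  pb <- stats::dbinom(b, M, p_alpha)
  trunc_mass <- 1 - sum(pd) * sum(pb)
  bb <- rep(b, times = length(d))
  dd <- rep(d, each = length(b))
  prob <- as.vector(pb %o% pd)
  frac <- beta2_fraction(beta)
  if (!is.null(frac)) {
    A <- (frac$den + frac$num) * dd
    B <- frac$den * (bb + dd) + frac$num * S
    g <- gcd_vec(A, B)
    g[g == 0] <- 1
    res <- group_support(A / B, prob, kA = A / g, kB = B / g)
  } else {
    res <- group_support((1 + b2) * dd / (bb + dd + b2 * S), prob)
  }
  new_score_dist(res$support, res$probs, trunc_mass,
                 meta = list(N = S + M, S = S, M = M, ps = ps,
                             p_alpha = p_alpha, beta = beta,
                             trunc_eps = trunc_eps))
}

#' Brute-force oracle for the score distribution
#'
#' Recomputes the distribution of the estimated score by the naive,
#' untruncated double loop over all `(b, d)` cells with scalar
#' rational-number grouping. Deliberately shares no code with
#' [score_pmf()]; intended as an independent oracle in tests and limited to
#' tiny instances (`S * M <= 10000`).
#'
#' @inheritParams expected_fbeta
#' @return An `"fb_dist"` as from [score_pmf()], with zero truncated mass.
#' @export
brute_force_pmf <- function(S, M, ps, p_alpha, beta = 1) {
  if (S * max(M, 1) > 10000) {
    stop_resource("brute_force_pmf is restricted to S * M <= 10000")
  }
  frac <- beta2_fraction(beta)
  if (is.null(frac)) stop_validation("brute_force_pmf needs a rational beta")
  gcd1 <- function(a, b) if (b == 0) a else gcd1(b, a %% b)
  acc <- new.env(parent = emptyenv())
  for (d in 0:S) {
    for (b in 0:M) {
      A <- (frac$den + frac$num) * d
      B <- frac$den * (b + d) + frac$num * S
      g <- gcd1(A, B); if (g == 0) g <- 1
      key <- sprintf("%d/%d", A %/% g, B %/% g)
      p <- stats::dbinom(d, S, ps) * stats::dbinom(b, M, p_alpha)
      prev <- if (is.null(acc[[key]])) c(0, A / B) else acc[[key]]
      acc[[key]] <- c(prev[1] + p, A / B)
    }
  }
  vals <- mget(ls(acc), envir = acc)
  support <- vapply(vals, `[`, numeric(1), 2L)
  probs <- vapply(vals, `[`, numeric(1), 1L)
  o <- order(support)
  new_score_dist(unname(support[o]), unname(probs[o]), trunc_mass = 0,
                 meta = list(N = S + M, S = S, M = M, ps = ps,
                             p_alpha = p_alpha, beta = beta, oracle = TRUE))
}

# Drop support points that jointly carry at most `eps` probability (kept
# points are the smallest set holding >= 1 - eps of the mass); the removed
# mass is added to trunc_mass. Used to keep difference convolutions small.
prune_dist <- function(dist, eps = 1e-13) {
  if (eps <= 0 || length(dist$support) < 64L) return(dist)
  o <- order(dist$probs, decreasing = TRUE)
  keep_n <- which(cumsum(dist$probs[o]) >= 1 - dist$trunc_mass - eps)[1L]
  if (is.na(keep_n) || keep_n >= length(dist$support)) return(dist)
  keep <- sort(o[seq_len(keep_n)])
  dropped <- 1 - dist$trunc_mass - sum(dist$probs[keep])
  new_score_dist(dist$support[keep], dist$probs[keep],
                 dist$trunc_mass + max(0, dropped), dist$meta,
                 diff = inherits(dist, "fb_diff_dist"))
}

#' Exact distribution of the difference of two estimated scores
#'
#' Convolves `dist1` with the negation of `dist2` (the two classifiers'
#' counts are independent), grouping differences that agree to 12 decimals.
#' Both inputs must be built on the same `(N, S)`.
#'
#' @param dist1,dist2 `"fb_dist"` objects from [score_pmf()].
#' @param conv_cap Maximum number of support pairs; an `fb_resource_error`
#'   is raised beyond it (callers normally fall back to the normal
#'   approximation).
#' @return An object of class `c("fb_diff_dist", "fb_dist")` with support in
#'   `[-1, 1]`.
#' @export
diff_pmf <- function(dist1, dist2, conv_cap = 5e7) {
  stopifnot(inherits(dist1, "fb_dist"), inherits(dist2, "fb_dist"))
  if (!is.null(dist1$meta$S) && !is.null(dist2$meta$S) &&
      (dist1$meta$S != dist2$meta$S || dist1$meta$N != dist2$meta$N)) {
    stop_validation("difference distributions require a shared (N, S)")
  }
  n1 <- length(dist1$support); n2 <- length(dist2$support)
  if (as.double(n1) * n2 > conv_cap) {
    stop_resource(sprintf(
      "difference convolution needs %.3g support pairs (cap %g); use the normal approximation",
      as.double(n1) * n2, conv_cap))
  }
  v <- round(rep(dist1$support, times = n2) - rep(dist2$support, each = n1), 12)
  p <- rep(dist1$probs, times = n2) * rep(dist2$probs, each = n1)
  if (length(v) <= 2e5) {
    res <- group_support(v, p)
    res <- list(v = res$support, p = res$probs)
  } else {
    DT <- data.table::data.table(v = v, p = p)
    res <- DT[, list(p = sum(p)), keyby = "v"]
  }
  new_score_dist(res$v, res$p,
                 trunc_mass = dist1$trunc_mass + dist2$trunc_mass,
                 meta = list(meta1 = dist1$meta, meta2 = dist2$meta),
                 diff = TRUE)
}

#' @export
print.fb_dist <- function(x, ...) {
  kind <- if (inherits(x, "fb_diff_dist")) "score-difference" else "score"
  cat(sprintf("Exact %s distribution: %d mass points on [%.4g, %.4g]\n",
              kind, length(x$support), min(x$support), max(x$support)))
  cat(sprintf("  mean %.6g, sd %.6g, truncated mass %.3g\n",
              dist_mean(x), dist_sd(x), x$trunc_mass))
  invisible(x)
}

#' Moments and quantiles of an exact score distribution
#'
#' @param dist An `"fb_dist"`.
#' @return `dist_mean()` and `dist_sd()` return single numbers;
#'   `dist_quantile()` returns the smallest support values whose cumulative
#'   probability reaches `probs`.
#' @export
dist_mean <- function(dist) sum(dist$support * dist$probs)

#' @rdname dist_mean
#' @export
dist_sd <- function(dist) {
  mu <- dist_mean(dist)
  sqrt(max(0, sum((dist$support - mu)^2 * dist$probs)))
}

#' @param probs Probabilities in `[0, 1]`.
#' @rdname dist_mean
#' @export
dist_quantile <- function(dist, probs) {
  cl <- cumsum(dist$probs)
  vapply(probs, function(q) {
    dist$support[which(cl >= q - 1e-12)[1L]]
  }, numeric(1))
}

# Equal-tail interval on a discrete support. One cdf vector drives both
# endpoints: L is the largest support value with F(L) <= alpha/2 (smallest
# support value when none qualifies) and U the smallest with
# F(U) >= 1 - alpha/2. This is the rule that reproduces the worked
# applications; the "upper tail mass <= alpha/2" reading differs from it by
# at most one support point.
equal_tail_interval <- function(dist, level, tie_tol = 1e-12) {
  a2 <- (1 - level) / 2
  cl <- cumsum(dist$probs)
  iL <- which(cl <= a2 + tie_tol)
  L <- if (length(iL)) dist$support[max(iL)] else dist$support[1L]
  U <- dist$support[which(cl >= 1 - a2 - tie_tol)[1L]]
  c(lower = L, upper = U)
}

# Minimum-tail p-value machinery for a discrete null distribution.
# C(u) = min(P(X <= u), P(X >= u)); the two-sided p-value of v is the null
# mass of {x : C(x) <= C(v) + tie_tol}. Returns vectorized evaluators
# (index 0 from findInterval is handled by prepending 0 to the prefix
# sums).
pv_machinery <- function(dist, tie_tol = 1e-12) {
  x <- dist$support; p <- dist$probs
  cl <- cumsum(p)
  cl0 <- c(0, cl)
  n <- length(x)
  cdf_left <- function(v) {            # P(X <= v)
    cl0[findInterval(v + tie_tol, x) + 1L]
  }
  cdf_right <- function(v) {           # P(X >= v)
    1 - cl0[findInterval(v - tie_tol, x) + 1L]
  }
  C <- pmin(cl, 1 - c(0, cl[-n]))      # C at each support point
  o <- order(C)
  Cs <- C[o]; cp0 <- c(0, cumsum(p[o]))
  pv_two <- function(v) {
    Cv <- pmin(cdf_left(v), cdf_right(v))
    cp0[findInterval(Cv + tie_tol, Cs) + 1L]
  }
  list(pv_two = pv_two, cdf_left = cdf_left, cdf_right = cdf_right,
       C = C)
}

pv_for_alternative <- function(mach, v, alternative) {
  switch(alternative,
         two.sided = mach$pv_two(v),
         greater   = mach$cdf_right(v),
         less      = mach$cdf_left(v),
         stop_validation("alternative must be two.sided, greater or less"))
}
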