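# Delta-method normal surrogates for the score and score-difference
# distributions, and the exact-vs-normal mode selector.

#' Delta-method normal surrogate for the estimated F-beta score
#'
#' First-order approximation to the distribution of
#' `fb = (1 + beta^2) d / (b + d + beta^2 S)`: with `x = b/S` and `y = d/S`,
#' the score is `w(x, y) = (1 + beta^2) y / (x + y + beta^2)`, and the
#' variance follows from the gradient of `w` at the mean
#' `(M p_alpha / S, ps)` with the independent binomial variances of `b/S`
#' and `d/S`.
#'
#' @inheritParams expected_fbeta
#' @return A list of class `"fb_normal"` with `mean`, `sd` and `source`.
#' @examples
#' approx_moments(S = 500, M = 1000, ps = 0.8, p_alpha = 0.1)
#' @export
approx_moments <- function(S, M, ps, p_alpha, beta = 1) {
  b2 <- beta^2
  x0 <- M * p_alpha / S
  y0 <- ps
  den <- x0 + y0 + b2
  m <- (1 + b2) * y0 / den
  wx <- -(1 + b2) * y0 / den^2
  wy <- (1 + b2) * (x0 + b2) / den^2
  v <- (wx^2 * (M / S) * p_alpha * (1 - p_alpha) +
        wy^2 * ps * (1 - ps)) / S
  structure(list(mean = m, sd = sqrt(max(0, v)), source = "score",
                 S = S, M = M, ps = ps, p_alpha = p_alpha, beta = beta),
            class = "fb_normal")
}

# Surrogate for the difference of two independent scores: means subtract,
# variances add.
diff_moments <- function(m1, m2) {
  structure(list(mean = m1$mean - m2$mean,
                 sd = sqrt(m1$sd^2 + m2$sd^2),
                 source = "difference"),
            class = "fb_normal")
}

#' Closed-form large-sample approximation to the calibrated rate
#'
#' In the large-`N` limit the calibration equation inverts in closed form:
#' `p_alpha ~ S ps (1 - pp) / (M pp)`, independent of `beta`. Useful as a
#' sanity check on [solve_p_alpha()] and as a starting value.
#'
#' @inheritParams expected_fbeta
#' @param pp Precision in `(0, 1]`.
#' @return The approximate `p_alpha`.
#' @export
p_alpha_approx <- function(S, M, ps, pp) {
  stopifnot(pp > 0)
  S * ps * (1 - pp) / (M * pp)
}

#' Choose between the exact distribution and the normal surrogate
#'
#' Under `"auto"` the exact route is taken when the projected number of mass
#' points is at most `threshold` (inclusive); a larger projection selects
#' the normal surrogate, mirroring the automatic selection by mass-point
#' count. Forcing `"normal"` with a small projected support triggers a
#' warning, since the discrete distribution is then coarse and the surrogate
#' unreliable.
#'
#' @param projected_points Projected number of mass points (for differences:
#'   support pairs).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param threshold Mass-point cutoff for `"auto"`.
#' @return `"exact"` or `"normal"`.
#' @export
select_mode <- function(projected_points, mode = c("auto", "exact", "normal"),
                        threshold = 20000) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    return(if (projected_points <= threshold) "exact" else "normal")
  }
  if (mode == "normal" && projected_points <= threshold / 10) {
    warning(sprintf(paste(
      "forcing the normal approximation with only %d projected mass points;",
      "the exact distribution is coarse here and the approximation may be",
      "unreliable"), projected_points))
  }
  mode
}

# Projected number of (b, d) enumeration cells for a score distribution,
# computed without building it.
projected_points <- function(S, M, ps, p_alpha, trunc_eps = 1e-12) {
  dw <- binom_window(S, ps, trunc_eps / 4)
  bw <- binom_window(M, p_alpha, trunc_eps / 4)
  as.double(dw[2] - dw[1] + 1) * (bw[2] - bw[1] + 1)
}

# Normal-mode equal-tail interval and two-sided p-value, applied to a
# continuous symmetric statistic: the min-tail convention reduces to
# 2 * min(tail, 1 - tail).
normal_interval <- function(mom, level, clip = c(0, 1)) {
  a2 <- (1 - level) / 2
  c(lower = max(clip[1], stats::qnorm(a2, mom$mean, mom$sd)),
    upper = min(clip[2], stats::qnorm(1 - a2, mom$mean, mom$sd)))
}

normal_pvalue <- function(mom, obs, alternative = "two.sided") {
  if (mom$sd == 0) {
    z_eq <- abs(obs - mom$mean) < 1e-12
    return(switch(alternative,
                  two.sided = as.numeric(z_eq),
                  greater = as.numeric(obs <= mom$mean + 1e-12),
                  less = as.numeric(obs >= mom$mean - 1e-12)))
  }
  lo <- stats::pnorm(obs, mom$mean, mom$sd)
  hi <- stats::pnorm(obs, mom$mean, mom$sd, lower.tail = FALSE)
  switch(alternative,
         two.sided = min(1, 2 * min(lo, hi)),
         greater = hi,
         less = lo)
}
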