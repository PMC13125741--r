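# Inference for the difference in F-beta scores of two independent
# classifiers evaluated on one shared test set.

# Decide exact vs normal for a difference distribution and build it. Takes
# per-arm (ps, pp) pairs; returns either the exact convolution or the
# normal surrogate of the difference.
build_diff <- function(S, M, ps1, pp1, ps2, pp2, beta, config) {
  b1 <- list(target = fbeta_score(ps1, pp1, beta))
  b2 <- list(target = fbeta_score(ps2, pp2, beta))
  pa1 <- if (b1$target > 0) solve_p_alpha(S, M, ps1, b1$target, beta, config$trunc_eps) else 0
  pa2 <- if (b2$target > 0) solve_p_alpha(S, M, ps2, b2$target, beta, config$trunc_eps) else 0
  proj1 <- projected_points(S, M, ps1, pa1, config$trunc_eps)
  proj2 <- projected_points(S, M, ps2, pa2, config$trunc_eps)
  method <- if (config$mode == "auto") {
    if (proj1 * proj2 <= config$conv_cap) "exact" else "normal"
  } else {
    select_mode(proj1 * proj2, config$mode, config$conv_cap)
  }
  if (method == "exact") {
    # prune jointly-negligible support points before convolving: the cost
    # is a further ~1e-13 of unaccounted mass, the gain is a much smaller
    # support product
    g1 <- prune_dist(score_pmf(S, M, ps1, pa1, beta, config$trunc_eps))
    g2 <- prune_dist(score_pmf(S, M, ps2, pa2, beta, config$trunc_eps))
    list(method = "exact", dist = diff_pmf(g1, g2, config$conv_cap),
         p_alpha = c(pa1, pa2), targets = c(b1$target, b2$target))
  } else {
    m1 <- approx_moments(S, M, ps1, pa1, beta)
    m2 <- approx_moments(S, M, ps2, pa2, beta)
    list(method = "normal", mom = diff_moments(m1, m2),
         p_alpha = c(pa1, pa2), targets = c(b1$target, b2$target))
  }
}

#' Confidence interval for the difference of two F-beta scores
#'
#' Equal-tail interval for `Fbeta1 - Fbeta2` of two independent classifiers
#' sharing one test set. Each arm's score distribution is calibrated at its
#' Jeffreys-style corrected plug-ins and the two are convolved exactly;
#' when the convolution would exceed `config$conv_cap` support pairs the
#' delta-method normal surrogate of the difference is used instead (the
#' `method` field records which).
#'
#' @param pair A [paired_observation()].
#' @inheritParams ci_fbeta_one
#' @return An `"fb_interval"` on `[-1, 1]` whose `estimate` is the observed
#'   score difference.
#' @export
ci_fbeta_two <- function(pair, beta = 1, level = 0.95, mode = NULL,
                         config = fb_config()) {
  stopifnot(inherits(pair, "paired_observation"), level > 0, level < 1)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  S <- pair$obs1$S; M <- pair$obs1$N - S
  pl1 <- plugin_rates(pair$obs1, corrected = TRUE)
  pl2 <- plugin_rates(pair$obs2, corrected = TRUE)
  bd <- build_diff(S, M, pl1$ps, pl1$pp, pl2$ps, pl2$pp, beta, config)
  ep <- if (bd$method == "exact") {
    equal_tail_interval(bd$dist, level, config$tie_tol)
  } else {
    normal_interval(bd$mom, level, clip = c(-1, 1))
  }
  est <- fbeta_estimate(pair$obs1, beta) - fbeta_estimate(pair$obs2, beta)
  new_interval(ep[["lower"]], ep[["upper"]], level, bd$method,
               corrected = TRUE, estimate = est,
               meta = c(list(N = pair$obs1$N, S = S, beta = beta,
                             plugin1 = pl1, plugin2 = pl2,
                             p_alpha = bd$p_alpha), config_meta(config)))
}

# Pooled estimates for the two-classifier null: averages of the raw
# per-arm plug-ins.
pooled_rates <- function(pair) {
  pl1 <- plugin_rates(pair$obs1, corrected = FALSE)
  pl2 <- plugin_rates(pair$obs2, corrected = FALSE)
  list(ps = (pl1$ps + pl2$ps) / 2, pp = (pl1$pp + pl2$pp) / 2)
}

#' Exact pooled-null test for equality of two F-beta scores
#'
#' Tests `H0: Fbeta1 = Fbeta2` by pooling the raw per-arm plug-ins
#' (`ps-bar`, `pp-bar` are their averages), building the null distribution
#' of the score difference with both margins at the pooled rates, and
#' applying the minimum-tail two-sided p-value to the observed difference.
#' The pooled null is symmetric about 0.
#'
#' @inheritParams ci_fbeta_two
#' @inheritParams test_fbeta_point
#' @return An `"fb_test"` whose `statistic` is the observed difference.
#' @export
test_fbeta_pooled <- function(pair, beta = 1, alpha = 0.05,
                              alternative = c("two.sided", "greater", "less"),
                              mode = NULL, config = fb_config()) {
  stopifnot(inherits(pair, "paired_observation"))
  alternative <- match.arg(alternative)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  S <- pair$obs1$S; M <- pair$obs1$N - S
  po <- pooled_rates(pair)
  dobs <- fbeta_estimate(pair$obs1, beta) - fbeta_estimate(pair$obs2, beta)
  if (fbeta_score(po$ps, po$pp, beta) == 0) {
    warning("pooled null score is 0 (no true positives in either arm); p-value 1")
    return(new_test(1, dobs, alternative,
                    null_spec = list(ps_bar = po$ps, pp_bar = po$pp),
                    method = "degenerate", alpha = alpha,
                    meta = list(N = pair$obs1$N, S = S, beta = beta)))
  }
  bd <- build_diff(S, M, po$ps, po$pp, po$ps, po$pp, beta, config)
  pv <- if (bd$method == "exact") {
    mach <- pv_machinery(bd$dist, config$tie_tol)
    pv_for_alternative(mach, dobs, alternative)
  } else {
    normal_pvalue(bd$mom, dobs, alternative)
  }
  new_test(pv, dobs, alternative,
           null_spec = list(ps_bar = po$ps, pp_bar = po$pp,
                            fbeta0 = fbeta_score(po$ps, po$pp, beta)),
           method = bd$method, alpha = alpha,
           meta = c(list(N = pair$obs1$N, S = S, beta = beta,
                         p_alpha = bd$p_alpha[1]), config_meta(config)))
}

#' Conservative supremum test for equality of two F-beta scores
#'
#' Tests `H0: Fbeta1 = Fbeta2 = Fbeta0` for all plausible benchmark values
#' at once: the p-value is the supremum, over benchmark scores `Fbeta0` and
#' over the iso-F-beta curve of each, of the pooled-style difference
#' p-value. The search region for `Fbeta0` is restricted to the 2.5th to
#' 97.5th percentile range of the pooled single-score distribution (the
#' full `(0, 1)` range is needlessly conservative); candidates are that
#' distribution's support points inside the window plus a uniform grid of
#' step `f0_grid_step`. Each candidate's inner supremum walks the curve on
#' a precision grid of step `curve_step` with one local refinement.
#'
#' This search is exhaustive and therefore expensive; it is intended for
#' small test sets, where the conservative test matters most.
#'
#' @inheritParams test_fbeta_pooled
#' @param f0_grid_step Benchmark-score grid step (default from `config`).
#' @param curve_step Precision grid step along each iso-F-beta curve.
#' @return An `"fb_test"`; its p-value dominates [test_fbeta_pooled()]'s.
#' @export
test_fbeta_sup <- function(pair, beta = 1, alpha = 0.05,
                           f0_grid_step = NULL, curve_step = 1e-2,
                           mode = NULL, config = fb_config()) {
  stopifnot(inherits(pair, "paired_observation"))
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  f0_grid_step <- f0_grid_step %||% max(config$f0_grid_step, 1e-3)
  S <- pair$obs1$S; M <- pair$obs1$N - S
  po <- pooled_rates(pair)
  dobs <- fbeta_estimate(pair$obs1, beta) - fbeta_estimate(pair$obs2, beta)
  pooled_target <- fbeta_score(po$ps, po$pp, beta)
  if (pooled_target == 0) {
    warning("pooled null score is 0; supremum test degenerates to p-value 1")
    return(new_test(1, dobs, "two.sided", list(fbeta0 = NA_real_),
                    method = "degenerate", alpha = alpha,
                    meta = list(N = pair$obs1$N, S = S, beta = beta)))
  }
  pa <- solve_p_alpha(S, M, po$ps, pooled_target, beta, config$trunc_eps)
  g_pooled <- score_pmf(S, M, po$ps, pa, beta, config$trunc_eps)
  win <- dist_quantile(g_pooled, c(0.025, 0.975))
  sup_in <- g_pooled$support[g_pooled$support >= win[1] & g_pooled$support <= win[2]]
  cand <- sort(unique(round(c(sup_in, seq(win[1], win[2], by = f0_grid_step)), 10)))
  cand <- cand[cand > 1e-9 & cand < 1 - 1e-9]
  pv_at <- function(ps, pp) {
    tryCatch({
      bd <- build_diff(S, M, ps, pp, ps, pp, beta, config)
      if (bd$method == "exact") {
        pv_machinery(bd$dist, config$tie_tol)$pv_two(dobs)
      } else {
        normal_pvalue(bd$mom, dobs)
      }
    }, fb_infeasible_error = function(e) NA_real_)
  }
  inner_sup <- function(f0, step, best_stop = 1 - 1e-12) {
    pp_min <- max(iso_curve_pp_min(f0, beta), 1e-9)
    grid <- unique(pmin(1, c(seq(pp_min, 1, by = step), 1)))
    best <- -Inf; pp_best <- NA_real_
    for (pp in grid) {
      ps <- min(1, iso_curve_ps(pp, f0, beta))
      if (is.na(ps) || ps <= 0) next
      v <- pv_at(ps, pp)
      if (!is.na(v) && v > best) { best <- v; pp_best <- pp }
      if (best >= best_stop) break
    }
    if (is.finite(best) && best < best_stop) {
      fine <- seq(max(pp_min, pp_best - step), min(1, pp_best + step),
                  by = step / 10)
      for (pp in fine) {
        ps <- min(1, iso_curve_ps(pp, f0, beta))
        if (is.na(ps) || ps <= 0) next
        v <- pv_at(ps, pp)
        if (!is.na(v) && v > best) best <- v
        if (best >= best_stop) break
      }
    }
    best
  }
  best <- -Inf; f0_best <- NA_real_
  for (f0 in cand) {
    v <- inner_sup(f0, curve_step)
    if (is.finite(v) && v > best) { best <- v; f0_best <- f0 }
    if (best >= 1 - 1e-12) break
  }
  if (!is.finite(best)) {
    stop_infeasible("no benchmark value in the percentile window is attainable")
  }
  new_test(best, dobs, "two.sided",
           null_spec = list(fbeta0 = f0_best),
           method = "exact", alpha = alpha,
           meta = c(list(N = pair$obs1$N, S = S, beta = beta,
                         f0_window = win, n_candidates = length(cand)),
                    config_meta(config)),
           search_trace = list(f0 = f0_best, window = win))
}

#' Analytic power for comparing two F-beta scores
#'
#' Power of the pooled-null exact test when the two classifiers truly
#' operate at `(ps1, pp1)` and `(ps2, pp2)`: the null difference
#' distribution puts both margins at the averaged rates
#' `ps-bar = (ps1 + ps2)/2`, `pp-bar = (pp1 + pp2)/2`; the rejection region
#' collects its support points with two-sided p-value below `alpha`, and
#' the power is the mass of that region under the difference distribution
#' with margins at the true rates.
#'
#' @inheritParams power_fbeta_one
#' @param ps2,pp2 Second classifier's sensitivity and precision.
#' @return An `"fb_power"`.
#' @examples
#' \donttest{
#' power_fbeta_two(0.8, 0.5, 0.9, 0.6, N = 100, S = 40)
#' }
#' @export
power_fbeta_two <- function(ps1, pp1, ps2, pp2, N, S, alpha = 0.05, beta = 1,
                            mode = NULL, config = fb_config()) {
  stopifnot(S >= 1, S < N)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  M <- N - S
  psb <- (ps1 + ps2) / 2; ppb <- (pp1 + pp2) / 2
  b0 <- build_diff(S, M, psb, ppb, psb, ppb, beta, config)
  b1 <- build_diff(S, M, ps1, pp1, ps2, pp2, beta, config)
  if (b0$method == "exact" && b1$method == "exact") {
    mach <- pv_machinery(b0$dist, config$tie_tol)
    pv <- mach$pv_two(b1$dist$support)
    power <- sum(b1$dist$probs[pv < alpha - config$tie_tol])
    method <- "exact"
  } else {
    m0 <- if (b0$method == "normal") b0$mom else
      list(mean = 0, sd = dist_sd(b0$dist))
    m1 <- if (b1$method == "normal") b1$mom else
      list(mean = dist_mean(b1$dist), sd = dist_sd(b1$dist))
    z <- stats::qnorm(1 - alpha / 2)
    power <- stats::pnorm(m0$mean - z * m0$sd, m1$mean, m1$sd) +
      stats::pnorm(m0$mean + z * m0$sd, m1$mean, m1$sd, lower.tail = FALSE)
    method <- "normal"
  }
  new_power(power, alpha, N, S,
            null_params = list(ps = psb, pp = ppb),
            alt_params = list(ps1 = ps1, pp1 = pp1, ps2 = ps2, pp2 = pp2),
            beta = beta, method = method,
            meta = c(list(p_alpha = c(b1$p_alpha)), config_meta(config)))
}

#' Sample size for comparing two F-beta scores
#'
#' As [sample_size_fbeta_one()], with [power_fbeta_two()] as the power
#' engine.
#'
#' @inheritParams power_fbeta_two
#' @inheritParams sample_size_fbeta_one
#' @return An `"fb_design"`.
#' @export
sample_size_fbeta_two <- function(ps1, pp1, ps2, pp2, pI, target_power,
                                  alpha = 0.05, beta = 1, mode = NULL,
                                  config = fb_config()) {
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  out <- sample_size_search(function(N, S) {
    power_fbeta_two(ps1, pp1, ps2, pp2, N, S, alpha, beta, config = config)$power
  }, pI, target_power, config)
  out$alpha <- alpha; out$beta <- beta
  out$params1 <- list(ps = ps1, pp = pp1)
  out$params2 <- list(ps = ps2, pp = pp2)
  out
}
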