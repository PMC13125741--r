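# Interval estimation, hypothesis tests, and power / sample-size
# calculation for one classifier's F-beta score.

# Build the calibrated score distribution (or its normal surrogate) for a
# (ps, pp) pair at the given counts. Returns the route actually taken.
build_score <- function(S, M, ps, pp, beta, config) {
  target <- fbeta_score(ps, pp, beta)
  if (target == 0) {
    # score identically 0 only when ps = 0; pp = 0 with ps > 0 cannot be
    # calibrated (any false-positive rate leaves E[fb] > 0)
    if (ps > 0) stop_infeasible("precision 0 with positive sensitivity is not attainable")
    d <- new_score_dist(0, 1, 0, meta = list(N = S + M, S = S, M = M,
                                             ps = ps, p_alpha = 0, beta = beta))
    return(list(method = "exact", dist = d, p_alpha = 0, target = 0))
  }
  p_alpha <- solve_p_alpha(S, M, ps, target, beta, config$trunc_eps)
  proj <- projected_points(S, M, ps, p_alpha, config$trunc_eps)
  method <- select_mode(proj, config$mode, config$mass_point_threshold)
  if (method == "exact") {
    dist <- score_pmf(S, M, ps, p_alpha, beta, config$trunc_eps)
    list(method = "exact", dist = dist, p_alpha = p_alpha, target = target)
  } else {
    list(method = "normal", mom = approx_moments(S, M, ps, p_alpha, beta),
         p_alpha = p_alpha, target = target)
  }
}

new_interval <- function(lower, upper, level, method, corrected, estimate, meta) {
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, corrected = corrected,
                 estimate = estimate, meta = meta),
            class = "fb_interval")
}

#' @export
print.fb_interval <- function(x, ...) {
  cat(sprintf("%.0f%% %s confidence interval (%s): (%.4f, %.4f)\n",
              100 * x$level, x$method,
              if (isTRUE(x$corrected)) "corrected plug-ins" else "plug-ins",
              x$lower, x$upper))
  cat(sprintf("  point estimate: %.4f\n", x$estimate))
  invisible(x)
}

#' Confidence interval for a single classifier's F-beta score
#'
#' Calibrates the score distribution at the Jeffreys-style corrected
#' plug-in rates (`(d + 0.5)/(S + 1)` for sensitivity and
#' `(d + 0.5)/(b + d + 1)` for precision, with `b` replaced by 0.5 when
#' `b = 0`) and takes the equal-tail interval on its support. Large
#' problems use the delta-method normal surrogate (see [select_mode()]).
#'
#' @param obs A [confusion_table()].
#' @param beta Positive score weight; 1 gives the F1 score.
#' @param level Confidence level in `(0, 1)`.
#' @param mode `"auto"`, `"exact"` or `"normal"` (overrides `config$mode`).
#' @param config An [fb_config()].
#' @return An `"fb_interval"` with `lower`, `upper`, `level`, `method`
#'   (`"exact"` or `"normal"`), the uncorrected point estimate, and run
#'   metadata.
#' @examples
#' ci_fbeta_one(confusion_table(150, 60, tp = 54, fp = 33))
#' @export
ci_fbeta_one <- function(obs, beta = 1, level = 0.95, mode = NULL,
                         config = fb_config()) {
  stopifnot(inherits(obs, "confusion_table"), level > 0, level < 1)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  pl <- plugin_rates(obs, corrected = TRUE)
  bs <- build_score(obs$S, obs$N - obs$S, pl$ps, pl$pp, beta, config)
  if (bs$method == "exact") {
    dist <- bs$dist
    # widen the enumeration window if the requested tail is not safely
    # larger than the truncated mass
    if ((1 - level) / 2 < 100 * max(dist$trunc_mass, 0)) {
      dist <- score_pmf(obs$S, obs$N - obs$S, pl$ps, bs$p_alpha, beta,
                        trunc_eps = (1 - level) * 1e-6)
    }
    ep <- equal_tail_interval(dist, level, config$tie_tol)
    npts <- length(dist$support)
  } else {
    ep <- normal_interval(bs$mom, level)
    npts <- NA_integer_
  }
  new_interval(ep[["lower"]], ep[["upper"]], level, bs$method,
               corrected = TRUE, estimate = fbeta_estimate(obs, beta),
               meta = c(list(N = obs$N, S = obs$S, tp = obs$tp, fp = obs$fp,
                             beta = beta, plugin = pl, target = bs$target,
                             p_alpha = bs$p_alpha, n_points = npts),
                        config_meta(config)))
}

new_test <- function(p_value, statistic, alternative, null_spec, method,
                     alpha, meta, search_trace = NULL) {
  structure(list(p_value = p_value, statistic = statistic,
                 alternative = alternative, null_spec = null_spec,
                 method = method, alpha = alpha, reject = p_value < alpha,
                 search_trace = search_trace, meta = meta),
            class = "fb_test")
}

#' @export
print.fb_test <- function(x, ...) {
  cat(sprintf("%s F-beta test (%s): observed %.4f, p-value %.4g\n",
              x$method, x$alternative, x$statistic, x$p_value))
  cat(sprintf("  H0: %s; %s at alpha = %g\n",
              paste(names(x$null_spec), signif(unlist(x$null_spec), 4),
                    sep = " = ", collapse = ", "),
              if (x$reject) "rejected" else "not rejected", x$alpha))
  invisible(x)
}

#' Exact test of a point null for a single F-beta score
#'
#' Tests whether the classifier's score differs from the target induced by
#' a designed sensitivity/precision pair `(ps0, pp0)`. The two-sided
#' p-value is the null mass of all support points whose minimum-tail
#' statistic `C(f) = min(P(f' <= f), P(f' >= f))` does not exceed that of
#' the observed score (ties included within `config$tie_tol`); one-sided
#' p-values are the corresponding single-tail sums.
#'
#' @inheritParams ci_fbeta_one
#' @param ps0,pp0 Null sensitivity and precision; their induced score must
#'   be attainable at the observed counts.
#' @param alpha Significance level (recorded, and used for the `reject`
#'   flag).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return An `"fb_test"` with the p-value, observed score, and metadata.
#' @examples
#' obs <- confusion_table(150, 60, tp = 54, fp = 33)
#' test_fbeta_point(obs, ps0 = 0.8, pp0 = 0.5)
#' @export
test_fbeta_point <- function(obs, ps0, pp0, beta = 1, alpha = 0.05,
                             alternative = c("two.sided", "greater", "less"),
                             mode = NULL, config = fb_config()) {
  stopifnot(inherits(obs, "confusion_table"))
  alternative <- match.arg(alternative)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  bs <- build_score(obs$S, obs$N - obs$S, ps0, pp0, beta, config)
  fobs <- fbeta_estimate(obs, beta)
  pv <- if (bs$method == "exact") {
    mach <- pv_machinery(bs$dist, config$tie_tol)
    pv_for_alternative(mach, fobs, alternative)
  } else {
    normal_pvalue(bs$mom, fobs, alternative)
  }
  new_test(pv, fobs, alternative,
           null_spec = list(ps0 = ps0, pp0 = pp0, fbeta0 = bs$target),
           method = bs$method, alpha = alpha,
           meta = c(list(N = obs$N, S = obs$S, beta = beta,
                         p_alpha = bs$p_alpha), config_meta(config)))
}

# Admissible precision range of the iso-F-beta curve {(ps, pp):
# fbeta_score(ps, pp) = f0}: sensitivity solves
# ps = beta^2 f0 pp / ((1 + beta^2) pp - f0) and ps <= 1 forces
# pp >= f0 / ((1 + beta^2) - beta^2 f0).
iso_curve_ps <- function(pp, f0, beta) {
  b2 <- beta^2
  b2 * f0 * pp / ((1 + b2) * pp - f0)
}

iso_curve_pp_min <- function(f0, beta) {
  b2 <- beta^2
  f0 / ((1 + b2) - b2 * f0)
}

#' Conservative exact test of a benchmark F-beta value
#'
#' Tests `H0: Fbeta = fbeta0` without committing to a sensitivity/precision
#' pair: the p-value is the supremum of the point-null p-value over the
#' iso-F-beta curve of `fbeta0`. The supremum is located on a coarse
#' precision grid (`config$grid_step`) and then refined locally
#' (`config$refine_step`); curve members whose target is not attainable at
#' the observed counts are skipped.
#'
#' @inheritParams test_fbeta_point
#' @param fbeta0 Benchmark score in `(0, 1)`.
#' @return An `"fb_test"`; its `search_trace` records the best curve point
#'   and the number of curve members evaluated. The p-value always
#'   dominates the point-null p-value at any curve member.
#' @export
test_fbeta_benchmark <- function(obs, fbeta0, beta = 1, alpha = 0.05,
                                 mode = NULL, config = fb_config()) {
  stopifnot(inherits(obs, "confusion_table"), fbeta0 > 0, fbeta0 < 1)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  fobs <- fbeta_estimate(obs, beta)
  eval_pp <- function(pp) {
    ps <- iso_curve_ps(pp, fbeta0, beta)
    if (is.na(ps) || ps <= 0 || ps > 1 + 1e-12) return(NA_real_)
    ps <- min(ps, 1)
    tryCatch(
      test_fbeta_point(obs, ps0 = ps, pp0 = pp, beta = beta, alpha = alpha,
                       config = config)$p_value,
      fb_infeasible_error = function(e) NA_real_)
  }
  pp_min <- max(iso_curve_pp_min(fbeta0, beta), 1e-9)
  grid <- unique(pmin(1, c(seq(pp_min, 1, by = config$grid_step), 1)))
  pv <- rep(NA_real_, length(grid))
  best <- -Inf
  for (i in seq_along(grid)) {
    pv[i] <- eval_pp(grid[i])
    if (!is.na(pv[i]) && pv[i] > best) best <- pv[i]
    if (best >= 1 - 1e-12) break
  }
  n_eval <- sum(!is.na(pv))
  i_best <- which.max(pv)
  pp_best <- grid[i_best]
  if (best < 1 - 1e-12) {
    lo <- max(pp_min, pp_best - config$grid_step)
    hi <- min(1, pp_best + config$grid_step)
    fine <- seq(lo, hi, by = config$refine_step)
    for (pp in fine) {
      v <- eval_pp(pp)
      n_eval <- n_eval + !is.na(v)
      if (!is.na(v) && v > best) { best <- v; pp_best <- pp }
      if (best >= 1 - 1e-12) break
    }
  }
  if (!is.finite(best)) {
    stop_infeasible("no member of the iso-F-beta curve is attainable at these counts")
  }
  new_test(best, fobs, "two.sided",
           null_spec = list(fbeta0 = fbeta0),
           method = "exact", alpha = alpha,
           meta = c(list(N = obs$N, S = obs$S, beta = beta),
                    config_meta(config)),
           search_trace = list(pp = pp_best,
                               ps = min(1, iso_curve_ps(pp_best, fbeta0, beta)),
                               n_evaluated = n_eval))
}

new_power <- function(power, alpha, N, S, null_params, alt_params, beta,
                      method, meta = list()) {
  structure(list(power = power, alpha = alpha, N = N, S = S,
                 null_params = null_params, alt_params = alt_params,
                 beta = beta, method = method, meta = meta),
            class = "fb_power")
}

#' @export
print.fb_power <- function(x, ...) {
  cat(sprintf("Analytic power (%s): %.4f at N = %d, S = %d, alpha = %g\n",
              x$method, x$power, x$N, x$S, x$alpha))
  invisible(x)
}

#' Analytic power for testing a single F-beta score
#'
#' Power of the exact point-null test of `(ps0, pp0)` when the classifier
#' truly operates at `(ps1, pp1)`: the rejection region collects the null
#' support points with two-sided p-value below `alpha`, and the power is
#' the alternative distribution's mass on that region. All p-values are
#' obtained in one pass from prefix sums of the minimum-tail statistic.
#'
#' @inheritParams test_fbeta_point
#' @param ps1,pp1 True (alternative) sensitivity and precision.
#' @param N,S Design counts.
#' @return An `"fb_power"` whose `power` element is the rejection
#'   probability.
#' @examples
#' power_fbeta_one(0.8, 0.5, 0.9, 0.6, N = 150, S = 60)
#' @export
power_fbeta_one <- function(ps0, pp0, ps1, pp1, N, S, alpha = 0.05, beta = 1,
                            mode = NULL, config = fb_config()) {
  stopifnot(S >= 1, S < N)
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  M <- N - S
  b0 <- build_score(S, M, ps0, pp0, beta, config)
  b1 <- build_score(S, M, ps1, pp1, beta, config)
  if (b0$method == "exact" && b1$method == "exact") {
    mach <- pv_machinery(b0$dist, config$tie_tol)
    pv <- mach$pv_two(b1$dist$support)
    power <- sum(b1$dist$probs[pv < alpha - config$tie_tol])
    method <- "exact"
  } else {
    m0 <- if (b0$method == "normal") b0$mom else
      approx_moments(S, M, ps0, b0$p_alpha, beta)
    m1 <- if (b1$method == "normal") b1$mom else
      approx_moments(S, M, ps1, b1$p_alpha, beta)
    z <- stats::qnorm(1 - alpha / 2)
    power <- stats::pnorm(m0$mean - z * m0$sd, m1$mean, m1$sd) +
      stats::pnorm(m0$mean + z * m0$sd, m1$mean, m1$sd, lower.tail = FALSE)
    method <- "normal"
  }
  new_power(power, alpha, N, S,
            null_params = list(ps = ps0, pp = pp0),
            alt_params = list(ps = ps1, pp = pp1),
            beta = beta, method = method,
            meta = c(list(p_alpha0 = b0$p_alpha, p_alpha1 = b1$p_alpha),
                     config_meta(config)))
}

#' @export
print.fb_design <- function(x, ...) {
  cat(sprintf("Sample size: N = %d (S = %d) achieves power %.4f (target %.3f) at alpha = %g\n",
              x$N, x$S, x$power, x$target_power, x$alpha))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# Shared sample-size search. power_fun(N, S) -> power or NA when the design
# is infeasible at those counts. Power is a sawtooth in N for discrete
# tests, so the target must also hold on a `lookahead`-step window, and the
# accepted N is walked down while the guarded target still holds.
sample_size_search <- function(power_fun, pI, target_power, config) {
  stopifnot(pI > 0, pI < 1, target_power > 0, target_power < 1)
  cache <- new.env(parent = emptyenv())
  S_of <- function(N) max(1L, round_half_up(N * pI))
  pow <- function(N) {
    key <- as.character(N)
    if (is.null(cache[[key]])) {
      S <- S_of(N)
      cache[[key]] <- if (S >= N) NA_real_ else
        tryCatch(power_fun(N, S), fb_infeasible_error = function(e) NA_real_)
    }
    cache[[key]]
  }
  guarded <- function(N) {
    for (i in 0:config$lookahead) {
      p <- pow(N + i)
      if (is.na(p) || p < target_power) return(FALSE)
    }
    TRUE
  }
  N <- max(2L, ceiling(0.5 / pI))
  while (N <= config$n_max && is.na(pow(N))) N <- N + 1L
  if (N > config$n_max) stop_infeasible("no feasible design below n_max")
  # bracket by doubling, then locate the smallest guarded N
  lo <- N
  while (N <= config$n_max && !guarded(N)) {
    lo <- N
    N <- min(2L * N, as.integer(config$n_max) + 1L)
    if (N > config$n_max) {
      stop_infeasible(sprintf("target power %.3f not reached below N = %g",
                              target_power, config$n_max))
    }
  }
  hi <- N
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (guarded(mid)) hi <- mid else lo <- mid
  }
  N <- hi
  while (N - 1L >= 2L && guarded(N - 1L)) N <- N - 1L
  structure(list(N = N, S = S_of(N), power = pow(N),
                 target_power = target_power, pI = pI),
            class = "fb_design")
}

#' Sample size for testing a single F-beta score
#'
#' Smallest `N` (with `S = round(N * pI)`, at least 1) whose analytic power
#' [power_fbeta_one()] reaches `target_power` and keeps it over the next
#' `config$lookahead` increments of `N` (discrete-test power is a sawtooth
#' in `N`).
#'
#' @inheritParams power_fbeta_one
#' @param pI Positive-class fraction `S / N` in `(0, 1)`.
#' @param target_power Desired power in `(0, 1)`.
#' @return An `"fb_design"` with `N`, `S`, the achieved `power`, and the
#'   search settings.
#' @export
sample_size_fbeta_one <- function(ps0, pp0, ps1, pp1, pI, target_power,
                                  alpha = 0.05, beta = 1, mode = NULL,
                                  config = fb_config()) {
  if (!is.null(mode)) config$mode <- match.arg(mode, c("auto", "exact", "normal"))
  out <- sample_size_search(function(N, S) {
    power_fbeta_one(ps0, pp0, ps1, pp1, N, S, alpha, beta, config = config)$power
  }, pI, target_power, config)
  out$alpha <- alpha; out$beta <- beta
  out$null_params <- list(ps = ps0, pp = pp0)
  out$alt_params <- list(ps = ps1, pp = pp1)
  out
}
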