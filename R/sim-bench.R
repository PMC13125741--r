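# Seeded synthetic confusion-table generator and the Monte-Carlo harness
# for coverage, size and power studies.

#' Define a simulation scenario
#'
#' A scenario fixes the generating model for synthetic confusion tables:
#' the true operating rates of one classifier (`ps1`, `pp1`) and optionally
#' a second (`ps2`, `pp2`; two-classifier scenarios draw the arms
#' independently on the shared test set), the design counts, the score
#' weight, the test/interval settings, the replicate count and the seed.
#' For power runs against a point null, `ps0`/`pp0` give the null rates.
#'
#' The generator is model-consistent: `d ~ Binomial(S, ps)` and
#' `b ~ Binomial(N - S, p_alpha)` with `p_alpha` calibrated by
#' [solve_p_alpha()] so that the expected estimated score equals
#' `fbeta_score(ps, pp, beta)`. `rate = "precision"` instead uses the
#' closed-form large-sample rate [p_alpha_approx()] (the two coincide as
#' `N` grows).
#'
#' @param ps1,pp1 True sensitivity and precision of classifier 1.
#' @param N,S Design counts, `0 < S < N`.
#' @param ps2,pp2 Optional second classifier.
#' @param ps0,pp0 Optional point-null rates for power/size runs.
#' @param beta Positive score weight.
#' @param alpha Significance level for tests.
#' @param level Confidence level for intervals.
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param rate `"calibrated"` (exact calibration) or `"precision"`
#'   (closed-form large-sample rate).
#' @return A list of class `"fb_scenario"`.
#' @export
fb_scenario <- function(ps1, pp1, N, S, ps2 = NULL, pp2 = NULL,
                        ps0 = NULL, pp0 = NULL, beta = 1, alpha = 0.05,
                        level = 0.95, reps = 1000L, seed = 1L,
                        rate = c("calibrated", "precision")) {
  stopifnot(S >= 1, S < N, reps >= 1)
  structure(list(ps1 = ps1, pp1 = pp1, ps2 = ps2, pp2 = pp2,
                 ps0 = ps0, pp0 = pp0, N = as.integer(N), S = as.integer(S),
                 beta = beta, alpha = alpha, level = level,
                 reps = as.integer(reps), seed = as.integer(seed),
                 rate = match.arg(rate)),
            class = "fb_scenario")
}

#' Reference simulation grids
#'
#' Returns the scenario lists used in the package's validation studies:
#' `"coverage_one"` (single-classifier interval coverage; high-sensitivity/
#' low-precision arm at four design sizes), `"power_one"` (single-classifier
#' tests of a weaker point null), `"power_two"` (two-classifier
#' comparisons), and their F-beta variants `"power_one_fbeta"` /
#' `"power_two_fbeta"` which cross the designs with `beta` of 0.5, 1 and 2.
#'
#' @param table One of `"coverage_one"`, `"power_one"`, `"power_two"`,
#'   `"power_one_fbeta"`, `"power_two_fbeta"`.
#' @param reps Replicates per scenario.
#' @param seed Base seed; scenario `i` uses `seed + i` so each is
#'   independently reproducible.
#' @return A list of [fb_scenario()] objects.
#' @export
fb_scenarios <- function(table = c("coverage_one", "power_one", "power_two",
                                   "power_one_fbeta", "power_two_fbeta"),
                         reps = 1000L, seed = 1L) {
  table <- match.arg(table)
  one_sizes <- list(c(150L, 60L), c(100L, 40L), c(50L, 20L), c(1000L, 20L))
  two_sizes <- list(c(250L, 100L), c(100L, 40L), c(50L, 20L), c(1000L, 20L))
  betas <- c(0.5, 1, 2)
  out <- switch(table,
    coverage_one = lapply(one_sizes, function(ns) {
      fb_scenario(ps1 = 0.9, pp1 = 0.6, N = ns[1], S = ns[2], reps = reps)
    }),
    power_one = lapply(one_sizes, function(ns) {
      fb_scenario(ps1 = 0.9, pp1 = 0.6, ps0 = 0.8, pp0 = 0.5,
                  N = ns[1], S = ns[2], reps = reps)
    }),
    power_two = lapply(two_sizes, function(ns) {
      fb_scenario(ps1 = 0.8, pp1 = 0.5, ps2 = 0.9, pp2 = 0.6,
                  N = ns[1], S = ns[2], reps = reps)
    }),
    power_one_fbeta = {
      grid <- expand.grid(i = seq_along(one_sizes), b = betas)
      lapply(seq_len(nrow(grid)), function(k) {
        ns <- one_sizes[[grid$i[k]]]
        fb_scenario(ps1 = 0.9, pp1 = 0.6, ps0 = 0.8, pp0 = 0.5,
                    N = ns[1], S = ns[2], beta = grid$b[k], reps = reps)
      })
    },
    power_two_fbeta = {
      grid <- expand.grid(i = seq_along(two_sizes), b = betas)
      lapply(seq_len(nrow(grid)), function(k) {
        ns <- two_sizes[[grid$i[k]]]
        fb_scenario(ps1 = 0.8, pp1 = 0.5, ps2 = 0.9, pp2 = 0.6,
                    N = ns[1], S = ns[2], beta = grid$b[k], reps = reps)
      })
    })
  for (i in seq_along(out)) out[[i]]$seed <- as.integer(seed + i)
  out
}

scenario_rate <- function(sc, ps, pp) {
  M <- sc$N - sc$S
  if (sc$rate == "precision") {
    min(1, p_alpha_approx(sc$S, M, ps, pp))
  } else {
    solve_p_alpha(sc$S, M, ps, fbeta_score(ps, pp, sc$beta), sc$beta)
  }
}

#' Draw synthetic confusion tables under a scenario
#'
#' Simulates `reps` confusion tables (or pairs) from the scenario's
#' generating model under its seed. Identical scenarios yield identical
#' streams.
#'
#' @param scenario An [fb_scenario()].
#' @return A list of [confusion_table()]s, or of [paired_observation()]s
#'   for two-classifier scenarios.
#' @export
simulate_tables <- function(scenario) {
  stopifnot(inherits(scenario, "fb_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  pa1 <- scenario_rate(sc, sc$ps1, sc$pp1)
  d1 <- stats::rbinom(sc$reps, sc$S, sc$ps1)
  b1 <- stats::rbinom(sc$reps, sc$N - sc$S, pa1)
  if (is.null(sc$ps2)) {
    return(lapply(seq_len(sc$reps), function(i) {
      confusion_table(sc$N, sc$S, d1[i], b1[i])
    }))
  }
  pa2 <- scenario_rate(sc, sc$ps2, sc$pp2)
  d2 <- stats::rbinom(sc$reps, sc$S, sc$ps2)
  b2 <- stats::rbinom(sc$reps, sc$N - sc$S, pa2)
  lapply(seq_len(sc$reps), function(i) {
    paired_observation(confusion_table(sc$N, sc$S, d1[i], b1[i]),
                       confusion_table(sc$N, sc$S, d2[i], b2[i]))
  })
}

#' Monte-Carlo coverage of the equal-tail interval
#'
#' Applies [ci_fbeta_one()] (or [ci_fbeta_two()] for paired scenarios) to
#' each simulated table and reports the fraction of intervals containing
#' the true score (or true difference), with the binomial standard error,
#' and the mean and standard deviation of the interval length. Repeated
#' `(tp, fp)` observations are computed once and cached.
#'
#' @param scenario An [fb_scenario()].
#' @param config An [fb_config()].
#' @return A list with `coverage`, `se`, `mean_length`, `sd_length`,
#'   `truth`, `reps`, `level`.
#' @export
run_coverage <- function(scenario, config = fb_config()) {
  sc <- scenario
  truth <- if (is.null(sc$ps2)) {
    fbeta_score(sc$ps1, sc$pp1, sc$beta)
  } else {
    fbeta_score(sc$ps1, sc$pp1, sc$beta) - fbeta_score(sc$ps2, sc$pp2, sc$beta)
  }
  tabs <- simulate_tables(sc)
  cache <- new.env(parent = emptyenv())
  ci_of <- function(tab) {
    key <- if (inherits(tab, "paired_observation")) {
      sprintf("%d.%d.%d.%d", tab$obs1$tp, tab$obs1$fp, tab$obs2$tp, tab$obs2$fp)
    } else {
      sprintf("%d.%d", tab$tp, tab$fp)
    }
    ci <- cache[[key]]
    if (is.null(ci)) {
      ci <- if (inherits(tab, "paired_observation")) {
        ci_fbeta_two(tab, sc$beta, sc$level, config = config)
      } else {
        ci_fbeta_one(tab, sc$beta, sc$level, config = config)
      }
      cache[[key]] <- ci
    }
    ci
  }
  hit <- logical(sc$reps); len <- numeric(sc$reps)
  for (i in seq_len(sc$reps)) {
    ci <- ci_of(tabs[[i]])
    hit[i] <- ci$lower - 1e-12 <= truth && truth <= ci$upper + 1e-12
    len[i] <- ci$upper - ci$lower
  }
  cov <- mean(hit)
  list(coverage = cov, se = sqrt(cov * (1 - cov) / sc$reps),
       mean_length = mean(len), sd_length = stats::sd(len),
       truth = truth, reps = sc$reps, level = sc$level)
}

#' Monte-Carlo rejection rate of the exact tests
#'
#' For single-classifier scenarios with null rates, applies the point-null
#' test to each simulated table; for two-classifier scenarios, the pooled
#' difference test with the null margins at the scenario's *generating*
#' averages. Reports the rejection fraction (empirical power, or type-I
#' error when the truth satisfies the null) with its binomial standard
#' error. The null distribution is built once; per-replicate work is a
#' vectorized p-value lookup.
#'
#' @inheritParams run_coverage
#' @return A list with `rejection_rate`, `se`, `reps`, `alpha`.
#' @export
run_power <- function(scenario, config = fb_config()) {
  sc <- scenario
  M <- sc$N - sc$S
  set.seed(sc$seed)
  if (is.null(sc$ps2)) {
    if (is.null(sc$ps0)) stop_validation("single-classifier power runs need ps0/pp0")
    pa0 <- solve_p_alpha(sc$S, M, sc$ps0, fbeta_score(sc$ps0, sc$pp0, sc$beta),
                         sc$beta, config$trunc_eps)
    g0 <- score_pmf(sc$S, M, sc$ps0, pa0, sc$beta, config$trunc_eps)
    mach <- pv_machinery(g0, config$tie_tol)
    pa1 <- scenario_rate(sc, sc$ps1, sc$pp1)
    d <- stats::rbinom(sc$reps, sc$S, sc$ps1)
    b <- stats::rbinom(sc$reps, M, pa1)
    b2 <- sc$beta^2
    fobs <- (1 + b2) * d / (b + d + b2 * sc$S)
    pv <- mach$pv_two(fobs)
  } else {
    psb <- (sc$ps1 + sc$ps2) / 2; ppb <- (sc$pp1 + sc$pp2) / 2
    bd <- build_diff(sc$S, M, psb, ppb, psb, ppb, sc$beta, config)
    pa1 <- scenario_rate(sc, sc$ps1, sc$pp1)
    pa2 <- scenario_rate(sc, sc$ps2, sc$pp2)
    d1 <- stats::rbinom(sc$reps, sc$S, sc$ps1)
    b1 <- stats::rbinom(sc$reps, M, pa1)
    d2 <- stats::rbinom(sc$reps, sc$S, sc$ps2)
    b2c <- stats::rbinom(sc$reps, M, pa2)
    bsq <- sc$beta^2
    dobs <- (1 + bsq) * d1 / (b1 + d1 + bsq * sc$S) -
            (1 + bsq) * d2 / (b2c + d2 + bsq * sc$S)
    pv <- if (bd$method == "exact") {
      pv_machinery(bd$dist, config$tie_tol)$pv_two(dobs)
    } else {
      vapply(dobs, function(x) normal_pvalue(bd$mom, x), numeric(1))
    }
  }
  rej <- mean(pv < sc$alpha - config$tie_tol)
  list(rejection_rate = rej, se = sqrt(rej * (1 - rej) / sc$reps),
       reps = sc$reps, alpha = sc$alpha)
}
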