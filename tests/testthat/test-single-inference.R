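test_that("ci_fbeta_one reproduces the prenatal-screening application", {
  # cfDNA arm: N = 15841, S = 38, tp = 38, fp = 9
  ci1 <- ci_fbeta_one(confusion_table(15841, 38, 38, 9))
  expect_equal(ci1$method, "exact")
  expect_equal(round(ci1$lower, 3), 0.817)
  expect_equal(round(ci1$upper, 3), 0.950)
  # standard-screening arm: much lower precision, far tighter interval
  ci2 <- ci_fbeta_one(confusion_table(15841, 38, 30, 854))
  expect_equal(round(ci2$lower, 3), 0.054)
  expect_equal(round(ci2$upper, 3), 0.077)
  expect_equal(round(ci2$upper - ci2$lower, 3), 0.023)
})

test_that("ci endpoints are support members and degenerate cases work", {
  obs <- confusion_table(50, 20, 18, 6)
  ci <- ci_fbeta_one(obs)
  pl <- list(ps = 18.5 / 21, pp = 18.5 / 25)
  pa <- solve_p_alpha(20, 30, pl$ps, fbeta_score(pl$ps, pl$pp))
  d <- score_pmf(20, 30, pl$ps, pa)
  expect_true(any(abs(d$support - ci$lower) < 1e-12))
  expect_true(any(abs(d$support - ci$upper) < 1e-12))
  expect_lte(ci$lower, ci$upper)
  # all-correct small observation: the upper endpoint is the maximal score
  ci_top <- ci_fbeta_one(confusion_table(4, 2, 2, 0))
  expect_equal(ci_top$upper, 1)
})

test_that("point-null test matches full-enumeration oracle at N = 10", {
  obs <- confusion_table(10, 4, 4, 1)
  tst <- test_fbeta_point(obs, ps0 = 0.8, pp0 = 0.5)
  pa0 <- solve_p_alpha(4, 6, 0.8, fbeta_score(0.8, 0.5))
  pmf <- enum_pmf(enum_cells(4, 6, 0.8, pa0))
  expect_equal(tst$p_value, enum_pv(pmf, fbeta_estimate(obs)),
               tolerance = 1e-10)
  expect_equal(tst$method, "exact")
})

test_that("least-extreme observations give p-value 1; one-sided tails sum", {
  pa0 <- solve_p_alpha(4, 6, 0.8, fbeta_score(0.8, 0.5))
  d <- score_pmf(4, 6, 0.8, pa0)
  # pick the support point with maximal min-tail statistic: an observation
  # there can never be extreme
  cl <- cumsum(d$probs); cr <- rev(cumsum(rev(d$probs)))
  f_mid <- d$support[which.max(pmin(cl, cr))]
  cand <- expand.grid(tp = 0:4, fp = 0:6)
  cand$f <- 2 * cand$tp / (cand$fp + cand$tp + 4)
  hit <- cand[abs(cand$f - f_mid) < 1e-12, ][1, ]
  obs <- confusion_table(10, 4, hit$tp, hit$fp)
  expect_equal(test_fbeta_point(obs, 0.8, 0.5)$p_value, 1, tolerance = 1e-12)
  # one-sided p-values are plain tail sums and add up to >= 1
  g <- test_fbeta_point(obs, 0.8, 0.5, alternative = "greater")$p_value
  l <- test_fbeta_point(obs, 0.8, 0.5, alternative = "less")$p_value
  expect_equal(g, sum(d$probs[d$support >= hit$f - 1e-12]), tolerance = 1e-12)
  expect_equal(l, sum(d$probs[d$support <= hit$f + 1e-12]), tolerance = 1e-12)
  expect_gte(g + l, 1)
})

test_that("exact point-null test is valid (size <= alpha) by enumeration", {
  for (cfg in list(list(N = 12, S = 5, ps0 = 0.8, pp0 = 0.5),
                   list(N = 16, S = 6, ps0 = 0.7, pp0 = 0.6),
                   list(N = 20, S = 8, ps0 = 0.9, pp0 = 0.6))) {
    M <- cfg$N - cfg$S
    pa0 <- solve_p_alpha(cfg$S, M, cfg$ps0, fbeta_score(cfg$ps0, cfg$pp0))
    d0 <- score_pmf(cfg$S, M, cfg$ps0, pa0)
    # p-value of every possible observation under the null
    cand <- expand.grid(tp = 0:cfg$S, fp = 0:M)
    pv <- vapply(seq_len(nrow(cand)), function(i) {
      test_fbeta_point(confusion_table(cfg$N, cfg$S, cand$tp[i], cand$fp[i]),
                       cfg$ps0, cfg$pp0)$p_value
    }, numeric(1))
    prob <- dbinom(cand$tp, cfg$S, cfg$ps0) * dbinom(cand$fp, M, pa0)
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_lte(sum(prob[pv <= alpha]), alpha + 1e-9)
    }
  }
})

test_that("benchmark-null p-value dominates the point-null p-value", {
  obs <- confusion_table(50, 20, 18, 6)
  f0 <- fbeta_score(0.8, 0.5)  # 0.615...
  pv_point <- test_fbeta_point(obs, 0.8, 0.5)$p_value
  pv_bench <- test_fbeta_benchmark(obs, f0)$p_value
  expect_gte(pv_bench, pv_point - 1e-12)
})

test_that("benchmark test is 1 at the observed operating point and stable under refinement", {
  obs <- confusion_table(10, 4, 3, 2)
  pl <- list(ps = 3 / 4, pp = 3 / 5)
  pv_self <- test_fbeta_benchmark(obs, fbeta_score(pl$ps, pl$pp))$p_value
  expect_equal(pv_self, 1, tolerance = 1e-9)
  # sup over a coarse grid agrees with a fine grid
  coarse <- test_fbeta_benchmark(obs, 0.5,
                                 config = fb_config(grid_step = 1e-2,
                                                    refine_step = 1e-3))
  fine <- test_fbeta_benchmark(obs, 0.5,
                               config = fb_config(grid_step = 1e-3,
                                                  refine_step = 1e-5))
  expect_equal(coarse$p_value, fine$p_value, tolerance = 1e-4)
})

test_that("analytic power reproduces the published single-classifier grid", {
  expect_equal(power_fbeta_one(0.8, 0.5, 0.9, 0.6, 150, 60)$power, 0.913,
               tolerance = 1e-3)
  expect_equal(power_fbeta_one(0.8, 0.5, 0.9, 0.6, 50, 20)$power, 0.460,
               tolerance = 1e-3)
  expect_equal(power_fbeta_one(0.8, 0.5, 0.9, 0.6, 100, 40, beta = 2)$power,
               0.619, tolerance = 1e-3)
})

test_that("power is bounded by alpha under the null and monotone in effect", {
  p_null <- power_fbeta_one(0.8, 0.5, 0.8, 0.5, 60, 24)$power
  expect_lte(p_null, 0.05 + 1e-12)
  pw <- vapply(c(0.82, 0.86, 0.9, 0.94), function(ps1) {
    power_fbeta_one(0.8, 0.5, ps1, 0.6, 80, 32)$power
  }, numeric(1))
  expect_true(all(diff(pw) >= -1e-12))
})

test_that("sample_size_fbeta_one finds a guarded minimal design", {
  des <- sample_size_fbeta_one(0.8, 0.5, 0.9, 0.6, pI = 0.4,
                               target_power = 0.90)
  # the published grid reaches power 0.913 at N = 150, S = 60
  expect_lte(des$N, 150)
  expect_gte(des$power, 0.90)
  expect_equal(des$S, max(1, floor(des$N * 0.4 + 0.5)))
  # guarded self-consistency: the window above N holds the target, and one
  # step below either fails the target or fails its own guard window
  pow_at <- function(N) {
    S <- max(1, floor(N * 0.4 + 0.5))
    power_fbeta_one(0.8, 0.5, 0.9, 0.6, N, S)$power
  }
  expect_true(all(vapply(des$N + 0:3, pow_at, numeric(1)) >= 0.90))
  below <- vapply((des$N - 1) + 0:3, pow_at, numeric(1))
  expect_true(any(below < 0.90))
  # a laxer target never needs a larger design
  des0 <- sample_size_fbeta_one(0.8, 0.5, 0.9, 0.6, pI = 0.4,
                                target_power = 0.30)
  expect_lte(des0$N, des$N)
  expect_gte(des0$power, 0.30)
})

test_that("interval and benchmark test cohere on small instances", {
  # a benchmark value strictly inside the interval should not be rejected
  # (soft duality; verified on these fixed cases)
  for (counts in list(c(30, 12, 10, 4), c(40, 16, 13, 8))) {
    obs <- confusion_table(counts[1], counts[2], counts[3], counts[4])
    ci <- ci_fbeta_one(obs)
    mid <- (ci$lower + ci$upper) / 2
    pv <- test_fbeta_benchmark(obs, mid,
                               config = fb_config(grid_step = 5e-3,
                                                  refine_step = 5e-4))$p_value
    expect_gt(pv, 0.05)
  }
})
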