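test_that("p_alpha calibration reproduces the published design values", {
  target <- fbeta_score(0.9, 0.6)  # 0.72
  expect_equal(round(solve_p_alpha(20, 30, 0.9, target), 2), 0.40)
  expect_equal(round(solve_p_alpha(20, 80, 0.9, target), 2), 0.15)
  expect_equal(round(solve_p_alpha(20, 130, 0.9, target), 2), 0.09)
})

test_that("the solved root satisfies the double-sum equation directly", {
  # independent oracle: full 6x6 double sum at the returned root
  pa <- solve_p_alpha(5, 5, 0.8, 0.7)
  expect_equal(enum_expectation(5, 5, 0.8, pa), 0.7, tolerance = 1e-9)
  # and a second instance with beta != 1
  pa2 <- solve_p_alpha(6, 8, 0.9, 0.8, beta = 2)
  expect_equal(enum_expectation(6, 8, 0.9, pa2, beta = 2), 0.8,
               tolerance = 1e-9)
})

test_that("boundary and infeasible calibrations behave as specified", {
  # a perfect score needs b = 0, d = S
  expect_equal(solve_p_alpha(20, 30, 1, 1), 0)
  # tiny S: no p_alpha can reach the target
  err <- tryCatch(solve_p_alpha(2, 1000, 0.5, 0.9),
                  fb_infeasible_error = function(e) e)
  expect_s3_class(err, "fb_infeasible_error")
  expect_match(conditionMessage(err), "Increase S")
  expect_error(solve_p_alpha(5, 5, 0.8, 0), class = "fb_validation_error")
})

test_that("the expected score is strictly decreasing in p_alpha", {
  for (cfg in list(c(10, 20, 0.8, 1), c(20, 30, 0.9, 0.5), c(8, 40, 0.6, 2))) {
    e <- vapply(seq(0, 1, by = 0.1), function(pa) {
      expected_fbeta(cfg[1], cfg[2], cfg[3], pa, cfg[4])
    }, numeric(1))
    expect_true(all(diff(e) < 0))
  }
})

test_that("score_pmf enumerates the S = 2, M = 2 lattice exactly", {
  d <- score_pmf(2, 2, ps = 0.5, p_alpha = 0.5)
  ref <- enum_pmf(enum_cells(2, 2, 0.5, 0.5))
  expect_equal(d$support, ref$v, tolerance = 1e-9)
  expect_equal(d$probs, ref$x, tolerance = 1e-12)
  expect_equal(sum(d$probs), 1, tolerance = 1e-12)
})

test_that("degenerate rates give point masses", {
  expect_equal(score_pmf(5, 7, ps = 1, p_alpha = 0)$support, 1)
  expect_equal(score_pmf(5, 7, ps = 1, p_alpha = 0)$probs, 1)
  d0 <- score_pmf(5, 7, ps = 0, p_alpha = 0.3)
  expect_equal(d0$support, 0)
  expect_equal(sum(d0$probs), 1)
})

test_that("rational grouping merges equal score values exactly", {
  # with S = 4: 2*1/(0+1+4) = 2*2/(2+2+6)? no -- construct a genuine tie:
  # f = 2d/(b+d+S); d=1,b=1 gives 2/6 and d=2,b=4 gives 4/10; with S = 4
  # d=1,b=1 -> 1/3 and d=2,b=4 -> 2/5. Use S = 3: d=1,b=0 -> 2/4 = 1/2 and
  # d=2,b=3 -> 4/8 = 1/2: a tie across different (b, d).
  d <- score_pmf(3, 5, ps = 0.6, p_alpha = 0.4)
  expect_true(all(diff(d$support) > 0))
  p_half <- d$probs[abs(d$support - 0.5) < 1e-12]
  manual <- dbinom(1, 3, 0.6) * dbinom(0, 5, 0.4) +
    dbinom(2, 3, 0.6) * dbinom(3, 5, 0.4)
  expect_equal(p_half, manual, tolerance = 1e-12)
})

test_that("score_pmf agrees with the brute-force oracle on sampled cases", {
  set.seed(42)
  for (i in 1:8) {
    S <- sample(2:12, 1); M <- sample(2:12, 1)
    ps <- runif(1, 0.2, 0.95); pa <- runif(1, 0.05, 0.6)
    beta <- sample(c(0.5, 1, 2), 1)
    a <- score_pmf(S, M, ps, pa, beta)
    b <- brute_force_pmf(S, M, ps, pa, beta)
    expect_equal(a$support, b$support, tolerance = 1e-12)
    expect_equal(max(abs(a$probs - b$probs)), 0, tolerance = 1e-12)
  }
})

test_that("brute_force_pmf refuses large instances and keeps unit mass", {
  expect_error(brute_force_pmf(200, 200, 0.5, 0.5),
               class = "fb_resource_error")
  b <- brute_force_pmf(5, 10, 0.7, 0.2)
  expect_equal(sum(b$probs), 1, tolerance = 1e-12)
  expect_equal(sum(b$support * b$probs), enum_expectation(5, 10, 0.7, 0.2),
               tolerance = 1e-12)
})

test_that("tail truncation keeps mass accounting at large N", {
  pa <- solve_p_alpha(38, 15803, 0.95, 0.85)
  d <- score_pmf(38, 15803, 0.95, pa)
  expect_lt(d$trunc_mass, 1e-10)
  expect_equal(sum(d$probs), 1, tolerance = 1e-9)
  # calibration invariant: mean of the enumerated pmf hits the target
  expect_equal(sum(d$support * d$probs), 0.85, tolerance = 1e-8)
})

test_that("diff_pmf of identical margins is symmetric about zero", {
  g <- score_pmf(6, 9, 0.8, 0.3)
  h <- diff_pmf(g, g)
  expect_equal(sum(h$probs), 1, tolerance = 1e-12)
  expect_equal(sum(h$support * h$probs), 0, tolerance = 1e-12)
  # exact symmetry point by point
  flip <- rev(-h$support)
  expect_equal(h$support, flip, tolerance = 1e-12)
  expect_lt(max(abs(h$probs - rev(h$probs))), 1e-12)
})

test_that("diff_pmf convolves point masses and matches the 4-fold oracle", {
  one <- score_pmf(3, 3, ps = 1, p_alpha = 0)
  zero <- score_pmf(3, 3, ps = 0, p_alpha = 0)
  h <- diff_pmf(one, zero)
  expect_equal(h$support, 1)
  expect_equal(h$probs, 1)

  pa1 <- solve_p_alpha(2, 2, 0.9, fbeta_score(0.9, 0.7))
  pa2 <- solve_p_alpha(2, 2, 0.5, fbeta_score(0.5, 0.7))
  h2 <- diff_pmf(score_pmf(2, 2, 0.9, pa1), score_pmf(2, 2, 0.5, pa2))
  ref <- enum_diff_pmf(2, 2, 0.9, pa1, 0.5, pa2)
  expect_equal(h2$support, ref$v, tolerance = 1e-9)
  expect_equal(h2$probs, ref$x, tolerance = 1e-12)
})

test_that("diff_pmf enforces the convolution cap and shared design", {
  g1 <- score_pmf(20, 60, 0.8, 0.3)
  g2 <- score_pmf(20, 60, 0.9, 0.2)
  expect_error(diff_pmf(g1, g2, conv_cap = 10), class = "fb_resource_error")
  g3 <- score_pmf(10, 60, 0.8, 0.3)
  expect_error(diff_pmf(g1, g3), class = "fb_validation_error")
})

test_that("the closed-form p_alpha approximation converges as N grows", {
  # relative error < 1% at N = 5000, S = 1000
  exact <- solve_p_alpha(1000, 4000, 0.9, fbeta_score(0.9, 0.6))
  approx <- p_alpha_approx(1000, 4000, 0.9, 0.6)
  expect_lt(abs(approx - exact) / exact, 0.01)
  # and the error shrinks with N at fixed S/N
  exact_small <- solve_p_alpha(100, 400, 0.9, fbeta_score(0.9, 0.6))
  approx_small <- p_alpha_approx(100, 400, 0.9, 0.6)
  expect_lt(abs(approx - exact) / exact,
            abs(approx_small - exact_small) / exact_small)
})

test_that("beta = 1 reproduces the F1 score identity 2d/(b+d+S)", {
  S <- 7; M <- 9
  d <- score_pmf(S, M, 0.75, 0.25, beta = 1)
  cells <- enum_cells(S, M, 0.75, 0.25, beta = 1)
  expect_true(all(vapply(d$support, function(f) {
    any(abs(2 * cells$d / (cells$b + cells$d + S) - f) < 1e-12)
  }, logical(1))))
})
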