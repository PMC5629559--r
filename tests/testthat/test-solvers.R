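test_that("lookup table has the documented grid and endpoints", {
  tbl <- build_lookup(0.01)
  expect_equal(nrow(tbl), 76)
  expect_equal(tbl$p_1st[1], 0.25)
  expect_equal(tbl$p_1st[76], 1.00)
  expect_equal(tbl$I[1], 0)
  expect_equal(tbl$I[76], 2)
  expect_true(all(diff(tbl$I) > 0))   # strictly increasing
  expect_error(build_lookup(0.3), "0.25")
  expect_error(build_lookup(0), "0.25")
})

test_that("single-strong inversion hits landmarks and the brute-force value", {
  expect_equal(solve_single_strong(2), 1)
  expect_equal(solve_single_strong(0), 0.25)
  # frozen from the 1e-6 grid-search oracle: I = 1 -> p ~ 0.81071
  expect_equal(solve_single_strong(1), 0.81071, tolerance = 1e-3)
  # small overshoot clamps, large errors
  expect_equal(solve_single_strong(2.04), 1)
  expect_equal(solve_single_strong(-0.04), 0.25)
  expect_error(solve_single_strong(2.2), "outside")
  expect_error(solve_single_strong(-0.2), "outside")
})

test_that("single-strong inversion is monotone in I", {
  ps <- vapply(seq(0, 2, by = 0.05), solve_single_strong, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("inversion round trip recovers p across the whole grid", {
  for (p in seq(0.25, 1, by = 0.005)) {
    I <- information_content(c(p, rep((1 - p) / 3, 3)))
    expect_lt(abs(solve_single_strong(I) - p), 0.01)
  }
})

test_that("two-strong inversion solves the landmark and derived cases", {
  s <- solve_two_strong(1, 1)
  expect_true(s$ok)
  expect_equal(s$p_1st, 0.5, tolerance = 1e-3)   # p_weak forced to 0
  expect_equal(s$p_2nd, 0.5, tolerance = 1e-3)

  s0 <- solve_two_strong(0, 1)
  expect_equal(s0$p_1st, 0.25, tolerance = 1e-3) # uniform column
  expect_equal(s0$p_2nd, 0.25, tolerance = 1e-3)

  # frozen from the 1e-6 grid-search oracle: I = 0.5, r = 0.5
  s5 <- solve_two_strong(0.5, 0.5)
  expect_equal(s5$p_1st, 0.576744, tolerance = 1e-3)
  expect_equal(s5$p_2nd / s5$p_1st, 0.5, tolerance = 1e-9)
  expect_lt(abs(oracle_ic_two(s5$p_1st, 0.5) - 0.5), 1e-4)

  # infeasible pair: two equal strong letters cannot carry 1.9 bits
  bad <- solve_two_strong(1.9, 1)
  expect_false(bad$ok)
  expect_error(solve_two_strong(1, 0), "height_ratio")
  expect_error(solve_two_strong(1, 1.5), "height_ratio")
})

test_that("two-strong round trip recovers (p1, p2) across a feasible grid", {
  for (p1 in seq(0.3, 0.9, by = 0.1)) {
    for (p2 in seq(0.1, p1, by = 0.1)) {
      w <- (1 - p1 - p2) / 2
      if (w < 0 || p2 < w) next                 # outside the model's premise
      I <- information_content(c(p1, p2, w, w))
      s <- solve_two_strong(I, p2 / p1)
      expect_true(s$ok)
      expect_lt(abs(s$p_1st - p1), 0.01)
      expect_lt(abs(s$p_2nd - p2), 0.01)
    }
  }
})

test_that("both solvers agree with the 1e-6 grid-search oracle", {
  set.seed(99)
  for (k in 1:25) {
    I <- runif(1, 0, 2)
    expect_lt(abs(solve_single_strong(I) - oracle_single(I)), 1e-3)
  }
  for (k in 1:25) {
    r <- runif(1, 0.15, 1)
    lo <- oracle_ic_two(1 / (1 + 3 * r), r)
    hi <- oracle_ic_two(1 / (1 + r), r)
    I <- runif(1, lo, hi)
    s <- solve_two_strong(I, r)
    expect_true(s$ok)
    expect_lt(abs(s$p_1st - oracle_two(I, r)), 1e-3)
  }
})

test_that("estimate_column applies the 3-pixel secondary-letter rule", {
  # full-height single letter
  e <- estimate_column(100, c(A = 100), 100)
  expect_equal(e$case_used, "single_strong")
  expect_equal(e$info_content, 2)
  expect_equal(unname(e$probs), c(1, 0, 0, 0))
  expect_equal(e$top_letter, "A")

  # 2-pixel secondary letter does NOT trigger the two-strong case
  e2 <- estimate_column(50, c(C = 30, G = 2), 100)
  expect_equal(e2$case_used, "single_strong")
  expect_equal(e2$top_letter, "C")
  expect_equal(e2$info_content, 1)
  expect_equal(unname(e2$probs["C"]), 0.81071, tolerance = 1e-3)
  expect_equal(unname(e2$probs["A"]), (1 - e2$probs[["C"]]) / 3)

  # 3-pixel secondary letter does
  e3 <- estimate_column(50, c(C = 30, G = 3), 100)
  expect_equal(e3$case_used, "two_strong")
  expect_equal(e3$second_letter, "G")

  # two equal strong letters at I = 1 force 0.5 / 0.5
  e4 <- estimate_column(50, c(C = 25, T = 25), 100)
  expect_equal(e4$case_used, "two_strong")
  expect_equal(unname(e4$probs), c(0, 0.5, 0, 0.5), tolerance = 1e-3)

  expect_error(estimate_column(10, c(A = 0, C = 0), 100), "empty column")
  expect_error(estimate_column(0, c(A = 0), 100), "empty column")
})

test_that("every column estimate lies on the probability simplex", {
  set.seed(4)
  for (k in 1:50) {
    full <- 150
    stack <- sample(5:150, 1)
    h <- sort(sample(0:stack, 4), decreasing = TRUE)
    h[1] <- max(h[1], 1)
    e <- estimate_column(stack, setNames(h, c("G", "A", "T", "C")), full)
    expect_true(all(e$probs >= 0))
    expect_equal(sum(e$probs), 1, tolerance = 1e-9)
    expect_gte(e$info_content, 0)
    expect_lte(e$info_content, 2)
  }
})
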