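test_that("proportion test matches the closed form and handles degeneracy", {
  r <- proportion_test(8, 10, 2, 10)
  # pooled p* = 0.5, se = sqrt(0.25 * 0.2)
  expect_equal(r$z, 0.6 / sqrt(0.05), tolerance = 1e-12)
  expect_equal(r$L1, 2 * pnorm(-0.6 / sqrt(0.05)), tolerance = 1e-12)

  eq <- proportion_test(5, 10, 5, 10)
  expect_identical(eq$z, 0)
  expect_identical(eq$L1, 1)

  allzero <- proportion_test(0, 10, 0, 10)
  expect_identical(allzero$z, 0)
  expect_identical(allzero$L1, 1)
  allon <- proportion_test(10, 10, 7, 7)
  expect_identical(allon$L1, 1)

  expect_error(proportion_test(11, 10, 2, 10), "0 <= m <= n")
  expect_error(proportion_test(1, 0, 1, 5), ">= 1")
})

test_that("proportion test is vectorised consistently", {
  m1 <- c(0, 3, 8); m2 <- c(0, 5, 2)
  r <- proportion_test(m1, 10, m2, 10)
  for (i in 1:3) {
    ri <- proportion_test(m1[i], 10, m2[i], 10)
    expect_equal(r$z[i], ri$z)
    expect_equal(r$L1[i], ri$L1)
  }
})

test_that("location test reproduces the Welch t-test", {
  r <- location_test(1:5, 6:10)
  expect_equal(r$t, -5, tolerance = 1e-12)
  expect_equal(r$df_t, 8, tolerance = 1e-12)
  expect_equal(r$L2, 2 * pt(-5, 8), tolerance = 1e-12)

  same <- location_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_identical(same$L2, 1)

  const <- location_test(c(2, 2, 2), c(2, 2, 2))
  expect_identical(const$L2, 1)
  expect_true(const$degenerate)

  shifted <- location_test(c(2, 2, 2), c(5, 5, 5))
  expect_lt(shifted$L2, 1e-250)
  expect_false(shifted$degenerate)

  expect_error(location_test(c(0, 1, 2), c(1, 2, 3)), "positive")
})

test_that("scale test reproduces the Brown-Forsythe statistic", {
  r <- scale_test(c(1, 2, 3, 4, 5), c(1, 1, 3, 5, 5))
  expect_equal(r$W, 8 * 0.4 / 6, tolerance = 1e-12)
  expect_equal(r$L3, pf(8 * 0.4 / 6, 1, 8, lower.tail = FALSE),
               tolerance = 1e-12)

  same <- scale_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$W, 0)
  expect_identical(same$L3, 1)

  spread <- scale_test(c(1, 1, 1, 1), c(1, 9, 1, 9))
  expect_lt(spread$L3, 0.05)

  expect_error(scale_test(c(1, -1, 2), c(1, 2, 3)), "positive")
})

test_that("components match reference implementations on random inputs", {
  set.seed(4711)
  n_checked <- 0
  for (i in 1:1000) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    m1 <- sample(0:n1, 1); m2 <- sample(0:n2, 1)
    mine <- proportion_test(m1, n1, m2, n2)
    pooled <- (m1 + m2) / (n1 + n2)
    if (pooled > 0 && pooled < 1) {
      ref <- suppressWarnings(prop.test(c(m1, m2), c(n1, n2),
                                        correct = FALSE))
      expect_equal(mine$z^2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$L1, ref$p.value, tolerance = 1e-10)
    }

    a <- rpois(sample(3:40, 1), sample(2:8, 1)) + 1
    b <- rpois(sample(3:40, 1), sample(2:8, 1)) + 1
    if (var(a) + var(b) > 0) {
      tref <- t.test(a, b)
      tmine <- location_test(a, b)
      expect_equal(tmine$t, unname(tref$statistic), tolerance = 1e-10)
      expect_equal(tmine$df_t, unname(tref$parameter), tolerance = 1e-10)
      expect_equal(tmine$L2, tref$p.value, tolerance = 1e-10)
    }

    smine <- scale_test(a, b)
    if (is.finite(smine$W) && smine$W > 0) {
      lev <- car::leveneTest(
        c(a, b), factor(rep(1:2, c(length(a), length(b)))),
        center = median)
      expect_equal(smine$W, lev$`F value`[1], tolerance = 1e-10)
      expect_equal(smine$L3, lev$`Pr(>F)`[1], tolerance = 1e-10)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 500)
})
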