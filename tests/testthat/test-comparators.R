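test_that("ICC matches an independent aov mean-squares oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    y <- matrix(runif(n * k, 0, 10), n, k)
    res <- icc(ratings_table(y))
    # oracle: mean squares from stats::aov on the long two-way layout
    long <- data.frame(y = as.vector(y),
                       case = factor(rep(seq_len(n), k)),
                       obs = factor(rep(seq_len(k), each = n)))
    ms <- summary(aov(y ~ case + obs, data = long))[[1]][["Mean Sq"]]
    expected <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    expect_equal(res$value, expected, tolerance = 1e-10)
  }
})

test_that("ICC extremes and input contract behave", {
  # identical observer columns: perfect reliability
  y <- cbind(1:6, 1:6)
  expect_equal(icc(ratings_table(y))$value, 1)
  # pure noise around a common constant: reliability near zero
  set.seed(23)
  noise <- matrix(100 + rnorm(3000 * 3), ncol = 3)
  expect_lt(abs(icc(ratings_table(noise))$value), 0.05)
  # invariant to case relabeling
  set.seed(2)
  m <- matrix(runif(24, 0, 10), 8, 3)
  expect_equal(icc(ratings_table(m))$value,
               icc(ratings_table(m[sample(8), ]))$value, tolerance = 1e-12)
  # ragged tables are refused with advice
  expect_error(icc(ratings_table(list(c(1, 2), c(1, 2, 3)))), "complete cases")
  expect_error(icc(ratings_table(list(c(1, 2)))), "two cases")
  expect_true(grepl("absolute agreement", icc(ratings_table(y))$measure))
})

test_that("CCC equals the hand moment formula and penalizes location shift", {
  res <- ccc(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2))
  # independent arithmetic: biased moments computed by hand
  expect_equal(res$value, 2 * 1.2625 / (1.25 + 1.286875 + 0.075^2),
               tolerance = 1e-12)
  x <- c(2, 4, 7, 8, 11)
  expect_equal(ccc(x, x)$value, 1)
  shifted <- ccc(x, x + 3)
  expect_lt(shifted$value, 1)
  expect_lt(abs(shifted$value), abs(shifted$extras[["pearson_r"]]))
  expect_error(ccc(c(2, 2), c(2, 2)), "undefined")
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("|CCC| never exceeds |Pearson r| on random pairs", {
  set.seed(31)
  for (rep in 1:1000) {
    n <- sample(3:20, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, mean = runif(1, -5, 5))
    res <- ccc(x, y)
    expect_lte(abs(res$value), abs(res$extras[["pearson_r"]]) + 1e-12)
  }
})

test_that("limits of agreement follow the closed form", {
  x <- c(3, 1, 5, 2)
  res <- limits_of_agreement(x, x)
  expect_equal(res$value, 0)
  expect_equal(unname(res$extras[c("loa_low", "loa_high")]), c(0, 0))
  # differences (1,-1,1,-1): bias 0, sd 2/sqrt(3)
  res2 <- limits_of_agreement(c(1, -1, 1, -1) + 10, c(10, 10, 10, 10))
  expect_equal(res2$value, 0)
  expect_equal(unname(res2$extras[["loa_high"]]), 1.96 * 2 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(unname(res2$extras[["loa_low"]]), -1.96 * 2 / sqrt(3),
               tolerance = 1e-12)
  expect_error(limits_of_agreement(1, 2), "at least two")
})

test_that("bias between two obstetricians equals the mean column difference", {
  hr <- split_ratings(load_maternal_hr())[["Initial hour"]]
  o1 <- vapply(hr$cases, `[[`, numeric(1), "obstetrician1")
  o2 <- vapply(hr$cases, `[[`, numeric(1), "obstetrician2")
  expect_equal(limits_of_agreement(o1, o2)$value, mean(o1) - mean(o2),
               tolerance = 1e-12)
})

test_that("reliability and disagreement diverge when trait variance changes", {
  # same additive observer error, very different trait spread: the ICC moves a
  # lot (reliability is population-dependent), IBMD barely moves
  wide <- simulate_ratings(n_cases = 400, observers = 3,
                           true_value_range = c(50, 150), noise_scale = 2,
                           error = "additive", seed = 101)
  narrow <- simulate_ratings(n_cases = 400, observers = 3,
                             true_value_range = c(98, 102), noise_scale = 2,
                             error = "additive", seed = 101)
  icc_gap <- abs(icc(wide)$value - icc(narrow)$value)
  ibmd_gap <- abs(ibmd(wide)$estimate - ibmd(narrow)$estimate)
  expect_gt(icc_gap, 0.3)
  expect_lt(ibmd_gap, 0.01)
})
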