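test_that("same seed reproduces the interval bit-for-bit", {
  rt <- random_ragged_seeded()
  a <- ibmd_ci(rt, n_boot = 200, seed = 99)
  b <- ibmd_ci(rt, n_boot = 200, seed = 99)
  expect_identical(a$ci, b$ci)
  expect_identical(a$replicates, b$replicates)
  # a different seed moves the replicates
  expect_false(identical(ibmd_ci(rt, n_boot = 200, seed = 100)$replicates,
                         a$replicates))
})

test_that("bootstrap leaves the caller's RNG stream untouched", {
  rt <- random_ragged_seeded()
  set.seed(1); before <- .Random.seed
  invisible(ibmd_ci(rt, n_boot = 50, seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("replicates match an independent resample-loop oracle on a shared stream", {
  rt <- ratings_table(list(c(10, 12, 11), c(30, 35)))
  est <- ibmd_ci(rt, n_boot = 50, seed = 123)
  set.seed(123)
  expect_equal(est$ci, oracle_bootstrap(rt$cases, n_boot = 50),
               tolerance = 1e-14)
})

test_that("point estimate is the plug-in value, not a bootstrap mean", {
  rt <- random_ragged_seeded()
  est <- ibmd_ci(rt, n_boot = 300, seed = 2)
  expect_identical(est$estimate, ibmd(rt)$estimate)
})

test_that("interval endpoints lie within the replicate range and [0, 1]", {
  set.seed(8)
  for (rep in 1:5) {
    rt <- random_ragged(n_cases = sample(3:20, 1), max_m = 6)
    est <- ibmd_ci(rt, n_boot = 100, seed = rep)
    expect_gte(est$ci[1], max(0, min(est$replicates)))
    expect_lte(est$ci[2], min(1, max(est$replicates)))
    expect_lte(est$ci[1], est$ci[2])
  }
})

test_that("internally constant tables give a degenerate [0, 0] interval", {
  rt <- ratings_table(list(c(4, 4, 4), c(9, 9)))
  est <- ibmd_ci(rt, n_boot = 64, seed = 1)
  expect_identical(unname(est$ci), c(0, 0))
  expect_identical(est$estimate, 0)
})

test_that("a single usable case yields an interval degenerate at the point", {
  rt <- ratings_table(list(c(5, 7, 6)))
  est <- ibmd_ci(rt, n_boot = 50, seed = 3)
  expect_equal(est$ci, rep(est$estimate, 2), tolerance = 1e-15)
})

test_that("unusable input and settings are rejected", {
  expect_error(ibmd_ci(ratings_table(list(1, 2)), n_boot = 100),
               "no comparable pairs")
  rt <- ratings_table(list(c(1, 2)))
  expect_error(ibmd_ci(rt, n_boot = 0), "n_boot")
  expect_error(ibmd_ci(rt, level = 1.2), "level")
})

test_that("each group's interval is independent of the other group", {
  a <- random_ragged_seeded(seed = 10)
  b_small <- random_ragged_seeded(seed = 20, n_cases = 8)
  b_large <- random_ragged_seeded(seed = 30, n_cases = 25)
  c1 <- compare_ibmd(a, b_small, n_boot = 150, seed = 5)
  c2 <- compare_ibmd(a, b_large, n_boot = 150, seed = 5)
  expect_identical(c1$a$ci, c2$a$ci)
  expect_identical(c1$a$replicates, c2$a$replicates)
})

test_that("a table compared against itself shows no difference", {
  rt <- random_ragged_seeded(seed = 14)
  cmp <- compare_ibmd(rt, rt, n_boot = 400, seed = 9)
  expect_true(cmp$ci_overlap)
  expect_lte(cmp$diff_ci[1], 0)
  expect_gte(cmp$diff_ci[2], 0)
})

test_that("overlap flag reflects interval intersection exactly", {
  rt_lo <- ratings_table(lapply(1:12, function(i) c(100, 100 + i %% 3)))
  rt_hi <- ratings_table(lapply(1:12, function(i) c(100, 160 + 5 * i)))
  cmp <- compare_ibmd(rt_lo, rt_hi, n_boot = 300, seed = 6)
  manual <- cmp$a$ci[1] <= cmp$b$ci[2] && cmp$b$ci[1] <= cmp$a$ci[2]
  expect_identical(cmp$ci_overlap, manual)
  expect_false(cmp$ci_overlap)
})

test_that("grouped tables can be compared directly and sizes are sanity-checked", {
  cmp <- compare_ibmd(load_maternal_hr(), n_boot = 100, seed = 2)
  expect_identical(cmp$labels, c("Initial hour", "Last hour"))
  three <- ratings_table(list(c(1, 2), c(2, 3), c(3, 4)),
                         group = c("a", "b", "c"))
  expect_error(compare_ibmd(three), "exactly two groups")
  big <- random_ragged_seeded(seed = 44, n_cases = 60)
  small <- ratings_table(list(c(1, 2), c(4, 5)))
  expect_warning(compare_ibmd(big, small, n_boot = 20, seed = 1),
                 "order of magnitude")
})
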