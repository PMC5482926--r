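test_that("reliable change threshold follows the Jacobson-Truax formula", {
  rci <- compute_rci(r = 0.86, sd = 2.37)
  expect_equal(round(rci$threshold, 2), 2.46)
  expect_equal(compute_rci(r = 1, sd = 5)$threshold, 0)
  expect_equal(compute_rci(r = 0.5, sd = 1, z = 1.96)$threshold, 1.96)
  expect_error(compute_rci(r = 0, sd = 1), "r")
  expect_error(compute_rci(r = 1.2, sd = 1), "r")
  expect_error(compute_rci(r = 0.8, sd = 0), "sd")
})

test_that("threshold is decreasing in r and linear in sd and z", {
  rs <- seq(0.5, 0.99, by = 0.07)
  th <- vapply(rs, function(r) compute_rci(r, 2)$threshold, numeric(1))
  expect_true(all(diff(th) < 0))
  expect_equal(compute_rci(0.8, 4)$threshold,
               2 * compute_rci(0.8, 2)$threshold)
  expect_equal(compute_rci(0.8, 2, z = 3)$threshold,
               1.5 * compute_rci(0.8, 2, z = 2)$threshold)
})

test_that("change classification uses strict inequalities around the threshold", {
  rci <- compute_rci(0.86, 2.37)
  df <- tibble::tibble(
    pre = c(12, 8, 10, 10 + rci$threshold, 10),
    post = c(8, 12, 8, 10, 10 + rci$threshold))
  cc <- classify_change(df, rci)
  expect_equal(as.character(cc$category),
               c("improved", "deteriorated", "unchanged", "unchanged",
                 "unchanged"))
  # exactly at the threshold stays unchanged (strict inequality)
  expect_equal(cc$change[4], rci$threshold, tolerance = 1e-12)
})

test_that("swapping pre and post swaps improved and deteriorated", {
  rci <- compute_rci(0.9, 3)
  withr::with_seed(7, {
    df <- tibble::tibble(pre = runif(200, 0, 27), post = runif(200, 0, 27))
    a <- classify_change(df, rci)
    b <- classify_change(tibble::tibble(pre = df$post, post = df$pre), rci)
    swap <- c(improved = "deteriorated", deteriorated = "improved",
              unchanged = "unchanged")
    expect_identical(unname(swap[as.character(a$category)]),
                     as.character(b$category))
  })
})

test_that("missing pre or post scores are excluded with a logged count", {
  df <- tibble::tibble(pre = c(10, NA, 12), post = c(7, 5, NA))
  expect_message(cc <- classify_change(df, 2.46), "2 subject")
  expect_equal(nrow(cc), 1)
  expect_equal(attr(cc, "n_excluded"), 2L)
})

test_that("within-group effect size is the mean change over the baseline SD", {
  pre <- c(10, 12, 9, 14)
  expect_equal(within_group_effect_size(pre, pre), 0)
  post <- pre - sd(pre)
  expect_equal(within_group_effect_size(pre, post), 1)
  # sample drawn so the true d is 1.63: recovery within sampling error
  withr::with_seed(17, {
    pre_s <- rnorm(4000, 12, 2.4)
    post_s <- pre_s - (1.63 * 2.4 + rnorm(4000, 0, 3))
    d <- within_group_effect_size(pre_s, post_s, sd_baseline = 2.4)
    expect_equal(d, 1.63, tolerance = 0.05)
  })
  expect_error(within_group_effect_size(numeric(0), numeric(0)), "pairs")
})

test_that("pooled-SD effect size reproduces the printed adherence contrasts", {
  expect_equal(round(pooled_sd_effect_size(9.84, 3.90, 158,
                                           8.64, 4.52, 185), 2), 0.28)
  expect_equal(round(pooled_sd_effect_size(2.80, 1.16, 158,
                                           2.37, 1.25, 185), 2), 0.36)
  expect_equal(pooled_sd_effect_size(5, 2, 20, 5, 3, 30), 0)
  expect_error(pooled_sd_effect_size(1, 1, 1, 2, 1, 30), "n >= 2")
  expect_error(pooled_sd_effect_size(1, 0, 10, 2, 0, 30), "SD")
})

test_that("pooled-SD d is antisymmetric and scale-equivariant", {
  d12 <- pooled_sd_effect_size(9.84, 3.9, 158, 8.64, 4.52, 185)
  d21 <- pooled_sd_effect_size(8.64, 4.52, 185, 9.84, 3.9, 158)
  expect_equal(d12, -d21)
  dsc <- pooled_sd_effect_size(9.84 * 3, 3.9 * 3, 158, 8.64 * 3,
                               4.52 * 3, 185)
  expect_equal(d12, dsc)
})

test_that("effect-size report covers classes, overall, and pairwise contrasts", {
  withr::with_seed(23, {
    df <- tibble::tibble(
      class = rep(c("C1", "C2"), each = 40),
      pre = rnorm(80, 11, 2),
      post = c(rnorm(40, 7, 2.5), rnorm(40, 9, 2.5)))
  })
  es <- effect_size_report(df)
  expect_equal(es$within$group, c("C1", "C2", "all"))
  expect_equal(nrow(es$between), 1)
  expect_gt(es$within$d[1], es$within$d[2])
  expect_gt(es$between$d[1], 0)
})
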