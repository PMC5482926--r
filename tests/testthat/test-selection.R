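test_that("BIC is minimized at K = 1 when one class generated the data", {
  lam <- early_lambda()
  sim <- withr::with_seed(101, simulate_pgmm(
    150, 1, matrix(c(10, -1, -1), 3, 1), psi = 1.7, theta = 1, lam))
  sq <- suppressMessages(suppressWarnings(
    fit_sequence(sim$scores, lam, K_max = 3, seed = 7, n_starts = 8)))
  tab <- tidy(sq)
  expect_equal(which.min(tab$bic), 1L)
})

test_that("an underdetermined sequence is rejected", {
  lam <- early_lambda()
  tiny <- matrix(rnorm(10 * 4, 10), 10, 4,
                 dimnames = list(NULL, rownames(lam)))
  expect_error(fit_sequence(tiny, lam, K_max = 4), "underdetermined")
})

test_that("BLRT p-values respect their bounds and hit the lower boundary
           for well-separated classes", {
  lam <- early_lambda()
  mu_true <- matrix(c(2, 0, -0.5, 20, 0, 0.5), 3, 2)
  sim <- withr::with_seed(111, simulate_pgmm(
    120, c(0.5, 0.5), mu_true, psi = 0.5, theta = 0.5, lam))
  b <- suppressMessages(suppressWarnings(
    blrt(sim$scores, lam, K = 2, B = 19, seed = 13, n_starts = 8)))
  expect_gte(b$p_value, 1 / (b$B + 1))
  expect_lte(b$p_value, 1)
  # the separation is enormous: the observed statistic beats every
  # null replicate, so p sits exactly at 1/(B+1)
  expect_equal(b$p_value, 1 / 20)
  expect_length(b$replicates, 19)
  expect_true(all(b$replicates < b$statistic))
})

test_that("the selector implements the two-fold BIC + BLRT loop", {
  runner_for <- function(p_by_k) function(K) list(p_value = p_by_k[[as.character(K)]])

  # step-down branch: BIC minimum at 3, BLRT(3 vs 2) n.s., BLRT(2 vs 1)
  # significant -> K = 2
  sel <- select_by_bic_blrt(c(100, 90, 80, 85),
                            runner_for(list(`3` = 0.40, `2` = 0.01)))
  expect_identical(sel$K, 2L)
  expect_equal(sel$blrt_tests$K, c(3L, 2L))
  expect_equal(sel$blrt_tests$significant, c(FALSE, TRUE))

  # BIC strictly increasing from K = 1: no BLRT may be invoked
  sel1 <- select_by_bic_blrt(c(100, 110, 120),
                             function(K) stop("BLRT must not run"))
  expect_identical(sel1$K, 1L)

  # chain exhaustion falls back to a single class
  sel0 <- select_by_bic_blrt(c(100, 90, 95),
                             runner_for(list(`2` = 0.50)))
  expect_identical(sel0$K, 1L)

  # BIC decreasing through K_max: the candidate is K_max itself
  sel4 <- select_by_bic_blrt(c(100, 90, 80, 70),
                             runner_for(list(`4` = 0.01)))
  expect_identical(sel4$K, 4L)
})

test_that("a recorded decision trail replays to the same K", {
  lam <- early_lambda()
  sim <- simulate_study(default_study_config(), seed = 121)
  sq <- suppressMessages(suppressWarnings(
    fit_sequence(sim$data, lam, K_max = 3, seed = 3, n_starts = 8)))
  sel <- suppressMessages(suppressWarnings(
    select_by_bic_blrt(sq, B = 9, seed = 17, replicate_starts = 3)))
  replay_runner <- function(K) {
    list(p_value = sel$blrt_tests$p_value[match(K, sel$blrt_tests$K)])
  }
  replay <- select_by_bic_blrt(sel$bic_path$bic, replay_runner,
                               alpha = sel$alpha)
  expect_identical(replay$K, sel$K)
  expect_equal(replay$bic_path, sel$bic_path)
})
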