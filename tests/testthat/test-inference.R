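test_that("permutation loss sampling produces the requested repetitions", {
  set.seed(1)
  X <- one_change_matrix(40, 40, 10)
  l <- permutation_losses(X, candidates = 40L, i = 1, rank = 2, nreps = 5)
  expect_length(l$observed, 5)
  expect_length(l$permuted, 5)
  expect_equal(l$candidate, 40L)
  expect_true(all(l$observed >= 0) && all(l$permuted >= 0))
})

test_that("a flanking segment shorter than 2 rows auto-rejects the candidate", {
  set.seed(2)
  X <- stationary_matrix(30, 6)
  expect_warning(out <- permutation_losses(X, candidates = c(1L, 15L), i = 1,
                                           rank = 2, nreps = 3),
                 "auto-rejected")
  expect_null(out)
})

test_that("a genuine regime change separates observed from permuted losses", {
  set.seed(3)
  lower <- replicate(10, {
    X <- one_change_matrix(60, 60, 20)
    l <- permutation_losses(X, candidates = 60L, i = 1, rank = 2, nreps = 10)
    mean(l$observed) < mean(l$permuted)
  })
  expect_gte(mean(lower), 0.9)
})

test_that("at an independently chosen split on stationary data the losses agree", {
  # under the null the observed arrangement is one draw from the
  # arrangement population, so its mean sits within ~2 permutation
  # standard deviations of the permuted mean
  set.seed(4)
  close_enough <- replicate(10, {
    X <- stationary_matrix(120, 20)
    l <- permutation_losses(X, candidates = 60L, i = 1, rank = 2, nreps = 20)
    abs(mean(l$observed) - mean(l$permuted)) < 2 * sd(l$permuted)
  })
  expect_gte(mean(close_enough), 0.8)
})

test_that("the Welch statistic matches the hand case and t.test", {
  # exact-moment samples: mean 8 var 1 vs mean 10 var 1, n = 100 each
  set.seed(5)
  mk <- function(m) as.numeric(scale(rnorm(100))) + m
  l <- list(candidate = 50, observed = mk(8), permuted = mk(10))
  res <- welch_bh_test(list(l), alpha = 0.01)[[1]]
  expect_equal(res$t_stat, -2 / sqrt(0.02), tolerance = 1e-10)
  expect_lt(res$p_adj, 1e-10)
  expect_true(res$significant)
  expect_equal(res$p_adj, res$p_raw)  # BH with one test is the identity

  # independent route: stats::t.test on the same samples
  tt <- t.test(l$observed, l$permuted, alternative = "less")
  expect_equal(res$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("equal means give t = 0 and one-sided p = 0.5", {
  x <- c(1, 2, 3, 4)
  l <- list(candidate = 10, observed = x, permuted = rev(x))
  res <- welch_bh_test(list(l), alpha = 0.01)[[1]]
  expect_equal(res$t_stat, 0)
  expect_equal(res$p_raw, 0.5)
  expect_false(res$significant)
})

test_that("degenerate zero-variance samples report p = 0.5 with a warning", {
  l <- list(candidate = 10, observed = rep(2, 5), permuted = rep(2, 5))
  expect_warning(res <- welch_bh_test(list(l), alpha = 0.01), "variance")
  expect_equal(res[[1]]$p_raw, 0.5)
  expect_false(res[[1]]$significant)
})

test_that("BH adjustment is monotone, bounded and caps at one", {
  set.seed(6)
  mk <- function(m, s) rnorm(30, m, s)
  losses <- lapply(c(0.1, 0.5, 1, 2, 3), function(shift) {
    list(candidate = shift * 100, observed = mk(10 - shift, 1),
         permuted = mk(10, 1))
  })
  res <- welch_bh_test(losses, alpha = 0.05)
  p_raw <- vapply(res, `[[`, numeric(1), "p_raw")
  p_adj <- vapply(res, `[[`, numeric(1), "p_adj")
  expect_true(all(p_adj >= p_raw))
  expect_true(all(p_adj <= 1))
  ord <- order(p_raw)
  expect_true(all(diff(p_adj[ord]) >= -1e-15))
})

test_that("the permutation p-value is conservative where Welch is not", {
  # observed sample nearly constant, one permutation-sd below the permuted
  # mean: Welch rejects strongly, the permutation rule does not
  set.seed(7)
  perm <- rnorm(50, 10, 1)
  obs <- rnorm(50, mean(perm) - sd(perm), 0.01)
  l <- list(candidate = 1, observed = obs, permuted = perm)
  welch <- welch_bh_test(list(l), alpha = 0.01, p_method = "welch")[[1]]
  permp <- welch_bh_test(list(l), alpha = 0.01, p_method = "permutation")[[1]]
  expect_lt(welch$p_raw, 0.001)
  expect_gt(permp$p_raw, 0.05)
  expect_equal(permp$t_stat, welch$t_stat)  # statistic reported either way
})

test_that("the full driver is deterministic and honours the alpha contract", {
  sim <- simulate_scenario(2, T_total = 120, p = 16, seed = 11)
  args <- list(sim$X, delta = 20, nrun = 3, nreps = 10, rank = 2, seed = 42)
  r1 <- do.call(detect_change_points, args)
  r2 <- do.call(detect_change_points, args)
  expect_identical(r1$change_points, r2$change_points)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # significant set is a subset of the candidate set
  expect_true(all(r1$change_points %in% r1$candidates))

  # alpha = 1 disables pruning entirely
  r3 <- detect_change_points(sim$X, delta = 20, nrun = 3, nreps = 10,
                             rank = 2, alpha = 1, seed = 42)
  expect_identical(sort(as.integer(r3$change_points)),
                   sort(as.integer(r3$candidates)))

  # result bookkeeping
  expect_identical(r1$input_shape, c(120L, 16L))
  expect_equal(r1$rank_used, 2L)
  expect_error(detect_change_points(sim$X[1:30, ], delta = 20), "too short")
})

test_that("permutation-rule null calibration holds at an independent split", {
  set.seed(8)
  rejected <- replicate(15, {
    X <- stationary_matrix(140, 20)
    l <- permutation_losses(X, candidates = 70L, i = 1, rank = 2, nreps = 20)
    welch_bh_test(list(l), alpha = 0.01,
                  p_method = "permutation")[[1]]$significant
  })
  expect_lte(mean(rejected), 0.1)
})
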