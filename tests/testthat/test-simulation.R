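test_that("block covariance matches its definition", {
  expect_equal(block_sigma(c(1, 1)), rbind(c(1, 0.75), c(0.75, 1)))
  expect_equal(block_sigma(c(1, 2)), rbind(c(1, 0.20), c(0.20, 1)))
  lab <- c(1, 1, 2, 3)
  S <- block_sigma(lab)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_true(all(eigen(S, only.values = TRUE)$values > 0))
})

test_that("every scenario produces a coherent truth object", {
  for (sid in 1:10) {
    out <- simulate_scenario(sid, p = 24, seed = 100 + sid)
    tr <- out$truth
    expect_equal(dim(out$X), c(tr$T_total, tr$p))
    expect_identical(tr$p, 24L)
    # change points strictly inside (1, T), increasing
    if (length(tr$changepoints)) {
      expect_true(all(tr$changepoints > 1 & tr$changepoints < tr$T_total))
      expect_identical(tr$changepoints, sort(tr$changepoints))
    }
    # segments partition [1, T]
    starts <- vapply(tr$segments, `[[`, integer(1), "start")
    ends <- vapply(tr$segments, `[[`, integer(1), "end")
    expect_equal(starts[1], 1L)
    expect_equal(ends[length(ends)], tr$T_total)
    if (length(starts) > 1) {
      expect_equal(starts[-1], ends[-length(ends)] + 1L)
    }
    # labels valid and all clusters non-empty
    for (seg in tr$segments) {
      expect_length(seg$labels, tr$p)
      expect_equal(sort(unique(seg$labels)), seq_len(seg$K0))
    }
  }
  expect_error(simulate_scenario(11), "sim_id")
})

test_that("scenario-specific structure is honoured", {
  s1 <- simulate_scenario(1, p = 20, seed = 1)$truth
  expect_length(s1$changepoints, 0)

  s2 <- simulate_scenario(2, p = 20, seed = 1)$truth
  expect_identical(s2$changepoints, 100L)
  expect_identical(s2$T_total, 200L)

  s3 <- simulate_scenario(3, p = 24, seed = 1)$truth
  expect_identical(s3$changepoints, c(100L, 200L, 300L))
  expect_identical(vapply(s3$segments, `[[`, integer(1), "K0"),
                   c(3L, 2L, 2L, 3L))

  s5 <- simulate_scenario(5, p = 20, seed = 1)$truth
  expect_identical(s5$segments[[1]]$labels, s5$segments[[3]]$labels)

  s6 <- simulate_scenario(6, p = 28, seed = 1)$truth
  expect_identical(vapply(s6$segments, `[[`, integer(1), "K0"),
                   c(7L, 2L, 7L))

  s7 <- simulate_scenario(7, p = 20, seed = 1)$truth
  expect_identical(s7$T_total, 250L)
  expect_equal(s7$transition$type, "sigmoid")
  expect_identical(s7$transition$window, c(101L, 150L))

  s8 <- simulate_scenario(8, p = 20, seed = 1)$truth
  expect_identical(s8$T_total, 205L)
  expect_identical(s8$transition$window, c(101L, 105L))

  s9 <- simulate_scenario(9, p = 20, seed = 1)$truth
  expect_true(s9$changepoints >= 50 && s9$changepoints <= 150)

  s10 <- simulate_scenario(10, p = 20, seed = 1)$truth
  expect_equal(s10$ar, 0.7)
})

test_that("the generator is deterministic under a seed", {
  a <- simulate_scenario(4, p = 24, seed = 9)
  b <- simulate_scenario(4, p = 24, seed = 9)
  expect_identical(a$X, b$X)
  expect_identical(a$truth, b$truth)
})

test_that("within-segment correlations converge to the block covariance", {
  out <- simulate_scenario(2, T_total = 2000, p = 20, seed = 3)
  seg1 <- out$X[1:out$truth$changepoints[1], ]
  lab <- out$truth$segments[[1]]$labels
  cc <- cor(seg1)
  same <- outer(lab, lab, `==`) & upper.tri(cc)
  expect_equal(mean(cc[same]), 0.75, tolerance = 0.03 / 0.75)
  expect_equal(mean(cc[!outer(lab, lab, `==`) & upper.tri(cc)]), 0.20,
               tolerance = 0.05 / 0.20)
})

test_that("transition weights match their closed forms", {
  w <- transition_weights("sigmoid", 50)
  expect_equal(w[25], 0.5)              # sigmoid centre
  expect_true(all(diff(w) > 0))
  expect_lt(w[1], 0.01)
  expect_gt(w[50], 0.99)

  wl <- transition_weights("linear", 5)
  expect_equal(wl, (1:5) / 10)          # t/10, tops out at 0.5
})

test_that("blended rows interpolate the two covariance regimes", {
  set.seed(4)
  sig_a <- block_sigma(c(1, 1, 2, 2))
  sig_b <- block_sigma(c(1, 2, 1, 2))
  xa <- blend_transition(sig_a, sig_b, rep(0, 4000))
  expect_equal(cov(xa), sig_a, tolerance = 0.35)  # elementwise, loose MC
  xb <- blend_transition(sig_a, sig_b, rep(1, 4000))
  expect_equal(cov(xb), sig_b, tolerance = 0.35)
  expect_warning(blend_transition(sig_a, sig_b, c(0.5, 1.2)), "clamped")
})

test_that("the AR(1) filter has the right marginal moments", {
  x <- matrix(rnorm(30), 30, 1)
  expect_identical(apply_ar1(x, 0), x)
  set.seed(5)
  innov <- matrix(rnorm(20000), ncol = 1)
  y <- apply_ar1(innov, 0.7)
  expect_equal(var(y[-(1:100)]), 1 / (1 - 0.49), tolerance = 0.1 / 1.96)
  expect_equal(cor(y[-1], y[-length(y)]), 0.7, tolerance = 0.05 / 0.7)
  expect_error(apply_ar1(innov, 1), "phi")
})
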