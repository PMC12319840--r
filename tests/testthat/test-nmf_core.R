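test_that("positivity shift hits the margin exactly and preserves covariance", {
  set.seed(1)
  m <- matrix(rnorm(250), 50, 5)
  m[1, 1] <- -3
  shifted <- shift_nonnegative(m, margin = 1)
  expect_equal(min(shifted), 1)
  expect_equal(shifted, m + (1 - min(m)), tolerance = 1e-15)
  expect_equal(cov(shifted), cov(m), tolerance = 1e-12)

  already_pos <- abs(m) + 0.5
  expect_identical(shift_nonnegative(already_pos), already_pos)

  expect_error(shift_nonnegative(matrix(c(1, NA_real_), 1, 2)), "finite")
  expect_error(shift_nonnegative(matrix(c(1, Inf), 1, 2)), "finite")
  expect_error(shift_nonnegative(m, margin = 0), "positive")
})

test_that("generalized KL divergence matches hand evaluations and conventions", {
  # single-entry hand case: 2 log 2 - 2 + 1
  expect_equal(kld_loss(matrix(2), matrix(1), matrix(1)), 2 * log(2) - 1,
               tolerance = 1e-12)
  # zero-entry convention: only +(WH)_ij survives
  expect_equal(kld_loss(matrix(0), matrix(0.5), matrix(1)), 0.5)
  # exact factorization gives zero
  set.seed(2)
  W <- matrix(runif(12), 4, 3)
  H <- matrix(runif(15), 3, 5)
  expect_equal(kld_loss(W %*% H, W, H), 0, tolerance = 1e-10)
  # non-negativity of the divergence on random instances
  for (i in 1:5) {
    X <- matrix(runif(20, 0.1, 2), 4, 5)
    expect_gte(kld_loss(X, W, H), 0)
  }
  expect_error(kld_loss(matrix(1, 2, 2), matrix(1, 2, 1), matrix(1, 1, 3)),
               "conform")
  expect_error(kld_loss(matrix(-1), matrix(1), matrix(1)), "non-negative")
})

test_that("multiplicative updates decrease the loss and solve exact problems", {
  set.seed(3)
  # exactly factorizable rank-1 input
  X1 <- outer(runif(20, 0.5, 2), runif(8, 0.5, 2))
  expect_lt(fit_nmf(X1, rank = 1, nrun = 3, max_iter = 500)$loss, 1e-6)

  # loss trace non-increasing within relative tolerance, random inputs
  for (s in 1:3) {
    set.seed(30 + s)
    X <- matrix(runif(300, 0.1, 3), 30, 10)
    tr <- fit_nmf(X, rank = 3, nrun = 1)$loss_trace
    increases <- diff(tr) / pmax(abs(tr[-length(tr)]), 1e-12)
    expect_true(all(increases <= 1e-8))
  }

  expect_error(fit_nmf(matrix(runif(12), 4, 3), rank = 4), "rank")
  expect_error(fit_nmf(matrix(-runif(12), 4, 3), rank = 1), "non-negative")
})

test_that("best-of-restarts rank-1 fit reaches the closed-form optimum", {
  # the KL-optimal rank-1 reconstruction is outer(rowsums, colsums)/total
  for (s in 1:4) {
    set.seed(40 + s)
    X <- matrix(runif(9, 0.5, 2), 3, 3)
    opt <- kld_loss(X, matrix(rowSums(X) / sum(X), 3, 1),
                    matrix(colSums(X), 1, 3))
    fit <- fit_nmf(X, rank = 1, nrun = 20, max_iter = 2000, tol = 1e-7)
    expect_lte(fit$loss, opt * 1.01 + 1e-12)
  }
})

test_that("rank selection finds the cluster count on structured data", {
  set.seed(5)
  hits <- replicate(10, {
    X <- stationary_matrix(150, 30, K = 2)
    select_rank(X, r_max = 5, nrun = 5)$selected == 2
  })
  expect_gte(mean(hits), 0.8)
})

test_that("rank selection on structureless data stays at small ranks", {
  # with no structure the permuted reference is exchangeable with the data,
  # so each stop test is a fair coin: small ranks dominate, no pile-up high
  set.seed(6)
  sel <- replicate(12, {
    X <- matrix(runif(150 * 30), 150, 30) + 0.5
    select_rank(X, r_max = 6, nrun = 5)$selected
  })
  expect_gte(mean(sel <= 2), 0.5)
})

test_that("rank selection trace is well-formed and r_max is enforced", {
  set.seed(7)
  X <- stationary_matrix(60, 20)
  sr <- select_rank(X, r_max = 4, nrun = 3)
  expect_s3_class(sr, "rank_trace")
  expect_gte(sr$selected, 1L)
  expect_identical(sr$trace$rank, seq_len(nrow(sr$trace)))
  expect_warning(sr5 <- select_rank(X[1:5, 1:5], r_max = 10, nrun = 2),
                 "truncating")
  expect_lte(sr5$selected, 5L)
  expect_error(suppressWarnings(
    select_rank(X[1:3, 1, drop = FALSE], r_max = 5, nrun = 2)
  ), "at least 2")
})

test_that("rank selection is invariant to relabeling columns", {
  set.seed(8)
  f <- function(permute) {
    mean(replicate(10, {
      X <- stationary_matrix(120, 24, K = 2)
      if (permute) X <- X[, sample(ncol(X))]
      select_rank(X, r_max = 4, nrun = 4)$selected == 2
    }))
  }
  expect_lte(abs(f(FALSE) - f(TRUE)), 0.2)
})
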