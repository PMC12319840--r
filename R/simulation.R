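# Piecewise-stationary multivariate Gaussian simulator with block
# covariance. Ten scenarios of increasing difficulty: no change, single and
# multiple abrupt regime changes, ABA (task on/off) structures, gradual
# sigmoid/linear transitions, a randomly placed change, and AR(1) noise.

.sim_defaults <- list(
  list(T_total = 200L, p = 400L, K0 = 2L),  # 1: stationary
  list(T_total = 200L, p = 400L, K0 = 2L),  # 2: one change at T/2
  list(T_total = 400L, p = 600L, K0 = 3L),  # 3: three changes, K0 3/2/2/3
  list(T_total = 600L, p = 800L, K0 = 2L),  # 4: two changes, half-swaps
  list(T_total = 300L, p = 200L, K0 = 2L),  # 5: ABA
  list(T_total = 300L, p = 200L, K0 = 7L),  # 6: ABA with 7 clusters
  list(T_total = 250L, p = 400L, K0 = 2L),  # 7: sigmoid transition
  list(T_total = 205L, p = 400L, K0 = 2L),  # 8: linear transition
  list(T_total = 200L, p = 400L, K0 = 2L),  # 9: random change location
  list(T_total = 200L, p = 400L, K0 = 2L)   # 10: one change + AR(1)
)

#' Block covariance matrix implied by a cluster assignment
#'
#' Unit variances, correlation `within` (default 0.75) for pairs in the
#' same cluster and `between` (default 0.20) otherwise. At the default
#' values the matrix is positive definite for any assignment.
#'
#' @param labels Integer vector of cluster labels, one per variable.
#' @param within,between Same-cluster and cross-cluster correlations.
#' @return A `length(labels)` square covariance matrix.
#' @export
block_sigma <- function(labels, within = 0.75, between = 0.20) {
  p <- length(labels)
  sigma <- matrix(between, p, p)
  sigma[outer(labels, labels, `==`)] <- within
  diag(sigma) <- 1
  sigma
}

# Draw n rows from N(0, sigma) via the Cholesky factor.
.rmvn <- function(n, sigma) {
  ch <- chol(sigma)  # errors if sigma is not positive definite
  matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma)) %*% ch
}

# p variables split into K clusters as evenly as possible, in index order.
.equal_labels <- function(p, K) {
  rep(seq_len(K), times = diff(round(seq(0, p, length.out = K + 1))))
}

#' Blending weights for a gradual regime transition
#'
#' Sigmoid weights rise from ~0 to ~1 over the window with midpoint 0.5 at
#' its centre (`1 / (1 + exp(-0.2 (t - 25)))` on a 50-point reference
#' window); linear weights grow as `t / 10` over a 5-point reference
#' window (so they top out at 0.5 — the transition ends abruptly while
#' still mixed). Other window lengths are rescaled to the same shape.
#'
#' @param type `"sigmoid"` or `"linear"`.
#' @param length Number of time points in the transition window.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
transition_weights <- function(type = c("sigmoid", "linear"), length) {
  type <- match.arg(type)
  t <- seq_len(length)
  if (type == "sigmoid") {
    tt <- t * 50 / length
    1 / (1 + exp(-0.2 * (tt - 25)))
  } else {
    tt <- t * 5 / length
    tt / 10
  }
}

#' Rows for a gradual transition between two covariance regimes
#'
#' Each transition row is `(1 - w_t) x_A + w_t x_B` with independent draws
#' `x_A ~ N(0, sigma_a)` and `x_B ~ N(0, sigma_b)`, giving a smooth
#' interpolation of the covariance from regime A to regime B.
#'
#' @param sigma_a,sigma_b Covariance matrices of the two regimes.
#' @param weights Blending weights, one per transition row; values outside
#'   `[0, 1]` are clamped with a warning.
#' @return Matrix with `length(weights)` rows.
#' @export
blend_transition <- function(sigma_a, sigma_b, weights) {
  if (any(weights < 0 | weights > 1)) {
    warning("blending weights outside [0, 1] clamped")
    weights <- pmin(pmax(weights, 0), 1)
  }
  n <- length(weights)
  xa <- .rmvn(n, sigma_a)
  xb <- .rmvn(n, sigma_b)
  (1 - weights) * xa + weights * xb
}

#' Apply an AR(1) filter to the rows of a matrix
#'
#' Treats the input rows as innovations: row 1 is kept, and
#' `row_t = phi * row_{t-1} + innovation_t` thereafter. No burn-in and no
#' variance renormalization, so the marginal variance inflates to
#' `1 / (1 - phi^2)` times the innovation variance in the long run.
#'
#' @param X Numeric matrix of innovations (rows = time).
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @return Filtered matrix of the same dimensions.
#' @export
apply_ar1 <- function(X, phi) {
  if (abs(phi) >= 1) stop("`phi` must satisfy |phi| < 1", call. = FALSE)
  X <- as.matrix(X)
  if (phi == 0 || nrow(X) < 2L) return(X)
  out <- X
  for (t in 2:nrow(X)) {
    out[t, ] <- phi * out[t - 1L, ] + X[t, ]
  }
  out
}

# Relabeling moves used by the scenarios ------------------------------------

# move half of each cluster, chosen at random, to the other cluster (K0 = 2)
.swap_halves <- function(labels) {
  out <- labels
  for (k in 1:2) {
    idx <- which(labels == k)
    mv <- sample(idx, round(length(idx) / 2))
    out[mv] <- 3L - k
  }
  out
}

#' Generate one simulation scenario with its ground truth
#'
#' Ten scenarios of piecewise-stationary Gaussian data with block
#' covariance (within-cluster correlation 0.75, between 0.20, unit
#' variance): (1) stationary, two clusters; (2) one change at T/2 with the
#' cluster labels reshuffled; (3) three changes with cluster merges,
#' a reshuffle, and a three-way split (K0 3, 2, 2, 3); (4) two changes,
#' each swapping random halves of the two clusters; (5) ABA — reshuffle
#' then restore; (6) ABA with seven clusters merged to two in the middle;
#' (7) a gradual sigmoid-weighted transition over a 50-point window;
#' (8) a gradual linear-weighted transition over a 5-point window;
#' (9) one change at a uniformly random location in the middle half;
#' (10) scenario 2 with AR(1) noise, coefficient 0.7.
#'
#' Defaults are the scenarios' native sizes (T 200-600, p 200-800).
#' `T_total`/`p` overrides rescale the change point locations and window
#' proportionally while preserving cluster counts and relabeling schemes.
#'
#' @param sim_id Scenario number, 1-10.
#' @param T_total,p Optional size overrides.
#' @param seed Optional integer seed (recorded in the truth object).
#' @return List with `X` (the T x p data matrix) and `truth`, an object of
#'   class `sim_truth` holding `sim_id`, `T_total`, `p`, `changepoints`
#'   (true change points, each the last index of its stationary segment),
#'   `segments` (start/end/labels/K0 per segment, transitions marked by
#'   `kind`), `transition`, `ar` and `seed`.
#' @export
simulate_scenario <- function(sim_id, T_total = NULL, p = NULL,
                              seed = NULL) {
  sim_id <- as.integer(sim_id)
  if (is.na(sim_id) || sim_id < 1L || sim_id > 10L) {
    stop("`sim_id` must be an integer in 1..10", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  def <- .sim_defaults[[sim_id]]
  t_tot <- if (is.null(T_total)) def$T_total else as.integer(T_total)
  p_tot <- if (is.null(p)) def$p else as.integer(p)
  sc <- t_tot / def$T_total  # time rescaling factor
  at <- function(q) as.integer(round(q * sc))

  K0 <- def$K0
  l1 <- .equal_labels(p_tot, K0)
  transition <- NULL
  ar <- 0

  if (sim_id == 1L) {
    cps <- integer(0)
    seg_labels <- list(l1)
  } else if (sim_id %in% c(2L, 10L)) {
    cps <- at(100)
    seg_labels <- list(l1, sample(l1))
    if (sim_id == 10L) ar <- 0.7
  } else if (sim_id == 3L) {
    cps <- at(c(100, 200, 300))
    # merge cluster 3 equally into clusters 1 and 2
    l2 <- l1
    idx3 <- sample(which(l1 == 3L))
    half <- seq_len(floor(length(idx3) / 2))
    l2[idx3[half]] <- 1L
    l2[idx3[-half]] <- 2L
    l3 <- sample(l2)
    # restore K0 = 3 by moving one-third of each cluster to a new cluster
    l4 <- l3
    for (k in 1:2) {
      idx <- which(l3 == k)
      l4[sample(idx, round(length(idx) / 3))] <- 3L
    }
    seg_labels <- list(l1, l2, l3, l4)
  } else if (sim_id == 4L) {
    cps <- at(c(200, 400))
    l2 <- .swap_halves(l1)
    l3 <- .swap_halves(l2)
    seg_labels <- list(l1, l2, l3)
  } else if (sim_id == 5L) {
    cps <- at(c(100, 200))
    seg_labels <- list(l1, sample(l1), l1)
  } else if (sim_id == 6L) {
    cps <- at(c(100, 200))
    # clusters 1-3 and 5-7 each merged; cluster 4 split between the two
    l2 <- integer(p_tot)
    l2[l1 %in% 1:3] <- 1L
    l2[l1 %in% 5:7] <- 2L
    idx4 <- sample(which(l1 == 4L))
    half <- seq_len(floor(length(idx4) / 2))
    l2[idx4[half]] <- 1L
    l2[idx4[-half]] <- 2L
    seg_labels <- list(l1, l2, l1)
  } else if (sim_id %in% c(7L, 8L)) {
    cps <- at(100)
    win_end <- if (sim_id == 7L) at(150) else at(105)
    seg_labels <- list(l1, sample(l1))
    transition <- list(
      type = if (sim_id == 7L) "sigmoid" else "linear",
      window = c(at(100) + 1L, win_end)
    )
  } else if (sim_id == 9L) {
    cps <- sample(at(50):at(150), 1L)
    seg_labels <- list(l1, sample(l1))
  }

  # assemble segment bounds, treating a transition window as its own block
  if (is.null(transition)) {
    bounds <- c(0L, cps, t_tot)
    segments <- lapply(seq_along(seg_labels), function(s) {
      list(start = bounds[s] + 1L, end = bounds[s + 1L],
           labels = seg_labels[[s]], K0 = length(unique(seg_labels[[s]])),
           kind = "stationary")
    })
    X <- do.call(rbind, lapply(segments, function(s) {
      .rmvn(s$end - s$start + 1L, block_sigma(s$labels))
    }))
  } else {
    win <- transition$window
    segments <- list(
      list(start = 1L, end = win[1L] - 1L, labels = seg_labels[[1L]],
           K0 = K0, kind = "stationary"),
      list(start = win[1L], end = win[2L], labels = seg_labels[[2L]],
           K0 = K0, kind = "transition"),
      list(start = win[2L] + 1L, end = t_tot, labels = seg_labels[[2L]],
           K0 = K0, kind = "stationary")
    )
    sig_a <- block_sigma(seg_labels[[1L]])
    sig_b <- block_sigma(seg_labels[[2L]])
    w <- transition_weights(transition$type, win[2L] - win[1L] + 1L)
    X <- rbind(.rmvn(win[1L] - 1L, sig_a),
               blend_transition(sig_a, sig_b, w),
               .rmvn(t_tot - win[2L], sig_b))
  }

  if (ar != 0) X <- apply_ar1(X, ar)

  truth <- structure(
    list(sim_id = sim_id, T_total = t_tot, p = p_tot,
         changepoints = as.integer(cps), segments = segments,
         transition = transition, ar = ar, seed = seed),
    class = "sim_truth"
  )
  list(X = X, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Scenario %d: %d x %d, change points: %s\n", x$sim_id,
              x$T_total, x$p,
              if (length(x$changepoints)) paste(x$changepoints, collapse = ", ") else "none"))
  if (!is.null(x$transition)) {
    cat(sprintf("  gradual %s transition over [%d, %d]\n",
                x$transition$type, x$transition$window[1],
                x$transition$window[2]))
  }
  if (x$ar != 0) cat("  AR(1) coefficient", x$ar, "\n")
  invisible(x)
}
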