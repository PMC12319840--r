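# Numerical floor applied to denominators and log arguments so the
# generalized KL divergence stays finite when the reconstruction
# underflows. Standard KL-NMF practice.
.kld_eps <- 1e-12

# Convergence is declared when the relative loss change over this many
# multiplicative-update iterations falls below `tol`.
.conv_window <- 10L

#' Shift a matrix so all entries are positive
#'
#' NMF requires a non-negative input, but real multivariate time series
#' (e.g. standardized fMRI ROI signals) are signed. Adding one constant to
#' every entry makes the matrix positive while leaving all pairwise column
#' covariances untouched, so the dependence structure the method works on
#' is preserved.
#'
#' @param raw A finite numeric matrix (rows = time points).
#' @param margin Positive value the new minimum is set to when a shift is
#'   needed (default 1). Results can be sensitive to extreme margins;
#'   a sensitivity check is advisable for unusual data scales.
#' @return The input matrix, unchanged if already strictly positive,
#'   otherwise with `-min(raw) + margin` added to every entry.
#' @examples
#' m <- matrix(c(-3, 0, 2, 5), 2, 2)
#' min(shift_nonnegative(m)) # 1
#' @export
shift_nonnegative <- function(raw, margin = 1) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw) || anyNA(raw) || !all(is.finite(raw))) {
    stop("`raw` must be a finite numeric matrix", call. = FALSE)
  }
  if (!is.numeric(margin) || length(margin) != 1L || margin <= 0) {
    stop("`margin` must be a single positive number", call. = FALSE)
  }
  mn <- min(raw)
  if (mn > 0) {
    return(raw)
  }
  raw + (margin - mn)
}

#' Generalized Kullback-Leibler divergence between a matrix and its NMF
#' reconstruction
#'
#' Computes `sum_ij( X_ij log(X_ij / (WH)_ij) - X_ij + (WH)_ij )` with the
#' convention `0 * log(0/y) = 0`. Reconstruction entries below the internal
#' floor (1e-12) where `X > 0` are floored inside the logarithm, with a
#' warning, to keep the divergence finite.
#'
#' @param X Non-negative numeric matrix.
#' @param W,H Non-negative factors with conforming dimensions.
#' @return A single non-negative number; 0 iff `X == WH` elementwise.
#' @examples
#' kld_loss(matrix(2), matrix(1), matrix(1)) # 2*log(2) - 1
#' @export
kld_loss <- function(X, W, H) {
  X <- as.matrix(X)
  W <- as.matrix(W)
  H <- as.matrix(H)
  if (ncol(W) != nrow(H) || nrow(W) != nrow(X) || ncol(H) != ncol(X)) {
    stop("dimensions of W, H do not conform with X", call. = FALSE)
  }
  if (min(X) < 0 || min(W) < 0 || min(H) < 0) {
    stop("X, W and H must be non-negative", call. = FALSE)
  }
  Y <- W %*% H
  if (any(Y < .kld_eps & X > 0)) {
    warning("reconstruction has near-zero entries where X > 0; ",
            "flooring inside the log to keep the divergence finite")
  }
  .kld_sum_cpp(X, Y, .kld_eps)
}

# Random initialization: i.i.d. uniform entries scaled so that the expected
# reconstruction mean matches mean(X).
.nmf_init <- function(X, rank) {
  s <- sqrt(mean(X) / (0.25 * rank))
  W <- matrix(s * stats::runif(nrow(X) * rank), nrow(X), rank)
  H <- matrix(s * stats::runif(rank * ncol(X)), rank, ncol(X))
  list(W = pmax(W, 1e-8), H = pmax(H, 1e-8))
}

#' Fit NMF by multiplicative updates under the generalized KL objective
#'
#' Runs Lee-Seung multiplicative updates from `nrun` independent random
#' initializations and keeps the factorization with the lowest final loss.
#' The objective is non-convex, so restarts guard against poor local optima.
#'
#' @param X Non-negative numeric matrix (T x p).
#' @param rank Factorization rank r, `1 <= r <= min(T, p)`.
#' @param nrun Number of random restarts (default 1).
#' @param max_iter Maximum update iterations per restart (default 200).
#' @param tol Relative loss-change convergence tolerance, assessed over a
#'   10-iteration window (default 1e-4).
#' @return An object of class `nmf_fit`: list with `W` (T x r), `H` (r x p),
#'   `rank`, `loss` (generalized KL divergence of the returned fit),
#'   `n_iterations`, `restart_index` and `loss_trace` (per-iteration loss
#'   of the winning restart, starting at the initialization).
#' @examples
#' set.seed(1)
#' X <- outer(runif(20), runif(8))
#' fit_nmf(X, rank = 1, nrun = 3)$loss # ~0: exactly rank-1
#' @export
fit_nmf <- function(X, rank, nrun = 1, max_iter = 200, tol = 1e-4) {
  X <- as.matrix(X)
  if (min(X) < 0) stop("`X` must be non-negative", call. = FALSE)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(X))) {
    stop("`rank` must be between 1 and min(T, p) = ", min(dim(X)),
         call. = FALSE)
  }
  if (nrun < 1L) stop("`nrun` must be at least 1", call. = FALSE)
  best <- NULL
  for (k in seq_len(nrun)) {
    init <- .nmf_init(X, rank)
    fit <- .nmf_kl_fit_cpp(X, init$W, init$H, as.integer(max_iter), tol,
                           .kld_eps, .conv_window)
    if (is.null(best) || fit$loss < best$loss) {
      best <- fit
      best$restart_index <- k
    }
  }
  structure(
    list(W = best$W, H = best$H, rank = rank, loss = best$loss,
         n_iterations = best$n_iter, restart_index = best$restart_index,
         loss_trace = best$trace),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("KL-NMF fit: %d x %d, rank %d, loss %.6g (%d iterations, restart %d)\n",
              nrow(x$W), ncol(x$H), x$rank, x$loss, x$n_iterations,
              x$restart_index))
  invisible(x)
}

#' Data-driven NMF rank selection against a permuted-noise reference
#'
#' Compares the loss improvement from increasing the rank on `X` with the
#' improvement on `X'`, a copy of `X` in which every column's entries have
#' been independently permuted over time (destroying the cross-variable
#' dependence the factorization models, while preserving each variable's
#' marginal distribution; note that permuting whole rows or whole columns
#' would leave the NMF loss invariant and carry no information). The rank
#' is increased while the
#' improvement on `X` is strictly larger in magnitude than on `X'`; the
#' selected rank `r*` is the current rank at the first failure. When real
#' data stop improving faster than structureless data, extra components are
#' fitting noise.
#'
#' @param X Non-negative numeric matrix.
#' @param r_max Largest rank considered (default 10; truncated with a
#'   warning if it exceeds `min(T, p)`).
#' @param nrun Restarts per NMF fit (default 10).
#' @inheritParams fit_nmf
#' @return Object of class `rank_trace`: list with `selected` (`r*`) and
#'   `trace`, a data frame with one row per rank examined holding
#'   `loss_X`, `loss_Xperm` and the forward differences `delta_X`,
#'   `delta_Xperm` (loss at r+1 minus loss at r; negative = improvement).
#' @export
select_rank <- function(X, r_max = 10, nrun = 10, max_iter = 200,
                        tol = 1e-4) {
  X <- as.matrix(X)
  n_t <- nrow(X)
  p <- ncol(X)
  if (r_max > min(n_t, p)) {
    warning("`r_max` exceeds min(T, p); truncating to ", min(n_t, p))
    r_max <- min(n_t, p)
  }
  if (r_max < 2L) stop("`r_max` must be at least 2", call. = FALSE)

  # independent within-column permutations, drawn once per call
  Xperm <- apply(X, 2L, sample)

  loss_x <- loss_xp <- rep(NA_real_, r_max + 1L)
  loss_at <- function(mat, r) fit_nmf(mat, r, nrun, max_iter, tol)$loss

  selected <- r_max
  rows <- vector("list", r_max)
  loss_x[1L] <- loss_at(X, 1L)
  loss_xp[1L] <- loss_at(Xperm, 1L)
  for (r in seq_len(r_max - 1L)) {
    loss_x[r + 1L] <- loss_at(X, r + 1L)
    loss_xp[r + 1L] <- loss_at(Xperm, r + 1L)
    d_x <- loss_x[r + 1L] - loss_x[r]
    d_xp <- loss_xp[r + 1L] - loss_xp[r]
    rows[[r]] <- data.frame(rank = r, loss_X = loss_x[r],
                            loss_Xperm = loss_xp[r],
                            delta_X = d_x, delta_Xperm = d_xp)
    if (!(d_x < d_xp)) {     # improvement on X no longer beats noise
      selected <- r
      break
    }
    selected <- r + 1L
  }
  structure(list(selected = as.integer(selected),
                 trace = do.call(rbind, rows[!vapply(rows, is.null, TRUE)])),
            class = "rank_trace")
}

#' @export
print.rank_trace <- function(x, ...) {
  cat("NMF rank selection: selected r* =", x$selected, "\n")
  if (!is.null(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}
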