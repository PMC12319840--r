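#' Locate one candidate change point by binary search over the time index
#'
#' Instead of scanning every admissible time point (as binary segmentation
#' does), the search keeps a window of admissible candidate indices,
#' initially `[start + delta, end - delta]`, and halves it each step. At the
#' window midpoint `m` two overlapping blocks are formed: the left block
#' runs from `delta` before the window start to `m + delta/2`, the right
#' block from `m - delta/2 + 1` to `delta` past the window end, so each
#' block carries `delta` of outer padding and the two share a `delta`-wide
#' overlap centred at `m`. (A wider overlap dilutes localization: rows past
#' the midpoint that sit in both blocks contribute the same misfit to each,
#' shrinking the loss contrast that steers the search.) NMF (best of `nrun`
#' restarts) is fitted to each block and
#' the search descends into the half whose block has the higher loss — the
#' side whose model fits worse is more likely to still contain the change
#' point. Ties descend left for reproducibility. The search ends when one
#' index remains, after at most `ceil(log2(window length))` block-pair fits.
#'
#' @param X Non-negative numeric matrix (rows = time points).
#' @param interval Length-2 integer vector, 1-based inclusive bounds of the
#'   segment searched. Must satisfy `end - start + 1 >= 2*delta + 1`.
#' @param delta Minimum distance between change points and from segment
#'   ends; also the block padding width (default 35).
#' @param rank NMF rank used for every block fit (held fixed so block
#'   losses are comparable).
#' @param nrun NMF restarts per block fit (default 50).
#' @inheritParams fit_nmf
#' @return Object of class `cp_candidate`: list with `index` (the candidate
#'   q-hat, the last index of the left child segment), `parent_interval`,
#'   `block_losses` (matrix of midpoint, left and right losses per
#'   iteration) and `n_fits` (number of NMF block fits, pairs counted as 2).
#' @export
binsearch_candidate <- function(X, interval = c(1L, nrow(X)), delta = 35,
                                rank, nrun = 50, max_iter = 200,
                                tol = 1e-4) {
  X <- as.matrix(X)
  start <- as.integer(interval[1L])
  end <- as.integer(interval[2L])
  if (start < 1L || end > nrow(X) || start > end) {
    stop("invalid interval", call. = FALSE)
  }
  delta <- as.integer(delta)
  if (delta < 2L) stop("`delta` must be at least 2", call. = FALSE)
  if (end - start + 1L < 2L * delta + 1L) {
    stop("interval too short to admit a candidate: need length >= ",
         2L * delta + 1L, call. = FALSE)
  }

  a <- start + delta
  b <- end - delta
  ov <- as.integer(ceiling(delta / 2))  # blocks share ~delta rows at m
  rows <- list()
  n_fits <- 0L
  while (a < b) {
    m <- (a + b) %/% 2L
    v_l <- X[max(start, a - delta):min(end, m + ov), , drop = FALSE]
    v_r <- X[max(start, m - ov + 1L):min(end, b + delta), , drop = FALSE]
    loss_l <- fit_nmf(v_l, rank, nrun, max_iter, tol)$loss
    loss_r <- fit_nmf(v_r, rank, nrun, max_iter, tol)$loss
    n_fits <- n_fits + 2L
    rows[[length(rows) + 1L]] <- c(midpoint = m, loss_L = loss_l,
                                   loss_R = loss_r)
    if (loss_l >= loss_r) b <- m else a <- m + 1L
  }
  structure(
    list(index = a, parent_interval = c(start, end),
         block_losses = if (length(rows)) do.call(rbind, rows) else NULL,
         n_fits = n_fits),
    class = "cp_candidate"
  )
}

#' Recursively collect candidate change points
#'
#' Applies [binsearch_candidate()] to the whole series, splits it at the
#' returned index into left child `[start, q]` and right child
#' `[q + 1, end]`, and recurses into any child long enough to admit a
#' further candidate (length at least `2*delta + 1`). By design this
#' over-segments — pruning of spurious candidates is the job of the
#' permutation test (see [detect_change_points()]).
#'
#' @inheritParams binsearch_candidate
#' @return List of `cp_candidate` objects sorted by index; empty when the
#'   series is too short.
#' @export
detect_candidates <- function(X, delta = 35, rank, nrun = 50,
                              max_iter = 200, tol = 1e-4) {
  X <- as.matrix(X)
  out <- list()
  recurse <- function(start, end) {
    if (end - start + 1L < 2L * delta + 1L) {
      return(invisible(NULL))
    }
    cand <- binsearch_candidate(X, c(start, end), delta, rank, nrun,
                                max_iter, tol)
    out[[length(out) + 1L]] <<- cand
    recurse(start, cand$index)
    recurse(cand$index + 1L, end)
  }
  recurse(1L, nrow(X))
  idx <- vapply(out, function(c) c$index, integer(1))
  out[order(idx)]
}
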