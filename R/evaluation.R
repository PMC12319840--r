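#' True/false positive counts at a detection margin
#'
#' Greedy one-to-one matching: true change points are processed in
#' ascending order, and each claims its nearest unclaimed detection within
#' `margin` time points (ties to the lower detection index). A detection
#' can satisfy at most one true point, so `tp <= min(|truth|, |detected|)`;
#' all unmatched detections count as false positives.
#'
#' @param detected,truth Integer vectors of detected and true change
#'   points.
#' @param margin Matching half-width in time points (e.g. 10 or 1).
#' @return Named numeric vector `c(tp = ..., fp = ...)`.
#' @export
match_tp_fp <- function(detected, truth, margin) {
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  if (length(detected) == 0L) {
    return(c(tp = 0, fp = 0))
  }
  claimed <- rep(FALSE, length(detected))
  tp <- 0
  for (q in truth) {
    d <- abs(detected - q)
    d[claimed] <- Inf
    j <- which.min(d)  # lower index wins ties
    if (d[j] <= margin) {
      claimed[j] <- TRUE
      tp <- tp + 1
    }
  }
  c(tp = tp, fp = sum(!claimed))
}

#' Scaled Hausdorff distance between detected and true change points
#'
#' The bidirectional max-min distance between the two point sets, divided
#' by the length of the largest true stationary segment, `n_s`. Undefined
#' (returned as `NA`) when either set is empty — there is then no distance
#' to scale.
#'
#' @param detected,truth Integer vectors of change points.
#' @param T_total Series length, used to derive the true segment lengths.
#' @return A non-negative number, or `NA_real_` when undefined.
#' @export
scaled_hausdorff <- function(detected, truth, T_total) {
  detected <- sort(as.numeric(detected))
  truth <- sort(as.numeric(truth))
  if (length(detected) == 0L || length(truth) == 0L) {
    return(NA_real_)
  }
  n_s <- max(diff(c(0, truth, T_total)))
  d1 <- max(vapply(truth, function(q) min(abs(detected - q)), numeric(1)))
  d2 <- max(vapply(detected, function(d) min(abs(truth - d)), numeric(1)))
  max(d1, d2) / n_s
}

#' Detection metrics for one iteration at one or more margins
#'
#' @param detected Integer vector of detected change points.
#' @param truth A `sim_truth` object or integer vector of true change
#'   points (then `T_total` must be given).
#' @param margins Matching margins evaluated (default `c(1, 10)`).
#' @param T_total Series length; taken from `truth` when it is a
#'   `sim_truth`.
#' @return Data frame with one row per margin: `margin`, `tp`, `fp`,
#'   `hausdorff` (the Hausdorff value is margin-free and repeated).
#' @export
evaluate_detections <- function(detected, truth, margins = c(1, 10),
                                T_total = NULL) {
  if (inherits(truth, "sim_truth")) {
    T_total <- truth$T_total
    truth <- truth$changepoints
  }
  if (is.null(T_total)) {
    stop("`T_total` is required when `truth` is a plain vector",
         call. = FALSE)
  }
  dh <- scaled_hausdorff(detected, truth, T_total)
  do.call(rbind, lapply(margins, function(m) {
    counts <- match_tp_fp(detected, truth, m)
    data.frame(margin = m, tp = counts[["tp"]], fp = counts[["fp"]],
               hausdorff = dh)
  }))
}

#' Aggregate per-iteration detection metrics into study-level rates
#'
#' TP and FP rates are means over iterations (an FP rate of 1 means one
#' false positive per iteration on average; rates above 1 are possible).
#' The Hausdorff distance is averaged over the iterations where it is
#' defined; it is `NA` when undefined everywhere.
#'
#' @param metrics Data frame of stacked [evaluate_detections()] rows, with
#'   columns `margin`, `tp`, `fp`, `hausdorff`.
#' @return Data frame with one row per margin: `margin`, `n_iterations`,
#'   `tp_rate`, `fp_rate`, `hausdorff`.
#' @export
summarize_metrics <- function(metrics) {
  stopifnot(all(c("margin", "tp", "fp", "hausdorff") %in% names(metrics)))
  out <- do.call(rbind, lapply(split(metrics, metrics$margin), function(g) {
    dh <- g$hausdorff[!is.na(g$hausdorff)]
    data.frame(margin = g$margin[1L], n_iterations = nrow(g),
               tp_rate = mean(g$tp), fp_rate = mean(g$fp),
               hausdorff = if (length(dh)) mean(dh) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$margin), , drop = FALSE]
}
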