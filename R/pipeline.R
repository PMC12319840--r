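#' Build a run configuration
#'
#' Collects every tunable of the detection + network pipeline with the
#' method's standard defaults (minimum change point distance 35, 50 NMF
#' restarts per block, 100 permutation repetitions, significance level
#' 0.01, automatic rank selection, positivity margin 1, 100 consensus
#' runs).
#'
#' @param delta,nrun,nreps,alpha,rank,r_max,shift_margin,max_iter,tol
#'   Detection parameters; see [detect_change_points()].
#' @param seed Master seed for the run (optional).
#' @param nruns_network Consensus runs per stationary segment.
#' @param network `"none"`, `"cut"` or `"threshold"` — whether and how to
#'   estimate per-segment networks.
#' @param K0 Cluster count for the cut method (default: the rank used in
#'   detection).
#' @param lambda Threshold for the threshold method.
#' @param orientation Input orientation, see [read_matrix()].
#' @return Named list of class `run_config`.
#' @export
run_config <- function(delta = 35, nrun = 50, nreps = 100, alpha = 0.01,
                       rank = "auto", r_max = 10, shift_margin = 1,
                       max_iter = 200, tol = 1e-4, seed = NULL,
                       nruns_network = 100,
                       network = c("none", "cut", "threshold"), K0 = NULL,
                       lambda = 0.5, orientation = "time") {
  network <- match.arg(network)
  stopifnot(delta >= 2, nrun >= 1, nreps >= 1, alpha > 0, alpha <= 1,
            shift_margin > 0, max_iter >= 1, tol > 0, nruns_network >= 1)
  structure(
    list(delta = delta, nrun = nrun, nreps = nreps, alpha = alpha,
         rank = rank, r_max = r_max, shift_margin = shift_margin,
         max_iter = max_iter, tol = tol, seed = seed,
         nruns_network = nruns_network, network = network, K0 = K0,
         lambda = lambda, orientation = orientation),
    class = "run_config"
  )
}

#' Run the full detection (and optional network estimation) pipeline
#'
#' Reads the input matrix, runs [detect_change_points()], optionally
#' estimates a consensus matrix and binary network per stationary segment,
#' and writes all artifacts to `output_dir`:
#' \describe{
#'   \item{changepoints.json}{full detection record incl. per-candidate
#'     loss samples}
#'   \item{changepoints.csv}{one row per candidate: candidate, t_stat, df,
#'     p_raw, p_adj, significant}
#'   \item{segment\\<i>_consensus.csv / _adjacency.csv / _edges.csv}{dense
#'     consensus and adjacency matrices plus a weighted edge list per
#'     segment (when networks are requested)}
#'   \item{segment\\<i>_network.json}{sidecar with the segment bounds and
#'     cut/threshold parameter}
#'   \item{manifest.json}{the full configuration, package version and rank
#'     trace — everything needed to reproduce the run}
#' }
#'
#' @param input Path to a delimited numeric matrix.
#' @param output_dir Directory for artifacts (created if missing).
#' @param config A [run_config()] object.
#' @return The `nmf_cpt` result, invisibly.
#' @export
run_pipeline <- function(input, output_dir, config = run_config()) {
  x <- read_matrix(input, orientation = config$orientation)
  result <- detect_change_points(
    x, delta = config$delta, nrun = config$nrun, nreps = config$nreps,
    alpha = config$alpha, rank = config$rank, r_max = config$r_max,
    shift_margin = config$shift_margin, max_iter = config$max_iter,
    tol = config$tol, seed = config$seed
  )
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  result_to_json(result, file.path(output_dir, "changepoints.json"))
  data.table::fwrite(as.data.frame(result),
                     file.path(output_dir, "changepoints.csv"))

  if (config$network != "none") {
    nets <- segment_networks(
      x, result, nruns = config$nruns_network,
      method = if (config$network == "cut") "cut" else "threshold",
      K0 = config$K0, lambda = config$lambda, max_iter = config$max_iter,
      tol = config$tol
    )
    for (s in seq_along(nets)) {
      seg <- nets[[s]]
      pre <- file.path(output_dir, sprintf("segment%d", s))
      write_matrix(seg$consensus$values, paste0(pre, "_consensus.csv"))
      write_matrix(seg$network$adjacency, paste0(pre, "_adjacency.csv"))
      data.table::fwrite(.edge_list(seg$consensus$values),
                         paste0(pre, "_edges.csv"))
      sidecar <- list(segment = s, start = seg$start, end = seg$end,
                      method = seg$network$method,
                      K0 = seg$network$K0, lambda = seg$network$lambda,
                      nruns = seg$consensus$nruns)
      writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                  null = "null", pretty = TRUE),
                 paste0(pre, "_network.json"))
    }
  }

  manifest <- list(
    package = "nmfcpd",
    version = as.character(utils::packageVersion("nmfcpd")),
    input = normalizePath(input),
    input_shape = result$input_shape,
    config = unclass(config),
    rank_used = result$rank_used,
    rank_trace = .rank_trace_payload(result$rank_trace)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(output_dir, "manifest.json"))
  invisible(result)
}
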