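#' Read a delimited numeric matrix
#'
#' Reads CSV/TSV (delimiter auto-detected) into a numeric matrix with rows
#' as time points. A header row is auto-detected and kept as column names.
#' Files whose rows are variables (one series per row) are transposed on
#' read via `orientation = "variables"`.
#'
#' @param path File path.
#' @param orientation `"time"` (rows are time points, default) or
#'   `"variables"` (rows are series; transposed on read).
#' @return Numeric T x p matrix.
#' @export
read_matrix <- function(path, orientation = c("time", "variables")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, header = "auto", fill = FALSE,
                          data.table = FALSE)
  for (j in seq_along(dt)) {
    if (!is.numeric(dt[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dt[[j]]))) &
                     !is.na(dt[[j]]))[1L]
      stop(sprintf("non-numeric cell at row %d, column %d (%s) of %s",
                   if (is.na(bad)) NA_integer_ else bad, j, names(dt)[j],
                   path), call. = FALSE)
    }
  }
  m <- as.matrix(dt)
  if (orientation == "variables") m <- t(m)
  if (nrow(m) < 2L) {
    stop("matrix must have at least 2 time points", call. = FALSE)
  }
  m
}

#' Write a numeric matrix as CSV
#'
#' @param m Numeric matrix.
#' @param path Output file path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  df <- as.data.frame(m)
  if (is.null(colnames(m))) {
    names(df) <- paste0("V", seq_len(ncol(m)))
  }
  data.table::fwrite(df, path)
  invisible(path)
}

# Serializable form of the rank-selection trace(s) stored on a result
# (a single rank_trace for the "global" policy, a list of them for the
# windowed "auto" policy, NULL for a fixed rank).
.rank_trace_payload <- function(rank_trace) {
  if (is.null(rank_trace)) {
    return(NULL)
  }
  if (inherits(rank_trace, "rank_trace")) {
    return(list(selected = rank_trace$selected, trace = rank_trace$trace))
  }
  lapply(rank_trace, .rank_trace_payload)
}

# Edge list (i, j, weight) of the upper triangle of a square matrix.
.edge_list <- function(m) {
  ut <- which(upper.tri(m), arr.ind = TRUE)
  data.frame(i = ut[, 1L], j = ut[, 2L], weight = m[ut])
}

#' Serialize a detection result to JSON
#'
#' Full record of a [detect_change_points()] run: parameters, rank trace,
#' candidates with per-candidate loss samples and test statistics, and the
#' final change points.
#'
#' @param result An `nmf_cpt` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
result_to_json <- function(result, path = NULL) {
  payload <- list(
    input_shape = result$input_shape,
    params = result$params,
    rank_used = result$rank_used,
    rank_trace = .rank_trace_payload(result$rank_trace),
    candidates = result$candidates,
    tests = lapply(result$tests, function(t) {
      t[c("candidate", "t_stat", "df", "p_raw", "p_adj", "significant",
          "observed", "permuted")]
    }),
    change_points = result$change_points
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
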