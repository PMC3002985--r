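#' Write a grid result as plain-text tables
#'
#' Persists a [run_grid()] result: `summaries.csv` (one row per
#' arrangement x delay), `spikes.csv` (long spike-time table), and, when
#' signatures exist, `signatures.csv` and `dendrogram.nwk`.
#'
#' @param result A `ca1_grid_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_grid_result <- function(result, dir) {
  stopifnot(inherits(result, "ca1_grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$summaries, file.path(dir, "summaries.csv"),
            row.names = FALSE)
  write.csv(result$spike_table, file.path(dir, "spikes.csv"),
            row.names = FALSE)
  if (!is.null(result$signatures)) {
    sm <- result$signatures
    len <- max(lengths(sm$signatures))
    mat <- t(vapply(sm$signatures, function(s) {
      length(s) <- len
      s
    }, numeric(len)))
    df <- data.frame(arrangement = sm$arrangement, delay = sm$delay, mat,
                     stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- paste0("pos", seq_len(len))
    write.csv(df, file.path(dir, "signatures.csv"), row.names = FALSE)
    if (length(sm$signatures) >= 2)
      as_newick(cluster_signatures(sm),
                path = file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

#' Export a return map as CSV
#'
#' @param points Return-map matrix from [build_return_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_return_map <- function(points, path) {
  write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Export an analysis report as JSON
#'
#' Serializes prediction results, sigmoid fits or classification reports
#' (any list of scalars/vectors) as pretty-printed JSON.
#'
#' @param x A list-like object (`isi_prediction`, `sigmoid_fit` or plain
#'   list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
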