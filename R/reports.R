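#' Per-sample read-count report
#'
#' One row per sample, one column per filtering stage (raw count, counts
#' removed by each record-level predicate, retained, extracted), written
#' as `nb_reads_per_sample.tsv`. Samples with zero reads get rows of
#' zeros, not absent rows.
#'
#' @param counts named list mapping sample to a named numeric vector of
#'   stage counts (e.g. the `filter_counts` attribute of
#'   [filter_alignments()] plus an `extracted` entry).
#' @param path output TSV path.
#' @return Invisibly, the report data.frame.
#' @export
write_reads_report <- function(counts, path) {
  cols <- unique(unlist(lapply(counts, names)))
  df <- data.frame(sample = names(counts), stringsAsFactors = FALSE)
  for (cl in cols)
    df[[cl]] <- vapply(counts, function(v)
      if (cl %in% names(v)) unname(v[[cl]]) else 0, 0)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Per-zone per-sample mean depth report
#'
#' Writes the `mean_depth_per_zone_per_sample.tsv` capture-efficiency
#' table: one line per zone, one column per sample.
#'
#' @param depth_matrix matrix from [mean_depth_per_zone_per_sample()].
#' @param path output TSV path.
#' @export
write_depth_report <- function(depth_matrix, path) {
  df <- data.frame(zone = rownames(depth_matrix), depth_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Append a run-provenance block
#'
#' Appends (never truncates) one human-readable block per run to a
#' `run_info.txt` file: timestamp, package version, the resolved
#' configuration, and the input/output files with their modification
#' times. Rerunning a workflow therefore leaves a complete trail of every
#' run that contributed to the outputs.
#'
#' @param path provenance file path.
#' @param config resolved parameter list ([load_config()]).
#' @param inputs,outputs character vectors of file paths.
#' @return Invisibly, the path.
#' @export
append_run_info <- function(path, config = list(), inputs = character(),
                            outputs = character()) {
  stamp_files <- function(fs) {
    if (!length(fs)) return("  (none)")
    info <- file.info(fs)
    paste0("  ", fs, " (", format(info$mtime, "%Y-%m-%d %H:%M:%S"), ")")
  }
  cfg_lines <- if (length(config)) {
    paste0("  ", names(config), ": ",
           vapply(config, function(v)
             if (is.null(v)) "disabled" else paste(v, collapse = ","), ""))
  } else "  (defaults)"
  block <- c(
    paste(rep("-", 60), collapse = ""),
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste("capcore version:",
          as.character(utils::packageVersion("capcore"))),
    "configuration:", cfg_lines,
    "inputs:", stamp_files(inputs),
    "outputs:", stamp_files(outputs))
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(block, con)
  invisible(path)
}
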