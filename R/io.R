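# Delimited-text exports for run artifacts. All outputs are plain
# tab-separated text with a header row.

#' Write a result table as tab-separated text
#'
#' @param x A data frame (blob site table, trajectory table, transit log,
#'   histogram, CI sweep, population series, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_export <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the transit log of a run
#'
#' Columns `cell_id`, `entry_min`, `exit_min` (empty while open),
#' `tagged`.
#'
#' @param sim A `"paracortex_sim"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transit_log <- function(sim, path) {
  write_tsv_export(sim$transits, path)
}
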