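#' Write / read a clonal dataset as CSV with provenance
#'
#' The CSV carries the provenance (seed, parameter hash, package version)
#' as `#`-prefixed header lines, so a dataset round-trips losslessly and
#' identical (design, seed) pairs produce byte-identical files.
#'
#' @param dataset a `clonal_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clonal_dataset <- function(dataset, path) {
  pv <- attr(dataset, "provenance") %||%
    list(seed = NA, parameter_hash = NA, package = "cryptdrift",
         version = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# cryptdrift clonal dataset",
    sprintf("# seed: %s", pv$seed),
    sprintf("# parameter_hash: %s", pv$parameter_hash),
    sprintf("# version: %s", pv$version)), con)
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clonal_dataset
#' @export
read_clonal_dataset <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                          stringsAsFactors = FALSE))
  get <- function(key) {
    line <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(line)) sub(sprintf("^# %s: ", key), "", line[1]) else NA
  }
  attr(df, "provenance") <- list(seed = get("seed"),
                                 parameter_hash = get("parameter_hash"),
                                 version = get("version"))
  class(df) <- c("clonal_dataset", class(df))
  df
}
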