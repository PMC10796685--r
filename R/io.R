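# Plain-text session persistence: rates as CSV (bins x channels), per-bin
# labels and the trial table as CSV, metadata as a small JSON file.

#' Write a session to a directory
#'
#' @param session A `bci_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "bci_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(session$rates),
                     file.path(dir, "rates.csv"))
  data.table::fwrite(session$labels, file.path(dir, "labels.csv"))
  data.table::fwrite(session$trial_table, file.path(dir, "trials.csv"))
  meta <- sprintf(
    '{"bin_width": %.3f, "block_means_removed": %s, "zscored": %s}',
    session$bin_width,
    tolower(isTRUE(session$preprocessing$block_means_removed)),
    tolower(isTRUE(session$preprocessing$zscored)))
  writeLines(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' Read a session from a directory
#'
#' @param dir Directory written by [write_session()].
#' @return A `bci_session`.
#' @export
read_session <- function(dir) {
  need <- file.path(dir, c("rates.csv", "labels.csv", "trials.csv", "meta.json"))
  if (!all(file.exists(need))) {
    stop("'", dir, "' is not a session directory (needs rates.csv, ",
         "labels.csv, trials.csv, meta.json)")
  }
  rates <- as.matrix(data.table::fread(need[1]))
  labels <- as.data.frame(data.table::fread(need[2]))
  trials <- as.data.frame(data.table::fread(need[3]))
  meta <- paste(readLines(need[4]), collapse = "")
  grab <- function(key, logical = FALSE) {
    m <- regmatches(meta, regexpr(paste0('"', key, '":\\s*[^,}]+'), meta))
    val <- trimws(sub(paste0('"', key, '":'), "", m))
    if (logical) identical(val, "true") else as.numeric(val)
  }
  bci_session(rates, labels, trials, bin_width = grab("bin_width"),
              preprocessing = list(
                block_means_removed = grab("block_means_removed", TRUE),
                zscored = grab("zscored", TRUE)))
}
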