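#' Write / read an epoch archive (plain-text container)
#'
#' Persists an [epoch_set()] as a directory of text files mirroring the
#' logical layout of an HDF5 store: `epochs.tsv` (long table: trial,
#' channel, sample, value), `channels.txt`, `times_ms.txt`,
#' `meta.tsv` and `attributes.json`. Everything is plain text so archives
#' survive source-only distribution; for large data prefer regenerating via
#' the simulators.
#'
#' @param epochs An `epoch_set`.
#' @param dir Directory to create/overwrite.
#' @return `write_epoch_archive` returns `dir` invisibly;
#'   `read_epoch_archive` the reconstructed `epoch_set`.
#' @export
write_epoch_archive <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  long <- data.table::data.table(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(epochs$data)
  )
  data.table::fwrite(long, file.path(dir, "epochs.tsv"), sep = "\t")
  writeLines(epochs$channels, file.path(dir, "channels.txt"))
  writeLines(format(epochs$times_ms, digits = 12),
             file.path(dir, "times_ms.txt"))
  data.table::fwrite(epochs$meta, file.path(dir, "meta.tsv"), sep = "\t")
  jsonlite::write_json(list(kept = epochs$kept,
                            rejection_rate = epochs$rejection_rate),
                       file.path(dir, "attributes.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_epoch_archive
#' @export
read_epoch_archive <- function(dir) {
  if (!dir.exists(dir)) stop("epoch archive not found: ", dir)
  long <- data.table::fread(file.path(dir, "epochs.tsv"))
  channels <- readLines(file.path(dir, "channels.txt"))
  times <- as.numeric(readLines(file.path(dir, "times_ms.txt")))
  meta <- data.table::fread(file.path(dir, "meta.tsv"))
  att <- jsonlite::read_json(file.path(dir, "attributes.json"),
                             simplifyVector = TRUE)
  d <- c(max(long$trial), length(channels), length(times))
  arr <- array(NA_real_, dim = d)
  arr[cbind(long$trial, long$channel, long$sample)] <- long$value
  out <- epoch_set(arr, times, channels, meta, kept = as.logical(att$kept))
  out$rejection_rate <- att$rejection_rate
  out
}
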