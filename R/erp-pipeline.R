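#' Container for epoched multi-channel data
#'
#' @param data Numeric array, trials x channels x time, in microvolt.
#' @param times_ms Strictly increasing time grid in ms (0 = stimulus onset).
#' @param channels Channel names.
#' @param meta Trial metadata (`data.table`), one row per trial; typically
#'   joined from an annotated `trial_sequence` and carrying a `condition`
#'   column.
#' @param kept Logical per-trial retention mask (default all `TRUE`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times_ms, channels, meta, kept = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[2] != length(channels))
    stop("channel dimension mismatch: array has ", dim(data)[2],
         " channels, names give ", length(channels))
  if (dim(data)[3] != length(times_ms))
    stop("time dimension mismatch")
  if (any(diff(times_ms) <= 0)) stop("times_ms must be strictly increasing")
  meta <- data.table::as.data.table(meta)
  if (nrow(meta) != dim(data)[1])
    stop("metadata rows (", nrow(meta), ") must equal trials (", dim(data)[1], ")")
  structure(list(data = data, times_ms = times_ms, channels = channels,
                 meta = meta, kept = kept %||% rep(TRUE, dim(data)[1]),
                 rejection_rate = 0),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d kept) x %d channels x %d samples [%g, %g] ms\n",
              dim(x$data)[1], sum(x$kept), length(x$channels),
              length(x$times_ms), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the prestimulus baseline
#' window; afterwards the baseline mean is zero.
#'
#' @param epochs An `epoch_set`.
#' @param window Baseline window in ms (default `c(-100, 0)`), inclusive.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- which(epochs$times_ms >= window[1] & epochs$times_ms <= window[2])
  if (length(idx) == 0L)
    stop("empty baseline window [", window[1], ", ", window[2], "] ms")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl) # recycles over time (3rd dim)
  epochs
}

#' Reject epochs by peak-to-peak signal range
#'
#' An epoch is removed iff `max - min` over its samples exceeds the
#' threshold on any channel.
#'
#' @param epochs An `epoch_set`.
#' @param range_threshold Rejection threshold in microvolt (default 100).
#' @return The `epoch_set` with `kept` updated and `rejection_rate` set.
#' @export
reject_epochs <- function(epochs, range_threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"), range_threshold > 0)
  rng <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  bad <- apply(rng > range_threshold, 1, any)
  epochs$kept <- epochs$kept & !bad
  epochs$rejection_rate <- mean(bad)
  epochs
}

#' Average retained epochs per condition
#'
#' Produces one channels x time average per averaging condition. First
#' deviants are pooled irrespective of the stimulus that followed in
#' Position 2 (the `condition` labels already encode this: `P1_dev_*` does
#' not distinguish the successor), and the global standard uses only trials
#' labelled `global_standard`.
#'
#' @param epochs An `epoch_set` whose metadata has a `condition` column (see
#'   [condition_label()] mapping inside [simulate_epoch_set()]).
#' @return An `erp_set`: list of per-condition `list(average, n_epochs)`
#'   plus `times_ms`, `channels` and the rejection rate; conditions with no
#'   retained epochs are flagged in `$empty_conditions`.
#' @export
average_conditions <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  meta <- epochs$meta
  if (!"condition" %in% names(meta))
    stop("epoch metadata must carry a 'condition' column")
  conds <- erp_conditions()
  avgs <- list(); empty <- character(0)
  for (cond in conds) {
    sel <- which(!is.na(meta$condition) & meta$condition == cond & epochs$kept)
    if (length(sel) == 0L) {
      empty <- c(empty, cond)
      next
    }
    avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    dimnames(avg) <- list(epochs$channels, NULL)
    avgs[[cond]] <- list(average = avg, n_epochs = length(sel))
  }
  if (length(empty))
    warning("conditions with no retained epochs: ", paste(empty, collapse = ", "))
  structure(list(conditions = avgs, times_ms = epochs$times_ms,
                 channels = epochs$channels,
                 rejection_rate = epochs$rejection_rate,
                 empty_conditions = empty),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> %d conditions x %d channels x %d samples\n",
              length(x$conditions), length(x$channels), length(x$times_ms)))
  invisible(x)
}

# build an erp_set directly from one participant's slice of a
# simulated_erp_study (averages already formed by the generator)
as_erp_set <- function(study, participant) {
  conds <- dimnames(study$averages)[[2]]
  avgs <- lapply(seq_along(conds), function(ci) {
    m <- study$averages[participant, ci, , ]
    dimnames(m) <- list(study$truth$channels, NULL)
    list(average = m, n_epochs = study$n_trials_per_condition[ci])
  })
  names(avgs) <- conds
  structure(list(conditions = avgs, times_ms = study$truth$times_ms,
                 channels = study$truth$channels, rejection_rate = 0,
                 empty_conditions = character(0)),
            class = "erp_set")
}

#' Frontocentral region-of-interest mean
#'
#' Unweighted mean over the ROI channels, per condition.
#'
#' @param erps An `erp_set`.
#' @param roi Channel names (default FCz, FC1, FC2, Fz).
#' @return Named list of per-condition ROI waveforms (numeric vectors over
#'   `erps$times_ms`).
#' @export
roi_mean <- function(erps, roi = c("FCz", "FC1", "FC2", "Fz")) {
  stopifnot(inherits(erps, "erp_set"))
  missing_ch <- setdiff(roi, erps$channels)
  if (length(missing_ch))
    stop("ROI channel(s) not present: ", paste(missing_ch, collapse = ", "))
  lapply(erps$conditions, function(x) colMeans(x$average[roi, , drop = FALSE]))
}

#' Crop condition averages to the factor-analysis window
#'
#' @param erps An `erp_set`.
#' @param window Window in ms, inclusive at grid-aligned endpoints
#'   (default `c(-100, 400)`).
#' @return The cropped `erp_set`.
#' @export
crop_for_efa <- function(erps, window = c(-100, 400)) {
  stopifnot(inherits(erps, "erp_set"))
  if (window[1] < min(erps$times_ms) - 1e-9 ||
      window[2] > max(erps$times_ms) + 1e-9)
    stop("crop window [", window[1], ", ", window[2],
         "] ms is outside the stored time range")
  idx <- which(erps$times_ms >= window[1] - 1e-9 &
                 erps$times_ms <= window[2] + 1e-9)
  erps$conditions <- lapply(erps$conditions, function(x) {
    x$average <- x$average[, idx, drop = FALSE]; x
  })
  erps$times_ms <- erps$times_ms[idx]
  erps
}
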