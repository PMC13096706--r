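#' Write / read a trial sequence as a BIDS-style events table
#'
#' Events are stored as tab-separated values with columns `onset` (seconds,
#' within block), `duration` (seconds, tone duration not modelled: 0),
#' `trial_type`, `block`, `trial_index`, `role`, `rule` and `pitch_hz`.
#' The round trip `read_events(write_events(x, f))` reproduces the trial
#' table exactly.
#'
#' @param seq An annotated `trial_sequence`.
#' @param path Output file path (`.tsv`).
#' @return `write_events` returns `path` invisibly; `read_events` returns a
#'   `trial_sequence` whose `config` holds the fields recoverable from the
#'   file (SOA, pitches).
#' @export
write_events <- function(seq, path) {
  stopifnot(inherits(seq, "trial_sequence"))
  tr <- seq$trials
  out <- data.table::data.table(
    onset = tr$onset_ms / 1000,
    duration = 0,
    trial_type = tr$stimulus,
    block = tr$block,
    trial_index = tr$trial_index,
    role = tr$role,
    rule = tr$preceding_rule,
    pitch_hz = tr$pitch_hz
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

valid_trial_types <- c("standard", "deviant_rep_rule", "deviant_nonrep_rule")
valid_roles <- c("lead_in", "global_standard", "first_deviant",
                 "second_deviant", "post2_standard", "other_standard")

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  tab <- data.table::fread(path, sep = "\t")
  need <- c("onset", "duration", "trial_type", "block", "trial_index",
            "role", "rule", "pitch_hz")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("malformed events file: missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("onset", "duration", "pitch_hz"))
    data.table::set(tab, j = col, value = as.numeric(tab[[col]]))
  for (col in c("block", "trial_index"))
    data.table::set(tab, j = col, value = as.integer(tab[[col]]))
  for (col in c("trial_type", "role", "rule"))
    data.table::set(tab, j = col, value = as.character(tab[[col]]))
  bad <- which(!tab$trial_type %in% valid_trial_types)
  if (length(bad))
    stop(sprintf("malformed events file: unknown trial_type '%s' at line %d",
                 tab$trial_type[bad[1L]], bad[1L] + 1L))
  bad <- which(!tab$role %in% valid_roles)
  if (length(bad))
    stop(sprintf("malformed events file: unknown role '%s' at line %d",
                 tab$role[bad[1L]], bad[1L] + 1L))
  trials <- data.table::data.table(
    block = tab$block,
    trial_index = tab$trial_index,
    onset_ms = tab$onset * 1000,
    stimulus = tab$trial_type,
    pitch_hz = tab$pitch_hz,
    role = tab$role,
    preceding_rule = tab$rule
  )
  soa <- if (nrow(trials) > 1L) {
    d <- diff(trials$onset_ms[trials$block == trials$block[1L]])
    if (length(d)) d[1L] else 800
  } else 800
  cfg <- design_config(soa_ms = soa)
  new_trial_sequence(cfg, trials)
}
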