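#' Attribute raw key presses to trials
#'
#' A press is attributed to the most recent tone onset no more than the
#' attribution window (800 ms) before it; because the stimulus onset
#' asynchrony equals the window length, windows are effectively half-open
#' `[onset, onset + 800)` and attribution is unique. At most one press per
#' trial is kept (the first); later presses in the same window and presses
#' before the first onset are logged as unassignable.
#'
#' @param seq An annotated `trial_sequence` (one block stream per
#'   participant run; onsets are taken per block).
#' @param raw_presses `data.frame`/`data.table` with columns `participant`,
#'   `block`, `time_ms` (press times on the block clock), time-sorted within
#'   participant x block.
#' @param window_ms Attribution window (default 800).
#' @return A `response_table`: `data.table` with one row per trial and
#'   participant (`participant`, `block`, `trial_index`, `stimulus`, `role`,
#'   `rule`, `press`, `rt_ms`) with attribute `n_unassignable`.
#' @export
attribute_presses <- function(seq, raw_presses, window_ms = 800) {
  stopifnot(inherits(seq, "trial_sequence"))
  presses <- data.table::as.data.table(raw_presses)
  trials <- seq$trials
  out <- list(); unassign <- 0L
  for (p in unique(presses$participant)) {
    tab <- data.table::copy(trials)
    tab[, `:=`(participant = p, press = FALSE, rt_ms = NA_real_)]
    for (b in unique(presses[participant == p, block])) {
      onsets <- tab[block == b, onset_ms]
      pt <- sort(presses[participant == p & block == b, time_ms])
      for (tm in pt) {
        i <- findInterval(tm, onsets)   # most recent onset <= tm
        if (i < 1L || tm - onsets[i] >= window_ms) {
          unassign <- unassign + 1L
          next
        }
        row <- which(tab$block == b & tab$trial_index == i - 1L)
        if (tab$press[row]) {
          unassign <- unassign + 1L     # second press in the same window
        } else {
          tab[row, `:=`(press = TRUE, rt_ms = tm - onsets[i])]
        }
      }
    }
    out[[length(out) + 1L]] <- tab
  }
  res <- data.table::rbindlist(out)
  data.table::setnames(res, "preceding_rule", "rule")
  data.table::setattr(res, "n_unassignable", unassign)
  data.table::setattr(res, "class",
                      c("response_table", class(res)))
  res
}

#' Exclude Position-2 trials whose Position-1 deviant was missed
#'
#' @param table A `response_table`.
#' @return The table with the affected rows removed; attributes
#'   `n_excluded_p2` records the count.
#' @export
apply_exclusions <- function(table) {
  tab <- data.table::as.data.table(table)
  tab <- tab[order(participant, block, trial_index)]
  # a Position-2 row is excluded when the directly preceding trial is a
  # first deviant with press == FALSE
  prev_role <- tab[, c(NA_character_, head(role, -1L)),
                   by = .(participant, block)]$V1
  prev_press <- tab[, c(NA, head(press, -1L)), by = .(participant, block)]$V1
  drop <- tab$role %in% c("second_deviant", "post2_standard") &
    !is.na(prev_role) & prev_role == "first_deviant" & prev_press == FALSE
  out <- tab[!drop]
  data.table::setattr(out, "n_excluded_p2", sum(drop))
  data.table::setattr(out, "class", c("response_table", class(out)))
  out
}

#' Hit and false-alarm rates per participant and rule
#'
#' Hits are presses on deviants (per rule and position); false alarms are
#' presses on Position-2 standards, the rule being that of the preceding
#' deviant. Run [apply_exclusions()] first.
#'
#' @param table A `response_table`.
#' @return List with `hits` (`participant`, `rule`, `position`, `n_targets`,
#'   `n_hits`, `hit_rate`) and `fas` (`participant`, `rule`,
#'   `n_nontargets`, `n_fas`, `fa_rate`); zero denominators yield `NA` with
#'   a flag column.
#' @export
response_rates <- function(table) {
  tab <- data.table::as.data.table(table)
  dev <- tab[role %in% c("first_deviant", "second_deviant")]
  dev[, rule := ifelse(role == "first_deviant",
                       ifelse(stimulus == "deviant_rep_rule", "rep", "nonrep"),
                       rule)]
  dev[, position := ifelse(role == "first_deviant", 1L, 2L)]
  hits <- dev[, .(n_targets = .N, n_hits = sum(press)),
              by = .(participant, rule, position)]
  hits[, hit_rate := ifelse(n_targets > 0, n_hits / n_targets, NA_real_)]
  fas <- tab[role == "post2_standard",
             .(n_nontargets = .N, n_fas = sum(press)),
             by = .(participant, rule)]
  fas[, fa_rate := ifelse(n_nontargets > 0, n_fas / n_nontargets, NA_real_)]
  list(hits = hits[order(participant, rule, position)],
       fas = fas[order(participant, rule)])
}

#' Log-linear correction of a proportion
#'
#' `(successes + 0.5) / (n + 1)`, keeping corrected rates strictly inside
#' (0, 1) so the inverse-normal transform is finite.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of opportunities (> 0).
#' @return Corrected rate(s).
#' @export
loglinear_correct <- function(successes, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(successes < 0 | successes > n)) stop("successes must be in [0, n]")
  (successes + 0.5) / (n + 1)
}

#' Sensitivity and criterion from corrected rates
#'
#' `d' = z(hit) - z(fa)`; `c = -0.5 * (z(hit) + z(fa))` with `z` the
#' standard-normal quantile. Rates must lie strictly in (0, 1); apply
#' [loglinear_correct()] first.
#'
#' @param hit_rate_corrected,fa_rate_corrected Corrected rates in (0, 1).
#' @return List with `d_prime` and `criterion_c` (vectorised).
#' @export
dprime_c <- function(hit_rate_corrected, fa_rate_corrected) {
  r <- c(hit_rate_corrected, fa_rate_corrected)
  if (any(r <= 0 | r >= 1))
    stop("rates must be strictly in (0, 1); apply the log-linear correction first")
  zh <- qnorm(hit_rate_corrected); zf <- qnorm(fa_rate_corrected)
  list(d_prime = zh - zf, criterion_c = -0.5 * (zh + zf))
}

#' Full SDT summary per participant and rule
#'
#' Position-2 discrimination: hits on second deviants (repetition trials)
#' against false alarms on Position-2 standards, log-linear corrected.
#'
#' @param table A `response_table` after exclusions.
#' @return `data.table` with counts, corrected rates, `d_prime`,
#'   `criterion_c` per `participant` x `rule`.
#' @export
sdt_summary <- function(table) {
  r <- response_rates(table)
  h2 <- r$hits[position == 2L]
  m <- merge(h2[, .(participant, rule, n_targets, n_hits)],
             r$fas, by = c("participant", "rule"))
  m[, hit_rate_corrected := loglinear_correct(n_hits, n_targets)]
  m[, fa_rate_corrected := loglinear_correct(n_fas, n_nontargets)]
  dc <- dprime_c(m$hit_rate_corrected, m$fa_rate_corrected)
  m[, `:=`(d_prime = dc$d_prime, criterion_c = dc$criterion_c)]
  m[]
}

#' Median response times per participant, position and rule
#'
#' First-deviant responses are pooled over what followed; medians use the
#' standard convention (mean of the two central order statistics for even
#' counts). `delta21` is the Position 2 minus Position 1 median difference
#' per rule.
#'
#' @param table A `response_table` (presses only are used).
#' @return List with `medians` (`participant`, `rule`, `position`,
#'   `median_rt_ms`, `n`) and `delta21` (`participant`, `rule`,
#'   `delta21_ms`); empty cells give `NA`.
#' @export
rt_summaries <- function(table) {
  tab <- data.table::as.data.table(table)
  dev <- tab[role %in% c("first_deviant", "second_deviant") & press == TRUE]
  dev[, rule := ifelse(role == "first_deviant",
                       ifelse(stimulus == "deviant_rep_rule", "rep", "nonrep"),
                       rule)]
  dev[, position := ifelse(role == "first_deviant", 1L, 2L)]
  med <- dev[, .(median_rt_ms = median(rt_ms), n = .N),
             by = .(participant, rule, position)]
  wide <- data.table::dcast(med, participant + rule ~ position,
                            value.var = "median_rt_ms")
  if (!"1" %in% names(wide)) wide[, `1` := NA_real_]
  if (!"2" %in% names(wide)) wide[, `2` := NA_real_]
  wide[, delta21_ms := `2` - `1`]
  list(medians = med[order(participant, rule, position)],
       delta21 = wide[, .(participant, rule, delta21_ms)])
}
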