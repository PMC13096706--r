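#' Generate one block of the conditional-oddball sequence
#'
#' A block is built from deviant "events" (a first deviant optionally
#' followed by an identical second deviant) separated by runs of standards.
#' Per-block composition is exact: with the defaults, 30 first deviants of
#' each type, of which 24 repetition-rule and 6 nonrepetition-rule first
#' deviants are followed by an identical deviant (the 0.8 / 0.2 conditional
#' rules), giving 345 standards and 90 deviants in 435 trials.
#'
#' @param config A [design_config()].
#' @param block_index 1-based block number (used for trial bookkeeping).
#' @param first_deviant_type Stimulus class of the first deviant event in the
#'   block: `"deviant_rep_rule"` or `"deviant_nonrep_rule"`.
#' @param seed Integer seed for this block's randomisation; defaults to a
#'   seed derived from `config$seed` and `block_index`.
#' @return A `trial_sequence`: list with `config` and a `data.table` of
#'   trials (columns `block`, `trial_index`, `onset_ms`, `stimulus`,
#'   `pitch_hz`, `role`, `preceding_rule`), roles annotated.
#' @seealso [generate_experiment()], [annotate_conditions()]
#' @export
generate_block <- function(config, block_index = 1L,
                           first_deviant_type = c("deviant_rep_rule",
                                                  "deviant_nonrep_rule"),
                           seed = NULL) {
  validate_design_config(config)
  first_deviant_type <- match.arg(first_deviant_type)
  seed <- seed %||% derive_seed(config$seed, block_index)

  n1 <- config$n_first_per_type_per_block
  n_rep_second <- as.integer(round(n1 * config$p_repeat_high))
  n_nonrep_second <- as.integer(round(n1 * config$p_repeat_low))

  stim <- local({
    set.seed(seed)
    if (n1 == 0L) {
      rep("standard", config$trials_per_block)
    } else {
      # event list: type + whether the first deviant is repeated
      ev_type <- c(rep("deviant_rep_rule", n1), rep("deviant_nonrep_rule", n1))
      ev_rep <- c(rep(c(TRUE, FALSE), c(n_rep_second, n1 - n_rep_second)),
                  rep(c(TRUE, FALSE), c(n_nonrep_second, n1 - n_nonrep_second)))
      ord <- sample.int(2L * n1)
      ev_type <- ev_type[ord]; ev_rep <- ev_rep[ord]
      # force the first event to be of first_deviant_type (swap with the
      # earliest event of that type)
      if (ev_type[1L] != first_deviant_type) {
        j <- which(ev_type == first_deviant_type)[1L]
        ev_type[c(1L, j)] <- ev_type[c(j, 1L)]
        ev_rep[c(1L, j)] <- ev_rep[c(j, 1L)]
      }
      n_events <- 2L * n1
      n_dev <- n_events + n_rep_second + n_nonrep_second
      n_std <- config$trials_per_block - n_dev
      # gaps of standards: g0 >= lead_in, g1..g_{E-1} >= min_sep, and
      # g_E >= min_sep so the final event always has its Position-2 slot
      # (and the count table is invariant over orderings)
      base <- c(config$lead_in_standards,
                rep(config$min_standards_between_events, n_events))
      extra <- n_std - sum(base)
      # uniform random composition of `extra` standards over E + 1 gaps
      gaps <- base + as.vector(stats::rmultinom(1L, extra,
                                                rep(1, n_events + 1L)))
      out <- character(0)
      for (e in seq_len(n_events)) {
        out <- c(out, rep("standard", gaps[e]), ev_type[e],
                 if (ev_rep[e]) ev_type[e])
      }
      c(out, rep("standard", gaps[n_events + 1L]))
    }
  })
  stopifnot(length(stim) == config$trials_per_block)

  trials <- data.table::data.table(
    block = as.integer(block_index),
    trial_index = seq_along(stim) - 1L,
    onset_ms = (seq_along(stim) - 1L) * config$soa_ms,
    stimulus = stim,
    pitch_hz = pitch_for_stimulus(config, stim)
  )
  seq_out <- new_trial_sequence(config, trials)
  annotate_conditions(seq_out)
}

new_trial_sequence <- function(config, trials) {
  structure(list(config = config, trials = trials),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> %d trials in %d block(s)\n",
              nrow(x$trials), length(unique(x$trials$block))))
  print(summarize_counts(x))
  invisible(x)
}

#' Generate a full experimental session
#'
#' Concatenates `n_blocks` blocks; when counterbalancing is on the deviant
#' type encountered first alternates across blocks. With the default
#' configuration the session contains 6900 standards and 1800 deviants, each
#' deviant type appearing in 600 trials as a first deviant.
#'
#' @inheritParams generate_block
#' @return A `trial_sequence` spanning all blocks, roles annotated.
#' @examples
#' seq <- generate_experiment(design_config(seed = 42))
#' summarize_counts(seq)
#' @export
generate_experiment <- function(config = design_config()) {
  validate_design_config(config)
  if (config$counterbalance_first_deviant && config$n_blocks %% 2L != 0L)
    stop_config("counterbalancing the first deviant type requires an even ",
                "number of blocks (got ", config$n_blocks, ")")
  types <- c("deviant_rep_rule", "deviant_nonrep_rule")
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    ft <- if (config$counterbalance_first_deviant)
      types[(b - 1L) %% 2L + 1L]
    else
      types[1L]
    generate_block(config, b, ft)$trials
  })
  new_trial_sequence(config, data.table::rbindlist(blocks))
}

#' Generate the active deviant-detection (behavioural control) task
#'
#' Six blocks of 220 trials each, with the same conditional rule structure
#' as the main session but a smaller composition: per block, 175 standards,
#' 15 first deviants per type, and 12 repetition-rule / 3 nonrepetition-rule
#' second deviants, preserving the exact 0.8 / 0.2 conditional probabilities.
#'
#' @param config A [design_config()]; block geometry fields are overridden
#'   by the behavioural composition, rule and pitch settings are kept.
#' @param n_blocks,trials_per_block,n_first_per_type_per_block Behavioural
#'   composition (defaults 6, 220, 15).
#' @return A `trial_sequence`.
#' @export
generate_behavioural_task <- function(config = design_config(),
                                      n_blocks = 6L,
                                      trials_per_block = 220L,
                                      n_first_per_type_per_block = 15L) {
  cfg <- config
  cfg$n_blocks <- assert_count(n_blocks, "n_blocks", 1L)
  cfg$trials_per_block <- assert_count(trials_per_block, "trials_per_block", 1L)
  cfg$n_first_per_type_per_block <-
    assert_count(n_first_per_type_per_block, "n_first_per_type_per_block")
  cfg$counterbalance_first_deviant <-
    config$counterbalance_first_deviant && cfg$n_blocks %% 2L == 0L
  validate_design_config(cfg)
  generate_experiment(cfg)
}

#' Annotate trial roles and preceding rules
#'
#' Assigns each trial its role in the averaging scheme, derived purely from
#' the stimulus sequence and block boundaries:
#' * `lead_in` - the first `lead_in_standards` trials of a block (standards
#'   preceding any possible deviant, excluded from the global standard so
#'   that the standard regularity can build up),
#' * `first_deviant` - a deviant preceded by a standard (Position 1),
#' * `second_deviant` - a deviant preceded by an identical deviant
#'   (Position 2),
#' * `post2_standard` - the standard directly following a single (first)
#'   deviant (Position 2),
#' * `global_standard` - any other standard-after-standard trial that does
#'   not directly follow a Position-2 stimulus,
#' * `other_standard` - remaining standards (those directly following a
#'   Position-2 stimulus).
#' `preceding_rule` carries the conditional rule of the governing deviant
#' for Position-2 trials (`"rep"` / `"nonrep"`, else `"none"`).
#'
#' @param seq A `trial_sequence`.
#' @return The sequence with `role` and `preceding_rule` columns rewritten.
#' @export
annotate_conditions <- function(seq) {
  stopifnot(inherits(seq, "trial_sequence"))
  tr <- data.table::copy(seq$trials)
  dev_classes <- c("deviant_rep_rule", "deviant_nonrep_rule")
  rule_of <- function(stim) {
    ifelse(stim == "deviant_rep_rule", "rep",
           ifelse(stim == "deviant_nonrep_rule", "nonrep", "none"))
  }
  lead_n <- seq$config$lead_in_standards
  annotate_one <- function(stim, idx) {
    n <- length(stim)
    prev <- c(NA_character_, stim[-n])
    prev2 <- c(NA_character_, NA_character_, stim[-c(n - 1L, n)])
    is_dev <- stim %in% dev_classes
    prev_dev <- !is.na(prev) & prev %in% dev_classes
    prev2_dev <- !is.na(prev2) & prev2 %in% dev_classes

    role <- rep("other_standard", n)
    pr <- rep("none", n)

    role[is_dev & !prev_dev] <- "first_deviant"
    second <- is_dev & prev_dev & stim == prev
    role[second] <- "second_deviant"
    pr[second] <- rule_of(stim[second])

    # standard in Position 2: directly after a single (first) deviant
    post2 <- !is_dev & prev_dev & !prev2_dev
    role[post2] <- "post2_standard"
    pr[post2] <- rule_of(prev[post2])

    # Position-2 stimulus at i-1 (second deviant or post2 standard) excludes
    # the following standard from the global standard
    is_pos2 <- second | post2
    prev_pos2 <- c(FALSE, is_pos2[-n])
    glob <- !is_dev & !prev_dev & !post2 & !prev_pos2 & idx >= lead_n
    role[glob] <- "global_standard"
    role[idx < lead_n & !is_dev] <- "lead_in"
    list(role = role, preceding_rule = pr)
  }
  tr[, c("role", "preceding_rule") := annotate_one(stimulus, trial_index),
     by = block]
  new_trial_sequence(seq$config, tr)
}

#' Tabulate trial counts by stimulus, role and preceding rule
#'
#' @param seq An annotated `trial_sequence`.
#' @return A `data.table` with columns `stimulus`, `role`, `preceding_rule`
#'   and `n`; `sum(n)` equals the number of trials.
#' @export
summarize_counts <- function(seq) {
  stopifnot(inherits(seq, "trial_sequence"))
  if (nrow(seq$trials) == 0L)
    return(data.table::data.table(stimulus = character(), role = character(),
                                  preceding_rule = character(), n = integer()))
  if (!"role" %in% names(seq$trials)) seq <- annotate_conditions(seq)
  seq$trials[, .(n = .N), by = .(stimulus, role, preceding_rule)][order(stimulus, role)]
}

# internal constraint audit used by tests: returns character vector of
# violations (empty when the sequence satisfies the design constraints)
check_sequence_constraints <- function(seq) {
  cfg <- seq$config
  bad <- character(0)
  for (b in unique(seq$trials$block)) {
    stim <- seq$trials[block == b, stimulus]
    is_dev <- stim %in% c("deviant_rep_rule", "deviant_nonrep_rule")
    n <- length(stim)
    if (any(stim[seq_len(min(cfg$lead_in_standards, n))] != "standard"))
      bad <- c(bad, sprintf("block %s: lead-in contains a deviant", b))
    prev <- c(NA, stim[-n])
    if (any(is_dev & !is.na(prev) & prev %in%
              c("deviant_rep_rule", "deviant_nonrep_rule") & stim != prev))
      bad <- c(bad, sprintf("block %s: nonidentical deviant adjacency", b))
    r <- rle(is_dev)
    if (any(r$lengths[r$values] > 2L))
      bad <- c(bad, sprintf("block %s: more than two consecutive deviants", b))
    # spacing between deviant events: standard runs flanked by deviants
    k <- length(r$values)
    inner <- which(!r$values & seq_len(k) > 1L & seq_len(k) < k)
    if (any(r$lengths[inner] < cfg$min_standards_between_events))
      bad <- c(bad, sprintf("block %s: deviant events closer than min spacing", b))
  }
  bad
}
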