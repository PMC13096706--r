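#' Configuration of the conditional-oddball stimulus design
#'
#' Describes one session of the modified oddball paradigm: a frequent
#' standard tone is occasionally replaced by one of two rare deviant pitches,
#' and each deviant type carries its own conditional repetition rule. The
#' repetition-rule deviant is followed by an identical deviant with
#' probability `p_repeat_high` (default 0.8), the nonrepetition-rule deviant
#' with probability `p_repeat_low` (default 0.2). Per-block repetition counts
#' are exact: `n_first_per_type_per_block * p_repeat_high` and
#' `* p_repeat_low` must be integers.
#'
#' @param n_blocks Number of blocks in the session (default 20).
#' @param trials_per_block Trials per block (default 435).
#' @param n_first_per_type_per_block First deviants of each type per block
#'   (default 30).
#' @param p_repeat_high,p_repeat_low Conditional repetition probabilities of
#'   the repetition-rule and nonrepetition-rule deviant (defaults 0.8, 0.2).
#' @param soa_ms Stimulus onset asynchrony in ms (default 800).
#' @param standard_hz,high_pitch_hz,low_pitch_hz Tone frequencies in Hz
#'   (defaults 440, 547.37, 349.23).
#' @param pitch_to_rule Which pitch carries the repetition rule; one of
#'   `"high_pitch_is_repetition_rule"`, `"low_pitch_is_repetition_rule"`.
#' @param lead_in_standards Standards opening every block (default 5).
#' @param min_standards_between_events Minimum standards separating two
#'   deviant events (default 2).
#' @param counterbalance_first_deviant Alternate the deviant type
#'   encountered first across blocks (default `TRUE`; requires even
#'   `n_blocks`).
#' @param seed Integer seed controlling the randomised trial order.
#' @return An object of class `design_config`.
#' @examples
#' cfg <- design_config()
#' cfg$trials_per_block
#' @export
design_config <- function(n_blocks = 20L,
                          trials_per_block = 435L,
                          n_first_per_type_per_block = 30L,
                          p_repeat_high = 0.8,
                          p_repeat_low = 0.2,
                          soa_ms = 800,
                          standard_hz = 440,
                          high_pitch_hz = 547.37,
                          low_pitch_hz = 349.23,
                          pitch_to_rule = c("high_pitch_is_repetition_rule",
                                            "low_pitch_is_repetition_rule"),
                          lead_in_standards = 5L,
                          min_standards_between_events = 2L,
                          counterbalance_first_deviant = TRUE,
                          seed = 1L) {
  pitch_to_rule <- match.arg(pitch_to_rule)
  cfg <- list(
    n_blocks = assert_count(n_blocks, "n_blocks", 1L),
    trials_per_block = assert_count(trials_per_block, "trials_per_block", 1L),
    n_first_per_type_per_block =
      assert_count(n_first_per_type_per_block, "n_first_per_type_per_block"),
    p_repeat_high = assert_prob(p_repeat_high, "p_repeat_high"),
    p_repeat_low = assert_prob(p_repeat_low, "p_repeat_low"),
    soa_ms = as.numeric(soa_ms),
    standard_hz = as.numeric(standard_hz),
    high_pitch_hz = as.numeric(high_pitch_hz),
    low_pitch_hz = as.numeric(low_pitch_hz),
    pitch_to_rule = pitch_to_rule,
    lead_in_standards = assert_count(lead_in_standards, "lead_in_standards"),
    min_standards_between_events =
      assert_count(min_standards_between_events, "min_standards_between_events"),
    counterbalance_first_deviant = isTRUE(counterbalance_first_deviant),
    seed = assert_count(seed, "seed")
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  n1 <- cfg$n_first_per_type_per_block
  if (n1 > 0L) {
    if (!(cfg$p_repeat_low < cfg$p_repeat_high))
      stop_config("p_repeat_low must be smaller than p_repeat_high")
    if (cfg$p_repeat_low <= 0 || cfg$p_repeat_high >= 1)
      stop_config("repetition probabilities must satisfy 0 < p_low < p_high < 1")
    for (p in c(cfg$p_repeat_high, cfg$p_repeat_low)) {
      k <- n1 * p
      if (abs(k - round(k)) > 1e-9)
        stop_config("n_first_per_type_per_block * ", p,
                    " must be an integer (exact per-block repetition counts)")
    }
  }
  n_dev <- 2L * n1 + round(n1 * (cfg$p_repeat_high + cfg$p_repeat_low))
  if (n_dev > cfg$trials_per_block)
    stop_config("implied deviant total per block (", n_dev,
                ") exceeds trials_per_block (", cfg$trials_per_block, ")")
  # packing feasibility: lead-in + minimum spacing must fit into the standards
  n_events <- 2L * n1
  n_std <- cfg$trials_per_block - n_dev
  need <- cfg$lead_in_standards +
    n_events * cfg$min_standards_between_events
  if (n_events > 0L && n_std < need)
    stop_config("infeasible packing: need at least ", need,
                " standards for lead-in and spacing but only ", n_std,
                " available")
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  %d blocks x %d trials, SOA %g ms\n",
              x$n_blocks, x$trials_per_block, x$soa_ms))
  cat(sprintf("  %d first deviants per type/block; p(repeat) = %.2f / %.2f\n",
              x$n_first_per_type_per_block, x$p_repeat_high, x$p_repeat_low))
  cat(sprintf("  pitches: std %g Hz, high %g Hz, low %g Hz (%s)\n",
              x$standard_hz, x$high_pitch_hz, x$low_pitch_hz, x$pitch_to_rule))
  invisible(x)
}

# pitch of each stimulus class under the configured pitch-rule mapping
pitch_for_stimulus <- function(cfg, stimulus) {
  rep_pitch <- if (cfg$pitch_to_rule == "high_pitch_is_repetition_rule")
    cfg$high_pitch_hz else cfg$low_pitch_hz
  nonrep_pitch <- if (cfg$pitch_to_rule == "high_pitch_is_repetition_rule")
    cfg$low_pitch_hz else cfg$high_pitch_hz
  out <- rep(cfg$standard_hz, length(stimulus))
  out[stimulus == "deviant_rep_rule"] <- rep_pitch
  out[stimulus == "deviant_nonrep_rule"] <- nonrep_pitch
  out
}
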