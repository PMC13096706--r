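#' Ground truth for simulated detection behaviour
#'
#' Decisions follow an equal-variance signal-detection rule: on a deviant
#' trial a press occurs iff a `Normal(d', 1)` draw exceeds the rule's
#' decision threshold (and no lapse occurs); on a Position-2 standard a
#' false-alarm press occurs iff a `Normal(0, 1)` draw exceeds the threshold.
#' Note the threshold `lambda` is the absolute criterion; the SDT bias
#' estimate recovers `c = lambda - d'/2`. Response times for presses are
#' lognormal with log-scale location `mu = a * trial^b` (the power-law
#' learning trend; coefficients default to published posterior means) and
#' log-scale SD `exp(sigma linear predictor)`. Sampled RTs above the
#' attribution window are recorded as misses (truncation).
#'
#' @param rt_coefs List with elements `a` (`intercept`, `position2`), `b`
#'   (`intercept`, `position2`, `rep_high`, `interaction`) on the log scale.
#' @param sigma_coefs Log-scale dispersion linear predictor (`intercept`,
#'   `position2`, `rep_high`, `interaction`).
#' @param participant_sd List with `a` and `b`: SDs of the participant
#'   random intercepts.
#' @param d_prime Matrix (2 x 2: position x rule `rep`/`nonrep`) of true
#'   sensitivities.
#' @param criterion Named threshold per rule (`rep`, `nonrep`).
#' @param lapse_rate Probability of missing a target regardless of evidence.
#' @param attribution_window_ms RT truncation bound (default 800).
#' @return An object of class `behaviour_ground_truth`.
#' @export
behaviour_ground_truth <- function(
    rt_coefs = list(
      a = c(intercept = 5.66933, position2 = 0.23541),
      b = c(intercept = 0.00367, position2 = -0.00818,
            rep_high = 0.00014, interaction = -0.00542)
    ),
    sigma_coefs = c(intercept = -1.75, position2 = 0.30,
                    rep_high = 0, interaction = 0.15),
    participant_sd = list(a = 0.15, b = 0.002),
    d_prime = matrix(c(4.04, 4.66, 3.522, 3.904), nrow = 2, byrow = TRUE,
                     dimnames = list(c("pos1", "pos2"), c("rep", "nonrep"))),
    criterion = c(rep = 1.462, nonrep = 2.085),
    lapse_rate = 0.01,
    attribution_window_ms = 800) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1,
            all(participant_sd$a >= 0), all(participant_sd$b >= 0))
  structure(list(rt_coefs = rt_coefs, sigma_coefs = sigma_coefs,
                 participant_sd = participant_sd, d_prime = d_prime,
                 criterion = criterion, lapse_rate = lapse_rate,
                 attribution_window_ms = attribution_window_ms),
            class = "behaviour_ground_truth")
}

# cell coefficients on the log scale for (position, rule); trial_number is
# the 1-based index of the deviant trial within the whole behavioural part
mu_cell <- function(truth, position, rule, trial_number,
                    a_re = 0, b_re = 0) {
  p2 <- as.numeric(position == 2L)
  hi <- as.numeric(rule == "rep")
  getc <- function(v, nm) if (nm %in% names(v)) v[[nm]] else 0
  a <- getc(truth$rt_coefs$a, "intercept") +
    getc(truth$rt_coefs$a, "position2") * p2 +
    getc(truth$rt_coefs$a, "rep_high") * hi +
    getc(truth$rt_coefs$a, "interaction") * p2 * hi + a_re
  b <- getc(truth$rt_coefs$b, "intercept") +
    getc(truth$rt_coefs$b, "position2") * p2 +
    getc(truth$rt_coefs$b, "rep_high") * hi +
    getc(truth$rt_coefs$b, "interaction") * p2 * hi + b_re
  a * trial_number^b
}

sigma_cell <- function(truth, position, rule) {
  p2 <- as.numeric(position == 2L)
  hi <- as.numeric(rule == "rep")
  exp(truth$sigma_coefs[["intercept"]] +
        truth$sigma_coefs[["position2"]] * p2 +
        truth$sigma_coefs[["rep_high"]] * hi +
        truth$sigma_coefs[["interaction"]] * p2 * hi)
}

#' Simulate single-trial detection behaviour for a task sequence
#'
#' @param truth A [behaviour_ground_truth()].
#' @param seq An annotated `trial_sequence` (typically from
#'   [generate_behavioural_task()]).
#' @param n_participants Number of participants.
#' @param seed Integer seed.
#' @return A `response_table` (one row per trial and participant) with
#'   columns as in [attribute_presses()] plus `position`, `trial_number`
#'   (deviant counter) and attribute `truncation_rate` (share of sampled
#'   RTs beyond the attribution window, recorded as misses).
#' @export
simulate_behaviour <- function(truth, seq, n_participants = 59, seed = 1L) {
  stopifnot(inherits(seq, "trial_sequence"))
  set.seed(seed)
  base <- data.table::copy(seq$trials)
  data.table::setnames(base, "preceding_rule", "rule")
  base[, position := data.table::fifelse(role == "first_deviant", 1L,
                      data.table::fifelse(role == "second_deviant", 2L, NA_integer_))]
  base[role == "first_deviant",
       rule := ifelse(stimulus == "deviant_rep_rule", "rep", "nonrep")]
  is_dev <- !is.na(base$position)
  base[, trial_number := NA_integer_]
  base[which(is_dev), trial_number := seq_len(sum(is_dev))]

  out <- vector("list", n_participants)
  n_trunc <- 0L; n_press_try <- 0L
  for (p in seq_len(n_participants)) {
    tab <- data.table::copy(base)
    tab[, participant := p]
    a_re <- rnorm(1, 0, truth$participant_sd$a)
    b_re <- rnorm(1, 0, truth$participant_sd$b)
    press <- rep(FALSE, nrow(tab)); rt <- rep(NA_real_, nrow(tab))

    dev_rows <- which(is_dev)
    for (i in dev_rows) {
      rl <- tab$rule[i]; pos <- tab$position[i]
      evid <- rnorm(1, truth$d_prime[pos, rl], 1)
      if (evid > truth$criterion[[rl]] && runif(1) > truth$lapse_rate) {
        mu <- mu_cell(truth, pos, rl, tab$trial_number[i], a_re, b_re)
        s <- sigma_cell(truth, pos, rl)
        r <- rlnorm(1, mu, s)
        n_press_try <- n_press_try + 1L
        if (r <= truth$attribution_window_ms) {
          press[i] <- TRUE; rt[i] <- r
        } else {
          n_trunc <- n_trunc + 1L
        }
      }
    }
    fa_rows <- which(tab$role == "post2_standard")
    for (i in fa_rows) {
      rl <- tab$rule[i]
      if (rnorm(1) > truth$criterion[[rl]]) {
        mu <- mu_cell(truth, 2L, rl, max(tab$trial_number[seq_len(i)],
                                         1L, na.rm = TRUE), a_re, b_re)
        s <- sigma_cell(truth, 2L, rl)
        r <- rlnorm(1, mu, s)
        n_press_try <- n_press_try + 1L
        if (r <= truth$attribution_window_ms) {
          press[i] <- TRUE; rt[i] <- r
        } else n_trunc <- n_trunc + 1L
      }
    }
    tab[, `:=`(press = press, rt_ms = rt)]
    out[[p]] <- tab
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "truncation_rate",
                      if (n_press_try > 0) n_trunc / n_press_try else 0)
  data.table::setattr(res, "class", c("response_table", class(res)))
  res
}
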