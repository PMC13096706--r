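# shared fixtures, built in code at test time

# small feasible design for fast sequence tests
tiny_design <- function(...) {
  design_config(n_blocks = 2L, trials_per_block = 60L,
                n_first_per_type_per_block = 5L, seed = 11L, ...)
}

# epoch_set with constant per-condition values on a small grid
const_epoch_set <- function(values_by_condition, n_per_cond = 2,
                            n_channels = 4, n_time = 12) {
  conds <- names(values_by_condition)
  n <- length(conds) * n_per_cond
  dat <- array(0, dim = c(n, n_channels, n_time))
  meta <- data.table::data.table(condition = rep(conds, each = n_per_cond))
  for (i in seq_len(n)) dat[i, , ] <- values_by_condition[[meta$condition[i]]]
  epoch_set(dat, seq(-100, 120, length.out = n_time),
            c("FCz", "FC1", "FC2", "Fz")[seq_len(n_channels)], meta)
}

# response_table skeleton: one participant, a run of P1 deviant followed by
# P2 stimulus pairs with given presses
pair_response_table <- function(p1_press, p2_role, p2_press,
                                rule = "rep", participant = 1L) {
  n <- length(p1_press)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[2 * i - 1]] <- data.table::data.table(
      participant = participant, block = 1L, trial_index = 2L * i - 2L,
      stimulus = if (rule == "rep") "deviant_rep_rule" else "deviant_nonrep_rule",
      role = "first_deviant", rule = "none",
      press = p1_press[i], rt_ms = if (p1_press[i]) 300 else NA_real_)
    rows[[2 * i]] <- data.table::data.table(
      participant = participant, block = 1L, trial_index = 2L * i - 1L,
      stimulus = if (p2_role[i] == "second_deviant") {
        if (rule == "rep") "deviant_rep_rule" else "deviant_nonrep_rule"
      } else "standard",
      role = p2_role[i], rule = rule,
      press = p2_press[i], rt_ms = if (p2_press[i]) 250 else NA_real_)
  }
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("response_table", class(out)))
  out
}

# full-coverage planted 5-factor study: factor curves span the EFA window so
# the Empirical Kaiser Criterion can count them (see methods vignette)
coverage_truth <- function() {
  factor_ground_truth(latencies_ms = c(-55, 50, 155, 260, 365),
                      widths_ms = 45)
}

equal_trials <- function(n = 500) {
  stats::setNames(rep(n, 7), erp_conditions())
}
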