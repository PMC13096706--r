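test_that("default block reproduces the exact design composition", {
  cfg <- design_config(seed = 5)
  blk <- generate_block(cfg, 1, "deviant_rep_rule")
  tr <- blk$trials
  expect_equal(nrow(tr), 435L)
  expect_equal(sum(tr$stimulus == "standard"), 345L)
  expect_equal(sum(tr$stimulus != "standard"), 90L)
  expect_equal(sum(tr$role == "first_deviant" &
                     tr$stimulus == "deviant_rep_rule"), 30L)
  expect_equal(sum(tr$role == "first_deviant" &
                     tr$stimulus == "deviant_nonrep_rule"), 30L)
  expect_equal(sum(tr$role == "second_deviant" &
                     tr$stimulus == "deviant_rep_rule"), 24L)
  expect_equal(sum(tr$role == "second_deviant" &
                     tr$stimulus == "deviant_nonrep_rule"), 6L)
  # first deviant event respects the requested type
  first_dev <- tr$stimulus[tr$stimulus != "standard"][1]
  expect_equal(first_dev, "deviant_rep_rule")
  # lead-in
  expect_true(all(tr$stimulus[1:5] == "standard"))
  expect_true(all(tr$role[1:5] == "lead_in"))
  expect_length(oddpred:::check_sequence_constraints(blk), 0)
})

test_that("degenerate designs and infeasible packings are handled", {
  cfg <- design_config(n_first_per_type_per_block = 0, seed = 2)
  blk <- generate_block(cfg, 1)
  expect_true(all(blk$trials$stimulus == "standard"))
  expect_equal(nrow(blk$trials), 435L)
  # too many deviant events for the block length
  expect_error(design_config(trials_per_block = 100,
                             n_first_per_type_per_block = 30),
               "exceeds|infeasible")
  # non-integer per-block repetition counts
  expect_error(design_config(n_first_per_type_per_block = 7),
               "integer")
  expect_error(design_config(p_repeat_high = 0.2, p_repeat_low = 0.8),
               "smaller")
})

test_that("conditional repetition fractions are exactly 0.8 / 0.2 per block", {
  cfg <- design_config(seed = 42)
  for (b in 1:25) {
    blk <- generate_block(cfg, b,
                          c("deviant_rep_rule", "deviant_nonrep_rule")[b %% 2 + 1])
    tr <- blk$trials
    n1_rep <- sum(tr$role == "first_deviant" & tr$stimulus == "deviant_rep_rule")
    n2_rep <- sum(tr$role == "second_deviant" & tr$stimulus == "deviant_rep_rule")
    n1_non <- sum(tr$role == "first_deviant" & tr$stimulus == "deviant_nonrep_rule")
    n2_non <- sum(tr$role == "second_deviant" & tr$stimulus == "deviant_nonrep_rule")
    expect_equal(n2_rep / n1_rep, 0.8)
    expect_equal(n2_non / n1_non, 0.2)
    expect_length(oddpred:::check_sequence_constraints(blk), 0)
  }
})

test_that("full session reproduces the aggregate trial arithmetic", {
  seqx <- generate_experiment(design_config(seed = 9))
  tr <- seqx$trials
  expect_equal(nrow(tr), 8700L)
  expect_equal(sum(tr$stimulus == "standard"), 6900L)
  expect_equal(sum(tr$stimulus != "standard"), 1800L)
  expect_equal(sum(tr$role == "first_deviant" &
                     tr$stimulus == "deviant_rep_rule"), 600L)
  expect_equal(sum(tr$role == "first_deviant" &
                     tr$stimulus == "deviant_nonrep_rule"), 600L)
  expect_equal(sum(tr$stimulus == "deviant_rep_rule"), 1080L)
  expect_equal(sum(tr$stimulus == "deviant_nonrep_rule"), 720L)
  # conforming / violating outcomes per rule
  expect_equal(sum(tr$role == "second_deviant" & tr$preceding_rule == "rep"), 480L)
  expect_equal(sum(tr$role == "post2_standard" & tr$preceding_rule == "rep"), 120L)
  expect_equal(sum(tr$role == "post2_standard" & tr$preceding_rule == "nonrep"), 480L)
  expect_equal(sum(tr$role == "second_deviant" & tr$preceding_rule == "nonrep"), 120L)
})

test_that("same seed gives identical sequences, different seeds same counts", {
  a <- generate_experiment(design_config(seed = 31))
  b <- generate_experiment(design_config(seed = 31))
  expect_identical(as.data.frame(a$trials), as.data.frame(b$trials))
  c <- generate_experiment(design_config(seed = 32))
  expect_false(identical(a$trials$stimulus, c$trials$stimulus))
  expect_identical(summarize_counts(a), summarize_counts(c))
})

test_that("counterbalancing alternates the first deviant type and needs even blocks", {
  seqx <- generate_experiment(design_config(n_blocks = 4, seed = 3))
  firsts <- seqx$trials[role == "first_deviant", .SD[1], by = block]$stimulus
  expect_equal(firsts, rep(c("deviant_rep_rule", "deviant_nonrep_rule"), 2))
  expect_error(generate_experiment(design_config(n_blocks = 3, seed = 3)),
               "even")
})

test_that("behavioural task has the fixed 6 x 220 composition", {
  bt <- generate_behavioural_task(design_config(seed = 8))
  tr <- bt$trials
  expect_equal(as.vector(table(tr$block)), rep(220L, 6))
  for (b in 1:6) {
    tb <- tr[tr$block == b, ]
    expect_equal(sum(tb$stimulus == "standard"), 175L)
    expect_equal(sum(tb$role == "first_deviant" &
                       tb$stimulus == "deviant_rep_rule"), 15L)
    expect_equal(sum(tb$role == "second_deviant" &
                       tb$stimulus == "deviant_rep_rule"), 12L)
    expect_equal(sum(tb$role == "second_deviant" &
                       tb$stimulus == "deviant_nonrep_rule"), 3L)
  }
  # zero-deviant behavioural config
  bt0 <- generate_behavioural_task(design_config(seed = 8),
                                   n_first_per_type_per_block = 0)
  expect_true(all(bt0$trials$stimulus == "standard"))
})

test_that("annotate_conditions assigns roles per the averaging scheme", {
  cfg <- tiny_design()
  # hand-built block: 6 standards, P1 deviant, P2 deviant, standards
  stim <- c(rep("standard", 6), "deviant_rep_rule", "deviant_rep_rule",
            rep("standard", 4))
  tr <- data.table::data.table(block = 1L, trial_index = seq_along(stim) - 1L,
                               onset_ms = (seq_along(stim) - 1) * 800,
                               stimulus = stim,
                               pitch_hz = oddpred:::pitch_for_stimulus(cfg, stim))
  seqx <- annotate_conditions(oddpred:::new_trial_sequence(cfg, tr))
  role <- seqx$trials$role
  expect_equal(role[1:5], rep("lead_in", 5))
  expect_equal(role[6], "global_standard")
  expect_equal(role[7], "first_deviant")
  expect_equal(role[8], "second_deviant")
  expect_equal(seqx$trials$preceding_rule[8], "rep")
  # standard directly after a Position-2 stimulus is excluded
  expect_equal(role[9], "other_standard")
  expect_equal(role[10:12], rep("global_standard", 3))

  # single deviant: following standard is post2, next one excluded
  stim2 <- c(rep("standard", 6), "deviant_nonrep_rule", rep("standard", 4))
  tr2 <- data.table::copy(tr)[seq_along(stim2)]
  tr2[, stimulus := stim2]
  seq2 <- annotate_conditions(oddpred:::new_trial_sequence(cfg, tr2))
  expect_equal(seq2$trials$role[8], "post2_standard")
  expect_equal(seq2$trials$preceding_rule[8], "nonrep")
  expect_equal(seq2$trials$role[9], "other_standard")

  # all-standard block: everything from index 5 on is global standard
  stim3 <- rep("standard", 12)
  tr3 <- data.table::copy(tr)[, stimulus := stim3]
  seq3 <- annotate_conditions(oddpred:::new_trial_sequence(cfg, tr3))
  expect_true(all(seq3$trials$role[6:12] == "global_standard"))
})

test_that("summarize_counts conserves totals and handles empty input", {
  seqx <- generate_experiment(tiny_design())
  counts <- summarize_counts(seqx)
  expect_equal(sum(counts$n), nrow(seqx$trials))
  empty <- oddpred:::new_trial_sequence(tiny_design(),
                                        seqx$trials[0])
  expect_equal(sum(summarize_counts(empty)$n), 0L)
})
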