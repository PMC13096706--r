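test_that("presses are attributed to the most recent onset within the window", {
  seqx <- generate_block(tiny_design(), 1)
  presses <- data.table::data.table(
    participant = 1L, block = 1L,
    time_ms = c(0 * 800 + 300,      # trial 0 at rt 300
                5 * 800 + 900,      # past trial 5's window: trial 6, rt 100
                10 * 800 + 100, 10 * 800 + 200))  # double press on trial 10
  tab <- attribute_presses(seqx, presses)
  expect_equal(tab[trial_index == 0, rt_ms], 300)
  expect_false(tab[trial_index == 5, press])
  expect_equal(tab[trial_index == 6, rt_ms], 100)
  expect_equal(tab[trial_index == 10, rt_ms], 100)   # first press wins
  expect_equal(attr(tab, "n_unassignable"), 1L)
  expect_true(all(tab[press == TRUE, rt_ms] >= 0 & tab[press == TRUE, rt_ms] < 800))
})

test_that("missed Position-1 deviants exclude their Position-2 rows", {
  p1 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  roles <- rep(c("second_deviant", "post2_standard"), 3)
  tab <- pair_response_table(p1, roles, p2_press = rep(FALSE, 6))
  out <- apply_exclusions(tab)
  expect_equal(attr(out, "n_excluded_p2"), 3L)
  # exactly the pairs with missed P1 lose their second row
  expect_equal(nrow(out), 12 - 3)
  expect_false(any(out$role %in% c("second_deviant", "post2_standard") &
                     c(NA, head(out$press, -1)) == FALSE &
                     c(NA, head(out$role, -1)) == "first_deviant", na.rm = TRUE))
  # nothing excluded when every P1 was hit
  tab2 <- pair_response_table(rep(TRUE, 4), rep("post2_standard", 4),
                              rep(FALSE, 4))
  expect_equal(attr(apply_exclusions(tab2), "n_excluded_p2"), 0L)
})

test_that("hit and false-alarm rates are simple counts after exclusions", {
  tab <- pair_response_table(rep(TRUE, 24), rep("post2_standard", 24),
                             c(rep(TRUE, 3), rep(FALSE, 21)))
  r <- response_rates(apply_exclusions(tab))
  expect_equal(r$hits[position == 1, hit_rate], 1)
  expect_equal(r$fas$fa_rate, 3 / 24)
  # zero denominator flagged as NA, not an error
  empty <- pair_response_table(TRUE, "second_deviant", TRUE)
  r2 <- response_rates(apply_exclusions(empty))
  expect_true(!"nonrep" %in% r2$fas$rule || is.na(r2$fas[rule == "nonrep", fa_rate]))
})

test_that("log-linear correction matches (k + 0.5) / (n + 1) exactly", {
  expect_equal(loglinear_correct(0, 20), 0.5 / 21)
  expect_equal(loglinear_correct(20, 20), 20.5 / 21)
  expect_equal(loglinear_correct(10, 20), 0.5)
  expect_error(loglinear_correct(1, 0), "positive")
  expect_error(loglinear_correct(5, 4), "successes")
})

test_that("d-prime and criterion follow their closed forms", {
  expect_equal(dprime_c(0.7, 0.7)$d_prime, 0)
  expect_equal(dprime_c(0.5, 0.5)$criterion_c, 0)
  r <- dprime_c(0.9286, 0.0714)
  expect_equal(r$d_prime, qnorm(0.9286) - qnorm(0.0714))
  expect_equal(r$d_prime, 2.93, tolerance = 0.01)
  expect_equal(r$criterion_c, 0, tolerance = 0.01)
  # swap symmetry: d' flips sign, c is invariant up to sign rule
  a <- dprime_c(0.8, 0.2); b <- dprime_c(0.2, 0.8)
  expect_equal(a$d_prime, -b$d_prime)
  expect_equal(a$criterion_c, -(-b$criterion_c))
  expect_error(dprime_c(1, 0.5), "strictly")
})

test_that("RT medians use the even-count convention and recover shifts", {
  tab <- pair_response_table(rep(TRUE, 4), rep("second_deviant", 4),
                             rep(TRUE, 4))
  tab[role == "first_deviant", rt_ms := c(100, 200, 300, 400)]
  tab[role == "second_deviant", rt_ms := c(30, 130, 230, 330)]
  r <- rt_summaries(tab)
  expect_equal(r$medians[position == 1, median_rt_ms], 250)  # mean of 200, 300
  expect_equal(r$medians[position == 2, median_rt_ms], 180)
  expect_equal(r$delta21[rule == "rep", delta21_ms], -70)
  # odd count: middle value
  tab3 <- tab[role == "first_deviant"][1:3]
  r3 <- rt_summaries(tab3)
  expect_equal(r3$medians$median_rt_ms, 200)
})

test_that("hits + misses and FAs + correct rejections are conserved", {
  truth <- behaviour_ground_truth()
  bt <- generate_behavioural_task(design_config(seed = 6))
  tab <- apply_exclusions(simulate_behaviour(truth, bt, n_participants = 3,
                                             seed = 2))
  r <- response_rates(tab)
  for (p in 1:3) {
    n_p2 <- r$hits[participant == p & position == 2, sum(n_targets)]
    expect_equal(n_p2, tab[participant == p & role == "second_deviant", .N])
    n_nt <- r$fas[participant == p, sum(n_nontargets)]
    expect_equal(n_nt, tab[participant == p & role == "post2_standard", .N])
  }
})

test_that("SDT estimates recover the generating sensitivity and bias", {
  # direct cell simulation at 1e4 trials per cell
  set.seed(31)
  n <- 10000
  d_true <- 3.5; lambda <- 1.4
  hits <- sum(rnorm(n, d_true, 1) > lambda)
  fas <- sum(rnorm(n) > lambda)
  est <- dprime_c(loglinear_correct(hits, n), loglinear_correct(fas, n))
  expect_lt(abs(est$d_prime - d_true), 0.05)
  expect_lt(abs(est$criterion_c - (lambda - d_true / 2)), 0.05)
  # simulated FA rate matches 1 - pnorm(lambda) within binomial error
  p_fa <- 1 - pnorm(lambda)
  expect_lt(abs(fas / n - p_fa), 3 * sqrt(p_fa * (1 - p_fa) / n))
})

test_that("full pipeline recovers behaviour ground truth end to end", {
  truth <- behaviour_ground_truth()
  bt <- generate_behavioural_task(design_config(seed = 10))
  tab <- apply_exclusions(simulate_behaviour(truth, bt, n_participants = 25,
                                             seed = 9))
  s <- sdt_summary(tab)
  # position-2 d' per rule close to generating values (ceiling-limited cells
  # shrink the estimate slightly; allow 0.3)
  expect_lt(abs(s[rule == "rep", mean(d_prime)] - 3.522), 0.3)
  expect_lt(abs(s[rule == "nonrep", mean(d_prime)] - 3.904), 0.45)
  # criterion ordering: more liberal under the repetition rule
  expect_lt(s[rule == "rep", mean(criterion_c)],
            s[rule == "nonrep", mean(criterion_c)])
  # FA rates track 1 - pnorm(lambda)
  fa_rep <- s[rule == "rep", sum(n_fas) / sum(n_nontargets)]
  expect_lt(abs(fa_rep - (1 - pnorm(1.462))), 0.02)
})

test_that("behaviour simulator honours its trivial limits", {
  truth <- behaviour_ground_truth(
    d_prime = matrix(20, 2, 2, dimnames = list(c("pos1", "pos2"),
                                               c("rep", "nonrep"))),
    lapse_rate = 0)
  bt <- generate_behavioural_task(design_config(seed = 2))
  tab <- simulate_behaviour(truth, bt, n_participants = 1, seed = 3)
  dev <- tab[role %in% c("first_deviant", "second_deviant")]
  expect_equal(mean(dev$press), 1)     # hit rate 1 at infinite sensitivity
  # determinism
  tab2 <- simulate_behaviour(truth, bt, n_participants = 1, seed = 3)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
  # median RT at fixed cell follows exp(a * t^b) within MC error
  truth2 <- behaviour_ground_truth(participant_sd = list(a = 0, b = 0),
                                   lapse_rate = 0)
  tabs <- lapply(1:8, function(s)
    simulate_behaviour(truth2, bt, n_participants = 1, seed = 100 + s))
  big <- data.table::rbindlist(tabs)
  p1 <- big[role == "first_deviant" & press == TRUE & trial_number <= 50]
  med_target <- exp(5.66933 * 25^0.00367)
  expect_lt(abs(median(p1$rt_ms) - med_target) / med_target, 0.05)
})
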