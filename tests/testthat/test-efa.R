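test_that("data matrix assembly gives one row per participant x channel x condition", {
  vals <- list(global_standard = 1, P1_dev_rep = 2)
  mk <- function(k) {
    avgs <- lapply(vals, function(v) list(average = matrix(v + k, 3, 20),
                                          n_epochs = 10))
    structure(list(conditions = avgs, times_ms = seq(-100, 400, length.out = 20),
                   channels = c("FCz", "FC1", "FC2"), rejection_rate = 0,
                   empty_conditions = character(0)), class = "erp_set")
  }
  dm <- build_data_matrix(list(mk(0), mk(1)))
  expect_equal(nrow(dm$values), 2 * 3 * 2)
  expect_equal(ncol(dm$values), 20)
  expect_equal(dm$row_meta$participant, rep(1:2, each = 6))
  # row metadata round trip
  expect_equal(dm$values[dm$row_meta$condition == "P1_dev_rep" &
                           dm$row_meta$participant == 1, 1],
               rep(2, 3))
  bad <- mk(0); bad$times_ms <- bad$times_ms + 1
  expect_error(build_data_matrix(list(mk(0), bad)), "inconsistent")
})

test_that("Empirical Kaiser Criterion behaves on canonical fixtures", {
  # independent standard-normal columns: at most one spurious factor
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(2000 * 20), 2000, 20)
    expect_lte(empirical_kaiser_k(X)$k, 1)
  }
  # one strong common factor
  set.seed(5)
  f <- rnorm(1500)
  X1 <- 0.9 * outer(f, rep(1, 12)) + matrix(rnorm(1500 * 12, 0, sqrt(1 - 0.81)),
                                            1500, 12)
  expect_equal(empirical_kaiser_k(X1)$k, 1L)
  # planted 5-factor structure at n = 5000
  set.seed(6)
  k <- 5; p <- 40
  lam <- matrix(0, p, k)
  for (j in seq_len(k)) lam[((j - 1) * 8 + 1):(j * 8), j] <- 0.85
  F5 <- matrix(rnorm(5000 * k), 5000, k)
  X5 <- F5 %*% t(lam) + matrix(rnorm(5000 * p, 0, 0.5), 5000, p)
  ek <- empirical_kaiser_k(X5)
  expect_equal(ek$k, 5L)
  # eigenvalues of the correlation matrix sum to p
  expect_equal(sum(ek$eigenvalues), p, tolerance = 1e-8)
  # zero-variance column is degenerate
  Xz <- cbind(X1, 0)
  expect_error(empirical_kaiser_k(Xz), "degenerate")
})

test_that("principal-component extraction reproduces the covariance", {
  set.seed(2)
  # rank-1 matrix: first loading recovers the generating vector up to sign
  v <- sin(seq(0, 3, length.out = 25))
  X <- outer(rnorm(300), v)
  ex <- extract_loadings(X, 1)
  cc <- abs(cor(ex$loadings[, 1], v))
  expect_gt(cc, 1 - 1e-10)
  # residual equals the tail eigenvalue sum
  Y <- matrix(rnorm(400 * 12), 400, 12) %*% matrix(rnorm(144), 12)
  exy <- extract_loadings(Y, 4)
  resid <- exy$cov - tcrossprod(exy$loadings)
  expect_equal(sum(diag(resid)), sum(exy$eigenvalues[-(1:4)]),
               tolerance = 1e-8)
  # complete extraction is exact
  exf <- extract_loadings(Y, 12)
  expect_equal(tcrossprod(exf$loadings), exy$cov, tolerance = 1e-8)
  expect_error(extract_loadings(Y, 13), "exceeds")
})

test_that("promax rotation keeps simple structure and preserves fit", {
  # disjoint loading blocks are left invariant up to permutation/sign
  lam <- cbind(c(rep(2, 6), rep(0, 6)), c(rep(0, 6), rep(1.5, 6)))
  sds <- rep(1, 12)
  rot <- promax_rotate(lam, sds, kappa = 3)
  expect_equal(abs(rot$Phi[1, 2]), 0, tolerance = 0.05)
  aligned <- tucker_congruence(lam, rot$unstandardised)
  expect_true(all(aligned > 0.999))
  # kappa = 1 reduces to the varimax pattern
  set.seed(3)
  lam2 <- matrix(rnorm(60), 20, 3)
  vm <- stats::varimax(lam2, normalize = TRUE, eps = 1e-10)
  rot1 <- promax_rotate(lam2, rep(1, 20), kappa = 1)
  expect_equal(abs(rot1$unstandardised), abs(lam2 %*% vm$rotmat),
               tolerance = 1e-6)
  # k = 1 passthrough
  r1 <- promax_rotate(lam[, 1, drop = FALSE], sds)
  expect_equal(r1$unstandardised, lam[, 1, drop = FALSE])
  expect_equal(r1$Phi, matrix(1, 1, 1))
})

test_that("rotation leaves the reproduced covariance unchanged", {
  st <- simulate_erp_study(coverage_truth(),
                           noise_spec(temporal_ar1_phi = 0, epoch_noise_sd = 8,
                                      spatial_rho = 0, seed = 5),
                           n_participants = 12,
                           n_trials_per_condition = equal_trials())
  dm <- build_data_matrix(st)
  ex <- extract_loadings(dm, 5)
  rot <- promax_rotate(ex$loadings, dm$col_sds, kappa = 3)
  before <- tcrossprod(ex$loadings)
  after <- rot$unstandardised %*% rot$Phi %*% t(rot$unstandardised)
  expect_lt(max(abs(after - before)), 1e-8)
})

test_that("regression factor scores recover generating amplitudes", {
  # noiseless one-factor data: scores correlate perfectly with truth
  set.seed(8)
  v <- exp(-0.5 * ((1:30 - 12) / 4)^2)
  amps <- rnorm(250, 2, 1)
  X <- outer(amps, v)
  suppressWarnings({
    ex <- extract_loadings(X, 1)
    rot <- promax_rotate(ex$loadings, apply(X, 2, sd))
    sc <- oddpred:::factor_scores_internal(X, ex$cov, rot$unstandardised,
                                           rot$Phi)$scores
  })
  expect_gt(abs(cor(sc[, 1], amps)), 1 - 1e-8)
  # score covariance approximates Phi under the model (planted oblique data)
  st <- simulate_erp_study(coverage_truth(),
                           noise_spec(temporal_ar1_phi = 0, epoch_noise_sd = 4,
                                      spatial_rho = 0, seed = 9),
                           n_participants = 12,
                           n_trials_per_condition = equal_trials())
  dm <- build_data_matrix(st)
  sol <- fit_temporal_efa(dm, k = 5)
  sc_cov <- cov(sol$scores)
  sc_cor <- stats::cov2cor(sc_cov)
  expect_lt(max(abs(sc_cor - sol$Phi)), 0.15)
})

test_that("reconstruction is complete and factor-wise", {
  # noiseless k-factor data reconstructed exactly (coverage truth keeps all
  # column SDs bounded away from zero, as the data-matrix contract requires)
  st <- simulate_erp_study(coverage_truth(),
                           noise_spec(epoch_noise_sd = 0, seed = 2),
                           n_participants = 4)
  dm <- build_data_matrix(st)
  suppressWarnings(sol <- fit_temporal_efa(dm, k = 5))
  est <- reconstruct(sol)
  expect_lt(max(abs(est - dm$values)), 1e-6)
  # single factor gives a rank-1 contribution
  one <- reconstruct(sol, factor_subset = 1, add_mean = FALSE)
  expect_equal(qr(one)$rank, 1L)
  # k = p reconstruction exact on arbitrary data
  set.seed(4)
  Y <- matrix(rnorm(200 * 10), 200, 10)
  exy <- extract_loadings(Y, 10)
  roty <- promax_rotate(exy$loadings, apply(Y, 2, sd))
  scy <- oddpred:::factor_scores_internal(Y, exy$cov, roty$unstandardised,
                                          roty$Phi)$scores
  Yhat <- scy %*% t(roty$unstandardised)
  expect_lt(max(abs(Yhat - scale(Y, scale = FALSE))), 1e-6)
})

test_that("planted five-factor studies are recovered (EKC count and loadings)", {
  st <- simulate_erp_study(coverage_truth(),
                           noise_spec(temporal_ar1_phi = 0, epoch_noise_sd = 8,
                                      spatial_rho = 0, seed = 5),
                           n_participants = 30,
                           n_trials_per_condition = equal_trials())
  dm <- build_data_matrix(st)
  expect_equal(empirical_kaiser_k(dm)$k, 5L)
  sol <- fit_temporal_efa(dm)
  truth_curves <- coverage_truth()$loading_curves[
    coverage_truth()$times_ms <= 400 + 1e-9, ]
  cong <- tucker_congruence(truth_curves, sol$unstandardised_loadings)
  expect_true(all(cong >= 0.95))
  # canonical narrow-bump truth: loadings also recovered at k = 5
  st2 <- simulate_erp_study(factor_ground_truth(),
                            noise_spec(temporal_ar1_phi = 0, epoch_noise_sd = 8,
                                       seed = 11),
                            n_participants = 30)
  dm2 <- build_data_matrix(st2)
  sol2 <- fit_temporal_efa(dm2, k = 5)
  tc2 <- tucker_congruence(
    factor_ground_truth()$loading_curves[factor_ground_truth()$times_ms <=
                                           400 + 1e-9, ],
    sol2$unstandardised_loadings)
  expect_true(all(tc2 >= 0.95))
})

test_that("EKC count drops from clean recovery to pure noise", {
  ks <- sapply(c(2, 8, 400), function(sdv) {
    st <- simulate_erp_study(coverage_truth(),
                             noise_spec(temporal_ar1_phi = 0,
                                        epoch_noise_sd = sdv,
                                        spatial_rho = 0, seed = 5),
                             n_participants = 12,
                             n_trials_per_condition = equal_trials())
    empirical_kaiser_k(build_data_matrix(st))$k
  })
  expect_equal(ks[1], 5L)
  expect_equal(ks[2], 5L)
  expect_lt(ks[3], 5L)
})

test_that("peak amplitudes equal ROI-mean score times peak loading", {
  st <- simulate_erp_study(factor_ground_truth(),
                           noise_spec(epoch_noise_sd = 2, seed = 3),
                           n_participants = 3)
  dm <- build_data_matrix(st)
  sol <- fit_temporal_efa(dm, k = 5)
  pk <- peak_amplitude(sol, 1, "global_standard", 2)
  lam <- sol$unstandardised_loadings[, 1]
  peak <- which.max(abs(lam))
  rows <- which(sol$row_meta$participant == 2 &
                  sol$row_meta$condition == "global_standard" &
                  sol$row_meta$channel %in% c("FCz", "FC1", "FC2", "Fz"))
  expect_equal(pk, mean(sol$scores[rows, 1]) * lam[peak])
  # hand rule: score 2, peak loading 0.5 -> 1.0 microvolt
  sol2 <- sol
  sol2$scores[rows, 1] <- 2
  sol2$unstandardised_loadings[, 1] <- 0.5 * lam / max(abs(lam))
  expect_equal(peak_amplitude(sol2, 1, "global_standard", 2), 1.0)
  # zero score -> 0
  sol2$scores[rows, 1] <- 0
  expect_equal(peak_amplitude(sol2, 1, "global_standard", 2), 0)
})

test_that("contrast table implements violation minus confirmation", {
  # synthetic peak table with a planted +1 violation effect on P2 deviants
  conds <- erp_conditions()
  peaks <- data.table::CJ(participant = 1:2, condition = conds, factor = 1L)
  peaks[, peak_uv := 0]
  peaks[condition == "P2_dev_nonrep", peak_uv := 1]    # violation
  ct <- contrast_table(peaks)
  expect_equal(ct$p2_dev_viol_minus_conf, c(1, 1))
  expect_equal(ct$p2_std_viol_minus_conf, c(0, 0))
  # identical conditions give all-zero contrasts
  peaks0 <- data.table::copy(peaks)[, peak_uv := 3]
  ct0 <- contrast_table(peaks0)
  expect_true(all(ct0$mmn_rep == 0 & ct0$p2_dev_viol_minus_conf == 0))
  # hand computation on a 2-participant fixture
  peaks2 <- data.table::copy(peaks)
  peaks2[participant == 1 & condition == "P1_dev_rep", peak_uv := -2]
  peaks2[participant == 1 & condition == "global_standard", peak_uv := -0.5]
  peaks2[participant == 1 & condition == "P2_std_after_rep", peak_uv := 1.2]
  peaks2[participant == 1 & condition == "P2_std_after_nonrep", peak_uv := 0.2]
  ct2 <- contrast_table(peaks2)
  expect_equal(ct2[participant == 1, mmn_rep], -1.5)
  expect_equal(ct2[participant == 1, p2_std_viol_minus_conf], 1.0)
  expect_error(contrast_table(peaks[condition != "global_standard"]),
               "missing condition")
})
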