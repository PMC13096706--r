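#' Ground-truth temporal factor structure for simulated ERP studies
#'
#' The generator emulates epoched ERP data whose signal is a known low-rank
#' temporal factor model: each factor has a loading time course (a Gaussian
#' bump, in microvolt per unit score), a channel topography, and per-condition
#' mean scores. The default five factors mimic the canonical auditory
#' components in an oddball study (N1-like at 105 ms, P2a-like at 145 ms,
#' P2b-like at 191 ms, early-P3a-like at 246 ms, late-P3a-like at 289 ms;
#' bump SD 25 ms), and the default condition score means place the
#' frontocentral region-of-interest (ROI) peak amplitudes at published
#' estimates for the seven averaging conditions.
#'
#' @param latencies_ms Peak latencies of the factor loading curves.
#' @param widths_ms Gaussian SD of each loading curve (recycled).
#' @param peak_uv Loading value at the peak, microvolt per unit score
#'   (recycled; default 1 so scores are read directly in microvolt).
#' @param channels Channel names; must include the ROI channels FCz, FC1,
#'   FC2, Fz and the mastoids M1, M2.
#' @param roi_weight,scalp_weight,mastoid_weight Topography weights for ROI
#'   channels, remaining scalp channels, and mastoids (the negative default
#'   mimics the polarity inversion of frontocentral components).
#' @param condition_score_means Conditions x factors matrix of mean scores;
#'   default derived from published frontocentral peak-amplitude estimates.
#' @param participant_score_sd Per-factor between-participant SD of scores.
#' @param sampling_rate_hz Sampling rate (default 512).
#' @param epoch_window_ms Epoch limits in ms (default c(-100, 700)).
#' @return An object of class `factor_ground_truth` with elements
#'   `times_ms`, `loading_curves` (time x k), `topographies` (channels x k),
#'   `condition_score_means`, `participant_score_sd`, `channels`,
#'   `conditions`.
#' @export
factor_ground_truth <- function(latencies_ms = c(105, 145, 191, 246, 289),
                                widths_ms = 25,
                                peak_uv = 1,
                                channels = default_channels(),
                                roi_weight = 1,
                                scalp_weight = 0.5,
                                mastoid_weight = -0.3,
                                condition_score_means = default_condition_means(),
                                participant_score_sd = default_participant_sd(),
                                sampling_rate_hz = 512,
                                epoch_window_ms = c(-100, 700)) {
  k <- length(latencies_ms)
  stopifnot(k >= 1)
  widths_ms <- rep_len(widths_ms, k)
  peak_uv <- rep_len(peak_uv, k)
  times <- time_grid(epoch_window_ms, sampling_rate_hz)
  curves <- vapply(seq_len(k), function(f) {
    peak_uv[f] * exp(-0.5 * ((times - latencies_ms[f]) / widths_ms[f])^2)
  }, numeric(length(times)))
  colnames(curves) <- paste0("F", seq_len(k))
  stopifnot(all(is.finite(curves)))

  roi <- c("FCz", "FC1", "FC2", "Fz")
  mast <- c("M1", "M2")
  if (!all(c(roi, mast) %in% channels))
    stop("channels must include the ROI channels (", paste(roi, collapse = ", "),
         ") and mastoids (M1, M2)")
  topo <- matrix(scalp_weight, nrow = length(channels), ncol = k,
                 dimnames = list(channels, colnames(curves)))
  topo[roi, ] <- roi_weight
  topo[mast, ] <- mastoid_weight

  cm <- as.matrix(condition_score_means)
  if (ncol(cm) != k)
    stop("condition_score_means must have one column per factor (k = ", k, ")")
  participant_score_sd <- rep_len(participant_score_sd, k)

  structure(list(
    times_ms = times,
    loading_curves = curves,
    topographies = topo,
    condition_score_means = cm,
    participant_score_sd = participant_score_sd,
    channels = channels,
    conditions = rownames(cm),
    sampling_rate_hz = sampling_rate_hz,
    epoch_window_ms = epoch_window_ms,
    latencies_ms = latencies_ms
  ), class = "factor_ground_truth")
}

default_channels <- function() {
  c("Fz", "F3", "F4", "FCz", "FC1", "FC2", "Cz", "C3", "C4",
    "Pz", "P3", "P4", "Oz", "T7", "T8", "M1", "M2")
}

#' The seven averaging conditions of the conditional-oddball design
#' @return Character vector of condition labels.
#' @export
erp_conditions <- function() {
  c("global_standard",
    "P1_dev_rep", "P1_dev_nonrep",
    "P2_dev_rep", "P2_dev_nonrep",
    "P2_std_after_rep", "P2_std_after_nonrep")
}

# Frontocentral ROI peak-amplitude means (microvolt) per condition and
# factor used as default generating scores; "rep" denotes the deviant with
# the high (0.8) repetition probability.
default_condition_means <- function() {
  m <- rbind(
    global_standard      = c(0.078,  2.336, 1.207, -0.513, -0.704),
    P1_dev_rep           = c(-1.013, 0.535, 0.855,  0.624, -0.167),
    P1_dev_nonrep        = c(-1.163, 0.491, 0.761,  0.672, -0.195),
    P2_dev_rep           = c(-0.755, 0.784, 0.352, -0.681, -0.599),
    P2_dev_nonrep        = c(-0.902, 0.413, 0.008, -0.579, -0.569),
    P2_std_after_rep     = c(0.059,  2.147, 1.565,  0.082, -0.489),
    P2_std_after_nonrep  = c(0.143,  2.078, 1.255, -0.147, -0.403)
  )
  colnames(m) <- c("F1_N1", "F2_P2a", "F3_P2b", "F4_P3a_early", "F5_P3a_late")
  m
}

# between-participant score SDs: global-standard SEs scaled by sqrt(60)
default_participant_sd <- function() {
  c(0.148, 0.197, 0.144, 0.135, 0.067) * sqrt(60)
}

time_grid <- function(window_ms, fs) {
  step <- 1000 / fs
  n <- floor((window_ms[2] - window_ms[1]) / step)
  window_ms[1] + step * (0:n)
}

#' Noise specification for simulated epochs
#'
#' Additive noise is an AR(1) process over time samples (stationary marginal
#' SD `epoch_noise_sd`), mixed across channels through a correlation matrix.
#'
#' @param temporal_ar1_phi AR(1) coefficient in `[0, 1)`.
#' @param epoch_noise_sd Single-epoch noise SD in microvolt.
#' @param spatial_mixing Channel correlation matrix, or `NULL` for an
#'   exchangeable correlation of `spatial_rho`.
#' @param spatial_rho Exchangeable channel correlation used when
#'   `spatial_mixing` is `NULL` (default 0.3).
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(temporal_ar1_phi = 0.3, epoch_noise_sd = 10,
                       spatial_mixing = NULL, spatial_rho = 0.3, seed = 1L) {
  if (temporal_ar1_phi < 0 || temporal_ar1_phi >= 1)
    stop("temporal_ar1_phi must be in [0, 1)")
  if (epoch_noise_sd < 0) stop("epoch_noise_sd must be >= 0")
  if (!is.null(spatial_mixing)) {
    sm <- as.matrix(spatial_mixing)
    if (!isSymmetric(sm) || any(abs(diag(sm) - 1) > 1e-8))
      stop("spatial_mixing must be a correlation matrix (symmetric, unit diagonal)")
    ev <- eigen(sm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("spatial_mixing must be positive semidefinite")
  }
  structure(list(temporal_ar1_phi = temporal_ar1_phi,
                 epoch_noise_sd = epoch_noise_sd,
                 spatial_mixing = spatial_mixing,
                 spatial_rho = spatial_rho,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

spatial_chol <- function(noise, n_channels) {
  R <- if (!is.null(noise$spatial_mixing)) {
    as.matrix(noise$spatial_mixing)
  } else {
    r <- noise$spatial_rho
    m <- matrix(r, n_channels, n_channels); diag(m) <- 1; m
  }
  if (nrow(R) != n_channels)
    stop("spatial_mixing dimension (", nrow(R),
         ") does not match channel count (", n_channels, ")")
  # tiny jitter guards exact semidefiniteness
  t(chol(R + diag(1e-10, n_channels)))
}

# channels x time AR(1) noise, spatially mixed; sd = stationary marginal SD
ar1_noise <- function(n_channels, n_time, phi, sd, L) {
  if (sd == 0) return(matrix(0, n_channels, n_time))
  w <- matrix(rnorm(n_channels * n_time), n_channels, n_time)
  if (phi > 0) {
    x <- w
    x[, 1] <- w[, 1]
    fac <- sqrt(1 - phi^2)
    for (t in 2:n_time) x[, t] <- phi * x[, t - 1] + fac * w[, t]
    w <- x
  }
  sd * (L %*% w)
}

#' Simulate a multi-participant ERP study with known factor structure
#'
#' For every participant and condition the noiseless signal is
#' `sum_f topography_f (x) loading_curve_f * score_f`, where the score is
#' drawn once per participant from
#' `Normal(condition mean, participant SD)`. Condition averages carry AR(1)
#' noise scaled by `1/sqrt(n_trials)` for that condition, which is
#' distributionally equal to averaging independent single-epoch noise.
#'
#' @param truth A [factor_ground_truth()].
#' @param noise A [noise_spec()].
#' @param n_participants Number of participants.
#' @param n_trials_per_condition Named vector of per-condition epoch counts
#'   entering each average (defaults mirror the session design arithmetic).
#' @param seed Integer seed (defaults to `noise$seed`).
#' @return A `simulated_erp_study`: list with `averages` (participants x
#'   conditions x channels x time array), `scores` (participants x
#'   conditions x factors ground-truth scores), `truth`, `noise`.
#' @export
simulate_erp_study <- function(truth, noise = noise_spec(),
                               n_participants = 60,
                               n_trials_per_condition = NULL,
                               seed = NULL) {
  seed <- seed %||% noise$seed
  set.seed(seed)
  conds <- truth$conditions
  if (is.null(n_trials_per_condition)) {
    n_trials_per_condition <- c(
      global_standard = 4000, P1_dev_rep = 600, P1_dev_nonrep = 600,
      P2_dev_rep = 480, P2_dev_nonrep = 120,
      P2_std_after_rep = 120, P2_std_after_nonrep = 480
    )[conds]
    n_trials_per_condition[is.na(n_trials_per_condition)] <- 500
  }
  n_trials_per_condition <- rep_len(n_trials_per_condition, length(conds))
  nt <- length(truth$times_ms)
  nc <- length(truth$channels)
  k <- ncol(truth$loading_curves)
  L <- spatial_chol(noise, nc)

  averages <- array(NA_real_,
                    dim = c(n_participants, length(conds), nc, nt),
                    dimnames = list(NULL, conds, truth$channels, NULL))
  scores <- array(NA_real_, dim = c(n_participants, length(conds), k),
                  dimnames = list(NULL, conds, colnames(truth$loading_curves)))
  for (p in seq_len(n_participants)) {
    for (ci in seq_along(conds)) {
      sc <- rnorm(k, truth$condition_score_means[ci, ],
                  truth$participant_score_sd)
      scores[p, ci, ] <- sc
      sig <- truth$topographies %*% (t(truth$loading_curves) * sc)
      eff_sd <- noise$epoch_noise_sd / sqrt(n_trials_per_condition[ci])
      averages[p, ci, , ] <- sig +
        ar1_noise(nc, nt, noise$temporal_ar1_phi, eff_sd, L)
    }
  }
  structure(list(averages = averages, scores = scores, truth = truth,
                 noise = noise, n_trials_per_condition = n_trials_per_condition,
                 seed = seed),
            class = "simulated_erp_study")
}

#' @export
print.simulated_erp_study <- function(x, ...) {
  d <- dim(x$averages)
  cat(sprintf("<simulated_erp_study> %d participants x %d conditions x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate a single participant's epochs for an annotated trial sequence
#'
#' Builds an [epoch_set()] whose signal follows the participant's
#' ground-truth condition scores; trials outside the seven averaging
#' conditions (lead-in and other standards) carry the global-standard
#' signal. Used to exercise the epoch-level pipeline end to end.
#'
#' @inheritParams simulate_erp_study
#' @param seq An annotated `trial_sequence`.
#' @param participant_scores Optional conditions x factors score matrix; by
#'   default drawn from the truth.
#' @param seed Integer seed.
#' @return An `epoch_set`.
#' @export
simulate_epoch_set <- function(truth, noise, seq, participant_scores = NULL,
                               seed = 1L) {
  set.seed(seed)
  conds <- truth$conditions
  k <- ncol(truth$loading_curves)
  if (is.null(participant_scores)) {
    participant_scores <- truth$condition_score_means +
      matrix(rnorm(length(conds) * k, 0, rep(truth$participant_score_sd,
                                             each = length(conds))),
             length(conds), k)
    dimnames(participant_scores) <- dimnames(truth$condition_score_means)
  }
  meta <- data.table::copy(seq$trials)
  meta[, condition := condition_label(role, preceding_rule, stimulus)]
  nc <- length(truth$channels); nt <- length(truth$times_ms)
  L <- spatial_chol(noise, nc)
  sig_by_cond <- lapply(seq_along(conds), function(ci) {
    truth$topographies %*% (t(truth$loading_curves) * participant_scores[ci, ])
  })
  names(sig_by_cond) <- conds
  dat <- array(NA_real_, dim = c(nrow(meta), nc, nt))
  for (i in seq_len(nrow(meta))) {
    cond <- meta$condition[i]
    sig <- if (!is.na(cond)) sig_by_cond[[cond]] else sig_by_cond[["global_standard"]]
    dat[i, , ] <- sig + ar1_noise(nc, nt, noise$temporal_ar1_phi,
                                  noise$epoch_noise_sd, L)
  }
  epoch_set(dat, truth$times_ms, truth$channels, meta)
}

# map role/rule/stimulus to the seven averaging conditions (NA otherwise)
condition_label <- function(role, preceding_rule, stimulus) {
  out <- rep(NA_character_, length(role))
  out[role == "global_standard"] <- "global_standard"
  out[role == "first_deviant" & stimulus == "deviant_rep_rule"] <- "P1_dev_rep"
  out[role == "first_deviant" & stimulus == "deviant_nonrep_rule"] <- "P1_dev_nonrep"
  out[role == "second_deviant" & preceding_rule == "rep"] <- "P2_dev_rep"
  out[role == "second_deviant" & preceding_rule == "nonrep"] <- "P2_dev_nonrep"
  out[role == "post2_standard" & preceding_rule == "rep"] <- "P2_std_after_rep"
  out[role == "post2_standard" & preceding_rule == "nonrep"] <- "P2_std_after_nonrep"
  out
}
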