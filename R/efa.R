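#' Assemble the temporal-EFA data matrix
#'
#' Time samples are the variables (columns); the observations (rows) are the
#' participant x channel x condition averages, so a factor's loading curve
#' is shared across channels, conditions and participants while its score
#' varies per observation.
#'
#' @param erpsets A list of per-participant `erp_set` objects (consistent
#'   time grids and channel sets), or a `simulated_erp_study`.
#' @param window Time window in ms retained for analysis
#'   (default `c(-100, 400)`).
#' @return A `data_matrix`: list with `values` (rows x time samples),
#'   `row_meta` (`participant`, `channel`, `condition`), `times_ms`,
#'   `col_means`, `col_sds`.
#' @export
build_data_matrix <- function(erpsets, window = c(-100, 400)) {
  if (inherits(erpsets, "simulated_erp_study"))
    erpsets <- lapply(seq_len(dim(erpsets$averages)[1]),
                      function(p) as_erp_set(erpsets, p))
  stopifnot(length(erpsets) >= 1L)
  t0 <- erpsets[[1]]$times_ms; ch0 <- erpsets[[1]]$channels
  for (e in erpsets) {
    if (!isTRUE(all.equal(e$times_ms, t0)) || !identical(e$channels, ch0))
      stop("inconsistent time grids or channel sets across participants")
  }
  rows <- list(); meta <- list(); r <- 0L
  idx <- which(t0 >= window[1] - 1e-9 & t0 <= window[2] + 1e-9)
  for (p in seq_along(erpsets)) {
    for (cond in names(erpsets[[p]]$conditions)) {
      avg <- erpsets[[p]]$conditions[[cond]]$average
      for (ci in seq_along(ch0)) {
        r <- r + 1L
        rows[[r]] <- avg[ci, idx]
        meta[[r]] <- data.table::data.table(participant = p,
                                            channel = ch0[ci],
                                            condition = cond)
      }
    }
  }
  values <- do.call(rbind, rows)
  if (nrow(values) < 2L) stop("data matrix needs at least 2 rows")
  structure(list(values = values,
                 row_meta = data.table::rbindlist(meta),
                 times_ms = t0[idx],
                 col_means = colMeans(values),
                 col_sds = apply(values, 2, sd)),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d observations x %d time samples [%g, %g] ms\n",
              nrow(x$values), ncol(x$values), min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Empirical Kaiser Criterion for the number of factors
#'
#' Computed on the correlation matrix: with `p` columns and `n` rows the
#' reference eigenvalue for position `j` is
#' `max(((p - sum(l[1..j-1])) / (p - j + 1)) * (1 + sqrt(p/n))^2, 1)`
#' and factors are retained sequentially while the sample eigenvalue
#' exceeds its reference.
#'
#' @param matrix A `data_matrix` (or a plain numeric matrix).
#' @return An `ekc_result`: list with `eigenvalues`, `reference_values`,
#'   `k`.
#' @export
empirical_kaiser_k <- function(matrix) {
  X <- if (inherits(matrix, "data_matrix")) matrix$values else as.matrix(matrix)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need more than one row")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("degenerate correlation matrix: zero-variance column")
  l <- eigen(cor(X), symmetric = TRUE, only.values = TRUE)$values
  if (any(!is.finite(l))) stop("degenerate correlation matrix")
  inflate <- (1 + sqrt(p / n))^2
  ref <- numeric(p); cum <- 0
  for (j in seq_len(p)) {
    ref[j] <- max((p - cum) / (p - j + 1) * inflate, 1)
    cum <- cum + l[j]
  }
  k <- 0L
  for (j in seq_len(p)) {
    if (l[j] > ref[j]) k <- j else break
  }
  structure(list(eigenvalues = l, reference_values = ref, k = k),
            class = "ekc_result")
}

#' @export
print.ekc_result <- function(x, ...) {
  cat(sprintf("<ekc_result> k = %d retained factors (first eigenvalues: %s)\n",
              x$k, paste(signif(head(x$eigenvalues, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Extract unrotated loadings from the covariance matrix
#'
#' Principal-component extraction: the loading matrix holds the top-`k`
#' eigenvectors of the column covariance matrix scaled by the square root of
#' their eigenvalues, so `Lambda %*% t(Lambda)` reproduces the covariance up
#' to the discarded tail.
#'
#' @param matrix A `data_matrix` or plain matrix.
#' @param k Number of factors, `1 <= k <= p`.
#' @return List with `loadings` (p x k, microvolt-scaled), `eigenvalues`
#'   (all p), `cov` (the covariance matrix).
#' @export
extract_loadings <- function(matrix, k) {
  X <- if (inherits(matrix, "data_matrix")) matrix$values else as.matrix(matrix)
  p <- ncol(X)
  k <- assert_count(k, "k", 1L)
  if (k > p) stop("k (", k, ") exceeds the number of columns (", p, ")")
  S <- cov(X)
  e <- eigen(S, symmetric = TRUE)
  if (k > sum(e$values > 1e-12 * max(e$values)))
    stop("k exceeds the numerical rank of the covariance matrix")
  lam <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  colnames(lam) <- paste0("F", seq_len(k))
  list(loadings = lam, eigenvalues = e$values, cov = S)
}

#' Promax rotation with standardisation during rotation only
#'
#' The unrotated microvolt-scale loadings are divided by the column SDs,
#' Kaiser-normalised varimax is applied, the varimax pattern is raised
#' elementwise to the power `kappa` (sign preserved) to form the target, and
#' an oblique least-squares target rotation yields the pattern and the
#' factor correlation matrix `Phi`. The pattern is then rescaled by the
#' column SDs to give unstandardised (microvolt) loadings.
#'
#' @param unrotated p x k unrotated loading matrix (microvolt scale).
#' @param column_sds Column SDs used for standardisation (length p).
#' @param kappa Promax power (default 3).
#' @return List with `rotated_standardised`, `unstandardised`, `Phi`,
#'   `varimax_rotation`; for `k = 1` the input is returned unchanged with
#'   `Phi = 1`.
#' @export
promax_rotate <- function(unrotated, column_sds, kappa = 3) {
  lam <- as.matrix(unrotated)
  k <- ncol(lam)
  if (k < 1L) stop("need at least one factor")
  std <- lam / column_sds
  if (k == 1L) {
    return(list(rotated_standardised = std, unstandardised = lam,
                Phi = matrix(1, 1, 1), varimax_rotation = matrix(1, 1, 1)))
  }
  vm <- stats::varimax(std, normalize = TRUE, eps = 1e-10)
  B <- std %*% vm$rotmat
  Q <- sign(B) * abs(B)^kappa
  U <- solve(crossprod(B), crossprod(B, Q))
  d <- diag(solve(crossprod(U)))
  U <- U %*% diag(sqrt(d), k)
  P <- B %*% U                      # standardised pattern
  Ui <- solve(U)
  Phi <- Ui %*% t(Ui)               # factor correlations
  Phi <- (Phi + t(Phi)) / 2
  dimnames(Phi) <- list(colnames(lam), colnames(lam))
  colnames(P) <- colnames(lam)
  list(rotated_standardised = P,
       unstandardised = P * column_sds,
       Phi = Phi,
       varimax_rotation = vm$rotmat %*% U)
}

#' Fit the full temporal EFA
#'
#' Convenience wrapper: extraction, Promax rotation, score estimation,
#' explained-variance ordering, sign fixing (peak unstandardised loading
#' positive) and peak metadata.
#'
#' @param matrix A `data_matrix`.
#' @param k Number of factors; default chosen by [empirical_kaiser_k()].
#' @param kappa Promax power (default 3).
#' @return A `factor_solution` with elements `unrotated_loadings`,
#'   `rotated_standardised_loadings`, `unstandardised_loadings`, `Phi`,
#'   `scores`, `explained_variance`, `peak_latency_ms`, `peak_loading`,
#'   `polarity`, `times_ms`, `row_meta`, `k`.
#' @export
fit_temporal_efa <- function(matrix, k = NULL, kappa = 3) {
  stopifnot(inherits(matrix, "data_matrix"))
  if (is.null(k)) k <- empirical_kaiser_k(matrix)$k
  if (k < 1L) stop("no factors retained (k = 0); supply k explicitly")
  ex <- extract_loadings(matrix, k)
  rot <- promax_rotate(ex$loadings, matrix$col_sds, kappa)
  lam <- rot$unstandardised
  Phi <- rot$Phi

  sc <- factor_scores_internal(matrix$values, ex$cov, lam, Phi)

  # order factors by explained variance of their factor-wise contribution
  ev <- vapply(seq_len(k), function(f) {
    sum((tcrossprod(sc$scores[, f], lam[, f]))^2)
  }, numeric(1))
  ord <- order(ev, decreasing = TRUE)
  lam <- lam[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  scores <- sc$scores[, ord, drop = FALSE]
  rot$rotated_standardised <- rot$rotated_standardised[, ord, drop = FALSE]
  ev <- ev[ord]

  # sign convention: loading at the absolute peak is positive
  peak_idx <- apply(abs(lam), 2, which.max)
  flip <- vapply(seq_len(k), function(f) sign(lam[peak_idx[f], f]), numeric(1))
  flip[flip == 0] <- 1
  lam <- sweep(lam, 2, flip, `*`)
  rot$rotated_standardised <- sweep(rot$rotated_standardised, 2, flip, `*`)
  scores <- sweep(scores, 2, flip, `*`)
  Phi <- diag(flip) %*% Phi %*% diag(flip)
  dimnames(Phi) <- list(paste0("F", seq_len(k)), paste0("F", seq_len(k)))
  colnames(lam) <- colnames(scores) <- paste0("F", seq_len(k))

  # polarity of the underlying component: sign of the mean score-weighted
  # deflection (positive peak loading with mostly negative scores = negative
  # component)
  polarity <- vapply(seq_len(k), function(f) {
    m <- mean(scores[, f]) * lam[peak_idx[f], f]
    if (m >= 0) "positive" else "negative"
  }, character(1))

  structure(list(
    unrotated_loadings = ex$loadings,
    rotated_standardised_loadings = rot$rotated_standardised,
    unstandardised_loadings = lam,
    Phi = Phi,
    scores = scores,
    explained_variance = ev,
    peak_latency_ms = matrix$times_ms[peak_idx],
    peak_loading = lam[cbind(peak_idx, seq_len(k))],
    polarity = polarity,
    times_ms = matrix$times_ms,
    row_meta = matrix$row_meta,
    col_sds = matrix$col_sds,
    col_means = matrix$col_means,
    cov = ex$cov,
    k = k,
    kappa = kappa
  ), class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor_solution> k = %d factors (kappa = %g)\n", x$k, x$kappa))
  cat("  peak latencies (ms):", paste(round(x$peak_latency_ms), collapse = ", "), "\n")
  invisible(x)
}

# Thurstone regression scores, oblique form: W = Sigma^-1 Lambda Phi.
# Near-singular Sigma gets a ridge of eps = 1e-8 * trace(Sigma)/p.
factor_scores_internal <- function(X, Sigma, lambda, Phi) {
  p <- ncol(Sigma)
  Xc <- sweep(X, 2, colMeans(X))
  struct <- lambda %*% Phi          # structure matrix
  W <- tryCatch(solve(Sigma, struct), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(W) || !all(is.finite(W)) ||
      rcond_est(Sigma) < 1e-12) {
    eps <- 1e-8 * sum(diag(Sigma)) / p
    W <- solve(Sigma + diag(eps, p), struct)
    ridged <- TRUE
    warning("near-singular covariance; ridge fallback applied (eps = ",
            signif(eps, 3), ")")
  }
  list(scores = Xc %*% W, ridged = ridged)
}

rcond_est <- function(S) {
  ev <- range(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  if (ev[2] == 0) 0 else ev[1] / ev[2]
}

#' Estimate factor scores for a fitted solution
#'
#' Regression (Thurstone) estimator in its oblique form:
#' `scores = centred data %*% solve(Sigma) %*% Lambda %*% Phi`.
#'
#' @param matrix The `data_matrix` the solution was fitted on (or new data
#'   on the same grid).
#' @param solution A `factor_solution`.
#' @return Rows x k score matrix.
#' @export
factor_scores <- function(matrix, solution) {
  stopifnot(inherits(solution, "factor_solution"))
  X <- if (inherits(matrix, "data_matrix")) matrix$values else as.matrix(matrix)
  factor_scores_internal(X, solution$cov, solution$unstandardised_loadings,
                         solution$Phi)$scores
}

#' Factor-wise reconstruction in microvolt
#'
#' The contribution of factor `f` to row `i` is
#' `scores[i, f] * unstandardised_loadings[, f]`; the estimated ERP is the
#' sum over the retained factors (plus the column means removed during
#' scoring when `add_mean = TRUE`).
#'
#' @param solution A `factor_solution`.
#' @param factor_subset Factors to include (default all).
#' @param row_subset Rows to reconstruct (default all).
#' @param add_mean Add back the column means (default `TRUE` for the full
#'   estimated ERP; factor-wise contributions are usually examined with
#'   `FALSE`).
#' @return Rows x time matrix of microvolt waveforms.
#' @export
reconstruct <- function(solution, factor_subset = NULL, row_subset = NULL,
                        add_mean = TRUE) {
  stopifnot(inherits(solution, "factor_solution"))
  fs <- factor_subset %||% seq_len(solution$k)
  rs <- row_subset %||% seq_len(nrow(solution$scores))
  out <- solution$scores[rs, fs, drop = FALSE] %*%
    t(solution$unstandardised_loadings[, fs, drop = FALSE])
  if (add_mean) out <- sweep(out, 2, solution$col_means, `+`)
  out
}

#' Estimated peak amplitude of a factor-wise reconstructed ERP
#'
#' The factor's contribution is read at its peak-loading latency (argmax of
#' the absolute unstandardised loading, fixed across conditions) and
#' averaged over the ROI rows of the requested participant and condition;
#' this equals (ROI-mean score) x (loading at the peak).
#'
#' @param solution A `factor_solution`.
#' @param factor Factor index.
#' @param condition Condition label.
#' @param participant Participant id as in the row metadata.
#' @param roi ROI channels (default FCz, FC1, FC2, Fz).
#' @param at_extremum If `TRUE`, read the extremum of the reconstructed
#'   factor waveform per observation instead of the fixed peak-loading
#'   latency.
#' @return Peak amplitude in microvolt.
#' @export
peak_amplitude <- function(solution, factor, condition, participant,
                           roi = c("FCz", "FC1", "FC2", "Fz"),
                           at_extremum = FALSE) {
  stopifnot(inherits(solution, "factor_solution"),
            factor >= 1, factor <= solution$k)
  meta <- solution$row_meta
  rows <- which(meta$participant == participant &
                  meta$condition == condition &
                  meta$channel %in% roi)
  if (length(rows) == 0L)
    stop("no rows for participant ", participant, ", condition ", condition)
  lam <- solution$unstandardised_loadings[, factor]
  if (at_extremum) {
    wave <- mean(solution$scores[rows, factor]) * lam
    return(wave[which.max(abs(wave))])
  }
  peak <- which.max(abs(lam))
  mean(solution$scores[rows, factor]) * lam[peak]
}

#' Peak-amplitude table for all factors, conditions and participants
#'
#' @inheritParams peak_amplitude
#' @return Long `data.table` with columns `participant`, `condition`,
#'   `factor`, `peak_uv`.
#' @export
peak_amplitude_table <- function(solution, roi = c("FCz", "FC1", "FC2", "Fz"),
                                 at_extremum = FALSE) {
  meta <- solution$row_meta
  participants <- unique(meta$participant)
  conditions <- unique(meta$condition)
  out <- data.table::CJ(participant = participants, condition = conditions,
                        factor = seq_len(solution$k))
  out[, peak_uv := mapply(function(p, cond, f) {
    peak_amplitude(solution, f, cond, p, roi, at_extremum)
  }, participant, condition, factor)]
  out[]
}

#' Violation-minus-confirmation contrasts of estimated peak amplitudes
#'
#' Per participant and factor:
#' * `mmn_rep` / `mmn_nonrep`: Position-1 deviant minus global standard for
#'   each rule (the traditional deviant-minus-standard contrast),
#' * `p2_dev_viol_minus_conf`: Position-2 deviants, low (nonrepetition,
#'   rule-violating) minus high (repetition, rule-conforming) repetition
#'   probability,
#' * `p2_std_viol_minus_conf`: Position-2 standards, high (rule-violating)
#'   minus low (rule-conforming) repetition probability,
#' plus the four Position-2 cell means for the global x conditional rule
#' analysis.
#'
#' @param peaks A peak table from [peak_amplitude_table()].
#' @return `data.table` keyed by `participant`, `factor`.
#' @export
contrast_table <- function(peaks) {
  need <- erp_conditions()
  have <- unique(peaks$condition)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing condition(s): ", paste(miss, collapse = ", "))
  wide <- data.table::dcast(peaks, participant + factor ~ condition,
                            value.var = "peak_uv")
  wide[, `:=`(
    mmn_rep = P1_dev_rep - global_standard,
    mmn_nonrep = P1_dev_nonrep - global_standard,
    p2_dev_viol_minus_conf = P2_dev_nonrep - P2_dev_rep,
    p2_std_viol_minus_conf = P2_std_after_rep - P2_std_after_nonrep,
    cell_dev_conf = P2_dev_rep,
    cell_dev_viol = P2_dev_nonrep,
    cell_std_conf = P2_std_after_nonrep,
    cell_std_viol = P2_std_after_rep
  )]
  wide[]
}

#' Tucker congruence between two loading matrices
#'
#' Columns of `est` are matched greedily to columns of `truth` by absolute
#' congruence (sign/permutation alignment).
#'
#' @param truth,est p x k matrices.
#' @return Per-truth-factor congruence coefficients after alignment.
#' @export
tucker_congruence <- function(truth, est) {
  truth <- as.matrix(truth); est <- as.matrix(est)
  k <- ncol(truth)
  cc <- abs(crossprod(truth, est) /
              outer(sqrt(colSums(truth^2)), sqrt(colSums(est^2))))
  out <- numeric(k); used <- integer(0)
  for (f in seq_len(k)) {
    j <- order(cc[f, ], decreasing = TRUE)
    j <- j[!j %in% used][1]
    used <- c(used, j)
    out[f] <- cc[f, j]
  }
  out
}
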