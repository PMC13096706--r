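#' JZS default Bayes factor for a one-sample / paired t statistic
#'
#' `BF10` is the marginal likelihood of the observed `t` under a Cauchy
#' prior (scale `r`, default `sqrt(2)/2`) on the standardised effect
#' divided by the likelihood under the point null. The Cauchy prior is
#' represented as a normal scale mixture with an inverse-gamma(1/2, 1/2)
#' mixing distribution and the mixture integral is evaluated by adaptive
#' quadrature on the log-transformed mixing variable.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design); `n >= 2`.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @param rel_tol Requested relative integration tolerance (default 1e-8).
#' @return A `bf_result`: list with `bf10`, `bf01`, `error` (integration
#'   error estimate relative to the integral) and `category` (Jeffreys
#'   label, see [categorize_bf()]).
#' @export
jzs_bf10 <- function(t, n, r = sqrt(2) / 2, rel_tol = 1e-8) {
  if (!is.finite(t)) stop("t must be finite")
  n <- assert_count(n, "n", 2L)
  if (r <= 0) stop("Cauchy scale r must be positive")
  nu <- n - 1
  # log integrand in u = log g: Student-t marginal given g times
  # inverse-gamma(1/2, 1/2) density of g, plus Jacobian g
  log_f <- function(u) {
    g <- exp(u)
    q <- 1 + n * g * r^2
    -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (q * nu)) -
      0.5 * log(2 * pi) - 1.5 * u - 1 / (2 * g) + u
  }
  # shift by the maximum for numerical stability
  m <- optimize(log_f, c(-20, 20), maximum = TRUE)$maximum
  c0 <- log_f(m)
  int <- integrate(function(u) exp(log_f(u) - c0), -Inf, Inf,
                   rel.tol = rel_tol, abs.tol = 0, subdivisions = 400L)
  if (int$message != "OK")
    stop("integration failure in jzs_bf10: ", int$message)
  log_num <- c0 + log(int$value)
  log_den <- -(nu + 1) / 2 * log1p(t^2 / nu)
  bf10 <- exp(log_num - log_den)
  structure(list(bf10 = bf10, bf01 = 1 / bf10,
                 error = int$abs.error / int$value,
                 category = categorize_bf(bf10)),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> BF10 = %.6g (%s)\n", x$bf10, x$category))
  invisible(x)
}

# brute-force oracle: fixed-grid trapezoid rule on the same mixture
# representation, used by the test suite as an independent quadrature route
jzs_bf10_trapezoid <- function(t, n, r = sqrt(2) / 2, nodes = 1e6,
                               lim = c(-30, 30)) {
  nu <- n - 1
  u <- seq(lim[1], lim[2], length.out = nodes)
  g <- exp(u)
  q <- 1 + n * g * r^2
  lf <- -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (q * nu)) -
    0.5 * log(2 * pi) - 0.5 * u - 1 / (2 * g)
  m <- max(lf)
  val <- sum(exp(lf - m)) * (u[2] - u[1]) # trapezoid; end corrections ~ 0
  exp(m + log(val) + (nu + 1) / 2 * log1p(t^2 / nu))
}

#' Bayes factor from paired differences
#'
#' Computes `t = mean / (sd / sqrt(n))` and delegates to [jzs_bf10()].
#'
#' @param values Numeric vector of paired differences.
#' @param r Cauchy prior scale.
#' @return A `bf_result` with the implied `t` and `n` attached.
#' @export
bf_from_data <- function(values, r = sqrt(2) / 2) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least two finite values")
  s <- sd(values)
  if (s == 0) stop("zero variance: t statistic undefined")
  t <- mean(values) / (s / sqrt(n))
  out <- jzs_bf10(t, n, r)
  out$t <- t; out$n <- n
  out
}

#' Jeffreys evidence category of a Bayes factor
#'
#' Thresholds (exclusive): `> 42` very strong, `> 10` strong, `> 3`
#' moderate evidence for the alternative; reciprocal bounds label evidence
#' for the null; values in `[1/3, 3]` are anecdotal/inconclusive.
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character label(s).
#' @export
categorize_bf <- function(bf10) {
  if (any(bf10 <= 0)) stop("bf10 must be positive")
  vapply(bf10, function(b) {
    if (b > 42) "very strong (H1)"
    else if (b > 10) "strong (H1)"
    else if (b > 3) "moderate (H1)"
    else if (b >= 1 / 3) "anecdotal"
    else if (b >= 1 / 10) "moderate (H0)"
    else if (b >= 1 / 42) "strong (H0)"
    else "very strong (H0)"
  }, character(1))
}

#' Cohen's d for paired differences with a percentile-bootstrap CI
#'
#' `d_z = mean(differences) / sd(differences)`.
#'
#' @param differences Numeric vector, `n >= 2`, nonzero SD.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List with `d_z`, `ci` (lower, upper), `n_boot`, `seed`.
#' @export
cohen_dz <- function(differences, n_boot = 2000, conf = 0.95, seed = 1L) {
  x <- differences[is.finite(differences)]
  n <- length(x)
  if (n < 2) stop("need at least two values")
  s <- sd(x)
  if (s == 0) stop("zero standard deviation: d_z undefined")
  dz <- mean(x) / s
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    sb <- sd(xb)
    if (sb == 0) NA_real_ else mean(xb) / sb
  }, numeric(1))
  ci <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  list(d_z = dz, ci = ci, n_boot = n_boot, seed = seed)
}

#' Fixed-n Bayes-factor design analysis
#'
#' Simulates `n_sims` paired datasets of size `n` with unit-variance normal
#' differences and true standardised effect `delta`; reports the fraction
#' whose JZS `BF10` reaches the evidence threshold, and the analogous
#' false-evidence rate under `delta = 0`.
#'
#' @param delta True standardised effect under H1.
#' @param n Sample size per dataset.
#' @param threshold BF10 evidence bound (default 6).
#' @param r Cauchy prior scale.
#' @param n_sims Number of simulated datasets (>= 1000).
#' @param seed Integer seed.
#' @param include_h0 Also simulate under `delta = 0` (default `TRUE`).
#' @return A `design_analysis_result`: list with `delta`, `n`, `threshold`,
#'   `n_sims`, `p_exceed_h1`, `p_exceed_h0`, `seed`.
#' @export
bfda_fixed_n <- function(delta, n, threshold = 6, r = sqrt(2) / 2,
                         n_sims = 10000, seed = 1L, include_h0 = TRUE) {
  if (n_sims < 1000) stop("n_sims must be at least 1000")
  p_exceed <- function(d, seed_i) {
    set.seed(seed_i)
    hits <- 0L
    for (i in seq_len(n_sims)) {
      x <- rnorm(n, d, 1)
      t <- mean(x) / (sd(x) / sqrt(n))
      if (jzs_bf10(t, n, r)$bf10 >= threshold) hits <- hits + 1L
    }
    hits / n_sims
  }
  res <- list(delta = delta, n = n, threshold = threshold, n_sims = n_sims,
              p_exceed_h1 = p_exceed(delta, seed),
              p_exceed_h0 = if (include_h0) p_exceed(0, derive_seed(seed, 1L))
                            else NA_real_,
              seed = seed)
  class(res) <- "design_analysis_result"
  res
}

#' @export
print.design_analysis_result <- function(x, ...) {
  cat(sprintf(
    "<design_analysis> delta = %g, n = %d, BF threshold %g: P(H1 hit) = %.3f, P(H0 false hit) = %.4f\n",
    x$delta, x$n, x$threshold, x$p_exceed_h1, x$p_exceed_h0))
  invisible(x)
}

#' Smallest sample size meeting a design-analysis target
#'
#' @param delta True standardised effect.
#' @param target_prob Required `P(BF10 >= threshold)` under H1.
#' @param threshold BF10 bound (default 6).
#' @param n_grid Increasing grid of candidate sample sizes.
#' @param n_sims Simulations per grid point.
#' @param seed Integer seed.
#' @return List with `required_n` (`NA` if the target is unreachable on the
#'   grid, flagged by `reached`), the per-grid probabilities and their
#'   Monte-Carlo standard errors.
#' @export
bfda_required_n <- function(delta, target_prob, threshold = 6,
                            n_grid = seq(20, 100, by = 10), n_sims = 2000,
                            seed = 1L) {
  if (is.unsorted(n_grid)) stop("n_grid must be increasing")
  probs <- numeric(length(n_grid))
  for (i in seq_along(n_grid)) {
    probs[i] <- bfda_fixed_n(delta, n_grid[i], threshold,
                             n_sims = max(n_sims, 1000),
                             seed = derive_seed(seed, i),
                             include_h0 = FALSE)$p_exceed_h1
  }
  se <- sqrt(probs * (1 - probs) / n_sims)
  hit <- which(probs >= target_prob)
  list(required_n = if (length(hit)) n_grid[min(hit)] else NA_integer_,
       reached = length(hit) > 0,
       n_grid = n_grid, p_exceed = probs, mc_se = se, seed = seed)
}

#' Inclusion Bayes factor over a set of model evidences
#'
#' `BF_incl` compares the prior-weighted average evidence of all models
#' containing an effect with that of all models without it.
#'
#' @param model_evidences Named numeric vector of marginal evidences.
#' @param effect_membership Named logical vector: does the model contain the
#'   effect?
#' @param prior_probs Named prior model probabilities (default uniform).
#' @return The inclusion Bayes factor (scalar).
#' @export
inclusion_bf <- function(model_evidences, effect_membership,
                         prior_probs = NULL) {
  stopifnot(length(model_evidences) == length(effect_membership))
  if (any(model_evidences <= 0)) stop("evidences must be positive")
  prior_probs <- prior_probs %||%
    rep(1 / length(model_evidences), length(model_evidences))
  w <- which(effect_membership); wo <- which(!effect_membership)
  if (length(w) == 0L || length(wo) == 0L)
    stop("effect_membership must split models into non-empty with/without sets")
  num <- sum(prior_probs[w] * model_evidences[w]) / sum(prior_probs[w])
  den <- sum(prior_probs[wo] * model_evidences[wo]) / sum(prior_probs[wo])
  num / den
}

#' Subsample robustness distribution of effect size and Bayes factor
#'
#' Draws subsamples of `m` participants without replacement and recomputes
#' Cohen's `d_z` and the JZS `BF10` for each draw.
#'
#' @param per_participant_values Numeric vector (one difference score per
#'   participant).
#' @param m Subsample size (default 40); `m <= N`.
#' @param draws Number of draws (default 10000).
#' @param r Cauchy prior scale.
#' @param seed Integer seed.
#' @return List with `draws` (`data.table` of `d_z`, `bf10`) and `summary`
#'   (means, medians, quantiles).
#' @export
subsample_bf_distribution <- function(per_participant_values, m = 40,
                                      draws = 10000, r = sqrt(2) / 2,
                                      seed = 1L) {
  x <- per_participant_values[is.finite(per_participant_values)]
  N <- length(x)
  if (m > N) stop("m must not exceed the number of participants")
  set.seed(seed)
  dz <- numeric(draws); bf <- numeric(draws)
  for (i in seq_len(draws)) {
    xs <- if (m == N) x else x[sample.int(N, m)]
    s <- sd(xs)
    dz[i] <- mean(xs) / s
    bf[i] <- jzs_bf10(mean(xs) / (s / sqrt(m)), m, r)$bf10
  }
  tab <- data.table::data.table(d_z = dz, bf10 = bf)
  list(draws = tab,
       summary = list(
         d_z_mean = mean(dz), d_z_q = quantile(dz, c(.025, .5, .975)),
         bf10_median = median(bf), bf10_q = quantile(bf, c(.025, .5, .975)),
         p_bf_above_3 = mean(bf > 3)),
       m = m, n_draws = draws, seed = seed)
}
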