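#' Specification of the lognormal response-time models
#'
#' All models are lognormal at the single-trial level with a
#' position x repetition-probability linear predictor for the log-scale
#' dispersion `sigma`. They differ in the location `mu`:
#' * `m0` (null): `mu = 1 + position * rep_prob + (1 | participant)` —
#'   no time trend;
#' * `m1`: `mu = a * trial^b` with
#'   `a = 1 + position + (1 | participant)` and
#'   `b = 1 + position * rep_prob + (1 | participant)`;
#' * `m2`: as `m1` but `a = 1 + position * rep_prob + (1 | participant)`
#'   (so `m1` is nested in `m2`).
#' `trial` is the 1-based index of the deviant trial within the whole
#' behavioural part. All coefficients are on the log scale.
#'
#' Priors are weakly informative: the `a` intercept is
#' `Normal(log 300, 1)`, every other fixed coefficient `Normal(0, 1)`,
#' random-intercept SDs half-normal(0, 1).
#'
#' @param name One of `"m0"`, `"m1"`, `"m2"`.
#' @return A `model_spec`.
#' @export
model_spec <- function(name = c("m1", "m0", "m2")) {
  name <- match.arg(name)
  a_terms <- switch(name,
                    m0 = c("intercept", "position2", "rep_high", "interaction"),
                    m1 = c("intercept", "position2"),
                    m2 = c("intercept", "position2", "rep_high", "interaction"))
  b_terms <- if (name == "m0") character(0)
             else c("intercept", "position2", "rep_high", "interaction")
  s_terms <- c("intercept", "position2", "rep_high", "interaction")
  structure(list(name = name, a_terms = a_terms, b_terms = b_terms,
                 s_terms = s_terms,
                 has_power_law = name != "m0",
                 prior = list(a_intercept_mean = log(300), fixed_sd = 1,
                              sd_scale = 1)),
            class = "model_spec")
}

# design columns for a term set
term_design <- function(terms, p2, hi) {
  X <- cbind(intercept = rep(1, length(p2)), position2 = p2,
             rep_high = hi, interaction = p2 * hi)
  X[, terms, drop = FALSE]
}

#' Prepare single-trial RT data for model fitting
#'
#' Keeps pressed deviant trials with positive RTs and builds the design
#' columns (`position2`, `rep_high` indicators and `trial_number`).
#'
#' @param table A `response_table` (e.g., from [simulate_behaviour()]).
#' @return `data.table` with `participant`, `position`, `rule`,
#'   `trial_number`, `rt_ms`.
#' @export
rt_model_data <- function(table) {
  tab <- data.table::as.data.table(table)
  dat <- tab[role %in% c("first_deviant", "second_deviant") & press == TRUE &
               is.finite(rt_ms)]
  if (any(dat$rt_ms <= 0)) stop("nonpositive RT encountered")
  dat[role == "first_deviant",
      rule := ifelse(stimulus == "deviant_rep_rule", "rep", "nonrep")]
  dat[, position := ifelse(role == "first_deviant", 1L, 2L)]
  dat[, .(participant, position, rule, trial_number, rt_ms)]
}

#' Model-implied log-scale location and median RT
#'
#' For the power-law models `mu = a_cell * trial^b_cell` and the median RT
#' is `exp(mu)` in ms.
#'
#' @param coefs List with named vectors `a` and `b` (elements `intercept`,
#'   `position2`, `rep_high`, `interaction`; missing elements are 0) and
#'   optionally `a_re`, `b_re` participant offsets.
#' @param trial_number Trial index, `>= 1`.
#' @param position 1 or 2.
#' @param rep_prob `"high"`/`"low"` (or `"rep"`/`"nonrep"`).
#' @param participant Optional participant id indexing `a_re`/`b_re`.
#' @return List with `mu` (log scale) and `median_ms`.
#' @export
mu_predict <- function(coefs, trial_number, position, rep_prob = "low",
                       participant = NULL) {
  if (any(trial_number < 1)) stop("trial_number must be >= 1 (power-law domain)")
  p2 <- as.numeric(position == 2 | position == "2")
  hi <- as.numeric(rep_prob %in% c("high", "rep"))
  pick <- function(v, nm) if (!is.null(v) && nm %in% names(v)) v[[nm]] else 0
  a_re <- if (!is.null(participant) && !is.null(coefs$a_re))
    coefs$a_re[participant] else 0
  b_re <- if (!is.null(participant) && !is.null(coefs$b_re))
    coefs$b_re[participant] else 0
  a <- pick(coefs$a, "intercept") + pick(coefs$a, "position2") * p2 +
    pick(coefs$a, "rep_high") * hi + pick(coefs$a, "interaction") * p2 * hi +
    a_re
  b <- pick(coefs$b, "intercept") + pick(coefs$b, "position2") * p2 +
    pick(coefs$b, "rep_high") * hi + pick(coefs$b, "interaction") * p2 * hi +
    b_re
  mu <- a * trial_number^b
  list(mu = mu, median_ms = exp(mu))
}

# internal: build the likelihood environment for a dataset and spec
rt_likelihood_env <- function(spec, data) {
  dat <- data.table::as.data.table(data)
  stopifnot(all(c("participant", "position", "rule", "trial_number",
                  "rt_ms") %in% names(dat)))
  if (nrow(dat) == 0L) stop("empty dataset")
  if (any(dat$rt_ms <= 0)) stop("nonpositive RT encountered")
  if (any(dat$trial_number < 1)) stop("trial_number must be >= 1")
  p2 <- as.numeric(dat$position == 2L)
  hi <- as.numeric(dat$rule %in% c("rep", "high"))
  pid <- match(dat$participant, sort(unique(dat$participant)))
  list(
    Xa = term_design(spec$a_terms, p2, hi),
    Xb = if (spec$has_power_law) term_design(spec$b_terms, p2, hi) else NULL,
    Xs = term_design(spec$s_terms, p2, hi),
    log_t = log(dat$trial_number),
    log_y = log(dat$rt_ms),
    pid = pid,
    J = max(pid),
    n = nrow(dat),
    participants = sort(unique(dat$participant))
  )
}

# pointwise log likelihood for a parameter list
rt_loglik_point <- function(spec, env, par) {
  A <- drop(env$Xa %*% par$a) + par$u_a[env$pid]
  mu <- if (spec$has_power_law) {
    B <- drop(env$Xb %*% par$b) + par$u_b[env$pid]
    A * exp(B * env$log_t)
  } else A
  sig <- exp(drop(env$Xs %*% par$s))
  dnorm(env$log_y, mu, sig, log = TRUE) - env$log_y
}

#' Total log likelihood of a coefficient set
#'
#' @param spec A [model_spec()].
#' @param data Single-trial data as from [rt_model_data()].
#' @param coefs List with `a`, `b`, `sigma` named fixed-effect vectors and
#'   optional `a_re`, `b_re` per-participant offsets (in participant order).
#' @return List with `total` and `pointwise` log-likelihood.
#' @export
rt_loglik <- function(spec, data, coefs) {
  env <- rt_likelihood_env(spec, data)
  grab <- function(v, terms) {
    out <- setNames(rep(0, length(terms)), terms)
    common <- intersect(names(v), terms)
    out[common] <- v[common]
    out
  }
  par <- list(
    a = grab(coefs$a %||% numeric(0), spec$a_terms),
    b = if (spec$has_power_law) grab(coefs$b %||% numeric(0), spec$b_terms),
    s = grab(coefs$sigma %||% numeric(0), spec$s_terms),
    u_a = rep_len(coefs$a_re %||% 0, env$J),
    u_b = rep_len(coefs$b_re %||% 0, env$J)
  )
  pw <- rt_loglik_point(spec, env, par)
  list(total = sum(pw), pointwise = pw)
}
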