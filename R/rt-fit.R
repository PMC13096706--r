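#' Fit a lognormal response-time model by Hamiltonian Monte Carlo
#'
#' Posterior sampling uses Hamiltonian Monte Carlo with analytic gradients
#' of the log posterior, a diagonal mass matrix estimated during warm-up,
#' dual-averaging step-size adaptation (target acceptance 0.8) and a
#' jittered number of leapfrog steps. All parameters — fixed effects of
#' `a`, `b` and `sigma`, participant random intercepts and the log
#' random-intercept SDs — are updated jointly, which handles the strong
#' posterior correlation between the power-law constant and exponent.
#' Adaptation stops at the end of warm-up.
#'
#' @param spec A [model_spec()].
#' @param data Single-trial data as from [rt_model_data()].
#' @param chains Number of chains (default 4).
#' @param iterations Iterations per chain including warm-up (default 6000).
#' @param warmup Warm-up iterations (default half).
#' @param seed Integer seed; chain `c` uses a seed derived from it.
#' @param max_leapfrog Upper bound of the jittered leapfrog step count
#'   (default 60).
#' @param progress Print progress (default `FALSE`).
#' @return An `rt_fit`: list with `draws` (list of per-chain post-warm-up
#'   matrices), `rhat`, `ess`, `converged` (all monitored Rhat < 1.01 and
#'   ESS > 1000), `accept_rates`, `spec`, `data`, and internals used by
#'   [rt_compare()] and [posterior_predictive()].
#' @export
rt_fit <- function(spec, data, chains = 4, iterations = 6000,
                   warmup = floor(iterations / 2), seed = 1L,
                   max_leapfrog = 60L, progress = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  env <- rt_likelihood_env(spec, data)
  draws <- vector("list", chains)
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    res <- hmc_chain(spec, env, iterations, warmup,
                     seed = derive_seed(seed, 100L + ch),
                     max_leapfrog = max_leapfrog,
                     progress = progress, chain_id = ch)
    draws[[ch]] <- res$draws
    acc[ch] <- res$accept_rate
  }
  diag <- mcmc_diagnostics(draws)
  monitored <- !grepl("^u_", colnames(draws[[1]]))
  converged <- all(diag$rhat[monitored] < 1.01, na.rm = TRUE) &&
    all(diag$ess[monitored] > 1000, na.rm = TRUE)
  structure(list(draws = draws, rhat = diag$rhat, ess = diag$ess,
                 converged = converged, accept_rates = acc,
                 spec = spec, data = data.table::as.data.table(data),
                 env = env, seed = seed, iterations = iterations,
                 warmup = warmup),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> %s: %d chains x %d post-warmup draws; %s\n",
              x$spec$name, length(x$draws), nrow(x$draws[[1]]),
              if (x$converged) "converged" else "NOT converged"))
  mon <- !grepl("^u_", names(x$rhat))
  cat(sprintf("  max Rhat %.3f, min ESS %.0f (monitored), mean accept %.2f\n",
              max(x$rhat[mon], na.rm = TRUE), min(x$ess[mon], na.rm = TRUE),
              mean(x$accept_rates)))
  invisible(x)
}

# ---- posterior density and gradient ------------------------------------

# theta layout: [beta_a | beta_b | gamma_s | log_sd_a (| log_sd_b) |
#                u_a (J) (| u_b (J))]
rt_theta_layout <- function(spec, J) {
  na <- length(spec$a_terms); nb <- length(spec$b_terms)
  ns <- length(spec$s_terms)
  pw <- spec$has_power_law
  idx <- list(a = seq_len(na),
              b = if (pw) na + seq_len(nb),
              s = na + nb + seq_len(ns),
              log_sd_a = na + nb + ns + 1L,
              log_sd_b = if (pw) na + nb + ns + 2L,
              u_a = na + nb + ns + 1L + pw + seq_len(J),
              u_b = if (pw) na + nb + ns + 2L + J + seq_len(J))
  idx$d <- na + nb + ns + 1L + pw + J + pw * J
  idx
}

# log posterior and its gradient; returns list(lp, grad)
rt_lp_grad <- function(theta, spec, env, lay, prior) {
  pw <- spec$has_power_law
  J <- env$J
  ba <- theta[lay$a]
  gs <- theta[lay$s]
  lsa <- theta[lay$log_sd_a]
  u_a <- theta[lay$u_a]
  A <- drop(env$Xa %*% ba) + u_a[env$pid]
  if (pw) {
    bb <- theta[lay$b]
    lsb <- theta[lay$log_sd_b]
    u_b <- theta[lay$u_b]
    B <- drop(env$Xb %*% bb) + u_b[env$pid]
    E <- exp(B * env$log_t)
    mu <- A * E
  } else {
    mu <- A
    E <- 1
  }
  s <- exp(drop(env$Xs %*% gs))
  z <- (env$log_y - mu) / s
  ll <- sum(-env$log_y - log(s) - 0.5 * log(2 * pi) - 0.5 * z^2)

  g_mu <- z / s
  grad <- numeric(lay$d)
  gaE <- g_mu * E
  grad[lay$a] <- drop(crossprod(env$Xa, gaE))
  grad[lay$u_a] <- rowsum_vec(gaE, env$pid, J)
  if (pw) {
    gbE <- g_mu * A * env$log_t * E
    grad[lay$b] <- drop(crossprod(env$Xb, gbE))
    grad[lay$u_b] <- rowsum_vec(gbE, env$pid, J)
  }
  grad[lay$s] <- drop(crossprod(env$Xs, z^2 - 1))

  # priors
  sda <- exp(lsa)
  lp <- ll +
    dnorm(ba[1], prior$a_intercept_mean, prior$fixed_sd, log = TRUE) +
    sum(dnorm(ba[-1], 0, prior$fixed_sd, log = TRUE)) +
    sum(dnorm(gs, 0, prior$fixed_sd, log = TRUE)) +
    dnorm(sda, 0, prior$sd_scale, log = TRUE) + log(2) + lsa +
    sum(dnorm(u_a, 0, sda, log = TRUE))
  grad[lay$a][1] <- grad[lay$a][1] -
    (ba[1] - prior$a_intercept_mean) / prior$fixed_sd^2
  if (length(ba) > 1)
    grad[lay$a][-1] <- grad[lay$a][-1] - ba[-1] / prior$fixed_sd^2
  grad[lay$s] <- grad[lay$s] - gs / prior$fixed_sd^2
  grad[lay$u_a] <- grad[lay$u_a] - u_a / sda^2
  grad[lay$log_sd_a] <- -sda^2 / prior$sd_scale^2 + 1 -
    J + sum(u_a^2) / sda^2
  if (pw) {
    sdb <- exp(lsb)
    lp <- lp + sum(dnorm(bb, 0, prior$fixed_sd, log = TRUE)) +
      dnorm(sdb, 0, prior$sd_scale, log = TRUE) + log(2) + lsb +
      sum(dnorm(u_b, 0, sdb, log = TRUE))
    grad[lay$b] <- grad[lay$b] - bb / prior$fixed_sd^2
    grad[lay$u_b] <- grad[lay$u_b] - u_b / sdb^2
    grad[lay$log_sd_b] <- -sdb^2 / prior$sd_scale^2 + 1 -
      J + sum(u_b^2) / sdb^2
  }
  list(lp = lp, grad = grad)
}

rowsum_vec <- function(x, pid, J) {
  out <- rowsum(x, pid)
  res <- numeric(J)
  res[as.integer(rownames(out))] <- out[, 1]
  res
}

# ---- HMC ---------------------------------------------------------------

hmc_chain <- function(spec, env, iterations, warmup, seed, max_leapfrog,
                      progress, chain_id) {
  set.seed(seed)
  J <- env$J
  lay <- rt_theta_layout(spec, J)
  prior <- spec$prior
  d <- lay$d

  theta <- rt_init_theta(spec, env, lay)
  cur <- rt_lp_grad(theta, spec, env, lay, prior)

  inv_mass <- rep(1, d)
  # crude initial scales: intercept-like ~1e-2, b terms small
  inv_mass[lay$a] <- 1e-3
  if (spec$has_power_law) inv_mass[lay$b] <- 1e-5
  inv_mass[lay$s] <- 1e-3
  inv_mass[c(lay$log_sd_a, lay$log_sd_b)] <- 1e-2
  inv_mass[lay$u_a] <- 1e-3
  if (spec$has_power_law) inv_mass[lay$u_b] <- 1e-6

  # dual averaging state
  eps <- 0.1; log_eps_bar <- log(eps)
  H_bar <- 0; mu_da <- log(10 * eps); t0 <- 10; gamma_da <- 0.05; kappa <- 0.75

  keep <- iterations - warmup
  par_names <- rt_par_names(spec, J)
  out <- matrix(NA_real_, keep, d, dimnames = list(NULL, par_names))
  n_acc <- 0

  # windowed variance estimation for the mass matrix
  var_start <- max(50L, floor(warmup * 0.25))
  var_end <- floor(warmup * 0.75)
  wsum <- numeric(d); wsum2 <- numeric(d); wn <- 0

  for (it in seq_len(iterations)) {
    p0 <- rnorm(d) / sqrt(inv_mass)
    L <- sample(seq.int(max(1L, ceiling(max_leapfrog / 2)), max_leapfrog), 1L)
    th <- theta; p <- p0; gr <- cur$grad
    # leapfrog
    p <- p + 0.5 * eps * gr
    diverged <- FALSE
    for (l in seq_len(L)) {
      th <- th + eps * inv_mass * p
      prop <- rt_lp_grad(th, spec, env, lay, prior)
      if (!is.finite(prop$lp) || any(!is.finite(prop$grad))) {
        diverged <- TRUE; break
      }
      p <- p + (if (l < L) eps else 0.5 * eps) * prop$grad
    }
    if (!diverged) {
      h0 <- -cur$lp + 0.5 * sum(p0^2 * inv_mass)
      h1 <- -prop$lp + 0.5 * sum(p^2 * inv_mass)
      a_prob <- min(1, exp(h0 - h1))
      if (runif(1) < a_prob) {
        theta <- th; cur <- prop
        if (it > warmup) n_acc <- n_acc + 1
      }
    } else a_prob <- 0

    if (it <= warmup) {
      # dual averaging
      m <- it
      H_bar <- (1 - 1 / (m + t0)) * H_bar + (0.8 - a_prob) / (m + t0)
      log_eps <- mu_da - sqrt(m) / gamma_da * H_bar
      eta <- m^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      if (it >= var_start && it <= var_end) {
        wsum <- wsum + theta; wsum2 <- wsum2 + theta^2; wn <- wn + 1
      }
      if (it == var_end && wn > 10) {
        v <- (wsum2 - wsum^2 / wn) / (wn - 1)
        ok <- v > 0 & is.finite(v)
        inv_mass[ok] <- v[ok]
        # re-tune the step size for the new metric
        mu_da <- log(10 * exp(log_eps_bar)); H_bar <- 0
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      out[it - warmup, ] <- theta
    }
    if (progress && it %% 500 == 0)
      message("chain ", chain_id, ": iteration ", it, "/", iterations,
              " (eps = ", signif(eps, 3), ")")
  }
  list(draws = out, accept_rate = n_acc / keep, step_size = eps)
}

rt_init_theta <- function(spec, env, lay) {
  m <- mean(env$log_y); s <- max(sd(env$log_y), 0.05)
  theta <- numeric(lay$d)
  theta[lay$a][1] <- m
  theta[lay$s][1] <- log(s)
  theta[lay$log_sd_a] <- log(0.1)
  if (spec$has_power_law) theta[lay$log_sd_b] <- log(0.01)
  theta
}

rt_par_names <- function(spec, J) {
  c(paste0("a_", spec$a_terms),
    if (spec$has_power_law) paste0("b_", spec$b_terms),
    paste0("s_", spec$s_terms),
    "log_sd_a", if (spec$has_power_law) "log_sd_b",
    paste0("u_a_", seq_len(J)),
    if (spec$has_power_law) paste0("u_b_", seq_len(J)))
}

rt_unflatten_draw <- function(spec, J, draw) {
  lay <- rt_theta_layout(spec, J)
  par <- list(a = setNames(draw[lay$a], spec$a_terms))
  par$b <- if (spec$has_power_law) setNames(draw[lay$b], spec$b_terms)
  par$s <- setNames(draw[lay$s], spec$s_terms)
  par$log_sd_a <- draw[lay$log_sd_a]
  par$log_sd_b <- if (spec$has_power_law) draw[lay$log_sd_b] else log(0.01)
  par$u_a <- draw[lay$u_a]
  par$u_b <- if (spec$has_power_law) draw[lay$u_b] else rep(0, J)
  par
}
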