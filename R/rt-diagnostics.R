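# ---- generic MCMC diagnostics ------------------------------------------

# split-Rhat and effective sample size (Geyer initial positive sequence),
# computed per parameter over a list of per-chain draw matrices
mcmc_diagnostics <- function(chains) {
  p <- ncol(chains[[1]])
  nm <- colnames(chains[[1]])
  rhat <- setNames(rep(NA_real_, p), nm)
  ess <- setNames(rep(NA_real_, p), nm)
  for (j in seq_len(p)) {
    segs <- list()
    for (ch in chains) {
      x <- ch[, j]
      h <- floor(length(x) / 2)
      segs <- c(segs, list(x[seq_len(h)], x[h + seq_len(h)]))
    }
    rhat[j] <- split_rhat(segs)
    ess[j] <- sum(vapply(chains, function(ch) ess_geyer(ch[, j]), numeric(1)))
  }
  list(rhat = rhat, ess = ess)
}

split_rhat <- function(segs) {
  m <- length(segs); n <- length(segs[[1]])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_geyer <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(0)
  rho <- acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  # sum of adjacent pairs until a pair goes nonpositive
  s <- 0; k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

# ---- posterior summaries ------------------------------------------------

# all post-warm-up draws, rbind-ed across chains
all_draws <- function(fit) do.call(rbind, fit$draws)

#' Posterior summary of the fixed effects
#'
#' @param fit An `rt_fit`.
#' @return `data.table` with posterior mean, SD, 2.5/97.5 percentiles,
#'   Rhat and ESS per fixed-effect parameter.
#' @export
fixed_effect_summary <- function(fit) {
  dr <- all_draws(fit)
  keep <- !grepl("^u_", colnames(dr))
  dr <- dr[, keep, drop = FALSE]
  data.table::data.table(
    parameter = colnames(dr),
    mean = colMeans(dr),
    sd = apply(dr, 2, sd),
    q2.5 = apply(dr, 2, quantile, 0.025),
    q97.5 = apply(dr, 2, quantile, 0.975),
    rhat = fit$rhat[colnames(dr)],
    ess = fit$ess[colnames(dr)]
  )
}

#' Directional hypothesis test on the posterior draws
#'
#' The contrast is a named numeric vector over draw columns (e.g.,
#' `c(b_position2 = 1, b_interaction = 1)` for the slope of high-probability
#' second deviants relative to the intercept terms included). `PP` is the
#' fraction of draws satisfying the direction; the evidence ratio
#' `PP / (1 - PP)` is reported as `>= n_draws` when every draw satisfies
#' the hypothesis.
#'
#' @param fit An `rt_fit` (should be converged; set `force = TRUE` to
#'   summarise anyway).
#' @param contrast Named numeric vector of draw-column weights.
#' @param direction `">"` or `"<"` (against 0).
#' @param force Summarise a non-converged fit (default `FALSE`).
#' @return List with `mean`, `ci95`, `pp`, `evidence_ratio`,
#'   `evidence_ratio_label`, `n_draws`.
#' @export
rt_hypothesis <- function(fit, contrast, direction = c(">", "<"),
                          force = FALSE) {
  direction <- match.arg(direction)
  if (!fit$converged && !force)
    stop("fit has not converged; pass force = TRUE to summarise anyway")
  dr <- all_draws(fit)
  miss <- setdiff(names(contrast), colnames(dr))
  if (length(miss))
    stop("contrast names not among sampled coefficients: ",
         paste(miss, collapse = ", "))
  v <- drop(dr[, names(contrast), drop = FALSE] %*% contrast)
  pp <- if (direction == ">") mean(v > 0) else mean(v < 0)
  n <- length(v)
  er <- if (pp == 1) Inf else pp / (1 - pp)
  list(mean = mean(v),
       ci95 = quantile(v, c(0.025, 0.975), names = FALSE),
       pp = pp,
       evidence_ratio = er,
       evidence_ratio_label = if (pp == 1) paste0(">= ", n) else
         formatC(er, digits = 4, format = "g"),
       n_draws = n)
}

# ---- model comparison ---------------------------------------------------

# pointwise log-likelihood matrix (draws x observations) on a thinned set
pointwise_loglik <- function(fit, n_draws = 400) {
  dr <- all_draws(fit)
  S <- nrow(dr)
  idx <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  env <- fit$env; spec <- fit$spec
  out <- matrix(NA_real_, length(idx), env$n)
  for (i in seq_along(idx)) {
    par <- rt_unflatten_draw(spec, env$J, dr[idx[i], ])
    out[i, ] <- rt_loglik_point(spec, env, par)
  }
  out
}

# generalized Pareto fit (Zhang & Stephens 2009) to exceedances x > 0
gpd_fit_k <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * q1)
  lb <- vapply(b, function(bj) {
    k <- -mean(log1p(-bj * x))
    n * (log(bj / k) + k - 1)
  }, numeric(1))
  w <- exp(lb - max(lb)); w <- w / sum(w)
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  list(k = k_hat, sigma = k_hat / b_hat, b = b_hat)
}

# PSIS-smoothed LOO from a pointwise log-likelihood matrix
psis_loo <- function(ll) {
  S <- nrow(ll); n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    lw <- -ll[, i]
    lw <- lw - max(lw)
    M <- min(ceiling(0.2 * S), S - 1)
    ord <- order(lw, decreasing = TRUE)
    tail_idx <- ord[seq_len(M)]
    cut <- max(lw[ord[M + 1]], -700)
    exc <- exp(lw[tail_idx]) - exp(cut)
    gp <- gpd_fit_k(exc[exc > 0])
    k_i[i] <- gp$k
    if (is.finite(gp$k) && gp$k < 0.7 && !is.na(gp$sigma) && gp$sigma > 0) {
      # replace tail weights by GPD quantiles at expected order statistics
      Mi <- length(exc)
      p <- (seq_len(Mi) - 0.5) / Mi
      q <- if (abs(gp$k) < 1e-6) -gp$sigma * log1p(-p)
           else gp$sigma / gp$k * ((1 - p)^(-gp$k) - 1)
      smoothed <- log(exp(cut) + sort(q))
      lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
    } else {
      lw <- pmin(lw, 0)  # plain truncation fallback
    }
    wl <- lw - max(lw)
    # elpd_i = log( sum w * lik / sum w )
    elpd_i[i] <- log(sum(exp(wl + ll[, i]))) - log(sum(exp(wl)))
  }
  list(elpd = sum(elpd_i), elpd_i = elpd_i, looic = -2 * sum(elpd_i),
       se = sqrt(n * var(elpd_i)), pareto_k = k_i)
}

waic <- function(ll) {
  lpd_i <- apply(ll, 2, function(v) {
    m <- max(v); m + log(mean(exp(v - m)))
  })
  p_i <- apply(ll, 2, var)
  elpd_i <- lpd_i - p_i
  list(elpd = sum(elpd_i), elpd_i = elpd_i, waic = -2 * sum(elpd_i),
       se = sqrt(length(elpd_i) * var(elpd_i)))
}

#' Compare fitted response-time models by predictive accuracy
#'
#' Computes PSIS-LOO (with WAIC as a cross-check) from the posterior draws
#' and reports the information criterion (lower is better), pairwise
#' differences in expected log predictive density with standard errors, and
#' Pareto-k tail diagnostics.
#'
#' @param fits Named list of `rt_fit` objects on the same data.
#' @param n_draws Posterior draws used for the pointwise likelihood
#'   (default 400).
#' @return A `comparison_result`: list with `table` (`model`, `looic`,
#'   `elpd`, `se`, `waic`, `max_pareto_k`), `delta` (pairwise elpd
#'   differences with SE), `preferred`.
#' @export
rt_compare <- function(fits, n_draws = 400) {
  stopifnot(length(fits) >= 2)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  n0 <- fits[[1]]$env$n
  y0 <- fits[[1]]$env$log_y
  for (f in fits)
    if (f$env$n != n0 || !isTRUE(all.equal(f$env$log_y, y0)))
      stop("fits must be on the same data")
  loos <- lapply(fits, function(f) {
    ll <- pointwise_loglik(f, n_draws)
    l <- psis_loo(ll)
    l$waic <- waic(ll)$waic
    l
  })
  tab <- data.table::data.table(
    model = names(fits),
    looic = vapply(loos, `[[`, numeric(1), "looic"),
    elpd = vapply(loos, `[[`, numeric(1), "elpd"),
    se = vapply(loos, `[[`, numeric(1), "se"),
    waic = vapply(loos, `[[`, numeric(1), "waic"),
    max_pareto_k = vapply(loos, function(l) max(l$pareto_k), numeric(1))
  )
  nm <- names(fits)
  delta <- list()
  for (i in seq_along(fits)) for (j in seq_along(fits)) {
    d_i <- loos[[i]]$elpd_i - loos[[j]]$elpd_i
    delta[[paste(nm[i], "vs", nm[j])]] <-
      c(delta_elpd = sum(d_i),
        se = sqrt(length(d_i) * var(d_i)))
  }
  structure(list(table = tab[order(looic)],
                 delta = delta,
                 preferred = tab$model[which.min(tab$looic)]),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> preferred:", x$preferred, "\n")
  print(x$table)
  invisible(x)
}

#' Posterior-predictive median-RT trajectories
#'
#' For each posterior draw and design cell the expected median RT
#' `exp(a_cell * trial^b_cell)` is evaluated over the trial grid at the
#' group level (random intercepts at zero); the mean over draws and
#' percentile bands are returned.
#'
#' @param fit A converged `rt_fit` of a power-law model (`force = TRUE`
#'   to override).
#' @param trial_grid Integer vector of trial numbers (default
#'   `1:max(data)`).
#' @param n_draws Posterior draws used (default 200).
#' @param bands Two-sided central band coverages (default
#'   `c(0.5, 0.8, 0.95, 0.99)`).
#' @param force Use a non-converged fit.
#' @return `data.table` with `position`, `rule`, `trial_number`,
#'   `median_rt_ms` (mean over draws) and `lo_*` / `hi_*` band columns.
#' @export
posterior_predictive <- function(fit, trial_grid = NULL, n_draws = 200,
                                 bands = c(0.5, 0.8, 0.95, 0.99),
                                 force = FALSE) {
  if (!fit$converged && !force)
    stop("fit has not converged; pass force = TRUE to override")
  dr <- all_draws(fit)
  S <- nrow(dr)
  idx <- unique(round(seq(1, S, length.out = min(n_draws, S))))
  trial_grid <- trial_grid %||% seq_len(max(fit$data$trial_number))
  cells <- data.table::CJ(position = c(1L, 2L), rule = c("nonrep", "rep"))
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    pos <- cells$position[ci]; rl <- cells$rule[ci]
    traj <- matrix(NA_real_, length(idx), length(trial_grid))
    for (s in seq_along(idx)) {
      par <- rt_unflatten_draw(fit$spec, fit$env$J, dr[idx[s], ])
      m <- mu_predict(list(a = par$a, b = par$b), trial_grid, pos, rl)
      traj[s, ] <- m$median_ms
    }
    res <- data.table::data.table(position = pos, rule = rl,
                                  trial_number = trial_grid,
                                  median_rt_ms = colMeans(traj))
    for (b in bands) {
      lo <- apply(traj, 2, quantile, (1 - b) / 2)
      hi <- apply(traj, 2, quantile, 1 - (1 - b) / 2)
      res[, (paste0("lo_", b * 100)) := lo]
      res[, (paste0("hi_", b * 100)) := hi]
    }
    out[[ci]] <- res
  }
  data.table::rbindlist(out)
}
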