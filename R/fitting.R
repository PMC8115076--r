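# Maximum-likelihood fitting of all observer models, parametric bootstrap,
# threshold extraction and BIC model comparison.

.P_EPS <- 1e-9

.clamp_p <- function(p) pmin(pmax(p, .P_EPS), 1 - .P_EPS)

#' Bayesian information criterion
#'
#' `BIC = logL - (K/2) * ln(n)` — the log-likelihood penalized by half the
#' parameter count times the log of the number of data points. In this sign
#' convention larger BIC is better, and exponentiating a BIC difference gives
#' the posterior odds ratio of the two models.
#'
#' @param logL Maximized log-likelihood (nats).
#' @param K Number of free parameters.
#' @param n Number of data points.
#' @return Scalar BIC.
#' @export
bic <- function(logL, K, n) {
  stopifnot(K >= 0, n > 0)
  logL - (K / 2) * log(n)
}

.fit_result <- function(model_id, params, logL, K, n, converged, start_points = NULL,
                        extra = list()) {
  structure(c(list(model_id = model_id, params = params, logL = logL,
                   K = K, n = n, BIC = bic(logL, K, n), converged = converged,
                   start_points = start_points), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: logL = %.3f, K = %d, n = %d, BIC = %.3f%s>\n",
              x$model_id, x$logL, x$K, x$n, x$BIC,
              if (x$converged) "" else " [NOT CONVERGED]"))
  vals <- vapply(x$params, function(v)
    if (is.numeric(v)) sprintf("%.4g", v) else as.character(v), character(1))
  cat("  params:", paste(names(x$params), vals, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

# Multi-start bounded minimization; returns the best optim() result plus a
# table of start points and their objective values.
.multistart <- function(nll, starts, lower, upper) {
  best <- NULL
  rows <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    res <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    rows[[i]] <- data.frame(t(p0), nll_start = nll(p0),
                            nll_opt = if (is.null(res)) NA_real_ else res$value)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("optimization failed from every start point")
  list(best = best, starts = do.call(rbind, rows))
}

#' Fit the SDT psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood of the proportion-correct data under
#' [sdt_pc()] over gain and transducer exponent (and, with `with_lapse = TRUE`,
#' the lapse rate constrained to \[0, 0.1\]). The search runs a bounded
#' quasi-Newton optimizer in log-parameter space from a small grid of start
#' points and keeps the best optimum.
#'
#' @param levels Stimulus levels (>= 0), at least two distinct.
#' @param n_correct Correct-response counts per level.
#' @param n_trials Trial counts per level.
#' @param with_lapse Fit the lapse rate as a third parameter (default TRUE).
#' @return A `fit_result` with `params` (`g`, `tau`, `lambda`), the maximized
#'   `logL`, `K` (2 or 3), `n` (total trials) and `BIC`.
#' @export
fit_sdt <- function(levels, n_correct, n_trials, with_lapse = TRUE) {
  stopifnot(length(levels) == length(n_correct),
            length(levels) == length(n_trials),
            all(n_trials > 0), all(n_correct >= 0), all(n_correct <= n_trials))
  if (length(unique(levels)) < 2)
    stop("need at least 2 distinct stimulus levels to fit a psychometric function")
  if (sum(n_correct) == sum(n_trials))
    stop("degenerate data: all trials correct at every level; the gain is unidentifiable")
  if (sum(n_correct) == 0)
    stop("degenerate data: no correct trials at any level")
  xpos <- levels[levels > 0]
  nll <- function(par) {
    g <- exp(par[1]); tau <- exp(par[2])
    lambda <- if (with_lapse) par[3] else 0
    p <- .clamp_p(sdt_pc(levels, g, tau, lambda))
    -sum(n_correct * log(p) + (n_trials - n_correct) * log(1 - p))
  }
  g0 <- 1 / stats::quantile(xpos, c(0.25, 0.5, 0.9), names = FALSE)
  starts <- expand.grid(log_g = log(g0), log_tau = log(c(0.5, 1, 2)))
  lower <- c(log(1e-6), log(0.1)); upper <- c(log(1e4), log(10))
  if (with_lapse) {
    starts$lambda <- 0.02
    lower <- c(lower, 0); upper <- c(upper, 0.1)
  }
  ms <- .multistart(nll, starts, lower, upper)
  par <- ms$best$par
  params <- list(g = exp(par[1]), tau = exp(par[2]),
                 lambda = if (with_lapse) par[3] else 0)
  .fit_result("sdt", params, logL = -ms$best$value,
              K = if (with_lapse) 3L else 2L, n = sum(n_trials),
              converged = ms$best$convergence == 0, start_points = ms$starts)
}

#' Stimulus level at a target proportion correct
#'
#' Inverts the SDT psychometric function: with lapse, the target is first
#' mapped back through the lapse stage, then
#' `x = (2 * qnorm(p'))^(1/tau) / g`. The default target 0.75 is the JND level
#' used throughout the experiments.
#'
#' @param params A list with `g`, `tau` and optionally `lambda` (e.g. the
#'   `params` of a [fit_sdt()] result).
#' @param target Target proportion correct in \[0.5, ceiling).
#' @return Stimulus level x (0 for `target = 0.5`).
#' @export
sdt_threshold <- function(params, target = 0.75) {
  lambda <- params$lambda %||% 0
  p <- (target - lambda / 2) / (1 - lambda)
  if (p < 0.5) stop("target below chance is unreachable")
  if (p >= 1) stop("target at or above the lapse ceiling is unreachable")
  dprime <- 2 * stats::qnorm(p)
  dprime^(1 / params$tau) / params$g
}

#' Parametric bootstrap of a psychometric function fit
#'
#' For each of `B` resamples, the correct count at every level is redrawn from
#' a binomial with the observed proportion correct, the SDT psychometric
#' function is refit, and percentile confidence intervals are formed for the
#' parameters and the target-level threshold. Resamples that are degenerate
#' (all correct or all incorrect overall) or fail to fit are counted and
#' skipped.
#'
#' @inheritParams fit_sdt
#' @param B Number of bootstrap resamples (200 by default).
#' @param target Proportion correct defining the threshold (default 0.75).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed for the resampling (independent of any stimulus RNG).
#' @return A list with `ci` (data frame: quantity, lower, upper), `samples`
#'   (data frame of per-resample estimates) and `n_degenerate`.
#' @export
bootstrap_pf <- function(levels, n_correct, n_trials, B = 200,
                         with_lapse = TRUE, target = 0.75, level = 0.95,
                         seed = 1) {
  p_hat <- n_correct / n_trials
  samples <- withr::with_seed(seed, {
    out <- vector("list", B)
    for (b in seq_len(B)) {
      cb <- stats::rbinom(length(levels), n_trials, p_hat)
      fit <- tryCatch(fit_sdt(levels, cb, n_trials, with_lapse = with_lapse),
                      error = function(e) NULL)
      if (is.null(fit)) next
      th <- tryCatch(sdt_threshold(fit$params, target), error = function(e) NA_real_)
      out[[b]] <- data.frame(g = fit$params$g, tau = fit$params$tau,
                             lambda = fit$params$lambda, threshold = th)
    }
    do.call(rbind, out)
  })
  n_degenerate <- B - NROW(samples)
  if (NROW(samples) == 0)
    return(list(ci = NULL, samples = NULL, n_degenerate = n_degenerate))
  alpha <- (1 - level) / 2
  ci <- do.call(rbind, lapply(names(samples), function(q) {
    v <- samples[[q]][is.finite(samples[[q]])]
    data.frame(quantity = q,
               lower = stats::quantile(v, alpha, names = FALSE),
               upper = stats::quantile(v, 1 - alpha, names = FALSE))
  }))
  list(ci = ci, samples = samples, n_degenerate = n_degenerate)
}

.check_trials <- function(trials, need = c("response")) {
  if (NROW(trials) == 0) stop("no trials to fit")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trials are missing columns: ", paste(missing, collapse = ", "))
  if (!all(trials$response %in% c("L", "R")))
    stop("response must be 'L' or 'R'")
  invisible(trials)
}

#' Fit the one-stage model to binary-choice trials
#'
#' Per-trial Bernoulli maximum likelihood of the left/right-oblique responses
#' under [ic1_prob_r()], over `g1` and `p1` (plus `g2` and `tau2` with
#' `divisive = TRUE`). Start points form a grid over gains scaled to the
#' feature magnitudes and exponents 0.5, 1, 2. On data where the global
#' contrast is constant across trials, the divisive and additive fits make
#' identical predictions (the denominator is absorbed into the gain).
#'
#' @param trials Data frame with columns `L_R`, `L_L`, `response` ("L"/"R")
#'   and, for the divisive variant, `C`.
#' @param divisive Include divisive contrast normalization (default FALSE).
#' @return A `fit_result` with `params` (`g1`, `p1`, `g2`, `tau2`), `K` = 2 or
#'   4, `n` = number of trials.
#' @export
fit_ic1 <- function(trials, divisive = FALSE) {
  .check_trials(trials, c("L_R", "L_L", "response", if (divisive) "C"))
  y <- as.integer(trials$response == "R")
  feat <- trials[, c("L_R", "L_L", if (divisive) "C"), drop = FALSE]
  if (!divisive) feat$C <- 0
  nll <- function(par) {
    g1 <- exp(par[1]); p1 <- exp(par[2])
    g2 <- if (divisive) exp(par[3]) else 0
    tau2 <- if (divisive) exp(par[4]) else 1
    p <- .clamp_p(stats::pnorm(ic1_u(feat, g1, p1, g2 = g2, tau2 = tau2)))
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  lscale <- stats::median(pmax(feat$L_R, feat$L_L))
  if (!is.finite(lscale) || lscale <= 0) lscale <- 1
  starts <- expand.grid(log_g1 = log(c(0.3, 1, 3) / lscale),
                        log_p1 = log(c(0.5, 1, 2)))
  lower <- c(log(1e-6), log(0.1)); upper <- c(log(1e6), log(10))
  if (divisive) {
    starts <- merge(starts, expand.grid(log_g2 = log(10^seq(-3, 1, length.out = 5)),
                                        log_tau2 = log(1)))
    lower <- c(lower, log(1e-6), log(0.1)); upper <- c(upper, log(1e4), log(10))
  }
  ms <- .multistart(nll, starts, lower, upper)
  par <- ms$best$par
  params <- list(g1 = exp(par[1]), p1 = exp(par[2]),
                 g2 = if (divisive) exp(par[3]) else 0,
                 tau2 = if (divisive) exp(par[4]) else 1)
  .fit_result("ic1", params, logL = -ms$best$value,
              K = if (divisive) 4L else 2L, n = length(y),
              converged = ms$best$convergence == 0, start_points = ms$starts)
}

# Stack the convolution values of every trial's four pooling half-discs into
# matrices (pixels x trials) for one DOG kernel, so pooled responses for any
# p1 come from vectorized column means.
.ic2_stack <- function(images, kernel) {
  f1 <- .ic2_field(images[[1]], kernel)
  idx <- lapply(f1$halves, which)
  stack <- lapply(idx, function(ix) {
    m <- matrix(0, length(ix), length(images))
    m[, 1] <- f1$conv[ix]
    m
  })
  if (length(images) > 1) {
    for (t in 2:length(images)) {
      conv <- EBImage::filter2(images[[t]]$pixels - 0.5, kernel$weights, boundary = 0)
      for (h in names(idx)) stack[[h]][, t] <- conv[idx[[h]]]
    }
  }
  stack
}

# Pooled L_R_ON/OFF, L_L_ON/OFF per trial for a given p1 (rectify-then-pool).
.ic2_pool_matrix <- function(stack, p1) {
  pool1 <- function(m) colMeans(pmax(m, 0)^p1)
  pool0 <- function(m) colMeans(pmax(-m, 0)^p1)
  cbind(L_R_ON  = abs(pool1(stack$rp) - pool1(stack$rm)),
        L_R_OFF = abs(pool0(stack$rp) - pool0(stack$rm)),
        L_L_ON  = abs(pool1(stack$lp) - pool1(stack$lm)),
        L_L_OFF = abs(pool0(stack$lp) - pool0(stack$lm)))
}

.ic2_pool_matrix_poolfirst <- function(stack, p1) {
  dr <- colMeans(stack$rp) - colMeans(stack$rm)
  dl <- colMeans(stack$lp) - colMeans(stack$lm)
  cbind(L_R_ON = pmax(dr, 0)^p1, L_R_OFF = pmax(-dr, 0)^p1,
        L_L_ON = pmax(dl, 0)^p1, L_L_OFF = pmax(-dl, 0)^p1)
}

# Negative log-likelihood of responses given pooled channel matrix.
.ic2_nll_pools <- function(pools, y, g2, p2) {
  u <- (g2 * pools[, "L_R_ON"])^p2 + (g2 * pools[, "L_R_OFF"])^p2 -
       (g2 * pools[, "L_L_ON"])^p2 - (g2 * pools[, "L_L_OFF"])^p2
  p <- .clamp_p(stats::pnorm(u))
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit the two-stage model to binary-choice trials
#'
#' For each surround-to-centre ratio on `rho_grid`, every stimulus is
#' pre-filtered once with that kernel; the remaining parameters
#' (`p1`, `p2`, `g2`) are then maximized by bounded local search. The search is
#' profiled: for a candidate `p1` the pooled channel responses of all trials
#' are computed in one vectorized pass and `(p2, g2)` are optimized from a grid
#' of start points (`p2` in 0.5/1/2, `g2` in five log steps from 1e-3 to 10);
#' `p1` itself starts on the grid 0.5/1/2 and is refined by golden-section
#' search around the best grid value. The best ratio is selected by profiled
#' likelihood; if it lands on an end of `rho_grid`, the grid is automatically
#' extended one step at a time (down to 0, up to `rho_max`) until the optimum
#' is interior.
#'
#' @param trials Data frame with a `response` column ("L"/"R"), one row per
#'   stimulus in `images`.
#' @param images List of `stimulus_image` objects, aligned with `trials`.
#' @param rho_grid Candidate surround-to-centre amplitude ratios.
#' @param sigma_c,support_halfwidth First-stage kernel geometry, see
#'   [build_dog()].
#' @param rectify_order Pooling order, see [ic2_channel_pools()].
#' @param rho_max Upper limit for automatic grid extension.
#' @return A `fit_result` with `params` (`rho_ie`, `p1`, `p2`, `g2` plus the
#'   kernel geometry), `K = 4`, `n` = number of trials, and a `profile` data
#'   frame of the per-ratio optima.
#' @export
fit_ic2 <- function(trials, images, rho_grid = seq(0.1, 0.4, by = 0.05),
                    sigma_c = 4, support_halfwidth = 16,
                    rectify_order = c("rectify_pool", "pool_rectify"),
                    rho_max = 1) {
  rectify_order <- match.arg(rectify_order)
  .check_trials(trials)
  if (length(images) != NROW(trials))
    stop("need exactly one stimulus image per trial")
  y <- as.integer(trials$response == "R")
  pool_fun <- if (rectify_order == "rectify_pool") .ic2_pool_matrix
              else .ic2_pool_matrix_poolfirst

  fit_one_rho <- function(rho) {
    kernel <- build_dog(rho, sigma_c, support_halfwidth)
    stack <- .ic2_stack(images, kernel)
    inner <- function(p1) {
      pools <- pool_fun(stack, p1)
      starts <- expand.grid(log_p2 = log(c(0.5, 1, 2)),
                            log_g2 = log(10^seq(-3, 1, length.out = 5)))
      ms <- .multistart(function(par) .ic2_nll_pools(pools, y, exp(par[2]), exp(par[1])),
                        starts, lower = c(log(0.1), log(1e-6)),
                        upper = c(log(10), log(1e4)))
      list(nll = ms$best$value, p2 = exp(ms$best$par[1]), g2 = exp(ms$best$par[2]),
           converged = ms$best$convergence == 0)
    }
    p1_grid <- c(0.5, 1, 2)
    grid_fits <- lapply(p1_grid, inner)
    best_i <- which.min(vapply(grid_fits, `[[`, numeric(1), "nll"))
    p1_best <- p1_grid[best_i]
    ref <- stats::optimize(function(lp1) inner(exp(lp1))$nll,
                           interval = log(c(max(0.1, p1_best / 3),
                                            min(10, p1_best * 3))),
                           tol = 1e-3)
    p1_hat <- exp(ref$minimum)
    fin <- inner(p1_hat)
    if (fin$nll > grid_fits[[best_i]]$nll) { p1_hat <- p1_best; fin <- grid_fits[[best_i]] }
    data.frame(rho_ie = rho, p1 = p1_hat, p2 = fin$p2, g2 = fin$g2,
               logL = -fin$nll, converged = fin$converged)
  }

  grid <- sort(unique(rho_grid))
  step <- if (length(grid) > 1) min(diff(grid)) else 0.05
  profile <- do.call(rbind, lapply(grid, fit_one_rho))
  repeat {
    best <- which.max(profile$logL)
    at_low <- profile$rho_ie[best] == min(profile$rho_ie) && min(profile$rho_ie) > 0
    at_high <- profile$rho_ie[best] == max(profile$rho_ie) &&
      max(profile$rho_ie) < rho_max
    if (at_low) {
      new_rho <- max(0, min(profile$rho_ie) - step)
    } else if (at_high) {
      new_rho <- min(rho_max, max(profile$rho_ie) + step)
    } else break
    profile <- rbind(profile, fit_one_rho(new_rho))
    profile <- profile[order(profile$rho_ie), ]
  }
  if (!any(profile$converged)) stop("two-stage fit failed to converge at every rho_ie")
  best <- profile[which.max(profile$logL), ]
  params <- list(rho_ie = best$rho_ie, p1 = best$p1, p2 = best$p2, g2 = best$g2,
                 sigma_c = sigma_c, support_halfwidth = support_halfwidth,
                 rectify_order = rectify_order)
  .fit_result("ic2", params, logL = best$logL, K = 4L, n = length(y),
              converged = best$converged,
              extra = list(profile = profile))
}
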