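# Maximum-likelihood fitting, thresholds, bootstrap, and BIC.

test_that("BIC formula and special cases", {
  expect_equal(bic(-100, 2, 250), -100 - log(250))
  expect_equal(bic(-50, 0, 1000), -50)
  # exponentiated difference is the posterior odds ratio
  expect_equal(exp(bic(-10, 1, 100) - bic(-12, 1, 100)), exp(2))
})

test_that("threshold inversion: closed form, chance target, gain scaling, lapse handling", {
  expect_equal(sdt_threshold(list(g = 1, tau = 1, lambda = 0)),
               2 * qnorm(0.75))
  expect_equal(sdt_threshold(list(g = 1, tau = 1), target = 0.5), 0)
  th1 <- sdt_threshold(list(g = 2, tau = 1.5))
  th2 <- sdt_threshold(list(g = 4, tau = 1.5))
  expect_equal(th1 / th2, 2)
  # with lapse, the inverted level reproduces the forward probability
  p <- list(g = 3, tau = 1.2, lambda = 0.06)
  x <- sdt_threshold(p, target = 0.8)
  expect_equal(sdt_pc(x, p$g, p$tau, p$lambda), 0.8)
  expect_error(sdt_threshold(list(g = 1, tau = 1, lambda = 0.1), target = 0.96),
               "ceiling")
})

test_that("psychometric fit refuses unidentifiable or degenerate data", {
  expect_error(fit_sdt(rep(0.5, 3), c(40, 41, 39), rep(50, 3)), "distinct")
  expect_error(fit_sdt(c(0.2, 0.5), c(50, 50), c(50, 50)), "degenerate")
  expect_error(fit_sdt(c(0.2, 0.5), c(0, 0), c(50, 50)), "degenerate")
})

test_that("psychometric fit recovers generating parameters and beats its start points", {
  set.seed(201)
  lv <- pi_u_ladder()
  n <- rep(200, length(lv))
  cc <- rbinom(length(lv), n, sdt_pc(lv, g = 3, tau = 1.5))
  fit <- fit_sdt(lv, cc, n, with_lapse = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$params$g, 3, tolerance = 0.25)
  expect_equal(fit$params$tau, 1.5, tolerance = 0.25)
  expect_equal(sdt_threshold(fit$params),
               sdt_threshold(list(g = 3, tau = 1.5)), tolerance = 0.1)
  # optimum is at least as good as every start point
  expect_true(all(-fit$logL <= fit$start_points$nll_start + 1e-8))
  # BIC field always equals the formula recomputed from its parts
  expect_equal(fit$BIC, bic(fit$logL, fit$K, fit$n))
})

test_that("with- and without-lapse fits agree on the threshold for lapse-free data", {
  set.seed(202)
  lv <- pi_u_ladder()
  n <- rep(100, length(lv))
  cc <- rbinom(length(lv), n, sdt_pc(lv, g = 3, tau = 1.5))
  th_l <- sdt_threshold(fit_sdt(lv, cc, n, with_lapse = TRUE)$params)
  th_0 <- sdt_threshold(fit_sdt(lv, cc, n, with_lapse = FALSE)$params)
  b <- bootstrap_pf(lv, cc, n, B = 100, seed = 7)
  ci <- b$ci[b$ci$quantity == "threshold", ]
  expect_gte(th_0, ci$lower)
  expect_lte(th_0, ci$upper)
  expect_lt(abs(th_l - th_0), 0.05)
})

test_that("bootstrap flags degenerate resamples instead of failing", {
  # observed proportions of 1 at every level resample to all-correct datasets
  b <- bootstrap_pf(c(0.1, 0.9), c(50, 50), c(50, 50), B = 20, seed = 3)
  expect_equal(b$n_degenerate, 20)
  expect_null(b$ci)
})

test_that("one-stage fit recovers generating parameters from simulated choices", {
  set.seed(203)
  n <- 400
  feats <- data.frame(L_R = runif(n, 0, 0.03), L_L = runif(n, 0, 0.03),
                      C = runif(n, 0.05, 0.15))
  p_r <- ic1_prob_r(feats, g1 = 60, p1 = 1.2)
  trials <- cbind(feats, response = ifelse(runif(n) < p_r, "R", "L"))
  fit <- fit_ic1(trials)
  expect_true(fit$converged)
  expect_equal(fit$K, 2L)
  expect_equal(fit$n, n)
  expect_equal(fit$params$p1, 1.2, tolerance = 0.3)
  expect_equal(log(fit$params$g1), log(60), tolerance = 0.15)
  expect_error(fit_ic1(trials[0, ]), "no trials")
})

test_that("divisive and additive one-stage fits predict identically on contrast-constant data", {
  set.seed(204)
  n <- 300
  feats <- data.frame(L_R = runif(n, 0, 0.03), L_L = runif(n, 0, 0.03),
                      C = rep(0.1, n))   # contrast never varies
  p_r <- ic1_prob_r(feats, g1 = 60, p1 = 1)
  trials <- cbind(feats, response = ifelse(runif(n) < p_r, "R", "L"))
  f_add <- fit_ic1(trials, divisive = FALSE)
  f_div <- fit_ic1(trials, divisive = TRUE)
  pred_add <- ic1_prob_r(feats, f_add$params$g1, f_add$params$p1)
  pred_div <- ic1_prob_r(feats, f_div$params$g1, f_div$params$p1,
                         f_div$params$g2, f_div$params$tau2)
  expect_equal(pred_div, pred_add, tolerance = 0.02)
  expect_lt(abs(f_div$logL - f_add$logL), 0.5)
})

test_that("two-stage fit recovers the surround ratio and extends an endpoint grid", {
  stim <- tiny_masking_set()
  gen <- ic2_observer(rho_ie = 0.25, p1 = 1, p2 = 1, g2 = 4)
  trials <- simulate_responses(gen, stim$design, stim$stimuli, seed = 31)
  fit <- fit_ic2(trials, stim$stimuli, rho_grid = c(0.2, 0.25, 0.3))
  expect_true(fit$converged)
  expect_equal(fit$K, 4L)
  expect_lte(abs(fit$params$rho_ie - 0.25), 0.05)
  expect_equal(fit$BIC, bic(fit$logL, fit$K, fit$n))
  # the profiled optimum beats every profiled grid point by construction
  expect_true(all(fit$logL >= fit$profile$logL - 1e-8))
  # endpoint rule: a generator below the grid floor pulls the grid downward
  gen_lo <- ic2_observer(rho_ie = 0.05, p1 = 1, p2 = 1, g2 = 2)
  tr_lo <- simulate_responses(gen_lo, stim$design, stim$stimuli, seed = 32)
  fit_lo <- fit_ic2(tr_lo, stim$stimuli, rho_grid = c(0.1, 0.15, 0.2))
  expect_lt(min(fit_lo$profile$rho_ie), 0.1)
})

test_that("two-stage fit validates its inputs", {
  stim <- tiny_masking_set()
  trials <- stim$design
  trials$response <- "R"
  expect_error(fit_ic2(trials[1:3, ], stim$stimuli), "one stimulus image per trial")
})
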