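# Observer models: SDT psychometric function, one-stage and two-stage models.

test_that("SDT psychometric function: chance at zero, closed-form interior point, lapse ceiling", {
  expect_equal(sdt_pc(0, g = 2, tau = 1.7), 0.5)
  # g*x = 1 gives Phi(1/2) regardless of tau
  for (tau in c(0.5, 1, 2)) expect_equal(sdt_pc(0.25, g = 4, tau = tau), pnorm(0.5))
  expect_equal(sdt_pc(1e9, g = 1, tau = 1, lambda = 0.1), 0.95)
  expect_error(sdt_pc(-1, 1, 1))
  # strictly increasing in x
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(sdt_pc(x, 1.5, 2)) > 0))
})

test_that("image-computable SDT discriminability: additive special case and divisive form", {
  expect_equal(ic_sdt_dprime(0.3, 0.5, g1 = 2, tau1 = 1.3, g2 = 0),
               (2 * 0.3)^1.3)
  expect_equal(ic_sdt_dprime(1, 1, 1, 1, 1, 1), 0.5)   # 1 / (1 + 1)
  expect_equal(ic_sdt_dprime(0, 0.5, 2, 1.3, 1, 1), 0)
  # strictly decreasing in contrast for the divisive form
  C <- seq(0, 2, by = 0.1)
  d <- ic_sdt_dprime(0.5, C, 2, 1, g2 = 3, tau2 = 2)
  expect_true(all(diff(d) < 0))
})

test_that("one-stage model: symmetry, mirror antisymmetry, and g2 = 0 reduction", {
  f_sym <- list(L_R = 0.2, L_L = 0.2, C = 0.1)
  expect_equal(ic1_prob_r(f_sym, 3, 1.5), 0.5)
  f <- list(L_R = 0.3, L_L = 0.1, C = 0.1)
  f_mir <- list(L_R = 0.1, L_L = 0.3, C = 0.1)
  expect_equal(ic1_prob_r(f, 3, 1.5) + ic1_prob_r(f_mir, 3, 1.5), 1)
  # divisive variant with g2 = 0 equals the additive variant exactly
  expect_equal(ic1_u(f, 3, 1.5, g2 = 0), ic1_u(f, 3, 1.5))
})

test_that("one-stage model nests the image-computable SDT model on balanced stimuli", {
  img <- small_ltb(pi_u = 0.5, seed = 13)
  f <- measure_features(img)
  expect_lt(f$L_L, 1e-12)
  g1 <- 60; tau1 <- 1.4
  pc_sdt <- pnorm(ic_sdt_dprime(f$L_R, f$C, g1, tau1) / 2)
  pc_ic1 <- ic1_prob_r(f, g1 / 2^(1 / tau1), tau1)
  expect_equal(pc_ic1, pc_sdt, tolerance = 1e-12)
  # and with matched divisive denominators (the same gain rescaling carries over)
  g2 <- 5; tau2 <- 2
  pc_sdt_div <- pnorm(ic_sdt_dprime(f$L_R, f$C, g1, tau1, g2, tau2) / 2)
  pc_ic1_div <- ic1_prob_r(f, g1 / 2^(1 / tau1), tau1, g2 = g2, tau2 = tau2)
  expect_equal(pc_ic1_div, pc_sdt_div, tolerance = 1e-12)
})

test_that("difference-of-Gaussians kernel: pure center at rho 0, DC zero crossing, OFF negation", {
  k0 <- build_dog(0, sigma_c = 4, support_halfwidth = 16)
  z <- -16:16
  expect_equal(k0$weights, exp(-outer(z^2, z^2, "+") / (2 * 16)))
  expect_gt(dog_dc_response(build_dog(0.25)), 0)
  expect_lt(dog_dc_response(build_dog(0.35)), 0)
  rhos <- seq(0, 0.5, by = 0.05)
  dc <- vapply(rhos, function(r) dog_dc_response(build_dog(r)), numeric(1))
  expect_true(all(diff(dc) < 0))   # strictly decreasing in rho
  rb <- dog_balanced_rho()
  expect_gt(rb, 0.25); expect_lt(rb, 0.35)
  expect_lt(abs(dog_dc_response(build_dog(rb))), 1e-10)
  # OFF kernel is the negated ON kernel: same DC magnitude, opposite sign
  expect_equal(sum(-build_dog(0.2)$weights), -dog_dc_response(build_dog(0.2)))
  expect_error(build_dog(0.2, sigma_c = 4, support_halfwidth = 10), "support")
})

test_that("two-stage decision variable matches a brute-force pixel-level oracle", {
  img <- make_ltb(ltb_spec(pi_u = 0.5, n_p = 4, A = 0.25, image_size = 64,
                           radius = 28, taper_width = 4, seed = 5))
  n <- 64; hw <- 12; sc <- 3; ss <- 6; rho <- 0.2; p1 <- 1.3
  dev <- img$pixels - 0.5
  conv <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    s <- 0
    for (a in -hw:hw) for (b in -hw:hw) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= n)
        s <- s + dev[ii, jj] *
          (exp(-(a^2 + b^2) / (2 * sc^2)) - rho * exp(-(a^2 + b^2) / (2 * ss^2)))
    }
    conv[i, j] <- s
  }
  g <- img$geometry
  pool <- g$disc & (g$r <= g$radius - hw)
  pl <- function(mask, v) mean(v[mask])
  po <- function(x) pmax(x, 0)^p1
  o <- list(
    L_R_ON  = abs(pl(pool & g$d_r > 0, po(conv)) - pl(pool & g$d_r < 0, po(conv))),
    L_R_OFF = abs(pl(pool & g$d_r > 0, po(-conv)) - pl(pool & g$d_r < 0, po(-conv))),
    L_L_ON  = abs(pl(pool & g$d_l > 0, po(conv)) - pl(pool & g$d_l < 0, po(conv))),
    L_L_OFF = abs(pl(pool & g$d_l > 0, po(-conv)) - pl(pool & g$d_l < 0, po(-conv))))
  kernel <- build_dog(rho, sigma_c = sc, support_halfwidth = hw)
  pools <- ic2_channel_pools(img, kernel, p1)
  for (nm in names(o)) expect_equal(pools[[nm]], o[[nm]], tolerance = 1e-10)
  u_pkg <- ic2_u(pools, g2 = 1.7, p2 = 0.9)
  u_oracle <- (1.7 * o$L_R_ON)^0.9 + (1.7 * o$L_R_OFF)^0.9 -
    (1.7 * o$L_L_ON)^0.9 - (1.7 * o$L_L_OFF)^0.9
  expect_equal(u_pkg, u_oracle, tolerance = 1e-10)
})

test_that("two-stage model: mirror antisymmetry and chance on mirror-symmetric input", {
  img <- small_ltb(pi_u = 0.5, seed = 14)
  params <- list(rho_ie = 0.25, p1 = 1, p2 = 1, g2 = 3,
                 sigma_c = 4, support_halfwidth = 16)
  p <- ic2_prob_r(img, params)
  mir <- img; mir$pixels <- img$pixels[, ncol(img$pixels):1]
  expect_equal(ic2_prob_r(mir, params) + p, 1, tolerance = 1e-10)
  expect_equal(ic2_prob_r(uniform_disc(), params), 0.5)
})

test_that("DC-balanced two-stage model ignores a uniform luminance offset", {
  img <- small_ltb(pi_u = 0.5, seed = 15)
  rb <- dog_balanced_rho(4, 16)
  params <- list(rho_ie = rb, p1 = 1, p2 = 1, g2 = 5)
  shifted <- img; shifted$pixels <- img$pixels + 0.05
  expect_equal(ic2_prob_r(shifted, params), ic2_prob_r(img, params),
               tolerance = 1e-8)
})

test_that("pool-then-rectify ordering splits each diagonal into one active channel", {
  img <- small_ltb(pi_u = 0.5, seed = 16)
  kernel <- build_dog(0.2)
  a <- ic2_channel_pools(img, kernel, p1 = 1.4, rectify_order = "pool_rectify")
  # the signed half-disc difference feeds exactly one of ON/OFF per diagonal
  expect_equal(min(a$L_R_ON, a$L_R_OFF), 0)
  expect_equal(min(a$L_L_ON, a$L_L_OFF), 0)
  expect_true(all(unlist(a) >= 0))
  # mirror antisymmetry of the decision variable holds in this ordering too
  mir <- img; mir$pixels <- img$pixels[, ncol(img$pixels):1]
  b <- ic2_channel_pools(mir, kernel, p1 = 1.4, rectify_order = "pool_rectify")
  expect_equal(ic2_u(a, 2, 1), -ic2_u(b, 2, 1), tolerance = 1e-10)
})
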