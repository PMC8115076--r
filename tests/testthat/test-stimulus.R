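# Texture-disc and step-edge stimulus construction.

test_that("LTB pixels stay in range with mid-gray background and exact Michelson contrast", {
  for (A in c(0.1, 0.25, 0.4)) {
    img <- small_ltb(pi_u = 0.5, A = A, seed = 11)
    expect_true(all(img$pixels >= 0 & img$pixels <= 1))
    expect_true(all(img$pixels[!img$disc_mask] == 0.5))
    expect_equal(michelson_contrast(img), 2 * A)
    expect_equal(range(img$pixels), c(0.5 - A, 0.5 + A))
  }
})

test_that("micropattern counts respect sides, quadrants and polarity balance", {
  img <- small_ltb(pi_u = 0.5, n_p = 16, seed = 4)
  cc <- img$micropattern_centers
  expect_equal(nrow(cc), 32)
  side <- sign(cc$cy - cc$cx)  # right-oblique boundary coordinate
  expect_equal(as.integer(table(side)), c(16L, 16L))
  # equal white and black totals over the whole stimulus
  expect_equal(sum(cc$polarity == 1), sum(cc$polarity == -1))
  # each polarity class split equally over the two quadrants of each side
  tab <- table(cc$quadrant, cc$polarity)
  expect_true(all(tab[c("s+a+", "s+a-"), "1"] == tab["s+a+", "1"]))
  expect_true(all(tab[c("s-a+", "s-a-"), "-1"] == tab["s-a+", "-1"]))
})

test_that("fully unbalanced texture segregates polarities by side; phase flips them", {
  img <- make_ltb(ltb_spec(pi_u = 1, n_p = 16, image_size = 96, phase = 0, seed = 2))
  cc <- img$micropattern_centers
  side <- sign(cc$cy - cc$cx)
  expect_true(all(cc$polarity[side > 0] == 1))
  expect_true(all(cc$polarity[side < 0] == -1))
  img180 <- make_ltb(ltb_spec(pi_u = 1, n_p = 16, image_size = 96, phase = 180, seed = 2))
  cc180 <- img180$micropattern_centers
  side180 <- sign(cc180$cy - cc180$cx)
  expect_true(all(cc180$polarity[side180 > 0] == -1))
})

test_that("anti-diagonal luminance difference is zero by construction for all seeds", {
  for (s in 1:8) {
    img <- small_ltb(pi_u = 0.5, seed = s)
    expect_lt(luminance_diffs(img)$L_L, 1e-12)
  }
  # fully balanced case: no cue across either diagonal
  img0 <- small_ltb(pi_u = 0, seed = 3)
  ld <- luminance_diffs(img0)
  expect_lt(ld$L_R, 1e-12)
  expect_lt(ld$L_L, 1e-12)
})

test_that("same spec and seed give a bit-identical image; different seeds differ", {
  a <- small_ltb(seed = 9)
  b <- small_ltb(seed = 9)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$micropattern_centers, b$micropattern_centers)
  expect_false(identical(a$pixels, small_ltb(seed = 10)$pixels))
})

test_that("RMS contrast scales as sqrt(n_p) at fixed amplitude", {
  n_seeds <- 30
  r64 <- mean(vapply(seq_len(n_seeds), function(s)
    rms_contrast(make_ltb(ltb_spec(0.5, n_p = 64, seed = s))), numeric(1)))
  r16 <- mean(vapply(seq_len(n_seeds), function(s)
    rms_contrast(make_ltb(ltb_spec(0.5, n_p = 16, seed = s))), numeric(1)))
  expect_equal(r64 / r16, 2, tolerance = 0.02)
})

test_that("requested proportion unbalanced snaps to a feasible multiple of 4 patterns", {
  sp <- ltb_spec(pi_u = 0.3, n_p = 32)
  expect_equal(sp$n_u, 8)           # 0.3 * 32 = 9.6 -> nearest multiple of 4
  expect_equal(sp$pi_u_snapped, 0.25)
  expect_equal(sp$pi_u, 0.3)        # request is preserved in metadata
  expect_equal(ltb_spec(pi_u = 0.125, n_p = 32)$pi_u_snapped, 0.125)
  expect_error(ltb_spec(pi_u = 0.5, n_p = 30), "multiple")
})

test_that("infeasible micropattern density fails with an informative error", {
  expect_error(
    make_ltb(ltb_spec(0.5, n_p = 64, image_size = 64), max_attempts = 200),
    "placement failed")
})

test_that("step boundary: contrast, phase rotation symmetry, and zero-contrast disc", {
  lsb <- small_lsb(c_m = 0.02)
  interior <- lsb$geometry$taper == 1
  v <- lsb$pixels[interior]
  expect_equal((max(v) - min(v)) / (max(v) + min(v)), 0.02)
  # phase 180 image is the 180-degree rotation of phase 0
  l180 <- small_lsb(c_m = 0.02, phase = 180)
  n <- nrow(lsb$pixels)
  expect_equal(l180$pixels, lsb$pixels[n:1, n:1])
  # zero contrast: uniform mid-gray disc
  expect_true(all(uniform_disc()$pixels == 0.5))
})

test_that("contrast ladder spans 11 log steps and pi_u ladder 9 even steps", {
  expect_equal(pi_u_ladder(), seq(0, 1, by = 0.125))
  cl <- lsb_contrast_ladder()
  expect_length(cl, 11)
  expect_equal(cl[1], 10^-2.7)
  expect_equal(cl[11], 10^-1.7)
  expect_equal(diff(log10(cl)), rep(0.1, 10))
})

test_that("composition: neutral identity, additive superposition, validation", {
  ltb <- ltb_spec(0.25, n_p = 16, image_size = 96, seed = 5)
  neu <- compose_stimulus(composite_spec(ltb, relation = "neu"))
  expect_equal(neu$pixels, make_ltb(ltb)$pixels)
  lsb <- lsb_spec(0.02, image_size = 96)
  con <- compose_stimulus(composite_spec(ltb, lsb, relation = "con_0"))
  expect_equal(con$pixels,
               pmin(pmax(make_ltb(ltb)$pixels + make_lsb(lsb)$pixels - 0.5, 0), 1))
  expect_equal(con$n_clipped, 0L)
  # clipping is counted when deviations exceed the range
  big <- compose_stimulus(composite_spec(ltb_spec(0.25, n_p = 16, A = 0.5, image_size = 96, seed = 5),
                                         lsb_spec(0.5, image_size = 96),
                                         relation = "con_0"))
  expect_gt(big$n_clipped, 0)
  expect_true(all(big$pixels >= 0 & big$pixels <= 1))
  # relation consistency checks
  expect_error(composite_spec(ltb, lsb, relation = "inc"), "orthogonal")
  expect_error(composite_spec(ltb, lsb_spec(0.02, image_size = 96,
                                            orientation = "left_oblique"),
                              relation = "con_0"), "matching orientations")
  expect_error(composite_spec(ltb, lsb, relation = "con_180"), "phases")
  expect_error(composite_spec(ltb, lsb_spec(0.02, image_size = 128),
                              relation = "con_0"), "geometry")
})

test_that("incongruent composition creates a cue across both diagonals", {
  ltb <- ltb_spec(0.5, n_p = 16, image_size = 96, seed = 7, orientation = "right_oblique")
  lsb <- lsb_spec(0.02, image_size = 96, orientation = "left_oblique")
  inc <- compose_stimulus(composite_spec(ltb, lsb, relation = "inc"))
  ld <- luminance_diffs(inc)
  expect_gt(ld$L_R, 1e-4)
  expect_gt(ld$L_L, 1e-4)
})

test_that("opposite-phase masking reduces the cross-boundary luminance difference", {
  ltb <- ltb_spec(0.25, n_p = 16, image_size = 96, seed = 6)
  lsb0 <- lsb_spec(0.02, image_size = 96, phase = 0)
  lsb180 <- lsb_spec(0.02, image_size = 96, phase = 180)
  l_con0 <- luminance_diffs(compose_stimulus(composite_spec(ltb, lsb0, "con_0")))$L_R
  l_con180 <- luminance_diffs(compose_stimulus(composite_spec(ltb, lsb180, "con_180")))$L_R
  l_neu <- luminance_diffs(make_ltb(ltb))$L_R
  expect_lt(l_con180, l_con0)
  expect_gte(l_con0, l_neu)
  expect_lte(l_con180, l_neu)
})
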