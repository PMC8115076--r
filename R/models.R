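# Observer models: SDT psychometric function with power-law transducer,
# one-stage luminance-difference models with optional divisive contrast
# normalization, and the two-stage filter-rectify-filter model built on
# ON/OFF difference-of-Gaussians channels.

#' SDT psychometric function with power-law transducer
#'
#' Proportion correct for a single-interval two-alternative classification at
#' stimulus level `x`:
#' `P_C = lambda/2 + (1 - lambda) * Phi(d'/2)` with `d' = (g x)^tau`, where
#' `Phi` is the standard normal CDF, `g` a gain, `tau` the transducer exponent
#' and `lambda` the lapse probability (a stimulus-independent random response).
#'
#' @param x Stimulus level(s), non-negative.
#' @param g Gain (> 0), in reciprocal stimulus-level units.
#' @param tau Transducer exponent (> 0).
#' @param lambda Lapse probability in \[0, 0.1\].
#' @return Proportion correct, same length as `x`.
#' @export
sdt_pc <- function(x, g, tau, lambda = 0) {
  stopifnot(all(x >= 0), g > 0, tau > 0, lambda >= 0, lambda <= 0.1)
  lambda / 2 + (1 - lambda) * stats::pnorm(((g * x)^tau) / 2)
}

#' Discriminability of the image-computable SDT model
#'
#' `d' = (g1 L)^tau1 / (1 + (g2 C)^tau2)`: the transduced cross-boundary
#' luminance difference `L`, divisively normalized by the global RMS contrast
#' `C`. With `g2 = 0` the denominator is 1 and the model reduces to the purely
#' additive form `d' = (g1 L)^tau1`.
#'
#' @param L Absolute luminance difference across the boundary diagonal (>= 0).
#' @param C Global RMS contrast (>= 0).
#' @param g1,tau1 First-stage gain and exponent (> 0).
#' @param g2,tau2 Contrast-normalization gain (>= 0; 0 disables) and exponent.
#' @return d-prime value(s); proportion correct is `Phi(d'/2)`.
#' @export
ic_sdt_dprime <- function(L, C, g1, tau1, g2 = 0, tau2 = 1) {
  stopifnot(all(L >= 0), all(C >= 0), g1 > 0, tau1 > 0, g2 >= 0, tau2 > 0)
  (g1 * L)^tau1 / (1 + (g2 * C)^tau2)
}

#' One-stage model decision variable and response probability
#'
#' The one-stage (IC-1) model compares transduced luminance differences across
#' the two oblique diagonals:
#' `u = (g1 L_R)^p1 - (g1 L_L)^p1`, and responds "right-oblique" with
#' probability `Phi(u)`. With `g2 > 0` both terms are divided by
#' `1 + (g2 C)^tau2` (divisive contrast normalization). On stimuli whose
#' anti-diagonal luminance difference is zero this model coincides with the
#' image-computable SDT model up to a gain rescaling.
#'
#' @param features A list or one-row data frame with `L_R`, `L_L` and (if
#'   `g2 > 0`) `C`; see [measure_features()].
#' @param g1,p1 Gain and exponent of the transducer (> 0).
#' @param g2,tau2 Optional divisive contrast-normalization parameters.
#' @return `ic1_u`: the decision variable; `ic1_prob_r`: `Phi(u)`.
#' @export
ic1_u <- function(features, g1, p1, g2 = 0, tau2 = 1) {
  stopifnot(g1 > 0, p1 > 0, g2 >= 0, tau2 > 0)
  den <- if (g2 > 0) 1 + (g2 * features$C)^tau2 else 1
  ((g1 * features$L_R)^p1 - (g1 * features$L_L)^p1) / den
}

#' @rdname ic1_u
#' @export
ic1_prob_r <- function(features, g1, p1, g2 = 0, tau2 = 1) {
  stats::pnorm(ic1_u(features, g1, p1, g2 = g2, tau2 = tau2))
}

#' Difference-of-Gaussians first-stage kernel
#'
#' `h(x, y) = c(x, y) - rho_ie * s(x, y)` on a discrete square support, where
#' centre `c` and surround `s` are unit-peak isotropic Gaussians with
#' `sigma_s = 2 * sigma_c`. `rho_ie` is the surround-to-centre amplitude ratio
#' (0 = no surround). The OFF kernel is the negated ON kernel. The DC response
#' (the filter's response to a uniform unit input) is the sum of the weights
#' and decreases strictly in `rho_ie`; [dog_balanced_rho()] returns the ratio
#' at which it is exactly zero for the given support.
#'
#' @param rho_ie Surround-to-centre amplitude ratio (>= 0).
#' @param sigma_c Centre Gaussian SD in pixels. The default 4 matches the
#'   radius of the default texture micropatterns (2 * sigma_mp).
#' @param support_halfwidth Half-width of the square support in pixels; must be
#'   at least `2 * sigma_s = 4 * sigma_c`.
#' @return An object of class `dog_kernel` with fields `weights` (matrix),
#'   `rho_ie`, `sigma_c`, `sigma_s`, `support_halfwidth`.
#' @export
build_dog <- function(rho_ie, sigma_c = 4, support_halfwidth = 16) {
  stopifnot(rho_ie >= 0, sigma_c > 0)
  sigma_s <- 2 * sigma_c
  if (support_halfwidth < 2 * sigma_s)
    stop("support_halfwidth must be at least 2 * sigma_s = ", 2 * sigma_s)
  z <- -support_halfwidth:support_halfwidth
  r2 <- outer(z^2, z^2, "+")
  w <- exp(-r2 / (2 * sigma_c^2)) - rho_ie * exp(-r2 / (2 * sigma_s^2))
  structure(list(weights = w, rho_ie = rho_ie, sigma_c = sigma_c,
                 sigma_s = sigma_s, support_halfwidth = support_halfwidth),
            class = "dog_kernel")
}

#' @rdname build_dog
#' @param kernel A `dog_kernel`.
#' @export
dog_dc_response <- function(kernel) {
  stopifnot(inherits(kernel, "dog_kernel"))
  sum(kernel$weights)
}

#' @rdname build_dog
#' @export
dog_balanced_rho <- function(sigma_c = 4, support_halfwidth = 16) {
  z <- -support_halfwidth:support_halfwidth
  r2 <- outer(z^2, z^2, "+")
  sum(exp(-r2 / (2 * sigma_c^2))) / sum(exp(-r2 / (2 * (2 * sigma_c)^2)))
}

# Convolve image deviations from mid-gray with the ON kernel (zero padding)
# and return the response field with the four pooling half-masks. Pooling is
# restricted to the disc interior eroded by the kernel half-width so that
# zero-padding edge artifacts never enter the pools.
.ic2_field <- function(image, kernel) {
  g <- image$geometry
  conv <- EBImage::filter2(image$pixels - 0.5, kernel$weights, boundary = 0)
  pool <- g$disc & (g$r <= g$radius - kernel$support_halfwidth)
  if (!any(pool)) stop("kernel support too large for this disc: empty pool mask")
  list(conv = conv,
       halves = list(rp = pool & g$d_r > 0, rm = pool & g$d_r < 0,
                     lp = pool & g$d_l > 0, lm = pool & g$d_l < 0))
}

# Pool one rectified channel over two half-discs and return |difference|.
.pool_pair <- function(v_plus, v_minus, p1, rectify_order) {
  if (rectify_order == "rectify_pool") {
    on  <- abs(mean(pmax(v_plus, 0)^p1) - mean(pmax(v_minus, 0)^p1))
    off <- abs(mean(pmax(-v_plus, 0)^p1) - mean(pmax(-v_minus, 0)^p1))
  } else {
    d <- mean(v_plus) - mean(v_minus)
    on  <- max(d, 0)^p1
    off <- max(-d, 0)^p1
  }
  c(on = on, off = off)
}

#' Pooled ON/OFF channel responses of the two-stage model
#'
#' First stage: the image's deviations from mid-gray are convolved with the ON
#' difference-of-Gaussians kernel (the OFF channel is the negated kernel,
#' equivalently the rectified negative lobe of the same convolution), each
#' output is half-wave rectified and raised pointwise to the exponent `p1`.
#' Second stage: each channel is pooled uniformly over the two half-discs
#' separated by each oblique diagonal (restricted to the disc interior eroded
#' by the kernel half-width), and the pooled response is the absolute
#' difference between the two halves. With
#' `rectify_order = "pool_rectify"` the half-disc means of the raw convolution
#' are taken first and the signed difference is rectified and exponentiated
#' afterwards (the alternative reading of "rectified with exponent p1").
#'
#' @param image A `stimulus_image`.
#' @param kernel A [build_dog()] kernel.
#' @param p1 First-stage rectification exponent (> 0).
#' @param rectify_order `"rectify_pool"` (default) or `"pool_rectify"`.
#' @return A list with non-negative pooled responses `L_R_ON`, `L_R_OFF`,
#'   `L_L_ON`, `L_L_OFF`.
#' @export
ic2_channel_pools <- function(image, kernel, p1,
                              rectify_order = c("rectify_pool", "pool_rectify")) {
  rectify_order <- match.arg(rectify_order)
  stopifnot(p1 > 0)
  f <- .ic2_field(image, kernel)
  r <- .pool_pair(f$conv[f$halves$rp], f$conv[f$halves$rm], p1, rectify_order)
  l <- .pool_pair(f$conv[f$halves$lp], f$conv[f$halves$lm], p1, rectify_order)
  list(L_R_ON = r[["on"]], L_R_OFF = r[["off"]],
       L_L_ON = l[["on"]], L_L_OFF = l[["off"]])
}

#' Two-stage model decision variable and response probability
#'
#' The two-stage (filter-rectify-filter) model's decision variable is
#' `u = (g2 L_R_ON)^p2 + (g2 L_R_OFF)^p2 - (g2 L_L_ON)^p2 - (g2 L_L_OFF)^p2`
#' over the pooled channel responses of [ic2_channel_pools()], and the
#' probability of a "right-oblique" response is `Phi(u)`. The model has four
#' free parameters: `rho_ie`, `p1`, `p2`, `g2`.
#'
#' @param pools Output of [ic2_channel_pools()].
#' @param g2,p2 Second-stage gain and exponent (> 0).
#' @return `ic2_u`: the decision variable.
#' @export
ic2_u <- function(pools, g2, p2) {
  stopifnot(g2 > 0, p2 > 0)
  (g2 * pools$L_R_ON)^p2 + (g2 * pools$L_R_OFF)^p2 -
    (g2 * pools$L_L_ON)^p2 - (g2 * pools$L_L_OFF)^p2
}

#' @rdname ic2_u
#' @param image A `stimulus_image`.
#' @param params List with `rho_ie`, `p1`, `p2`, `g2` and optionally
#'   `sigma_c`, `support_halfwidth`, `rectify_order`.
#' @export
ic2_prob_r <- function(image, params) {
  kernel <- build_dog(params$rho_ie,
                      sigma_c = params$sigma_c %||% 4,
                      support_halfwidth = params$support_halfwidth %||% 16)
  pools <- ic2_channel_pools(image, kernel, params$p1,
                             rectify_order = params$rectify_order %||% "rectify_pool")
  stats::pnorm(ic2_u(pools, params$g2, params$p2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
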