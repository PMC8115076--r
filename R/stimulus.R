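# Stimulus synthesis: micropattern texture discs (LTB), cosine-tapered step
# edges (LSB), and their congruent/incongruent superpositions.

.geom_env <- new.env(parent = emptyenv())

#' Disc geometry for a stimulus frame
#'
#' Precomputes (and caches) the coordinate fields shared by all stimuli of a
#' given frame size: pixel-centred Cartesian coordinates with the origin at the
#' image centre, the two oblique diagonal coordinates, the disc mask and the
#' raised-cosine edge taper. The right-oblique diagonal is the line running
#' from lower-left to upper-right (+45 deg from vertical); its signed
#' coordinate `d_r` is zero on that line. The left-oblique coordinate `d_l` is
#' zero on the orthogonal diagonal. For even frame sizes both coordinates take
#' integer values, so "on-diagonal" pixels are exactly identifiable.
#'
#' @param image_size Frame side length in pixels.
#' @param radius Disc radius in pixels. Default `image_size/2 - 4`, filling the
#'   frame with a small margin.
#' @param taper_width Width in pixels of the raised-cosine taper at the disc
#'   edge. Default `image_size/16`.
#' @return A list with coordinate matrices `cx`, `cy`, `r`, `d_r`, `d_l`, the
#'   logical `disc` mask (r <= radius), the `taper` field (1 in the interior,
#'   raised-cosine falloff over the outer `taper_width` pixels, 0 outside), and
#'   the scalars `image_size`, `radius`, `taper_width`.
#' @export
stim_geometry <- function(image_size = 256, radius = NULL, taper_width = NULL) {
  if (is.null(radius)) radius <- image_size / 2 - 4
  if (is.null(taper_width)) taper_width <- image_size / 16
  stopifnot(image_size >= 16, radius > taper_width, taper_width > 0,
            radius <= image_size / 2)
  key <- paste(image_size, radius, taper_width, sep = "|")
  hit <- .geom_env[[key]]
  if (!is.null(hit)) return(hit)
  n <- image_size
  cx <- matrix(rep(seq_len(n) - (n + 1) / 2, each = n), n, n)
  cy <- matrix(rep((n + 1) / 2 - seq_len(n), times = n), n, n)
  r <- sqrt(cx^2 + cy^2)
  taper <- ifelse(r <= radius - taper_width, 1,
                  ifelse(r <= radius,
                         0.5 * (1 + cos(pi * (r - (radius - taper_width)) / taper_width)),
                         0))
  g <- list(cx = cx, cy = cy, r = r,
            d_r = cy - cx, d_l = cy + cx,
            disc = r <= radius, taper = taper,
            image_size = image_size, radius = radius, taper_width = taper_width)
  .geom_env[[key]] <- g
  g
}

.check_orientation <- function(orientation) {
  match.arg(orientation, c("right_oblique", "left_oblique"))
}

.check_phase <- function(phase) {
  if (!phase %in% c(0, 180)) stop("phase must be 0 or 180 (degrees)")
  phase
}

#' Specification of a luminance texture boundary stimulus
#'
#' An LTB disc carries `n_p` non-overlapping Gaussian micropatterns on each
#' side of an oblique boundary. A proportion `pi_u` of the micropatterns on
#' each side are *unbalanced*: they have no same-polarity counterpart on the
#' opposite side, so they carry the luminance cue. The remaining micropatterns
#' come in balanced cross-boundary pairs and carry no net cue. The unbalanced
#' count `pi_u * n_p` must be a whole multiple of 4 so that every
#' polarity class can be split equally over the four disc quadrants, which
#' makes the luminance difference across the anti-diagonal exactly zero by
#' construction; a requested `pi_u` is snapped to the nearest feasible value
#' (recorded in the spec as `pi_u_snapped`).
#'
#' @param pi_u Requested proportion of unbalanced micropatterns, in \[0, 1\].
#' @param n_p Micropatterns per side; a positive multiple of 4 (16, 32 or 64
#'   in the experiments simulated here).
#' @param A Micropattern peak amplitude about the mid-gray background 0.5, in
#'   (0, 0.5\]. The stimulus Michelson contrast is `2 * A`.
#' @param sigma_mp Micropattern Gaussian SD in pixels; the blob is truncated to
#'   a circular footprint of radius `2 * sigma_mp` (an "8-pixel" dot for the
#'   default `sigma_mp = 2`).
#' @param orientation Boundary orientation, `"right_oblique"` (+45 deg from
#'   vertical) or `"left_oblique"` (-45 deg).
#' @param phase 0 or 180; which half is brighter. Phase 0 puts the white
#'   majority on the positive side of the boundary coordinate; phase 180 is the
#'   180-degree rotation of phase 0.
#' @param image_size,radius,taper_width Frame geometry, see [stim_geometry()].
#' @param seed Integer RNG seed controlling micropattern placement; the same
#'   spec and seed give a bit-identical image.
#' @return An object of class `ltb_spec`.
#' @export
ltb_spec <- function(pi_u, n_p = 32, A = 0.25, sigma_mp = 2,
                     orientation = "right_oblique", phase = 0,
                     image_size = 256, radius = NULL, taper_width = NULL,
                     seed = 1) {
  orientation <- .check_orientation(orientation)
  phase <- .check_phase(phase)
  stopifnot(length(pi_u) == 1, pi_u >= 0, pi_u <= 1,
            A > 0, A <= 0.5, sigma_mp > 0)
  if (n_p <= 0 || n_p %% 4 != 0)
    stop("n_p must be a positive multiple of 4 so that each quadrant holds equal counts")
  n_u <- round(pi_u * n_p / 4) * 4
  n_u <- min(max(n_u, 0L), n_p)
  if (is.null(radius)) radius <- image_size / 2 - 4
  if (is.null(taper_width)) taper_width <- image_size / 16
  structure(list(pi_u = pi_u, pi_u_snapped = n_u / n_p, n_u = n_u,
                 n_p = n_p, A = A, sigma_mp = sigma_mp,
                 orientation = orientation, phase = phase,
                 image_size = image_size, radius = radius,
                 taper_width = taper_width, seed = seed),
            class = "ltb_spec")
}

#' Specification of a luminance step boundary stimulus
#'
#' An LSB is an oblique step edge of Michelson contrast `c_m` about mid-gray,
#' multiplied by a cosine-tapered circular disc.
#'
#' @param c_m Michelson contrast in \[0, 1\].
#' @inheritParams ltb_spec
#' @return An object of class `lsb_spec`.
#' @export
lsb_spec <- function(c_m, orientation = "right_oblique", phase = 0,
                     image_size = 256, radius = NULL, taper_width = NULL) {
  orientation <- .check_orientation(orientation)
  phase <- .check_phase(phase)
  stopifnot(length(c_m) == 1, c_m >= 0, c_m <= 1)
  if (is.null(radius)) radius <- image_size / 2 - 4
  if (is.null(taper_width)) taper_width <- image_size / 16
  structure(list(c_m = c_m, orientation = orientation, phase = phase,
                 image_size = image_size, radius = radius,
                 taper_width = taper_width),
            class = "lsb_spec")
}

#' Specification of a texture-plus-step composite stimulus
#'
#' Describes the superposition of a target LTB and a masking LSB, in one of the
#' four masking relations: `"neu"` (no masker), `"con_0"` (congruent
#' orientation, phase-aligned), `"con_180"` (congruent orientation, opposite
#' phase) and `"inc"` (orthogonal orientations).
#'
#' @param ltb An [ltb_spec()].
#' @param lsb An [lsb_spec()], or `NULL` for `relation = "neu"`.
#' @param relation One of `"neu"`, `"con_0"`, `"con_180"`, `"inc"`.
#' @return An object of class `composite_spec`.
#' @export
composite_spec <- function(ltb, lsb = NULL, relation = c("neu", "con_0", "con_180", "inc")) {
  relation <- match.arg(relation)
  stopifnot(inherits(ltb, "ltb_spec"))
  if (relation == "neu") {
    if (!is.null(lsb)) stop("relation 'neu' requires lsb = NULL")
  } else {
    if (!inherits(lsb, "lsb_spec")) stop("relation '", relation, "' requires an lsb_spec")
    if (lsb$image_size != ltb$image_size || lsb$radius != ltb$radius ||
        lsb$taper_width != ltb$taper_width)
      stop("ltb and lsb must share the same frame geometry")
    same_ori <- lsb$orientation == ltb$orientation
    if (relation %in% c("con_0", "con_180") && !same_ori)
      stop("congruent relations require matching orientations")
    if (relation == "inc" && same_ori)
      stop("relation 'inc' requires orthogonal orientations")
    if (relation == "con_0" && lsb$phase != ltb$phase)
      stop("relation 'con_0' requires matching phases")
    if (relation == "con_180" && lsb$phase == ltb$phase)
      stop("relation 'con_180' requires phases differing by 180 degrees")
  }
  structure(list(ltb = ltb, lsb = lsb, relation = relation),
            class = "composite_spec")
}

.stimulus_image <- function(pixels, geometry, spec, centers = NULL, n_clipped = 0L) {
  structure(list(pixels = pixels, disc_mask = geometry$disc, spec = spec,
                 micropattern_centers = centers, geometry = geometry,
                 n_clipped = n_clipped),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image %dx%d, class '%s', range [%.4f, %.4f]>\n",
              nrow(x$pixels), ncol(x$pixels), class(x$spec)[1],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Circular micropattern footprint offsets and Gaussian stamp weights.
.mp_footprint <- function(sigma_mp) {
  rs <- ceiling(2 * sigma_mp)
  off <- expand.grid(di = -rs:rs, dj = -rs:rs)
  keep <- off$di^2 + off$dj^2 <= rs^2
  off <- off[keep, , drop = FALSE]
  list(di = off$di, dj = off$dj, rs = rs,
       w = exp(-(off$di^2 + off$dj^2) / (2 * sigma_mp^2)),
       max_diag_shift = max(abs(off$di) + abs(off$dj)))
}

#' Generate a luminance texture boundary stimulus
#'
#' Places `n_p` non-overlapping Gaussian micropatterns on each side of the
#' oblique boundary by sequential rejection sampling against an occupancy map.
#' Candidate centres are drawn uniformly within the quadrant of the disc
#' interior that keeps every stamp pixel strictly inside one quadrant (clear of
#' both diagonals) and clear of the edge taper, so the cross-boundary and
#' anti-diagonal luminance sums are exact by construction. Within each side,
#' the majority-polarity and minority-polarity micropattern counts are split
#' equally between the side's two quadrants, which forces the luminance
#' difference across the anti-diagonal to be exactly zero for every seed.
#'
#' @param spec An [ltb_spec()].
#' @param max_attempts Rejection-sampling budget per micropattern before the
#'   placement is declared infeasible (density too high).
#' @return A `stimulus_image`: pixel matrix in \[0, 1\] (background 0.5), disc
#'   mask, generating spec and a data frame of micropattern centres
#'   (`i`, `j` matrix indices, `cx`, `cy` centred coordinates, `polarity`
#'   +1/-1, `quadrant`).
#' @export
make_ltb <- function(spec, max_attempts = 10000) {
  stopifnot(inherits(spec, "ltb_spec"))
  g <- stim_geometry(spec$image_size, spec$radius, spec$taper_width)
  fp <- .mp_footprint(spec$sigma_mp)
  side <- if (spec$orientation == "right_oblique") g$d_r else g$d_l
  anti <- if (spec$orientation == "right_oblique") g$d_l else g$d_r
  margin <- fp$max_diag_shift + 1
  interior <- g$r <= (g$radius - g$taper_width - fp$rs)
  eligible <- interior & abs(side) >= margin & abs(anti) >= margin

  n_u <- spec$n_u
  n_b <- spec$n_p - n_u
  # white-majority side: positive boundary coordinate for phase 0
  major_sign <- if (spec$phase == 0) 1 else -1
  # per-quadrant counts: (side sign, anti sign) x polarity
  quads <- expand.grid(s = c(1, -1), a = c(1, -1))
  n <- spec$image_size
  occ <- matrix(FALSE, n, n)
  dev <- matrix(0, n, n)
  centers <- vector("list", 2 * spec$n_p)
  k <- 0
  withr::with_seed(spec$seed, {
    for (qi in seq_len(nrow(quads))) {
      s <- quads$s[qi]; a <- quads$a[qi]
      qmask <- eligible & (sign(side) == s) & (sign(anti) == a)
      qidx <- which(qmask)
      if (length(qidx) == 0) stop("no eligible micropattern locations in quadrant")
      major_pol <- if (s == major_sign) 1 else -1
      counts <- c(n_u / 2 + n_b / 4, n_b / 4)   # majority, minority
      pols <- c(major_pol, -major_pol)
      for (ci in 1:2) {
        if (counts[ci] == 0) next
        for (m in seq_len(counts[ci])) {
          placed <- FALSE
          for (att in seq_len(max_attempts)) {
            lin <- qidx[sample.int(length(qidx), 1)]
            i0 <- (lin - 1) %% n + 1
            j0 <- (lin - 1) %/% n + 1
            fidx <- (j0 + fp$dj - 1) * n + (i0 + fp$di)
            if (!any(occ[fidx])) {
              occ[fidx] <- TRUE
              dev[fidx] <- pols[ci] * spec$A * fp$w
              k <- k + 1
              centers[[k]] <- data.frame(
                i = i0, j = j0, cx = g$cx[i0, j0], cy = g$cy[i0, j0],
                polarity = pols[ci],
                quadrant = paste0(if (s > 0) "s+" else "s-",
                                  if (a > 0) "a+" else "a-"))
              placed <- TRUE
              break
            }
          }
          if (!placed)
            stop("micropattern placement failed after ", max_attempts,
                 " attempts; density too high for this geometry")
        }
      }
    }
  })
  centers <- do.call(rbind, centers[seq_len(k)])
  .stimulus_image(0.5 + dev, g, spec, centers)
}

#' Generate a luminance step boundary stimulus
#'
#' The luminance is `0.5 * (1 + c_m * taper(r))` on one side of the oblique
#' boundary and `0.5 * (1 - c_m * taper(r))` on the other, where `taper` is the
#' raised-cosine disc taper; pixels exactly on the boundary line and outside
#' the disc sit at mid-gray. Phase 180 is the 180-degree rotation of phase 0.
#'
#' @param spec An [lsb_spec()].
#' @return A `stimulus_image`.
#' @export
make_lsb <- function(spec) {
  stopifnot(inherits(spec, "lsb_spec"))
  g <- stim_geometry(spec$image_size, spec$radius, spec$taper_width)
  d <- if (spec$orientation == "right_oblique") g$d_r else g$d_l
  ph <- if (spec$phase == 0) 1 else -1
  px <- 0.5 + 0.5 * spec$c_m * ph * sign(d) * g$taper
  .stimulus_image(px, g, spec)
}

#' Superimpose a texture boundary and a masking step boundary
#'
#' Deviations from mid-gray add; the sum is clipped to \[0, 1\] with the number
#' of clipped pixels recorded in the result (`n_clipped`). For
#' `relation = "neu"` the LTB is returned unchanged.
#'
#' @param spec A [composite_spec()].
#' @inheritParams make_ltb
#' @return A `stimulus_image`; `$spec` is the composite spec and the LTB's
#'   micropattern centres are carried over.
#' @export
compose_stimulus <- function(spec, max_attempts = 10000) {
  stopifnot(inherits(spec, "composite_spec"))
  ltb <- make_ltb(spec$ltb, max_attempts = max_attempts)
  if (spec$relation == "neu") {
    ltb$spec <- spec
    return(ltb)
  }
  lsb <- make_lsb(spec$lsb)
  px <- 0.5 + (ltb$pixels - 0.5) + (lsb$pixels - 0.5)
  n_clipped <- sum(px < 0 | px > 1)
  px <- pmin(pmax(px, 0), 1)
  .stimulus_image(px, ltb$geometry, spec, ltb$micropattern_centers,
                  n_clipped = as.integer(n_clipped))
}

#' Michelson contrast of a stimulus
#'
#' `(Lmax - Lmin) / (Lmax + Lmin)` over the stimulus pixels.
#'
#' @param image A `stimulus_image`.
#' @return Scalar Michelson contrast.
#' @export
michelson_contrast <- function(image) {
  stopifnot(inherits(image, "stimulus_image"))
  lo <- min(image$pixels); hi <- max(image$pixels)
  (hi - lo) / (hi + lo)
}

#' Standard stimulus-level ladders
#'
#' `pi_u_ladder()` gives the nine evenly spaced proportion-unbalanced levels
#' from 0 to 1 in steps of 0.125 used for texture-boundary staircases;
#' `lsb_contrast_ladder()` gives the eleven logarithmic Michelson-contrast
#' steps from `10^-2.7` to `10^-1.7` used for step-boundary staircases.
#'
#' @return Numeric vector of stimulus levels, ascending.
#' @export
pi_u_ladder <- function() seq(0, 1, by = 0.125)

#' @rdname pi_u_ladder
#' @export
lsb_contrast_ladder <- function() 10^seq(-2.7, -1.7, length.out = 11)
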