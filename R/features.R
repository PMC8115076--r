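# Scalar image features consumed by the one-stage models: diagonal luminance
# differences and global RMS contrast.

.half_means <- function(image, coord) {
  m <- image$disc_mask
  hp <- m & coord > 0
  hm <- m & coord < 0   # pixels exactly on the diagonal belong to neither half
  if (!any(hp) || !any(hm)) stop("empty half-disc mask")
  c(mean(image$pixels[hp]), mean(image$pixels[hm]))
}

#' Diagonal luminance differences of a stimulus
#'
#' For each oblique diagonal, the mean luminance is taken over the two
#' half-discs it separates (within the disc mask; pixels exactly on the
#' diagonal are excluded from both halves) and the feature is the absolute
#' difference of the two half means. `L_R` is the difference across the
#' right-oblique diagonal, `L_L` across the left-oblique diagonal. A pure
#' texture boundary has a nonzero difference only across its own boundary
#' diagonal; the anti-diagonal difference is zero by construction.
#'
#' @param image A `stimulus_image`.
#' @return A list with non-negative scalars `L_R` and `L_L`.
#' @export
luminance_diffs <- function(image) {
  stopifnot(inherits(image, "stimulus_image"))
  g <- image$geometry
  hr <- .half_means(image, g$d_r)
  hl <- .half_means(image, g$d_l)
  list(L_R = abs(hr[1] - hr[2]), L_L = abs(hl[1] - hl[2]))
}

#' Global RMS contrast of a stimulus
#'
#' Standard deviation of the disc-interior pixels divided by their mean
#' (population SD; the constant background outside the disc is excluded so it
#' cannot dilute the contrast by an arbitrary factor).
#'
#' @param image A `stimulus_image`.
#' @return Non-negative scalar contrast.
#' @export
rms_contrast <- function(image) {
  stopifnot(inherits(image, "stimulus_image"))
  v <- image$pixels[image$disc_mask]
  mu <- mean(v)
  if (mu <= 0) stop("mean luminance over the disc is not positive")
  sqrt(mean((v - mu)^2)) / mu
}

#' Full feature vector of a stimulus
#'
#' @param image A `stimulus_image`.
#' @return A one-row data frame with columns `L_R`, `L_L`, `C`.
#' @export
measure_features <- function(image) {
  ld <- luminance_diffs(image)
  data.frame(L_R = ld$L_R, L_L = ld$L_L, C = rms_contrast(image))
}
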