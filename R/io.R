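# Serialization: stimuli as 16-bit grayscale TIFF plus a JSON spec sidecar,
# trial records as CSV, fit results as JSON.

#' Write and read stimuli
#'
#' `write_stimulus()` writes the pixel matrix as a 16-bit grayscale TIFF
#' (luminance 0-1 mapped to the full integer range) and a JSON sidecar holding
#' the complete generating spec (including the snapped proportion-unbalanced
#' value and the seed) and the micropattern centres, so the stimulus can be
#' regenerated exactly. `read_stimulus()` reads the raster and sidecar back;
#' the returned pixels carry 16-bit quantization, while the sidecar spec
#' allows lossless regeneration through [make_ltb()] and friends.
#'
#' @param image A `stimulus_image`.
#' @param path_prefix Output path without extension; writes
#'   `<path_prefix>.tiff` and `<path_prefix>.json`.
#' @return `write_stimulus()`: the two paths, invisibly. `read_stimulus()`: a
#'   list with `pixels`, `sidecar`.
#' @export
write_stimulus <- function(image, path_prefix) {
  stopifnot(inherits(image, "stimulus_image"))
  tif <- paste0(path_prefix, ".tiff")
  js <- paste0(path_prefix, ".json")
  tiff::writeTIFF(image$pixels, tif, bits.per.sample = 16,
                  compression = "none")
  spec <- image$spec
  sidecar <- list(
    spec_class = class(spec)[1],
    spec = .spec_to_list(spec),
    n_clipped = image$n_clipped,
    micropattern_centers = image$micropattern_centers)
  jsonlite::write_json(sidecar, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(c(tiff = tif, json = js))
}

.spec_to_list <- function(spec) {
  if (inherits(spec, "composite_spec")) {
    list(relation = spec$relation, ltb = unclass(spec$ltb),
         lsb = if (!is.null(spec$lsb)) unclass(spec$lsb))
  } else unclass(spec)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path_prefix) {
  px <- tiff::readTIFF(paste0(path_prefix, ".tiff"))
  sidecar <- jsonlite::read_json(paste0(path_prefix, ".json"),
                                 simplifyVector = TRUE)
  list(pixels = px, sidecar = sidecar)
}

#' Write and read trial records
#'
#' Plain CSV round-trip for trial-record data frames (as produced by
#' [run_staircase()] and [simulate_responses()]).
#'
#' @param trials Trial-record data frame.
#' @param path CSV path.
#' @return `read_trials()`: the data frame.
#' @export
write_trials <- function(trials, path) {
  stopifnot(is.data.frame(trials))
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a fit result as JSON
#'
#' Serializes a `fit_result` (parameters, log-likelihood, K, n, BIC,
#' convergence flag and, when present, the per-ratio profile and bootstrap
#' CI table) to JSON.
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @param ci Optional CI table (e.g. from [bootstrap_pf()]).
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path, ci = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(model_id = fit$model_id, params = fit$params, logL = fit$logL,
              K = fit$K, n = fit$n, BIC = fit$BIC, converged = fit$converged)
  if (!is.null(fit$profile)) out$profile <- fit$profile
  if (!is.null(ci)) out$ci <- ci
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
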