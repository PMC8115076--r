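# Small-frame stimulus helpers shared across tests. The 64/96/128-pixel frames
# keep unit tests fast; geometry (radius, taper) scales with the frame by the
# package defaults.

small_ltb <- function(pi_u = 0.5, seed = 1, image_size = 96, n_p = 16, ...) {
  make_ltb(ltb_spec(pi_u = pi_u, n_p = n_p, image_size = image_size,
                    seed = seed, ...))
}

small_lsb <- function(c_m = 0.02, image_size = 96, ...) {
  make_lsb(lsb_spec(c_m = c_m, image_size = image_size, ...))
}

# uniform mid-gray disc in a small frame (a zero-contrast step boundary)
uniform_disc <- function(image_size = 96) {
  make_lsb(lsb_spec(c_m = 0, image_size = image_size))
}

# masking stimulus set reused by experiment/fitting tests (built once per run)
tiny_masking_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- masking_design(24, seed = 301)
      stimuli <- build_masking_stimuli(design, pi_u = 0.25, c_m = 0.015,
                                       ltb_args = list(image_size = 128))
      cache <<- list(design = design, stimuli = stimuli,
                     features = do.call(rbind, lapply(stimuli, measure_features)))
    }
    cache
  }
})
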