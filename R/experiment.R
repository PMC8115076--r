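# Simulated observers and experiment protocols: 1-up-2-down staircases and
# the constant-stimuli masking design (neutral / congruent / incongruent).

#' Simulated observers
#'
#' A simulated observer stands in for a human participant: its responses are
#' Bernoulli draws from the corresponding model's response probability.
#' `sdt_observer` responds to a stimulus *level* through the SDT psychometric
#' function; `ic1_observer` and `ic2_observer` respond to a stimulus *image*
#' through the one-stage and two-stage models.
#'
#' @param g,tau,lambda SDT psychometric parameters, see [sdt_pc()].
#' @return An object of class `simulated_observer`.
#' @export
sdt_observer <- function(g, tau, lambda = 0) {
  structure(list(model_id = "sdt", params = list(g = g, tau = tau, lambda = lambda)),
            class = "simulated_observer")
}

#' @rdname sdt_observer
#' @param g1,p1,g2,tau2 One-stage model parameters, see [ic1_u()].
#' @export
ic1_observer <- function(g1, p1, g2 = 0, tau2 = 1) {
  structure(list(model_id = "ic1",
                 params = list(g1 = g1, p1 = p1, g2 = g2, tau2 = tau2)),
            class = "simulated_observer")
}

#' @rdname sdt_observer
#' @param rho_ie,p2 Two-stage model parameters, see [ic2_u()] and [build_dog()].
#' @param sigma_c,support_halfwidth,rectify_order First-stage kernel geometry
#'   and pooling order.
#' @export
ic2_observer <- function(rho_ie, p1, p2, g2, sigma_c = 4, support_halfwidth = 16,
                         rectify_order = "rectify_pool") {
  structure(list(model_id = "ic2",
                 params = list(rho_ie = rho_ie, p1 = p1, p2 = p2, g2 = g2,
                               sigma_c = sigma_c,
                               support_halfwidth = support_halfwidth,
                               rectify_order = rectify_order),
                 kernel = build_dog(rho_ie, sigma_c, support_halfwidth)),
            class = "simulated_observer")
}

#' Response probability of a simulated observer
#'
#' Probability of a "right-oblique" response. Image-computable observers need
#' the stimulus image (the one-stage observer only its features); the SDT
#' observer needs the stimulus level and true orientation, responding correctly
#' with probability `sdt_pc(level)`.
#'
#' @param observer A `simulated_observer`.
#' @param image A `stimulus_image` (ic1/ic2 observers).
#' @param features Optional precomputed [measure_features()] row (ic1 observer;
#'   measured from `image` when absent).
#' @param level,true_orientation Stimulus level and "L"/"R" orientation (SDT
#'   observer).
#' @return Probability in \[0, 1\] of responding "R".
#' @export
observer_prob_r <- function(observer, image = NULL, features = NULL,
                            level = NULL, true_orientation = NULL) {
  stopifnot(inherits(observer, "simulated_observer"))
  switch(observer$model_id,
    sdt = {
      if (is.null(level) || is.null(true_orientation))
        stop("SDT observer needs level and true_orientation")
      pc <- sdt_pc(level, observer$params$g, observer$params$tau,
                   observer$params$lambda)
      if (true_orientation == "R") pc else 1 - pc
    },
    ic1 = {
      if (is.null(features)) features <- measure_features(image)
      ic1_prob_r(features, observer$params$g1, observer$params$p1,
                 observer$params$g2, observer$params$tau2)
    },
    ic2 = {
      pools <- ic2_channel_pools(image, observer$kernel, observer$params$p1,
                                 observer$params$rectify_order)
      stats::pnorm(ic2_u(pools, observer$params$g2, observer$params$p2))
    })
}

#' Run a 1-up-2-down adaptive staircase
#'
#' Trials start at the top of the ladder. After any error the level moves up
#' one ladder step; after two consecutive correct responses it moves down one
#' step (the counter resets on every move); the index is clipped at the ladder
#' ends. The rule concentrates trials near the level yielding 70.71% correct.
#' The true boundary orientation and the luminance phase (which half is
#' brighter) are randomized independently on every trial.
#'
#' For an SDT observer, responses are drawn directly from the psychometric
#' function at the trial level. For image-computable observers, supply
#' `stim_fun(level, orientation, phase, seed)` returning a `stimulus_image`
#' for the trial.
#'
#' @param observer A `simulated_observer`.
#' @param ladder Ascending vector of stimulus levels.
#' @param n_trials Number of trials (250 in the experiments simulated here).
#' @param stim_fun Stimulus factory for image-computable observers.
#' @param seed Master RNG seed; the whole run is reproducible from it.
#' @return A data frame of trial records: `trial`, `condition` ("plain"),
#'   `level`, `level_index`, `true_orientation`, `response`, `correct`,
#'   `reversal` (logical: the staircase changed direction after this trial).
#' @export
run_staircase <- function(observer, ladder, n_trials = 250, stim_fun = NULL,
                          seed = 1) {
  stopifnot(length(ladder) >= 2, !is.unsorted(ladder))
  needs_images <- observer$model_id != "sdt"
  if (needs_images && is.null(stim_fun))
    stop("image-computable observers need a stim_fun")
  withr::with_seed(seed, {
    idx <- length(ladder)
    cc <- 0L
    last_move <- 0L
    v_idx <- integer(n_trials)
    v_ori <- sample(c("L", "R"), n_trials, replace = TRUE)
    v_phase <- sample(c(0, 180), n_trials, replace = TRUE)
    v_resp <- character(n_trials)
    v_correct <- logical(n_trials)
    v_rev <- logical(n_trials)
    stim_seeds <- if (needs_images) sample.int(.Machine$integer.max, n_trials)
    u <- stats::runif(n_trials)
    for (t in seq_len(n_trials)) {
      ori <- v_ori[t]
      lev <- ladder[idx]
      if (needs_images) {
        img <- stim_fun(lev, ori, v_phase[t], stim_seeds[t])
        p_r <- observer_prob_r(observer, image = img)
        resp <- if (u[t] < p_r) "R" else "L"
        correct <- resp == ori
      } else {
        pc <- sdt_pc(lev, observer$params$g, observer$params$tau,
                     observer$params$lambda)
        correct <- u[t] < pc
        resp <- if (correct) ori else if (ori == "R") "L" else "R"
      }
      v_idx[t] <- idx; v_resp[t] <- resp; v_correct[t] <- correct
      move <- 0L
      if (correct) {
        cc <- cc + 1L
        if (cc == 2L) { move <- -1L; cc <- 0L }
      } else {
        move <- 1L; cc <- 0L
      }
      if (move != 0L) {
        if (last_move != 0L && move != last_move) v_rev[t] <- TRUE
        last_move <- move
        idx <- min(max(idx + move, 1L), length(ladder))
      }
    }
    data.frame(trial = seq_len(n_trials), condition = "plain",
               level = ladder[v_idx], level_index = v_idx,
               true_orientation = v_ori, response = v_resp,
               correct = v_correct, reversal = v_rev)
  })
}

#' Mean staircase level at reversals
#'
#' Averages the trial levels at which the staircase reversed direction, after
#' discarding an initial burn-in; with a fine ladder and a long run this
#' converges to the level whose true proportion correct is
#' `2^(-1/2)` = 70.71%.
#'
#' @param trials Output of [run_staircase()].
#' @param drop_first Number of initial reversals discarded as burn-in.
#' @return Mean reversal level.
#' @export
reversal_level <- function(trials, drop_first = 10) {
  lv <- trials$level[trials$reversal]
  if (length(lv) <= drop_first)
    stop("not enough reversals (", length(lv), ") for burn-in of ", drop_first)
  mean(lv[-seq_len(drop_first)])
}

#' Fit a psychometric function to staircase trials and extract the JND
#'
#' Aggregates the trial records by level, fits [fit_sdt()] and returns the
#' 75%-correct threshold together with the fit.
#'
#' @param trials Trial records with `level` and `correct` columns.
#' @param with_lapse Fit the lapse rate (default TRUE; thresholds are reported
#'   from the with-lapse fit since lapse-free fits can understate the slope).
#' @param target Proportion correct defining the threshold.
#' @return List with `threshold` and the `fit_result`.
#' @export
jnd_from_trials <- function(trials, with_lapse = TRUE, target = 0.75) {
  agg <- stats::aggregate(cbind(n_correct = correct, n_trials = rep(1, length(correct))) ~ level,
                          data = trials, FUN = sum)
  fit <- fit_sdt(agg$level, agg$n_correct, agg$n_trials, with_lapse = with_lapse)
  list(threshold = sdt_threshold(fit$params, target), fit = fit)
}

#' Trial design of the masking experiment
#'
#' Builds the per-trial condition table of the masking design:
#' `n_per_condition` neutral trials, `n_per_condition` congruent trials split
#' equally between phase-aligned (`con_0`) and opposite-phase (`con_180`), and
#' `n_per_condition` incongruent trials. True orientations are balanced L/R
#' within every condition (to within one trial) and the texture phase is
#' randomized; trial order is shuffled.
#'
#' @param n_per_condition Trials per condition (200 in the design simulated
#'   here, so 100 per congruent phase).
#' @param seed RNG seed for randomization.
#' @return Data frame with `trial`, `condition`, `true_orientation`,
#'   `phase_ltb`, `stim_seed`.
#' @export
masking_design <- function(n_per_condition = 200, seed = 1) {
  stopifnot(n_per_condition >= 2, n_per_condition %% 2 == 0)
  half <- n_per_condition / 2
  cond <- c(rep("neu", n_per_condition), rep("con_0", half),
            rep("con_180", half), rep("inc", n_per_condition))
  withr::with_seed(seed, {
    ori <- unlist(lapply(table(cond)[unique(cond)], function(n)
      sample(rep(c("L", "R"), length.out = n))))
    d <- data.frame(condition = cond, true_orientation = ori,
                    phase_ltb = sample(c(0, 180), length(cond), replace = TRUE),
                    stim_seed = sample.int(.Machine$integer.max, length(cond)))
    d <- d[sample.int(nrow(d)), ]
    d$trial <- seq_len(nrow(d))
    rownames(d) <- NULL
    d[, c("trial", "condition", "true_orientation", "phase_ltb", "stim_seed")]
  })
}

#' Build the stimuli of a masking-experiment design
#'
#' Generates one composite stimulus per design row: the target texture
#' boundary at level `pi_u` (its JND in the original design) and, in the
#' masking conditions, a step boundary at contrast `c_m`. Congruent maskers
#' share the texture's orientation with equal (`con_0`) or opposite
#' (`con_180`) phase; incongruent maskers take the orthogonal orientation with
#' random phase. If snapping `pi_u` to a feasible micropattern count moves it
#' by more than one ladder step (0.125), the request is reported as infeasible.
#'
#' @param design Output of [masking_design()].
#' @param pi_u Texture-boundary level (proportion unbalanced).
#' @param c_m Masker Michelson contrast.
#' @param ltb_args Named list of extra arguments to [ltb_spec()] (e.g.
#'   `image_size`, `n_p`, `A`).
#' @return List of `stimulus_image` objects aligned with `design`.
#' @export
build_masking_stimuli <- function(design, pi_u, c_m, ltb_args = list()) {
  probe <- do.call(ltb_spec, c(list(pi_u = pi_u), ltb_args))
  if (abs(probe$pi_u_snapped - pi_u) > 0.125)
    stop("requested pi_u = ", pi_u, " snaps to ", probe$pi_u_snapped,
         ", more than one ladder step away")
  other <- c(right_oblique = "left_oblique", left_oblique = "right_oblique")
  lapply(seq_len(nrow(design)), function(t) {
    ori <- if (design$true_orientation[t] == "R") "right_oblique" else "left_oblique"
    ph <- design$phase_ltb[t]
    ltb <- do.call(ltb_spec, c(list(pi_u = pi_u, orientation = ori, phase = ph,
                                    seed = design$stim_seed[t]), ltb_args))
    cnd <- design$condition[t]
    lsb <- switch(cnd,
      neu = NULL,
      con_0 = lsb_spec(c_m, orientation = ori, phase = ph,
                       image_size = ltb$image_size, radius = ltb$radius,
                       taper_width = ltb$taper_width),
      con_180 = lsb_spec(c_m, orientation = ori, phase = (ph + 180) %% 360,
                         image_size = ltb$image_size, radius = ltb$radius,
                         taper_width = ltb$taper_width),
      inc = lsb_spec(c_m, orientation = other[[ori]],
                     phase = if (design$stim_seed[t] %% 2 == 0) 0 else 180,
                     image_size = ltb$image_size, radius = ltb$radius,
                     taper_width = ltb$taper_width))
    compose_stimulus(composite_spec(ltb, lsb, relation = cnd))
  })
}

#' Simulate an observer's responses to a stimulus set
#'
#' Draws one Bernoulli response per stimulus from the observer's response
#' probability.
#'
#' @param observer A `simulated_observer` (image-computable).
#' @param design Output of [masking_design()].
#' @param stimuli Output of [build_masking_stimuli()].
#' @param seed RNG seed for the response draws.
#' @return The design with `response`, `correct` and `level` columns appended.
#' @export
simulate_responses <- function(observer, design, stimuli, seed = 1) {
  stopifnot(length(stimuli) == nrow(design))
  p_r <- vapply(stimuli, function(img) observer_prob_r(observer, image = img),
                numeric(1))
  withr::with_seed(seed, {
    resp <- ifelse(stats::runif(length(p_r)) < p_r, "R", "L")
  })
  out <- design
  out$response <- resp
  out$correct <- out$response == out$true_orientation
  out
}

#' Run the full masking experiment on a simulated observer
#'
#' Convenience wrapper: builds the design, the stimuli (texture level
#' `jnd_ltb`, masker contrast `jnd_lsb`) and the simulated responses.
#'
#' @param observer An image-computable `simulated_observer`.
#' @param jnd_ltb Texture-boundary level (the observer's JND in the original
#'   design).
#' @param jnd_lsb Masker Michelson contrast (likewise a JND).
#' @param n_per_condition Trials per condition.
#' @param ltb_args Extra [ltb_spec()] arguments.
#' @param seed Master seed (design, stimuli and responses all derive from it).
#' @param keep_stimuli Also return the stimulus list (needed for model fits).
#' @return List with `trials` (data frame) and, if requested, `stimuli`.
#' @export
run_masking_experiment <- function(observer, jnd_ltb, jnd_lsb,
                                   n_per_condition = 200, ltb_args = list(),
                                   seed = 1, keep_stimuli = TRUE) {
  design <- masking_design(n_per_condition, seed = seed)
  stimuli <- build_masking_stimuli(design, jnd_ltb, jnd_lsb, ltb_args = ltb_args)
  trials <- simulate_responses(observer, design, stimuli, seed = seed + 1)
  if (keep_stimuli) list(trials = trials, stimuli = stimuli)
  else list(trials = trials)
}

#' Calibrate an observer's gain to a target accuracy
#'
#' Rescales the observer's gain (`g1` for the one-stage model, `g2` for the
#' two-stage model) so that its mean probability of a correct response over
#' the supplied stimuli equals `target`. Deterministic: works on response
#' probabilities, not simulated draws.
#'
#' @param observer An image-computable `simulated_observer`.
#' @param design,stimuli A stimulus set (typically the neutral trials).
#' @param target Target mean proportion correct.
#' @return The observer with its gain rescaled.
#' @export
calibrate_gain <- function(observer, design, stimuli, target = 0.75) {
  stopifnot(observer$model_id %in% c("ic1", "ic2"))
  feats <- if (observer$model_id == "ic1")
    lapply(stimuli, measure_features) else NULL
  pools <- if (observer$model_id == "ic2")
    lapply(stimuli, function(img)
      ic2_channel_pools(img, observer$kernel, observer$params$p1,
                        observer$params$rectify_order)) else NULL
  acc <- function(log_scale) {
    s <- exp(log_scale)
    p_r <- if (observer$model_id == "ic1") {
      vapply(feats, function(f)
        ic1_prob_r(f, observer$params$g1 * s, observer$params$p1,
                   observer$params$g2, observer$params$tau2), numeric(1))
    } else {
      vapply(pools, function(pl)
        stats::pnorm(ic2_u(pl, observer$params$g2 * s, observer$params$p2)),
        numeric(1))
    }
    pc <- ifelse(design$true_orientation == "R", p_r, 1 - p_r)
    mean(pc) - target
  }
  root <- stats::uniroot(acc, lower = -12, upper = 12, tol = 1e-6)
  s <- exp(root$root)
  if (observer$model_id == "ic1") {
    ic1_observer(observer$params$g1 * s, observer$params$p1,
                 observer$params$g2, observer$params$tau2)
  } else {
    ic2_observer(observer$params$rho_ie, observer$params$p1,
                 observer$params$p2, observer$params$g2 * s,
                 observer$params$sigma_c, observer$params$support_halfwidth,
                 observer$params$rectify_order)
  }
}

#' Step-boundary JND of a deterministic observer
#'
#' Finds the Michelson contrast at which the observer's probability of a
#' correct response on an isolated step boundary equals `target`. Step
#' boundaries are deterministic stimuli, so no simulation is involved. An
#' optional uninformative texture masker (`pi_u = 0`) can be superimposed,
#' matching the control condition in which the masker JND is measured in the
#' presence of a cue-free texture; in that case the probability is averaged
#' over `n_masker_seeds` masker layouts.
#'
#' @param observer An image-computable `simulated_observer`.
#' @param target Target proportion correct.
#' @param interval Search interval of Michelson contrasts.
#' @param with_ltb_masker Superimpose a `pi_u = 0` texture masker.
#' @param ltb_args Extra [ltb_spec()] arguments for the masker.
#' @param n_masker_seeds Masker layouts averaged over.
#' @param image_size,radius,taper_width Frame geometry of the step stimulus.
#' @return Michelson contrast at the target accuracy.
#' @export
lsb_jnd <- function(observer, target = 0.75, interval = c(1e-4, 0.9),
                    with_ltb_masker = FALSE, ltb_args = list(),
                    n_masker_seeds = 5, image_size = 256, radius = NULL,
                    taper_width = NULL) {
  pc_at <- function(c_m) {
    if (!with_ltb_masker) {
      img <- make_lsb(lsb_spec(c_m, orientation = "right_oblique",
                               image_size = image_size, radius = radius,
                               taper_width = taper_width))
      observer_prob_r(observer, image = img)
    } else {
      mean(vapply(seq_len(n_masker_seeds), function(s) {
        ltb <- do.call(ltb_spec, c(list(pi_u = 0, orientation = "left_oblique",
                                        image_size = image_size, seed = s),
                                   ltb_args))
        lsb <- lsb_spec(c_m, orientation = "right_oblique",
                        image_size = ltb$image_size, radius = ltb$radius,
                        taper_width = ltb$taper_width)
        img <- compose_stimulus(composite_spec(ltb, lsb, relation = "inc"))
        observer_prob_r(observer, image = img)
      }, numeric(1)))
    }
  }
  f <- function(c_m) pc_at(c_m) - target
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo * hi > 0)
    stop("observer accuracy does not reach ", target,
         " within the contrast interval [", interval[1], ", ", interval[2], "]")
  stats::uniroot(f, interval = interval, tol = 1e-6)$root
}
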