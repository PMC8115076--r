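# Condition-level statistics: Pearson chi-squared homogeneity of
# correct/incorrect counts and binomial proportion confidence intervals.

#' Pearson chi-squared homogeneity test on correct/incorrect counts
#'
#' Tests whether the proportion of correct responses is homogeneous across
#' conditions, using the standard Pearson statistic on the
#' conditions-by-(correct, incorrect) contingency table with
#' `df = #conditions - 1` and no continuity correction.
#'
#' @param counts Data frame with columns `condition`, `n_correct`, `n_trials`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_homogeneity <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("condition", "n_correct", "n_trials") %in% names(counts)))
  if (nrow(counts) < 2) stop("need at least 2 conditions")
  if (any(counts$n_trials <= 0)) stop("all conditions need n_trials > 0")
  if (any(counts$n_correct < 0 | counts$n_correct > counts$n_trials))
    stop("n_correct must lie in [0, n_trials]")
  tab <- rbind(correct = counts$n_correct,
               incorrect = counts$n_trials - counts$n_correct)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("zero expected cell count; test undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Binomial proportion confidence interval
#'
#' Two-sided interval for a binomial proportion. The default is the Wilson
#' score interval (the score test inverted without continuity correction);
#' `method = "exact"` gives the Clopper-Pearson interval.
#'
#' @param n_correct Number of successes.
#' @param n_trials Number of trials.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"exact"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
binomial_ci <- function(n_correct, n_trials, level = 0.95,
                        method = c("wilson", "exact")) {
  method <- match.arg(method)
  stopifnot(n_trials > 0, n_correct >= 0, n_correct <= n_trials)
  ci <- if (method == "wilson") {
    suppressWarnings(stats::prop.test(n_correct, n_trials, conf.level = level,
                                      correct = FALSE))$conf.int
  } else {
    stats::binom.test(n_correct, n_trials, conf.level = level)$conf.int
  }
  c(lower = ci[1], upper = ci[2])
}

#' Convert printed proportions to integer counts
#'
#' Published tables print proportions correct to a few decimals; this maps
#' them back to integer counts by rounding `p * n`, recording the rounding
#' residual for each condition.
#'
#' @param proportions Proportions correct.
#' @param n_trials Trial counts.
#' @return Data frame with `n_correct`, `n_trials`, `rounding` (count minus
#'   `p * n`).
#' @export
proportions_to_counts <- function(proportions, n_trials) {
  stopifnot(all(proportions >= 0), all(proportions <= 1), all(n_trials > 0))
  n_correct <- round(proportions * n_trials)
  data.frame(n_correct = n_correct, n_trials = n_trials,
             rounding = n_correct - proportions * n_trials)
}

#' Pooled masking-experiment proportions and their chi-squared tests
#'
#' `masking_pooled_proportions()` loads the published pooled
#' proportions-correct of the masking experiment (9 observers, 200 trials per
#' condition each, 100 per congruent phase) bundled with the package.
#' `masking_pooled_stats()` converts them to integer counts and recomputes the
#' five condition comparisons reported with them: the three-condition omnibus
#' test and the four pairwise tests.
#'
#' @return `masking_pooled_proportions()`: data frame with `condition`,
#'   `prop_correct`, `n_trials`. `masking_pooled_stats()`: data frame with
#'   `comparison`, `statistic`, `df`, `p_value`.
#' @export
masking_pooled_proportions <- function() {
  path <- system.file("extdata", "masking_pooled_proportions.csv",
                      package = "ltbseg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname masking_pooled_proportions
#' @export
masking_pooled_stats <- function() {
  pp <- masking_pooled_proportions()
  cnt <- cbind(condition = pp$condition,
               proportions_to_counts(pp$prop_correct, pp$n_trials))
  pick <- function(conds) cnt[match(conds, cnt$condition), ]
  comparisons <- list(
    omnibus_neu_con_inc = c("neu", "con", "inc"),
    neu_vs_con_0 = c("neu", "con_0"),
    con_0_vs_con_180 = c("con_0", "con_180"),
    neu_vs_inc = c("neu", "inc"),
    neu_vs_con_180 = c("neu", "con_180"))
  do.call(rbind, lapply(names(comparisons), function(nm) {
    res <- chi2_homogeneity(pick(comparisons[[nm]]))
    data.frame(comparison = nm, statistic = res$statistic, df = res$df,
               p_value = res$p_value)
  }))
}
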