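# Cumulative confusion counts at every distinct score threshold, scores
# descending; "positive" means score >= threshold.
threshold_counts <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  list(threshold = s[last], tp = tp, fp = fp,
       n_pos = sum(y), n_neg = sum(1 - y))
}

#' Area under the ROC curve
#'
#' Trapezoidal area over all distinct score thresholds. Ties are handled by
#' stepping over whole tie groups, which makes the area equal to the
#' pairwise-concordance (rank) statistic with ties counted one half.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 classes (both must be present).
#' @return list with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  tc <- threshold_counts(scores, labels)
  if (tc$n_pos == 0 || tc$n_neg == 0) {
    stopf("AUROC undefined: both classes required")
  }
  tpr <- c(0, tc$tp / tc$n_pos)
  fpr <- c(0, tc$fp / tc$n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, tc$threshold),
                          fpr = fpr, tpr = tpr))
}

#' Area under the precision-recall curve
#'
#' Average-precision summation: the sum over distinct thresholds of the
#' recall increment times the precision at that threshold (no linear
#' interpolation in PR space).
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 classes (at least one positive).
#' @return list with `auc` and `curve` (data.frame `threshold`, `recall`,
#'   `precision`).
#' @export
pr_auc <- function(scores, labels) {
  tc <- threshold_counts(scores, labels)
  if (tc$n_pos == 0) stopf("APR undefined: no positive labels")
  recall <- tc$tp / tc$n_pos
  precision <- tc$tp / (tc$tp + tc$fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(auc = auc,
       curve = data.frame(threshold = tc$threshold,
                          recall = recall, precision = precision))
}

#' Operating-point metrics at a target sensitivity
#'
#' Chooses, among all distinct score thresholds, the one whose sensitivity
#' is closest to the target (ties broken toward higher specificity, then
#' toward the lower threshold) and reports the confusion-matrix summary
#' there. Infinite likelihood/odds ratios (a zero cell) are flagged rather
#' than averaged away.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 classes.
#' @param target_sensitivity target operating sensitivity.
#' @return list with `threshold`, `sensitivity`, `specificity`, `f1`,
#'   `dor`, `lr_plus`, `lr_minus`, `accuracy`, the confusion counts, and
#'   `degenerate` (`TRUE` when a ratio is infinite/undefined).
#' @export
operating_metrics <- function(scores, labels, target_sensitivity = 0.80) {
  tc <- threshold_counts(scores, labels)
  if (tc$n_pos == 0 || tc$n_neg == 0) {
    stopf("operating metrics undefined: both classes required")
  }
  sens <- tc$tp / tc$n_pos
  spec <- 1 - tc$fp / tc$n_neg
  gap <- abs(sens - target_sensitivity)
  # thresholds are listed in descending order, so among ties on (gap, spec)
  # the last index has the lower threshold
  ord <- order(gap, -spec)
  best_gap <- gap[ord[1]]
  best_spec <- spec[ord[1]]
  cand <- which(gap == best_gap & spec == best_spec)
  i <- cand[length(cand)]
  if (min(sens) > target_sensitivity || max(sens) < target_sensitivity) {
    warnf("no threshold attains the target sensitivity; best effort used")
  }
  tp <- tc$tp[i]; fp <- tc$fp[i]
  fn <- tc$n_pos - tp; tn <- tc$n_neg - fp
  lr_plus <- (tp / tc$n_pos) / (fp / tc$n_neg)
  lr_minus <- (fn / tc$n_pos) / (tn / tc$n_neg)
  dor <- (tp * tn) / (fp * fn)
  list(threshold = tc$threshold[i],
       sensitivity = sens[i], specificity = spec[i],
       f1 = 2 * tp / (2 * tp + fp + fn),
       dor = dor, lr_plus = lr_plus, lr_minus = lr_minus,
       accuracy = (tp + tn) / (tc$n_pos + tc$n_neg),
       tp = tp, fp = fp, fn = fn, tn = tn,
       degenerate = !is.finite(dor))
}

#' Compare cross-validation fold values to a benchmark constant
#'
#' One-sample two-sided t test of the fold values against the pooled
#' benchmark value, assuming normality of fold-level performance; reports
#' the mean and standard deviation across folds. Zero-variance fold values
#' fall back to an exact comparison.
#'
#' @param fold_values per-fold metric values (at least 2).
#' @param benchmark_value the comparator's pooled metric.
#' @return list with `mean`, `sd`, `p_value`, `direction` (`"above"`,
#'   `"below"`, `"equal"`).
#' @export
compare_to_benchmark <- function(fold_values, benchmark_value) {
  stopifnot(length(fold_values) >= 2)
  m <- mean(fold_values)
  s <- stats::sd(fold_values)
  direction <- if (m > benchmark_value) "above"
    else if (m < benchmark_value) "below" else "equal"
  if (s == 0) {
    p <- if (m == benchmark_value) 1 else 0
  } else {
    p <- stats::t.test(fold_values, mu = benchmark_value)$p.value
  }
  list(mean = m, sd = s, p_value = p, direction = direction)
}

#' Randomly delete raw observations
#'
#' Simulates data sparsity: within each stay and affected channel the first
#' observation is always retained; every later observation is kept
#' independently with probability `1 - p`. Events and unaffected channels
#' are untouched. With `p = 0` the observations are returned unchanged.
#'
#' @param observations observation data.table (keyed by stay, channel,
#'   time as in a [vs_cohort()]).
#' @param p deletion probability in `[0, 1)`.
#' @param seed integer seed.
#' @param channels affected channels (default: the extended vitals).
#' @return thinned observation data.table.
#' @export
random_dropout <- function(observations, p, seed = 1L,
                           channels = vital_channels()) {
  stopifnot(p >= 0, p < 1)
  obs <- data.table::copy(observations)
  data.table::setorder(obs, stay_id, channel, time_h)
  affected <- obs$channel %in% channels
  first <- !duplicated(obs[, list(stay_id, channel)])
  u <- with_seed(seed, stats::runif(nrow(obs)))
  keep <- !affected | first | (u <= 1 - p)
  obs[keep]
}

#' Run the dropout robustness experiment
#'
#' For each deletion probability: thin the raw observations, rebuild and
#' re-impute the timelines, and rerun the cross-validated experiment. The
#' gold-standard labels are always the ones computed on the full data and
#' are held fixed across all deletion levels.
#'
#' @param cohort a [vs_cohort()] (full observations).
#' @param labels full-data labels from [label_cohort()].
#' @param stay_ids included stays.
#' @param plan a [vs_plan()] (horizons default to 0, 1, 2, 4 here).
#' @param p_grid deletion probabilities.
#' @param config a [vs_config()].
#' @param dropout_seed seed for the deletion draws (independent of the
#'   plan's CV seeds, so the `p = 0` run is identical to the plain
#'   pipeline).
#' @return list with `results` (CV results with a `dropout_p` column) and
#'   `scores`.
#' @export
run_dropout_experiment <- function(cohort, labels, stay_ids,
                                   plan = vs_plan(horizons = c(0, 1, 2, 4)),
                                   p_grid = c(0, 0.1, 0.2, 0.4, 0.6),
                                   config = vs_config(),
                                   dropout_seed = 1L) {
  res <- list(); sc <- list()
  for (p in p_grid) {
    thinned <- random_dropout(cohort$observations, p,
                              derive_seed(dropout_seed, round(100 * p)))
    sub <- cohort
    sub$observations <- thinned
    tl <- build_timelines(sub, config)
    cv <- run_cv_experiment(sub, labels, stay_ids, plan, config,
                            timelines = tl)
    cv$results$dropout_p <- p
    cv$scores$dropout_p <- p
    res[[length(res) + 1]] <- cv$results
    sc[[length(sc) + 1]] <- cv$scores
  }
  list(results = do.call(rbind, res), scores = do.call(rbind, sc))
}
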