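#' Choose the prediction hour for each stay
#'
#' For septic stays the prediction hour is locked to the onset minus the
#' horizon, so the classifier's two-hour input window ends `horizon_h` hours
#' before onset. Nonseptic stays have no anchor; a prediction hour is drawn
#' uniformly from the eligible integer hours (at least 2, so two full hourly
#' bins of history exist, and at least `7 - horizon_h` to mirror the septic
#' floor implied by the 7-hour onset inclusion rule).
#'
#' @param labels label data.frame from [label_cohort()], one row per stay.
#' @param n_hours named integer vector of stay lengths in bins.
#' @param horizon_h prediction horizon in hours (0-4).
#' @param seed integer seed for the nonseptic draws.
#' @return named integer vector of prediction hours `t`; `x1` is bin
#'   `(t-1, t]`, `x2` is bin `(t-2, t-1]`.
#' @export
select_sample_times <- function(labels, n_hours, horizon_h, seed = 1L) {
  stopifnot(horizon_h %in% 0:4)
  nh <- n_hours[labels$stay_id]
  t <- integer(nrow(labels))
  sep <- labels$is_septic
  t[sep] <- labels$onset_hour[sep] - horizon_h
  lo <- max(2L, 7L - horizon_h)
  with_seed(seed, {
    for (i in which(!sep)) {
      if (nh[i] < lo) stopf("insufficient history: stay %s has %d bins",
                            labels$stay_id[i], nh[i])
      t[i] <- sample(seq.int(lo, nh[i]), 1L)
    }
  })
  if (any(t < 2)) stopf("insufficient history: prediction hour below 2")
  names(t) <- labels$stay_id
  t
}

clamp_prior <- function(labels) {
  p <- mean(labels)
  if (p <= 0 || p >= 1) {
    warnf("single-class training data; posterior maps degenerate to prior")
    p <- (sum(labels) + 0.5) / (length(labels) + 1)
  }
  p
}

# Quantile bin interior breaks for one variable; may collapse below the
# requested count when the data are heavily tied.
quantile_breaks <- function(x, n_bins) {
  qs <- stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins,
                        names = FALSE, type = 7)
  unique(qs)
}

#' Fit a smoothed one-dimensional posterior-probability map
#'
#' Estimates `P(class = 1 | v)` for a single clinical variable (a level or
#' an hour-to-hour delta) on training data only. The variable is cut into
#' equal-mass (quantile) bins; each bin's posterior is the shrunken count
#' ratio `(n1 + alpha * prior) / (n + alpha)` where `prior` is the training
#' prevalence, so empty or tiny bins fall back toward the prior and every
#' value lies strictly inside (0, 1). Evaluation interpolates linearly
#' between bin centers and extrapolates as a constant.
#'
#' @param values training values of the variable (at least 2 distinct).
#' @param labels 0/1 training classes.
#' @param n_bins number of quantile bins.
#' @param alpha shrinkage pseudo-count.
#' @return object of class `vs_posterior_map` with `breaks`, `centers`,
#'   `posterior`, `prior`.
#' @export
fit_posterior_1d <- function(values, labels, n_bins = 20, alpha = 10) {
  stopifnot(length(values) == length(labels))
  prior <- clamp_prior(labels)
  breaks <- quantile_breaks(values, n_bins)
  bin <- findInterval(values, breaks) + 1L
  k <- length(breaks) + 1L
  n <- tabulate(bin, k)
  n1 <- tabulate(bin[labels == 1], k)
  posterior <- (n1 + alpha * prior) / (n + alpha)
  edges <- c(min(values), breaks, max(values))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(breaks = breaks, centers = centers,
                 posterior = posterior, prior = prior),
            class = "vs_posterior_map")
}

#' Evaluate a one-dimensional posterior map
#'
#' @param map a `vs_posterior_map`.
#' @param x values to evaluate at.
#' @return posterior probabilities in (0, 1).
#' @export
eval_posterior_1d <- function(map, x) {
  if (length(map$posterior) == 1) return(rep(map$posterior, length(x)))
  if (length(unique(map$centers)) < 2) {
    # degenerate zero-width bins (heavily tied variable): bin lookup only
    return(map$posterior[findInterval(x, map$breaks) + 1L])
  }
  stats::approx(map$centers, map$posterior, xout = x, rule = 2,
                ties = list("ordered", mean))$y
}

#' Fit a tabular posterior over 2 or 3 delta variables
#'
#' Each variable is discretized into equal-mass bins on the training data;
#' the joint cell posterior is the same shrunken count ratio as in
#' [fit_posterior_1d()], so cells with no training mass equal the training
#' prevalence exactly.
#'
#' @param deltas training matrix (rows = samples) whose columns include the
#'   combination.
#' @param labels 0/1 training classes.
#' @param combo character vector of 2 or 3 column names.
#' @param bins_per_var equal-mass bins per variable.
#' @param alpha shrinkage pseudo-count.
#' @return object of class `vs_posterior_table`.
#' @export
fit_posterior_table <- function(deltas, labels, combo, bins_per_var = 5,
                                alpha = 10) {
  stopifnot(length(combo) %in% c(2, 3), all(combo %in% colnames(deltas)))
  prior <- clamp_prior(labels)
  breaks <- lapply(combo, function(ch)
    quantile_breaks(deltas[, ch], bins_per_var))
  names(breaks) <- combo
  dims <- vapply(breaks, function(b) length(b) + 1L, integer(1))
  cell <- table_cell_index(deltas[, combo, drop = FALSE], breaks, dims)
  k <- prod(dims)
  n <- tabulate(cell, k)
  n1 <- tabulate(cell[labels == 1], k)
  posterior <- (n1 + alpha * prior) / (n + alpha)
  structure(list(combo = combo, breaks = breaks, dims = dims,
                 posterior = posterior, prior = prior),
            class = "vs_posterior_table")
}

table_cell_index <- function(x, breaks, dims) {
  cell <- rep(1L, nrow(x))
  stride <- 1L
  for (j in seq_along(dims)) {
    bj <- findInterval(x[, j], breaks[[j]])
    cell <- cell + bj * stride
    stride <- stride * dims[j]
  }
  cell
}

#' Evaluate a tabular posterior
#'
#' @param tab a `vs_posterior_table`.
#' @param deltas matrix with the table's columns.
#' @return posterior probabilities in (0, 1).
#' @export
eval_posterior_table <- function(tab, deltas) {
  cell <- table_cell_index(deltas[, tab$combo, drop = FALSE],
                           tab$breaks, tab$dims)
  tab$posterior[cell]
}

delta_combos <- function(config) {
  dyn <- dynamic_channels()
  pairs <- config$pairs
  triples <- config$triples
  if (identical(pairs, "all")) {
    pairs <- utils::combn(dyn, 2, simplify = FALSE)
  }
  if (identical(triples, "all")) {
    triples <- utils::combn(dyn, 3, simplify = FALSE)
  }
  c(pairs, triples)
}

#' Extract the two-hour input window for a set of stays
#'
#' For each stay, `x1` holds the imputed values of hourly bin `(t-1, t]` for
#' the seven dynamic channels plus age, and `x2` the values of bin
#' `(t-2, t-1]` for the dynamic channels only (age is static and enters
#' once).
#'
#' @param timelines named list of `vs_timeline`.
#' @param sample_hours named integer vector of prediction hours `t >= 2`.
#' @param ages named numeric vector of ages.
#' @return list with matrices `x1` (n x 8) and `x2` (n x 7), rows named by
#'   stay.
#' @export
extract_window <- function(timelines, sample_hours, ages) {
  ids <- names(sample_hours)
  dyn <- dynamic_channels()
  x1 <- matrix(NA_real_, length(ids), length(dyn) + 1L,
               dimnames = list(ids, c(dyn, "age")))
  x2 <- matrix(NA_real_, length(ids), length(dyn),
               dimnames = list(ids, dyn))
  for (i in seq_along(ids)) {
    tl <- timelines[[ids[i]]]
    t <- sample_hours[[i]]
    if (t < 2 || t > tl$n_hours) stopf("insufficient history for stay %s",
                                       ids[i])
    if (any(tl$all_missing[dyn])) {
      stopf("incomplete stay %s: channel(s) %s never observed", ids[i],
            paste(dyn[tl$all_missing[dyn]], collapse = ", "))
    }
    x1[i, ] <- c(tl$values[t, dyn], ages[[ids[i]]])
    x2[i, ] <- tl$values[t - 1L, dyn]
  }
  list(x1 = x1, x2 = x2)
}

#' Fit the full feature model on a training fold
#'
#' Fits, exclusively on the training rows: z-score standardization of the
#' `x1`/`x2` blocks, one-dimensional posterior maps for each `x1` channel
#' and each delta channel, and tabular posteriors for every configured pair
#' and triple of delta channels.
#'
#' @param x1,x2 window matrices from [extract_window()] (training rows).
#' @param labels 0/1 training classes.
#' @param config a [vs_config()].
#' @return object of class `vs_feature_model` with a fixed feature layout.
#' @export
fit_feature_model <- function(x1, x2, labels, config = vs_config()) {
  dyn <- dynamic_channels()
  dx <- x1[, dyn, drop = FALSE] - x2
  std <- function(m) {
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    sd[!is.finite(sd) | sd == 0] <- 1
    list(mean = mu, sd = sd)
  }
  maps_x1 <- lapply(colnames(x1), function(ch)
    fit_posterior_1d(x1[, ch], labels, config$n_bins_1d, config$alpha_1d))
  names(maps_x1) <- colnames(x1)
  maps_dx <- lapply(dyn, function(ch)
    fit_posterior_1d(dx[, ch], labels, config$n_bins_1d, config$alpha_1d))
  names(maps_dx) <- dyn
  combos <- delta_combos(config)
  tables <- lapply(combos, function(cmb)
    fit_posterior_table(dx, labels, cmb, config$n_bins_table,
                        config$alpha_table))
  layout <- c(paste0("z_x1_", colnames(x1)),
              paste0("z_x2_", dyn),
              paste0("p_x1_", colnames(x1)),
              paste0("p_dx_", dyn),
              vapply(combos, function(cmb)
                paste0("p_", paste(cmb, collapse = ".")), character(1)))
  structure(list(std_x1 = std(x1), std_x2 = std(x2),
                 maps_x1 = maps_x1, maps_dx = maps_dx,
                 tables = tables, layout = layout,
                 prior = clamp_prior(labels)),
            class = "vs_feature_model")
}

#' @export
print.vs_feature_model <- function(x, ...) {
  cat(sprintf(
    "<vs_feature_model> %d features (%d 1-D maps, %d tables), prior %.3f\n",
    length(x$layout), length(x$maps_x1) + length(x$maps_dx),
    length(x$tables), x$prior))
  invisible(x)
}

#' Build the feature matrix for a set of window rows
#'
#' Concatenates, in fixed order: standardized `x1` (8 channels including
#' age), standardized `x2` (7 dynamic channels), the one-dimensional
#' posterior features of each `x1` channel and each delta channel, and the
#' tabular pair/triple posterior features. With the default configuration
#' the feature vector has length 8 + 7 + 8 + 7 + 21 + 35 = 86.
#'
#' @param fm a `vs_feature_model`.
#' @param x1,x2 window matrices from [extract_window()].
#' @return numeric matrix, columns named by the model layout.
#' @export
build_feature_matrix <- function(fm, x1, x2) {
  dyn <- dynamic_channels()
  dx <- x1[, dyn, drop = FALSE] - x2
  z1 <- sweep(sweep(x1, 2, fm$std_x1$mean), 2, fm$std_x1$sd, "/")
  z2 <- sweep(sweep(x2, 2, fm$std_x2$mean), 2, fm$std_x2$sd, "/")
  p1 <- vapply(colnames(x1), function(ch)
    eval_posterior_1d(fm$maps_x1[[ch]], x1[, ch]),
    numeric(nrow(x1)))
  pd <- vapply(dyn, function(ch)
    eval_posterior_1d(fm$maps_dx[[ch]], dx[, ch]),
    numeric(nrow(x1)))
  pt <- vapply(fm$tables, function(tab)
    eval_posterior_table(tab, dx), numeric(nrow(x1)))
  as_cols <- function(m) if (is.matrix(m)) m else matrix(m, nrow = nrow(x1))
  xi <- cbind(z1, z2, as_cols(p1), as_cols(pd), as_cols(pt))
  colnames(xi) <- fm$layout
  rownames(xi) <- rownames(x1)
  xi
}
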