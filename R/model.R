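#' Cross-validation experiment plan
#'
#' @param n_partitionings independent random partitionings of the cohort
#'   into folds.
#' @param n_folds folds per partitioning (stays are assigned to exactly one
#'   fold; folds are stay-disjoint).
#' @param horizons prediction horizons in hours.
#' @param base_seed seed from which every partitioning, sampling and
#'   training seed is derived.
#' @param stratify stratify fold assignment by class so every fold contains
#'   both classes.
#' @return list of class `vs_plan`.
#' @export
vs_plan <- function(n_partitionings = 4, n_folds = 4, horizons = 0:4,
                    base_seed = 20160930, stratify = TRUE) {
  structure(list(n_partitionings = n_partitionings, n_folds = n_folds,
                 horizons = horizons, base_seed = as.integer(base_seed),
                 stratify = stratify),
            class = "vs_plan")
}

#' Train the elastic-net sepsis classifier
#'
#' Penalized logistic regression (logistic loss with an elastic-net
#' penalty), which induces sparsity among the feature weights. Classes are
#' weighted inversely to their frequency so sensitivity and specificity are
#' valued equally. The penalty mixing and strength are chosen by an inner
#' cross-validation over a grid of mixing values and an automatic
#' logarithmic path of strengths.
#'
#' @param xi feature matrix from [build_feature_matrix()] (training rows).
#' @param labels 0/1 training classes (both must be present).
#' @param config a [vs_config()].
#' @param seed seed for the inner-CV fold assignment.
#' @return object of class `vs_model` with elements `fit` (the selected
#'   `cv.glmnet` object), `alpha`, `lambda`, `weights` (fitted coefficient
#'   vector), `intercept`, `layout`.
#' @export
train_model <- function(xi, labels, config = vs_config(), seed = 1L) {
  if (length(unique(labels)) < 2) stopf("training set has a single class")
  p1 <- mean(labels)
  w <- ifelse(labels == 1, 0.5 / p1, 0.5 / (1 - p1))
  fits <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(config$inner_folds), length(labels)))
    lapply(config$enet_alpha, function(a) {
      withCallingHandlers(
        glmnet::cv.glmnet(xi, labels, family = "binomial", alpha = a,
                          weights = w, foldid = foldid,
                          nlambda = config$enet_nlambda,
                          # floor the penalty path: separable synthetic folds
                          # otherwise chase unbounded log-odds at tiny lambda
                          lambda.min.ratio = 0.01,
                          type.measure = "deviance"),
        # routine on small inner folds; the fit is still usable
        warning = function(w) {
          if (grepl("fewer than 8", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    })
  })
  best <- which.min(vapply(fits, function(f) min(f$cvm), numeric(1)))
  fit <- fits[[best]]
  beta <- as.numeric(stats::coef(fit, s = "lambda.min"))
  structure(list(fit = fit, alpha = config$enet_alpha[best],
                 lambda = fit$lambda.min,
                 weights = beta[-1], intercept = beta[1],
                 layout = colnames(xi)),
            class = "vs_model")
}

#' @export
print.vs_model <- function(x, ...) {
  cat(sprintf(
    "<vs_model> %d features, %d nonzero weights, alpha %.2f, lambda %.4g\n",
    length(x$weights), sum(x$weights != 0), x$alpha, x$lambda))
  invisible(x)
}

#' Predict sepsis risk scores
#'
#' Deterministic sigmoid of the linear predictor of a fitted model; rows
#' must use the model's own feature layout.
#'
#' @param model a `vs_model`.
#' @param xi feature matrix with the model's columns.
#' @return numeric risk scores in (0, 1).
#' @export
predict_risk <- function(model, xi) {
  if (!identical(colnames(xi), model$layout)) {
    stopf("feature layout mismatch between model and input rows")
  }
  as.numeric(stats::plogis(model$intercept +
                             drop(xi %*% model$weights)))
}

#' Write a fitted model to a structured text file
#'
#' Serializes the coefficient vector, intercept, selected hyperparameters
#' and feature layout as JSON. A model read back with [read_model()]
#' produces bit-identical risk scores.
#'
#' @param model a `vs_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(package = "vitalsep", class = "vs_model",
         alpha = model$alpha, lambda = model$lambda,
         intercept = model$intercept, weights = model$weights,
         layout = model$layout),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON model file.
#' @return a `vs_model` (coefficients only; the cross-validation object is
#'   not persisted).
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$class, "vs_model")) stopf("not a vs_model file: %s", path)
  structure(list(fit = NULL, alpha = m$alpha, lambda = m$lambda,
                 weights = as.numeric(m$weights),
                 intercept = as.numeric(m$intercept),
                 layout = as.character(m$layout)),
            class = "vs_model")
}

assign_folds <- function(labels, n_folds, seed, stratify = TRUE) {
  n <- length(labels)
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(n_folds), n))
    }
    fold
  })
}

#' Run the cross-validated multi-horizon experiment
#'
#' For each independent partitioning, each held-out fold, and each
#' prediction horizon: prediction hours are sampled (nonseptic stays are
#' resampled per partitioning, seeded), the feature model is fit on the
#' three training folds only, the elastic-net classifier is trained on the
#' training features, and discrimination is measured on the held-out fold.
#'
#' @param cohort a [vs_cohort()].
#' @param labels labels from [label_cohort()] (full data).
#' @param stay_ids included stays (e.g. from [apply_inclusion_criteria()]).
#' @param plan a [vs_plan()].
#' @param config a [vs_config()].
#' @param timelines optional prebuilt timelines (e.g. thinned ones for
#'   dropout runs); defaults to timelines of the cohort's observations.
#' @return list with `results` (one row per partitioning/fold/horizon:
#'   `auroc`, `apr`, `n_test`, `n_pos`) and `scores` (per-stay test-fold
#'   risk scores, pooled across folds).
#' @export
run_cv_experiment <- function(cohort, labels, stay_ids, plan = vs_plan(),
                              config = vs_config(), timelines = NULL) {
  timelines <- timelines %||% build_timelines(cohort, config)
  labels <- labels[match(stay_ids, labels$stay_id), ]
  y <- as.integer(labels$is_septic)
  ages <- stats::setNames(cohort$stays$age_years, cohort$stays$stay_id)
  n_hours <- vapply(timelines, function(tl) tl$n_hours, integer(1))

  res <- list()
  sc <- list()
  for (p in seq_len(plan$n_partitionings)) {
    fold <- assign_folds(y, plan$n_folds,
                         derive_seed(plan$base_seed, p, 0L), plan$stratify)
    for (h in plan$horizons) {
      t_all <- select_sample_times(labels, n_hours, h,
                                   derive_seed(plan$base_seed, p, 100L + h))
      win <- extract_window(timelines, t_all, ages)
      for (f in seq_len(plan$n_folds)) {
        tr <- fold != f
        te <- fold == f
        if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
          warnf("partition %d fold %d horizon %d skipped: single class",
                p, f, h)
          next
        }
        fm <- fit_feature_model(win$x1[tr, , drop = FALSE],
                                win$x2[tr, , drop = FALSE], y[tr], config)
        m <- train_model(
          build_feature_matrix(fm, win$x1[tr, , drop = FALSE],
                               win$x2[tr, , drop = FALSE]),
          y[tr], config, derive_seed(plan$base_seed, p, 200L + h, f))
        s <- predict_risk(
          m, build_feature_matrix(fm, win$x1[te, , drop = FALSE],
                                  win$x2[te, , drop = FALSE]))
        res[[length(res) + 1]] <- data.frame(
          partitioning = p, fold = f, horizon = h,
          auroc = roc_auc(s, y[te])$auc, apr = pr_auc(s, y[te])$auc,
          n_test = sum(te), n_pos = sum(y[te]))
        sc[[length(sc) + 1]] <- data.frame(
          partitioning = p, fold = f, horizon = h,
          stay_id = stay_ids[te], hour = t_all[te],
          score = s, label = y[te])
      }
    }
  }
  out <- list(results = do.call(rbind, res), scores = do.call(rbind, sc))
  rownames(out$results) <- rownames(out$scores) <- NULL
  out
}

#' Pooled cross-validated AUROC per horizon
#'
#' Pools test-fold scores within each partitioning and averages the
#' resulting AUROC across partitionings.
#'
#' @param cv result of [run_cv_experiment()].
#' @return data.frame `horizon`, `auroc_pooled` (mean over partitionings),
#'   `auroc_mean`, `auroc_sd` (over the individual fold results).
#' @export
summarize_cv <- function(cv) {
  sc <- data.table::as.data.table(cv$scores)
  pooled <- sc[, list(auroc = roc_auc(score, label)$auc),
               by = list(horizon, partitioning)]
  pooled <- pooled[, list(auroc_pooled = mean(auroc)), by = horizon]
  res <- data.table::as.data.table(cv$results)
  folds <- res[, list(auroc_mean = mean(auroc), auroc_sd = stats::sd(auroc),
                      apr_mean = mean(apr)), by = horizon]
  as.data.frame(merge(pooled, folds, by = "horizon"))
}
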