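# Multivariate stage: the classification-power statistic
# (sensitivity + specificity, range [0, 2]) estimated by repeated
# stratified train/test splits of a small classifier, and its null
# distribution over random marker subsets.

#' Classifier settings
#'
#' The default classifier is a single-hidden-layer neural network
#' (`nnet::nnet`, logistic activations) with weight decay — small enough to
#' fit on training sets of a dozen subjects. A closed-form ridge
#' least-squares discriminant (`type = "ridge"`) is provided as a fully
#' deterministic alternative for reproducibility checks.
#'
#' @param type `"nnet"` (default) or `"ridge"`.
#' @param hidden_units Hidden-layer size (default 2; `nnet` only).
#' @param weight_decay L2 penalty (default 0.01; ridge penalty for
#'   `type = "ridge"`).
#' @param max_iterations Optimizer iteration cap (default 500).
#' @param seed Integer seed for weight initialization (default 1).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(type = c("nnet", "ridge"), hidden_units = 2,
                              weight_decay = 0.01, max_iterations = 500,
                              seed = 1L) {
  type <- match.arg(type)
  if (hidden_units < 1) abort("`hidden_units` must be at least 1.")
  if (weight_decay < 0) abort("`weight_decay` must be non-negative.")
  structure(list(type = type, hidden_units = as.integer(hidden_units),
                 weight_decay = weight_decay,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Cross-validation settings
#'
#' A "50-fold" resampling of 20 subjects cannot be a 50-way partition; the
#' harness is Monte-Carlo cross-validation: `n_splits` independent
#' stratified random train/test splits, each holding out `test_fraction`
#' of every class.
#'
#' @param n_splits Number of random splits (default 50).
#' @param test_fraction Fraction of each class held out per split
#'   (default 1/3).
#' @param stratified Stratify the split by class (default `TRUE`).
#' @param seed Integer seed driving the splits (default 1).
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_splits = 50, test_fraction = 1 / 3,
                      stratified = TRUE, seed = 1L) {
  if (n_splits < 1) abort("`n_splits` must be at least 1.")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    abort("`test_fraction` must be in (0, 1).")
  }
  structure(list(n_splits = as.integer(n_splits),
                 test_fraction = test_fraction,
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_config")
}

#' Fit the risk classifier on a feature matrix
#'
#' Trains the configured classifier to predict the probability that a
#' subject is caries-active. Features are expected already scaled (the CV
#' harness z-scores on the training split); labels must contain both
#' classes. Training is deterministic given `config$seed`.
#'
#' @param features Numeric matrix, subjects in rows, markers in columns; no
#'   missing values.
#' @param labels Character vector of `"CA"` / `"CF"`, one per row.
#' @param config A [classifier_config()].
#' @return A `simma_classifier` with a `predict()` method returning the
#'   probability of caries-active.
#' @export
fit_classifier <- function(features, labels, config = classifier_config()) {
  features <- as.matrix(features)
  if (anyNA(features)) abort("Features must be imputed before fitting.")
  if (length(unique(labels)) < 2) {
    abort("Training labels contain a single class; both CA and CF are required.")
  }
  y <- as.numeric(labels == "CA")
  fit <- switch(config$type,
    nnet = with_local_seed(config$seed, {
      nnet::nnet(x = features, y = y, size = config$hidden_units,
                 decay = config$weight_decay, maxit = config$max_iterations,
                 entropy = TRUE, trace = FALSE)
    }),
    ridge = {
      # closed-form ridge regression on 0/1 labels, intercept unpenalized
      X <- cbind(1, features)
      pen <- diag(c(0, rep(config$weight_decay, ncol(features))))
      beta <- solve(crossprod(X) + pen, crossprod(X, y))
      list(beta = drop(beta))
    }
  )
  structure(list(type = config$type, fit = fit, config = config,
                 feature_names = colnames(features)),
            class = "simma_classifier")
}

#' Predict caries-active probability
#'
#' @param object A `simma_classifier`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.simma_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- switch(object$type,
    nnet = as.numeric(predict(object$fit, newdata)),
    ridge = {
      raw <- drop(cbind(1, newdata) %*% object$fit$beta)
      pmin(pmax(raw, 0), 1)
    }
  )
  p
}

# Predicted probability -> class call. Exact ties at the threshold go to
# CF, the risk-averse convention documented in the vignette.
call_class <- function(prob, threshold = 0.5) {
  ifelse(prob > threshold, "CA", "CF")
}

# Build the subject x marker feature matrix for one (timepoint, condition)
# cell, averaging duplicate observations.
panel_feature_matrix <- function(panel, markers, timepoint_h,
                                 condition = "baseline") {
  unknown <- setdiff(markers, panel$markers$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown marker name(s): ", paste(unknown, collapse = ", ")))
  }
  cell <- subset_panel(panel, timepoint_h, condition, markers = markers)
  if (nrow(cell$data) == 0) {
    abort(paste0("No samples at ", timepoint_h, " h (", condition, ")."))
  }
  wide <- tidyr::pivot_wider(
    dplyr::summarise(
      dplyr::group_by(cell$data, .data$subject_id, .data$group, .data$marker),
      concentration = mean(.data$concentration, na.rm = TRUE),
      .groups = "drop"),
    names_from = "marker", values_from = "concentration")
  X <- as.matrix(wide[, markers, drop = FALSE])
  X[is.nan(X)] <- NA_real_
  rownames(X) <- wide$subject_id
  list(X = X, labels = wide$group, subjects = wide$subject_id)
}

# Column means of the training block with an all-missing fallback of 0,
# used both for imputation and (with sds) z-scoring.
train_scaling <- function(X_train) {
  centers <- colMeans(X_train, na.rm = TRUE)
  centers[is.nan(centers)] <- 0
  scales <- apply(X_train, 2, stats::sd, na.rm = TRUE)
  scales[is.na(scales) | scales == 0] <- 1
  list(center = centers, scale = scales)
}

apply_scaling <- function(X, scaling) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- scaling$center[j]           # mean imputation from train
    X[, j] <- (x - scaling$center[j]) / scaling$scale[j]
  }
  X
}

#' Estimate the classification power of a marker set
#'
#' The headline multivariate statistic: power = sensitivity + specificity,
#' where sensitivity is the proportion of caries-active test subjects
#' classified correctly and specificity the proportion of caries-free,
#' each averaged over `cv$n_splits` stratified random train/test splits.
#' A chance-level classifier has expected power 1; a perfect one reaches
#' the maximum of 2. Within each split, features are z-scored with
#' training-split statistics only and missing values are mean-imputed from
#' the training split.
#'
#' @param panel A `marker_panel`.
#' @param markers Marker names forming the candidate set.
#' @param timepoint_h Hours since toothbrushing.
#' @param condition Condition label (default `"baseline"`).
#' @param cv A [cv_config()].
#' @param clf A [classifier_config()].
#' @return A `power_estimate`: list with `power`, `sensitivity`,
#'   `specificity`, `per_split` (tibble of per-split rates), `markers`,
#'   `timepoint_h`.
#' @export
classification_power <- function(panel, markers, timepoint_h,
                                 condition = "baseline",
                                 cv = cv_config(), clf = classifier_config()) {
  fm <- panel_feature_matrix(panel, markers, timepoint_h, condition)
  idx_ca <- which(fm$labels == "CA")
  idx_cf <- which(fm$labels == "CF")
  if (length(idx_ca) < 2 || length(idx_cf) < 2) {
    abort("Each group needs at least two subjects at the timepoint.")
  }
  n_test_ca <- max(1L, round(cv$test_fraction * length(idx_ca)))
  n_test_cf <- max(1L, round(cv$test_fraction * length(idx_cf)))
  n_all <- length(fm$labels)
  # Randomness attaches to subjects (one uniform per subject per split),
  # not to label names, so relabeling the groups reuses the same splits.
  splits <- with_local_seed(cv$seed, {
    lapply(seq_len(cv$n_splits), function(k) {
      if (cv$stratified) {
        u <- runif(n_all)
        c(idx_ca[order(u[idx_ca])][seq_len(n_test_ca)],
          idx_cf[order(u[idx_cf])][seq_len(n_test_cf)])
      } else {
        # unstratified draws are redrawn (bounded) until both classes
        # appear in train and test
        n_test <- max(2L, round(cv$test_fraction * n_all))
        for (try in 1:100) {
          test <- order(runif(n_all))[seq_len(n_test)]
          ok <- length(unique(fm$labels[test])) == 2 &&
            length(unique(fm$labels[-test])) == 2
          if (ok) return(test)
        }
        abort("Could not draw a split with both classes in train and test.")
      }
    })
  })
  per_split <- lapply(seq_along(splits), function(k) {
    test <- splits[[k]]
    scaling <- train_scaling(fm$X[-test, , drop = FALSE])
    X_train <- apply_scaling(fm$X[-test, , drop = FALSE], scaling)
    X_test <- apply_scaling(fm$X[test, , drop = FALSE], scaling)
    clf_k <- clf
    clf_k$seed <- clf$seed + k
    model <- fit_classifier(X_train, fm$labels[-test], clf_k)
    calls <- call_class(predict(model, X_test))
    truth <- fm$labels[test]
    tibble::tibble(
      split = k,
      sensitivity = mean(calls[truth == "CA"] == "CA"),
      specificity = mean(calls[truth == "CF"] == "CF")
    )
  })
  per_split <- dplyr::bind_rows(per_split)
  sens <- mean(per_split$sensitivity)
  spec <- mean(per_split$specificity)
  structure(list(power = sens + spec, sensitivity = sens, specificity = spec,
                 per_split = per_split, markers = markers,
                 timepoint_h = timepoint_h),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat("<power_estimate> ", length(x$markers), " markers at ",
      x$timepoint_h, " h\n", sep = "")
  cat(sprintf("  power %.3f = sensitivity %.3f + specificity %.3f (%d splits)\n",
              x$power, x$sensitivity, x$specificity, nrow(x$per_split)))
  invisible(x)
}

#' Null distribution of power over random marker subsets
#'
#' Draws `n_combinations` uniform random `k_markers`-subsets of the
#' panel's roster (subsets may repeat across draws), estimates each
#' subset's classification power, and summarizes the resulting empirical
#' distribution — the backdrop against which a selected panel is judged.
#' When `reference_markers` is supplied, its power and percentile within
#' the null are recorded.
#'
#' @param panel A `marker_panel` with at least `k_markers` markers.
#' @param timepoint_h Hours since toothbrushing.
#' @param k_markers Subset size (default 6).
#' @param n_combinations Number of random subsets (default 1000).
#' @param condition Condition label (default `"baseline"`).
#' @param cv,clf Cross-validation and classifier settings.
#' @param seed Integer seed for the subset draws and all nested resampling.
#' @param reference_markers Optional marker set to locate within the null.
#' @return A `null_distribution`: list with `powers`, `combinations`,
#'   `k_markers`, `n_combinations`, `median_power`, `reference_power`,
#'   `reference_percentile`.
#' @export
random_combination_null <- function(panel, timepoint_h, k_markers = 6,
                                    n_combinations = 1000,
                                    condition = "baseline",
                                    cv = cv_config(), clf = classifier_config(),
                                    seed = 1L, reference_markers = NULL) {
  roster <- panel$markers$name
  if (k_markers > length(roster)) {
    abort(paste0("`k_markers` (", k_markers, ") exceeds the roster size (",
                 length(roster), ")."))
  }
  combos <- with_local_seed(seed, {
    lapply(seq_len(n_combinations), function(i) sample(roster, k_markers))
  })
  powers <- vapply(seq_along(combos), function(i) {
    cv_i <- cv; cv_i$seed <- seed + i
    clf_i <- clf; clf_i$seed <- seed + i
    classification_power(panel, combos[[i]], timepoint_h, condition,
                         cv = cv_i, clf = clf_i)$power
  }, numeric(1))
  ref_power <- NULL
  ref_pct <- NULL
  if (!is.null(reference_markers)) {
    cv_r <- cv; cv_r$seed <- seed
    clf_r <- clf; clf_r$seed <- seed
    ref_power <- classification_power(panel, reference_markers, timepoint_h,
                                      condition, cv = cv_r, clf = clf_r)$power
    ref_pct <- 100 * mean(powers <= ref_power)
  }
  structure(list(powers = powers, combinations = combos,
                 k_markers = as.integer(k_markers),
                 n_combinations = as.integer(n_combinations),
                 median_power = median(powers),
                 reference_power = ref_power,
                 reference_percentile = ref_pct),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_combinations, " random ",
      x$k_markers, "-marker subsets\n", sep = "")
  cat(sprintf("  median power %.3f\n", x$median_power))
  if (!is.null(x$reference_power)) {
    cat(sprintf("  reference set: power %.3f (percentile %.1f)\n",
                x$reference_power, x$reference_percentile))
  }
  invisible(x)
}

#' Summarize a power estimate as a diagnostic report
#'
#' @param estimate A `power_estimate`.
#' @return A tibble with raw proportions and percentage renderings of
#'   sensitivity, specificity, power and the false-positive rate
#'   (1 - specificity).
#' @export
sensitivity_specificity_report <- function(estimate) {
  tibble::tibble(
    sensitivity = estimate$sensitivity,
    specificity = estimate$specificity,
    power = estimate$power,
    false_positive_rate = 1 - estimate$specificity,
    sensitivity_pct = 100 * estimate$sensitivity,
    specificity_pct = 100 * estimate$specificity,
    false_positive_pct = 100 * (1 - estimate$specificity)
  )
}
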