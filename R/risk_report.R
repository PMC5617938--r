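# Patient-facing output: per-marker local risk against caries-free
# reference intervals, per-category imbalance counts, a multivariate
# global risk probability, and an urgency count.

# A sample's concentration for one marker, NA when unobserved.
sample_value <- function(sample, marker) {
  v <- sample$concentrations
  if (marker %in% names(v)) unname(v[[marker]]) else NA_real_
}

#' Build caries-free reference intervals
#'
#' Computes, for each requested marker at one timepoint, a quantile
#' interval from caries-free subjects only — the healthy reference range a
#' patient's value is compared against. The default 0.05/0.95 pair is
#' wider than the screening dispersion boxes on purpose: an interquartile
#' flag would mark half of the healthy population out-of-range per marker.
#'
#' @param panel A `marker_panel` containing caries-free subjects at the
#'   timepoint.
#' @param timepoint_h Hours since toothbrushing.
#' @param markers Marker names to build references for.
#' @param ref_q_low,ref_q_high Reference quantile probabilities
#'   (default 0.05 and 0.95).
#' @param condition Condition label (default `"baseline"`).
#' @return A `reference_intervals` tibble with columns `marker`,
#'   `category`, `lower`, `upper`, `n_reference`, `available`; markers
#'   without caries-free data are kept with `available = FALSE`.
#' @export
build_reference_intervals <- function(panel, timepoint_h, markers,
                                      ref_q_low = 0.05, ref_q_high = 0.95,
                                      condition = "baseline") {
  validate_panel(panel)
  unknown <- setdiff(markers, panel$markers$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown marker name(s): ", paste(unknown, collapse = ", ")))
  }
  cf_any <- any(panel$data$group == "CF" &
                  tp_match(panel$data$timepoint_h, timepoint_h) &
                  panel$data$condition == condition)
  if (!cf_any) {
    abort(paste0("No caries-free subjects at ", timepoint_h,
                 " h (", condition, ") to build references from."))
  }
  cats <- setNames(panel$markers$category, panel$markers$name)
  rows <- lapply(markers, function(mk) {
    v <- panel_values(panel, mk, "CF", timepoint_h, condition)
    if (length(v) == 0) {
      return(tibble::tibble(marker = mk, category = cats[[mk]],
                            lower = NA_real_, upper = NA_real_,
                            n_reference = 0L, available = FALSE))
    }
    qi <- quantile_interval(v, ref_q_low, ref_q_high)
    tibble::tibble(marker = mk, category = cats[[mk]],
                   lower = qi$lower, upper = qi$upper,
                   n_reference = length(v), available = TRUE)
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("reference_intervals", class(res))
  attr(res, "timepoint_h") <- timepoint_h
  attr(res, "q_low") <- ref_q_low
  attr(res, "q_high") <- ref_q_high
  res
}

#' Flag a patient's markers against healthy reference intervals
#'
#' The univariate ("local") arm of the risk report. A marker is
#' `out_of_range` iff its value lies strictly outside the closed reference
#' interval — boundary values count as in-range. Missing values and
#' unavailable references yield `no_data` and are excluded from counts.
#'
#' @param sample A `saliva_sample` (see [extract_sample()]).
#' @param refs A `reference_intervals` table.
#' @return A list with `marker_flags` (named character:
#'   `"in_range"` / `"out_of_range"` / `"no_data"`), `category_imbalance`
#'   (named integer count of out-of-range markers per category) and
#'   `urgency_count` (their sum).
#' @export
local_risk <- function(sample, refs) {
  flags <- vapply(seq_len(nrow(refs)), function(i) {
    mk <- refs$marker[i]
    v <- sample_value(sample, mk)
    if (!refs$available[i] || is.na(v)) return("no_data")
    if (v < refs$lower[i] || v > refs$upper[i]) "out_of_range" else "in_range"
  }, character(1))
  names(flags) <- refs$marker
  imbalance <- vapply(simma_categories(), function(cc) {
    sum(flags == "out_of_range" & refs$category == cc)
  }, integer(1))
  list(marker_flags = flags,
       category_imbalance = imbalance,
       urgency_count = sum(imbalance))
}

#' Train the multivariate risk model on a cohort
#'
#' Fits the configured classifier to the full cohort at one timepoint,
#' storing the training scaling statistics (means, standard deviations)
#' and imputation means so later patient samples are mapped into the same
#' feature space.
#'
#' @param panel A `marker_panel` with both groups at the timepoint.
#' @param markers Marker names used as features.
#' @param timepoint_h Hours since toothbrushing.
#' @param condition Condition label (default `"baseline"`).
#' @param clf A [classifier_config()].
#' @return A `risk_model`: list with the fitted classifier, `markers`,
#'   `timepoint_h`, `condition` and `scaling`.
#' @export
train_risk_model <- function(panel, markers, timepoint_h,
                             condition = "baseline",
                             clf = classifier_config()) {
  fm <- panel_feature_matrix(panel, markers, timepoint_h, condition)
  scaling <- train_scaling(fm$X)
  X <- apply_scaling(fm$X, scaling)
  model <- fit_classifier(X, fm$labels, clf)
  structure(list(classifier = model, markers = markers,
                 timepoint_h = timepoint_h, condition = condition,
                 scaling = scaling),
            class = "risk_model")
}

#' Multivariate caries risk probability for one sample
#'
#' The "global" arm of the risk report: the trained model's probability
#' that the sample comes from a caries-active subject. Missing marker
#' values are imputed with the training means and reported via the
#' `imputed` attribute.
#'
#' @param sample A `saliva_sample`.
#' @param model A `risk_model` from [train_risk_model()].
#' @return Probability in \[0, 1\], with attribute `imputed` naming any
#'   mean-imputed markers.
#' @export
global_risk <- function(sample, model) {
  vals <- vapply(model$markers, function(mk) sample_value(sample, mk),
                 numeric(1))
  imputed <- model$markers[is.na(vals)]
  X <- matrix(vals, nrow = 1, dimnames = list(NULL, model$markers))
  X <- apply_scaling(X, model$scaling)
  p <- predict(model$classifier, X)
  structure(min(max(p, 0), 1), imputed = imputed)
}

#' Assemble the full risk report for one patient sample
#'
#' Combines the local (reference-interval) and global (multivariate) risk
#' arms into one report. The overall call is `"elevated"` iff the global
#' risk probability exceeds 0.5 or at least `urgency_threshold` markers
#' are out of range — a reporting convention of this package, configurable
#' here.
#'
#' @param sample A `saliva_sample`.
#' @param refs A `reference_intervals` table covering the sample's
#'   timepoint.
#' @param model A `risk_model` trained on the same markers and timepoint.
#' @param markers Marker names reported on (default: the model's).
#' @param urgency_threshold Out-of-range count that alone triggers an
#'   elevated call (default 2).
#' @return A `risk_report`: list with `subject_id`, `timepoint_h`,
#'   `marker_flags`, `category_imbalance`, `urgency_count`, `global_risk`,
#'   `overall_call`.
#' @export
simma_report <- function(sample, refs, model, markers = model$markers,
                         urgency_threshold = 2) {
  if (!setequal(markers, model$markers)) {
    abort("`markers` must match the marker set the risk model was trained on.")
  }
  if (!isTRUE(all.equal(attr(refs, "timepoint_h"), sample$timepoint_h))) {
    abort("Reference intervals do not cover the sample's timepoint.")
  }
  refs <- refs[refs$marker %in% markers, , drop = FALSE]
  loc <- local_risk(sample, refs)
  g <- global_risk(sample, model)
  call <- if (as.numeric(g) > 0.5 || loc$urgency_count >= urgency_threshold) {
    "elevated"
  } else {
    "low"
  }
  structure(list(subject_id = sample$subject_id,
                 timepoint_h = sample$timepoint_h,
                 marker_flags = loc$marker_flags,
                 category_imbalance = loc$category_imbalance,
                 urgency_count = loc$urgency_count,
                 global_risk = as.numeric(g),
                 overall_call = call),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("<risk_report> subject ", x$subject_id, " at ", x$timepoint_h, " h\n",
      sep = "")
  cat("  overall call:", x$overall_call,
      sprintf("(global risk %.3f, %d marker(s) out of range)\n",
              x$global_risk, x$urgency_count))
  oor <- names(x$marker_flags)[x$marker_flags == "out_of_range"]
  if (length(oor) > 0) cat("  out of range:", paste(oor, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a risk report to a flat record
#'
#' Flattens a `risk_report` into a named list of scalars (marker flags and
#' category counts become prefixed fields) suitable for JSON or CSV
#' persistence; [parse_risk_report()] inverts it losslessly.
#'
#' @param report A `risk_report`.
#' @return A named list of scalar fields.
#' @export
serialize_risk_report <- function(report) {
  rec <- list(subject_id = report$subject_id,
              timepoint_h = report$timepoint_h,
              urgency_count = report$urgency_count,
              global_risk = report$global_risk,
              overall_call = report$overall_call)
  for (mk in names(report$marker_flags)) {
    rec[[paste0("flag.", mk)]] <- unname(report$marker_flags[[mk]])
  }
  for (cc in names(report$category_imbalance)) {
    rec[[paste0("imbalance.", cc)]] <- unname(report$category_imbalance[[cc]])
  }
  rec
}

#' @rdname serialize_risk_report
#' @param record A named list produced by [serialize_risk_report()] (or
#'   parsed back from JSON).
#' @export
parse_risk_report <- function(record) {
  nm <- names(record)
  flag_fields <- nm[startsWith(nm, "flag.")]
  imb_fields <- nm[startsWith(nm, "imbalance.")]
  flags <- vapply(flag_fields, function(f) as.character(record[[f]]),
                  character(1))
  names(flags) <- sub("^flag\\.", "", flag_fields)
  imb <- vapply(imb_fields, function(f) as.integer(record[[f]]), integer(1))
  names(imb) <- sub("^imbalance\\.", "", imb_fields)
  structure(list(subject_id = record$subject_id,
                 timepoint_h = as.numeric(record$timepoint_h),
                 marker_flags = flags,
                 category_imbalance = imb,
                 urgency_count = as.integer(record$urgency_count),
                 global_risk = as.numeric(record$global_risk),
                 overall_call = record$overall_call),
            class = "risk_report")
}
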