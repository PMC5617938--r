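# Univariate screening: Wilcoxon rank-sum p-values, quantile intervals, the
# non-overlap criterion, per-category selection and within-group time
# contrasts.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' The univariate screen of the pipeline. Missing values are removed
#' test-wise. The exact null distribution is used when the smaller sample
#' has at most `exact_max_n` observations and there are no ties; otherwise
#' mid-ranks with the tie-corrected normal approximation and continuity
#' correction. Symmetric in its arguments and invariant under strictly
#' monotone transforms of the pooled values.
#'
#' @param x,y Numeric vectors (one group each); at least one non-missing
#'   value per group.
#' @param exact_max_n Largest min(n, m) for which the exact distribution is
#'   used (default 25).
#' @return The two-sided p-value.
#' @examples
#' rank_sum_p(c(1, 2), c(3, 4))   # 1/3, exact
#' @export
rank_sum_p <- function(x, y, exact_max_n = 25) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("Insufficient data: each group needs at least one non-missing value.")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= exact_max_n
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Empirical quantile interval of a sample
#'
#' Lower/upper quantiles by linear interpolation of order statistics
#' (`stats::quantile()` type 7). The interquartile interval (0.25/0.75) is
#' the dispersion box of the screening stage; wider pairs such as 0.05/0.95
#' serve as clinical reference intervals.
#'
#' @param values Numeric vector; missing values dropped; at least one
#'   non-missing value.
#' @param q_low,q_high Quantile probabilities, `0 <= q_low < q_high <= 1`.
#' @return A `quantile_interval`: list with `lower`, `upper`, `q_low`,
#'   `q_high`.
#' @export
quantile_interval <- function(values, q_low = 0.25, q_high = 0.75) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    abort("Insufficient data: no non-missing values for a quantile interval.")
  }
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1)) {
    abort("Quantile probabilities must satisfy 0 <= q_low < q_high <= 1.")
  }
  qq <- unname(quantile(values, c(q_low, q_high), type = 7))
  structure(list(lower = qq[1], upper = qq[2],
                 q_low = q_low, q_high = q_high),
            class = "quantile_interval")
}

#' Do two quantile intervals overlap?
#'
#' Closed-interval test: touching endpoints count as overlap, so a pair
#' that merely touches is never called "non-overlapping". Symmetric and
#' reflexive.
#'
#' @param a,b `quantile_interval` objects.
#' @return `TRUE` iff the closed intervals intersect.
#' @export
intervals_overlap <- function(a, b) {
  max(a$lower, b$lower) <= min(a$upper, b$upper)
}

#' Selection settings for the univariate screen
#'
#' @param alpha Significance level for the rank-sum screen (default 0.05;
#'   no multiple-testing correction is applied — see the vignette).
#' @param per_category Markers to select from each category (default 2).
#' @param require_nonoverlap Require group dispersion boxes not to overlap
#'   for unforced selection (default `TRUE`).
#' @param q_low,q_high Quantiles of the dispersion boxes (default the
#'   interquartile range, 0.25/0.75).
#' @return A `selection_config` list.
#' @export
selection_config <- function(alpha = 0.05, per_category = 2,
                             require_nonoverlap = TRUE,
                             q_low = 0.25, q_high = 0.75) {
  if (per_category < 1) abort("`per_category` must be at least 1.")
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1).")
  structure(list(alpha = alpha, per_category = as.integer(per_category),
                 require_nonoverlap = require_nonoverlap,
                 q_low = q_low, q_high = q_high),
            class = "selection_config")
}

#' Screen every marker for group separation at one timepoint
#'
#' For each marker, compares caries-active against caries-free
#' concentrations at the given (timepoint, condition) cell with
#' [rank_sum_p()], computes per-group quantile intervals and their overlap
#' flag, and returns one row per marker ordered by ascending p-value.
#' Markers with no usable data in one group are kept with
#' `insufficient = TRUE` rather than dropped.
#'
#' @param panel A `marker_panel` containing both groups at the timepoint.
#' @param timepoint_h Hours since toothbrushing.
#' @param condition Condition label (default `"baseline"`).
#' @param config A [selection_config()].
#' @return A `screen_result` tibble with columns `marker`, `category`,
#'   `timepoint_h`, `n_CA`, `n_CF`, `p_value`, `ca_lower`, `ca_upper`,
#'   `cf_lower`, `cf_upper`, `overlap`, `gap`, `insufficient`, `selected`,
#'   `forced`.
#' @export
screen_markers <- function(panel, timepoint_h, condition = "baseline",
                           config = selection_config()) {
  validate_panel(panel)
  cell <- subset_panel(panel, timepoint_h, condition)
  for (g in c("CA", "CF")) {
    if (!any(cell$data$group == g)) {
      abort(paste0("Group ", g, " has no samples at ", timepoint_h,
                   " h (", condition, "); both groups are required."))
    }
  }
  rows <- lapply(seq_len(nrow(panel$markers)), function(i) {
    mk <- panel$markers$name[i]
    ca <- panel_values(cell, mk, "CA", timepoint_h, condition)
    cf <- panel_values(cell, mk, "CF", timepoint_h, condition)
    base <- tibble::tibble(marker = mk,
                           category = panel$markers$category[i],
                           timepoint_h = timepoint_h,
                           n_CA = length(ca), n_CF = length(cf))
    if (length(ca) == 0 || length(cf) == 0) {
      return(dplyr::mutate(base, p_value = NA_real_,
                           ca_lower = NA_real_, ca_upper = NA_real_,
                           cf_lower = NA_real_, cf_upper = NA_real_,
                           overlap = NA, gap = NA_real_,
                           insufficient = TRUE))
    }
    int_ca <- quantile_interval(ca, config$q_low, config$q_high)
    int_cf <- quantile_interval(cf, config$q_low, config$q_high)
    dplyr::mutate(base,
                  p_value = rank_sum_p(ca, cf),
                  ca_lower = int_ca$lower, ca_upper = int_ca$upper,
                  cf_lower = int_cf$lower, cf_upper = int_cf$upper,
                  overlap = intervals_overlap(int_ca, int_cf),
                  # signed distance between the boxes: positive when they
                  # are separated, used to break p-value ties
                  gap = max(int_ca$lower, int_cf$lower) -
                    min(int_ca$upper, int_cf$upper),
                  insufficient = FALSE)
  })
  res <- dplyr::bind_rows(rows)
  res$selected <- FALSE
  res$forced <- FALSE
  res <- res[order(res$p_value, -res$gap, na.last = TRUE), , drop = FALSE]
  class(res) <- c("screen_result", class(res))
  attr(res, "config") <- config
  res
}

#' Select biomarkers per category from screen results
#'
#' Picks `per_category` markers from each of the three categories. Within a
#' category, markers meeting both criteria (p-value at most `alpha` and,
#' when required, non-overlapping group dispersion boxes) are ranked by
#' ascending p-value, ties broken by the larger separation between the
#' group intervals. When a category has fewer qualifying markers than
#' slots — as acid/buffering markers can in a morning sample — the
#' remaining slots are filled by ascending p-value regardless of the
#' criteria, and those picks are flagged `forced`.
#'
#' @param results A `screen_result` tibble from [screen_markers()].
#' @param config The [selection_config()] used (defaults to the one stored
#'   on `results`).
#' @return A character vector of `3 * per_category` marker names (category
#'   order immune, adhesion, pH), with attributes `forced` (logical,
#'   parallel to the names) and `results` (the input with `selected` and
#'   `forced` flags set).
#' @export
select_biomarkers <- function(results, config = NULL) {
  config <- config %||% attr(results, "config") %||% selection_config()
  missing_cat <- setdiff(simma_categories(), unique(results$category))
  if (length(missing_cat) > 0) {
    abort(paste0("No screened markers in category: ",
                 paste(missing_cat, collapse = ", ")))
  }
  picked <- character(0)
  picked_forced <- logical(0)
  for (cc in simma_categories()) {
    sub <- results[results$category == cc & !results$insufficient, ,
                   drop = FALSE]
    if (nrow(sub) == 0) {
      abort(paste0("No screened markers in category: ", cc))
    }
    sub <- sub[order(sub$p_value, -sub$gap), , drop = FALSE]
    ok <- sub$p_value <= config$alpha
    if (config$require_nonoverlap) ok <- ok & !sub$overlap
    eligible <- sub$marker[ok]
    take <- head(eligible, config$per_category)
    n_missing <- config$per_category - length(take)
    fill <- head(setdiff(sub$marker, take), n_missing)
    picked <- c(picked, take, fill)
    picked_forced <- c(picked_forced,
                       rep(FALSE, length(take)), rep(TRUE, length(fill)))
  }
  results$selected <- results$marker %in% picked
  results$forced <- results$marker %in% picked[picked_forced]
  structure(picked, forced = picked_forced, results = results)
}

#' Within-group Wilcoxon contrast between two timepoints
#'
#' Compares one marker's concentrations at two timepoints inside a single
#' clinical group — the test used to call a marker circadian (morning vs
#' afternoon) or clock-stable (morning vs next-morning). Unpaired rank-sum
#' by default; `paired = TRUE` runs the signed-rank test on within-subject
#' differences.
#'
#' @param panel A `marker_panel`.
#' @param marker Marker name.
#' @param group `"CA"` or `"CF"`.
#' @param t_a,t_b The two timepoints (hours since toothbrushing).
#' @param paired Use the signed-rank test on subject-matched differences?
#' @param condition Condition label (default `"baseline"`).
#' @return The two-sided p-value.
#' @export
time_contrast <- function(panel, marker, group, t_a, t_b,
                          paired = FALSE, condition = "baseline") {
  validate_panel(panel)
  if (!marker %in% panel$markers$name) {
    abort(paste0("Unknown marker name(s): ", marker))
  }
  if (paired) {
    dt <- panel$data
    pick <- function(tp) {
      keep <- dt$marker == marker & dt$group == group &
        tp_match(dt$timepoint_h, tp) & dt$condition == condition
      setNames(dt$concentration[keep], dt$subject_id[keep])
    }
    va <- pick(t_a); vb <- pick(t_b)
    common <- intersect(names(va)[!is.na(va)], names(vb)[!is.na(vb)])
    if (length(common) == 0) {
      abort(paste0("Insufficient data: no subjects of group ", group,
                   " observed at both ", t_a, " and ", t_b, " h."))
    }
    return(suppressWarnings(
      wilcox.test(va[common], vb[common], paired = TRUE)$p.value))
  }
  va <- panel_values(panel, marker, group, t_a, condition)
  vb <- panel_values(panel, marker, group, t_b, condition)
  if (length(va) == 0 || length(vb) == 0) {
    abort(paste0("Insufficient data: group ", group, " lacks observations of ",
                 marker, " at one of the timepoints."))
  }
  rank_sum_p(va, vb)
}
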