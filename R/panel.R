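#' Construct a longitudinal marker panel
#'
#' A `marker_panel` holds a salivary biomarker study in tidy long format: a
#' marker table (name, category, dilution) and an observation table with one
#' row per (subject, timepoint, condition, marker). Concentrations are
#' non-negative reals on opaque per-marker scales; missing values are `NA`.
#'
#' @param markers A data frame with columns `name` (unique marker
#'   identifiers), `category` (one of `"immune"`, `"adhesion"`, `"pH"`) and
#'   optionally `dilution` (positive ratio, metadata only; defaults to 1).
#' @param data A data frame with columns `subject_id`, `group` (`"CA"` for
#'   caries-active or `"CF"` for caries-free), `timepoint_h` (hours since
#'   toothbrushing), `condition` (`"baseline"` or `"sugar_rinse"`), `marker`
#'   and `concentration`.
#' @return An object of class `marker_panel` with elements `markers` and
#'   `data`, both tibbles.
#' @examples
#' mk <- tibble::tibble(name = c("IgA", "formate"),
#'                      category = c("immune", "pH"))
#' obs <- tibble::tibble(subject_id = "S1", group = "CF", timepoint_h = 0.5,
#'                       condition = "baseline",
#'                       marker = c("IgA", "formate"),
#'                       concentration = c(2.1, 0.4))
#' marker_panel(mk, obs)
#' @export
marker_panel <- function(markers, data) {
  markers <- tibble::as_tibble(markers)
  if (!"dilution" %in% names(markers)) {
    markers$dilution <- 1
  }
  markers <- markers[, c("name", "category", "dilution")]
  data <- tibble::as_tibble(data)[, panel_columns()[panel_columns() != "category"]]
  data$subject_id <- as.character(data$subject_id)
  data$marker <- as.character(data$marker)
  panel <- structure(list(markers = markers, data = data),
                     class = "marker_panel")
  validate_panel(panel)
}

panel_columns <- function() {
  c("subject_id", "group", "timepoint_h", "condition",
    "marker", "category", "concentration")
}

#' Validate a marker panel's invariants
#'
#' Checks marker-name uniqueness, category membership, group-label
#' consistency per subject, non-negative concentrations, and that every
#' observed marker is declared in the marker table.
#'
#' @param panel A `marker_panel`.
#' @return The panel, invisibly, if valid; otherwise an error naming the
#'   offending marker, subject or column.
#' @export
validate_panel <- function(panel) {
  if (!inherits(panel, "marker_panel")) {
    abort("`panel` must be a marker_panel object.")
  }
  mk <- panel$markers
  if (anyDuplicated(mk$name)) {
    dup <- unique(mk$name[duplicated(mk$name)])
    abort(paste0("Duplicate marker name(s) in panel: ",
                 paste(dup, collapse = ", ")))
  }
  bad_cat <- setdiff(unique(mk$category), simma_categories())
  if (length(bad_cat) > 0) {
    abort(paste0("Unknown marker category: ", paste(bad_cat, collapse = ", "),
                 " (must be one of ", paste(simma_categories(), collapse = ", "), ")"))
  }
  dt <- panel$data
  bad_grp <- setdiff(unique(dt$group), c("CA", "CF"))
  if (length(bad_grp) > 0) {
    abort(paste0("Unknown group label: ", paste(bad_grp, collapse = ", "),
                 " (must be CA or CF)"))
  }
  undeclared <- setdiff(unique(dt$marker), mk$name)
  if (length(undeclared) > 0) {
    abort(paste0("Observed marker(s) not declared in the marker table: ",
                 paste(undeclared, collapse = ", ")))
  }
  grp_per_subj <- tapply(dt$group, dt$subject_id, function(g) length(unique(g)))
  if (any(grp_per_subj > 1)) {
    bad <- names(grp_per_subj)[grp_per_subj > 1]
    abort(paste0("Inconsistent group label for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(dt$concentration < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative or missing.")
  }
  if (any(dt$timepoint_h < 0, na.rm = TRUE)) {
    abort("`timepoint_h` must be non-negative.")
  }
  invisible(panel)
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel>\n")
  cat("  markers: ", nrow(x$markers), " (",
      paste(vapply(simma_categories(), function(cc)
        paste0(cc, ": ", sum(x$markers$category == cc)), character(1)),
        collapse = ", "), ")\n", sep = "")
  cat("  subjects:", length(unique(x$data$subject_id)),
      " observations:", nrow(x$data), "\n")
  tps <- sort(unique(x$data$timepoint_h))
  cat("  timepoints (h):", paste(tps, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a panel to one timepoint and condition
#'
#' The screening and classification stages always work on a single
#' (timepoint, condition) cell of the study; this is the restriction they
#' use. Group labels are preserved.
#'
#' @param panel A `marker_panel`.
#' @param timepoint_h Hours since toothbrushing to keep.
#' @param condition Condition label to keep (default `"baseline"`).
#' @param markers Optional character vector of marker names to keep; all
#'   requested names must exist in the panel.
#' @return A `marker_panel` containing only the matching observations.
#' @export
subset_panel <- function(panel, timepoint_h, condition = "baseline",
                         markers = NULL) {
  validate_panel(panel)
  keep_mk <- panel$markers
  if (!is.null(markers)) {
    unknown <- setdiff(markers, keep_mk$name)
    if (length(unknown) > 0) {
      abort(paste0("Unknown marker name(s): ", paste(unknown, collapse = ", ")))
    }
    keep_mk <- keep_mk[keep_mk$name %in% markers, , drop = FALSE]
  }
  dt <- panel$data
  keep <- tp_match(dt$timepoint_h, timepoint_h) &
    dt$condition == condition &
    dt$marker %in% keep_mk$name
  structure(list(markers = keep_mk, data = dt[keep, , drop = FALSE]),
            class = "marker_panel")
}

#' The default 25-marker salivary roster
#'
#' The canonical panel measured in the underlying study design: 12 immune
#' markers (immunoglobulins, defensins, antimicrobial peptides, complement),
#' 7 adhesion markers (salivary scaffold proteins micro-organisms bind to)
#' and 6 acid-production/pH-buffering markers. Dilutions are assay metadata
#' only.
#'
#' @return A tibble with columns `name`, `category`, `dilution`.
#' @export
default_marker_roster <- function() {
  tibble::tribble(
    ~name,                    ~category,  ~dilution,
    "IgA",                    "immune",   1000,
    "IgG",                    "immune",   10,
    "IgM",                    "immune",   1,
    "alpha_defensin_1_3",     "immune",   10,
    "beta_defensin_1",        "immune",   1,
    "beta_defensin_2",        "immune",   1,
    "beta_defensin_3",        "immune",   1,
    "LL_37",                  "immune",   200,
    "lactoferrin",            "immune",   20,
    "calprotectin",           "immune",   1,
    "lysozyme",               "immune",   8000,
    "C3a",                    "immune",   10,
    "PRB1",                   "adhesion", 10,
    "statherin",              "adhesion", 200,
    "collagen_I",             "adhesion", 1,
    "mucin_7",                "adhesion", 50,
    "mucin_5B",               "adhesion", 100,
    "alpha_2_macroglobulin",  "adhesion", 4,
    "fibronectin",            "adhesion", 20,
    "lactate",                "pH",       20,
    "formate",                "pH",       5,
    "calcium",                "pH",       1,
    "phosphate",              "pH",       200,
    "urea",                   "pH",       25,
    "alpha_amylase",          "pH",       10
  )
}

#' Extract one subject's sample at a timepoint
#'
#' Pulls a single saliva sample — the unit the risk report operates on —
#' out of a panel.
#'
#' @param panel A `marker_panel`.
#' @param subject_id Subject identifier.
#' @param timepoint_h Hours since toothbrushing.
#' @param condition Condition label (default `"baseline"`).
#' @return A `saliva_sample`: a list with `subject_id`, `group`,
#'   `timepoint_h`, `condition` and `concentrations` (a named numeric
#'   vector, `NA` for missing).
#' @export
extract_sample <- function(panel, subject_id, timepoint_h,
                           condition = "baseline") {
  dt <- panel$data
  keep <- dt$subject_id == subject_id &
    tp_match(dt$timepoint_h, timepoint_h) &
    dt$condition == condition
  rows <- dt[keep, , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("No observations for subject ", subject_id,
                 " at ", timepoint_h, " h (", condition, ")."))
  }
  conc <- setNames(rows$concentration, rows$marker)
  structure(list(subject_id = subject_id,
                 group = rows$group[1],
                 timepoint_h = timepoint_h,
                 condition = condition,
                 concentrations = conc),
            class = "saliva_sample")
}

# Non-missing concentrations of one marker for one group at a
# (timepoint, condition) cell.
panel_values <- function(panel, marker, group, timepoint_h,
                         condition = "baseline", drop_na = TRUE) {
  dt <- panel$data
  keep <- dt$marker == marker & dt$group == group &
    tp_match(dt$timepoint_h, timepoint_h) & dt$condition == condition
  v <- dt$concentration[keep]
  if (drop_na) v <- v[!is.na(v)]
  v
}
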