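# Panel CSV persistence. The dialect is deliberately rigid: UTF-8, comma
# separated, header exactly
#   subject_id,group,timepoint_h,condition,marker,category,concentration
# one row per observation, empty string = missing concentration.

panel_csv_header <- function() {
  c("subject_id", "group", "timepoint_h", "condition",
    "marker", "category", "concentration")
}

#' Read a marker panel from a panel-CSV file
#'
#' Reads the tidy long panel dialect (header
#' `subject_id,group,timepoint_h,condition,marker,category,concentration`,
#' empty cells for missing concentrations) and validates all panel
#' invariants. Concentration cells that cannot be parsed as numbers become
#' missing, with one warning giving the count.
#'
#' @param path Path to a panel-CSV file.
#' @return A `marker_panel`.
#' @seealso [write_panel()] for the inverse operation.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Panel file not found: ", path))
  }
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, lazy = FALSE)
  missing_cols <- setdiff(panel_csv_header(), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Panel file is missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw$timepoint_h <- as.numeric(raw$timepoint_h)
  conc <- suppressWarnings(as.numeric(raw$concentration))
  n_bad <- sum(is.na(conc) & !is.na(raw$concentration) &
                 trimws(raw$concentration) != "")
  if (n_bad > 0) {
    warn(paste0(n_bad, " unparseable concentration cell(s) set to missing."))
  }
  raw$concentration <- conc
  markers <- dplyr::distinct(raw, name = .data$marker, category = .data$category)
  cat_per_marker <- tapply(markers$category, markers$name,
                           function(x) length(unique(x)))
  if (any(cat_per_marker > 1)) {
    bad <- names(cat_per_marker)[cat_per_marker > 1]
    abort(paste0("Marker(s) with more than one category: ",
                 paste(bad, collapse = ", ")))
  }
  marker_panel(markers, raw[, setdiff(panel_csv_header(), "category")])
}

#' Write a marker panel to a panel-CSV file
#'
#' Emits one row per (subject, timepoint, condition, marker) observation in
#' the panel-CSV dialect; missing concentrations become empty cells. Writing
#' then reading a panel reproduces its values, labels and missingness
#' exactly (dilution is metadata and is not persisted).
#'
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- dplyr::left_join(panel$data,
                          dplyr::rename(panel$markers, marker = "name"),
                          by = "marker")
  out <- out[, panel_csv_header()]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
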