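# Synthetic longitudinal panels.
#
# Concentrations are generated on the log scale and exponentiated, so they
# are positive and right-skewed as immunoassay panels are. For subject i in
# group g, marker m at t hours after toothbrushing:
#
#   log C = mu_m + beta_m * [g = CA] + u_i
#           + a_{m,g} * cos(2*pi * (clock(t) - peak) / period)
#           + s_m * t + eps,     eps ~ N(0, sigma_m^2),  u_i ~ N(0, sigma_subj^2)
#
# clock(t) = (brushing_clock_h + t) mod 24. The circadian term runs on clock
# time, not hours since brushing, so two morning samples taken 24 h apart
# agree — the structural signature of a clock-driven marker. The trend term
# runs on hours since brushing and models dental-plaque regrowth.

#' Specify generative effects for a set of markers
#'
#' Builds the per-marker effect table used by [simulate_panel()]. All
#' effects are on the natural-log concentration scale.
#'
#' @param name Character vector of marker names (unique).
#' @param category Marker categories (`"immune"`, `"adhesion"`, `"pH"`),
#'   recycled.
#' @param baseline_log_mean Log-concentration intercept, recycled.
#' @param group_shift Caries-active minus caries-free shift in log units,
#'   recycled. A planted discriminative marker has a nonzero shift.
#' @param circadian_amplitude_CF,circadian_amplitude_CA Non-negative
#'   amplitude of the 24 h cosine term per group, recycled. A positive CF
#'   amplitude with a zero CA amplitude reproduces the pattern where only
#'   healthy subjects show the morning-elevated U shape.
#' @param trend_slope Log-units per hour since toothbrushing, recycled;
#'   positive for markers that accumulate with plaque maturity, negative
#'   for those that wash out.
#' @param noise_sd Residual log-scale standard deviation, recycled; zero
#'   gives a noise-free deterministic panel.
#' @return A tibble with one row per marker.
#' @export
marker_effects <- function(name, category,
                           baseline_log_mean = 2,
                           group_shift = 0,
                           circadian_amplitude_CF = 0,
                           circadian_amplitude_CA = 0,
                           trend_slope = 0,
                           noise_sd = 0.5) {
  eff <- tibble::tibble(
    name = as.character(name),
    category = category,
    baseline_log_mean = baseline_log_mean,
    group_shift = group_shift,
    circadian_amplitude_CF = circadian_amplitude_CF,
    circadian_amplitude_CA = circadian_amplitude_CA,
    trend_slope = trend_slope,
    noise_sd = noise_sd
  )
  if (anyDuplicated(eff$name)) {
    abort("Marker names in an effect table must be unique.")
  }
  if (any(eff$noise_sd < 0)) {
    abort("`noise_sd` must be non-negative.")
  }
  if (any(eff$circadian_amplitude_CF < 0) || any(eff$circadian_amplitude_CA < 0)) {
    abort("Circadian amplitudes must be non-negative.")
  }
  eff
}

#' Configure a synthetic longitudinal study
#'
#' @param effects An effect table from [marker_effects()].
#' @param n_CA,n_CF Number of caries-active / caries-free subjects.
#' @param timepoints_h Sampling times in hours since toothbrushing.
#' @param circadian_period_h Period of the clock-time cosine (default 24).
#' @param circadian_peak_h Clock hour at which clock-driven markers peak
#'   (default 9, i.e. the morning samples sit near the crest).
#' @param brushing_clock_h Clock hour of toothbrushing, mapping hours since
#'   brushing onto clock time (default 9).
#' @param sigma_subject Standard deviation of the per-subject random
#'   intercept inducing within-subject correlation (default 0.3; set to 0
#'   for independent samples).
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate identical panels.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(effects, n_CA = 10, n_CF = 10,
                              timepoints_h = c(0.5, 6, 12, 24),
                              circadian_period_h = 24,
                              circadian_peak_h = 9,
                              brushing_clock_h = 9,
                              sigma_subject = 0.3,
                              seed = 1L) {
  if (n_CA < 1 || n_CF < 1) abort("Both groups need at least one subject.")
  if (length(timepoints_h) < 1) abort("At least one timepoint is required.")
  if (anyDuplicated(effects$name)) {
    abort("Marker names in an effect table must be unique.")
  }
  structure(list(effects = tibble::as_tibble(effects),
                 n_CA = as.integer(n_CA), n_CF = as.integer(n_CF),
                 timepoints_h = as.numeric(timepoints_h),
                 circadian_period_h = circadian_period_h,
                 circadian_peak_h = circadian_peak_h,
                 brushing_clock_h = brushing_clock_h,
                 sigma_subject = sigma_subject,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic marker panel
#'
#' Draws a full longitudinal panel (baseline condition) under the log-normal
#' model described in the package vignette: per-marker intercept, group
#' shift, per-subject random intercept, group-specific circadian cosine on
#' clock time, linear plaque-maturity trend on hours since brushing, and
#' log-normal noise. Deterministic given the config seed, and invariant to
#' the row order of the effect table.
#'
#' @param config A `simulation_config`.
#' @return A `marker_panel`.
#' @examples
#' eff <- marker_effects(c("IgA", "formate"), c("immune", "pH"),
#'                       group_shift = c(0, 1))
#' panel <- simulate_panel(simulation_config(eff, seed = 42))
#' panel
#' @export
simulate_panel <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("`config` must come from simulation_config().")
  }
  eff <- config$effects
  eff <- eff[order(eff$name), , drop = FALSE]  # RNG order fixed by name
  subjects <- tibble::tibble(
    subject_id = c(sprintf("CA%02d", seq_len(config$n_CA)),
                   sprintf("CF%02d", seq_len(config$n_CF))),
    group = rep(c("CA", "CF"), c(config$n_CA, config$n_CF))
  )
  grid <- tidyr::expand_grid(subjects,
                             marker = eff$name,
                             timepoint_h = config$timepoints_h)
  grid <- dplyr::left_join(grid, dplyr::rename(eff, marker = "name"),
                           by = "marker")
  draws <- with_local_seed(config$seed, {
    u <- rnorm(nrow(subjects), 0, config$sigma_subject)
    eps <- rnorm(nrow(grid)) * grid$noise_sd
    list(u = setNames(u, subjects$subject_id), eps = eps)
  })
  clock <- (config$brushing_clock_h + grid$timepoint_h) %% 24
  circ <- cos(2 * pi * (clock - config$circadian_peak_h) /
                config$circadian_period_h)
  amp <- ifelse(grid$group == "CA",
                grid$circadian_amplitude_CA, grid$circadian_amplitude_CF)
  log_conc <- grid$baseline_log_mean +
    grid$group_shift * (grid$group == "CA") +
    draws$u[grid$subject_id] +
    amp * circ +
    grid$trend_slope * grid$timepoint_h +
    draws$eps
  data <- tibble::tibble(
    subject_id = grid$subject_id,
    group = grid$group,
    timepoint_h = grid$timepoint_h,
    condition = "baseline",
    marker = grid$marker,
    concentration = exp(log_conc)
  )
  marker_panel(eff[, c("name", "category")], data)
}

#' Canonical synthetic study configuration
#'
#' Reproduces the structure of the motivating 24 h study: 10 caries-active
#' and 10 caries-free adults, the 25-marker default roster, sampling at
#' 0.5, 6, 12 and 24 h after a 9 a.m. toothbrushing. A chosen subset of
#' markers is "planted" with a caries-associated log-scale group shift; IgA,
#' beta-defensin 2 and beta-defensin 3 carry a circadian U shape in the
#' caries-free group (flat in caries-active for IgA and beta-defensin 2),
#' IgG declines and calprotectin rises with plaque maturity.
#'
#' @param planted Marker names receiving a nonzero group shift; must come
#'   from [default_marker_roster()]. Default: the six-marker afternoon
#'   panel (beta-defensin 2, LL-37, collagen I, fibronectin, formate,
#'   phosphate) — two markers per category.
#' @param effect_size Log-units of caries-active vs caries-free shift for
#'   planted markers (default 2).
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
default_study_config <- function(planted = canonical_biomarkers(),
                                 effect_size = 2, seed = 1L) {
  roster <- default_marker_roster()
  unknown <- setdiff(planted, roster$name)
  if (length(unknown) > 0) {
    abort(paste0("Planted marker(s) not in the default roster: ",
                 paste(unknown, collapse = ", ")))
  }
  circadian_cf <- c("IgA", "beta_defensin_2", "beta_defensin_3")
  circadian_ca <- "beta_defensin_3"  # clock-driven in both groups
  eff <- marker_effects(
    name = roster$name,
    category = roster$category,
    baseline_log_mean = 2,
    group_shift = ifelse(roster$name %in% planted, effect_size, 0),
    circadian_amplitude_CF = ifelse(roster$name %in% circadian_cf, 0.4, 0),
    circadian_amplitude_CA = ifelse(roster$name %in% circadian_ca, 0.4, 0),
    trend_slope = dplyr::case_when(
      roster$name == "IgG" ~ -0.03,
      roster$name == "calprotectin" ~ 0.03,
      .default = 0
    ),
    noise_sd = 0.5
  )
  simulation_config(eff, n_CA = 10, n_CF = 10,
                    timepoints_h = c(0.5, 6, 12, 24), seed = seed)
}

#' The canonical six-marker afternoon panel
#'
#' Two immune, two adhesion and two pH markers with the strongest
#' afternoon (6 h) discrimination in the motivating study design.
#'
#' @return A character vector of six marker names.
#' @export
canonical_biomarkers <- function() {
  c("beta_defensin_2", "LL_37", "collagen_I",
    "fibronectin", "formate", "phosphate")
}
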