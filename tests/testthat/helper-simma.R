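# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data files.

# Independent brute-force oracle for the two-sided rank-sum p-value:
# enumerate every C(n+m, n) assignment of the pooled ranks to group x and
# count assignments whose rank sum is at least as extreme (two-sided,
# distance from the null mean) as the observed one. Only valid without
# ties; deliberately shares no code with rank_sum_p().
rank_sum_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  assignments <- utils::combn(length(pooled), n)
  W <- apply(assignments, 2, function(i) sum(r[i]))
  mean(abs(W - mu) >= abs(obs - mu) - 1e-9)
}

# A small panel built from a wide table: one row per subject, columns are
# markers. All observations at a single timepoint/condition.
wide_panel <- function(values, groups, categories, timepoint_h = 6,
                       condition = "baseline") {
  markers <- tibble::tibble(name = colnames(values), category = categories)
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(values),
                  subject_id = sprintf("S%02d", seq_len(nrow(values))),
                  group = groups),
    cols = -c("subject_id", "group"),
    names_to = "marker", values_to = "concentration")
  long$timepoint_h <- timepoint_h
  long$condition <- condition
  marker_panel(markers, long)
}

# Panel with one marker per category where CA and CF are fully separated
# (no ties), plus optional pure-noise markers.
separated_panel <- function(n_per_group = 10, n_noise = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  vals <- cbind(
    imm = c(seq(11, 10 + n_per_group), seq_len(n_per_group)),
    adh = c(seq(21, 20 + n_per_group), seq(5, 4 + n_per_group)) + 0.5,
    acid = c(seq(31, 30 + n_per_group), seq(2, 1 + n_per_group)) + 0.25
  )
  cats <- c("immune", "adhesion", "pH")
  if (n_noise > 0) {
    noise <- matrix(rlnorm(n * n_noise), nrow = n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
    vals <- cbind(vals, noise)
    cats <- c(cats, rep(c("immune", "adhesion", "pH"), length.out = n_noise))
  }
  wide_panel(vals, rep(c("CA", "CF"), each = n_per_group), cats)
}

# A random valid panel for round-trip properties: random structure,
# missingness, and ragged observation sets.
random_panel <- function(seed) {
  set.seed(seed)
  n_mk <- sample(2:6, 1)
  markers <- tibble::tibble(
    name = paste0("m", seq_len(n_mk)),
    category = sample(c("immune", "adhesion", "pH"), n_mk, replace = TRUE)
  )
  n_subj <- sample(2:5, 1)
  subjects <- tibble::tibble(
    subject_id = paste0("P", seq_len(n_subj)),
    group = sample(c("CA", "CF"), n_subj, replace = TRUE)
  )
  grid <- tidyr::expand_grid(subjects,
                             timepoint_h = c(0.5, 6),
                             condition = c("baseline", "sugar_rinse"),
                             marker = markers$name)
  grid <- grid[runif(nrow(grid)) > 0.2, , drop = FALSE]  # ragged
  grid$concentration <- rlnorm(nrow(grid))
  grid$concentration[runif(nrow(grid)) < 0.15] <- NA_real_
  marker_panel(markers, grid)
}

# Effect-free default-study configuration (25 noise markers).
null_study_config <- function(seed) {
  default_study_config(planted = character(0), effect_size = 0, seed = seed)
}

# Fast CV/classifier settings for tests that do not probe the defaults.
fast_cv <- function(n_splits = 10, seed = 1) cv_config(n_splits = n_splits, seed = seed)
ridge_clf <- function(seed = 1) classifier_config(type = "ridge", seed = seed)
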