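test_that("rank_sum_p reproduces hand-derived exact values", {
  expect_equal(rank_sum_p(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rank_sum_p(c(1, 2), c(3, 4)), 1 / 3)
  # complete separation at n = m = 10: 1 of C(20,10) assignments per tail
  expect_equal(rank_sum_p(11:20, 1:10), 2 / 184756)
  # near-separation with rank-sum statistic three steps from the extreme:
  # 7 assignments per tail, i.e. the exact value 14/184756
  expect_equal(rank_sum_p(c(8, 12:20), c(1:7, 9, 10, 11)), 14 / 184756)
})

test_that("rank_sum_p agrees with brute-force enumeration on tie-free cases", {
  set.seed(1)
  for (n in 2:6) {
    for (m in n:min(6, 12 - n)) {
      for (rep in 1:3) {
        pooled <- sample(seq_len(50), n + m)  # distinct => tie-free
        x <- pooled[seq_len(n)]
        y <- pooled[-seq_len(n)]
        expect_equal(rank_sum_p(x, y), rank_sum_oracle(x, y),
                     tolerance = 1e-12,
                     label = sprintf("n=%d m=%d rep=%d", n, m, rep))
      }
    }
  }
})

test_that("rank_sum_p is symmetric, monotone-invariant and NA-tolerant", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rlnorm(6)
    y <- rlnorm(8) * 1.5
    expect_equal(rank_sum_p(x, y), rank_sum_p(y, x))
    expect_equal(rank_sum_p(x, y), rank_sum_p(log(x), log(y)))
    expect_equal(rank_sum_p(x, y), rank_sum_p(x^3, y^3))
    expect_equal(rank_sum_p(c(x, NA), y), rank_sum_p(x, y))
  }
  expect_error(rank_sum_p(NA_real_, c(1, 2)), "Insufficient data")
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  set.seed(3)
  x <- rnorm(60); y <- rnorm(60) + 0.3
  expect_equal(rank_sum_p(x, y),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  xt <- c(1, 2, 2, 3); yt <- c(2, 4, 5, 6)
  expect_equal(rank_sum_p(xt, yt),
               suppressWarnings(wilcox.test(xt, yt, correct = TRUE)$p.value))
})

test_that("quantile intervals follow the linear-interpolation rule", {
  qi <- quantile_interval(c(1, 2, 3, 4), 0.25, 0.75)
  expect_equal(qi$lower, 1.75)
  expect_equal(qi$upper, 3.25)
  const <- quantile_interval(rep(3.3, 5), 0.25, 0.75)
  expect_equal(c(const$lower, const$upper), c(3.3, 3.3))
  full <- quantile_interval(c(5, 1, 9, 2), 0, 1)
  expect_equal(c(full$lower, full$upper), c(1, 9))
  expect_error(quantile_interval(NA_real_), "Insufficient data")
  expect_error(quantile_interval(1:4, 0.75, 0.25), "q_low")
})

test_that("interval overlap is a closed-interval test, symmetric and reflexive", {
  qi <- function(lo, hi) quantile_interval(c(lo, hi), 0, 1)
  expect_false(intervals_overlap(qi(0, 1), qi(2, 3)))
  expect_true(intervals_overlap(qi(0, 2), qi(1, 3)))
  expect_true(intervals_overlap(qi(0, 1), qi(1, 2)))  # touching counts
  set.seed(11)
  for (rep in 1:20) {
    a <- qi(runif(1), runif(1) + 1)
    b <- qi(runif(1, 0.5), runif(1, 0.5) + 1)
    expect_equal(intervals_overlap(a, b), intervals_overlap(b, a))
    expect_true(intervals_overlap(a, a))
  }
})

test_that("a fully separated marker tops the screen at the exact minimum p", {
  panel <- separated_panel(n_per_group = 10, n_noise = 5, seed = 2)
  res <- screen_markers(panel, 6)
  expect_setequal(res$marker[1:3], c("imm", "adh", "acid"))
  expect_equal(res$p_value[1:3], rep(2 / 184756, 3))
  expect_false(any(res$overlap[1:3]))
  expect_true(all(res$n_CA == 10 & res$n_CF == 10))
})

test_that("screening demands both groups and flags insufficient markers", {
  panel <- separated_panel(n_per_group = 4)
  cf_only <- panel
  cf_only$data <- cf_only$data[cf_only$data$group == "CF", ]
  expect_error(screen_markers(cf_only, 6), "CA")

  holed <- separated_panel(n_per_group = 4)
  holed$data$concentration[holed$data$marker == "adh" &
                             holed$data$group == "CA"] <- NA_real_
  res <- screen_markers(holed, 6)
  row <- res[res$marker == "adh", ]
  expect_true(row$insufficient)
  expect_true(is.na(row$p_value))
  expect_equal(nrow(res), nrow(panel$markers))  # not dropped
})

test_that("selection takes the per-category best and honors the criteria", {
  panel <- simulate_panel(default_study_config(seed = 21))
  res <- screen_markers(panel, 6)
  sel <- select_biomarkers(res)
  expect_length(sel, 6)
  marked <- attr(sel, "results")
  expect_setequal(marked$marker[marked$selected], as.character(sel))
  by_cat <- table(marked$category[marked$selected])
  expect_true(all(by_cat == 2))
  expect_setequal(as.character(sel), canonical_biomarkers())
  # deterministic re-run
  expect_identical(as.character(select_biomarkers(res)), as.character(sel))
})

test_that("slots are force-filled by p-value when a category fails the criteria", {
  # pH markers here overlap heavily and are non-significant
  set.seed(4)
  vals <- cbind(
    i1 = c(11:20, 1:10), i2 = c(31:40, 11:20) + 0.5,
    a1 = c(21:30, 5:14) + 0.25, a2 = c(51:60, 31:40) + 0.125,
    p1 = rlnorm(20), p2 = rlnorm(20), p3 = rlnorm(20)
  )
  panel <- wide_panel(vals, rep(c("CA", "CF"), each = 10),
                      c("immune", "immune", "adhesion", "adhesion",
                        "pH", "pH", "pH"))
  res <- screen_markers(panel, 6)
  sel <- select_biomarkers(res)
  expect_length(sel, 6)
  forced <- attr(sel, "forced")
  expect_equal(sum(forced), 2)
  forced_markers <- as.character(sel)[forced]
  expect_true(all(forced_markers %in% c("p1", "p2", "p3")))
  # forced picks are still the best available by p-value
  ph <- res[res$category == "pH", ]
  expect_setequal(forced_markers, ph$marker[order(ph$p_value)][1:2])
})

test_that("p-value ties are broken by the larger gap between group boxes", {
  # two immune markers with identical value patterns (hence identical p)
  # but different spreads: m_wide has the larger inter-box separation
  vals <- cbind(
    m_narrow = c(11:14, 1:4),
    m_wide = c(11:14, 1:4) * 10,
    adh = c(21:24, 5:8) + 0.5,
    acid = c(31:34, 2:5) + 0.25
  )
  panel <- wide_panel(vals, rep(c("CA", "CF"), each = 4),
                      c("immune", "immune", "adhesion", "pH"))
  res <- screen_markers(panel, 6, config = selection_config(per_category = 1))
  imm <- res[res$category == "immune", ]
  expect_equal(imm$p_value[1], imm$p_value[2])
  sel <- select_biomarkers(res, selection_config(per_category = 1))
  expect_equal(as.character(sel)[1], "m_wide")
})

test_that("selection errors when a category was never screened", {
  panel <- separated_panel(n_per_group = 4)
  res <- screen_markers(panel, 6)
  expect_error(select_biomarkers(res[res$category != "pH", ]), "pH")
})

test_that("time contrasts detect the planted circadian pattern and not its absence", {
  panel <- simulate_panel(default_study_config(seed = 15))
  # beta-defensin 2: U-shaped in CF (amplitude 0.4), flat in CA
  p_cf <- time_contrast(panel, "beta_defensin_2", "CF", 0.5, 12)
  morning <- time_contrast(panel, "beta_defensin_2", "CF", 0.5, 24)
  expect_lt(p_cf, 0.05)
  expect_gt(morning, 0.05)
  expect_equal(time_contrast(panel, "IgM", "CA", 0.5, 0.5), 1)
  # paired mode runs on within-subject differences
  p_paired <- time_contrast(panel, "beta_defensin_2", "CF", 0.5, 12,
                            paired = TRUE)
  expect_lt(p_paired, 0.05)
  expect_error(time_contrast(panel, "nope", "CF", 0.5, 6), "nope")
  expect_error(time_contrast(panel, "IgA", "CF", 0.5, 7), "Insufficient")
})

test_that("the null screen rejects at the nominal rate", {
  # effect-free panels: per-marker rejection at alpha = 0.05; pool many
  # marker tests across seeds and compare to the binomial band
  alpha <- 0.05
  rejections <- 0L
  total <- 0L
  for (seed in 1:30) {
    panel <- simulate_panel(null_study_config(seed))
    res <- screen_markers(panel, 6)
    rejections <- rejections + sum(res$p_value <= alpha)
    total <- total + nrow(res)
  }
  rate <- rejections / total
  se <- sqrt(alpha * (1 - alpha) / total)
  expect_lt(abs(rate - alpha), 4 * se + 0.01)
})

test_that("time_contrast p-values are uniform under the null", {
  # no circadian/trend terms: morning-vs-afternoon contrast is null
  pvals <- vapply(1:60, function(seed) {
    panel <- simulate_panel(simulation_config(
      marker_effects("m", "immune"), n_CA = 2, n_CF = 8,
      timepoints_h = c(0.5, 6), seed = 1000 + seed))
    time_contrast(panel, "m", "CF", 0.5, 6)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
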