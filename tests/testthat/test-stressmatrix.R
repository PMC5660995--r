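test_that("stress score follows the qualifying rule on the hand example", {
  cell <- stress_score(tibble::tibble(
    log2_mean = c(-2.0, -1.2, 2.6, -3.0),
    expected_direction = c("down", "down", "up", "up")
  ))
  expect_equal(cell$score, 2.3)
  expect_equal(cell$n_qualifying, 2)
  expect_equal(cell$n_assigned, 4)
})

test_that("stress score is undefined, not zero, when nothing qualifies", {
  cell <- stress_score(tibble::tibble(
    log2_mean = c(0, 0, 0),
    expected_direction = c("up", "down", "up")
  ))
  expect_true(is.na(cell$score))
  expect_equal(cell$n_qualifying, 0)
  one <- stress_score(tibble::tibble(
    log2_mean = 1.6, expected_direction = "up"
  ))
  expect_equal(one$score, 1.6)
})

test_that("a defined stress score always exceeds the threshold", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    vals <- tibble::tibble(
      log2_mean = rnorm(n, 0, 2.5),
      expected_direction = sample(c("up", "down"), n, replace = TRUE)
    )
    thr <- runif(1, 0.5, 2.5)
    cell <- stress_score(vals, threshold = thr)
    if (!is.na(cell$score)) expect_gt(cell$score, thr)
    expect_lte(cell$n_qualifying, cell$n_assigned)
  }
})

test_that("uniformly stronger stress intensity dominates cell-by-cell", {
  cfg <- noisefree_config(n_markers = 16, n_varieties = 4)
  exp <- simulate_experiment(cfg)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  sm <- build_stress_matrix(ratios, exp$panel)
  wide <- tidyr::pivot_wider(
    sm,
    id_cols = c("variety", "stress"),
    names_from = "location", values_from = "score"
  )
  both <- wide[!is.na(wide$Pegoes) & !is.na(wide$DoisPortos), ]
  expect_gt(nrow(both), 0)
  expect_true(all(both$Pegoes >= both$DoisPortos))
  loc <- location_stress_summary(sm)
  expect_gt(
    loc$mean_score[loc$location == "Pegoes"],
    loc$mean_score[loc$location == "DoisPortos"]
  )
})

test_that("a threshold above every ratio leaves all cells undefined", {
  cfg <- noisefree_config(n_markers = 8, n_varieties = 2)
  exp <- simulate_experiment(cfg)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  sm <- build_stress_matrix(ratios, exp$panel, threshold = 99)
  expect_true(all(is.na(sm$score)))
  expect_true(all(sm$n_qualifying == 0))
})

test_that("classification recognises the reference profiles themselves", {
  t_ref <- c(3.4, 0.6, -3.4, -0.6, 2, -2)
  s_ref <- c(0.6, 3.4, -0.6, -3.4, 2, -2)
  self_t <- classify_profile(t_ref, t_ref, s_ref)
  expect_equal(self_t$sim_tolerant, 1)
  expect_equal(self_t$label, "tolerant")
  self_s <- classify_profile(s_ref, t_ref, s_ref)
  expect_equal(self_s$sim_sensitive, 1)
  expect_equal(self_s$label, "sensitive")
  mid <- classify_profile((t_ref + s_ref) / 2, t_ref, s_ref)
  expect_lt(abs(mid$margin), 0.2)
  expect_equal(mid$label, "indeterminate")
})

test_that("classification degrades to indeterminate with reasons", {
  few <- classify_profile(c(1, 2), c(1, 2), c(2, 1))
  expect_equal(few$label, "indeterminate")
  expect_equal(few$flag, "insufficient_genes")
  flat <- classify_profile(c(1, 1, 1, 1), c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(flat$label, "indeterminate")
  expect_equal(flat$flag, "zero_variance")
})

test_that("classification ignores gene order and missing-value genes", {
  set.seed(5)
  v <- rnorm(8)
  t_ref <- v + rnorm(8, 0, 0.1)
  s_ref <- rnorm(8)
  base <- classify_profile(v, t_ref, s_ref)
  perm <- sample(8)
  expect_equal(
    classify_profile(v[perm], t_ref[perm], s_ref[perm])[
      c("sim_tolerant", "sim_sensitive", "label")
    ],
    base[c("sim_tolerant", "sim_sensitive", "label")]
  )
  withna <- classify_profile(
    c(v, 99, NA), c(t_ref, NA, 1), c(s_ref, 2, 2)
  )
  expect_equal(
    withna[c("sim_tolerant", "sim_sensitive", "label")],
    base[c("sim_tolerant", "sim_sensitive", "label")]
  )
})

test_that("end-to-end tolerance calls recover planted archetypes (noise-free)", {
  cfg <- noisefree_config(n_markers = 24, n_varieties = 4)
  exp <- simulate_experiment(cfg)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  prof <- reference_profiles(ratios)
  calls <- classify_tolerance(
    ratios, exp$panel, prof,
    exclude_varieties = c("TN", "TR")
  )
  arch <- cfg$archetypes
  expect_true(all(calls$label == unname(arch[calls$variety])))
})

test_that("bin aggregation averages within bin and flags inversions", {
  panel <- tibble::tibble(
    gene_id = c("G001", "G002", "G003"),
    mapman_bin = c("stress", "stress", "photosynthesis"),
    expected_direction = c("up", "up", "down"),
    stresses = "WS", is_reference = FALSE
  )
  ratios <- ratio_rows(c("G001", "G002", "G003"), "V01", c(2, 4, 1.2))
  bins <- bin_aggregate(ratios, panel)
  stress_bin <- bins[bins$mapman_bin == "stress", ]
  expect_equal(stress_bin$mean_log2, 3)
  expect_false(stress_bin$inverted)
  photo <- bins[bins$mapman_bin == "photosynthesis", ]
  expect_equal(photo$mean_log2, 1.2)
  expect_true(photo$inverted) # a-priori down, observed up
})

test_that("bin means conserve the overall mean when size-weighted", {
  cfg <- noisefree_config(n_markers = 12, n_varieties = 2)
  exp <- simulate_experiment(cfg)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  bins <- bin_aggregate(ratios, exp$panel)
  recon <- bins |>
    dplyr::group_by(.data$variety, .data$location) |>
    dplyr::summarise(
      m = sum(.data$mean_log2 * .data$n_genes) / sum(.data$n_genes),
      .groups = "drop"
    )
  direct <- ratios |>
    dplyr::filter(
      .data$treatment == "stress", .data$control_ref == "tolerant_control",
      !(.data$gene_id %in% c("ACT", "TIF", "TIF-GTP"))
    ) |>
    dplyr::group_by(.data$variety, .data$location) |>
    dplyr::summarise(m = mean(.data$log2_mean), .groups = "drop")
  cmp <- dplyr::inner_join(recon, direct,
    by = c("variety", "location"), suffix = c("_bins", "_direct")
  )
  expect_equal(cmp$m_bins, cmp$m_direct, tolerance = 1e-12)
})

test_that("unlabeled genes fall into an 'unknown' bin with a warning", {
  panel <- tibble::tibble(
    gene_id = "G001", mapman_bin = NA_character_,
    expected_direction = "up", stresses = "WS", is_reference = FALSE
  )
  ratios <- ratio_rows("G001", "V01", 2)
  expect_warning(bins <- bin_aggregate(ratios, panel), "unknown")
  expect_equal(bins$mapman_bin, "unknown")
})

test_that("distribution summaries use type-7 quartiles and Tukey whiskers", {
  panel <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:5), mapman_bin = "stress",
    expected_direction = "up", stresses = "WS", is_reference = FALSE
  )
  ratios <- ratio_rows(panel$gene_id, "V01", c(1, 2, 3, 4, 5))
  ds <- distribution_summary(ratios, panel)
  expect_equal(ds$median, 3)
  expect_equal(ds$q1, 2)
  expect_equal(ds$q3, 4)
  expect_equal(ds$iqr, 2)
  expect_equal(ds$stability, 2)
  expect_equal(ds$n_outliers, 0)

  const <- distribution_summary(
    ratio_rows(panel$gene_id, "V01", rep(1.5, 5)), panel
  )
  expect_equal(const$iqr, 0)

  single <- distribution_summary(
    ratio_rows("G001", "V01", 2.2), panel[1, ]
  )
  expect_true(all(
    unlist(single[c("min", "q1", "median", "q3", "max")]) == 2.2
  ))
})

test_that("an outlying gene lands outside the whiskers", {
  panel <- tibble::tibble(
    gene_id = sprintf("G%03d", 1:7), mapman_bin = "stress",
    expected_direction = "up", stresses = "WS", is_reference = FALSE
  )
  ds <- distribution_summary(
    ratio_rows(panel$gene_id, "V01", c(1, 1.1, 1.2, 1.3, 1.4, 1.5, 9)),
    panel
  )
  expect_equal(ds$n_outliers, 1)
  expect_lt(ds$whisker_high, 9)
})
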