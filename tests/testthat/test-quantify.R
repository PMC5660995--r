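flat_trace <- function(drn24 = 0, drn25 = 0, tail = NULL) {
  rn <- rep(0, 40)
  rn[24] <- drn24
  rn[25] <- drn25
  if (!is.null(tail)) rn[26:40] <- tail
  tibble::tibble(cycle = 1:40, rn = rn)
}

test_that("Cq is the interpolated threshold crossing of the baselined trace", {
  tr <- flat_trace(0.15, 0.35, tail = 0.5)
  expect_equal(call_cq(tr), 24.25)
})

test_that("flat and sub-threshold traces are called no-amplification", {
  expect_true(is.na(call_cq(tibble::tibble(cycle = 1:40, rn = rep(0, 40)))))
  expect_true(is.na(call_cq(flat_trace(0.1, 0.19, tail = 0.19))))
})

test_that("a trace already above threshold at cycle 1 is invalid", {
  tr <- tibble::tibble(cycle = 1:40, rn = c(5, rep(0, 39)))
  expect_error(call_cq(tr), "invalid trace")
})

test_that("Cq calling is invariant to any added linear baseline", {
  for (seed in 1:5) {
    set.seed(seed)
    tc <- runif(1, 22, 33)
    drift <- runif(1, -0.01, 0.01)
    lvl <- runif(1, 0, 0.1)
    tr <- simulate_trace(tc)
    tr_lin <- tr
    tr_lin$rn <- tr$rn + lvl + drift * tr$cycle
    expect_equal(call_cq(tr_lin), call_cq(tr), tolerance = 1e-9)
  }
})

test_that("Cq calling recovers designed crossings within 0.05 cycles", {
  for (tc in seq(22, 34, by = 0.5)) {
    expect_lt(abs(call_cq(simulate_trace(tc)) - tc), 0.05)
  }
})

test_that("perfect-doubling dilution series gives slope -3.32 and E 100%", {
  fit <- fit_standard_curve(simulate_dilution_series(1))
  expect_equal(fit$slope, -log2(5) / log10(5), tolerance = 1e-12)
  expect_equal(100 * fit$efficiency, 100, tolerance = 1e-9)
  expect_true(fit$qc_pass)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # the E-from-slope identity is recomputable from the emitted slope
  expect_equal(fit$efficiency, 10^(-1 / fit$slope) - 1)
})

test_that("2-cycle spacing on a five-fold series means E = 123.6%, QC fail", {
  ser <- tibble::tibble(quantity = 5^-(0:4), cq = 20 + 2 * (0:4))
  fit <- fit_standard_curve(ser)
  expect_equal(fit$efficiency, sqrt(5) - 1, tolerance = 1e-9)
  expect_false(fit$qc_pass)
})

test_that("degenerate dilution inputs are rejected", {
  expect_error(
    fit_standard_curve(tibble::tibble(quantity = c(1, 0.2), cq = c(20, 22))),
    "3 points"
  )
  expect_error(
    fit_standard_curve(
      tibble::tibble(quantity = c(1, 1, 1), cq = c(20, 21, 22))
    ),
    "3 distinct"
  )
  expect_error(
    fit_standard_curve(
      tibble::tibble(quantity = c(1, 0.2, -1), cq = c(20, 22, 24))
    ),
    "positive"
  )
})

test_that("technical replicates aggregate by mean with QC flags", {
  wells <- tibble::tibble(
    gene_id = "G001", sample_id = "s", variety = "V01", location = "L",
    treatment = "stress", bio_rep = c(1, 1, 2, 2, 3, 3, 4, 4),
    tech_rep = rep(1:2, 4),
    cq = c(24.0, 24.2, 24.0, 25.0, NA, 24.0, NA, NA)
  )
  agg <- aggregate_technical(wells)
  agg <- agg[order(agg$bio_rep), ]
  expect_equal(agg$cq, c(24.1, 24.5, 24.0, NA))
  expect_equal(agg$flag_spread, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(agg$flag_single, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(agg$n_tech, c(2, 2, 1, 0))
})

test_that("relative quantity follows the efficiency-corrected ratio", {
  # sample identical to control: ratio 1
  expect_equal(relative_quantity(24, 24, c(20, 21, 22), c(20, 21, 22)), 1)
  # target dCq = 2, references unchanged, E = 1: ratio 4
  expect_equal(relative_quantity(22, 24, c(20, 20), c(20, 20)), 4)
  # uniform +3 cycle shift of every Cq leaves the ratio unchanged
  expect_equal(
    relative_quantity(22 + 3, 24, c(20, 20) + 3, c(20, 20)),
    relative_quantity(22, 24, c(20, 20), c(20, 20)) * 2^-3 * 2^3
  )
  expect_equal(
    relative_quantity(25, 27, c(23, 23), c(23, 23)),
    relative_quantity(22, 24, c(20, 20), c(20, 20))
  )
  # target-only shift of -1 cycle doubles the ratio at E = 1
  expect_equal(
    relative_quantity(21, 24, c(20, 20), c(20, 20)),
    2 * relative_quantity(22, 24, c(20, 20), c(20, 20))
  )
  # efficiency correction: E = 0.9 scales the per-cycle gain
  expect_equal(
    relative_quantity(22, 24, 20, 20, e_target = 0.9),
    1.9^2
  )
})

test_that("noise-free pipeline recovers planted log2 effects exactly", {
  cfg <- noisefree_config()
  exp <- simulate_experiment(cfg)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  chk <- ratios |>
    dplyr::filter(
      .data$treatment == "stress", .data$control_ref == "tolerant_control"
    ) |>
    dplyr::inner_join(
      exp$truth_total,
      by = c("gene_id", "variety", "location")
    )
  expect_gt(nrow(chk), 0)
  expect_lt(max(abs(chk$log2_mean - chk$planted_log2_effect)), 1e-6)
  # reference genes self-normalize to exactly zero
  refs <- dplyr::filter(ratios, .data$gene_id %in% c("ACT", "TIF", "TIF-GTP"))
  expect_equal(max(abs(refs$log2_mean)), 0)
  # both control references are always computed
  expect_setequal(
    unique(ratios$control_ref),
    c("tolerant_control", "sensitive_control")
  )
  # the tolerant control variety against its own controls is all zeros
  self <- dplyr::filter(
    ratios, .data$variety == "TN", .data$treatment == "control",
    .data$control_ref == "tolerant_control"
  )
  expect_equal(max(abs(self$log2_mean)), 0)
})

test_that("a missing reference-gene Cq propagates as missing, never imputed", {
  cfg <- noisefree_config(n_markers = 4, n_varieties = 2)
  exp <- simulate_experiment(cfg)
  wells <- exp$wells
  drop <- wells$gene_id == "ACT" & wells$variety == "V01" &
    wells$location == "Pegoes" & wells$bio_rep == 1
  wells$cq[drop] <- NA
  ratios <- log2_ratio_table(wells, exp$panel, keep_reps = TRUE)
  reps <- attr(ratios, "reps")
  broken <- dplyr::filter(
    reps, .data$variety == "V01", .data$location == "Pegoes",
    .data$bio_rep == 1
  )
  expect_true(all(is.na(broken$log2_rq)))
  summ <- dplyr::filter(
    ratios, .data$variety == "V01", .data$location == "Pegoes",
    .data$treatment == "stress"
  )
  expect_true(all(summ$n_bio == cfg$n_bio - 1))
})
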