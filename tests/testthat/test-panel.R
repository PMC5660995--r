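one_gene_panel <- function(direction = "down") {
  tibble::tibble(
    gene_id = "G001", probeset_id = "PS1", annotation = "m",
    mapman_bin = "stress", expected_direction = direction,
    stresses = "WS", is_reference = FALSE, baseline_cq = 24,
    match_control = "tolerant_control"
  )
}

test_that("majority rule: fails must exceed half the evaluated varieties", {
  panel <- one_gene_panel("down")
  vs <- sprintf("V%02d", 1:10)
  # 7 of 10 in the expected direction: 3 fails <= 5, pass
  r <- ratio_rows("G001", vs, c(rep(-2, 7), rep(2, 3)))
  rep7 <- evaluate_panel(r, panel)
  expect_equal(rep7$n_fail, 3)
  expect_true(all(rep7$retained))
  # exactly 5 of 10 fail: not *more* than half, still a pass
  r5 <- ratio_rows("G001", vs, c(rep(-2, 5), rep(2, 5)))
  rep5 <- evaluate_panel(r5, panel)
  expect_equal(rep5$n_fail, 5)
  expect_true(all(rep5$retained))
  # 6 of 10 fail: discarded
  r6 <- ratio_rows("G001", vs, c(rep(-2, 4), rep(2, 6)))
  expect_false(any(evaluate_panel(r6, panel)$retained))
})

test_that("a gene must pass in every location to stay on the array", {
  panel <- one_gene_panel("up")
  vs <- sprintf("V%02d", 1:10)
  r <- dplyr::bind_rows(
    ratio_rows("G001", vs, rep(-1, 10), location = "DoisPortos"), # 0 match
    ratio_rows("G001", vs, c(rep(2, 8), rep(-1, 2)), location = "Pegoes")
  )
  rep2 <- evaluate_panel(r, panel)
  expect_equal(
    rep2$pass_location[rep2$location == "Pegoes"], TRUE
  )
  expect_equal(
    rep2$pass_location[rep2$location == "DoisPortos"], FALSE
  )
  expect_false(any(rep2$retained))
})

test_that("zero means never match a signed direction", {
  panel <- one_gene_panel("up")
  r <- ratio_rows("G001", sprintf("V%02d", 1:4), c(0, 0, 0, 2))
  rep0 <- evaluate_panel(r, panel)
  expect_equal(rep0$n_match, 1)
})

test_that("filter_panel partitions and always keeps the references", {
  panel <- default_panel(6)
  vs <- sprintf("V%02d", 1:4)
  d <- ifelse(panel$expected_direction[!panel$is_reference] == "up", 2, -2)
  ratios <- purrr::map(
    seq_along(d),
    ~ ratio_rows(panel$gene_id[.x], vs, rep(d[.x], 4))
  ) |> purrr::list_rbind()
  report <- evaluate_panel(ratios, panel)
  part <- filter_panel(panel, report)
  expect_equal(part$n_retained_markers, 6)
  expect_equal(part$n_discarded, 0)
  expect_true(all(c("ACT", "TIF", "TIF-GTP") %in% part$retained$gene_id))

  # flip one gene everywhere: exactly that gene is discarded
  flipped <- ratios
  flipped$log2_mean[flipped$gene_id == "G002"] <-
    -flipped$log2_mean[flipped$gene_id == "G002"]
  part2 <- filter_panel(panel, evaluate_panel(flipped, panel))
  expect_equal(part2$discarded$gene_id, "G002")
})

test_that("an empty non-reference panel filters vacuously", {
  refs <- default_panel(1)[-1, ]
  report <- evaluate_panel(
    ratio_rows("GX", "V01", 1), refs
  )
  expect_equal(nrow(report), 0)
  part <- filter_panel(refs, report)
  expect_equal(part$n_retained_markers, 0)
  expect_equal(nrow(part$retained), nrow(refs))
})

test_that("strengthening the match gate never grows the retained set", {
  panel <- default_panel(10)
  vs <- sprintf("V%02d", 1:6)
  set.seed(77)
  markers <- panel[!panel$is_reference, ]
  ratios <- purrr::map(seq_len(nrow(markers)), function(i) {
    ratio_rows(
      markers$gene_id[i], vs,
      rnorm(6,
        mean = ifelse(markers$expected_direction[i] == "up", 1.2, -1.2),
        sd = 1.5
      )
    )
  }) |> purrr::list_rbind()
  retained_at <- function(min_effect) {
    rep <- evaluate_panel(ratios, panel, min_effect = min_effect)
    sort(unique(rep$gene_id[rep$retained]))
  }
  sets <- lapply(c(0, 0.5, 1, 1.5, 2.5), retained_at)
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("the consistency vote is invariant to variety order", {
  panel <- default_panel(5)
  vs <- sprintf("V%02d", 1:8)
  set.seed(3)
  markers <- panel[!panel$is_reference, ]
  ratios <- purrr::map(seq_len(nrow(markers)), function(i) {
    ratio_rows(markers$gene_id[i], vs, rnorm(8))
  }) |> purrr::list_rbind()
  a <- evaluate_panel(ratios, panel)
  b <- evaluate_panel(ratios[sample(nrow(ratios)), ], panel)
  expect_equal(a, b)
})

test_that("planted direction-inverted genes are discarded, others kept", {
  fx <- fault_config(seed = 1234)
  exp <- simulate_experiment(fx$config)
  ratios <- log2_ratio_table(exp$wells, exp$panel)
  part <- filter_panel(exp$panel, evaluate_panel(ratios, exp$panel))
  expect_setequal(part$discarded$gene_id, fx$fault_ids)
})

test_that("array assembly counts slots and rejects duplicates", {
  panel45 <- default_panel(45)
  arr <- assemble_array(panel45)
  expect_equal(nrow(arr), 48)
  expect_equal(sum(arr$role == "reference"), 3)
  expect_equal(arr$role[46:48], rep("reference", 3))
  # markers are grouped by first stress assignment
  first_stress <- sub(";.*$", "", arr$stresses[arr$role == "marker"])
  expect_false(is.unsorted(match(first_stress, c("WS", "HS", "LS", "FIELD"))))

  refs_only <- assemble_array(panel45[panel45$is_reference, ])
  expect_equal(nrow(refs_only), 3)

  dup <- panel45
  dup$gene_id[1] <- "ACT"
  expect_error(assemble_array(dup), "duplicate")
})
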