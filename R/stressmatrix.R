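#' Stress score for one variety x location
#'
#' A marker qualifies when its mean log2 ratio exceeds the threshold in
#' magnitude *and* has the expected sign; the score is the mean |log2 ratio|
#' over qualifying markers. With no qualifying marker the score is undefined
#' (`NA`), deliberately distinct from a weak-but-present signal of 0.
#'
#' @param values Tibble with `log2_mean` and `expected_direction` for the
#'   markers assigned to one stress, restricted to one variety x location.
#' @param threshold Qualification threshold in log2 units (default 1.5).
#' @return One-row tibble: `score`, `n_qualifying`, `n_assigned`.
#' @export
#' @examples
#' stress_score(tibble::tibble(
#'   log2_mean = c(-2, -1.2, 2.6, -3),
#'   expected_direction = c("down", "down", "up", "up")
#' )) # score 2.3 over 2 of 4
stress_score <- function(values, threshold = 1.5) {
  stopifnot(threshold > 0, nrow(values) >= 1)
  qual <- !is.na(values$log2_mean) &
    abs(values$log2_mean) > threshold &
    sign(values$log2_mean) == direction_sign(values$expected_direction)
  tibble::tibble(
    score = if (any(qual)) mean(abs(values$log2_mean[qual])) else NA_real_,
    n_qualifying = sum(qual),
    n_assigned = nrow(values)
  )
}

#' Build the stress matrix
#'
#' The per-variety stress fingerprint: for every variety x location x
#' stress, the mean |log2 ratio| of that stress's markers that qualify
#' (magnitude above the threshold with the expected sign), with qualifying
#' and assigned counts. Per-location marginal means of the defined scores
#' ride along as attribute `"location_summary"`, making between-location
#' stress-pressure comparisons a computed output.
#'
#' @param ratios Expression-ratio table (see [log2_ratio_table()]).
#' @param panel Panel tibble with stress assignments.
#' @param threshold Qualification threshold in log2 units (default 1.5).
#' @param control_ref Which control reference's ratios to score (default
#'   `"tolerant_control"`).
#' @param treatment Treatment whose ratios are scored.
#' @return Tibble of class `stress_matrix`: `variety`, `location`, `stress`,
#'   `score`, `n_qualifying`, `n_assigned`.
#' @export
build_stress_matrix <- function(ratios, panel, threshold = 1.5,
                                control_ref = "tolerant_control",
                                treatment = "stress") {
  assigned <- panel_stress_assignments(panel)
  obs <- ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref
    ) |>
    dplyr::inner_join(assigned, by = "gene_id",
      relationship = "many-to-many"
    )
  out <- obs |>
    dplyr::group_by(.data$variety, .data$location, .data$stress) |>
    dplyr::group_modify(~ stress_score(.x, threshold = threshold)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$location, .data$variety, .data$stress)
  loc <- out |>
    dplyr::group_by(.data$location) |>
    dplyr::summarise(
      mean_score = mean(.data$score, na.rm = TRUE),
      n_defined = sum(!is.na(.data$score)),
      .groups = "drop"
    )
  attr(out, "location_summary") <- loc
  attr(out, "threshold") <- threshold
  class(out) <- c("stress_matrix", class(out))
  out
}

# Expand the ';'-separated stress assignments into long form, validating
# the labels.
panel_stress_assignments <- function(panel) {
  assigned <- panel |>
    dplyr::filter(!.data$is_reference) |>
    dplyr::select("gene_id", "stresses", "expected_direction") |>
    tidyr::separate_longer_delim("stresses", delim = ";") |>
    dplyr::rename(stress = "stresses")
  bad <- setdiff(unique(assigned$stress), stress_levels())
  if (length(bad) > 0) {
    stop("unknown stress label(s) in panel: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  assigned
}

#' Per-location marginal stress scores
#'
#' @param matrix A `stress_matrix` from [build_stress_matrix()].
#' @return Tibble `location`, `mean_score`, `n_defined`.
#' @export
location_stress_summary <- function(matrix) {
  attr(matrix, "location_summary")
}

#' Aggregate log2 ratios into functional-category relevance
#'
#' Mean log2 ratio per variety x location x functional (MapMan-style) bin,
#' computed separately for the a-priori upregulated and downregulated marker
#' sets. A bin whose mean contradicts its a-priori direction (e.g. a
#' downregulated set with positive mean) is flagged as an inversion.
#'
#' @inheritParams build_stress_matrix
#' @return Tibble: `variety`, `location`, `mapman_bin`,
#'   `expected_direction`, `mean_log2`, `n_genes`, `inverted`.
#' @export
bin_aggregate <- function(ratios, panel, control_ref = "tolerant_control",
                          treatment = "stress") {
  markers <- dplyr::filter(panel, !.data$is_reference)
  if (any(is.na(markers$mapman_bin) | markers$mapman_bin == "")) {
    warning("unlabeled gene(s) assigned to bin \"unknown\"", call. = FALSE)
    markers$mapman_bin[
      is.na(markers$mapman_bin) | markers$mapman_bin == ""
    ] <- "unknown"
  }
  ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref,
      !is.na(.data$log2_mean)
    ) |>
    dplyr::inner_join(
      dplyr::select(
        markers, "gene_id", "mapman_bin", "expected_direction"
      ),
      by = "gene_id"
    ) |>
    dplyr::group_by(
      .data$variety, .data$location, .data$mapman_bin,
      .data$expected_direction
    ) |>
    dplyr::summarise(
      mean_log2 = mean(.data$log2_mean),
      n_genes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      inverted = sign(.data$mean_log2) != 0 &
        sign(.data$mean_log2) != direction_sign(.data$expected_direction)
    )
}

#' Distribution summary of expression ratios
#'
#' Five-number summaries of the log2 ratio distributions per variety x
#' location x a-priori direction, with Tukey box-plot whiskers (most extreme
#' points within 1.5 x IQR of the quartiles), outlier counts and an IQR
#' stability score (smaller IQR = more stable expression). Quartiles use
#' linear interpolation between order statistics (quantile type 7).
#'
#' @inheritParams build_stress_matrix
#' @return Tibble per variety x location x `expected_direction`: `n`,
#'   `min`, `q1`, `median`, `q3`, `max`, `iqr`, `whisker_low`,
#'   `whisker_high`, `n_outliers`, `stability` (= IQR).
#' @export
distribution_summary <- function(ratios, panel,
                                 control_ref = "tolerant_control",
                                 treatment = "stress") {
  markers <- dplyr::filter(panel, !.data$is_reference)
  ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref,
      !is.na(.data$log2_mean)
    ) |>
    dplyr::inner_join(
      dplyr::select(markers, "gene_id", "expected_direction"),
      by = "gene_id"
    ) |>
    dplyr::group_by(
      .data$variety, .data$location, .data$expected_direction
    ) |>
    dplyr::summarise(five_number_row(.data$log2_mean), .groups = "drop")
}

five_number_row <- function(x) {
  stopifnot(length(x) >= 1)
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- x >= lo_fence & x <= hi_fence
  tibble::tibble(
    n = length(x),
    min = min(x), q1 = qs[1], median = qs[2], q3 = qs[3], max = max(x),
    iqr = iqr,
    whisker_low = min(x[inside]),
    whisker_high = max(x[inside]),
    n_outliers = sum(!inside),
    stability = iqr
  )
}
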