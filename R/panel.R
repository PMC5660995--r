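#' Evaluate marker direction consistency across varieties
#'
#' Scores every non-reference panel gene against the observed log2 ratios:
#' a variety "matches" when the sign of its mean log2 ratio equals the
#' gene's expected regulation direction and the configured gate holds. A
#' gene passes a location when the varieties that fail there are not more
#' than half of those evaluated (a tie at exactly half passes, since only
#' "more than half" discards), and it is retained only when it passes every
#' location — an array meant for use across climates must work in each one.
#'
#' @param ratios Expression-ratio table (see [log2_ratio_table()]).
#' @param panel Panel tibble; each gene is matched against the control
#'   reference named in its `match_control` column (default
#'   `tolerant_control`).
#' @param gate Match gate: `"sign"` (direction only, the default),
#'   `"sign+threshold"` (additionally `|log2| > threshold`), or
#'   `"sign+significant"` (additionally the `significant` flag from
#'   [flag_significance()]).
#' @param min_effect Minimum `|log2_mean|` for a match (default 0).
#' @param threshold Gate threshold in log2 units for `"sign+threshold"`.
#' @param exclude_varieties Varieties left out of the vote (default: the
#'   control genotypes themselves, whose self-ratios are 0 by construction).
#' @param treatment Treatment whose ratios are evaluated.
#' @return Consistency report: one row per gene x location with `n_eval`,
#'   `n_match`, `n_fail`, `pass_location`, and the across-location verdict
#'   `retained` (repeated within gene). A location with no evaluable
#'   variety fails by policy (`evaluable = FALSE`).
#' @export
evaluate_panel <- function(ratios, panel,
                           gate = c("sign", "sign+threshold",
                             "sign+significant"),
                           min_effect = 0, threshold = 1.5,
                           exclude_varieties = c("TN", "TR"),
                           treatment = "stress") {
  gate <- match.arg(gate)
  stopifnot(min_effect >= 0, threshold >= 0)
  markers <- dplyr::filter(panel, !.data$is_reference)
  if (nrow(markers) == 0) {
    return(tibble::tibble(
      gene_id = character(), location = character(),
      n_eval = integer(), n_match = integer(), n_fail = integer(),
      evaluable = logical(), pass_location = logical(), retained = logical()
    ))
  }
  locations <- unique(ratios$location)
  obs <- ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      !(.data$variety %in% exclude_varieties)
    ) |>
    dplyr::inner_join(
      dplyr::select(
        markers, "gene_id", "expected_direction", "match_control"
      ),
      by = "gene_id"
    ) |>
    dplyr::filter(.data$control_ref == .data$match_control) |>
    dplyr::mutate(
      match = !is.na(.data$log2_mean) &
        sign(.data$log2_mean) == direction_sign(.data$expected_direction) &
        abs(.data$log2_mean) >= min_effect &
        switch(gate,
          "sign" = TRUE,
          "sign+threshold" = abs(.data$log2_mean) > threshold,
          "sign+significant" = !is.na(.data$significant) & .data$significant
        ),
      evaluated = !is.na(.data$log2_mean)
    )
  report <- tidyr::crossing(
    gene_id = markers$gene_id, location = locations
  ) |>
    dplyr::left_join(
      obs |>
        dplyr::group_by(.data$gene_id, .data$location) |>
        dplyr::summarise(
          n_eval = sum(.data$evaluated),
          n_match = sum(.data$match & .data$evaluated),
          .groups = "drop"
        ),
      by = c("gene_id", "location")
    ) |>
    dplyr::mutate(
      n_eval = dplyr::coalesce(.data$n_eval, 0L),
      n_match = dplyr::coalesce(.data$n_match, 0L),
      n_fail = .data$n_eval - .data$n_match,
      evaluable = .data$n_eval > 0,
      pass_location = .data$evaluable &
        .data$n_fail <= floor(.data$n_eval / 2)
    ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(retained = all(.data$pass_location)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id, .data$location)
  report
}

#' Evaluate a single marker gene
#'
#' Convenience wrapper around [evaluate_panel()] for one gene.
#'
#' @param gene One-row panel tibble (or a `gene_id` present in `panel`).
#' @param panel Panel tibble.
#' @inheritParams evaluate_panel
#' @param ... Passed to [evaluate_panel()].
#' @return One row per location of the consistency report.
#' @export
evaluate_marker <- function(gene, ratios, panel, ...) {
  id <- if (is.character(gene)) gene else gene$gene_id
  stopifnot(length(id) == 1)
  sub <- dplyr::filter(panel, .data$gene_id == id)
  if (nrow(sub) != 1) stop("gene not found in panel: ", id, call. = FALSE)
  if (sub$is_reference) {
    stop("reference genes are not evaluated for direction consistency",
      call. = FALSE
    )
  }
  evaluate_panel(ratios, sub, ...)
}

#' Partition a panel into retained and discarded markers
#'
#' Applies the consistency verdicts: markers whose report says `retained`
#' stay, the rest are discarded; reference genes are always retained.
#'
#' @param panel Panel tibble.
#' @param report Consistency report from [evaluate_panel()] (one verdict per
#'   non-reference gene).
#' @return List with `retained` (panel rows, references included),
#'   `discarded` (marker rows), `n_retained_markers`, `n_discarded`.
#' @export
filter_panel <- function(panel, report) {
  markers <- dplyr::filter(panel, !.data$is_reference)
  verdicts <- dplyr::distinct(report, .data$gene_id, .data$retained)
  missing <- setdiff(markers$gene_id, verdicts$gene_id)
  if (length(missing) > 0) {
    stop(
      "no consistency report for marker(s): ",
      paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  keep_ids <- verdicts$gene_id[verdicts$retained]
  retained <- dplyr::filter(
    panel, .data$is_reference | .data$gene_id %in% keep_ids
  )
  discarded <- dplyr::filter(
    markers, !(.data$gene_id %in% keep_ids)
  )
  list(
    retained = retained,
    discarded = discarded,
    n_retained_markers = sum(!retained$is_reference),
    n_discarded = nrow(discarded)
  )
}

#' Assemble the final custom-array layout
#'
#' Orders the retained markers by stress assignment (water, heat, light,
#' field, using each gene's first listed stress) and appends the reference
#' genes last, assigning consecutive array slots.
#'
#' @param retained Panel tibble of retained markers (non-reference rows; a
#'   full partition's `retained` element is accepted and split internally).
#' @param reference_genes Panel tibble of reference genes (must be disjoint
#'   from the markers).
#' @return Array-definition tibble: `slot`, `gene_id`, `role`
#'   (`marker`/`reference`), `stresses`, `expected_direction`, `mapman_bin`.
#' @export
assemble_array <- function(retained, reference_genes = NULL) {
  if (is.null(reference_genes)) {
    reference_genes <- dplyr::filter(retained, .data$is_reference)
    retained <- dplyr::filter(retained, !.data$is_reference)
  }
  ids <- c(retained$gene_id, reference_genes$gene_id)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate gene_id in array: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  first_stress <- factor(
    sub(";.*$", "", retained$stresses),
    levels = stress_levels()
  )
  markers <- retained[order(first_stress, retained$gene_id), ]
  out <- dplyr::bind_rows(
    dplyr::mutate(markers, role = "marker"),
    dplyr::mutate(reference_genes, role = "reference")
  )
  out |>
    dplyr::mutate(slot = dplyr::row_number()) |>
    dplyr::select(
      "slot", "gene_id", "role",
      dplyr::any_of(c("stresses", "expected_direction", "mapman_bin"))
    )
}
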