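#' Extract reference-genotype expression profiles
#'
#' Pulls the measured stress-response profiles of the tolerant and sensitive
#' reference genotypes out of an expression-ratio table, per location, in
#' the shape [classify_tolerance()] consumes.
#'
#' @param ratios Expression-ratio table (see [log2_ratio_table()]).
#' @param tolerant,sensitive Variety names of the reference genotypes.
#' @param control_ref Which control reference's ratios to use (profiles and
#'   test varieties must use the same one).
#' @param treatment Treatment whose ratios form the profiles.
#' @return Tibble `gene_id`, `location`, `tolerant`, `sensitive` (log2).
#' @export
reference_profiles <- function(ratios, tolerant = "TN", sensitive = "TR",
                               control_ref = "tolerant_control",
                               treatment = "stress") {
  ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref,
      .data$variety %in% c(tolerant, sensitive)
    ) |>
    dplyr::mutate(
      role = dplyr::if_else(.data$variety == tolerant,
        "tolerant", "sensitive"
      )
    ) |>
    dplyr::select("gene_id", "location", "role", "log2_mean") |>
    tidyr::pivot_wider(
      names_from = "role", values_from = "log2_mean"
    )
}

#' Classify one expression profile against the reference genotypes
#'
#' Pearson correlation of a variety's stress-response profile with the
#' tolerant and the sensitive reference profile over their common genes
#' (genes missing in any profile are excluded pairwise). The call is
#' `tolerant` when `sim_tolerant - sim_sensitive > delta`, `sensitive` when
#' below `-delta`, otherwise `indeterminate`; fewer than `min_genes` common
#' genes or a zero-variance profile also gives `indeterminate`, with the
#' reason recorded.
#'
#' @param profile,tolerant_ref,sensitive_ref Numeric vectors of log2 ratios
#'   over the same genes (same length/order; `NA`s allowed).
#' @param delta Decision margin on the correlation difference (default 0.2).
#' @param min_genes Minimum number of common genes (default 3).
#' @return One-row tibble: `sim_tolerant`, `sim_sensitive`, `margin`,
#'   `label`, `n_common`, `flag`.
#' @export
#' @examples
#' classify_profile(c(3, 0.5, -2), c(3.2, 0.4, -1.9), c(0.5, 3, -0.2))
classify_profile <- function(profile, tolerant_ref, sensitive_ref,
                             delta = 0.2, min_genes = 3) {
  stopifnot(
    length(profile) == length(tolerant_ref),
    length(profile) == length(sensitive_ref),
    delta >= 0, min_genes >= 2
  )
  ok <- !is.na(profile) & !is.na(tolerant_ref) & !is.na(sensitive_ref)
  v <- profile[ok]
  t <- tolerant_ref[ok]
  s <- sensitive_ref[ok]
  out <- tibble::tibble(
    sim_tolerant = NA_real_, sim_sensitive = NA_real_, margin = NA_real_,
    label = "indeterminate", n_common = length(v), flag = NA_character_
  )
  if (length(v) < min_genes) {
    out$flag <- "insufficient_genes"
    return(out)
  }
  if (sd(v) == 0 || sd(t) == 0 || sd(s) == 0) {
    out$flag <- "zero_variance"
    return(out)
  }
  out$sim_tolerant <- cor(v, t)
  out$sim_sensitive <- cor(v, s)
  out$margin <- out$sim_tolerant - out$sim_sensitive
  out$label <- if (out$margin > delta) {
    "tolerant"
  } else if (out$margin < -delta) {
    "sensitive"
  } else {
    "indeterminate"
  }
  out
}

#' Tolerance/sensitivity calls for every variety x location x stress
#'
#' For each stress, each variety's profile over that stress's markers is
#' compared (Pearson correlation) with the tolerant and sensitive reference
#' profiles from the same location, and labelled by the margin rule of
#' [classify_profile()].
#'
#' @param ratios Expression-ratio table (see [log2_ratio_table()]).
#' @param panel Panel tibble with stress assignments.
#' @param ref_profiles Reference profiles from [reference_profiles()] or
#'   [read_ref_profiles()].
#' @param delta Decision margin (default 0.2).
#' @param min_genes Minimum common genes per comparison (default 3).
#' @param control_ref Which control reference's ratios to use.
#' @param treatment Treatment whose ratios are classified.
#' @param exclude_varieties Varieties not to classify (default: none).
#' @return Tibble of class `tolerance_calls`: `variety`, `location`,
#'   `stress`, `sim_tolerant`, `sim_sensitive`, `margin`, `label`,
#'   `n_common`, `flag`.
#' @export
classify_tolerance <- function(ratios, panel, ref_profiles,
                               delta = 0.2, min_genes = 3,
                               control_ref = "tolerant_control",
                               treatment = "stress",
                               exclude_varieties = character()) {
  assigned <- panel_stress_assignments(panel)
  obs <- ratios |>
    dplyr::filter(
      .data$treatment == !!treatment,
      .data$control_ref == !!control_ref,
      !(.data$variety %in% exclude_varieties)
    ) |>
    dplyr::inner_join(assigned, by = "gene_id",
      relationship = "many-to-many"
    ) |>
    dplyr::inner_join(ref_profiles, by = c("gene_id", "location"))
  out <- obs |>
    dplyr::group_by(.data$variety, .data$location, .data$stress) |>
    dplyr::group_modify(~ classify_profile(
      .x$log2_mean, .x$tolerant, .x$sensitive,
      delta = delta, min_genes = min_genes
    )) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$location, .data$variety, .data$stress)
  class(out) <- c("tolerance_calls", class(out))
  out
}
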