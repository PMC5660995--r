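#' Built-in synthetic marker panel
#'
#' A synthetic 65-marker + 3-reference-gene panel mirroring the layout of a
#' custom abiotic-stress qPCR array for grapevine leaves: each marker carries
#' an a-priori expected regulation direction (up/down), one or two stress
#' assignments (water, heat, light, field), a MapMan-style functional bin and
#' a baseline Cq. The references are the stable normalizers ACT, TIF and
#' TIF-GTP. Directions alternate in blocks so every stress carries both up-
#' and downregulated markers (33 down, 32 up overall), and every fifth marker
#' is assigned to a second stress.
#'
#' @param n_markers Number of (synthetic) marker genes.
#' @return A tibble with one row per gene: `gene_id`, `probeset_id`,
#'   `annotation`, `mapman_bin`, `expected_direction` (`NA` for references),
#'   `stresses` (`;`-separated labels, `NA` for references), `is_reference`,
#'   `baseline_cq` (cycles), and `match_control` (which control reference the
#'   expected direction was defined against).
#' @export
#' @examples
#' default_panel()
default_panel <- function(n_markers = 65) {
  stopifnot(n_markers >= 1)
  i <- seq_len(n_markers)
  stress <- stress_levels()[(i - 1) %% 4 + 1]
  dirn <- ifelse(((i - 1) %/% 4) %% 2 == 0, "down", "up")
  second <- stress_levels()[i %% 4 + 1]
  stresses <- ifelse(i %% 5 == 0 & second != stress,
    paste(stress, second, sep = ";"), stress
  )
  bins <- rep(
    c(
      "stress", "photosynthesis", "hormone metabolism", "protein",
      "transport", "secondary metabolism", "signalling", "cell wall",
      "not assigned"
    ),
    length.out = n_markers
  )
  markers <- tibble::tibble(
    gene_id = sprintf("G%03d", i),
    probeset_id = sprintf("PS%05d", 10000L + i),
    annotation = sprintf("synthetic stress marker %02d", i),
    mapman_bin = bins,
    expected_direction = dirn,
    stresses = stresses,
    is_reference = FALSE,
    baseline_cq = 22 + ((i - 1) %% 9) * 0.5,
    match_control = "tolerant_control"
  )
  refs <- tibble::tibble(
    gene_id = c("ACT", "TIF", "TIF-GTP"),
    probeset_id = sprintf("PS%05d", 9000L + 1:3),
    annotation = c(
      "actin 2",
      "translation initiation factor eIF-3 subunit 4",
      "translation initiation factor eIF-2B alpha subunit"
    ),
    mapman_bin = "protein",
    expected_direction = NA_character_,
    stresses = NA_character_,
    is_reference = TRUE,
    baseline_cq = c(19, 20, 21),
    match_control = "tolerant_control"
  )
  dplyr::bind_rows(markers, refs)
}

#' Planted archetype effect sizes for a panel
#'
#' Builds the ground-truth effect table the generator plants: for every
#' marker gene and each of its assigned stresses, the log2 response of the
#' tolerant and of the sensitive variety archetype. Signs follow the gene's
#' expected direction; magnitudes alternate between a strong and a weak
#' response in anti-phase between the two archetypes, so that the two
#' archetype profiles are sign-consistent (both respond in the expected
#' direction, as retained markers must) yet clearly distinguishable by
#' correlation — different marker subsets dominate in each archetype, which
#' is what makes reference-genotype classification informative.
#'
#' @param panel A panel tibble as from [default_panel()].
#' @param strong,weak Strong/weak response magnitudes in log2 units. The
#'   default pair (3.4, 0.6) averages to the 2 log2 planted effect used
#'   throughout validation.
#' @return A tibble: `gene_id`, `stress`, `tolerant`, `sensitive` (planted
#'   log2 effects per archetype).
#' @export
default_effects <- function(panel = default_panel(), strong = 3.4, weak = 0.6) {
  markers <- dplyr::filter(panel, !.data$is_reference)
  if (nrow(markers) == 0) {
    return(tibble::tibble(
      gene_id = character(), stress = character(),
      tolerant = numeric(), sensitive = numeric()
    ))
  }
  idx <- seq_len(nrow(markers))
  phase <- ((idx - 1) %/% 8) %% 2
  long <- markers |>
    dplyr::mutate(phase = phase) |>
    tidyr::separate_longer_delim("stresses", delim = ";") |>
    dplyr::rename(stress = "stresses")
  d <- direction_sign(long$expected_direction)
  tibble::tibble(
    gene_id = long$gene_id,
    stress = long$stress,
    tolerant = d * ifelse(long$phase == 0, strong, weak),
    sensitive = d * ifelse(long$phase == 0, weak, strong)
  )
}

#' Default variety archetype assignment
#'
#' Labels the first half of the test varieties tolerant and the second half
#' sensitive (an odd last variety becomes mixed), emulating a trial of
#' uncharacterized genotypes with empirically expected contrasting behaviour.
#'
#' @param n_varieties Number of test varieties (`V01`, `V02`, ...).
#' @return Named character vector variety -> archetype label in
#'   `c("tolerant", "sensitive", "mixed")`.
#' @export
default_archetypes <- function(n_varieties = 10) {
  stopifnot(n_varieties >= 1)
  half <- n_varieties %/% 2
  labels <- c(
    rep("tolerant", half), rep("sensitive", half),
    rep("mixed", n_varieties - 2 * half)
  )
  setNames(labels, sprintf("V%02d", seq_len(n_varieties)))
}

#' Default location-by-stress intensity grid
#'
#' Two field locations with uniformly different stress pressure: a hot, dry
#' site where stress is fully expressed (multiplier 1) and a milder site at
#' 0.7, so per-location contrasts (including markers slipping under the
#' stress-matrix threshold at the mild site) are part of the default data.
#'
#' @param locations Character vector of location names.
#' @param intensities Numeric multipliers, one per location, recycled over
#'   all stresses.
#' @return A tibble `location`, `stress`, `intensity`.
#' @export
default_stress_intensity <- function(locations = c("Pegoes", "DoisPortos"),
                                     intensities = c(1, 0.7)) {
  stopifnot(length(locations) == length(intensities), all(intensities >= 0))
  tidyr::crossing(
    tibble::tibble(location = locations, intensity = intensities),
    stress = stress_levels()
  ) |>
    dplyr::select("location", "stress", "intensity")
}
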