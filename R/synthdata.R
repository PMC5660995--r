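#' Simulation configuration for a synthetic qPCR experiment
#'
#' Bundles and validates everything the generator needs: the marker panel,
#' the planted per-archetype effect table, the variety -> archetype map, the
#' location-by-stress intensity grid, the replication structure and the two
#' noise components. The Cq model is
#' `Cq = baseline_cq(gene) - effect + bio + tech`, where `effect` is the
#' archetype's planted log2 response summed over the gene's assigned stresses
#' and scaled by the location's stress intensity (upregulation by d log2
#' units lowers Cq by d cycles, i.e. perfect doubling is assumed when
#' planting), `bio` is biological noise shared by a sample's technical
#' replicates and `tech` is independent per well.
#'
#' @param panel Panel tibble (see [default_panel()]).
#' @param effects Planted effect table (see [default_effects()]); reference
#'   genes must be absent or have all effects equal to zero.
#' @param archetypes Named character vector variety -> label in
#'   `c("tolerant", "sensitive", "mixed")`; mixed varieties respond with the
#'   mean of the two archetype effects.
#' @param stress_intensity Tibble `location`, `stress`, `intensity` with
#'   non-negative multipliers.
#' @param n_bio,n_tech Biological / technical replicates per sample.
#' @param sd_bio,sd_tech Noise standard deviations in cycles (non-negative).
#' @param dropout_cq_limit Cq above which a well is recorded as
#'   no-amplification (default 38 of a 40-cycle run).
#' @param control_varieties Named vector mapping the two control-reference
#'   roles (`tolerant_control`, `sensitive_control`) to variety names; each
#'   control variety is grown under both the stress and the unstressed
#'   control treatment in every location.
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(panel = default_panel(),
                       effects = default_effects(panel),
                       archetypes = default_archetypes(10),
                       stress_intensity = default_stress_intensity(),
                       n_bio = 3, n_tech = 2,
                       sd_bio = 0.3, sd_tech = 0.15,
                       dropout_cq_limit = 38,
                       control_varieties = c(
                         tolerant_control = "TN",
                         sensitive_control = "TR"
                       ),
                       seed = 1L) {
  if (sd_bio < 0 || sd_tech < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  stopifnot(
    n_bio >= 1, n_tech >= 1,
    is.numeric(dropout_cq_limit), dropout_cq_limit > 0,
    all(c("location", "stress", "intensity") %in% names(stress_intensity)),
    all(c("tolerant_control", "sensitive_control") %in%
      names(control_varieties))
  )
  if (any(stress_intensity$intensity < 0)) {
    stop("stress intensities must be non-negative", call. = FALSE)
  }
  bad <- setdiff(archetypes, c("tolerant", "sensitive", "mixed"))
  if (length(bad) > 0) {
    stop("unknown archetype label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(names(archetypes)) || anyDuplicated(names(archetypes))) {
    stop("archetypes must be a uniquely named vector", call. = FALSE)
  }
  ref_ids <- panel$gene_id[panel$is_reference]
  ref_eff <- effects[effects$gene_id %in% ref_ids, ]
  if (nrow(ref_eff) > 0 &&
    any(ref_eff$tolerant != 0 | ref_eff$sensitive != 0)) {
    stop("reference genes must have all planted effects equal to 0",
      call. = FALSE
    )
  }
  markers <- panel[!panel$is_reference, ]
  want <- markers |>
    tidyr::separate_longer_delim("stresses", delim = ";") |>
    dplyr::rename(stress = "stresses")
  missing <- dplyr::anti_join(
    want, effects,
    by = c("gene_id", "stress")
  )
  if (nrow(missing) > 0) {
    stop(
      "effects table is missing ", nrow(missing),
      " marker gene x stress combination(s)",
      call. = FALSE
    )
  }
  structure(
    list(
      panel = panel, effects = effects, archetypes = archetypes,
      stress_intensity = stress_intensity,
      n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
      sd_bio = sd_bio, sd_tech = sd_tech,
      dropout_cq_limit = dropout_cq_limit,
      control_varieties = control_varieties,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Planted total log2 effect per gene x variety x location x treatment.
# Control-treatment samples carry no effect by construction.
planted_effects <- function(config) {
  arch_all <- c(
    config$archetypes,
    setNames(
      c("tolerant", "sensitive"),
      unname(config$control_varieties[c(
        "tolerant_control",
        "sensitive_control"
      )])
    )
  )
  arch_tbl <- tibble::tibble(
    variety = names(arch_all),
    archetype = unname(arch_all)
  )
  per_stress <- tidyr::crossing(config$effects, arch_tbl) |>
    dplyr::inner_join(config$stress_intensity, by = "stress",
      relationship = "many-to-many"
    ) |>
    dplyr::mutate(
      planted_log2_effect = dplyr::case_when(
        .data$archetype == "tolerant" ~ .data$tolerant,
        .data$archetype == "sensitive" ~ .data$sensitive,
        TRUE ~ (.data$tolerant + .data$sensitive) / 2
      ) * .data$intensity
    ) |>
    dplyr::select(
      "gene_id", "variety", "location", "stress", "archetype",
      "planted_log2_effect"
    ) |>
    dplyr::arrange(.data$gene_id, .data$variety, .data$location, .data$stress)
  total <- per_stress |>
    dplyr::group_by(.data$gene_id, .data$variety, .data$location,
      .data$archetype
    ) |>
    dplyr::summarise(
      planted_log2_effect = sum(.data$planted_log2_effect),
      .groups = "drop"
    )
  list(per_stress = per_stress, total = total)
}

#' Simulate a full qPCR marker-array experiment
#'
#' Generates one well per gene x variety x location x biological x technical
#' replicate under the planted-effect Cq model of [sim_config()], plus
#' unstressed control samples for the two control varieties. Ground truth
#' (the planted log2 effects, per stress and summed per gene) is returned
#' alongside the wells so every downstream stage can be checked against it.
#' Wells whose Cq exceeds `dropout_cq_limit` are recorded as
#' no-amplification (`NA`).
#'
#' @param config A `sim_config`.
#' @return A list of class `cq_experiment`: `wells` (tibble of well records:
#'   plate, well, gene, sample identifiers, variety, location, treatment,
#'   replicate indices, `cq`), `truth` (planted log2 effect per gene x
#'   variety x location x stress), `truth_total` (summed over stresses),
#'   `panel`, and `config`.
#' @export
#' @examples
#' exp <- simulate_experiment(sim_config(seed = 42))
#' dplyr::count(exp$wells, location)
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  locations <- unique(config$stress_intensity$location)
  ctrl <- unname(config$control_varieties)
  samples <- dplyr::bind_rows(
    tidyr::crossing(
      variety = c(names(config$archetypes), ctrl),
      location = locations, treatment = "stress"
    ),
    tidyr::crossing(
      variety = ctrl, location = locations, treatment = "control"
    )
  ) |>
    dplyr::mutate(sample_id = paste(.data$variety, .data$location,
      .data$treatment,
      sep = "."
    ))

  truth <- planted_effects(config)
  eff <- truth$total |>
    dplyr::select("gene_id", "variety", "location", "planted_log2_effect")

  wells <- tidyr::crossing(
    samples,
    dplyr::select(config$panel, "gene_id", "baseline_cq"),
    bio_rep = seq_len(config$n_bio),
    tech_rep = seq_len(config$n_tech)
  ) |>
    dplyr::left_join(eff, by = c("gene_id", "variety", "location")) |>
    dplyr::mutate(
      effect = dplyr::if_else(
        .data$treatment == "control" | is.na(.data$planted_log2_effect),
        0, .data$planted_log2_effect
      )
    ) |>
    dplyr::arrange(
      .data$location, .data$variety, .data$treatment, .data$gene_id,
      .data$bio_rep, .data$tech_rep
    )

  bio_units <- wells |>
    dplyr::distinct(
      .data$gene_id, .data$variety, .data$location, .data$treatment,
      .data$bio_rep
    ) |>
    dplyr::mutate(bio_noise = rnorm(dplyr::n(), 0, config$sd_bio))
  wells <- wells |>
    dplyr::left_join(
      bio_units,
      by = c("gene_id", "variety", "location", "treatment", "bio_rep")
    ) |>
    dplyr::mutate(
      tech_noise = rnorm(dplyr::n(), 0, config$sd_tech),
      cq = .data$baseline_cq - .data$effect + .data$bio_noise +
        .data$tech_noise,
      cq = dplyr::if_else(.data$cq > config$dropout_cq_limit,
        NA_real_, .data$cq
      )
    ) |>
    dplyr::group_by(.data$location) |>
    dplyr::mutate(
      plate_id = paste0("P_", .data$location),
      well = sprintf("W%05d", dplyr::row_number())
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "plate_id", "well", "gene_id", "sample_id", "variety", "location",
      "treatment", "bio_rep", "tech_rep", "cq"
    )

  structure(
    list(
      wells = wells,
      truth = truth$per_stress,
      truth_total = truth$total,
      panel = config$panel,
      config = config
    ),
    class = "cq_experiment"
  )
}

#' @export
print.cq_experiment <- function(x, ...) {
  cat(
    "<cq_experiment> ", nrow(x$wells), " wells | ",
    length(unique(x$wells$gene_id)), " genes x ",
    length(unique(x$wells$variety)), " varieties x ",
    length(unique(x$wells$location)), " locations\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate a single amplification trace
#'
#' Produces a logistic (sigmoid) amplification curve on top of a linear
#' baseline, constructed so that the baseline-subtracted signal crosses the
#' detection threshold at `true_cq`: the trace is the designed inverse of
#' [call_cq()]. A plateau at or below the threshold gives a designed-negative
#' trace that never amplifies.
#'
#' @param true_cq Target quantification cycle (cycles). Accurate recovery
#'   needs `true_cq` comfortably above the baseline window (>= ~20 with the
#'   default window 5--17).
#' @param plateau Maximum baseline-subtracted fluorescence (arbitrary units).
#' @param slope_k Logistic growth rate per cycle; with the default 0.9 the
#'   designed crossing is recovered by [call_cq()] to well within 0.05
#'   cycles for `true_cq` >= 22 (the sigmoid's low tail is negligible
#'   inside the default baseline window there).
#' @param baseline_drift Linear baseline slope (signal per cycle).
#' @param baseline_level Baseline intercept (signal).
#' @param rn_threshold Threshold the construction targets (default 0.2).
#' @param noise_sd Optional i.i.d. Gaussian noise on the signal.
#' @param n_cycles Number of PCR cycles (default 40).
#' @param seed Optional seed for the noise.
#' @return A tibble of class `fluor_trace` with columns `cycle` (1-based,
#'   gapless) and `rn`.
#' @export
#' @examples
#' call_cq(simulate_trace(24.25))
simulate_trace <- function(true_cq, plateau = 1, slope_k = 0.9,
                           baseline_drift = 0, baseline_level = 0.05,
                           rn_threshold = 0.2, noise_sd = 0,
                           n_cycles = 40, seed = NULL) {
  stopifnot(plateau > 0, slope_k > 0, noise_sd >= 0, n_cycles >= 2)
  if (!is.null(seed)) set.seed(seed)
  cycles <- seq_len(n_cycles)
  if (plateau > rn_threshold) {
    if (true_cq < 2 || true_cq > n_cycles - 1) {
      stop("true_cq must lie within the cycle range", call. = FALSE)
    }
    # Start from the centre at which the continuous logistic passes through
    # the threshold at true_cq, then calibrate it so that the *sampled*
    # curve, read the way call_cq reads it (linear interpolation between
    # the bracketing integer cycles), crosses exactly at true_cq. This
    # makes the trace the designed inverse of the caller; the only residual
    # error is the sigmoid tail leaking into the baseline window.
    c0 <- true_cq + log(plateau / rn_threshold - 1) / slope_k
    cross_of <- function(centre) {
      sig <- plateau / (1 + exp(-slope_k * (cycles - centre)))
      j <- which(sig >= rn_threshold)[1]
      if (is.na(j) || j == 1) {
        return(if (is.na(j)) n_cycles + 1 else 0)
      }
      cycles[j - 1] + (rn_threshold - sig[j - 1]) / (sig[j] - sig[j - 1])
    }
    c0 <- stats::uniroot(
      function(x) cross_of(x) - true_cq, c(c0 - 1.5, c0 + 1.5),
      tol = 1e-10
    )$root
    signal <- plateau / (1 + exp(-slope_k * (cycles - c0)))
  } else {
    # designed-negative trace: plateau never reaches the threshold
    signal <- rep(0, n_cycles)
  }
  rn <- baseline_level + baseline_drift * cycles + signal
  if (noise_sd > 0) rn <- rn + rnorm(n_cycles, 0, noise_sd)
  structure(
    tibble::tibble(cycle = cycles, rn = rn),
    class = c("fluor_trace", class(tibble::tibble()))
  )
}

#' Simulate a dilution-series standard curve
#'
#' Emulates the serial-dilution calibration run used to estimate a primer
#' pair's amplification efficiency: starting from an undiluted input
#' (relative quantity 1), each step dilutes `fold`-fold and shifts Cq up by
#' `log(fold) / log(1 + true_efficiency)` cycles, plus optional Gaussian
#' noise. The default five-point five-fold design (1, 1:5, 1:25, 1:125,
#' 1:625) is the standard curve layout for array validation.
#'
#' @param true_efficiency Amplification efficiency as a fraction in (0, 1.1];
#'   1 means perfect doubling.
#' @param top_cq Cq of the undiluted input (cycles).
#' @param n_points Number of dilution points (>= 3).
#' @param fold Dilution factor per step (> 1).
#' @param noise_sd Gaussian Cq noise in cycles.
#' @param seed Optional seed.
#' @return A tibble `quantity` (relative input), `cq`.
#' @export
#' @examples
#' glance(fit_standard_curve(simulate_dilution_series(1)))
simulate_dilution_series <- function(true_efficiency, top_cq = 20,
                                     n_points = 5, fold = 5,
                                     noise_sd = 0, seed = NULL) {
  if (true_efficiency <= 0 || true_efficiency > 1.1) {
    stop("true_efficiency must be in (0, 1.1]", call. = FALSE)
  }
  if (n_points < 3) stop("n_points must be at least 3", call. = FALSE)
  if (fold <= 1) stop("fold must exceed 1", call. = FALSE)
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  k <- seq_len(n_points) - 1
  cq <- top_cq + k * log(fold) / log(1 + true_efficiency)
  if (noise_sd > 0) cq <- cq + rnorm(n_points, 0, noise_sd)
  tibble::tibble(quantity = fold^(-k), cq = cq)
}
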