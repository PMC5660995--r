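#' Call the quantification cycle from an amplification trace
#'
#' Fits a least-squares straight line to the raw fluorescence over the
#' baseline window, subtracts it from the whole trace (so any linear drift
#' is absorbed), and reports the first fractional cycle at which the
#' baseline-subtracted signal crosses the detection threshold from below,
#' by linear interpolation between the bracketing integer cycles.
#'
#' @param trace A `fluor_trace` (or any data frame with `cycle`, `rn`);
#'   cycles must be 1-based, gapless and strictly increasing.
#' @param baseline_window Inclusive cycle interval for the baseline fit
#'   (default cycles 5--17).
#' @param rn_threshold Detection threshold on the baseline-subtracted signal
#'   (default 0.2).
#' @return The Cq in fractional cycles, or `NA_real_` when the signal never
#'   reaches the threshold (no amplification). A trace already at or above
#'   the threshold at cycle 1 is invalid and raises an error.
#' @export
#' @examples
#' call_cq(simulate_trace(30))
call_cq <- function(trace, baseline_window = c(5, 17), rn_threshold = 0.2) {
  stopifnot(
    all(c("cycle", "rn") %in% names(trace)),
    length(baseline_window) == 2, rn_threshold > 0
  )
  cyc <- trace$cycle
  rn <- trace$rn
  if (length(cyc) < 2 || any(diff(cyc) != 1) || cyc[1] != 1) {
    stop("trace cycles must be 1-based, gapless and increasing",
      call. = FALSE
    )
  }
  if (any(!is.finite(rn))) stop("trace rn must be finite", call. = FALSE)
  if (baseline_window[1] < cyc[1] || baseline_window[2] > cyc[length(cyc)] ||
    baseline_window[1] >= baseline_window[2]) {
    stop("baseline_window must be a valid interval within the trace",
      call. = FALSE
    )
  }
  in_win <- cyc >= baseline_window[1] & cyc <= baseline_window[2]
  base_fit <- lm(rn ~ cycle, data = data.frame(cycle = cyc, rn = rn)[in_win, ])
  drn <- rn - (coef(base_fit)[1] + coef(base_fit)[2] * cyc)
  if (drn[1] >= rn_threshold) {
    stop("invalid trace: signal above threshold at cycle 1", call. = FALSE)
  }
  above <- which(drn >= rn_threshold)
  if (length(above) == 0) {
    return(NA_real_)
  }
  j <- above[1]
  cyc[j - 1] + (rn_threshold - drn[j - 1]) / (drn[j] - drn[j - 1])
}

#' Fit a dilution-series standard curve and derive amplification efficiency
#'
#' Ordinary least squares of Cq on log10(input quantity); the amplification
#' efficiency is derived from the slope `a` as `E = 10^(-1/a) - 1`, and the
#' fit passes QC when the efficiency in percent lies inside
#' `efficiency_range` (default 100 +/- 10, corresponding to an absolute
#' slope of 3.3 +/- 0.33).
#'
#' @param dilution_points Data frame with columns `quantity` (> 0) and `cq`;
#'   at least 3 points over at least 3 distinct quantities.
#' @param gene_id Optional gene label carried on the result.
#' @param efficiency_range QC acceptance band for `100 * E`.
#' @return An object of class `standard_curve` with elements `gene_id`,
#'   `slope`, `intercept`, `r2`, `efficiency` (fraction), `qc_pass`, `n`
#'   and the fitted points. Has [tidy()], [glance()], [autoplot()] and
#'   `print()` methods.
#' @export
#' @examples
#' fit_standard_curve(simulate_dilution_series(1))
fit_standard_curve <- function(dilution_points, gene_id = NA_character_,
                               efficiency_range = c(90, 110)) {
  stopifnot(all(c("quantity", "cq") %in% names(dilution_points)))
  q <- dilution_points$quantity
  cq <- dilution_points$cq
  keep <- !is.na(cq)
  q <- q[keep]
  cq <- cq[keep]
  if (any(q <= 0)) {
    stop("dilution quantities must be positive", call. = FALSE)
  }
  if (length(q) < 3 || length(unique(q)) < 3) {
    stop("need at least 3 points over 3 distinct dilutions", call. = FALSE)
  }
  lq <- log10(q)
  fit <- lm(cq ~ lq)
  a <- unname(coef(fit)[2])
  b <- unname(coef(fit)[1])
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_
  efficiency <- 10^(-1 / a) - 1
  qc_pass <- is.finite(efficiency) &&
    100 * efficiency >= efficiency_range[1] &&
    100 * efficiency <= efficiency_range[2]
  structure(
    list(
      gene_id = gene_id, slope = a, intercept = b, r2 = r2,
      efficiency = efficiency, qc_pass = qc_pass, n = length(q),
      points = tibble::tibble(quantity = q, cq = cq)
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(
    "<standard_curve>",
    if (!is.na(x$gene_id)) paste0(" ", x$gene_id), "\n",
    sprintf(
      "  slope %.4f  intercept %.2f  R2 %.4f\n  efficiency %.1f%%  QC %s\n",
      x$slope, x$intercept, x$r2, 100 * x$efficiency,
      if (x$qc_pass) "pass" else "FAIL"
    ),
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_standard_curve
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, slope = x$slope, intercept = x$intercept,
    r2 = x$r2, efficiency_pct = 100 * x$efficiency, qc_pass = x$qc_pass,
    n = x$n
  )
}

#' Aggregate technical replicates to per-biological-replicate Cq
#'
#' Takes well-level records and averages technical replicates within each
#' gene x sample x biological replicate. Quality flags (never failures) mark
#' wide technical spread and bio-reps left with a single informative well;
#' a bio-rep whose technical replicates are all no-amplification stays
#' no-amplification.
#'
#' @param wells Well-record tibble (as in `simulate_experiment()$wells` or
#'   from [read_cq_table()]).
#' @param max_spread Technical-spread flag threshold in cycles (default 0.5).
#' @return Tibble per gene x sample x bio_rep: `cq` (mean of informative
#'   technical replicates, `NA` if none), `n_tech`, `n_tech_total`,
#'   `tech_spread`, `flag_spread`, `flag_single`.
#' @export
aggregate_technical <- function(wells, max_spread = 0.5) {
  stopifnot(max_spread >= 0)
  keys <- intersect(
    c("gene_id", "sample_id", "variety", "location", "treatment", "bio_rep"),
    names(wells)
  )
  wells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_tech_total = dplyr::n(),
      n_tech = sum(!is.na(.data$cq)),
      tech_spread = {
        x <- .data$cq[!is.na(.data$cq)]
        if (length(x) >= 2) max(x) - min(x) else NA_real_
      },
      cq = {
        x <- .data$cq[!is.na(.data$cq)]
        if (length(x) >= 1) mean(x) else NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flag_spread = !is.na(.data$tech_spread) &
        .data$tech_spread > max_spread,
      flag_single = .data$n_tech == 1 & .data$n_tech_total > 1
    )
}

#' Efficiency-corrected relative quantity against multiple reference genes
#'
#' The Pfaffl-style ratio: target fold change between sample and control,
#' divided by the geometric mean of the reference genes' fold changes,
#' with per-gene amplification efficiencies:
#' `ratio = (1 + E_t)^(Cq_control - Cq_sample) /
#'   geomean_r (1 + E_r)^(Cq_control,r - Cq_sample,r)`.
#'
#' @param target_cq_sample,target_cq_control Target-gene Cq in the sample
#'   and in the control (cycles).
#' @param ref_cq_sample,ref_cq_control Numeric vectors of reference-gene Cq
#'   (same length and order).
#' @param e_target Target amplification efficiency (fraction; 1 = doubling).
#' @param e_ref Reference efficiencies, recycled to the references.
#' @return The unitless ratio; `NA` if any required Cq is missing.
#' @export
#' @examples
#' relative_quantity(22, 24, c(20, 20), c(20, 20)) # ratio 4
relative_quantity <- function(target_cq_sample, target_cq_control,
                              ref_cq_sample, ref_cq_control,
                              e_target = 1, e_ref = 1) {
  stopifnot(length(ref_cq_sample) == length(ref_cq_control))
  e_ref <- rep_len(e_ref, length(ref_cq_sample))
  log2_target <- (target_cq_control - target_cq_sample) * log2(1 + e_target)
  log2_refs <- (ref_cq_control - ref_cq_sample) * log2(1 + e_ref)
  2^(log2_target - mean(log2_refs))
}

# Internal engine: per-bio-rep log2 relative quantities for every sample,
# against each control reference. `bio_cq` is aggregate_technical() output.
# A bio-rep missing any reference gene propagates NA (never imputed).
log2_ratio_reps <- function(bio_cq, panel,
                            control_varieties = c(
                              tolerant_control = "TN",
                              sensitive_control = "TR"
                            ),
                            efficiencies = NULL,
                            control_treatment = "control") {
  stopifnot(all(c("gene_id", "variety", "location", "treatment", "bio_rep",
    "cq") %in% names(bio_cq)))
  missing_genes <- setdiff(panel$gene_id, unique(bio_cq$gene_id))
  if (length(missing_genes) > 0) {
    warning(
      "panel gene(s) absent from dataset: ",
      paste(missing_genes, collapse = ", "),
      call. = FALSE
    )
  }
  refs <- panel$gene_id[panel$is_reference]
  if (length(refs) == 0) {
    stop("panel contains no reference genes", call. = FALSE)
  }
  eff_tbl <- if (is.null(efficiencies)) {
    tibble::tibble(gene_id = panel$gene_id, efficiency = 1)
  } else if (is.data.frame(efficiencies)) {
    dplyr::select(efficiencies, "gene_id", "efficiency")
  } else {
    tibble::tibble(
      gene_id = names(efficiencies),
      efficiency = unname(efficiencies)
    )
  }

  purrr::map(names(control_varieties), function(ref_name) {
    ctrl_var <- control_varieties[[ref_name]]
    ctrl <- bio_cq |>
      dplyr::filter(
        .data$variety == ctrl_var,
        .data$treatment == control_treatment
      ) |>
      dplyr::group_by(.data$gene_id, .data$location) |>
      dplyr::summarise(
        cq_control = mean(.data$cq, na.rm = TRUE),
        .groups = "drop"
      )
    if (nrow(ctrl) == 0) {
      stop("no control samples found for ", ref_name, " (", ctrl_var, ")",
        call. = FALSE
      )
    }
    d <- bio_cq |>
      dplyr::inner_join(ctrl, by = c("gene_id", "location")) |>
      dplyr::left_join(eff_tbl, by = "gene_id") |>
      dplyr::mutate(
        efficiency = dplyr::coalesce(.data$efficiency, 1),
        dlog2 = (.data$cq_control - .data$cq) * log2(1 + .data$efficiency)
      )
    norm <- d |>
      dplyr::filter(.data$gene_id %in% refs) |>
      dplyr::group_by(
        .data$variety, .data$location, .data$treatment, .data$bio_rep
      ) |>
      dplyr::summarise(ref_norm = mean(.data$dlog2), .groups = "drop")
    d |>
      dplyr::left_join(
        norm,
        by = c("variety", "location", "treatment", "bio_rep")
      ) |>
      dplyr::mutate(
        control_ref = ref_name,
        log2_rq = .data$dlog2 - .data$ref_norm
      ) |>
      dplyr::select(
        "gene_id", "variety", "location", "treatment", "bio_rep",
        "control_ref", "log2_rq"
      )
  }) |>
    purrr::list_rbind()
}

# Aggregate per-bio-rep log2 quantities into the expression-ratio table.
summarize_ratios <- function(reps) {
  reps |>
    dplyr::group_by(
      .data$gene_id, .data$variety, .data$location, .data$treatment,
      .data$control_ref
    ) |>
    dplyr::summarise(
      n_bio = sum(!is.na(.data$log2_rq)),
      log2_mean = ifelse(.data$n_bio >= 1,
        mean(.data$log2_rq, na.rm = TRUE), NA_real_
      ),
      log2_sd = ifelse(.data$n_bio >= 2,
        sd(.data$log2_rq, na.rm = TRUE), NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = NA)
}

#' Multi-reference-normalized log2 expression-ratio table
#'
#' The full quantification step: technical replicates are averaged per
#' biological replicate, each bio-rep is turned into an efficiency-corrected
#' relative quantity against the mean of the control samples (per gene and
#' location, separately for the tolerant-control and the sensitive-control
#' reference), normalized by the geometric mean of the reference genes, and
#' log2 quantities are then averaged across biological replicates.
#'
#' @param wells Well-record tibble (see [aggregate_technical()]).
#' @param panel Panel tibble; its `is_reference` flags define the
#'   normalizers.
#' @param control_varieties Named vector mapping `tolerant_control` /
#'   `sensitive_control` to variety names.
#' @param curves Optional list of `standard_curve` objects (or a tibble
#'   `gene_id`, `efficiency`) supplying per-gene efficiencies; genes without
#'   a curve assume perfect doubling (E = 1).
#' @param control_treatment Treatment label identifying control samples.
#' @param keep_reps If `TRUE`, also return the per-bio-rep log2 quantities
#'   (needed for significance screening) as attribute `"reps"`.
#' @return Expression-ratio tibble: `gene_id`, `variety`, `location`,
#'   `treatment`, `control_ref`, `n_bio`, `log2_mean`, `log2_sd`,
#'   `significant` (`NA` until [flag_significance()] fills it).
#' @export
log2_ratio_table <- function(wells, panel,
                             control_varieties = c(
                               tolerant_control = "TN",
                               sensitive_control = "TR"
                             ),
                             curves = NULL,
                             control_treatment = "control",
                             keep_reps = FALSE) {
  efficiencies <- NULL
  if (!is.null(curves)) {
    efficiencies <- if (is.data.frame(curves)) {
      curves
    } else {
      purrr::map(curves, glance) |>
        purrr::list_rbind() |>
        dplyr::transmute(
          gene_id = .data$gene_id,
          efficiency = .data$efficiency_pct / 100
        )
    }
  }
  bio_cq <- aggregate_technical(wells)
  reps <- log2_ratio_reps(
    bio_cq, panel,
    control_varieties = control_varieties,
    efficiencies = efficiencies, control_treatment = control_treatment
  )
  out <- summarize_ratios(reps)
  if (keep_reps) attr(out, "reps") <- reps
  out
}
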