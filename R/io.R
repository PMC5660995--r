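#' Run configuration
#'
#' Collects the pipeline's tunable parameters with their defaults: baseline
#' window cycles 5--17 (inclusive, 1-based), Rn threshold 0.2, efficiency
#' acceptance 90--110%, significance level 0.05, stress-matrix threshold
#' 1.5 log2 units, technical-spread flag 0.5 cycles, classification margin
#' 0.2. The whole configuration is echoed into every JSON run report.
#'
#' @param baseline_window Inclusive cycle interval for baseline fitting.
#' @param rn_threshold Detection threshold on baseline-subtracted signal.
#' @param efficiency_range_pct Acceptance band for amplification efficiency.
#' @param alpha ANOVA/Tukey significance level.
#' @param matrix_threshold Stress-matrix qualification threshold (log2).
#' @param tech_spread_flag Technical-replicate spread flag (cycles).
#' @param margin_delta Classification margin on correlation difference.
#' @param gate Marker-retention match gate (see [evaluate_panel()]).
#' @param control_varieties Named `tolerant_control`/`sensitive_control`
#'   variety map.
#' @param reference_gene_ids Reference (normalizer) gene identifiers.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(baseline_window = c(5, 17), rn_threshold = 0.2,
                       efficiency_range_pct = c(90, 110), alpha = 0.05,
                       matrix_threshold = 1.5, tech_spread_flag = 0.5,
                       margin_delta = 0.2, gate = "sign",
                       control_varieties = c(
                         tolerant_control = "TN",
                         sensitive_control = "TR"
                       ),
                       reference_gene_ids = c("ACT", "TIF", "TIF-GTP"),
                       seed = 1L) {
  structure(
    list(
      baseline_window = baseline_window, rn_threshold = rn_threshold,
      efficiency_range_pct = efficiency_range_pct, alpha = alpha,
      matrix_threshold = matrix_threshold,
      tech_spread_flag = tech_spread_flag, margin_delta = margin_delta,
      gate = gate, control_varieties = as.list(control_varieties),
      reference_gene_ids = reference_gene_ids, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

cq_table_cols <- c(
  "plate_id", "well", "gene_id", "sample_id", "variety", "location",
  "treatment", "bio_rep", "tech_rep", "cq"
)

#' Read / write a long-format Cq table
#'
#' Comma-separated instrument-style export, one row per well, with an empty
#' `cq` field meaning no amplification. Duplicate
#' (gene, sample, bio_rep, tech_rep) keys are rejected, naming the row.
#'
#' @param path File path.
#' @return `read_cq_table()`: a validated well-record tibble.
#' @export
read_cq_table <- function(path) {
  # parse issues are surfaced below via readr::problems(); readr's own
  # warnings (e.g. a typed column missing entirely) would only obscure the
  # structured errors raised here
  wells <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      bio_rep = readr::col_integer(),
      tech_rep = readr::col_integer(),
      cq = readr::col_double(),
      .default = readr::col_character()
    )
  ))
  missing <- setdiff(cq_table_cols, names(wells))
  if (length(missing) > 0) {
    stop("Cq table is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  probs <- readr::problems(wells)
  if (nrow(probs) > 0) {
    stop("non-numeric cq or malformed field at row ", probs$row[1],
      call. = FALSE
    )
  }
  key <- paste(
    wells$gene_id, wells$sample_id, wells$bio_rep, wells$tech_rep
  )
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (gene, sample, bio_rep, tech_rep) key at row ", dup[1],
      call. = FALSE
    )
  }
  if (any(!is.na(wells$cq) & wells$cq <= 0)) {
    stop("cq values must be positive", call. = FALSE)
  }
  wells[cq_table_cols]
}

#' @rdname read_cq_table
#' @param wells Well-record tibble.
#' @export
write_cq_table <- function(wells, path) {
  readr::write_csv(wells[cq_table_cols], path, na = "")
  invisible(path)
}

#' Read / write a marker-panel table
#'
#' Tab-separated annotation table: one row per gene with expected direction
#' (`up`/`down`, empty for reference genes), `;`-separated stress
#' assignments (labels `WS`, `HS`, `LS`, `FIELD`), functional bin and
#' reference flag.
#'
#' @param path File path.
#' @return `read_panel()`: a validated panel tibble.
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(
    path,
    col_types = readr::cols(
      is_reference = readr::col_logical(),
      baseline_cq = readr::col_double(),
      .default = readr::col_character()
    )
  )
  need <- c(
    "gene_id", "expected_direction", "stresses", "is_reference"
  )
  missing <- setdiff(need, names(panel))
  if (length(missing) > 0) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"mapman_bin" %in% names(panel)) panel$mapman_bin <- "unknown"
  if (!"match_control" %in% names(panel)) {
    panel$match_control <- "tolerant_control"
  }
  markers <- panel[!panel$is_reference, ]
  bad_dir <- setdiff(unique(markers$expected_direction), c("up", "down"))
  if (length(bad_dir) > 0) {
    stop("unknown expected_direction: ", paste(bad_dir, collapse = ", "),
      call. = FALSE
    )
  }
  refs <- panel[panel$is_reference, ]
  if (any(!is.na(refs$expected_direction)) ||
    any(!is.na(refs$stresses))) {
    stop("reference genes must have no direction or stress assignment",
      call. = FALSE
    )
  }
  if (any(is.na(markers$stresses) | markers$stresses == "")) {
    stop("every marker needs at least one stress assignment", call. = FALSE)
  }
  stress_labels <- unique(unlist(strsplit(markers$stresses, ";",
    fixed = TRUE
  )))
  bad_stress <- setdiff(stress_labels, stress_levels())
  if (length(bad_stress) > 0) {
    stop("unknown stress label(s): ", paste(bad_stress, collapse = ", "),
      call. = FALSE
    )
  }
  panel
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path, na = "")
  invisible(path)
}

#' Read / write reference-genotype expression profiles
#'
#' Tab-separated: `gene_id`, `location`, `tolerant`, `sensitive` log2
#' expression ratios of the two reference genotypes.
#'
#' @param path File path.
#' @return `read_ref_profiles()`: a profile tibble as produced by
#'   [reference_profiles()].
#' @export
read_ref_profiles <- function(path) {
  prof <- readr::read_tsv(
    path,
    col_types = readr::cols(
      tolerant = readr::col_double(),
      sensitive = readr::col_double(),
      .default = readr::col_character()
    )
  )
  need <- c("gene_id", "location", "tolerant", "sensitive")
  missing <- setdiff(need, names(prof))
  if (length(missing) > 0) {
    stop(
      "reference profiles missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  prof
}

#' @rdname read_ref_profiles
#' @param profiles Profile tibble.
#' @export
write_ref_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path, na = "")
  invisible(path)
}

#' Write a deterministic JSON run report
#'
#' Serializes the stage outputs plus the configuration echo and package
#' version with sorted keys and fixed numeric formatting, so identical
#' inputs give byte-identical reports. Empty optional stages are emitted as
#' `null`.
#'
#' @param stages Named list of stage outputs (tibbles or scalars); `NULL`
#'   elements are kept as JSON `null`.
#' @param config A `run_config` (echoed verbatim).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_report <- function(stages, config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    config = unclass(config),
    software = list(
      package = "stresspanel",
      version = as.character(utils::packageVersion("stresspanel"))
    ),
    stages = stages
  )
  json <- jsonlite::toJSON(
    sort_names_rec(payload),
    auto_unbox = TRUE, digits = 10, null = "null", na = "null",
    dataframe = "rows", pretty = TRUE
  )
  writeLines(json, path)
  invisible(path)
}

sort_names_rec <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nm != "")) x <- x[order(nm)]
    lapply(x, sort_names_rec)
  } else {
    x
  }
}

#' Read a JSON run report
#'
#' @param path File path.
#' @return The report as a nested list.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
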