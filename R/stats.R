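#' One-way ANOVA on log2 relative quantities
#'
#' Classical between/within mean-square F test across groups of log2
#' expression values (log2 transformation is what renders qPCR relative
#' quantities approximately parametric). A degenerate configuration with
#' zero between-group and zero within-group variance has an undefined F,
#' reported as `NaN` with `NA` p-value rather than an error.
#'
#' @param values Numeric vector of log2 relative quantities.
#' @param groups Grouping vector (coerced to factor), same length.
#' @return Object of class `panel_anova`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `alpha`, plus the underlying `aov` fit and the
#'   Tukey pair table (`tukey_pairs`, empty unless the ANOVA gate passes;
#'   see [tukey_hsd()]). Has `tidy()`/`glance()` methods.
#' @param alpha Gate for the post hoc test (default 0.05): Tukey pairs are
#'   only computed when the ANOVA p-value is below it.
#' @export
#' @examples
#' fit <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' glance(fit)
one_way_anova <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n_per <- table(groups)
  if (length(n_per) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n_per < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  fit <- aov(values ~ groups, data = data.frame(values, groups))
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p_value <- tab[["Pr(>F)"]][1]
  ss <- tab[["Sum Sq"]]
  scale2 <- mean(values^2) + 1
  if (all(ss / scale2 < 1e-24)) {
    # zero between- and zero within-group variance: F is 0/0, undefined
    f_stat <- NaN
    p_value <- NA_real_
  }
  pairs <- empty_tukey_pairs()
  if (!is.na(p_value) && p_value < alpha) {
    pairs <- tukey_pairs_from_fit(fit)
  }
  structure(
    list(
      f_stat = f_stat,
      df_between = tab[["Df"]][1],
      df_within = tab[["Df"]][2],
      p_value = p_value,
      alpha = alpha,
      tukey_pairs = pairs,
      fit = fit
    ),
    class = "panel_anova"
  )
}

empty_tukey_pairs <- function() {
  tibble::tibble(
    group_a = character(), group_b = character(),
    diff = numeric(), p_adj = numeric()
  )
}

tukey_pairs_from_fit <- function(fit) {
  tk <- TukeyHSD(fit)[[1]]
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(
    group_a = purrr::map_chr(nm, 1),
    group_b = purrr::map_chr(nm, 2),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"])
  )
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values.
#' Exposed separately for direct use; in the screening pipeline it is gated
#' on the ANOVA p-value (see [one_way_anova()]).
#'
#' @inheritParams one_way_anova
#' @return Tibble `group_a`, `group_b`, `diff` (mean difference, log2
#'   units), `p_adj`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  n_per <- table(groups)
  if (length(n_per) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(n_per < 2)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  tukey_pairs_from_fit(
    aov(values ~ groups, data = data.frame(values, groups))
  )
}

#' @export
print.panel_anova <- function(x, ...) {
  cat(sprintf(
    "<panel_anova> F = %.4g on (%d, %d) df, p = %.4g (alpha %.3g)\n",
    x$f_stat, x$df_between, x$df_within, x$p_value, x$alpha
  ))
  if (nrow(x$tukey_pairs) > 0) {
    cat("  ", nrow(x$tukey_pairs), " Tukey pair(s)\n", sep = "")
  }
  invisible(x)
}

#' @rdname one_way_anova
#' @param x A `panel_anova`.
#' @param ... Unused.
#' @method tidy panel_anova
#' @export
tidy.panel_anova <- function(x, ...) x$tukey_pairs

#' @rdname one_way_anova
#' @method glance panel_anova
#' @export
glance.panel_anova <- function(x, ...) {
  tibble::tibble(
    f_stat = x$f_stat, df_between = x$df_between,
    df_within = x$df_within, p_value = x$p_value
  )
}

#' Significance screening of expression ratios
#'
#' For every gene x location x control reference, the per-biological-
#' replicate log2 relative quantities are grouped by variety (the control
#' variety's unstressed samples form the control group) and screened with a
#' one-way ANOVA; when its p-value is below `alpha` a Tukey HSD follows, and
#' a variety's ratio is flagged significant when the adjusted p of the
#' variety-vs-control comparison is below `alpha`. Varieties with fewer than
#' two informative replicates are never flagged significant and carry a
#' warning flag instead. No correction is applied across genes.
#'
#' @param ratios Expression-ratio table from
#'   [log2_ratio_table()]`(..., keep_reps = TRUE)` (the per-replicate values
#'   ride along as attribute `"reps"`), or the table plus `reps=` given
#'   explicitly.
#' @param reps Per-bio-rep log2 quantities (columns `gene_id`, `variety`,
#'   `location`, `treatment`, `bio_rep`, `control_ref`, `log2_rq`).
#' @param control_varieties Named vector as in [log2_ratio_table()].
#' @param alpha Significance level (default 0.05) for both the ANOVA gate
#'   and the Tukey comparison.
#' @param control_treatment Treatment label of the control samples.
#' @return `ratios` with `significant` filled (logical) and a
#'   `flag_insufficient` column marking groups that could not be tested.
#' @export
flag_significance <- function(ratios, reps = attr(ratios, "reps"),
                              control_varieties = c(
                                tolerant_control = "TN",
                                sensitive_control = "TR"
                              ),
                              alpha = 0.05,
                              control_treatment = "control") {
  if (is.null(reps)) {
    stop("per-replicate values are required; run log2_ratio_table(..., ",
      "keep_reps = TRUE) or pass reps=",
      call. = FALSE
    )
  }
  calls <- reps |>
    dplyr::filter(!is.na(.data$log2_rq)) |>
    dplyr::group_by(.data$gene_id, .data$location, .data$control_ref) |>
    dplyr::group_modify(~ significance_one_gene(
      .x,
      ctrl_var = control_varieties[[.y$control_ref]],
      alpha = alpha, control_treatment = control_treatment
    )) |>
    dplyr::ungroup()
  ratios |>
    dplyr::select(-"significant") |>
    dplyr::left_join(
      calls,
      by = c("gene_id", "location", "control_ref", "variety", "treatment")
    ) |>
    dplyr::mutate(
      significant = dplyr::coalesce(.data$significant, FALSE),
      flag_insufficient = dplyr::coalesce(.data$flag_insufficient, TRUE)
    )
}

significance_one_gene <- function(df, ctrl_var, alpha, control_treatment) {
  ctrl <- df[df$variety == ctrl_var & df$treatment == control_treatment, ]
  test <- df[df$treatment != control_treatment, ]
  out <- test |>
    dplyr::distinct(.data$variety, .data$treatment) |>
    dplyr::mutate(significant = FALSE, flag_insufficient = FALSE)
  counts <- table(test$variety)
  ok_vars <- names(counts)[counts >= 2]
  out$flag_insufficient <- !(out$variety %in% ok_vars)
  if (nrow(ctrl) < 2 || length(ok_vars) < 1) {
    out$flag_insufficient <- TRUE
    return(out)
  }
  keep <- test$variety %in% ok_vars
  values <- c(ctrl$log2_rq, test$log2_rq[keep])
  groups <- c(
    rep(".control", nrow(ctrl)),
    paste0("v.", test$variety[keep])
  )
  an <- one_way_anova(values, groups, alpha = alpha)
  if (nrow(an$tukey_pairs) > 0) {
    hits <- an$tukey_pairs |>
      dplyr::filter(
        .data$group_a == ".control" | .data$group_b == ".control",
        .data$p_adj < alpha
      )
    hit_vars <- sub(
      "^v\\.", "",
      setdiff(c(hits$group_a, hits$group_b), ".control")
    )
    out$significant <- out$variety %in% hit_vars
  }
  out
}
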