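# Shared fixture builders: small synthetic experiments with known ground
# truth, constructed in code at test time.

# Effect table with the same planted magnitude for both archetypes.
uniform_effects <- function(panel, effect = 2) {
  eff <- default_effects(panel)
  d <- ifelse(eff$tolerant >= 0, 1, -1)
  eff$tolerant <- d * effect
  eff$sensitive <- d * effect
  eff
}

# Equal stress pressure in both locations (planted effects appear at face
# value everywhere).
flat_intensity <- function(locations = c("LocA", "LocB")) {
  default_stress_intensity(
    locations = locations,
    intensities = rep(1, length(locations))
  )
}

# Noise-free default-shaped experiment config.
noisefree_config <- function(n_markers = 16, n_varieties = 4, seed = 1) {
  panel <- default_panel(n_markers)
  sim_config(
    panel = panel,
    archetypes = default_archetypes(n_varieties),
    sd_bio = 0, sd_tech = 0, seed = seed
  )
}

# Direction-inconsistency fixture: 4 tolerant vs 6 sensitive varieties and
# the sensitive-archetype effect of `fault_ids` flipped, so fault genes show
# the wrong direction in 6 of 10 varieties (more than half) everywhere.
fault_config <- function(seed, n_markers = 12, n_fault = 3, effect = 2,
                         sd_bio = 0.3, sd_tech = 0.15) {
  panel <- default_panel(n_markers)
  eff <- uniform_effects(panel, effect)
  fault_ids <- panel$gene_id[!panel$is_reference][seq_len(n_fault)]
  eff$sensitive[eff$gene_id %in% fault_ids] <-
    -eff$sensitive[eff$gene_id %in% fault_ids]
  arch <- setNames(
    c(rep("tolerant", 4), rep("sensitive", 6)),
    sprintf("V%02d", 1:10)
  )
  list(
    config = sim_config(
      panel = panel, effects = eff, archetypes = arch,
      stress_intensity = flat_intensity(),
      sd_bio = sd_bio, sd_tech = sd_tech, seed = seed
    ),
    fault_ids = fault_ids
  )
}

# Hand-built expression-ratio rows in the shape log2_ratio_table() emits.
ratio_rows <- function(gene_id, variety, log2_mean, location = "LocA",
                       control_ref = "tolerant_control",
                       treatment = "stress") {
  tibble::tibble(
    gene_id = gene_id, variety = variety, location = location,
    treatment = treatment, control_ref = control_ref,
    n_bio = 3L, log2_mean = log2_mean, log2_sd = 0.1, significant = NA
  )
}

# Independent one-way ANOVA oracle: sums of squares written out by hand.
anova_oracle <- function(groups) {
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  df1 <- length(groups) - 1
  df2 <- length(all_x) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(
    f = f, df1 = df1, df2 = df2,
    p = stats::pf(f, df1, df2, lower.tail = FALSE)
  )
}

# Independent Tukey HSD oracle: studentized-range p from group summaries.
tukey_oracle <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df2 <- sum(ns) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    df2
  pairs <- utils::combn(k, 2)
  apply(pairs, 2, function(ij) {
    i <- ij[1]
    j <- ij[2]
    se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
    stats::ptukey(abs(means[j] - means[i]) / se, k, df2,
      lower.tail = FALSE
    )
  })
}
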