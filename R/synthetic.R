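default_class_counts <- c(
  CE = 10, Cer = 20, CL = 5, DAG = 15, HexCer = 10, LPA = 5, LPC = 10,
  LPE = 8, LPG = 4, LPI = 4, LPS = 4, PA = 10, PC = 40, PE = 30, PG = 10,
  PI = 15, PS = 12, SM = 20, TAG = 20, `PC O-` = 12, `PE O-` = 10
)

#' Simulation configuration
#'
#' Parameters of the synthetic shotgun-lipidomics generator. The defaults
#' emulate the study design: a healthy control line plus cancer lines probed
#' with a Wnt-pathway perturbation, three biological replicates per
#' condition, a Lipotype-like species composition over ~20 classes,
#' lognormal pmol abundances with multiplicative replicate noise, and
#' below-detection-limit censoring.
#'
#' @param n_lipids_per_class Named integer vector: species count per lipid
#'   class. The default spans 21 classes (~270 species).
#' @param cell_lines Cancer cell-line labels.
#' @param control_line Healthy control line label (untreated only).
#' @param treatments Treatment label per cancer line (recycled if length 1).
#' @param n_replicates Biological replicates per condition. Default 3.
#' @param base_log10_pmol_mean,base_log10_pmol_sd Baseline species abundance
#'   model: log10(pmol) ~ Normal(mean, sd). Defaults 2 and 0.6 (median
#'   100 pmol, spanning roughly 1-10000 pmol).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   (lognormal) replicate noise. Default 0.1; 0 gives noise-free data.
#' @param detection_limit_pmol Values below this are censored to missing.
#'   Default 10 (roughly 5-15% censoring under the defaults).
#' @param interaction_mix Named fractions over the five interaction
#'   categories (`moderates`, `amplifies`, `no_treatment_effect`,
#'   `side_effect`, `unaffected`); must sum to 1. Category counts per cell
#'   line are exact (largest-remainder apportionment), not sampled.
#' @param effect_log2fc_magnitude Absolute planted log2 fold change of
#'   cancer and treatment effects. Default 2.
#' @param seed Integer seed governing all randomness.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_lipids_per_class = default_class_counts,
                       cell_lines = c("HUH7", "SNU475", "Hep3B"),
                       control_line = "THLE2",
                       treatments = "Wnt3a",
                       n_replicates = 3L,
                       base_log10_pmol_mean = 2,
                       base_log10_pmol_sd = 0.6,
                       replicate_cv = 0.1,
                       detection_limit_pmol = 10,
                       interaction_mix = c(moderates = 0.2, amplifies = 0.2,
                                           no_treatment_effect = 0.2,
                                           side_effect = 0.2, unaffected = 0.2),
                       effect_log2fc_magnitude = 2,
                       seed = 1L) {
  n_lipids_per_class <- unlist(n_lipids_per_class)
  storage.mode(n_lipids_per_class) <- "integer"
  if (is.null(names(n_lipids_per_class)) ||
      !all(names(n_lipids_per_class) %in% lipid_classes()$lipid_class)) {
    abort("validation_error", "n_lipids_per_class must be named by known classes")
  }
  if (any(n_lipids_per_class < 0)) {
    abort("validation_error", "class counts must be >= 0")
  }
  if (sum(n_lipids_per_class) == 0) {
    abort("validation_error", "configuration yields 0 lipids")
  }
  interaction_mix <- unlist(interaction_mix)
  if (!setequal(names(interaction_mix), interaction_levels) ||
      abs(sum(interaction_mix) - 1) > 1e-9 || any(interaction_mix < 0)) {
    abort("validation_error",
          "interaction_mix must cover the five categories and sum to 1")
  }
  interaction_mix <- interaction_mix[interaction_levels]
  if (length(treatments) == 1L) {
    treatments <- rep(treatments, length(cell_lines))
  }
  if (length(treatments) != length(cell_lines)) {
    abort("validation_error", "one treatment per cancer cell line")
  }
  names(treatments) <- cell_lines
  if (!is.numeric(effect_log2fc_magnitude) || effect_log2fc_magnitude <= 0) {
    abort("validation_error", "effect_log2fc_magnitude must be > 0")
  }
  if (replicate_cv < 0 || detection_limit_pmol < 0 || n_replicates < 1) {
    abort("validation_error", "replicate_cv, detection limit and replicate count must be non-negative")
  }
  structure(list(
    n_lipids_per_class = n_lipids_per_class, cell_lines = cell_lines,
    control_line = control_line, treatments = treatments,
    n_replicates = as.integer(n_replicates),
    base_log10_pmol_mean = base_log10_pmol_mean,
    base_log10_pmol_sd = base_log10_pmol_sd,
    replicate_cv = replicate_cv,
    detection_limit_pmol = detection_limit_pmol,
    interaction_mix = interaction_mix,
    effect_log2fc_magnitude = effect_log2fc_magnitude,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are [sim_config()]
#'   arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort("validation_error", sprintf("unknown config key(s): %s",
                                      paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, cfg)
}

# Chain composition model per class family; ;2 marks the di-hydroxylated
# long-chain base of sphingolipids, matching the shorthand dialect.
random_chain <- function(kind, widen = FALSE) {
  if (kind == "base") {
    sprintf("%d:%d;2", sample(16:20, 1L), sample(1:2, 1L))
  } else {
    carbons <- if (widen) sample(12:26, 1L) else sample(seq(12, 26, 2), 1L)
    db <- sample(0:min(6, carbons - 10), 1L)
    sprintf("%d:%d", carbons, db)
  }
}

#' Grammar-random lipid species names
#'
#' Draws `n` distinct species names of one class from the shorthand grammar
#' (realistic even-carbon acyl chains; sphingolipids get a di-hydroxylated
#' long-chain base). Uses the current RNG state.
#'
#' @param lipid_class A class token from [lipid_classes()].
#' @param n Number of distinct names.
#' @return Character vector of length `n`.
#' @export
random_lipid_names <- function(lipid_class, n) {
  tab <- lipid_classes()
  row <- match(lipid_class, tab$lipid_class)
  if (is.na(row)) {
    abort("nomenclature_error",
          sprintf("unknown lipid class token: '%s'", lipid_class))
  }
  arity <- tab$n_chains[row]
  sphingo <- tab$category[row] == "sphingolipids"
  out <- character(0)
  tries <- 0L
  max_tries <- 1000L + 200L * n
  while (length(out) < n) {
    tries <- tries + 1L
    # admit odd-carbon chains if the even grid is getting exhausted
    widen <- tries > 25L + 5L * n
    kinds <- if (sphingo) c("base", rep("acyl", arity - 1L)) else rep("acyl", arity)
    chains <- vapply(kinds, random_chain, character(1), widen = widen)
    out <- unique(c(out, paste(lipid_class, paste(chains, collapse = "/"))))
    if (tries > max_tries) {
      abort("validation_error", sprintf(
        "cannot draw %d distinct %s species from the grammar", n, lipid_class))
    }
  }
  out[seq_len(n)]
}

# Mass-conserving effect planting. A plasma membrane's total lipid content
# is (to first order) fixed: regulation shifts the composition, not the
# amount. The planted multipliers are therefore constrained so that each
# condition's total pmol equals the control total; otherwise every
# unaffected species would show a spurious mol% fold change equal to the
# (shared) shift of the normalization denominator. Directions are assigned
# by greedy two-dimensional balancing of each lipid's contribution to the
# (untreated, treated) condition totals, processed in descending baseline
# order; the small greedy residuals are then zeroed exactly by adjusting the
# magnitude (never the sign, hence never the category) of the
# largest-baseline moderated lipid (whose treated-condition contribution is
# identically zero) and the largest-baseline side-effect lipid (whose
# untreated-condition contribution is identically zero).
plant_effects <- function(baseline, category, mag) {
  n <- length(baseline)
  s <- rep(1L, n)
  u1 <- 2^mag - 1
  d1 <- 2^(-mag) - 1
  u2 <- 2^(2 * mag) - 1
  d2 <- 2^(-2 * mag) - 1
  delta_for <- function(i, sgn) {
    b <- baseline[i]
    f1 <- switch(category[i],
                 moderates = , amplifies = ,
                 no_treatment_effect = if (sgn > 0) u1 else d1,
                 0)
    f2 <- switch(category[i],
                 moderates = 0,
                 amplifies = if (sgn > 0) u2 else d2,
                 no_treatment_effect = ,
                 side_effect = if (sgn > 0) u1 else d1,
                 0)
    b * c(f1, f2)
  }
  affected <- which(category != "unaffected")
  r <- c(0, 0)
  for (i in affected[order(baseline[affected], decreasing = TRUE)]) {
    dp <- delta_for(i, 1L)
    dm <- delta_for(i, -1L)
    if (sum((r + dp)^2) <= sum((r + dm)^2)) {
      s[i] <- 1L; r <- r + dp
    } else {
      s[i] <- -1L; r <- r + dm
    }
  }
  cancer <- ifelse(category %in% c("moderates", "amplifies",
                                   "no_treatment_effect"), s * mag, 0)
  treat <- ifelse(category == "moderates", -s * mag,
           ifelse(category %in% c("amplifies", "side_effect"), s * mag, 0))
  r1 <- sum(baseline * (2^cancer - 1))
  mod <- which(category == "moderates")
  if (length(mod) && r1 != 0) {
    k <- mod[which.max(baseline[mod])]
    target <- 2^cancer[k] - r1 / baseline[k]
    if (target > 0) {
      cancer[k] <- log2(target)
      treat[k] <- -cancer[k]
    }
  }
  r2 <- sum(baseline * (2^(cancer + treat) - 1))
  side <- which(category == "side_effect")
  if (length(side) && r2 != 0) {
    k <- side[which.max(baseline[side])]
    target <- 2^treat[k] - r2 / baseline[k]
    if (target > 0) treat[k] <- log2(target)
  }
  list(cancer_log2fc = cancer, treatment_log2fc = treat)
}

# Exact apportionment of n items to fractions (largest remainder).
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a synthetic lipidomics dataset with known ground truth
#'
#' Produces a pmol concentration table shaped like a delivered shotgun
#' lipidomics run, plus the planted truth. Baseline species abundances are
#' lognormal; per cell line each lipid is assigned one of the five
#' interaction categories (exact counts per `interaction_mix`), which
#' determines its planted cancer and treatment log2 fold changes; effects
#' are applied multiplicatively (`2^log2fc`) on top of the baseline;
#' replicate noise is lognormal with the configured coefficient of
#' variation (mean-preserving); and any value below the detection limit is
#' censored to missing. Identical seeds give bitwise-identical output.
#'
#' Planted effects conserve the total lipid content of each condition
#' (up- and down-regulation are mass-balanced), reflecting that membrane
#' regulation shifts composition rather than total amount; this makes the
#' mol% fold change of each species equal its planted pmol fold change
#' instead of absorbing a shared normalization shift. Up/Down assignments
#' are therefore balanced against the abundance distribution rather than
#' independent coin flips, and the magnitude (never the sign or category)
#' of one moderated and one side-effect lipid per line is adjusted slightly
#' to close the balance exactly.
#'
#' @param config A [sim_config()].
#' @return List with `table` (a pmol [conc_table()]), `truth` (list:
#'   `effects` data.frame with one row per lipid per cancer line giving
#'   `cancer_log2fc`, `treatment_log2fc` and the true `category`; `censored`
#'   logical matrix; `baseline_pmol`), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  counts <- config$n_lipids_per_class[config$n_lipids_per_class > 0]
  names_by_class <- lapply(names(counts), function(cl) {
    random_lipid_names(cl, counts[[cl]])
  })
  lipid_names <- unlist(names_by_class)
  n_lip <- length(lipid_names)
  baseline <- 10^stats::rnorm(n_lip, config$base_log10_pmol_mean,
                              config$base_log10_pmol_sd)

  mag <- config$effect_log2fc_magnitude
  effects <- do.call(rbind, lapply(config$cell_lines, function(line) {
    cat_counts <- apportion(n_lip, config$interaction_mix)
    category <- sample(rep(names(cat_counts), cat_counts))
    fc <- plant_effects(baseline, category, mag)
    data.frame(lipid = lipid_names, cell_line = line,
               treatment = config$treatments[[line]],
               cancer_log2fc = fc$cancer_log2fc,
               treatment_log2fc = fc$treatment_log2fc,
               category = category, stringsAsFactors = FALSE)
  }))

  samples <- data.frame(
    cell_line = config$control_line, treatment = "none",
    replicate = seq_len(config$n_replicates), stringsAsFactors = FALSE
  )
  for (line in config$cell_lines) {
    samples <- rbind(
      samples,
      data.frame(cell_line = line, treatment = "none",
                 replicate = seq_len(config$n_replicates)),
      data.frame(cell_line = line, treatment = config$treatments[[line]],
                 replicate = seq_len(config$n_replicates))
    )
  }
  samples$sample_id <- paste(samples$cell_line, samples$treatment,
                             samples$replicate, sep = "_")
  samples <- samples[, c("sample_id", "cell_line", "treatment", "replicate")]

  sigma <- sqrt(log1p(config$replicate_cv^2))
  values <- matrix(NA_real_, n_lip, nrow(samples),
                   dimnames = list(lipid_names, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    line <- samples$cell_line[j]
    mult <- rep(1, n_lip)
    if (line != config$control_line) {
      eff <- effects[effects$cell_line == line, ]
      mult <- 2^eff$cancer_log2fc
      if (samples$treatment[j] != "none") {
        mult <- mult * 2^eff$treatment_log2fc
      }
    }
    noise <- if (sigma > 0) {
      exp(stats::rnorm(n_lip, 0, sigma) - sigma^2 / 2)  # mean-1 lognormal
    } else rep(1, n_lip)
    values[, j] <- baseline * mult * noise
  }
  censored <- values < config$detection_limit_pmol
  values[censored] <- NA_real_

  table <- conc_table(values, samples, unit = "pmol")
  rownames(censored) <- rownames(table$values)
  list(table = table,
       truth = list(effects = effects, censored = censored,
                    baseline_pmol = stats::setNames(baseline, lipid_names)),
       config = config)
}

#' Synthetic intensity layer for the acquisition filter
#'
#' Derives signal/noise/blank intensity grids from a pmol table so that
#' [acquisition_filter()] produces a controllable censoring pattern: a
#' configurable fraction of cells is forced to a failing signal-to-noise
#' ratio, everything else passes.
#'
#' @param table A pmol [conc_table()] (missing cells get zero signal and are
#'   always dropped).
#' @param intensity_per_pmol Linear response factor. Default 1000.
#' @param snr Signal-to-noise ratio of passing cells. Default 10.
#' @param fail_snr Ratio assigned to sub-threshold cells. Default 5, which
#'   fails the strict `> 5` rule.
#' @param sub_threshold_frac Fraction of cells forced below threshold
#'   (Bernoulli per cell). Default 0.
#' @param blank_fold Signal-to-blank ratio of the per-lipid blank level;
#'   `Inf` (default) gives zero blanks.
#' @return List with `signal`, `noise` (matrices) and `blank` (per-lipid
#'   vector).
#' @export
generate_intensity_layer <- function(table, intensity_per_pmol = 1000,
                                     snr = 10, fail_snr = 5,
                                     sub_threshold_frac = 0,
                                     blank_fold = Inf) {
  stopifnot(inherits(table, "conc_table"))
  signal <- table$values * intensity_per_pmol
  signal[is.na(signal)] <- 0
  snr_cell <- matrix(snr, nrow(signal), ncol(signal))
  if (sub_threshold_frac > 0) {
    fail <- matrix(stats::runif(length(signal)) < sub_threshold_frac,
                   nrow(signal))
    snr_cell[fail] <- fail_snr
  }
  noise <- ifelse(signal > 0, signal / snr_cell, 1)
  dimnames(noise) <- dimnames(signal)
  blank <- if (is.infinite(blank_fold)) {
    rep(0, nrow(signal))
  } else {
    rowMeans(signal) / blank_fold
  }
  list(signal = signal, noise = noise, blank = blank)
}
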