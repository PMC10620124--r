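small_config <- function(...) {
  sim_config(n_lipids_per_class = c(PC = 30, Cer = 10, LPC = 10),
             cell_lines = "HUH7", ...)
}

test_that("the same seed reproduces the dataset bitwise", {
  a <- generate_dataset(small_config(seed = 5))
  b <- generate_dataset(small_config(seed = 5))
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth$effects, b$truth$effects)
  c <- generate_dataset(small_config(seed = 6))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("generated class composition matches the configuration exactly", {
  sim <- generate_dataset(small_config(seed = 8))
  counts <- table(sim$table$lipids$lipid_class)
  expect_identical(counts[["PC"]], 30L)
  expect_identical(counts[["Cer"]], 10L)
  expect_identical(counts[["LPC"]], 10L)
  mix_counts <- table(sim$truth$effects$category)
  expect_identical(sort(unname(as.integer(mix_counts))), c(10L, 10L, 10L, 10L, 10L))
  expect_error(sim_config(n_lipids_per_class = c(PC = 0)),
               class = "validation_error")
})

test_that("censoring is monotone in the detection limit", {
  rates <- vapply(c(0, 5, 20, 80, 1e6), function(dl) {
    sim <- generate_dataset(small_config(seed = 9, detection_limit_pmol = dl))
    mean(is.na(sim$table$values))
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_identical(rates[1], 0)
  expect_identical(rates[5], 1)
})

test_that("no noise and no effects give exactly zero fold changes and no DRLs", {
  cfg <- small_config(
    seed = 10, replicate_cv = 0, detection_limit_pmol = 0,
    interaction_mix = c(moderates = 0, amplifies = 0, no_treatment_effect = 0,
                        side_effect = 0, unaffected = 1))
  sim <- generate_dataset(cfg)
  tab <- normalize_mol_pct(sim$table)
  cc <- compute_contrast(tab, c("THLE2", "none"), c("HUH7", "none"))
  expect_true(all(cc$log2fc == 0))
  expect_true(all(cc$p_value == 1))
  expect_identical(sum(cc$is_drl), 0L)
})

test_that("a detection limit above every value censors everything", {
  sim <- generate_dataset(small_config(seed = 12, detection_limit_pmol = 1e9))
  expect_true(all(is.na(sim$table$values)))
  expect_error(normalize_mol_pct(sim$table),
               class = "degenerate_sample_error")
})

test_that("noise-free planted data is recovered perfectly by the pipeline", {
  cfg <- small_config(seed = 13, replicate_cv = 0, detection_limit_pmol = 0)
  sim <- generate_dataset(cfg)
  tab <- normalize_mol_pct(sim$table)
  cc <- compute_contrast(tab, c("THLE2", "none"), c("HUH7", "none"))
  tc <- compute_contrast(tab, c("HUH7", "none"), c("HUH7", "Wnt3a"))
  calls <- classify_interaction(cc, tc)
  truth <- sim$truth$effects
  m <- match(calls$lipid, truth$lipid)
  expect_identical(nrow(calls), nrow(truth))
  expect_identical(as.character(calls$interaction), truth$category[m])
})

test_that("planted truth is internally consistent with the category algebra", {
  sim <- generate_dataset(sim_config(seed = 14))
  eff <- sim$truth$effects
  sgn <- function(x) ifelse(x > 0, "Up", ifelse(x < 0, "Down", "none"))
  cd <- sgn(eff$cancer_log2fc); td <- sgn(eff$treatment_log2fc)
  expect_true(all(
    (eff$category == "moderates") ==
      (cd != "none" & td != "none" & cd != td)))
  expect_true(all(
    (eff$category == "amplifies") ==
      (cd != "none" & td != "none" & cd == td)))
  expect_true(all((eff$category == "no_treatment_effect") ==
                    (cd != "none" & td == "none")))
  expect_true(all((eff$category == "side_effect") ==
                    (cd == "none" & td != "none")))
  expect_true(all((eff$category == "unaffected") == (cd == "none" & td == "none")))
})

test_that("planted effects conserve each condition's total lipid content", {
  cfg <- small_config(seed = 15, replicate_cv = 0, detection_limit_pmol = 0)
  sim <- generate_dataset(cfg)
  totals <- colSums(sim$table$values)
  expect_equal(unname(totals), rep(totals[[1]], length(totals)),
               tolerance = 1e-9)
})

test_that("a planted moderated lipid is recovered in at least 95 of 100 seeds", {
  hits <- 0L; total <- 0L
  for (seed in 1:100) {
    cfg <- sim_config(n_lipids_per_class = c(PC = 25), cell_lines = "HUH7",
                      n_replicates = 5, replicate_cv = 0.05,
                      detection_limit_pmol = 0, seed = seed)
    sim <- generate_dataset(cfg)
    tab <- normalize_mol_pct(sim$table)
    cc <- compute_contrast(tab, c("THLE2", "none"), c("HUH7", "none"))
    tc <- compute_contrast(tab, c("HUH7", "none"), c("HUH7", "Wnt3a"))
    calls <- classify_interaction(cc, tc)
    truth <- sim$truth$effects
    mod <- truth$lipid[truth$category == "moderates"]
    got <- as.character(calls$interaction[match(mod, calls$lipid)])
    hits <- hits + sum(got == "moderates", na.rm = TRUE)
    total <- total + length(mod)
  }
  expect_gte(hits / total, 0.95)
})

test_that("the intensity layer drives the acquisition filter as configured", {
  sim <- generate_dataset(small_config(seed = 16, detection_limit_pmol = 0))
  # generous SNR, zero blank: everything kept
  layer <- generate_intensity_layer(sim$table, snr = 10, blank_fold = Inf)
  keep <- acquisition_filter(layer$signal, layer$noise, layer$blank)
  expect_true(all(keep))
  # SNR exactly at the threshold: strict inequality drops everything
  layer5 <- generate_intensity_layer(sim$table, snr = 5)
  keep5 <- acquisition_filter(layer5$signal, layer5$noise, layer5$blank)
  expect_false(any(keep5))
  # a configured 20% sub-threshold fraction keeps ~80% of cells
  big <- generate_dataset(sim_config(
    n_lipids_per_class = c(PC = 400, PE = 400, TAG = 400),
    cell_lines = "HUH7", detection_limit_pmol = 0, seed = 17))
  set.seed(18)
  layer20 <- generate_intensity_layer(big$table, sub_threshold_frac = 0.2)
  keep20 <- acquisition_filter(layer20$signal, layer20$noise, layer20$blank)
  expect_gt(length(keep20), 10000)
  expect_lt(abs(mean(keep20) - 0.8), 0.02)
  # censored cells always end up dropped
  cens <- generate_dataset(small_config(seed = 19, detection_limit_pmol = 30))
  layerc <- generate_intensity_layer(cens$table)
  keepc <- acquisition_filter(layerc$signal, layerc$noise, layerc$blank)
  expect_false(any(keepc[is.na(cens$table$values)]))
  # and censor_cells writes the mask back into the table
  censored <- censor_cells(cens$table, keepc)
  expect_true(all(is.na(censored$values[!keepc])))
})

test_that("configs are validated and readable from YAML", {
  expect_error(sim_config(interaction_mix = c(moderates = 0.5, amplifies = 0.5)),
               class = "validation_error")
  expect_error(sim_config(n_lipids_per_class = c(WAT = 5)),
               class = "validation_error")
  expect_error(sim_config(effect_log2fc_magnitude = 0),
               class = "validation_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_lipids_per_class:", "  PC: 12", "  Cer: 4",
    "cell_lines: [HUH7, Hep3B]",
    "treatments: Wnt3a",
    "n_replicates: 3",
    "replicate_cv: 0.08",
    "seed: 21"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_identical(sum(cfg$n_lipids_per_class), 16L)
  sim <- generate_dataset(cfg)
  expect_identical(dim(sim$table), c(16L, 15L))
  writeLines("bogus_key: 1", path)
  expect_error(read_sim_config(path), class = "validation_error")
})
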