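cancer_ref <- c("THLE2", "none")
line_untreated <- c("HUH7", "none")
line_treated <- c("HUH7", "Wnt3a")

make_pair <- function(lipid, cancer_fc, cancer_p, treat_fc, treat_p) {
  list(
    cancer = fake_contrast(lipid, cancer_fc, cancer_p,
                           reference_group = cancer_ref,
                           test_group = line_untreated),
    treat = fake_contrast(lipid, treat_fc, treat_p,
                          reference_group = line_untreated,
                          test_group = line_treated)
  )
}

test_that("the five interaction patterns are classified as defined", {
  lip <- c("PC 16:0/18:1", "PE 16:0/18:1", "Cer 18:1;2/16:0",
           "SM 18:1;2/16:0", "TAG 16:0/18:1/18:2")
  pair <- make_pair(
    lip,
    cancer_fc = c(1.2, 1.0, -1.5, 0.3, 0.2),
    cancer_p = c(0.01, 0.02, 0.002, 0.30, 0.60),
    treat_fc = c(-0.8, 0.9, 0.1, 1.1, -0.1),
    treat_p = c(0.03, 0.01, 0.40, 0.01, 0.70))
  calls <- classify_interaction(pair$cancer, pair$treat)
  got <- setNames(as.character(calls$interaction), calls$lipid)
  expect_identical(got[["PC 16:0/18:1"]], "moderates")          # Up then Down
  expect_identical(got[["PE 16:0/18:1"]], "amplifies")          # Up & Up
  expect_identical(got[["Cer 18:1;2/16:0"]], "no_treatment_effect")
  expect_identical(got[["SM 18:1;2/16:0"]], "side_effect")
  expect_identical(got[["TAG 16:0/18:1/18:2"]], "unaffected")
  counts <- interaction_counts(calls)
  expect_identical(unname(counts), rep(1L, 5L))
})

test_that("contrasts from different cell lines are refused", {
  a <- fake_contrast("PC 16:0/18:1", 1, 0.01,
                     reference_group = cancer_ref,
                     test_group = c("HUH7", "none"))
  b <- fake_contrast("PC 16:0/18:1", 1, 0.01,
                     reference_group = c("Hep3B", "none"),
                     test_group = c("Hep3B", "Wnt3a"))
  expect_error(classify_interaction(a, b), class = "validation_error")
})

test_that("lipids evaluable in only one contrast get direction none and a flag", {
  cancer <- fake_contrast(c("PC 16:0/18:1", "PE 16:0/18:1"), c(1.5, -1.2),
                          c(0.01, 0.02), reference_group = cancer_ref,
                          test_group = line_untreated)
  treat <- fake_contrast("PC 16:0/18:1", -0.7, 0.01,
                         reference_group = line_untreated,
                         test_group = line_treated)
  calls <- classify_interaction(cancer, treat)
  pe <- calls[calls$lipid == "PE 16:0/18:1", ]
  expect_identical(pe$treatment_direction, "none")
  expect_true(pe$not_evaluable_treatment)
  expect_identical(as.character(pe$interaction), "no_treatment_effect")
  # strict counting drops it
  expect_identical(sum(interaction_counts(calls, strict = TRUE)), 1L)
  expect_identical(sum(interaction_counts(calls)), 2L)
})

test_that("categories partition every fixture and ignore input order", {
  set.seed(66)
  for (rep in 1:10) {
    n <- 40L
    lip <- paste0("PC ", sample(12:60, n), ":0/18:", sample(0:3, n, TRUE))
    pair <- make_pair(lip,
                      cancer_fc = rnorm(n), cancer_p = runif(n),
                      treat_fc = rnorm(n), treat_p = runif(n))
    calls <- classify_interaction(pair$cancer, pair$treat)
    expect_identical(nrow(calls), n)
    expect_false(any(is.na(calls$interaction)))
    expect_identical(sum(interaction_counts(calls)), n)
    # exclusivity/exhaustiveness against a brute-force re-derivation
    derived <- mapply(function(cd, td) {
      if (cd != "none" && td != "none") {
        if (cd == td) "amplifies" else "moderates"
      } else if (cd != "none") "no_treatment_effect"
      else if (td != "none") "side_effect" else "unaffected"
    }, calls$cancer_direction, calls$treatment_direction)
    expect_identical(as.character(calls$interaction), unname(derived))
    # order invariance
    shuf <- sample(n)
    pair2 <- make_pair(lip[shuf],
                       cancer_fc = pair$cancer$log2fc[match(lip[shuf], pair$cancer$lipid)],
                       cancer_p = pair$cancer$p_value[match(lip[shuf], pair$cancer$lipid)],
                       treat_fc = pair$treat$log2fc[match(lip[shuf], pair$treat$lipid)],
                       treat_p = pair$treat$p_value[match(lip[shuf], pair$treat$lipid)])
    calls2 <- classify_interaction(pair2$cancer, pair2$treat)
    expect_identical(calls, calls2)
  }
})

test_that("overlap analysis counts exact combinations, split by direction", {
  sets <- list(A = c("PC 16:0/18:1" = "Up", "PE 16:0/18:1" = "Down"),
               B = c("PC 16:0/18:1" = "Up", "PI 16:0/18:1" = "Up"))
  out <- overlap_analysis(sets, mode = "concordant")
  ab <- out[out$combination == "A&B", ]
  expect_identical(ab$n, 1L)
  expect_identical(ab$n_up, 1L)
  expect_identical(ab$n_down, 0L)
  expect_identical(out$n[out$combination == "A"], 1L)
  expect_identical(out$n[out$combination == "B"], 1L)

  # discordant shared lipid is counted apart
  sets2 <- list(A = c("PC 16:0/18:1" = "Up"), B = c("PC 16:0/18:1" = "Down"))
  out2 <- overlap_analysis(sets2, mode = "concordant")
  ab2 <- out2[out2$combination == "A&B", ]
  expect_identical(ab2$n, 1L)
  expect_identical(ab2$n_up + ab2$n_down, 0L)
  expect_identical(ab2$n_discordant, 1L)

  # disjoint sets: every degree >= 2 region empty
  sets3 <- list(A = c("PC 16:0/18:1" = "Up"), B = c("PE 16:0/18:1" = "Up"))
  out3 <- overlap_analysis(sets3)
  expect_identical(out3$n[out3$degree == 2], 0L)

  # identical sets: exclusive regions empty, intersection = |A|
  sets4 <- list(A = sets$A, B = sets$A)
  out4 <- overlap_analysis(sets4)
  expect_identical(out4$n[out4$degree == 1], c(0L, 0L))
  expect_identical(out4$n[out4$degree == 2], 2L)

  expect_error(overlap_analysis(sets[1]), class = "validation_error")
})

test_that("overlap counts equal brute-force membership enumeration", {
  set.seed(77)
  pool <- paste0("PC ", 12:23, ":0/18:1")
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    sets <- lapply(seq_len(k), function(i) {
      members <- sample(pool, sample(2:8, 1))
      setNames(sample(c("Up", "Down"), length(members), TRUE), members)
    })
    names(sets) <- LETTERS[seq_len(k)]
    out <- overlap_analysis(sets)
    oracle <- brute_force_upset(sets)
    for (i in seq_len(nrow(out))) {
      expected <- if (out$combination[i] %in% names(oracle)) {
        as.integer(oracle[[out$combination[i]]])
      } else 0L
      expect_identical(out$n[i], expected)
    }
    expect_identical(sum(out$n), length(unique(unlist(lapply(sets, names)))))
  }
})

test_that("membership matrix is upset-ready", {
  sets <- list(A = c("PC 16:0/18:1" = "Up", "PE 16:0/18:1" = "Down"),
               B = c("PC 16:0/18:1" = "Up"))
  m <- membership_matrix(sets)
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m["PC 16:0/18:1", ], c(A = 1L, B = 1L))
  expect_identical(m["PE 16:0/18:1", ], c(A = 1L, B = 0L))
})
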