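# Fixture builders and independent brute-force oracles used across tests.

# Two-group table: ref and test are lipids x replicates matrices (may contain
# NA). Lipid names default to distinct PC species.
make_two_group_table <- function(ref, test, lipids = NULL, unit = "mol_pct") {
  ref <- as.matrix(ref); test <- as.matrix(test)
  n <- nrow(ref)
  if (is.null(lipids)) lipids <- paste0("PC ", seq_len(n) + 11, ":0/18:1")
  values <- cbind(ref, test)
  rownames(values) <- lipids
  samples <- data.frame(
    sample_id = c(paste0("R", seq_len(ncol(ref))), paste0("T", seq_len(ncol(test)))),
    cell_line = rep(c("REF", "TEST"), c(ncol(ref), ncol(test))),
    treatment = "none",
    replicate = c(seq_len(ncol(ref)), seq_len(ncol(test)))
  )
  colnames(values) <- samples$sample_id
  conc_table(values, samples, unit = unit)
}

ref_group <- c("REF", "none")
test_group <- c("TEST", "none")

# Minimal hand-built contrast_result, for units that consume contrasts.
fake_contrast <- function(lipid, log2fc, p_value,
                          reference_group = c("THLE2", "none"),
                          test_group = c("HUH7", "none"),
                          alpha = 0.05, n = 3L) {
  lipid <- vapply(lipid, canonical_name, character(1), USE.NAMES = FALSE)
  ann <- annotate_lipids(lipid)
  is_drl <- p_value < alpha & log2fc != 0
  k <- length(lipid)
  structure(
    data.frame(lipid = ann$canonical, lipid_class = ann$lipid_class,
               category = ann$category, log2fc = log2fc,
               t = rep(NA_real_, k), p_value = p_value,
               n_ref = rep(n, k), n_test = rep(n, k),
               is_drl = is_drl,
               direction = ifelse(!is_drl, "none",
                                  ifelse(log2fc > 0, "Up", "Down")),
               stringsAsFactors = FALSE),
    class = c("contrast_result", "data.frame"),
    reference_group = reference_group, test_group = test_group
  )
}

# Brute-force average-linkage agglomeration: returns sorted merge heights.
# Cluster-to-cluster distance is the mean of pairwise original distances.
brute_force_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Brute-force exact-combination (upset) counts by per-lipid enumeration.
brute_force_upset <- function(sets) {
  labels <- names(sets)
  lipids <- unique(unlist(lapply(sets, names)))
  combos <- vapply(lipids, function(l) {
    paste(labels[vapply(sets, function(s) l %in% names(s), logical(1))],
          collapse = "&")
  }, character(1))
  table(combos)
}
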