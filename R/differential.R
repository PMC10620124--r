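#' Differential-regulation analysis parameters
#'
#' Defaults reproduce the study rules: two-tailed Student's t-test on mol%
#' replicate values, significance at raw P < 0.05, and a lipid is considered
#' in a contrast only with at least two present replicates in both
#' conditions.
#'
#' @param alpha Significance level in (0, 1). Default 0.05 (raw P-values; no
#'   multiple-testing correction by default).
#' @param min_replicates Minimum present replicates required in each group.
#'   Default 2.
#' @param equal_variance If `TRUE` (default) the classical pooled-variance
#'   Student test; `FALSE` gives the Welch test.
#' @param p_adjust Method passed to [stats::p.adjust()] before the DRL call.
#'   Default `"none"`; anything else (e.g. `"BH"`) is a deliberate deviation
#'   from the raw-P rule and is recorded in the result.
#' @export
analysis_params <- function(alpha = 0.05, min_replicates = 2L,
                            equal_variance = TRUE, p_adjust = "none") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("validation_error", "alpha must be in (0, 1)")
  }
  if (!is.numeric(min_replicates) || min_replicates < 2) {
    abort("validation_error", "min_replicates must be an integer >= 2")
  }
  structure(list(alpha = alpha, min_replicates = as.integer(min_replicates),
                 equal_variance = isTRUE(equal_variance),
                 p_adjust = match.arg(p_adjust, stats::p.adjust.methods)),
            class = "analysis_params")
}

# Vectorised two-sample two-tailed t-test over matrix rows.
# Zero-variance conventions: means equal (within 1e-8 relative, so that
# numerically identical groups are not declared different) -> t = 0, p = 1;
# unequal means with zero pooled variance -> |t| = Inf, p = 0.
row_t_test <- function(x_ref, x_test, equal_variance = TRUE) {
  n1 <- rowSums(!is.na(x_ref)); n2 <- rowSums(!is.na(x_test))
  m1 <- rowSums(x_ref, na.rm = TRUE) / n1
  m2 <- rowSums(x_test, na.rm = TRUE) / n2
  v1 <- rowSums((x_ref - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x_test - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  if (equal_variance) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- is.finite(m1) & is.finite(m2) & (!is.finite(se) | se == 0)
  same <- abs(m2 - m1) <= 1e-8 * pmax(abs(m1), abs(m2))
  tstat[degenerate] <- ifelse(same[degenerate], 0,
                              sign(m2[degenerate] - m1[degenerate]) * Inf)
  p[degenerate] <- ifelse(same[degenerate], 1, 0)
  list(t = tstat, p = p, df = df,
       mean_ref = m1, mean_test = m2, n_ref = n1, n_test = n2)
}

#' Per-lipid two-group contrast
#'
#' For each lipid, the log2 fold change of the test-group mean over the
#' reference-group mean (means over present mol% replicate values only) and
#' a two-tailed t-test on the per-replicate values. Lipids with fewer than
#' `min_replicates` present values in either group are excluded from the
#' output, as are lipids whose group mean is exactly zero (log2 fold change
#' undefined); exclusions and their reasons are attached as the `"excluded"`
#' attribute.
#'
#' @param table A mol%-normalized [conc_table()].
#' @param reference_group,test_group `c(cell_line, treatment)` keys; the fold
#'   change is test over reference.
#' @param params An [analysis_params()].
#' @return data.frame of class `contrast_result` with columns `lipid`,
#'   `lipid_class`, `category`, `log2fc`, `t`, `p_value`, `n_ref`, `n_test`,
#'   `is_drl`, `direction`; attributes `reference_group`, `test_group`,
#'   `params`, `excluded`.
#' @export
compute_contrast <- function(table, reference_group, test_group,
                             params = analysis_params()) {
  stopifnot(inherits(table, "conc_table"))
  if (!identical(table$unit, "mol_pct")) {
    abort("validation_error",
          "contrasts are computed on mol%-normalized tables; call normalize_mol_pct() first")
  }
  reference_group <- as_group_key(reference_group)
  test_group <- as_group_key(test_group)
  if (identical(reference_group, test_group)) {
    abort("self_contrast_error", "test group is identical to the reference group")
  }
  ref_cols <- group_columns(table, reference_group)
  test_cols <- group_columns(table, test_group)
  if (length(ref_cols) == 0L || length(test_cols) == 0L) {
    abort("lookup_error", "both groups must exist in the table")
  }
  x_ref <- table$values[, ref_cols, drop = FALSE]
  x_test <- table$values[, test_cols, drop = FALSE]
  tt <- row_t_test(x_ref, x_test, params$equal_variance)

  enough <- tt$n_ref >= params$min_replicates & tt$n_test >= params$min_replicates
  positive <- enough & tt$mean_ref > 0 & tt$mean_test > 0
  excluded <- data.frame(
    lipid = rownames(table$values)[!positive],
    reason = ifelse(!enough[!positive], "insufficient_replicates", "zero_mean"),
    stringsAsFactors = FALSE
  )
  keep <- which(positive)
  p <- stats::p.adjust(tt$p[keep], method = params$p_adjust)
  log2fc <- log2(tt$mean_test[keep] / tt$mean_ref[keep])
  is_drl <- p < params$alpha
  direction <- ifelse(!is_drl | log2fc == 0, "none",
                      ifelse(log2fc > 0, "Up", "Down"))
  res <- data.frame(
    lipid = rownames(table$values)[keep],
    lipid_class = table$lipids$lipid_class[keep],
    category = table$lipids$category[keep],
    log2fc = log2fc,
    t = tt$t[keep],
    p_value = p,
    n_ref = tt$n_ref[keep],
    n_test = tt$n_test[keep],
    is_drl = is_drl,
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  if (nrow(res) < 2L) {
    warning("fewer than 2 eligible lipids in this contrast",
            call. = FALSE)
  }
  structure(res, class = c("contrast_result", "data.frame"),
            reference_group = reference_group, test_group = test_group,
            params = params, excluded = excluded)
}

#' Differentially regulated lipids of one contrast
#'
#' Filters a contrast to its DRLs (significant lipids), sorts stably by
#' class then canonical name, and attaches Up/Down roll-up counts by lipid
#' class and by lipid category as the `"class_summary"` and
#' `"category_summary"` attributes.
#'
#' @param contrasts A `contrast_result` from [compute_contrast()].
#' @return The DRL subset, same columns.
#' @export
drl_table <- function(contrasts) {
  stopifnot(inherits(contrasts, "contrast_result") || is.data.frame(contrasts))
  drl <- contrasts[contrasts$is_drl, , drop = FALSE]
  drl <- drl[order(drl$lipid_class, drl$lipid, method = "radix"), , drop = FALSE]
  rownames(drl) <- NULL
  roll <- function(key) {
    if (nrow(drl) == 0L) {
      return(data.frame(key = character(), Up = integer(), Down = integer(),
                        stringsAsFactors = FALSE))
    }
    tab <- table(drl[[key]], factor(drl$direction, levels = c("Up", "Down")))
    data.frame(key = rownames(tab), Up = as.integer(tab[, "Up"]),
               Down = as.integer(tab[, "Down"]), stringsAsFactors = FALSE)
  }
  cls <- roll("lipid_class"); names(cls)[1] <- "lipid_class"
  cat_ <- roll("category"); names(cat_)[1] <- "category"
  structure(drl, class = c("drl_table", "data.frame"),
            reference_group = attr(contrasts, "reference_group"),
            test_group = attr(contrasts, "test_group"),
            class_summary = cls, category_summary = cat_)
}
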