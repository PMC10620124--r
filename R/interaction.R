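interaction_levels <- c("moderates", "amplifies", "no_treatment_effect",
                        "side_effect", "unaffected")

#' Classify the cancer-by-treatment interaction of each lipid
#'
#' Combines, for one cell line, the cancer contrast (untreated cancer cells
#' vs. healthy control) with the treatment contrast (treated vs. untreated
#' of the same line) into the five-way taxonomy:
#'
#' * `moderates` — the lipid is a DRL in both contrasts with opposite
#'   directions (the treatment reverses the cancer effect);
#' * `amplifies` — a DRL in both with the same direction;
#' * `no_treatment_effect` — a cancer DRL unaffected by the treatment;
#' * `side_effect` — not a cancer DRL but regulated by the treatment;
#' * `unaffected` — a DRL in neither contrast.
#'
#' Directions are significance-gated: a lipid that is non-significant in a
#' contrast has direction `none` there. A lipid that was excluded from one
#' contrast by the replicate rule is also `none` for that contrast but is
#' flagged `not_evaluable_*` so absence of evidence can be told apart from
#' evidence of no effect.
#'
#' @param cancer_contrast `contrast_result`, cancer line vs. healthy control
#'   (test group is the cancer line, untreated).
#' @param treatment_contrast `contrast_result`, treated vs. untreated of the
#'   same cancer line.
#' @return data.frame of class `interaction_calls` with one row per lipid in
#'   the union of the two eligible sets: `lipid`, `lipid_class`,
#'   `lipid_category`, `cell_line`, `treatment`, `cancer_direction`,
#'   `treatment_direction`, `interaction`, `not_evaluable_cancer`,
#'   `not_evaluable_treatment`.
#' @export
classify_interaction <- function(cancer_contrast, treatment_contrast) {
  cancer_line <- attr(cancer_contrast, "test_group")[1]
  treat_ref <- attr(treatment_contrast, "reference_group")
  treat_test <- attr(treatment_contrast, "test_group")
  if (!identical(cancer_line, treat_ref[1]) ||
      !identical(cancer_line, treat_test[1])) {
    abort("validation_error", sprintf(
      "contrasts are from different cell lines (%s vs %s)",
      cancer_line, treat_test[1]))
  }
  lipids <- sort(union(cancer_contrast$lipid, treatment_contrast$lipid),
                 method = "radix")
  ci <- match(lipids, cancer_contrast$lipid)
  ti <- match(lipids, treatment_contrast$lipid)
  cdir <- ifelse(is.na(ci), "none", cancer_contrast$direction[ci])
  tdir <- ifelse(is.na(ti), "none", treatment_contrast$direction[ti])
  category <- ifelse(
    cdir != "none" & tdir != "none",
    ifelse(cdir == tdir, "amplifies", "moderates"),
    ifelse(cdir != "none", "no_treatment_effect",
           ifelse(tdir != "none", "side_effect", "unaffected"))
  )
  ann_src <- ifelse(is.na(ci), "t", "c")
  calls <- data.frame(
    lipid = lipids,
    lipid_class = ifelse(ann_src == "c", cancer_contrast$lipid_class[ci],
                         treatment_contrast$lipid_class[ti]),
    lipid_category = ifelse(ann_src == "c", cancer_contrast$category[ci],
                            treatment_contrast$category[ti]),
    cell_line = cancer_line,
    treatment = treat_test[2],
    cancer_direction = cdir,
    treatment_direction = tdir,
    interaction = factor(category, levels = interaction_levels),
    not_evaluable_cancer = is.na(ci),
    not_evaluable_treatment = is.na(ti),
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL
  structure(calls, class = c("interaction_calls", "data.frame"))
}

#' Per-category interaction counts
#'
#' @param calls An `interaction_calls` table.
#' @param strict If `TRUE`, lipids not evaluable in either contrast are
#'   dropped before counting, so every counted lipid carries evidence in
#'   both contrasts.
#' @return Named integer vector over the five categories.
#' @export
interaction_counts <- function(calls, strict = FALSE) {
  stopifnot(inherits(calls, "interaction_calls"))
  if (strict) {
    calls <- calls[!calls$not_evaluable_cancer & !calls$not_evaluable_treatment, ,
                   drop = FALSE]
  }
  counts <- table(calls$interaction)
  stats::setNames(as.integer(counts), names(counts))
}

#' Directional DRL set
#'
#' @param label Set label, e.g. the contrast name.
#' @param members Named character vector mapping lipid canonical names to
#'   `"Up"` or `"Down"`, or a `drl_table` / `contrast_result` from which the
#'   DRL directions are taken.
#' @return Object of class `drl_set`.
#' @export
drl_set <- function(label, members) {
  if (is.data.frame(members)) {
    members <- members[members$is_drl %||% rep(TRUE, nrow(members)), , drop = FALSE]
    members <- stats::setNames(members$direction, members$lipid)
  }
  if (length(members) && (is.null(names(members)) ||
                          !all(members %in% c("Up", "Down")))) {
    abort("validation_error",
          "set members must be a named vector of 'Up'/'Down' directions")
  }
  structure(list(label = label, members = members), class = "drl_set")
}

#' Exact set-overlap (upset) counts of DRL sets
#'
#' For every non-empty combination of the input sets, the number of lipids
#' belonging to exactly that combination (upset semantics, not cumulative
#' intersections). In `concordant` mode a lipid in several sets contributes
#' to its combination's `n_up`/`n_down` only if its direction is identical
#' in all of them; otherwise it is counted as discordant.
#'
#' @param sets List of two or more [drl_set()] objects (or named
#'   `Up`/`Down` vectors, converted with their list names as labels).
#' @param mode `"any_direction"` or `"concordant"`.
#' @return data.frame with one row per non-empty set combination:
#'   `combination`, `degree`, `n`, and in concordant mode `n_up`, `n_down`,
#'   `n_discordant`.
#' @export
overlap_analysis <- function(sets, mode = c("any_direction", "concordant")) {
  mode <- match.arg(mode)
  if (!is.list(sets) || length(sets) < 2L) {
    abort("validation_error", "overlap analysis needs at least 2 DRL sets")
  }
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "drl_set")) s else drl_set(names(sets)[i] %||% paste0("set", i), s)
  })
  labels <- vapply(sets, function(s) as.character(s$label), character(1))
  if (anyDuplicated(labels)) {
    abort("validation_error", "set labels must be unique")
  }
  lipids <- sort(unique(unlist(lapply(sets, function(s) names(s$members)))),
                 method = "radix")
  member <- vapply(sets, function(s) lipids %in% names(s$members),
                   logical(length(lipids)))
  member <- matrix(member, nrow = length(lipids),
                   dimnames = list(lipids, labels))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  res <- lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    in_combo <- if (length(lipids)) {
      rowSums(member[, inc, drop = FALSE]) == sum(inc) &
        rowSums(member[, !inc, drop = FALSE]) == 0
    } else logical(0)
    row <- data.frame(
      combination = paste(labels[inc], collapse = "&"),
      degree = sum(inc),
      n = sum(in_combo),
      stringsAsFactors = FALSE
    )
    if (mode == "concordant") {
      dirs <- lapply(sets[inc], function(s) s$members[lipids[in_combo]])
      if (sum(in_combo) == 0L) {
        row$n_up <- 0L; row$n_down <- 0L; row$n_discordant <- 0L
      } else {
        dmat <- do.call(cbind, dirs)
        agree <- apply(dmat, 1L, function(d) length(unique(d)) == 1L)
        shared <- dmat[, 1L][agree]
        row$n_up <- sum(shared == "Up")
        row$n_down <- sum(shared == "Down")
        row$n_discordant <- sum(!agree)
      }
    }
    row
  })
  out <- do.call(rbind, res)
  out <- out[order(out$degree, out$combination, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upset-ready membership matrix
#'
#' @param sets List of [drl_set()] objects.
#' @return 0/1 integer matrix, lipids in rows, sets in columns.
#' @export
membership_matrix <- function(sets) {
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "drl_set")) s else drl_set(names(sets)[i] %||% paste0("set", i), s)
  })
  labels <- vapply(sets, function(s) as.character(s$label), character(1))
  lipids <- sort(unique(unlist(lapply(sets, function(s) names(s$members)))),
                 method = "radix")
  m <- vapply(sets, function(s) as.integer(lipids %in% names(s$members)),
              integer(length(lipids)))
  matrix(m, nrow = length(lipids), dimnames = list(lipids, labels))
}
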