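#' Concentration table
#'
#' Container for a lipids-by-samples concentration matrix with explicit
#' missingness and sample metadata. Missing cells (concentrations below the
#' detection limit) are `NA` and stay `NA`: they are never imputed and are
#' excluded from sums, means and tests. A measured `0` is kept as a zero and
#' is distinct from missing.
#'
#' @param values Numeric matrix, lipids in rows (rownames are shorthand
#'   species names), samples in columns (colnames are sample ids). `NA`
#'   marks below-detection-limit cells; present values must be `>= 0`.
#' @param samples data.frame with columns `sample_id`, `cell_line`,
#'   `treatment` (the string `"none"` means untreated), `replicate`. One row
#'   per matrix column; `(cell_line, treatment, replicate)` must be unique.
#' @param lipids Optional pre-computed annotation from [annotate_lipids()];
#'   derived from `rownames(values)` when `NULL`.
#' @param unit `"pmol"` (absolute amounts) or `"mol_pct"` (each sample's
#'   present values sum to 100).
#' @return An object of class `conc_table`.
#' @export
conc_table <- function(values, samples, lipids = NULL, unit = c("pmol", "mol_pct")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    abort("validation_error", "concentration values must be numeric")
  }
  if (is.null(rownames(values))) {
    abort("validation_error", "values must have lipid names as rownames")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort("validation_error", "negative concentration values are not allowed")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "treatment", "replicate")
  if (!all(need %in% names(samples))) {
    abort("schema_error", sprintf(
      "sample metadata must have columns %s", paste(need, collapse = ", ")))
  }
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    missing_meta <- setdiff(colnames(values), samples$sample_id)
    if (length(missing_meta)) {
      abort("schema_error", sprintf(
        "matrix sample(s) absent from metadata: %s",
        paste(missing_meta, collapse = ", ")))
    }
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  }
  key <- paste(samples$cell_line, samples$treatment, samples$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort("validation_error",
          "(cell_line, treatment, replicate) triples must be unique")
  }
  if (is.null(lipids)) lipids <- annotate_lipids(rownames(values))
  rownames(values) <- lipids$canonical
  rownames(samples) <- NULL
  structure(list(values = values, lipids = lipids, samples = samples, unit = unit),
            class = "conc_table")
}

#' @export
print.conc_table <- function(x, ...) {
  cat(sprintf("<conc_table> %d lipids x %d samples [%s], %d missing cells\n",
              nrow(x$values), ncol(x$values), x$unit, sum(is.na(x$values))))
  cat(sprintf("  cell lines: %s\n",
              paste(unique(x$samples$cell_line), collapse = ", ")))
  invisible(x)
}

#' @export
dim.conc_table <- function(x) dim(x$values)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a concentration matrix and its sample metadata
#'
#' Reads a delimited-text matrix (comma or tab, auto-detected; first column
#' lipid shorthand names, remaining columns sample ids) and a metadata table
#' mapping sample ids to `(cell_line, treatment, replicate)`. Empty cells in
#' the matrix denote below-detection-limit missingness and become `NA`,
#' never zero.
#'
#' @param matrix_path Path to the concentration matrix (pmol).
#' @param metadata_path Path to the sample metadata table.
#' @return A [conc_table()] in pmol.
#' @export
read_table <- function(matrix_path, metadata_path) {
  sep <- detect_sep(matrix_path)
  raw <- utils::read.table(matrix_path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (ncol(raw) < 2L) {
    abort("schema_error", "matrix must have a lipid column plus >= 1 sample column")
  }
  lipid_names <- as.character(raw[[1]])
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- lipid_names
  meta <- utils::read.table(metadata_path, sep = detect_sep(metadata_path),
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
  conc_table(values, meta, unit = "pmol")
}

#' Write a concentration table to delimited text
#'
#' @param table A [conc_table()].
#' @param matrix_path,metadata_path Output paths (comma-separated). Missing
#'   cells are written as empty fields.
#' @return Invisibly, the paths written.
#' @export
write_table <- function(table, matrix_path, metadata_path) {
  stopifnot(inherits(table, "conc_table"))
  out <- data.frame(lipid = rownames(table$values), table$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  utils::write.table(table$samples, metadata_path, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(c(matrix_path, metadata_path))
}

#' Acquisition filter parameters
#'
#' Thresholds for the identification-stage filters: a cell is kept only if
#' its signal-to-noise ratio is strictly greater than `snr_min` and its
#' signal is strictly greater than `blank_fold_min` times the corresponding
#' blank-sample intensity.
#'
#' @param snr_min Minimum signal-to-noise ratio (exclusive). Default 5.
#' @param blank_fold_min Minimum fold over blank (exclusive). Default 5.
#' @export
filter_params <- function(snr_min = 5, blank_fold_min = 5) {
  if (!is.numeric(snr_min) || snr_min <= 0 ||
      !is.numeric(blank_fold_min) || blank_fold_min <= 0) {
    abort("validation_error", "filter thresholds must be positive numbers")
  }
  structure(list(snr_min = snr_min, blank_fold_min = blank_fold_min),
            class = "filter_params")
}

#' Acquisition-stage identification filter
#'
#' Applies the two identification filters to intensity-level data: keep a
#' lipid-sample cell iff `signal/noise > snr_min` AND
#' `signal > blank_fold_min * blank`. Both inequalities are strict. Cells
#' failing either test are treated as missing downstream.
#'
#' @param signal,noise Conformable lipids-by-samples intensity matrices;
#'   `noise` must be positive wherever `signal` is present.
#' @param blank Per-lipid blank-sample intensity (length `nrow(signal)`),
#'   non-negative.
#' @param params A [filter_params()].
#' @return Logical keep-mask with the dimensions of `signal`.
#' @export
acquisition_filter <- function(signal, noise, blank, params = filter_params()) {
  signal <- as.matrix(signal); noise <- as.matrix(noise)
  if (!identical(dim(signal), dim(noise))) {
    abort("validation_error", "signal and noise grids must have the same shape")
  }
  if (length(blank) != nrow(signal)) {
    abort("validation_error",
          "blank must have one intensity per lipid (row of signal)")
  }
  if (any(noise <= 0, na.rm = TRUE)) {
    abort("validation_error", "noise intensities must be positive")
  }
  if (any(blank < 0, na.rm = TRUE)) {
    abort("validation_error", "blank intensities must be non-negative")
  }
  keep <- (signal / noise > params$snr_min) &
    (signal > params$blank_fold_min * blank)
  keep[is.na(keep)] <- FALSE
  dimnames(keep) <- dimnames(signal)
  keep
}

#' Censor concentration cells failing the acquisition filter
#'
#' @param table A [conc_table()].
#' @param keep Logical keep-mask from [acquisition_filter()], same shape as
#'   the table's values.
#' @return The table with dropped cells set to missing.
#' @export
censor_cells <- function(table, keep) {
  stopifnot(inherits(table, "conc_table"))
  if (!identical(dim(keep), dim(table$values))) {
    abort("validation_error", "keep-mask shape does not match the table")
  }
  table$values[!keep] <- NA_real_
  table
}

#' Normalize concentrations to mol percent
#'
#' Divides each present value by the sum of the present values in the same
#' sample and multiplies by 100, so every non-degenerate sample's present
#' values sum to 100. Missing cells stay missing and are excluded from the
#' denominator. The operation is idempotent and invariant to rescaling any
#' single sample's raw vector.
#'
#' @param table A [conc_table()].
#' @return The table with unit `"mol_pct"`.
#' @export
normalize_mol_pct <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  sums <- colSums(table$values, na.rm = TRUE)
  n_present <- colSums(!is.na(table$values))
  bad <- n_present == 0L | sums <= 0
  if (any(bad)) {
    abort("degenerate_sample_error", sprintf(
      "sample(s) with no positive present values: %s",
      paste(colnames(table$values)[bad], collapse = ", ")),
      samples = colnames(table$values)[bad])
  }
  table$values <- sweep(table$values, 2L, sums, "/") * 100
  table$unit <- "mol_pct"
  table
}

group_columns <- function(table, group) {
  group <- as_group_key(group)
  which(table$samples$cell_line == group[1] & table$samples$treatment == group[2])
}

#' Average replicates within a condition group
#'
#' Per-lipid mean over the present replicate values of one
#' `(cell_line, treatment)` group. Missing replicates are neglected, not
#' zero-filled; a lipid with no present replicate gets a missing mean and a
#' count of 0.
#'
#' @param table A [conc_table()].
#' @param group `c(cell_line, treatment)`; `"none"` means untreated.
#' @return data.frame with columns `lipid`, `mean`, `n_present`.
#' @export
average_replicates <- function(table, group) {
  stopifnot(inherits(table, "conc_table"))
  cols <- group_columns(table, group)
  if (length(cols) == 0L) {
    abort("lookup_error", sprintf("no samples in group (%s)",
                                  paste(as_group_key(group), collapse = ", ")))
  }
  sub <- table$values[, cols, drop = FALSE]
  n <- rowSums(!is.na(sub))
  m <- rowSums(sub, na.rm = TRUE) / n  # NaN (missing) when n == 0
  data.frame(lipid = rownames(table$values),
             mean = ifelse(n > 0, m, NA_real_),
             n_present = as.integer(n),
             stringsAsFactors = FALSE)
}
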