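#' Write / read a contrast table
#'
#' Tab-delimited round-trippable serialization of a `contrast_result` (or
#' DRL subset), with the group keys kept in header comment lines so the
#' table can be reloaded and fed to [classify_interaction()].
#'
#' @param contrast A `contrast_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contrast <- function(contrast, path) {
  ref <- attr(contrast, "reference_group")
  test <- attr(contrast, "test_group")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# reference_group: %s\t%s", ref[1], ref[2]),
               sprintf("# test_group: %s\t%s", test[1], test[2])), con)
  utils::write.table(as.data.frame(contrast), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contrast
#' @export
read_contrast <- function(path) {
  header <- readLines(path, n = 2L)
  parse_group <- function(line) {
    strsplit(sub("^# [a-z_]+: ", "", line), "\t", fixed = TRUE)[[1]]
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                          stringsAsFactors = FALSE, check.names = FALSE)
  structure(df, class = c("contrast_result", "data.frame"),
            reference_group = parse_group(header[1]),
            test_group = parse_group(header[2]))
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

file_digests <- function(paths) {
  digests <- tools::md5sum(paths)
  data.frame(file = basename(paths), md5 = unname(digests),
             stringsAsFactors = FALSE)
}

#' Simulate a dataset to disk
#'
#' Runs [generate_dataset()] and writes the concentration matrix, sample
#' metadata, planted truth and a manifest (config snapshot, seed, file
#' digests, row counts) under `out_dir`.
#'
#' @param config A [sim_config()] or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the generated dataset (as from [generate_dataset()]).
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_dataset(config)
  paths <- file.path(out_dir, c("concentrations.csv", "samples.csv",
                                "truth.tsv"))
  write_table(sim$table, paths[1], paths[2])
  utils::write.table(sim$truth$effects, paths[3], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    stage = "simulate",
    seed = config$seed,
    config = unclass(config),
    n_lipids = nrow(sim$table$values),
    n_samples = ncol(sim$table$values),
    n_censored_cells = sum(is.na(sim$table$values)),
    files = file_digests(paths)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(quiet, "simulate: %d lipids x %d samples, %d censored cells",
            manifest$n_lipids, manifest$n_samples, manifest$n_censored_cells)
  invisible(sim)
}

#' Run one contrast from files to a contrast table
#'
#' Reads the matrix and metadata, normalizes to mol%, computes the contrast
#' and writes it (plus a provenance sidecar with parameters and exclusion
#' counts) to `out_path`.
#'
#' @param matrix_path,metadata_path Inputs for [read_table()].
#' @param reference_group,test_group `c(cell_line, treatment)` keys.
#' @param params An [analysis_params()].
#' @param out_path Output contrast table path.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `contrast_result`.
#' @export
run_contrast <- function(matrix_path, metadata_path, reference_group,
                         test_group, out_path, params = analysis_params(),
                         quiet = FALSE) {
  table <- read_table(matrix_path, metadata_path)
  table <- normalize_mol_pct(table)
  contrast <- compute_contrast(table, reference_group, test_group, params)
  write_contrast(contrast, out_path)
  excluded <- attr(contrast, "excluded")
  sidecar <- list(
    stage = "contrast",
    reference_group = as_group_key(reference_group),
    test_group = as_group_key(test_group),
    params = unclass(params),
    n_lipids_read = nrow(table$values),
    n_eligible = nrow(contrast),
    n_excluded = nrow(excluded),
    excluded_reasons = as.list(table(excluded$reason)),
    n_drl = sum(contrast$is_drl),
    files = file_digests(out_path)
  )
  jsonlite::write_json(sidecar, paste0(out_path, ".log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(quiet, "contrast %s vs %s: %d read, %d eligible, %d DRLs",
            group_label(test_group), group_label(reference_group),
            sidecar$n_lipids_read, sidecar$n_eligible, sidecar$n_drl)
  invisible(contrast)
}

#' Classify interactions from two contrast files
#'
#' @param cancer_contrast_path,treatment_contrast_path Contrast tables
#'   written by [run_contrast()] / [write_contrast()].
#' @param out_prefix Output prefix: writes `<prefix>_calls.tsv` and
#'   `<prefix>_counts.json` (inclusive and strict per-category counts).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the `interaction_calls` table.
#' @export
run_classify <- function(cancer_contrast_path, treatment_contrast_path,
                         out_prefix, quiet = FALSE) {
  cancer <- read_contrast(cancer_contrast_path)
  treatment <- read_contrast(treatment_contrast_path)
  calls <- classify_interaction(cancer, treatment)
  calls_path <- paste0(out_prefix, "_calls.tsv")
  utils::write.table(as.data.frame(calls), calls_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  counts <- list(
    cell_line = calls$cell_line[1],
    treatment = calls$treatment[1],
    n_lipids = nrow(calls),
    counts = as.list(interaction_counts(calls)),
    counts_strict = as.list(interaction_counts(calls, strict = TRUE))
  )
  json_path <- paste0(out_prefix, "_counts.json")
  jsonlite::write_json(counts, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stage_log(quiet, "classify %s: %d lipids (%s)", counts$cell_line,
            counts$n_lipids,
            paste(names(counts$counts), unlist(counts$counts),
                  sep = "=", collapse = ", "))
  invisible(calls)
}

write_tsv <- function(x, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    x <- data.frame(stats::setNames(list(rownames(x)), rownames_as),
                    as.data.frame(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Summarize a run directory into a manifest
#'
#' Collects the stage outputs of a run directory (simulated dataset,
#' contrast tables, interaction calls), cross-checks their row counts,
#' exports the multivariate summaries, and writes `run_manifest.json`
#' listing every output file with a content digest.
#'
#' When the directory holds a concentration matrix
#' (`concentrations.csv`/`samples.csv`), the mol% PCA score and loading
#' tables are written; when it holds two or more contrast tables
#' (`*.contrast.tsv`), the zero-filled log2 fold-change matrix is exported
#' together with the lipid clustering leaf order and merge heights, and an
#' upset-ready DRL membership matrix.
#'
#' @param run_dir Directory holding stage outputs.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_report <- function(run_dir, quiet = FALSE) {
  files <- list.files(run_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "run_manifest.json"]
  if (length(files) == 0L) {
    abort("validation_error", sprintf("run directory '%s' is empty", run_dir))
  }
  contrast_files <- files[grepl("\\.contrast\\.tsv$", files)]
  stage_counts <- lapply(contrast_files, function(f) {
    cr <- read_contrast(f)
    list(file = basename(f), n_eligible = nrow(cr), n_drl = sum(cr$is_drl))
  })

  written <- character(0)
  mat_path <- file.path(run_dir, "concentrations.csv")
  meta_path <- file.path(run_dir, "samples.csv")
  if (file.exists(mat_path) && file.exists(meta_path)) {
    tab <- normalize_mol_pct(read_table(mat_path, meta_path))
    k <- min(2L, min(ncol(tab$values) - 1L, nrow(tab$values)))
    pca <- pca_molpct(tab, n_components = k)
    written <- c(written,
      write_tsv(pca$scores, file.path(run_dir, "pca_scores.tsv"), "sample_id"),
      write_tsv(pca$loadings, file.path(run_dir, "pca_loadings.tsv"), "lipid"))
  }
  if (length(contrast_files) >= 2L) {
    contrasts <- lapply(contrast_files, read_contrast)
    names(contrasts) <- sub("\\.contrast\\.tsv$", "", basename(contrast_files))
    fc <- build_log2fc_matrix(contrasts)
    cl <- cluster_profiles(fc, axis = "lipids")
    written <- c(written,
      write_tsv(fc$values, file.path(run_dir, "log2fc_matrix.tsv"), "lipid"),
      write_tsv(data.frame(order = seq_along(cl$order), lipid = cl$order),
                file.path(run_dir, "cluster_leaf_order.tsv")),
      write_tsv(data.frame(merge = seq_along(cl$hclust$height),
                           height = cl$hclust$height),
                file.path(run_dir, "cluster_merge_heights.tsv")),
      write_tsv(membership_matrix(lapply(names(contrasts), function(l) {
                  drl_set(l, drl_table(contrasts[[l]]))
                })),
                file.path(run_dir, "drl_membership.tsv"), "lipid"))
  }
  files <- sort(unique(c(files, written)))
  call_files <- files[grepl("_calls\\.tsv$", files)]
  for (f in call_files) {
    calls <- utils::read.table(f, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    counts_file <- sub("_calls\\.tsv$", "_counts.json", f)
    if (file.exists(counts_file)) {
      declared <- jsonlite::read_json(counts_file)
      if (!identical(as.integer(declared$n_lipids), nrow(calls))) {
        abort("validation_error", sprintf(
          "incomplete run: %s declares %s lipids but %s has %d rows",
          basename(counts_file), declared$n_lipids, basename(f), nrow(calls)))
      }
    }
  }
  manifest <- list(
    stage = "report",
    run_dir = normalizePath(run_dir),
    contrasts = stage_counts,
    files = file_digests(files)
  )
  jsonlite::write_json(manifest, file.path(run_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log(quiet, "report: %d files digested in %s", length(files), run_dir)
  invisible(manifest)
}
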