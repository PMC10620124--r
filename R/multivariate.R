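#' Zero-filled log2 fold-change matrix
#'
#' Assembles contrasts into a lipids-by-contrasts matrix for correlation
#' clustering. A cell carries the lipid's log2 fold change when the lipid is
#' a DRL in that contrast; non-significant effects and lipids missing from a
#' contrast (excluded by the replicate rule) are replaced by zero. A
#' provenance mask records why each cell holds its value (`"drl"`,
#' `"nonsignificant_zeroed"`, `"missing_zeroed"`), so the fill never
#' silently overwrites a significant effect.
#'
#' @param contrasts Named list of `contrast_result` objects; names are the
#'   contrast labels (column names).
#' @return Object of class `log2fc_matrix`: list with `values` (numeric
#'   matrix, no missing entries) and `fill_mask` (character matrix, same
#'   shape).
#' @export
build_log2fc_matrix <- function(contrasts) {
  if (!is.list(contrasts) || length(contrasts) < 1L) {
    abort("validation_error", "need at least one contrast")
  }
  labels <- names(contrasts)
  if (is.null(labels) || any(!nzchar(labels))) {
    abort("validation_error", "contrasts must be a named list (labels)")
  }
  if (anyDuplicated(labels)) {
    abort("validation_error", "duplicate contrast labels")
  }
  lipids <- sort(unique(unlist(lapply(contrasts, `[[`, "lipid"))),
                 method = "radix")
  values <- matrix(0, nrow = length(lipids), ncol = length(labels),
                   dimnames = list(lipids, labels))
  mask <- matrix("missing_zeroed", nrow = length(lipids), ncol = length(labels),
                 dimnames = list(lipids, labels))
  for (j in seq_along(contrasts)) {
    cr <- contrasts[[j]]
    i <- match(cr$lipid, lipids)
    values[i, j] <- ifelse(cr$is_drl, cr$log2fc, 0)
    mask[i, j] <- ifelse(cr$is_drl, "drl", "nonsignificant_zeroed")
  }
  structure(list(values = values, fill_mask = mask), class = "log2fc_matrix")
}

#' @export
print.log2fc_matrix <- function(x, ...) {
  cat(sprintf("<log2fc_matrix> %d lipids x %d contrasts (%d DRL cells)\n",
              nrow(x$values), ncol(x$values), sum(x$fill_mask == "drl")))
  invisible(x)
}

# Pearson-correlation distance between the rows of m; zero-variance rows
# have undefined correlation and get distance 1 to everything (treated as
# uncorrelated).
pearson_distance <- function(m) {
  r <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  d
}

#' Cluster lipids or contrasts on zero-filled fold-change profiles
#'
#' Agglomerative clustering with distance `1 - Pearson r` between profiles
#' and (by default) average linkage, as used for the differential-regulation
#' heatmaps.
#'
#' @param x A `log2fc_matrix` (or plain numeric matrix, lipids in rows).
#' @param axis `"lipids"` (rows) or `"contrasts"` (columns).
#' @param linkage Linkage method for [stats::hclust()]. Default
#'   `"average"`.
#' @return List of class `profile_clustering` with `hclust` (the tree),
#'   `order` (leaf labels in dendrogram order), `distance` (the full
#'   distance matrix), and `zero_variance` (labels of profiles with no
#'   variance, whose correlation to others is undefined).
#' @export
cluster_profiles <- function(x, axis = c("lipids", "contrasts"),
                             linkage = "average") {
  axis <- match.arg(axis)
  m <- if (inherits(x, "log2fc_matrix")) x$values else as.matrix(x)
  if (axis == "contrasts") m <- t(m)
  if (nrow(m) < 2L) {
    abort("validation_error", sprintf("need >= 2 %s to cluster", axis))
  }
  zv <- rownames(m)[apply(m, 1L, stats::var) == 0]
  d <- pearson_distance(m)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc, order = rownames(m)[hc$order], distance = d,
                 axis = axis, linkage = linkage, zero_variance = zv),
            class = "profile_clustering")
}

#' @export
print.profile_clustering <- function(x, ...) {
  cat(sprintf("<profile_clustering> %d %s, %s linkage, 1 - Pearson r\n",
              length(x$order), x$axis, x$linkage))
  invisible(x)
}

#' PCA of mol% lipid profiles
#'
#' Column-centered principal component analysis of the samples-by-lipids
#' mol% matrix (no unit-variance scaling by default: mol% values share a
#' scale). Lipids with any missing value across the included samples are
#' dropped and reported. Component signs are fixed by making the
#' largest-magnitude entry of each loading vector positive, so results are
#' reproducible across platforms.
#'
#' @param table A mol%-normalized [conc_table()].
#' @param n_components Number of components to keep; at most
#'   `min(n_samples - 1, n_lipids)`.
#' @param scale Unit-variance scaling flag passed to [stats::prcomp()].
#'   Default `FALSE`.
#' @return Object of class `lipid_pca`: `scores` (samples x components),
#'   `loadings` (lipids x components), `explained_variance_fraction`
#'   (per kept component, non-increasing), `dropped_lipids`, `samples`
#'   (the metadata, for plotting).
#' @export
pca_molpct <- function(table, n_components = 2L, scale = FALSE) {
  stopifnot(inherits(table, "conc_table"))
  if (!identical(table$unit, "mol_pct")) {
    abort("validation_error", "PCA expects a mol%-normalized table")
  }
  complete <- !apply(is.na(table$values), 1L, any)
  dropped <- rownames(table$values)[!complete]
  x <- t(table$values[complete, , drop = FALSE])  # samples x lipids
  if (nrow(x) < 2L) {
    abort("validation_error", "PCA needs at least 2 samples")
  }
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k) {
    abort("validation_error", sprintf(
      "n_components must be <= min(n_samples - 1, n_lipids) = %d", max_k))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale)
  evf <- pr$sdev^2 / sum(pr$sdev^2)
  k <- seq_len(n_components)
  scores <- pr$x[, k, drop = FALSE]
  loadings <- pr$rotation[, k, drop = FALSE]
  for (j in k) {
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf[k],
                 dropped_lipids = dropped, samples = table$samples),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat(sprintf("<lipid_pca> %d samples, %d components (%s%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(round(100 * x$explained_variance_fraction, 1),
                    collapse = "/")))
  if (length(x$dropped_lipids)) {
    cat(sprintf("  %d lipids dropped for missing values\n",
                length(x$dropped_lipids)))
  }
  invisible(x)
}
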