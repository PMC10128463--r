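#' PCA of a methylation matrix with low-variance filtering
#'
#' Drops the zero-variance sites, then the lowest-variance fraction of the
#' remainder (`remove_var_fraction`, default 0.1 — the conventional
#' `removeVar` filter), and runs a singular-value decomposition of the
#' column-centered samples x sites matrix. The sign of each component is
#' fixed so that its largest-magnitude loading is positive, making scores
#' reproducible across platforms.
#'
#' @param mat A `methyl_matrix` (or sites x samples numeric matrix).
#' @param remove_var_fraction Fraction of lowest-variance sites to drop
#'   before the decomposition (default 0.1).
#' @param center,scale Center / scale columns (defaults `TRUE` / `FALSE`).
#' @return A `methyl_pca` object: list with `scores` (samples x
#'   components), `loadings` (sites x components), `variance_explained`,
#'   `removed_fraction`, `kept_sites`.
#' @export
methyl_pca <- function(mat, remove_var_fraction = 0.1, center = TRUE,
                       scale = FALSE) {
  lv <- if (inherits(mat, "methyl_matrix")) mat$levels else as.matrix(mat)
  n <- ncol(lv)
  if (n < 3L) stop_input("PCA needs at least 3 samples")
  v <- apply(lv, 1L, stats::var)
  keep <- which(v > 0)
  if (!length(keep)) stop_input("all sites have zero variance across samples")
  n_drop <- floor(remove_var_fraction * length(keep))
  if (n_drop > 0) {
    ord <- order(v[keep])         # ascending variance
    keep <- sort(keep[ord[(n_drop + 1L):length(keep)]])
  }
  x <- t(lv[keep, , drop = FALSE])          # samples x sites
  pc <- stats::prcomp(x, center = center, scale. = scale)
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve,
                 removed_fraction = remove_var_fraction,
                 kept_sites = rownames(lv)[keep] %||% keep,
                 center = center, scale = scale),
            class = "methyl_pca")
}

#' @export
print.methyl_pca <- function(x, ...) {
  cat("PCA of methylation matrix: ", nrow(x$scores), " samples, ",
      length(x$kept_sites), " sites kept (removeVar = ",
      x$removed_fraction, ")\n", sep = "")
  ve <- round(100 * x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat("  variance explained: ", paste0("PC", seq_along(ve), " ", ve, "%",
                                       collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Squared correlation of each principal component with age
#'
#' @param pca A `methyl_pca` object (or a samples x components score
#'   matrix).
#' @param ages Numeric age per sample.
#' @return Named numeric vector of per-component squared Pearson
#'   correlations with age (`NA` for constant score vectors).
#' @export
pc_age_correlation <- function(pca, ages) {
  scores <- if (inherits(pca, "methyl_pca")) pca$scores else as.matrix(pca)
  if (nrow(scores) != length(ages)) {
    stop_input("one score row per sample is required")
  }
  apply(scores, 2L, function(s) {
    if (stats::sd(s) == 0 || stats::sd(ages) == 0) NA_real_
    else stats::cor(s, ages)^2
  })
}

#' Sample-sample correlation and hierarchical clustering
#'
#' Spearman (default) correlation between sample columns, distance
#' `1 - correlation`, and complete-linkage agglomeration. Rank-based
#' correlation makes the view invariant to any strictly monotone
#' per-sample transform of the levels.
#'
#' @param mat A `methyl_matrix` (or sites x samples matrix).
#' @param method Correlation method (default `"spearman"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @param k Optional number of flat clusters to cut.
#' @return List with `correlation` (samples x samples), `hclust`, and
#'   `clusters` (named integer vector, or `NULL` when `k` is missing).
#' @export
sample_correlation_cluster <- function(mat, method = "spearman",
                                       linkage = "complete", k = NULL) {
  lv <- if (inherits(mat, "methyl_matrix")) mat$levels else as.matrix(mat)
  if (ncol(lv) < 2L) stop_input("need at least 2 samples")
  sds <- apply(lv, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_validation("constant methylation column for sample(s): ",
                    paste(colnames(lv)[sds == 0], collapse = ", "))
  }
  cm <- stats::cor(lv, method = method)
  hc <- stats::hclust(stats::as.dist(1 - cm), method = linkage)
  clusters <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(correlation = cm, hclust = hc, clusters = clusters)
}

#' Export a dendrogram in Newick format
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Top variable sites of a methylation matrix
#'
#' The `n` sites of largest cross-sample variance, ties broken by genomic
#' order; constant sites are never selected while any varying site
#' remains.
#'
#' @param mat A `methyl_matrix`.
#' @param n Number of sites (default 500).
#' @return A `methyl_matrix` restricted to the selected sites, ordered by
#'   decreasing variance.
#' @export
top_variable_sites <- function(mat, n = 500) {
  if (n > nrow(mat$sites)) stop_input("n exceeds the number of sites")
  v <- apply(mat$levels, 1L, stats::var)
  ord <- order(-v, mat$sites$chrom, mat$sites$pos, method = "radix")
  subset_sites(mat, ord[seq_len(n)])
}

#' Cluster sites by their cross-sample methylation profile
#'
#' Complete-linkage (default) hierarchical clustering of sites on the
#' Euclidean distance between their level vectors, cut into `k` flat
#' clusters. When ages are supplied, each cluster is summarized by its
#' mean per-site age trend (mean Pearson correlation with age), which
#' separates rising from falling clusters.
#'
#' @param mat A `methyl_matrix` (typically [top_variable_sites()] output).
#' @param k Number of clusters (default 5).
#' @param linkage Agglomeration method (default `"complete"`).
#' @param ages Optional numeric age per sample for the trend summary.
#' @return List with `labels` (integer per site), `hclust`, and `summary`
#'   (data frame `cluster`, `n_sites`, `mean_age_trend`).
#' @export
site_cluster <- function(mat, k = 5, linkage = "complete", ages = NULL) {
  lv <- if (inherits(mat, "methyl_matrix")) mat$levels else as.matrix(mat)
  if (k > nrow(lv)) stop_input("k exceeds the number of sites")
  hc <- stats::hclust(stats::dist(lv), method = linkage)
  labels <- stats::cutree(hc, k = k)
  trend <- rep(NA_real_, k)
  if (!is.null(ages)) {
    site_cor <- apply(lv, 1L, function(x)
      if (stats::sd(x) > 0) stats::cor(x, ages) else NA_real_)
    trend <- vapply(seq_len(k), function(cl)
      mean(site_cor[labels == cl], na.rm = TRUE), numeric(1))
  }
  list(labels = labels, hclust = hc,
       summary = data.frame(cluster = seq_len(k),
                            n_sites = as.integer(table(factor(labels,
                                                              levels = seq_len(k)))),
                            mean_age_trend = trend))
}
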