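#' Normalize a feature table for chemometrics
#'
#' The fixed three-step chain used before PCA/HCA of extract profiles:
#' (1) sum-normalize each sample column to unit total; (2) replace zeros
#' by half the smallest positive value in the table and take log10;
#' (3) auto-scale each feature row to mean 0, variance 1. Zero-variance
#' rows cannot be auto-scaled and are dropped with a message.
#'
#' @param t A [feature_table].
#' @return A normalized [feature_table]; dropped feature ids are recorded
#'   in the `"dropped"` attribute.
#' @export
normalize_table <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  x <- t$intensities
  totals <- colSums(x)
  if (any(totals == 0)) {
    stop("all-zero sample column(s): ",
         paste(t$samples[totals == 0], collapse = ", "))
  }
  x <- sweep(x, 2, totals, "/")
  pos <- x[x > 0]
  if (!length(pos)) stop("feature table has no positive entries")
  x[x == 0] <- min(pos) / 2
  x <- log10(x)
  rv <- apply(x, 1, stats::var)
  drop <- rv < .Machine$double.eps
  if (any(drop)) {
    message("dropping ", sum(drop), " zero-variance feature(s): ",
            paste(utils::head(t$features$feature_id[drop], 5), collapse = ", "))
  }
  x <- x[!drop, , drop = FALSE]
  x <- t(scale(t(x)))
  out <- feature_table(t$features[!drop, , drop = FALSE], x, t$samples,
                       normalized = TRUE)
  attr(out, "dropped") <- t$features$feature_id[drop]
  attr(out, "normalized") <- TRUE
  out
}

#' Principal component analysis of a normalized feature table
#'
#' Singular-value decomposition of the samples x features matrix (rows =
#' samples). Because auto-scaling centres every feature across samples,
#' the SVD is the classical centred PCA and the explained percentages sum
#' to 100 over all components. Component signs are fixed by forcing the
#' largest-magnitude loading of each component to be positive, so score
#' plots are reproducible.
#'
#' @param t A [normalize_table()] output (or any feature table whose rows
#'   are centred).
#' @param n_components Number of components to return (default: full rank,
#'   `min(samples, features)`).
#' @return A `pca_result`: `scores` (samples x components), `loadings`
#'   (features x components), `explained_pct` (over all components, the
#'   first `n_components` of which correspond to the returned columns).
#' @export
pca_table <- function(t, n_components = NULL) {
  stopifnot(inherits(t, "feature_table"))
  x <- t(t$intensities)           # samples x features
  full <- min(dim(x))
  if (is.null(n_components)) n_components <- full
  if (n_components > full) {
    stop("n_components (", n_components, ") exceeds min(samples, features) = ", full)
  }
  sv <- svd(x)
  d2 <- sv$d^2
  explained <- 100 * d2 / sum(d2)
  flip <- vapply(seq_len(full), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(sv$u[, seq_len(n_components), drop = FALSE], 2,
             flip[seq_len(n_components)], "*")
  v <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2,
             flip[seq_len(n_components)], "*")
  scores <- u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(t$samples, paste0("PC", seq_len(n_components)))
  dimnames(v) <- list(rownames(t$intensities), paste0("PC", seq_len(n_components)))
  structure(list(scores = scores, loadings = v,
                 explained_pct = explained),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, ncol(x$scores))
  cat("<pca_result> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components; ", paste(sprintf("PC%d=%.1f%%", seq_len(k),
                                     x$explained_pct[seq_len(k)]),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the sample columns of a (normalized)
#' feature table; defaults to Ward linkage (`ward.D2`) on Euclidean
#' distances.
#'
#' @param t A [feature_table] with at least two samples.
#' @param distance Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @param k Optional number of flat clusters to cut.
#' @return An `hcluster_result`: the `hclust` object, the merge list, a
#'   Newick string of the dendrogram, and (when `k` is given) integer
#'   cluster `labels` named by sample.
#' @export
hcluster <- function(t, distance = "euclidean", linkage = "ward.D2", k = NULL) {
  stopifnot(inherits(t, "feature_table"))
  if (length(t$samples) < 2) stop("need at least two samples to cluster")
  d <- stats::dist(t(t$intensities), method = distance)
  hc <- stats::hclust(d, method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, merge = hc$merge, height = hc$height,
                 newick = newick, labels = labels,
                 distance = distance, linkage = linkage),
            class = "hcluster_result")
}

#' @export
print.hcluster_result <- function(x, ...) {
  cat("<hcluster_result> ", length(x$hclust$labels), " samples, ",
      x$linkage, " linkage on ", x$distance, " distance\n", sep = "")
  if (!is.null(x$labels)) {
    cat("cluster labels:\n"); print(x$labels)
  }
  invisible(x)
}

#' Write PCA results as CSV files
#'
#' @param p A `pca_result`.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Paths written, invisibly.
#' @export
write_pca_csv <- function(p, dir, prefix = "pca") {
  paths <- file.path(dir, paste0(prefix, c("_scores.csv", "_loadings.csv",
                                           "_explained.csv")))
  utils::write.csv(data.frame(sample = rownames(p$scores), p$scores,
                              check.names = FALSE),
                   paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(feature_id = rownames(p$loadings), p$loadings,
                              check.names = FALSE),
                   paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(component = seq_along(p$explained_pct),
                              explained_pct = p$explained_pct),
                   paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
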