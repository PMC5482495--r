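#' Cluster genes by their score profiles across compounds
#'
#' Groups genes by k-means on their per-compound scores, the first step of
#' co-functional complex discovery: genes targeted or buffered by the same
#' compounds land in the same cluster.
#'
#' @param scores Genes x compounds [score_matrix()] (any method).
#' @param n_clusters Number of clusters (<= number of genes).
#' @param seed Optional integer seed (k-means initialization).
#' @param missing_fill Value imputed for missing entries before clustering
#'   (default 0 = "no measured effect").
#' @param standardize Standardize each compound column first.
#' @param nstart,iter.max Passed to [stats::kmeans()].
#' @return Named integer vector gene -> cluster id in `1..n_clusters`,
#'   class `cluster_assignment`, with attributes `n_clusters`, `seed`,
#'   `sizes`.
#' @export
cluster_genes <- function(scores, n_clusters = 100, seed = NULL,
                          missing_fill = 0, standardize = FALSE,
                          nstart = 5L, iter.max = 50L) {
  x <- check_fd(scores)
  if (n_clusters < 1L || n_clusters > nrow(x))
    stop("'n_clusters' must be between 1 and the number of genes")
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warning("compound(s) with all-missing scores dropped from features: ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  if (standardize) x <- zscore_matrix(x)
  x[is.na(x)] <- missing_fill
  if (!is.null(seed)) set.seed(seed)
  cl <- if (n_clusters == nrow(x)) seq_len(nrow(x))  # degenerate k: singletons
        else stats::kmeans(x, centers = n_clusters, nstart = nstart,
                           iter.max = iter.max)$cluster
  assign <- stats::setNames(as.integer(cl), rownames(x))
  structure(assign, n_clusters = as.integer(n_clusters), seed = seed,
            sizes = tabulate(assign, nbins = n_clusters),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sz <- attr(x, "sizes")
  cat(sprintf("cluster_assignment: %d genes in %d clusters (%d empty), sizes %d-%d\n",
              length(x), attr(x, "n_clusters"), sum(sz == 0L),
              min(sz[sz > 0L]), max(sz)))
  invisible(x)
}

#' Gene-set enrichment of clusters by Fisher's exact test
#'
#' Tests every (cluster, gene set) pair for over-representation with the
#' one-sided (upper-tail) hypergeometric test -- equivalent to Fisher's
#' exact test with `alternative = "greater"` on the 2x2 table of cluster
#' membership against set membership within the universe -- and adjusts
#' across all pairs by Benjamini-Hochberg.
#'
#' @param assign A `cluster_assignment` from [cluster_genes()].
#' @param sets Named list of gene-id vectors, e.g. from [read_gmt()]; sets
#'   are intersected with the universe and empty intersections are skipped.
#' @param universe Gene universe (default: all clustered genes).
#' @param fdr_threshold FDR level for the per-row `enriched` flag.
#' @param adjust `"global"` adjusts across all (cluster, set) pairs;
#'   `"per_cluster"` adjusts within each cluster.
#' @return Data frame (class `enrichment_result`) with one row per tested
#'   (cluster, set): `cluster`, `set`, `overlap`, `cluster_size`,
#'   `set_size`, `universe_size`, `p`, `q`, `enriched`.
#' @export
enrich_clusters <- function(assign, sets, universe = NULL,
                            fdr_threshold = 0.005,
                            adjust = c("global", "per_cluster")) {
  stopifnot(inherits(assign, "cluster_assignment"))
  adjust <- match.arg(adjust)
  if (is.null(universe)) universe <- names(assign)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  assign <- assign[names(assign) %in% universe]
  N <- length(universe)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0L]
  if (length(sets) == 0L) stop("no gene set overlaps the universe")
  clusters <- sort(unique(as.integer(assign)))
  rows <- vector("list", length(clusters) * length(sets))
  idx <- 0L
  for (cl in clusters) {
    members <- names(assign)[assign == cl]
    n <- length(members)
    for (si in seq_along(sets)) {
      set <- sets[[si]]
      K <- length(set)
      ov <- sum(members %in% set)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        cluster = cl, set = names(sets)[si], overlap = ov,
        cluster_size = n, set_size = K, universe_size = N,
        # P(X >= ov) for X ~ Hypergeom(N, K, n); includes the observed table
        p = stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- if (adjust == "global") stats::p.adjust(res$p, "BH")
           else stats::ave(res$p, res$cluster,
                           FUN = function(p) stats::p.adjust(p, "BH"))
  res$enriched <- res$q <= fdr_threshold
  structure(res, fdr_threshold = fdr_threshold, adjust = adjust,
            class = c("enrichment_result", "data.frame"))
}

#' Count enriched clusters over a grid of FDR thresholds
#'
#' For each threshold r, counts the clusters enriched (BH q <= r) in at
#' least one gene set -- the y-axis of an enriched-complex curve.  The
#' count is non-decreasing in r.
#'
#' @param result An `enrichment_result` from [enrich_clusters()].
#' @param r_grid Numeric vector of FDR thresholds.
#' @return Data frame with columns `r` and `n_enriched`.
#' @export
enriched_cluster_counts <- function(result, r_grid) {
  stopifnot(inherits(result, "enrichment_result"), is.numeric(r_grid))
  min_q <- tapply(result$q, result$cluster, min)
  data.frame(r = r_grid,
             n_enriched = vapply(r_grid, function(r) sum(min_q <= r),
                                 integer(1L)))
}
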