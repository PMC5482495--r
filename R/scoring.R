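#' GIT scores: network-assisted target identification
#'
#' The GIT score corrects a gene's fitness-defect score by the signed,
#' weighted FD-scores of its genetic-interaction neighbors.  For gene i and
#' compound c the one-hop (HIP) score is
#' \deqn{GIT^{HIP}_{ic} = FD_{ic} - \sum_j FD_{jc} \, g_{ij},}
#' the sum running over gene i's retained neighbors.  A low score flags a
#' candidate target: an inhibited target's alleviating (positive g) partners
#' tend to show high FD while its aggravating (negative g) partners show
#' low FD, and both patterns push the sum positive.  The two-hop (HOP)
#' score replaces neighbor FDs by their first-order GIT scores,
#' \deqn{GIT^{HOP}_{ic} = FD_{ic} - \sum_j GIT^{1st}_{jc} \, g_{ij},}
#' capturing the pathway-buffer effect of homozygous screens, and the
#' general k-order recursion is `GIT^(k) = FD - G %*% GIT^(k-1)` with
#' `GIT^(0) = FD`.
#'
#' Missing values: a missing `FD_ic` yields a missing score for (i, c);
#' missing neighbor terms contribute 0 to the sum, so the score stays
#' defined wherever the gene's own FD is observed.  Genes screened but
#' absent from the network keep their FD (empty neighborhood); network
#' genes that were not screened contribute nothing.
#'
#' @param fd Numeric genes x compounds FD matrix (see [compute_fd()]).
#' @param nbh A `gi_neighborhood` from [truncate_neighbors()] (or
#'   [randomize_network()]); truncation applies to every propagation pass,
#'   including the inner first-order pass of the HOP score.
#' @param k Propagation order for `git_k()` (k = 1 is `git_hip()`, k = 2 is
#'   `git_hop()`).
#' @return A [score_matrix()] with orientation `"low"`.
#' @examples
#' fd <- matrix(c(-1, -2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "c1"))
#' net <- gi_network(data.frame(from = c("A", "A"), to = c("B", "C"),
#'                              weight = c(-0.5, 0.5)))
#' nbh <- truncate_neighbors(net, q = 100)
#' git_hip(fd, nbh)   # A: -2.5, B: -2.5, C: 1.5
#' git_hop(fd, nbh)   # A: -3.0
#' @export
git_hip <- function(fd, nbh) git_k(fd, nbh, k = 1L)

#' @rdname git_hip
#' @export
git_first <- function(fd, nbh) {
  # the first-order score used inside the HOP recursion is the same
  # expression as the HIP score; kept as a named alias
  out <- git_k(fd, nbh, k = 1L)
  attr(out, "method") <- "git_first"
  out
}

#' @rdname git_hip
#' @export
git_hop <- function(fd, nbh) git_k(fd, nbh, k = 2L)

#' @rdname git_hip
#' @export
git_k <- function(fd, nbh, k) {
  fd <- check_fd(fd)
  stopifnot(inherits(nbh, "gi_neighborhood"))
  if (!(is.numeric(k) && length(k) == 1L && k >= 0 && k == round(k)))
    stop("'k' must be a nonnegative integer")
  if (k == 0L) {
    warning("k = 0 returns the FD-score unchanged")
    return(score_matrix(unclass(fd), method = "fd", orientation = "low"))
  }
  genes <- rownames(fd)
  if (all(lengths(unclass(nbh)[intersect(genes, names(nbh))]) == 0L))
    warning("neighborhood is empty for all scored genes; GIT equals FD")
  G <- neighborhood_matrix(nbh, genes)
  M <- is.na(fd)
  X <- unclass(fd)
  X[M] <- 0
  Z <- X
  for (m in seq_len(k)) {
    Z <- X - G %*% Z
    Z[M] <- 0               # missing scores contribute 0 as neighbor terms
  }
  Z[M] <- NA_real_
  dimnames(Z) <- dimnames(fd)
  method <- if (k == 1L) "git_hip" else if (k == 2L) "git_hop"
            else sprintf("git_k%d", k)
  score_matrix(Z, method = method, orientation = "low",
               q = attr(nbh, "q"), order = as.integer(k))
}

check_fd <- function(fd) {
  fd <- as.matrix(fd)
  if (!is.numeric(fd)) stop("'fd' must be a numeric matrix")
  if (is.null(rownames(fd)) || is.null(colnames(fd)))
    stop("'fd' needs gene row names and compound column names")
  fd
}

#' Correlation-based rho-score baseline
#'
#' For gene i and compound c, the rho-score is the Pearson correlation
#' between the FD-scores of i's genetic-interaction neighbors under c and
#' i's interaction weights to those neighbors.  A high positive value flags
#' a candidate target (chemical inhibition of i mimics genetic perturbation
#' of i).  Neighbor entries with missing FD are excluded pairwise; a score
#' is reported only when at least `min_pairs` usable neighbors remain and
#' both sides have nonzero variance.
#'
#' @inheritParams git_hip
#' @param min_pairs Minimum usable (FD, weight) pairs; default 3.
#' @return A [score_matrix()] with orientation `"high"`.
#' @export
rho_score <- function(fd, nbh, min_pairs = 3L) {
  fd <- check_fd(fd)
  stopifnot(inherits(nbh, "gi_neighborhood"))
  genes <- rownames(fd)
  out <- matrix(NA_real_, nrow(fd), ncol(fd), dimnames = dimnames(fd))
  rows <- unclass(nbh)
  for (g in genes) {
    w <- rows[[g]]
    if (is.null(w)) next
    w <- w[names(w) %in% genes]
    if (length(w) < min_pairs) next
    sub <- fd[names(w), , drop = FALSE]
    ok <- !is.na(sub)
    n_use <- colSums(ok)
    for (ci in which(n_use >= min_pairs)) {
      y <- sub[ok[, ci], ci]
      x <- w[ok[, ci]]
      if (stats::sd(y) == 0 || stats::sd(x) == 0) next
      out[g, ci] <- stats::cor(y, x)
    }
  }
  score_matrix(out, method = "rho", orientation = "high",
               q = attr(nbh, "q"))
}

#' Combine HIP and HOP scores by z-score averaging
#'
#' Each input score matrix is standardized per compound across genes (mean
#' 0, sample standard deviation 1, missing entries excluded) and the two
#' z-scores are averaged, boosting the two complementary assays into one
#' scoring method.
#'
#' @param hip,hop [score_matrix()] objects with orientation `"low"`
#'   (typically `git_hip()` of the HIP screen and `git_hop()` of the HOP
#'   screen).
#' @param gene_policy `"union"` scores a gene present in only one assay by
#'   that assay's z-score alone; `"intersection"` restricts to genes scored
#'   in both.
#' @param scope `"compound"` (default) standardizes each compound column
#'   separately; `"global"` standardizes over the whole matrix.
#' @return A [score_matrix()] with orientation `"low"` over the union (or
#'   intersection) of genes and the union of compounds; a compound present
#'   in only one input is scored from that input with a warning.
#' @export
combine_hip_hop <- function(hip, hop,
                            gene_policy = c("union", "intersection"),
                            scope = c("compound", "global")) {
  gene_policy <- match.arg(gene_policy)
  scope <- match.arg(scope)
  for (x in list(hip, hop))
    if (score_orientation(x) != "low")
      stop("combine_hip_hop() expects low-is-hit inputs")
  zh <- zscore_matrix(hip, scope)
  zo <- zscore_matrix(hop, scope)
  genes <- switch(gene_policy,
                  union = sort(union(rownames(zh), rownames(zo))),
                  intersection = sort(intersect(rownames(zh), rownames(zo))))
  if (length(genes) == 0L) stop("no genes shared between the two assays")
  compounds <- sort(union(colnames(zh), colnames(zo)))
  only <- c(setdiff(colnames(zh), colnames(zo)),
            setdiff(colnames(zo), colnames(zh)))
  if (length(only))
    warning("compound(s) present in a single assay scored from it alone: ",
            paste(only, collapse = ", "))
  expand <- function(z) {
    out <- matrix(NA_real_, length(genes), length(compounds),
                  dimnames = list(genes, compounds))
    gi <- intersect(genes, rownames(z))
    ci <- intersect(compounds, colnames(z))
    out[gi, ci] <- z[gi, ci]
    out
  }
  a <- expand(zh)
  b <- expand(zo)
  comb <- ifelse(is.na(a), b, ifelse(is.na(b), a, (a + b) / 2))
  dimnames(comb) <- list(genes, compounds)
  score_matrix(comb, method = "git_combined", orientation = "low")
}

zscore_matrix <- function(x, scope = "compound") {
  x <- unclass(as.matrix(x))
  if (scope == "global") {
    mu <- mean(x, na.rm = TRUE)
    s <- stats::sd(as.vector(x), na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero variance; cannot z-score")
    return((x - mu) / s)
  }
  mu <- colMeans(x, na.rm = TRUE)
  s <- apply(x, 2L, stats::sd, na.rm = TRUE)
  if (any(!is.na(s) & s == 0))
    warning("compound(s) with zero score variance z-scored to 0")
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
  z[, !is.na(s) & s == 0] <- 0
  z
}

#' Decompose a GIT score into neighbor contributions
#'
#' Reports, for one (gene, compound) pair, the gene's own FD-score and the
#' per-neighbor product terms `score_jc * g_ij` whose sum is subtracted
#' from it, sorted by absolute contribution.  For `method = "hip"` the
#' neighbor score is the neighbor's FD; for `"hop"` it is the neighbor's
#' first-order GIT score.  The decomposition satisfies
#' `own_fd - sum(term) == score` to numerical tolerance.
#'
#' @inheritParams git_hip
#' @param gene,compound Identifiers present in `fd`.
#' @param method `"hip"` or `"hop"`.
#' @return A `data.frame` (class `git_contributions`) with columns
#'   `neighbor`, `weight`, `neighbor_score`, `term`, and attributes
#'   `own_fd`, `score`, `gene`, `compound`, `method`.
#' @export
explain_score <- function(fd, nbh, gene, compound,
                          method = c("hip", "hop")) {
  method <- match.arg(method)
  fd <- check_fd(fd)
  stopifnot(inherits(nbh, "gi_neighborhood"))
  if (!gene %in% rownames(fd)) stop("unknown gene: ", gene)
  if (!compound %in% colnames(fd)) stop("unknown compound: ", compound)
  w <- unclass(nbh)[[gene]]
  if (is.null(w)) w <- stats::setNames(numeric(0), character(0))
  w <- w[names(w) %in% rownames(fd)]
  nb_scores <- if (method == "hip") fd[, compound]
               else unclass(git_first(fd, nbh))[, compound]
  s <- nb_scores[names(w)]
  s[is.na(s)] <- 0
  terms <- data.frame(neighbor = names(w), weight = as.numeric(w),
                      neighbor_score = as.numeric(s),
                      term = as.numeric(s * w),
                      stringsAsFactors = FALSE)
  terms <- terms[order(-abs(terms$term), terms$neighbor), , drop = FALSE]
  rownames(terms) <- NULL
  own <- fd[gene, compound]
  structure(terms,
            own_fd = own,
            score = if (is.na(own)) NA_real_ else own - sum(terms$term),
            gene = gene, compound = compound, method = method,
            class = c("git_contributions", "data.frame"))
}

#' @export
print.git_contributions <- function(x, n = 10L, ...) {
  cat(sprintf("GIT^%s contributions for %s under %s\n",
              toupper(attr(x, "method")), attr(x, "gene"),
              attr(x, "compound")))
  cat(sprintf("own FD = %.4g; score = own FD - sum(terms) = %.4g\n",
              attr(x, "own_fd"), attr(x, "score")))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more neighbors)\n", sep = "")
  invisible(x)
}
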