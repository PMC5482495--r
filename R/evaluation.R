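#' Rank genes per compound under a scoring method
#'
#' Produces 1-based ranks of every scored gene for each compound, best
#' first.  Low-is-hit methods sort ascending, high-is-hit descending; ties
#' are broken by gene-id lexicographic order and genes with missing scores
#' are placed after all finite scores (still ranked).  Compounds whose
#' scores are all missing are dropped with a warning.
#'
#' @param scores A [score_matrix()] (or plain matrix, assumed low-is-hit).
#' @return Integer matrix of ranks (genes x compounds), class `rank_table`.
#' @export
rank_genes <- function(scores) {
  x <- check_fd(scores)
  orient <- score_orientation(scores)
  all_na <- colSums(!is.na(x)) == 0L
  if (any(all_na)) {
    warning("compound(s) with all-missing scores omitted: ",
            paste(colnames(x)[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
  }
  key <- if (orient == "high") -x else x
  ranks <- apply(key, 2L, function(col) {
    ord <- order(col, rownames(x), na.last = TRUE)
    r <- integer(length(col))
    r[ord] <- seq_along(col)
    r
  })
  ranks <- matrix(as.integer(ranks), nrow(x), ncol(x),
                  dimnames = dimnames(x))
  structure(ranks, orientation = orient,
            method = attr(scores, "method"),
            class = c("rank_table", "matrix", "array"))
}

#' Top-k recovery curves against a compound-target benchmark
#'
#' Two evaluation criteria: `counts_t(k)`, the number of benchmark
#' compound-target pairs whose target ranks in the top k genes for its
#' compound, and `counts_d(k)`, the number of compounds with at least one
#' target in the top k.  Benchmark pairs whose gene or compound is not in
#' the scored universe are excluded from the denominator and reported via
#' the `n_excluded` field.
#'
#' @param ranks A `rank_table` from [rank_genes()].
#' @param bench Benchmark data frame (columns `compound`, `gene`), e.g.
#'   from [read_benchmark()] or [make_benchmark()].
#' @param K Largest rank cutoff of the curve (default: all scored genes).
#' @return Object of class `recovery_curve`: list with `k` (1..K),
#'   `counts_t`, `counts_d`, `n_pairs`, `n_compounds`, `n_excluded`.
#' @export
recovery_curves <- function(ranks, bench, K = nrow(ranks)) {
  stopifnot(inherits(ranks, "rank_table"), is.data.frame(bench))
  if (K < 1L || K > nrow(ranks))
    stop("'K' must be between 1 and the number of scored genes")
  scored <- bench$gene %in% rownames(ranks) &
    bench$compound %in% colnames(ranks)
  n_excluded <- sum(!scored)
  bench <- bench[scored, , drop = FALSE]
  if (nrow(bench) == 0L)
    stop("no benchmark pair overlaps the scored gene/compound universe")
  pair_rank <- ranks[cbind(bench$gene, bench$compound)]
  best_rank <- tapply(pair_rank, bench$compound, min)
  kk <- seq_len(K)
  counts_t <- cumsum(tabulate(pair_rank, nbins = K))
  counts_d <- cumsum(tabulate(best_rank, nbins = K))
  structure(list(k = kk,
                 counts_t = as.integer(counts_t),
                 counts_d = as.integer(counts_d),
                 n_pairs = nrow(bench),
                 n_compounds = length(best_rank),
                 n_excluded = n_excluded,
                 method = attr(ranks, "method")),
            class = "recovery_curve")
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf(
    "recovery_curve [%s]: K = %d; %d pairs / %d compounds (%d excluded)\n",
    if (is.null(x$method)) "?" else x$method,
    length(x$k), x$n_pairs, x$n_compounds, x$n_excluded))
  cat(sprintf("  interactions recovered at K: %d; compounds hit at K: %d\n",
              x$counts_t[length(x$k)], x$counts_d[length(x$k)]))
  invisible(x)
}

#' Area under the recovery curve and normalized AUC
#'
#' The AUC is the sum of per-k recovery counts over the integer k grid
#' (unit-width rectangles); nAUC is the ratio of a method's AUC to a
#' reference method's AUC on the same grid and benchmark.  The customary
#' reference is the FD-score, so nAUC > 1 means better than FD; by
#' construction the reference's own nAUC is exactly 1.
#'
#' @param curve A `recovery_curve`.
#' @param reference The reference method's `recovery_curve` on an identical
#'   k grid (omit to get the raw AUC with `nauc = NA`).
#' @param criterion `"interactions"` uses `counts_t`, `"drugs"` uses
#'   `counts_d`.
#' @return List with `auc` and `nauc`.
#' @export
auc_nauc <- function(curve, reference = NULL,
                     criterion = c("interactions", "drugs")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(curve, "recovery_curve"))
  pick <- function(cv) switch(criterion, interactions = cv$counts_t,
                              drugs = cv$counts_d)
  auc <- sum(as.numeric(pick(curve)))
  if (is.null(reference)) return(list(auc = auc, nauc = NA_real_))
  stopifnot(inherits(reference, "recovery_curve"))
  if (!identical(curve$k, reference$k))
    stop("curve and reference must share the same k grid")
  ref_auc <- sum(as.numeric(pick(reference)))
  if (ref_auc == 0) stop("reference AUC is zero; nAUC undefined")
  list(auc = auc, nauc = auc / ref_auc)
}

# one-call convenience: scores + benchmark -> curve
method_curve <- function(scores, bench, K = NULL) {
  ranks <- rank_genes(scores)
  if (is.null(K)) K <- nrow(ranks)
  recovery_curves(ranks, bench, K = K)
}

#' Network-randomization significance test for a GIT score
#'
#' Recomputes the method's nAUC on random networks in which every gene
#' keeps its number of positive and negative neighbors and its incident
#' weights but the neighbor identities are drawn at random (see
#' [randomize_network()]).  The empirical p-value is the add-one estimate
#' `(1 + #\{random nAUC >= observed\}) / (1 + n_random)`: it tests whether
#' the method's advantage comes from exploiting neighbor FD information
#' rather than from network degree structure alone.
#'
#' @inheritParams git_hip
#' @param net The original [gi_network()].
#' @param bench Benchmark data frame (`compound`, `gene`).
#' @param method `"hip"`, `"hop"`, or a propagation order k.
#' @param q Neighborhood truncation applied to the original and each
#'   random network.
#' @param n_random Number of random networks (>= 1).
#' @param seed Optional integer seed.
#' @param K Rank cutoff of the curves (default all genes).
#' @param criterion Passed to [auc_nauc()].
#' @return Object of class `git_permtest`: list with `p`, `observed` (the
#'   observed nAUC vs the FD reference), `random` (vector of random-network
#'   nAUCs), `n_random`.
#' @export
empirical_pvalue <- function(fd, net, bench, method = "hip", q = 100,
                             n_random = 99, seed = NULL, K = NULL,
                             criterion = "interactions") {
  fd <- check_fd(fd)
  stopifnot(n_random >= 1)
  k_order <- if (identical(method, "hip")) 1L
             else if (identical(method, "hop")) 2L
             else as.integer(method)
  if (!is.null(seed)) set.seed(seed)
  score_net <- function(neigh) {
    sc <- git_k(fd, truncate_neighbors(neigh, q = q), k = k_order)
    method_curve(sc, bench, K = K)
  }
  ref_curve <- method_curve(score_matrix(fd, "fd", "low"), bench, K = K)
  obs <- auc_nauc(score_net(net), ref_curve, criterion)$nauc
  rand <- vapply(seq_len(n_random), function(i)
    auc_nauc(score_net(randomize_network(net)), ref_curve, criterion)$nauc,
    numeric(1L))
  structure(list(p = (1 + sum(rand >= obs)) / (1 + n_random),
                 observed = obs, random = rand, n_random = n_random,
                 method = method, criterion = criterion),
            class = "git_permtest")
}

#' @export
print.git_permtest <- function(x, ...) {
  cat(sprintf("Network randomization test (%s criterion, %d random networks)\n",
              x$criterion, x$n_random))
  cat(sprintf("observed nAUC = %.4f; random nAUC median = %.4f; p = %.4g\n",
              x$observed, stats::median(x$random), x$p))
  invisible(x)
}
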