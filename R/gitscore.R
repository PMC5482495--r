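#' Fit network-assisted target scores for a chemical-genomic screen
#'
#' High-level front-end tying the pieces together: truncates the
#' genetic-interaction network to per-gene top-q neighborhoods, propagates
#' the screen's FD-scores over it (one hop for HIP screens, two hops for
#' HOP screens, or any order k), and returns a classed object with the
#' usual accessor methods.
#'
#' @param fd Genes x compounds FD matrix ([compute_fd()] /
#'   [read_fd_matrix()]).
#' @param network A [gi_network()] (or a ready-made `gi_neighborhood`).
#' @param assay `"hip"` (one-hop), `"hop"` (two-hop), or `"rho"` (the
#'   correlation baseline).
#' @param q Per-gene neighborhood truncation: top q positive and top q
#'   negative neighbors (default 100).
#' @param order Override of the propagation order k (defaults to 1 for
#'   `"hip"`, 2 for `"hop"`; ignored for `"rho"`).
#' @return Object of class `gitscore`: list with `scores` (a
#'   [score_matrix()]), `assay`, `q`, `order`, `n_genes`, `n_compounds`,
#'   `call`.
#' @examples
#' spec <- simulation_spec(n_genes = 60, n_compounds = 5,
#'                         mean_pos_degree = 4, mean_neg_degree = 6)
#' net <- simulate_network(spec)
#' truth <- make_truth(net, spec)
#' fd <- simulate_hip(net, truth, spec)
#' fit <- gitscore(fd, net, assay = "hip")
#' print(fit)
#' head(predict(fit, n = 3))
#' @export
gitscore <- function(fd, network, assay = c("hip", "hop", "rho"),
                     q = 100, order = NULL) {
  assay <- match.arg(assay)
  fd <- check_fd(fd)
  nbh <- if (inherits(network, "gi_neighborhood")) network
         else truncate_neighbors(network, q = q)
  if (assay == "rho") {
    scores <- rho_score(fd, nbh)
    order <- NA_integer_
  } else {
    if (is.null(order)) order <- if (assay == "hip") 1L else 2L
    scores <- git_k(fd, nbh, k = order)
  }
  structure(list(scores = scores, assay = assay, q = attr(nbh, "q"),
                 order = order, n_genes = nrow(fd), n_compounds = ncol(fd),
                 call = match.call()),
            class = "gitscore")
}

#' @export
print.gitscore <- function(x, ...) {
  cat("Network-assisted target scores\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("assay %s (order %s, q = %s): %d genes x %d compounds, %s-is-hit\n",
              x$assay, format(x$order), format(x$q),
              x$n_genes, x$n_compounds, score_orientation(x$scores)))
  invisible(x)
}

#' @export
coef.gitscore <- function(object, ...) object$scores

#' Top-ranked candidate targets per compound
#'
#' @param object A [gitscore()] fit.
#' @param n Number of top genes per compound.
#' @param compounds Optional subset of compound ids.
#' @param ... Unused.
#' @return Data frame with columns `compound`, `gene`, `score`, `rank`.
#' @export
predict.gitscore <- function(object, n = 5L, compounds = NULL, ...) {
  ranks <- rank_genes(object$scores)
  if (is.null(compounds)) compounds <- colnames(ranks)
  out <- do.call(rbind, lapply(compounds, function(cm) {
    r <- ranks[, cm]
    top <- names(sort(r))[seq_len(min(n, length(r)))]
    data.frame(compound = cm, gene = top,
               score = as.numeric(object$scores[top, cm]),
               rank = as.integer(r[top]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.gitscore <- function(object, bench = NULL, ...) {
  top1 <- predict(object, n = 1L)
  out <- list(fit = object, top1 = top1,
              score_range = range(object$scores, na.rm = TRUE),
              missing = sum(is.na(object$scores)))
  if (!is.null(bench))
    out$curve <- method_curve(object$scores, bench)
  structure(out, class = "summary.gitscore")
}

#' @export
print.summary.gitscore <- function(x, ...) {
  print(x$fit)
  cat(sprintf("score range [%.3g, %.3g]; %d missing entries\n",
              x$score_range[1L], x$score_range[2L], x$missing))
  cat("top candidate per compound:\n")
  print(utils::head(x$top1, 10L))
  if (nrow(x$top1) > 10L) cat("...\n")
  invisible(x)
}

#' Plot a recovery curve or score distribution
#'
#' With a benchmark, draws the top-k recovery curve of the fit against the
#' raw FD-score reference; without one, a histogram of the scores.
#'
#' @param x A [gitscore()] fit.
#' @param bench Optional benchmark data frame (`compound`, `gene`).
#' @param fd Optional FD matrix for the reference curve (required with
#'   `bench`).
#' @param K Rank cutoff for the curves.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.gitscore <- function(x, bench = NULL, fd = NULL, K = NULL, ...) {
  if (is.null(bench)) {
    graphics::hist(as.numeric(x$scores), breaks = 50,
                   main = sprintf("%s scores", attr(x$scores, "method")),
                   xlab = "score", ...)
    return(invisible(x))
  }
  if (is.null(fd)) stop("supply the FD matrix for the reference curve")
  cv <- method_curve(x$scores, bench, K = K)
  ref <- method_curve(score_matrix(check_fd(fd), "fd", "low"), bench, K = K)
  nauc <- auc_nauc(cv, ref)$nauc
  graphics::plot(cv$k, cv$counts_t, type = "s", col = "firebrick",
                 xlab = "top k genes", ylab = "interactions recovered",
                 main = sprintf("recovery: %s (nAUC = %.3f) vs FD",
                                attr(x$scores, "method"), nauc), ...)
  graphics::lines(ref$k, ref$counts_t, type = "s", col = "grey40")
  graphics::legend("bottomright", legend = c(attr(x$scores, "method"), "fd"),
                   col = c("firebrick", "grey40"), lty = 1, bty = "n")
  invisible(x)
}
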