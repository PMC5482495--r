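#' Construct a signed, weighted genetic-interaction network
#'
#' The network is an undirected edge list of gene pairs with real-valued
#' interaction weights `g_ij` (negative = aggravating interaction, positive
#' = alleviating).  Self-edges are dropped with a warning, duplicate
#' unordered pairs are merged by averaging their weights with a warning,
#' and zero-weight edges are removed.
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param genes Optional character vector of the gene universe; defaults to
#'   the genes occurring in `edges`. Genes listed here but absent from
#'   `edges` are isolated nodes.
#' @param signed `TRUE` for genetic-interaction networks; `FALSE` for
#'   unsigned weighted networks such as physical-interaction (PI) networks,
#'   whose weights are all treated as positive by the scoring functions.
#' @return Object of class `gi_network`: list with `edges` (canonical
#'   `from < to`), `genes`, `signed`.
#' @seealso [build_network()], [truncate_neighbors()], [randomize_network()]
#' @export
gi_network <- function(edges, genes = NULL, signed = TRUE) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "weight") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight)))
    stop("edge weights must be finite")
  if (!signed && any(edges$weight < 0))
    stop("unsigned network cannot have negative weights")
  self <- edges$from == edges$to
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical unordered orientation
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicate edge record(s) merged by averaging")
    w <- tapply(edges$weight, key, mean)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$weight <- as.numeric(w[key[first]])
  }
  zero <- edges$weight == 0
  if (any(zero)) edges <- edges[!zero, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(c(edges$from, edges$to)))
  else {
    genes <- as.character(genes)
    extra <- setdiff(unique(c(edges$from, edges$to)), genes)
    if (length(extra))
      stop("edges reference genes outside the supplied universe: ",
           paste(utils::head(extra, 5L), collapse = ", "))
  }
  rownames(edges) <- NULL
  structure(list(edges = edges[c("from", "to", "weight")],
                 genes = genes, signed = signed),
            class = "gi_network")
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf("gi_network: %d genes, %d edges (%s)\n",
              length(x$genes), nrow(x$edges),
              if (x$signed)
                sprintf("signed: %d positive, %d negative",
                        sum(x$edges$weight > 0), sum(x$edges$weight < 0))
              else "unsigned"))
  invisible(x)
}

#' Build the genetic-interaction network from mutant fitness tables
#'
#' The interaction weight of a gene pair is the deviation of the measured
#' double-mutant fitness from the multiplicative expectation:
#' `g_ij = f_ij - f_i * f_j`.  Pairs at exactly the expectation (or with
#' `|g_ij|` at or below `cutoff`) carry no interaction and are dropped.
#'
#' @param singles Named numeric vector of single-mutant fitness `f_i`, or a
#'   two-column data frame (gene, fitness).
#' @param doubles Data frame with columns `gene_i`, `gene_j`, `fitness`
#'   holding double-mutant fitness `f_ij`, keyed on unordered pairs.
#' @param cutoff Optional magnitude threshold; edges with
#'   `|g_ij| <= cutoff` are dropped (default 0, i.e. only exact zeros).
#' @return A [gi_network()].
#' @examples
#' s <- c(A = 0.8, B = 0.7)
#' d <- data.frame(gene_i = "A", gene_j = "B", fitness = 0.4)
#' build_network(s, d)$edges  # g_AB = 0.4 - 0.56 = -0.16
#' @export
build_network <- function(singles, doubles, cutoff = 0) {
  if (is.data.frame(singles))
    singles <- stats::setNames(as.numeric(singles[[2L]]),
                               as.character(singles[[1L]]))
  stopifnot(is.numeric(singles), !is.null(names(singles)),
            is.data.frame(doubles))
  if (any(!is.finite(singles))) stop("single-mutant fitness must be finite")
  gi <- as.character(doubles[[1L]])
  gj <- as.character(doubles[[2L]])
  fij <- as.numeric(doubles[[3L]])
  miss <- setdiff(unique(c(gi, gj)), names(singles))
  if (length(miss))
    stop("no single-mutant fitness for gene(s): ",
         paste(miss, collapse = ", "))
  g <- fij - singles[gi] * singles[gj]
  edges <- data.frame(from = gi, to = gj, weight = as.numeric(g),
                      stringsAsFactors = FALSE)
  edges <- edges[abs(edges$weight) > cutoff, , drop = FALSE]
  gi_network(edges, genes = sort(names(singles)))
}

# full symmetric per-gene neighbor rows: named list gene -> named weights
full_rows <- function(net) {
  e <- net$edges
  nb <- c(split(stats::setNames(e$weight, e$to), e$from),
          split(stats::setNames(e$weight, e$from), e$to))
  rows <- lapply(split(nb, names(nb)), function(parts)
    do.call(c, unname(parts)))
  out <- stats::setNames(vector("list", length(net$genes)), net$genes)
  for (g in names(rows)) out[[g]] <- rows[[g]]
  empty <- vapply(out, is.null, TRUE)
  out[empty] <- list(stats::setNames(numeric(0), character(0)))
  out
}

new_neighborhood <- function(rows, genes, q, signed) {
  structure(rows, genes = genes, q = q, signed = signed,
            class = "gi_neighborhood")
}

#' Per-gene truncated neighborhoods
#'
#' For each gene, retain its top `q` positive neighbors by weight and its
#' top `q` negative neighbors by absolute weight.  Truncation is per gene
#' (row-wise), so the retained relation may be asymmetric: j can be in i's
#' top list while i is not in j's.  Weight ties at the q-th slot are broken
#' by keeping the lexicographically smaller gene id, for reproducibility.
#'
#' @param x A [gi_network()] or an existing `gi_neighborhood` (e.g. from
#'   [randomize_network()]) to truncate further.
#' @param q Positive integer (or `Inf` to keep all neighbors).
#' @return Object of class `gi_neighborhood`: named list mapping each gene
#'   to a named numeric vector of retained neighbor weights.
#' @export
truncate_neighbors <- function(x, q = 100) {
  if (!(is.numeric(q) && length(q) == 1L && (is.infinite(q) || q >= 1)))
    stop("'q' must be a positive integer or Inf")
  if (inherits(x, "gi_network")) {
    rows <- full_rows(x)
    genes <- x$genes
    signed <- x$signed
  } else if (inherits(x, "gi_neighborhood")) {
    rows <- unclass(x)
    genes <- attr(x, "genes")
    signed <- attr(x, "signed")
  } else stop("'x' must be a gi_network or gi_neighborhood")
  rows <- lapply(rows, function(w) {
    if (length(w) == 0L) return(w)
    pos <- w[w > 0]
    neg <- w[w < 0]
    if (length(pos) > q) {
      ord <- order(-pos, names(pos))
      pos <- pos[ord[seq_len(q)]]
    }
    if (length(neg) > q) {
      ord <- order(-abs(neg), names(neg))
      neg <- neg[ord[seq_len(q)]]
    }
    c(pos, neg)
  })
  new_neighborhood(rows, genes, q, signed)
}

#' @export
print.gi_neighborhood <- function(x, ...) {
  deg <- lengths(unclass(x))
  cat(sprintf("gi_neighborhood: %d genes, q = %s, mean retained degree %.1f\n",
              length(x), format(attr(x, "q")), mean(deg)))
  invisible(x)
}

#' Signed-degree-preserving network randomization
#'
#' For each gene, every neighbor slot is reassigned to another gene drawn
#' uniformly at random (no self-neighbors, no duplicates within a gene's
#' list) while the slot's weight -- and hence its sign -- is kept.  Each
#' gene therefore retains exactly its original number of positive and
#' negative neighbors and its incident-weight multiset; only the identity
#' of the neighbors is randomized.  The result is a directed per-gene
#' neighbor relation, returned as a `gi_neighborhood` and consumed row-wise
#' by the scoring functions exactly like a truncated neighborhood.
#'
#' @param net A [gi_network()] or `gi_neighborhood`.
#' @param seed Optional integer seed for reproducibility.
#' @return A `gi_neighborhood` with randomized neighbor identities.
#' @seealso [empirical_pvalue()]
#' @export
randomize_network <- function(net, seed = NULL) {
  if (inherits(net, "gi_network")) {
    rows <- full_rows(net)
    genes <- net$genes
    signed <- net$signed
    q <- Inf
  } else if (inherits(net, "gi_neighborhood")) {
    rows <- unclass(net)
    genes <- attr(net, "genes")
    signed <- attr(net, "signed")
    q <- attr(net, "q")
  } else stop("'net' must be a gi_network or gi_neighborhood")
  if (length(genes) < 3L)
    stop("randomization needs at least 3 genes")
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  rows <- stats::setNames(lapply(names(rows), function(g) {
    w <- rows[[g]]
    if (length(w) == 0L) return(w)
    if (length(w) > n - 1L)
      stop("gene ", g, " has more neighbor slots than available genes")
    pool <- genes[genes != g]
    stats::setNames(as.numeric(w), sample(pool, length(w)))
  }), names(rows))
  new_neighborhood(rows, genes, q, signed)
}

#' Read / write a network edge list
#'
#' TSV with three columns: `gene_i`, `gene_j`, `weight`; an optional header
#' line is detected (non-numeric third field) and skipped, as are `#`
#' comment lines.  Duplicate records of the same unordered pair are merged
#' by averaging with a warning; self-edges are dropped with a warning.
#'
#' @param path File path.
#' @param signed Whether the weights are signed interaction scores.
#' @return `read_edges()`: a [gi_network()].
#' @export
read_edges <- function(path, signed = TRUE) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(fields) == 0L) stop("empty edge file: ", path)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop(sprintf("edge line %d does not have 3 tab-separated fields",
                 lineno[bad[1L]]))
  w1 <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  if (is.na(w1)) {           # header line
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(w))
    stop(sprintf("non-numeric weight at line %d", lineno[which(is.na(w))[1L]]))
  gi_network(data.frame(from = vapply(fields, `[[`, "", 1L),
                        to = vapply(fields, `[[`, "", 2L),
                        weight = w, stringsAsFactors = FALSE),
             signed = signed)
}

#' @param net A [gi_network()].
#' @rdname read_edges
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "gi_network"))
  e <- net$edges
  writeLines(c("gene_i\tgene_j\tweight",
               sprintf("%s\t%s\t%s", e$from, e$to,
                       format(e$weight, digits = 17, trim = TRUE,
                              scientific = FALSE))),
             path)
  invisible(path)
}

# dense row-truncated adjacency over a given gene universe (fd rows);
# genes outside the universe contribute nothing, genes without network
# rows get zero rows (their score reduces to FD).
neighborhood_matrix <- function(nbh, genes) {
  stopifnot(inherits(nbh, "gi_neighborhood"))
  G <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  rows <- unclass(nbh)
  for (g in intersect(genes, names(rows))) {
    w <- rows[[g]]
    w <- w[names(w) %in% genes]
    if (length(w)) G[g, names(w)] <- w
  }
  G
}
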