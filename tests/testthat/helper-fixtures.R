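# shared in-code fixtures

# 3-gene worked example: FD = (-1, -2, 1), edges A-B (-0.5), A-C (+0.5)
toy_fd <- function() {
  matrix(c(-1, -2, 1), 3, 1, dimnames = list(c("A", "B", "C"), "c1"))
}

toy_net <- function() {
  gi_network(data.frame(from = c("A", "A"), to = c("B", "C"),
                        weight = c(-0.5, 0.5)))
}

toy_nbh <- function(q = 100) truncate_neighbors(toy_net(), q = q)

# dense random instance for oracle comparisons: complete-data FD and a
# random signed network over the same genes
random_instance <- function(n_genes, n_compounds, p_edge = 0.3,
                            weight_scale = 0.3) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  compounds <- sprintf("c%02d", seq_len(n_compounds))
  fd <- matrix(rnorm(n_genes * n_compounds), n_genes, n_compounds,
               dimnames = list(genes, compounds))
  pairs <- which(upper.tri(matrix(FALSE, n_genes, n_genes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  edges <- data.frame(from = genes[pairs[keep, 1]],
                      to = genes[pairs[keep, 2]],
                      weight = rnorm(sum(keep), 0, weight_scale))
  list(fd = fd, net = gi_network(edges, genes = genes))
}

# independent oracle: dense row-truncated adjacency built directly from a
# neighborhood object, bypassing the scoring code path
dense_G <- function(nbh, genes) {
  G <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (g in genes) {
    w <- unclass(nbh)[[g]]
    if (!is.null(w) && length(w)) G[g, names(w)] <- w
  }
  G
}

small_sim <- function(...) {
  spec <- simulation_spec(n_genes = 120, n_compounds = 12,
                          mean_pos_degree = 5, mean_neg_degree = 8, ...)
  net <- simulate_network(spec)
  truth <- make_truth(net, spec)
  list(spec = spec, net = net, truth = truth,
       bench = make_benchmark(truth))
}
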