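#' Specification of a synthetic chemical-genomic study
#'
#' Collects the parameters of the synthetic network/screen generator: a
#' signed random interaction network, HIP and HOP fitness-defect screens
#' with planted compound-target structure, and the matching benchmark.
#'
#' Defaults describe a desk-scale study: 500 genes, 50 compounds with one
#' planted target each, i.i.d. Gaussian screen noise of unit standard
#' deviation.  Negative interactions are drawn more frequently than
#' positive ones (as observed in genome-scale genetic-interaction maps) and
#' weight magnitudes are half-normal with scale 0.2, typical of interaction
#' scores.  `target_fd` is the full drug effect on the target's fitness and
#' `attenuation` the fraction of it visible in the target's own FD (the
#' neighboring-gene effect hides the rest); the defaults put the direct FD
#' signal at -2.25, so the FD-score alone recovers roughly half of the
#' planted targets in the top 10, leaving headroom for network-assisted
#' scoring.  `neighbor_gain` couples one-hop neighbor FD responses to the
#' interaction sign (HIP mechanism); `buffer_gain` couples two-hop
#' responses (HOP pathway-buffer mechanism) and is larger because in HOP
#' screens the buffering deletions are the strongly responding strains.
#'
#' @param n_genes,n_compounds Universe sizes.
#' @param mean_pos_degree,mean_neg_degree Expected number of positive /
#'   negative interaction partners per gene.
#' @param weight_scale Scale of the half-normal weight magnitudes.
#' @param targets_per_compound Planted targets per compound.
#' @param target_fd Full drug effect on a target's FD (negative).
#' @param attenuation Fraction of `target_fd` visible in the target's own
#'   FD, in \[0, 1\].
#' @param neighbor_gain,buffer_gain One-hop (HIP) and two-hop (HOP) signal
#'   couplings, >= 0.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian screen noise.
#' @param seed Integer seed; all generator functions derive their streams
#'   from it (small fixed offsets per stage), so a spec is bit-reproducible.
#' @return Object of class `simulation_spec`.
#' @seealso [simulate_network()], [simulate_hip()], [simulate_hop()],
#'   [make_benchmark()]
#' @export
simulation_spec <- function(n_genes = 500, mean_pos_degree = 6,
                            mean_neg_degree = 10, weight_scale = 0.2,
                            n_compounds = 50, targets_per_compound = 1,
                            target_fd = -4.5, attenuation = 0.5,
                            neighbor_gain = 0.4, buffer_gain = 2,
                            noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 3, n_compounds >= 1, targets_per_compound >= 1,
            mean_pos_degree >= 0, mean_neg_degree >= 0,
            weight_scale >= 0, neighbor_gain >= 0, buffer_gain >= 0,
            noise_sd >= 0)
  if (attenuation < 0 || attenuation > 1)
    stop("'attenuation' must be in [0, 1]")
  if (mean_pos_degree + mean_neg_degree >= n_genes)
    stop("requested mean degree must be smaller than the number of genes")
  structure(list(n_genes = as.integer(n_genes),
                 mean_pos_degree = mean_pos_degree,
                 mean_neg_degree = mean_neg_degree,
                 weight_scale = weight_scale,
                 n_compounds = as.integer(n_compounds),
                 targets_per_compound = as.integer(targets_per_compound),
                 target_fd = target_fd, attenuation = attenuation,
                 neighbor_gain = neighbor_gain, buffer_gain = buffer_gain,
                 noise_sd = noise_sd, seed = as.integer(seed)),
        class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_spec: %d genes, %d compounds (%d target(s) each), seed %d\n",
    "  degrees +%.3g/-%.3g, weight scale %.3g, noise sd %.3g\n",
    "  target_fd %.3g, attenuation %.3g, gains one-hop %.3g / two-hop %.3g\n"),
    x$n_genes, x$n_compounds, x$targets_per_compound, x$seed,
    x$mean_pos_degree, x$mean_neg_degree, x$weight_scale, x$noise_sd,
    x$target_fd, x$attenuation, x$neighbor_gain, x$buffer_gain))
  invisible(x)
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))
sim_compound_ids <- function(n) sprintf("cmpd%03d", seq_len(n))

#' Simulate a signed, weighted genetic-interaction network
#'
#' Each unordered gene pair is independently positive with probability
#' `mean_pos_degree / (n - 1)`, negative with probability
#' `mean_neg_degree / (n - 1)`, or absent; weights are sign times a
#' half-normal magnitude of scale `weight_scale`.
#'
#' @param spec A [simulation_spec()].
#' @return A [gi_network()] over genes `g0001..`.
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sim_gene_ids(n)
  pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  p_pos <- spec$mean_pos_degree / (n - 1)
  p_neg <- spec$mean_neg_degree / (n - 1)
  u <- stats::runif(nrow(pairs))
  sign <- ifelse(u < p_pos, 1, ifelse(u < p_pos + p_neg, -1, 0))
  keep <- sign != 0
  m <- sum(keep)
  w <- sign[keep] * abs(stats::rnorm(m, 0, spec$weight_scale))
  gi_network(data.frame(from = genes[pairs[keep, 1L]],
                        to = genes[pairs[keep, 2L]],
                        weight = w, stringsAsFactors = FALSE),
             genes = genes)
}

#' Plant compound-target ground truth
#'
#' Draws `targets_per_compound` targets per compound among genes that have
#' at least one positive and one negative interaction partner (so the
#' planted mechanisms have a substrate); a gene may be the target of
#' several compounds.
#'
#' @param net The simulated [gi_network()].
#' @param spec The [simulation_spec()].
#' @return Data frame (class `ground_truth`) with columns `compound`,
#'   `gene`.
#' @export
make_truth <- function(net, spec) {
  stopifnot(inherits(net, "gi_network"), inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  rows <- full_rows(net)
  eligible <- names(rows)[vapply(rows, function(w)
    any(w > 0) && any(w < 0), TRUE)]
  if (length(eligible) < spec$targets_per_compound)
    stop("too few genes with both positive and negative neighbors")
  compounds <- sim_compound_ids(spec$n_compounds)
  truth <- do.call(rbind, lapply(compounds, function(cm)
    data.frame(compound = cm,
               gene = sample(eligible, spec$targets_per_compound),
               stringsAsFactors = FALSE)))
  structure(truth, class = c("ground_truth", "data.frame"))
}

# noise matrix shared by both assay simulators
sim_noise <- function(spec, offset) {
  set.seed(spec$seed + offset)
  matrix(stats::rnorm(spec$n_genes * spec$n_compounds, 0, spec$noise_sd),
         spec$n_genes, spec$n_compounds,
         dimnames = list(sim_gene_ids(spec$n_genes),
                         sim_compound_ids(spec$n_compounds)))
}

#' Simulate a HIP fitness-defect screen with planted targets
#'
#' For each compound with planted target t: the target's own FD is
#' `attenuation * target_fd` (plus noise) and every interaction partner j
#' responds along the sign of its interaction,
#' `FD_jc = -neighbor_gain * target_fd * g_tj` (plus noise) -- an inhibited
#' target's alleviating partners show high FD, its aggravating partners low
#' FD.  All other entries are pure noise.
#'
#' @param net The simulated [gi_network()].
#' @param truth Ground truth from [make_truth()].
#' @param spec The [simulation_spec()].
#' @return FD matrix as a [score_matrix()] (orientation `"low"`).
#' @export
simulate_hip <- function(net, truth, spec) {
  stopifnot(inherits(net, "gi_network"), is.data.frame(truth),
            inherits(spec, "simulation_spec"))
  fd <- sim_noise(spec, 2L)
  rows <- full_rows(net)
  for (r in seq_len(nrow(truth))) {
    t <- truth$gene[r]
    cm <- truth$compound[r]
    fd[t, cm] <- fd[t, cm] + spec$attenuation * spec$target_fd
    w <- rows[[t]]
    if (length(w))
      fd[names(w), cm] <- fd[names(w), cm] -
        spec$neighbor_gain * spec$target_fd * w
  }
  score_matrix(fd, method = "fd", orientation = "low")
}

#' Simulate a HOP fitness-defect screen with planted targets
#'
#' Homozygous screens report the pathway-buffer effect: the responding
#' strains are not the target (whose own FD stays near zero) but genes two
#' interaction hops away.  For target t, neighbor j and j's partner m, the
#' planted signal is `FD_mc = buffer_gain * target_fd * g_tj * g_jm` (plus
#' noise): the response sign composes along the two-hop path, so the
#' first-order GIT scores of t's positive partners come out high and those
#' of its negative partners low, and only two-hop propagation ([git_hop()])
#' recovers the target.
#'
#' @inheritParams simulate_hip
#' @return FD matrix as a [score_matrix()] (orientation `"low"`).
#' @export
simulate_hop <- function(net, truth, spec) {
  stopifnot(inherits(net, "gi_network"), is.data.frame(truth),
            inherits(spec, "simulation_spec"))
  fd <- sim_noise(spec, 3L)
  rows <- full_rows(net)
  for (r in seq_len(nrow(truth))) {
    t <- truth$gene[r]
    cm <- truth$compound[r]
    w1 <- rows[[t]]
    for (j in names(w1)) {
      w2 <- rows[[j]]
      w2 <- w2[names(w2) != t]
      if (length(w2))
        fd[names(w2), cm] <- fd[names(w2), cm] +
          spec$buffer_gain * spec$target_fd * w1[[j]] * w2
    }
  }
  score_matrix(fd, method = "fd", orientation = "low")
}

#' Benchmark table from planted ground truth
#'
#' Planted pairs get confidence 1.0; optional random decoy pairs at a
#' sub-threshold confidence exercise the benchmark filter.
#'
#' @param truth Ground truth from [make_truth()].
#' @param decoys Number of random non-target decoy pairs to append.
#' @param decoy_confidence Confidence assigned to decoys (default 0.3,
#'   below the customary 0.4 filter).
#' @param genes Gene universe to draw decoys from (default: truth genes).
#' @param seed Optional seed for decoy sampling.
#' @return Data frame with columns `compound`, `gene`, `confidence`.
#' @export
make_benchmark <- function(truth, decoys = 0L, decoy_confidence = 0.3,
                           genes = NULL, seed = NULL) {
  if (!is.data.frame(truth) || nrow(truth) == 0L)
    stop("'truth' must be a non-empty ground-truth table")
  bench <- data.frame(compound = truth$compound, gene = truth$gene,
                      confidence = 1.0, stringsAsFactors = FALSE)
  if (decoys > 0L) {
    if (is.null(genes)) genes <- unique(truth$gene)
    if (!is.null(seed)) set.seed(seed)
    planted <- paste(bench$compound, bench$gene)
    dec <- data.frame(compound = sample(unique(truth$compound), decoys,
                                        replace = TRUE),
                      gene = sample(genes, decoys, replace = TRUE),
                      confidence = decoy_confidence,
                      stringsAsFactors = FALSE)
    dec <- dec[!paste(dec$compound, dec$gene) %in% planted, , drop = FALSE]
    bench <- rbind(bench, dec)
  }
  rownames(bench) <- NULL
  bench
}
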