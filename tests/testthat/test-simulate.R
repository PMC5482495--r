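test_that("network generator hits the requested signed degrees", {
  spec <- simulation_spec(n_genes = 1000, mean_pos_degree = 5,
                          mean_neg_degree = 5, n_compounds = 1, seed = 3)
  net <- simulate_network(spec)
  rows <- lapply(net$genes, function(g) net$edges$weight[
    net$edges$from == g | net$edges$to == g])
  pos_deg <- mean(vapply(rows, function(w) sum(w > 0), numeric(1)))
  neg_deg <- mean(vapply(rows, function(w) sum(w < 0), numeric(1)))
  # binomial sampling: SE of the mean degree ~ sqrt(5/1000)
  se <- sqrt(5 / 1000)
  expect_lt(abs(pos_deg - 5), 3 * se + 0.2)
  expect_lt(abs(neg_deg - 5), 3 * se + 0.2)
  # reproducible under seed
  expect_identical(simulate_network(spec)$edges, net$edges)
  # no negative edges when the negative degree is zero
  spec0 <- simulation_spec(n_genes = 200, mean_pos_degree = 4,
                           mean_neg_degree = 0, n_compounds = 1)
  expect_true(all(simulate_network(spec0)$edges$weight > 0))
  expect_error(simulation_spec(n_genes = 10, mean_pos_degree = 6,
                               mean_neg_degree = 6), "degree")
})

test_that("HIP generator plants direct and one-hop neighbor signal", {
  spec <- simulation_spec(n_genes = 80, n_compounds = 4,
                          mean_pos_degree = 4, mean_neg_degree = 6,
                          noise_sd = 0, attenuation = 1, seed = 2)
  net <- simulate_network(spec)
  truth <- make_truth(net, spec)
  fd <- simulate_hip(net, truth, spec)
  # noiseless, full attenuation: the target has the lowest FD per compound
  for (r in seq_len(nrow(truth)))
    expect_equal(names(which.min(fd[, truth$compound[r]])), truth$gene[r])
  # same seed -> identical matrix
  expect_identical(unclass(simulate_hip(net, truth, spec)), unclass(fd))
  # neighbor_gain 0: only targets carry signal
  spec0 <- simulation_spec(n_genes = 80, n_compounds = 4,
                           mean_pos_degree = 4, mean_neg_degree = 6,
                           noise_sd = 0, neighbor_gain = 0, seed = 2)
  fd0 <- simulate_hip(net, make_truth(net, spec0), spec0)
  expect_equal(sum(fd0 != 0), spec0$n_compounds)
})

test_that("attenuated targets are invisible to FD but found by git_hip", {
  # the hidden-target scenario: the target's own FD carries no signal,
  # yet its neighbors' responses give it away at one hop
  spec <- simulation_spec(n_genes = 80, n_compounds = 4,
                          mean_pos_degree = 4, mean_neg_degree = 6,
                          noise_sd = 0, attenuation = 0, seed = 1)
  net <- simulate_network(spec)
  truth <- make_truth(net, spec)
  fd <- simulate_hip(net, truth, spec)
  nbh <- truncate_neighbors(net, q = 100)
  rk_fd <- rank_genes(score_matrix(unclass(fd), "fd", "low"))
  rk_git <- rank_genes(git_hip(fd, nbh))
  idx <- cbind(truth$gene, truth$compound)
  expect_true(all(rk_git[idx] == 1L))
  expect_true(all(rk_fd[idx] > 1L))   # negative neighbors outrank the target
})

test_that("HOP generator hides the target from one-hop scoring", {
  spec <- simulation_spec(n_genes = 80, n_compounds = 4,
                          mean_pos_degree = 4, mean_neg_degree = 6,
                          noise_sd = 0, seed = 1)
  net <- simulate_network(spec)
  truth <- make_truth(net, spec)
  fd <- simulate_hop(net, truth, spec)
  nbh <- truncate_neighbors(net, q = 100)
  rk_hip <- rank_genes(git_hip(fd, nbh))
  rk_hop <- rank_genes(git_hop(fd, nbh))
  idx <- cbind(truth$gene, truth$compound)
  expect_true(all(rk_hop[idx] < rk_hip[idx]))
  expect_identical(unclass(simulate_hop(net, truth, spec)), unclass(fd))
  # buffer_gain 0: no signal anywhere
  spec0 <- simulation_spec(n_genes = 80, n_compounds = 4,
                           mean_pos_degree = 4, mean_neg_degree = 6,
                           noise_sd = 0, buffer_gain = 0, seed = 1)
  expect_true(all(simulate_hop(net, make_truth(net, spec0), spec0) == 0))
})

test_that("benchmark generation composes with the confidence filter", {
  sim <- small_sim()
  bench <- make_benchmark(sim$truth)
  expect_equal(nrow(bench), nrow(sim$truth))
  expect_true(all(bench$confidence == 1))
  withdec <- make_benchmark(sim$truth, decoys = 5, decoy_confidence = 0.3,
                            genes = sim$net$genes, seed = 8)
  expect_gt(nrow(withdec), nrow(sim$truth))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(withdec, p)
  kept <- suppressMessages(read_benchmark(p, min_confidence = 0.4))
  expect_equal(nrow(kept), nrow(sim$truth))   # decoys filtered out
  expect_error(make_benchmark(data.frame()), "non-empty")
})
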