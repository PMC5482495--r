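test_that("one-hop score matches the hand-worked 3-gene example", {
  sc <- git_hip(toy_fd(), toy_nbh())
  expect_equal(unname(sc[, "c1"]), c(-2.5, -2.5, 1.5))
  # first-order score is the same expression
  expect_equal(unclass(git_first(toy_fd(), toy_nbh())), unclass(sc),
               ignore_attr = "method")
  # two-hop score for gene A: -1 - [(-2.5)(-0.5) + (1.5)(0.5)] = -3
  hop <- git_hop(toy_fd(), toy_nbh())
  expect_equal(unname(hop["A", "c1"]), -3.0)
})

test_that("scores with no edges reduce to FD, with warnings for edge cases", {
  fd <- toy_fd()
  empty <- gi_network(data.frame(from = character(), to = character(),
                                 weight = numeric()),
                      genes = c("A", "B", "C"))
  expect_warning(sc <- git_hip(fd, truncate_neighbors(empty)), "empty")
  expect_equal(unclass(sc)[, ], fd[, ])
  expect_warning(sc0 <- git_k(fd, toy_nbh(), k = 0), "k = 0")
  expect_equal(unclass(sc0)[, ], fd[, ])
})

test_that("propagation matches closed matrix forms on dense random instances", {
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(50, 4)
    nbh <- truncate_neighbors(inst$net, q = Inf)
    G <- dense_G(nbh, rownames(inst$fd))
    I <- diag(nrow(G))
    expect_equal(unclass(git_hip(inst$fd, nbh))[, ],
                 ((I - G) %*% inst$fd)[, ], tolerance = 1e-12)
    expect_equal(unclass(git_hop(inst$fd, nbh))[, ],
                 ((I - G + G %*% G) %*% inst$fd)[, ], tolerance = 1e-12)
    expect_equal(unclass(git_k(inst$fd, nbh, 3))[, ],
                 ((I - G + G %*% G - G %*% G %*% G) %*% inst$fd)[, ],
                 tolerance = 1e-12)
  }
})

test_that("missing FD propagates to the score; missing neighbors add zero", {
  fd <- toy_fd()
  fd["B", "c1"] <- NA
  sc <- git_hip(fd, toy_nbh())
  expect_true(is.na(sc["B", "c1"]))
  # A's B-term drops out: -1 - (1)(0.5) = -1.5
  expect_equal(unname(sc["A", "c1"]), -1.5)
  hop <- git_hop(fd, toy_nbh())
  expect_true(is.na(hop["B", "c1"]))
  # screened gene absent from the network keeps its FD
  fd2 <- rbind(toy_fd(), D = 4)
  expect_equal(unname(git_hip(fd2, toy_nbh())["D", "c1"]), 4)
})

test_that("GIT scores are linear in FD and permutation-equivariant", {
  set.seed(21)
  inst <- random_instance(30, 3)
  nbh <- truncate_neighbors(inst$net, q = 5)
  base <- unclass(git_hop(inst$fd, nbh))
  expect_equal(unclass(git_hop(inst$fd * 2.5, nbh)), base * 2.5)
  perm <- sample(nrow(inst$fd))
  scp <- git_hop(inst$fd[perm, ], nbh)
  expect_equal(unclass(scp)[rownames(inst$fd), ], base[, ])
})

test_that("rho-score is the neighbor-profile correlation with guards", {
  fd <- matrix(c(-2, 1, 0, 9), 4, 1,
               dimnames = list(c("n1", "n2", "n3", "i"), "c1"))
  net <- gi_network(data.frame(from = "i", to = c("n1", "n2", "n3"),
                               weight = c(-0.5, 0.3, 0.4)))
  nbh <- truncate_neighbors(net)
  r <- rho_score(fd, nbh)
  expect_equal(unname(r["i", "c1"]),
               cor(c(-2, 1, 0), c(-0.5, 0.3, 0.4)))
  expect_equal(unname(r["i", "c1"]), 0.9069, tolerance = 1e-4)
  expect_identical(attr(r, "orientation"), "high")
  # perfect alignment gives rho = 1; |rho| <= 1 wherever defined
  fd1 <- fd
  fd1[c("n1", "n2", "n3"), 1] <- c(-0.5, 0.3, 0.4) * 7
  expect_equal(unname(rho_score(fd1, nbh)["i", "c1"]), 1)
  # fewer than 3 usable neighbors -> missing
  fd2 <- fd
  fd2["n3", 1] <- NA
  expect_true(is.na(rho_score(fd2, nbh)["i", "c1"]))
  # zero variance on either side -> missing
  fd3 <- fd
  fd3[c("n1", "n2", "n3"), 1] <- 1
  expect_true(is.na(rho_score(fd3, nbh)["i", "c1"]))
})

test_that("rho stays in [-1, 1] on random instances", {
  set.seed(33)
  inst <- random_instance(40, 5)
  r <- rho_score(inst$fd, truncate_neighbors(inst$net, q = 10))
  vals <- r[!is.na(r)]
  expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
})

test_that("HIP/HOP combination averages per-compound z-scores", {
  m <- function(v, genes) matrix(v, length(genes), 1,
                                 dimnames = list(genes, "c1"))
  hip <- score_matrix(m(c(-2, 0, 2), c("A", "B", "C")), "git_hip", "low")
  hop <- score_matrix(m(c(4, 0, -4), c("A", "B", "C")), "git_hop", "low")
  comb <- combine_hip_hop(hip, hop)
  # z-scores (-1,0,1) and (1,0,-1) cancel
  expect_equal(unname(comb[, "c1"]), c(0, 0, 0))
  # identical inputs: combination equals the shared z-score
  comb2 <- combine_hip_hop(hip, hip)
  expect_equal(unname(comb2[, "c1"]), c(-1, 0, 1))   # sample-sd z of (-2,0,2)
  # gene policies
  hop3 <- score_matrix(m(c(1, 2, -3), c("B", "C", "D")), "git_hop", "low")
  inter <- combine_hip_hop(hip, hop3, gene_policy = "intersection")
  expect_setequal(rownames(inter), c("B", "C"))
  uni <- combine_hip_hop(hip, hop3, gene_policy = "union")
  expect_setequal(rownames(uni), c("A", "B", "C", "D"))
  zh <- (-2 - 0) / sd(c(-2, 0, 2))
  expect_equal(unname(uni["A", "c1"]), zh)           # HIP-only gene: HIP z
  expect_error(combine_hip_hop(hip, rho_score(toy_fd(), toy_nbh())),
               "low-is-hit")
  # compound present in one input only is scored from it, with warning
  hop4 <- score_matrix(matrix(c(1, 2, 3), 3, 1,
                              dimnames = list(c("A", "B", "C"), "c9")),
                       "git_hop", "low")
  expect_warning(combine_hip_hop(hip, hop4), "c9")
})

test_that("contribution report reconstructs the score exactly", {
  rep <- explain_score(toy_fd(), toy_nbh(), "A", "c1", method = "hip")
  expect_identical(rep$neighbor, c("B", "C"))         # sorted by |term|
  expect_equal(rep$term, c(1.0, 0.5))
  expect_equal(attr(rep, "own_fd") - sum(rep$term), attr(rep, "score"))
  expect_equal(attr(rep, "score"),
               unname(git_hip(toy_fd(), toy_nbh())["A", "c1"]))
  # hop report uses first-order neighbor scores
  rep2 <- explain_score(toy_fd(), toy_nbh(), "A", "c1", method = "hop")
  expect_equal(rep2$neighbor_score[rep2$neighbor == "B"], -2.5)
  expect_equal(attr(rep2, "score"),
               unname(git_hop(toy_fd(), toy_nbh())["A", "c1"]))
  # no neighbors: empty terms, score = FD
  fd2 <- rbind(toy_fd(), D = 4)
  rep3 <- explain_score(fd2, toy_nbh(), "D", "c1")
  expect_equal(nrow(rep3), 0L)
  expect_equal(attr(rep3, "score"), 4)
  expect_error(explain_score(toy_fd(), toy_nbh(), "Z", "c1"), "unknown gene")
  # reconstruction identity on a random instance
  set.seed(5)
  inst <- random_instance(30, 2)
  nbh <- truncate_neighbors(inst$net, q = 4)
  sc <- git_hop(inst$fd, nbh)
  for (g in sample(rownames(inst$fd), 5)) {
    r <- explain_score(inst$fd, nbh, g, "c01", method = "hop")
    expect_equal(attr(r, "score"), unname(sc[g, "c01"]), tolerance = 1e-9)
  }
})

test_that("an unsigned equal-weight network deprioritizes or favors hubs
           linearly in degree", {
  # star-like unsigned net: gene hub_k has degree k; with exchangeable FD
  # fixed at mu the score is mu * (1 - w * degree), linear in degree, so
  # with mu > 0 the highest-degree gene always comes out best (hub bias)
  w <- 0.1
  mu <- 2
  edges <- do.call(rbind, lapply(1:4, function(k)
    data.frame(from = sprintf("hub%d", k),
               to = sprintf("leaf%d_%d", k, seq_len(k)),
               weight = w)))
  net <- gi_network(edges, signed = FALSE)
  genes <- net$genes
  fd <- matrix(mu, length(genes), 1, dimnames = list(genes, "c1"))
  sc <- git_hip(fd, truncate_neighbors(net))
  hubs <- sprintf("hub%d", 1:4)
  expect_equal(unname(sc[hubs, 1]), mu * (1 - w * (1:4)))
  expect_equal(diff(sc[hubs, 1]), rep(-mu * w, 3), ignore_attr = TRUE)
  rk <- rank_genes(sc)
  expect_equal(unname(rk["hub4", 1]), 1L)             # biggest hub ranks first
})
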