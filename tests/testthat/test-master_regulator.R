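# Upstream reachability, key-node scoring, empirical null, rank fusion.

chain_net <- function() {
  suppressMessages(signaling_network(
    data.frame(source = c("A", "B"), target = c("B", "TF1"),
               interaction = "activation"),
    data.frame(node = c("A", "B", "TF1"), gene_symbols = c("A", "B", "TF1"),
               is_tf = c(FALSE, FALSE, TRUE))))
}

test_that("upstream reachability respects the radius on a chain", {
  net <- chain_net()
  r12 <- upstream_reach(net, "TF1", max_radius = 12)
  expect_equal(unname(r12$reached$A), 2)
  expect_equal(unname(r12$reached$B), 1)
  r1 <- upstream_reach(net, "TF1", max_radius = 1)
  expect_false("A" %in% names(r1$reached))
  expect_equal(unname(r1$reached$B), 1)
  # radius monotonicity: reached sets grow with r
  expect_true(all(names(r1$reached) %in% names(r12$reached)))
  expect_message(r <- upstream_reach(net, c("TF1", "GHOST")), "GHOST")
  expect_error(upstream_reach(net, "GHOST"), "no input TF")
})

test_that("reachability and keynode scores match the BFS oracle on random graphs", {
  withr::local_seed(51)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    adj <- matrix(rbinom(n * n, 1, 0.25), n, n,
                  dimnames = list(nodes, nodes))
    diag(adj) <- 0
    edges <- which(adj == 1, arr.ind = TRUE)
    if (!nrow(edges)) next
    tfs <- sample(nodes, 2)
    net <- suppressMessages(signaling_network(
      data.frame(source = nodes[edges[, 1]], target = nodes[edges[, 2]],
                 interaction = "x"),
      data.frame(node = nodes, gene_symbols = nodes, is_tf = nodes %in% tfs)))
    radius <- sample(c(2, 4, 12), 1)
    reach <- upstream_reach(net, tfs, max_radius = radius)
    D <- oracle_distances(adj)
    for (nd in nodes) {
      want <- D[match(nd, nodes), match(tfs, nodes)]
      names(want) <- tfs
      want <- want[want <= radius]
      got <- reach$reached[[nd]]
      if (!length(want)) {
        expect_null(got)
      } else {
        expect_equal(got[order(names(got))],
                     want[order(names(want))])
        expect_equal(keynode_score(got), sum(1 / (1 + want)))
      }
    }
  }
})

test_that("keynode score rewards coverage at short distance", {
  expect_equal(keynode_score(c(t1 = 1, t2 = 1, t3 = 1)), 3 / 2)
  expect_equal(keynode_score(c(t1 = 12)), 1 / 13)
  # strictly increases when another TF becomes reachable
  expect_gt(keynode_score(c(t1 = 3, t2 = 12)), keynode_score(c(t1 = 3)))
  expect_error(keynode_score(numeric()), "unscored")
})

test_that("empirical null: bounds, determinism, and TF-universe errors", {
  spec <- synthetic_spec(seed = 53, n_network_nodes = 60, n_tf_nodes = 10)
  net <- suppressMessages(gen_network(spec))
  nul1 <- empirical_null(net, 3, n_runs = 200, seed = 4)
  nul2 <- empirical_null(net, 3, n_runs = 200, seed = 4)
  expect_identical(nul1$null_scores, nul2$null_scores)
  expect_error(empirical_null(net, 50, n_runs = 10, seed = 1), "fewer TF")

  kn <- keynode_search(net, spec$planted_tfs, n_runs = 500, seed = 6)
  expect_true(all(kn$empirical_p >= 1 / 501 & kn$empirical_p <= 1))
  expect_true(all(kn$fdr >= 0 & kn$fdr <= 1))
  expect_true(all(kn$n_reached >= 1))
  expect_false(any(kn$node %in% spec$planted_tfs))  # inputs excluded
  # planted direct regulator is the top key node here
  expect_equal(kn$node[1], "PRMT1")
  expect_equal(kn$keynode_score[1], 3 / 2)
})

test_that("keynode results are invariant to node relabeling", {
  edges <- data.frame(source = c("X", "X", "Y", "Z"),
                      target = c("T1", "T2", "T1", "X"),
                      interaction = "x")
  nodes <- data.frame(node = c("X", "Y", "Z", "T1", "T2"),
                      gene_symbols = "", is_tf = c(FALSE, FALSE, FALSE,
                                                   TRUE, TRUE))
  net <- suppressMessages(signaling_network(edges, nodes))
  relab <- c(X = "q1", Y = "q2", Z = "q3", T1 = "u1", T2 = "u2")
  net2 <- suppressMessages(signaling_network(
    data.frame(source = unname(relab[edges$source]),
               target = unname(relab[edges$target]), interaction = "x"),
    data.frame(node = unname(relab[nodes$node]), gene_symbols = "",
               is_tf = nodes$is_tf)))
  r1 <- upstream_reach(net, c("T1", "T2"))
  r2 <- upstream_reach(net2, c("u1", "u2"))
  for (nd in names(r1$reached))
    expect_equal(keynode_score(r1$reached[[nd]]),
                 keynode_score(r2$reached[[unname(relab[nd])]]))
})

test_that("total rank fuses components with midpoint substitution", {
  spec <- synthetic_spec(seed = 55, n_network_nodes = 60, n_tf_nodes = 10)
  net <- suppressMessages(gen_network(spec))
  kn <- keynode_search(net, spec$planted_tfs, n_runs = 300, seed = 2)

  # single candidate: every component rank is 1 -> total 4
  one <- kn[1, , drop = FALSE]; class(one) <- class(kn)
  ranked1 <- total_rank(one, net, NULL, NULL, NULL)
  expect_equal(ranked1$total_rank, 4)

  # two candidates ranked 1st,2nd,1st,2nd -> totals 4 and 8; with all
  # omics/cma components missing both get the midpoint 1.5 three times
  two <- kn[1:2, , drop = FALSE]; class(two) <- class(kn)
  ranked2 <- total_rank(two, net, NULL, NULL, NULL)
  expect_equal(sort(ranked2$keynode_rank), c(1, 2))
  expect_equal(ranked2$cma_rank, c(1.5, 1.5))
  expect_equal(ranked2$total_rank, ranked2$keynode_rank + 4.5)

  # supplying omics tables ranks |logFC| with blanks midpoint-substituted
  tx <- diff_table(c(two$node[1], "OTHER"), c(1.57, 0.2), c(0.01, 0.5))
  ranked3 <- total_rank(two, net, NULL, tx_table = tx)
  expect_equal(ranked3$log_fc_tx[ranked3$node == two$node[1]], 1.57)
  expect_true(is.na(ranked3$log_fc_tx[ranked3$node == two$node[2]]))
  expect_equal(ranked3$tx_lfc_rank[ranked3$node == two$node[1]], 1)
  expect_equal(ranked3$tx_lfc_rank[ranked3$node == two$node[2]], 1.5)
})
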