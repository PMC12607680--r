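# Master-regulator search: bounded-radius upstream reachability from the
# discovered transcription factors, a key-node score rewarding short-range
# coverage of many input TFs, an empirical resampling null over random TF
# sets, and rank fusion with composite-module and omics evidence.

#' Upstream reachability within a bounded radius
#'
#' For every network node, the subset of input TFs reachable by directed
#' paths node -> ... -> TF of length at most `max_radius`, with
#' shortest-path distances (standard shortest-path semantics; cycles are
#' allowed). Input TFs missing from the network are logged and skipped; it
#' is an error if none remain.
#'
#' @param network A [signaling_network()].
#' @param tf_nodes Character vector of TF node names (the input set).
#' @param max_radius Maximum upstream path length (default 12).
#' @return List with `dist` (matrix, TFs x nodes, `Inf` beyond the radius),
#'   `tf_nodes` (those found), and `reached` (named list node -> named
#'   distance vector over reached TFs, scored nodes only).
#' @export
upstream_reach <- function(network, tf_nodes, max_radius = 12L) {
  stopifnot(inherits(network, "SignalingNetwork"))
  assert_that(nrow(network$edges) > 0, "empty network")
  assert_that(max_radius >= 1, "max_radius must be >= 1")
  present <- tf_nodes %in% network$nodes$node
  if (any(!present))
    log_msg("upstream_reach: skipping %d TF(s) absent from network: %s",
            sum(!present), paste(tf_nodes[!present], collapse = ", "))
  tf_nodes <- tf_nodes[present]
  assert_that(length(tf_nodes) > 0, "no input TF present in the network")
  # mode = "in": shortest path lengths along reversed edges, i.e. the
  # length of the directed path node -> ... -> TF.
  d <- igraph::distances(network$graph, v = tf_nodes, mode = "in")
  d[d > max_radius] <- Inf
  nodes <- colnames(d)
  reached <- lapply(nodes, function(n) {
    v <- d[, n]
    v[is.finite(v)]
  })
  names(reached) <- nodes
  reached <- reached[lengths(reached) > 0]
  list(dist = d, tf_nodes = tf_nodes, reached = reached,
       max_radius = as.integer(max_radius))
}

#' Key-node score of one candidate node
#'
#' `sum over reached TFs of 1 / (1 + distance)`: rewards covering many
#' input TFs at short upstream distance. A node directly upstream of all k
#' TFs scores k/2; one reaching a single TF at distance 12 scores 1/13.
#'
#' @param distances Named numeric vector of shortest upstream distances to
#'   the reached input TFs (finite values only).
#' @return Non-negative numeric score.
#' @export
keynode_score <- function(distances) {
  assert_that(length(distances) > 0, "no reached TFs: node is unscored")
  assert_that(all(is.finite(distances) & distances >= 0),
              "distances must be finite and >= 0")
  sum(1 / (1 + distances))
}

# Key-node scores of all nodes for an arbitrary TF subset, from a
# precomputed contribution matrix C (all TF nodes x nodes) where
# C[t, n] = 1/(1 + d(n -> t)) within the radius and 0 beyond.
#' @noRd
scores_from_contrib <- function(contrib, tf_set) {
  if (length(tf_set) == 1L) contrib[tf_set, ] else
    colSums(contrib[tf_set, , drop = FALSE])
}

#' Empirical key-node null over random TF sets
#'
#' Draws `n_runs` random TF sets of the given size (without replacement,
#' from the network's TF-annotated nodes) and computes every node's
#' key-node score under each draw within `max_radius`.
#'
#' @param network A [signaling_network()].
#' @param set_size Size of each random TF set (match the observed input).
#' @param n_runs Number of resampling runs (default 10000; scale down for
#'   fast runs).
#' @param seed RNG seed.
#' @param max_radius Upstream radius (default 12).
#' @return List with `null_scores` (nodes x n_runs matrix), `null_mean`,
#'   `null_sd` (per node), `tf_universe`.
#' @export
empirical_null <- function(network, set_size, n_runs = 10000L, seed = 1L,
                           max_radius = 12L) {
  stopifnot(inherits(network, "SignalingNetwork"))
  tf_universe <- network$nodes$node[network$nodes$is_tf]
  assert_that(length(tf_universe) >= set_size,
              "fewer TF nodes (%d) than set size (%d)",
              length(tf_universe), set_size)
  d <- igraph::distances(network$graph, v = tf_universe, mode = "in")
  contrib <- 1 / (1 + d)
  contrib[d > max_radius] <- 0
  nodes <- colnames(d)
  null_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_runs), function(i) {
      s <- sample(tf_universe, set_size)
      scores_from_contrib(contrib, s)
    }, numeric(length(nodes)))
  })
  rownames(null_scores) <- nodes
  list(null_scores = null_scores,
       null_mean = rowMeans(null_scores),
       null_sd = apply(null_scores, 1, stats::sd),
       tf_universe = tf_universe, max_radius = as.integer(max_radius))
}

#' Search a network for master-regulator key nodes
#'
#' Scores every node that reaches at least one input TF within the radius
#' (input TFs themselves are excluded as candidates), then compares each
#' observed score with an empirical null from random same-size TF sets.
#' The smoothed empirical p is `(1 + #null >= observed) / (1 + n_runs)`;
#' because that p is floor-limited at `1/(n_runs+1)`, the FDR is computed
#' by Benjamini-Hochberg on the normal-tail p of the per-node Z-score
#' (observed minus null mean over null sd), which is how resampling-based
#' rank FDRs are conventionally obtained. Nodes with a degenerate null
#' (sd = 0) fall back to the empirical p and are flagged.
#'
#' @param network A [signaling_network()].
#' @param input_tfs Character vector of input TF node names.
#' @param max_radius Upstream radius (default 12).
#' @param n_runs Resampling runs (default 10000).
#' @param seed RNG seed.
#' @param fdr_threshold Significance threshold on the FDR (default 0.05).
#' @return Data frame of class `KeyNodeTable`, one row per scored
#'   candidate: `node`, `keynode_score`, `n_reached`, `reached_tfs`
#'   (comma-joined), `mean_distance`, `z_score`, `empirical_p`, `p_value`,
#'   `fdr`, `significant`, `degenerate_null`; sorted by descending score.
#'   Zero rows (with a log message) when no candidate reaches any input TF.
#' @export
keynode_search <- function(network, input_tfs, max_radius = 12L,
                           n_runs = 10000L, seed = 1L,
                           fdr_threshold = 0.05) {
  reach <- upstream_reach(network, input_tfs, max_radius)
  cand <- setdiff(names(reach$reached), reach$tf_nodes)
  if (!length(cand)) {
    log_msg("keynode_search: no candidate reaches any input TF")
    out <- data.frame(node = character(), keynode_score = numeric(),
                      n_reached = integer(), reached_tfs = character(),
                      mean_distance = numeric(), z_score = numeric(),
                      empirical_p = numeric(), p_value = numeric(),
                      fdr = numeric(), significant = logical(),
                      degenerate_null = logical())
    attr(out, "input_tfs") <- reach$tf_nodes
    attr(out, "seed") <- seed
    class(out) <- c("KeyNodeTable", "data.frame")
    return(out)
  }
  nul <- empirical_null(network, length(reach$tf_nodes), n_runs = n_runs,
                        seed = seed, max_radius = max_radius)
  obs <- vapply(cand, function(n) keynode_score(reach$reached[[n]]),
                numeric(1))
  emp_p <- z <- pz <- numeric(length(cand))
  degen <- logical(length(cand))
  for (i in seq_along(cand)) {
    ns <- nul$null_scores[cand[i], ]
    emp_p[i] <- (1 + sum(ns >= obs[i] - 1e-12)) / (1 + n_runs)
    sdv <- nul$null_sd[cand[i]]
    if (sdv > 0) {
      z[i] <- (obs[i] - nul$null_mean[cand[i]]) / sdv
      pz[i] <- stats::pnorm(z[i], lower.tail = FALSE)
    } else {
      z[i] <- NA_real_
      pz[i] <- emp_p[i]
      degen[i] <- TRUE
    }
  }
  fdr <- stats::p.adjust(pz, method = "BH")
  out <- data.frame(
    node = cand, keynode_score = obs,
    n_reached = lengths(reach$reached[cand]),
    reached_tfs = vapply(reach$reached[cand],
                         function(v) paste(names(v), collapse = ","), ""),
    mean_distance = vapply(reach$reached[cand], mean, numeric(1)),
    z_score = z, empirical_p = emp_p, p_value = pz, fdr = fdr,
    significant = fdr < fdr_threshold, degenerate_null = degen,
    stringsAsFactors = FALSE)
  out <- out[order(-out$keynode_score, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "input_tfs") <- reach$tf_nodes
  attr(out, "seed") <- seed
  class(out) <- c("KeyNodeTable", "data.frame")
  out
}

#' Fuse key-node, module and omics evidence into a total rank
#'
#' Each candidate is ranked four ways: by key-node score (descending), by
#' the best regulatory score among the input TFs it reaches (descending),
#' and by absolute transcriptome / proteome log fold-change of its mapped
#' gene symbols (descending; a node mapping to several symbols uses the
#' symbol with the largest absolute log fold-change). A component missing
#' for a candidate (e.g. protein not detected) receives the midpoint rank
#' `(N + 1) / 2`. The total rank is the sum of the four; the report is
#' ordered by ascending total rank, ties broken by key-node rank then node
#' name.
#'
#' @param candidates A `KeyNodeTable` (typically filtered to
#'   `significant` rows).
#' @param network The [signaling_network()] (for node -> gene symbol
#'   mapping).
#' @param cma_result A `CMAResult`, or a named numeric vector of per-TF
#'   regulatory scores (as serialized by the pipeline); may be `NULL`.
#' @param tx_table,prot_table [diff_table()]s; either may be `NULL`.
#' @return Data frame of class `MasterRegulatorTable`: `node`,
#'   `gene_symbols`, `keynode_score`, `keynode_rank`, `cma_rank`,
#'   `tx_lfc_rank`, `prot_lfc_rank`, `total_rank`, `log_fc_tx`,
#'   `log_fc_prot` (NA preserved as blanks in reports).
#' @export
total_rank <- function(candidates, network, cma_result = NULL,
                       tx_table = NULL, prot_table = NULL) {
  stopifnot(inherits(candidates, "KeyNodeTable"))
  n <- nrow(candidates)
  assert_that(n > 0, "no candidates to rank")
  mid <- (n + 1) / 2
  # component 1: key-node score, descending
  keynode_rank <- rank(-candidates$keynode_score, ties.method = "min")
  # component 2: best regulatory score among reached TFs, descending
  cma_score <- rep(NA_real_, n)
  if (!is.null(cma_result)) {
    reg <- if (inherits(cma_result, "CMAResult"))
      cma_result$tf_regulatory_scores else cma_result
    stopifnot(is.numeric(reg), !is.null(names(reg)))
    reached <- strsplit(candidates$reached_tfs, ",", fixed = TRUE)
    cma_score <- vapply(reached, function(tfs) {
      tfs <- intersect(tfs, names(reg))
      if (!length(tfs)) NA_real_ else max(reg[tfs])
    }, numeric(1))
  }
  # components 3-4: |logFC| of the best mapped symbol, per layer
  lfc_of <- function(tab, node) {
    if (is.null(tab)) return(NA_real_)
    syms <- node_symbols(network, node)
    i <- match(syms, tab$feature_id)
    v <- tab$log_fc[i[!is.na(i)]]
    if (!length(v)) NA_real_ else v[which.max(abs(v))]
  }
  lfc_tx <- vapply(candidates$node, lfc_of, numeric(1), tab = tx_table)
  lfc_pr <- vapply(candidates$node, lfc_of, numeric(1), tab = prot_table)
  rank_desc_mid <- function(x) {
    r <- rep(mid, n)
    ok <- !is.na(x)
    if (any(ok)) r[ok] <- rank(-x[ok], ties.method = "min")
    r
  }
  cma_rank <- rank_desc_mid(cma_score)
  tx_rank <- rank_desc_mid(abs(lfc_tx))
  prot_rank <- rank_desc_mid(abs(lfc_pr))
  total <- keynode_rank + cma_rank + tx_rank + prot_rank
  out <- data.frame(
    node = candidates$node,
    gene_symbols = vapply(candidates$node, function(nd)
      paste(node_symbols(network, nd), collapse = ","), ""),
    keynode_score = candidates$keynode_score,
    keynode_rank = keynode_rank, cma_rank = cma_rank,
    tx_lfc_rank = tx_rank, prot_lfc_rank = prot_rank,
    total_rank = total, log_fc_tx = lfc_tx, log_fc_prot = lfc_pr,
    stringsAsFactors = FALSE)
  out <- out[order(out$total_rank, out$keynode_rank, out$node), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MasterRegulatorTable", "data.frame")
  out
}
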