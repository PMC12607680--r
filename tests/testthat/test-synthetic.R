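# Generators: determinism, planted structure, and stated edge cases.

test_that("gen_diff_tables plants signal, discordance, and is pure", {
  spec <- synthetic_spec(seed = 7, n_genes = 400)
  a <- gen_diff_tables(spec)
  b <- gen_diff_tables(spec)
  expect_identical(a, b)                          # bit-identical on re-call

  # discordance 0: signs agree for every signal gene measured in both
  s0 <- synthetic_spec(seed = 3, n_genes = 400, discordance_frac = 0)
  d0 <- gen_diff_tables(s0)
  sig <- d0$truth$gene[d0$truth$status != "null" & d0$truth$in_proteome]
  tx <- d0$transcriptome; pr <- d0$proteome
  expect_true(all(sign(tx$log_fc[match(sig, tx$feature_id)]) ==
                    sign(pr$log_fc[match(sig, pr$feature_id)])))

  # stated discordant fraction is hit exactly (round(frac * n_signal))
  d <- gen_diff_tables(synthetic_spec(seed = 5, n_genes = 500,
                                      discordance_frac = 0.2))
  n_sig_prot <- sum(d$truth$status != "null" & d$truth$in_proteome)
  expect_equal(sum(d$truth$discordant), round(0.2 * n_sig_prot))
  flip <- d$truth$gene[d$truth$discordant]
  expect_true(all(sign(d$transcriptome$log_fc[
    match(flip, d$transcriptome$feature_id)]) !=
      sign(d$proteome$log_fc[match(flip, d$proteome$feature_id)])))

  # no signal at all
  dn <- gen_diff_tables(synthetic_spec(seed = 2, n_genes = 100,
                                       frac_up = 0, frac_down = 0))
  expect_true(all(dn$truth$status == "null"))
  expect_lt(max(abs(dn$transcriptome$log_fc)), 1)  # null sigma scale

  expect_error(synthetic_spec(frac_up = 0.7, frac_down = 0.5), "<= 1")
})

test_that("gen_promoters implants max-scoring co-occurring sites", {
  spec <- synthetic_spec(seed = 11, n_yes = 8, n_no = 8, site_prob = 1)
  lib <- gen_pwm_library(spec)
  ps <- gen_promoters(spec, lib)
  expect_identical(ps$sequence, gen_promoters(spec, lib)$sequence)

  truth <- attr(ps, "truth")
  lib_ids <- vapply(lib, function(m) m$matrix_id, "")
  # every yes promoter carries every planted TF's site at norm score 1.0
  for (g in ps$gene_id[ps$label == "yes"]) {
    rows <- truth[truth$gene_id == g, ]
    expect_setequal(rows$tf, spec$planted_tfs)
    # implanted positions all pairwise within module_window
    expect_lte(max(rows$start) + spec$motif_length - min(rows$start),
               spec$module_window)
    for (i in seq_len(nrow(rows))) {
      m <- lib[[match(paste0("M_", rows$tf[i]), lib_ids)]]
      win <- substr(ps$sequence[ps$gene_id == g], rows$start[i] + 1,
                    rows$start[i] + spec$motif_length)
      sc <- if (rows$strand[i] == "+") normalized_pwm_score(m, win) else
        normalized_pwm_score(m, oracle_revcomp(win))
      expect_equal(sc, 1.0)
    }
  }

  # site_prob 0: nothing implanted
  sp0 <- synthetic_spec(seed = 11, n_yes = 8, n_no = 8, site_prob = 0)
  expect_equal(nrow(attr(gen_promoters(sp0, lib), "truth")), 0L)

  # a planted TF without a matrix is an error
  expect_error(gen_promoters(spec, lib[1:2]), "lacking a matrix")
})

test_that("gen_network guarantees bounded planted paths", {
  spec <- synthetic_spec(seed = 13, n_network_nodes = 60, n_tf_nodes = 10)
  net <- suppressMessages(gen_network(spec))
  expect_identical(net$edges, suppressMessages(gen_network(spec))$edges)

  # max_path_len 1 (default): direct edges regulator -> each planted TF
  for (tf in spec$planted_tfs)
    expect_true(any(net$edges$source == "PRMT1" & net$edges$target == tf))

  # longer chains: BFS-oracle distance from regulator to TF <= max_path_len
  sp3 <- synthetic_spec(seed = 13, n_network_nodes = 60, n_tf_nodes = 10,
                        max_path_len = 4)
  net3 <- suppressMessages(gen_network(sp3))
  nodes <- net3$nodes$node
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(match(net3$edges$source, nodes),
            match(net3$edges$target, nodes))] <- 1
  D <- oracle_distances(adj)
  for (tf in sp3$planted_tfs)
    expect_lte(D[match("PRMT1", nodes), match(tf, nodes)], 4)

  # null network has no planted node
  spn <- synthetic_spec(seed = 13, n_network_nodes = 60, n_tf_nodes = 10,
                        planted_regulator = NA)
  netn <- suppressMessages(gen_network(spn))
  expect_false("PRMT1" %in% netn$nodes$node)
  expect_true(is.na(attr(netn, "truth")$planted))

  expect_error(synthetic_spec(max_path_len = 0), "max_path_len")
})

test_that("gen_drug_tables honors requested compound counts", {
  spec <- synthetic_spec(seed = 17)
  toys <- gen_drug_tables(spec, drugs_per_target = c(PRMT1 = 14, STAT3 = 3,
                                                     LEF1 = 0))
  expect_equal(curated_druggability("PRMT1", toys$drug_targets), 14L)
  expect_equal(curated_druggability("STAT3", toys$drug_targets), 3L)
  expect_false("LEF1" %in% toys$drug_targets$target_gene)
  expect_true(all(toys$compound_activities$rows$pa >= 0 &
                    toys$compound_activities$rows$pa <= 1))
  expect_equal(toys$truth[1], "PRMT1")
  expect_identical(toys, gen_drug_tables(spec, drugs_per_target =
                                           c(PRMT1 = 14, STAT3 = 3, LEF1 = 0)))
})

test_that("gen_bundle writes a coherent, re-readable bundle", {
  td <- withr::local_tempdir()
  spec <- synthetic_spec(seed = 19, n_genes = 120, n_yes = 6, n_no = 6,
                         n_network_nodes = 40, n_tf_nodes = 8)
  paths <- suppressMessages(gen_bundle(spec, td))
  expect_true(all(file.exists(unlist(paths))))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$planted_regulator, "PRMT1")
  tx <- suppressMessages(read_diff_table(paths$transcriptome))
  expect_equal(nrow(tx), 120L)
  lib <- suppressMessages(read_pwm_library(paths$pwm_library))
  expect_length(lib, length(spec$planted_tfs) + spec$n_decoy_matrices)
  cfgf <- jsonlite::read_json(paths$config, simplifyVector = TRUE)
  expect_true(file.exists(cfgf$inputs$network_edges))
})
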