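# Seeded generators producing inputs with the statistical structure the
# analysis assumes: two-layer differential tables with planted signal and
# controlled discordance, promoter sets with co-occurring implanted motifs,
# signaling networks with a planted upstream regulator, and toy drug /
# compound tables. All generators are pure functions of (spec, arguments):
# equal inputs give bit-identical outputs.

#' Specification of the synthetic world
#'
#' Defaults state the conditions the pipeline is designed for: a
#' two-group rodent-style experiment with ~10% of features perturbed per
#' direction, modest discordance between transcript and protein responses,
#' 50+50 promoters of 1100 bp with three planted TF motifs co-occurring in
#' a 250 bp module window, and a 200-node signaling network whose planted
#' regulator is a direct upstream effector of every planted TF (longer
#' planted cascades are configurable via `max_path_len`).
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_genes Number of features in the transcriptome table.
#' @param frac_up,frac_down Fractions of truly up-/down-regulated features.
#' @param effect_mu,effect_sigma Signal |log2 FC| distribution parameters.
#' @param null_sigma Null log2 FC standard deviation.
#' @param discordance_frac Fraction of proteome-measured signal genes whose
#'   proteome log FC sign is flipped.
#' @param proteome_coverage Fraction of genes measured in the proteome.
#' @param n_yes,n_no Promoter counts for the Yes and No sets.
#' @param planted_tfs TF symbols whose motifs are implanted.
#' @param site_prob Per-Yes-promoter probability of receiving the module.
#' @param module_window Planted co-occurrence window length (1-300 bp).
#' @param gc_content Background GC fraction.
#' @param motif_length Length of each generated motif.
#' @param n_decoy_matrices Non-planted matrices added to the library.
#' @param n_network_nodes,n_tf_nodes Network size and TF-annotated count.
#' @param mean_out_degree Mean random out-degree of network nodes.
#' @param planted_regulator Name of the planted master-regulator node
#'   (`NA` generates a null network with no planted structure).
#' @param max_path_len Length of the guaranteed regulator-to-TF paths
#'   (1-12).
#' @return List of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 1000L, frac_up = 0.1,
                           frac_down = 0.1, effect_mu = 1.2,
                           effect_sigma = 0.3, null_sigma = 0.15,
                           discordance_frac = 0.05,
                           proteome_coverage = 0.8,
                           n_yes = 50L, n_no = 50L,
                           planted_tfs = c("STAT3", "HNF4A", "LEF1"),
                           site_prob = 0.9, module_window = 250L,
                           gc_content = 0.45, motif_length = 6L,
                           n_decoy_matrices = 5L,
                           n_network_nodes = 200L, n_tf_nodes = 40L,
                           mean_out_degree = 2,
                           planted_regulator = "PRMT1",
                           max_path_len = 1L) {
  for (f in c(frac_up, frac_down, discordance_frac, site_prob, gc_content,
              proteome_coverage))
    assert_that(f >= 0 && f <= 1, "fractions must be in [0,1]")
  assert_that(frac_up + frac_down <= 1, "frac_up + frac_down must be <= 1")
  assert_that(module_window >= 1 && module_window <= 300,
              "module_window must be in [1, 300]")
  assert_that(max_path_len >= 1 && max_path_len <= 12,
              "max_path_len must be in [1, 12]")
  assert_that(n_network_nodes >= n_tf_nodes + 2,
              "n_network_nodes must exceed n_tf_nodes + 1")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 frac_up = frac_up, frac_down = frac_down,
                 effect_mu = effect_mu, effect_sigma = effect_sigma,
                 null_sigma = null_sigma,
                 discordance_frac = discordance_frac,
                 proteome_coverage = proteome_coverage,
                 n_yes = as.integer(n_yes), n_no = as.integer(n_no),
                 planted_tfs = planted_tfs, site_prob = site_prob,
                 module_window = as.integer(module_window),
                 gc_content = gc_content,
                 motif_length = as.integer(motif_length),
                 n_decoy_matrices = as.integer(n_decoy_matrices),
                 n_network_nodes = as.integer(n_network_nodes),
                 n_tf_nodes = as.integer(n_tf_nodes),
                 mean_out_degree = mean_out_degree,
                 planted_regulator = planted_regulator,
                 max_path_len = as.integer(max_path_len)),
            class = "SyntheticSpec")
}

#' Generate paired differential tables with planted signal
#'
#' Signal genes draw `|log2 FC| ~ Normal(effect_mu, effect_sigma)` with the
#' planted sign and small p-values (`10^Uniform(-8, -4)`); null genes draw
#' `log2 FC ~ Normal(0, null_sigma)` and `p ~ Uniform(0, 1)`. A
#' `proteome_coverage` subset of genes is measured in the proteome, where
#' a `discordance_frac` fraction of the measured signal genes has its
#' fold-change sign flipped.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `transcriptome`, `proteome` ([diff_table()]s) and
#'   `truth` (data frame `gene`, `status` in up/down/null,
#'   `in_proteome`, `discordant`).
#' @export
gen_diff_tables <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withr::with_seed(child_seed(spec$seed, 1L), {
    n <- spec$n_genes
    genes <- sprintf("G%05d", seq_len(n))
    n_up <- round(spec$frac_up * n); n_down <- round(spec$frac_down * n)
    status <- rep("null", n)
    status[seq_len(n_up)] <- "up"
    if (n_down > 0) status[n_up + seq_len(n_down)] <- "down"
    sign_tx <- ifelse(status == "up", 1, ifelse(status == "down", -1, 0))
    is_sig <- status != "null"
    lfc_tx <- ifelse(is_sig,
                     sign_tx * abs(stats::rnorm(n, spec$effect_mu,
                                                spec$effect_sigma)),
                     stats::rnorm(n, 0, spec$null_sigma))
    p_tx <- ifelse(is_sig, 10^stats::runif(n, -8, -4), stats::runif(n))
    in_prot <- stats::runif(n) < spec$proteome_coverage
    sig_prot <- which(is_sig & in_prot)
    n_flip <- round(spec$discordance_frac * length(sig_prot))
    flip <- if (n_flip > 0) sample(sig_prot, n_flip) else integer()
    sign_pr <- sign_tx
    sign_pr[flip] <- -sign_pr[flip]
    lfc_pr <- ifelse(is_sig,
                     sign_pr * abs(stats::rnorm(n, spec$effect_mu,
                                                spec$effect_sigma)),
                     stats::rnorm(n, 0, spec$null_sigma))
    p_pr <- ifelse(is_sig, 10^stats::runif(n, -8, -4), stats::runif(n))
    truth <- data.frame(gene = genes, status = status,
                        in_proteome = in_prot,
                        discordant = seq_len(n) %in% flip,
                        stringsAsFactors = FALSE)
    list(transcriptome = diff_table(genes, lfc_tx, p_tx, "transcriptome"),
         proteome = diff_table(genes[in_prot], lfc_pr[in_prot],
                               p_pr[in_prot], "proteome"),
         truth = truth)
  })
}

#' Generate a PWM library with one matrix per planted TF plus decoys
#'
#' Each matrix mixes conserved and degenerate positions (dominant-base
#' counts drawn from 45/60/75/90 of 100), the profile real TF motifs show.
#' The consensus window still scores exactly 1 under min-max
#' normalization, while background sequence produces sporadic single-motif
#' matches at the default cutoff -- the regime in which motif
#' co-occurrence carries information beyond any single motif.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [pw_matrix()] objects; planted matrices are named
#'   `M_<TF>` and decoys `M_DECOYi` (TF symbols `DTFi`).
#' @export
gen_pwm_library <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withr::with_seed(child_seed(spec$seed, 2L), {
    make_matrix <- function(id, tf) {
      cons <- sample.int(4, spec$motif_length, replace = TRUE)
      dom <- sample(c(45, 60, 75, 90), spec$motif_length, replace = TRUE)
      counts <- matrix(rep((100 - dom) / 3, 4), spec$motif_length, 4)
      counts[cbind(seq_len(spec$motif_length), cons)] <- dom
      pw_matrix(id, counts, tf_symbols = tf, cutoff = 0.95)
    }
    planted <- lapply(spec$planted_tfs, function(tf)
      make_matrix(paste0("M_", tf), tf))
    decoys <- lapply(seq_len(spec$n_decoy_matrices), function(i)
      make_matrix(sprintf("M_DECOY%d", i), sprintf("DTF%d", i)))
    c(planted, decoys)
  })
}

# Background sequence of given length at the spec's GC content.
#' @noRd
background_seq <- function(len, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  int_to_dna(sample.int(4, len, replace = TRUE, prob = probs))
}

# Consensus (argmax base per position) of a PWMatrix, as character.
#' @noRd
matrix_consensus <- function(m) {
  int_to_dna(apply(m$counts, 1, which.max))
}

#' Generate a promoter set with implanted composite modules
#'
#' No promoters are i.i.d. background at the spec's GC content. Each Yes
#' promoter receives, with probability `site_prob`, one maximum-scoring
#' site (the consensus, or its reverse complement on the minus strand) per
#' planted TF, all inside one uniformly placed window of `module_window`
#' bp; implanted sites never overlap (positions are rejection-sampled).
#'
#' @param spec A [synthetic_spec()].
#' @param pwm_library Library containing a matrix for every planted TF
#'   (matched through the matrices' `tf_symbols`).
#' @param yes_ids,no_ids Optional record IDs (defaults `YESi` / `NOi`);
#'   lengths override `spec$n_yes` / `spec$n_no`.
#' @param width Promoter width (default 1100).
#' @return A [promoter_set()] with a `truth` attribute (data frame
#'   `gene_id`, `tf`, `start`, `strand` of every implanted site).
#' @export
gen_promoters <- function(spec, pwm_library, yes_ids = NULL, no_ids = NULL,
                          width = 1100L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  tf_map <- library_tf_map(pwm_library)
  missing <- setdiff(spec$planted_tfs, tf_map$tf_symbol)
  if (length(missing))
    to_abort("planted TF(s) lacking a matrix: %s",
             paste(missing, collapse = ", "))
  lib_ids <- vapply(pwm_library, `[[`, "", "matrix_id")
  planted_mats <- lapply(spec$planted_tfs, function(tf) {
    mid <- tf_map$matrix_id[tf_map$tf_symbol == tf][1]
    pwm_library[[match(mid, lib_ids)]]
  })
  yes_ids <- yes_ids %||% sprintf("YES%03d", seq_len(spec$n_yes))
  no_ids <- no_ids %||% sprintf("NO%03d", seq_len(spec$n_no))
  withr::with_seed(child_seed(spec$seed, 3L), {
    n_yes <- length(yes_ids); n_no <- length(no_ids)
    seqs <- vapply(seq_len(n_yes + n_no), function(i)
      background_seq(width, spec$gc_content), "")
    truth <- list()
    for (i in seq_len(n_yes)) {
      if (stats::runif(1) >= spec$site_prob) next
      win0 <- sample.int(width - spec$module_window + 1L, 1) - 1L
      placed <- data.frame(start = integer(), end = integer())
      s <- seqs[i]
      for (m in planted_mats) {
        L <- nrow(m$counts)
        assert_that(spec$module_window >= L,
                    "module_window shorter than motif %s", m$matrix_id)
        for (try in 1:200) {
          st <- win0 + sample.int(spec$module_window - L + 1L, 1) - 1L
          if (!any(st < placed$end & st + L > placed$start)) break
          if (try == 200) to_abort("could not place non-overlapping sites")
        }
        placed <- rbind(placed, data.frame(start = st, end = st + L))
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        site <- matrix_consensus(m)
        if (strand == "-") site <- revcomp_chr(site)
        substr(s, st + 1L, st + L) <- site
        truth[[length(truth) + 1L]] <-
          data.frame(gene_id = yes_ids[i], tf = m$tf_symbols[1],
                     start = st, strand = strand, stringsAsFactors = FALSE)
      }
      seqs[i] <- s
    }
    ps <- promoter_set(c(yes_ids, no_ids), seqs,
                       c(rep("yes", n_yes), rep("no", n_no)), width = width)
    attr(ps, "truth") <- if (length(truth)) do.call(rbind, truth) else
      data.frame(gene_id = character(), tf = character(),
                 start = integer(), strand = character())
    ps
  })
}

#' Generate a signaling network with a planted upstream regulator
#'
#' A random directed graph (out-degrees ~ Poisson(`mean_out_degree`),
#' uniform targets, no self-loops; cycles allowed) over TF-annotated and
#' plain signaling nodes, plus guaranteed node-disjoint directed chains of
#' length `max_path_len` from the planted regulator to every planted TF.
#' With `planted_regulator = NA` no structure is planted (a null network).
#'
#' @param spec A [synthetic_spec()].
#' @param tf_symbols TF node names; defaults to `spec$planted_tfs` padded
#'   with generic TFs up to `spec$n_tf_nodes`.
#' @return A [signaling_network()] with a `truth` attribute
#'   (`list(planted, path_nodes)`).
#' @export
gen_network <- function(spec, tf_symbols = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  planted <- spec$planted_regulator
  plant <- !is.na(planted) && nzchar(planted)
  tf_nodes <- tf_symbols %||%
    c(spec$planted_tfs,
      sprintf("TF%02d", seq_len(spec$n_tf_nodes - length(spec$planted_tfs))))
  assert_that(spec$n_network_nodes >= length(tf_nodes) + 2,
              "n_network_nodes must be >= number of TF nodes + 2")
  withr::with_seed(child_seed(spec$seed, 4L), {
    n_other <- spec$n_network_nodes - length(tf_nodes) - as.integer(plant)
    other <- sprintf("N%03d", seq_len(n_other))
    nodes <- c(tf_nodes, if (plant) planted, other)
    # random background edges
    deg <- stats::rpois(length(nodes), spec$mean_out_degree)
    src <- rep(nodes, deg)
    tgt <- sample(nodes, length(src), replace = TRUE)
    edges <- data.frame(source = src, target = tgt,
                        interaction = "interaction",
                        stringsAsFactors = FALSE)
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$source, edges$target)), ,
                   drop = FALSE]
    path_nodes <- character()
    if (plant) {
      pool <- setdiff(other, path_nodes)
      for (tf in spec$planted_tfs) {
        chain <- c(planted,
                   if (spec$max_path_len > 1) {
                     picked <- pool[seq_len(spec$max_path_len - 1L)]
                     pool <- setdiff(pool, picked)
                     path_nodes <- c(path_nodes, picked)
                     picked
                   },
                   tf)
        new_e <- data.frame(source = chain[-length(chain)],
                            target = chain[-1],
                            interaction = "activation",
                            stringsAsFactors = FALSE)
        edges <- rbind(edges, new_e)
      }
      edges <- edges[!duplicated(paste(edges$source, edges$target)), ,
                     drop = FALSE]
    }
    ann <- data.frame(node = nodes, gene_symbols = nodes,
                      is_tf = nodes %in% tf_nodes, stringsAsFactors = FALSE)
    net <- signaling_network(edges, ann)
    attr(net, "truth") <- list(planted = if (plant) planted else NA,
                               path_nodes = path_nodes)
    net
  })
}

#' Generate toy drug-target and compound-activity tables
#'
#' Each requested target gets exactly `drugs_per_target[gene]` distinct
#' compounds in the curated table (a gene given 0 compounds is absent), so
#' its curated druggability equals that count by construction. The
#' compound-activity table gives each compound mechanism rows for its
#' primary target plus one secondary target (so the at-least-2-targets
#' filter is satisfiable), a toxicity row and a disease-effect row, with
#' Pa values drawn in `[0, 1]`.
#'
#' @param spec A [synthetic_spec()].
#' @param drugs_per_target Named integer vector gene -> compound count;
#'   defaults to decreasing counts over the planted regulator and TFs.
#' @param disease Disease ID used in both tables.
#' @return List with `drug_targets` ([drug_target_table()]),
#'   `compound_activities` ([compound_activity_table()]) and `truth`
#'   (genes ordered by intended curated druggability, descending).
#' @export
gen_drug_tables <- function(spec, drugs_per_target = NULL,
                            disease = "nephrotoxicity") {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(drugs_per_target)) {
    genes <- c(if (!is.na(spec$planted_regulator)) spec$planted_regulator,
               spec$planted_tfs)
    drugs_per_target <- stats::setNames(
      pmax(1L, 14L - 4L * (seq_along(genes) - 1L)), genes)
  }
  drugs_per_target <- drugs_per_target[drugs_per_target > 0]
  assert_that(length(drugs_per_target) > 0, "no targets requested")
  withr::with_seed(child_seed(spec$seed, 5L), {
    genes <- names(drugs_per_target)
    rows <- list(); act <- list()
    for (g in genes) {
      for (k in seq_len(drugs_per_target[[g]])) {
        cid <- sprintf("CPD_%s_%02d", g, k)
        phase <- sample(0:4, 1)
        rows[[length(rows) + 1L]] <-
          data.frame(compound_id = cid, target_gene = g,
                     disease_id = disease, max_trial_phase = phase,
                     stringsAsFactors = FALSE)
        secondary <- if (length(genes) > 1) sample(setdiff(genes, g), 1)
          else g
        act[[length(act) + 1L]] <- data.frame(
          compound_id = cid,
          activity_name = c(paste0("inhibition of ", g),
                            paste0("inhibition of ", secondary),
                            "hepatotoxicity", disease),
          activity_class = c("mechanism", "mechanism", "toxicity",
                             "disease_effect"),
          pa = c(stats::runif(2, 0.55, 0.95), stats::runif(1, 0, 0.6),
                 stats::runif(1, 0.55, 0.95)),
          mapped_genes = c(g, secondary, "", ""),
          stringsAsFactors = FALSE)
      }
    }
    gw <- data.frame(gene = genes,
                     iap = stats::runif(length(genes), 0.6, 1),
                     opt_weight = 1, stringsAsFactors = FALSE)
    list(drug_targets = drug_target_table(do.call(rbind, rows)),
         compound_activities =
           compound_activity_table(do.call(rbind, act), gw),
         truth = genes[order(-unlist(drugs_per_target))])
  })
}

#' Write a complete synthetic input bundle plus truth manifest
#'
#' Generates differential tables, PWM library, a promoter FASTA covering
#' planted up genes, planted down genes and background (null) genes, the
#' signaling network, drug tables, a ready-to-run pipeline config
#' (`config.json`) and a `truth.json` manifest, all under `dir`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
gen_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  diffs <- gen_diff_tables(spec)
  lib <- gen_pwm_library(spec)
  up_genes <- diffs$truth$gene[diffs$truth$status == "up"]
  down_genes <- diffs$truth$gene[diffs$truth$status == "down"]
  null_genes <- diffs$truth$gene[diffs$truth$status == "null"]
  yes_up <- utils::head(up_genes, spec$n_yes)
  yes_down <- utils::head(down_genes, spec$n_yes)
  no_genes <- utils::head(null_genes, spec$n_no)
  ps_up <- gen_promoters(spec, lib, yes_ids = yes_up, no_ids = character())
  spec_down <- spec; spec_down$seed <- child_seed(spec$seed, 31L)
  ps_down <- gen_promoters(spec_down, lib, yes_ids = yes_down,
                           no_ids = character())
  spec_no <- spec; spec_no$seed <- child_seed(spec$seed, 32L)
  spec_no$site_prob <- 0
  ps_no <- gen_promoters(spec_no, lib, yes_ids = character(),
                         no_ids = no_genes)
  all_prom <- promoter_set(
    c(ps_up$gene_id, ps_down$gene_id, ps_no$gene_id),
    c(ps_up$sequence, ps_down$sequence, ps_no$sequence),
    c(ps_up$label, ps_down$label, ps_no$label))
  net <- gen_network(spec)
  drugs <- gen_drug_tables(spec)
  paths <- list(
    transcriptome = pth("transcriptome.tsv"),
    proteome = pth("proteome.tsv"),
    pwm_library = pth("pwm_library.txt"),
    promoters = pth("promoters.fasta"),
    network_edges = pth("network_edges.tsv"),
    network_nodes = pth("network_nodes.tsv"),
    drug_targets = pth("drug_targets.tsv"),
    compound_activities = pth("compound_activities.tsv"),
    gene_weights = pth("gene_weights.tsv"))
  write_diff_table(diffs$transcriptome, paths$transcriptome)
  write_diff_table(diffs$proteome, paths$proteome)
  write_pwm_library(lib, paths$pwm_library)
  write_promoters_fasta(all_prom, paths$promoters)
  write_network(net, paths$network_edges, paths$network_nodes)
  write_drug_table(drugs$drug_targets, paths$drug_targets)
  write_compound_table(drugs$compound_activities,
                       paths$compound_activities, paths$gene_weights)
  config <- list(inputs = lapply(paths, normalizePath),
                 seed = spec$seed, out_dir = file.path(dir, "reports"))
  jsonlite::write_json(config, pth("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  truth <- list(
    up_genes = up_genes, down_genes = down_genes,
    discordant_genes = diffs$truth$gene[diffs$truth$discordant],
    planted_tfs = spec$planted_tfs,
    implants_up = attr(ps_up, "truth"),
    implants_down = attr(ps_down, "truth"),
    planted_regulator = attr(net, "truth")$planted,
    druggability_order = drugs$truth)
  jsonlite::write_json(truth, pth("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       dataframe = "columns")
  paths$config <- pth("config.json")
  paths$truth <- pth("truth.json")
  invisible(paths)
}
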