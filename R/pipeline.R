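# End-to-end orchestration: validate a config, run the five analysis
# stages (differential integration, enrichment, composite modules, master
# regulators, druggability) over the up- and down-regulated gene sets, and
# emit six TSV reports plus a run manifest. Stages communicate only through
# written artifacts, so a run can resume from any stage.

PIPELINE_STAGES <- c("diff", "enrich", "cma", "master", "drugs")

#' @noRd
default_config <- function() {
  list(
    inputs = list(transcriptome = NULL, proteome = NULL, pwm_library = NULL,
                  promoters = NULL, network_edges = NULL,
                  network_nodes = NULL, drug_targets = NULL,
                  compound_activities = NULL, gene_weights = NULL),
    significance = list(alpha = 0.05, lfc_min = 0, top_n = 300L),
    enrichment = list(alpha = 0.01, test = "fisher"),
    cma = list(population_size = 30L, n_generations = 15L,
               mutation_prob = 0.2, lambda = 0.1, stride = 10L),
    master = list(radius = 12L, n_runs = 10000L, fdr = 0.05),
    drugs = list(tox_threshold = 0.7, effect_threshold = 0.3,
                 target_threshold = 0.3, w = 1, diseases = list()),
    seed = 1L,
    out_dir = "transomic_out")
}

# Recursively overlay user values on defaults, erroring on unknown keys.
#' @noRd
merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    to_abort("unknown config key(s)%s: %s",
             if (nzchar(path)) paste0(" in ", path) else "",
             paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration file
#'
#' Parses JSON (or YAML when the `yaml` package is installed and the file
#' extension is `.yml`/`.yaml`), checks every key against the schema
#' (unknown keys are an error listing them), fills defaults, and verifies
#' that all referenced input paths exist.
#'
#' @param path Config file path, or a named list already parsed.
#' @return Object of class `PipelineConfig`.
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) {
    path
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      to_abort("YAML config requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), user)
  required <- c("transcriptome", "proteome", "pwm_library", "promoters",
                "network_edges")
  for (k in required)
    if (is.null(cfg$inputs[[k]]))
      to_abort("config: missing required input path '%s'", k)
  for (k in names(cfg$inputs)) {
    p <- cfg$inputs[[k]]
    if (!is.null(p) && !file.exists(p))
      to_abort("config: input '%s' does not exist: %s", k, p)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$hash <- object_hash(cfg[setdiff(names(cfg), "hash")])
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @noRd
config_cma <- function(cfg, seed) {
  do.call(cma_config, c(cfg$cma, list(seed = seed)))
}

#' Run the full pipeline
#'
#' Executes differential integration, top-N selection, motif enrichment,
#' composite-module search, master-regulator search and druggability
#' scoring for the up- and down-regulated gene sets independently (both
#' directions share the non-significant genes' promoters as the No set).
#' Six TSV reports plus a JSON run manifest are written under
#' `config$out_dir`; intermediate artifacts go to
#' `out_dir/intermediate/` and allow resuming via `from_stage`. Outputs of
#' a failing stage are renamed with a `.partial` suffix and the error is
#' re-signalled with the stage name.
#'
#' @param config A `PipelineConfig` from [validate_config()] (or a path /
#'   list accepted by it).
#' @param from_stage Resume from this stage (one of `diff`, `enrich`,
#'   `cma`, `master`, `drugs`), reading earlier stages' artifacts from
#'   disk.
#' @return Invisibly, a list with the report paths and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, from_stage = "diff") {
  if (!inherits(config, "PipelineConfig")) config <- validate_config(config)
  from_stage <- match.arg(from_stage, PIPELINE_STAGES)
  out <- config$out_dir
  intdir <- file.path(out, "intermediate")
  dir.create(intdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  run_from <- match(from_stage, PIPELINE_STAGES)
  stage_files <- character()
  for (si in seq(run_from, length(PIPELINE_STAGES))) {
    stage <- PIPELINE_STAGES[si]
    stage_files <- character()
    tryCatch({
      switch(stage,
             diff = stage_diff(config, state, out, intdir),
             enrich = stage_enrich(config, state, out, intdir),
             cma = stage_cma(config, state, out, intdir),
             master = stage_master(config, state, out, intdir),
             drugs = stage_drugs(config, state, out, intdir))
      stage_files <- state$last_files %||% character()
    }, error = function(e) {
      for (f in state$last_files %||% character())
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      to_abort("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  manifest <- list(package = "transomic",
                   version = as.character(utils::packageVersion("transomic")),
                   seed = config$seed, config_hash = config$hash,
                   reports = state$reports,
                   row_counts = state$row_counts)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline complete: %d reports under %s",
          length(state$reports), out)
  invisible(list(reports = state$reports, state = as.list(state)))
}

#' @noRd
note_report <- function(state, path, n) {
  state$reports <- c(state$reports, path)
  state$row_counts <- c(state$row_counts,
                        stats::setNames(list(n), basename(path)))
  state$last_files <- c(state$last_files, path)
  invisible(NULL)
}

#' @noRd
stage_diff <- function(cfg, state, out, intdir) {
  state$last_files <- character()
  tx <- read_diff_table(cfg$inputs$transcriptome, "transcriptome")
  pr <- read_diff_table(cfg$inputs$proteome, "proteome")
  sg <- cfg$significance
  state$sig_tx <- call_significance(tx, sg$alpha, sg$lfc_min)
  state$sig_prot <- call_significance(pr, sg$alpha, sg$lfc_min)
  state$tx_table <- tx; state$prot_table <- pr
  conc <- classify_concordance(state$sig_tx, state$sig_prot)
  state$top_up <- top_n_by_significance(state$sig_tx, sg$top_n, "up")
  state$top_down <- top_n_by_significance(state$sig_tx, sg$top_n, "down")
  write_report_tsv(state$sig_tx, file.path(intdir, "significance_tx.tsv"))
  write_report_tsv(state$sig_prot, file.path(intdir, "significance_prot.tsv"))
  writeLines(state$top_up, file.path(intdir, "top_up.txt"))
  writeLines(state$top_down, file.path(intdir, "top_down.txt"))
  summary_df <- data.frame(class = names(conc$summary),
                           count = as.integer(conc$summary))
  rep_path <- file.path(out, "diff_summary.tsv")
  write_report_tsv(summary_df, rep_path, seed = cfg$seed,
                   config_hash = cfg$hash)
  write_report_tsv(conc$records, file.path(intdir, "concordance.tsv"))
  note_report(state, rep_path, nrow(summary_df))
  log_msg("stage diff: %d tx rows, %d prot rows, top %d up / %d down",
          nrow(tx), nrow(pr), length(state$top_up), length(state$top_down))
}

# Load diff artifacts from disk when resuming past the diff stage.
#' @noRd
ensure_diff <- function(cfg, state, intdir) {
  if (!is.null(state$sig_tx)) return(invisible(NULL))
  as_calls <- function(path) {
    x <- read_report_tsv(path)
    x$significant <- as.logical(x$significant)
    class(x) <- c("SignificanceCalls", "data.frame")
    x
  }
  state$sig_tx <- as_calls(file.path(intdir, "significance_tx.tsv"))
  state$sig_prot <- as_calls(file.path(intdir, "significance_prot.tsv"))
  state$top_up <- readLines(file.path(intdir, "top_up.txt"))
  state$top_down <- readLines(file.path(intdir, "top_down.txt"))
  state$tx_table <- read_diff_table(cfg$inputs$transcriptome,
                                    "transcriptome")
  state$prot_table <- read_diff_table(cfg$inputs$proteome, "proteome")
  invisible(NULL)
}

# Promoter sets per direction: Yes = top up (or down) genes present in the
# FASTA, No = non-significant genes' promoters (shared by both runs).
#' @noRd
direction_promoters <- function(cfg, state) {
  if (!is.null(state$promoters)) return(invisible(NULL))
  fasta_ids <- sub("\\s.*$", "",
                   names(Biostrings::readDNAStringSet(cfg$inputs$promoters)))
  ns_genes <- state$sig_tx$feature_id[!state$sig_tx$significant]
  no_ids <- intersect(fasta_ids, ns_genes)
  assert_that(length(no_ids) > 0, "no background promoter available")
  sets <- list()
  for (dir in c("up", "down")) {
    yes_ids <- intersect(fasta_ids,
                         if (dir == "up") state$top_up else state$top_down)
    assert_that(length(yes_ids) > 0,
                "no promoter found for top %s genes", dir)
    lm <- c(stats::setNames(rep("yes", length(yes_ids)), yes_ids),
            stats::setNames(rep("no", length(no_ids)), no_ids))
    sets[[dir]] <- read_promoters_fasta(cfg$inputs$promoters, lm)
  }
  state$promoters <- sets
  invisible(NULL)
}

#' @noRd
stage_enrich <- function(cfg, state, out, intdir) {
  state$last_files <- character()
  ensure_diff(cfg, state, intdir)
  direction_promoters(cfg, state)
  state$library <- read_pwm_library(cfg$inputs$pwm_library)
  for (dir in c("up", "down")) {
    enr <- enrich_matrices(state$library, state$promoters[[dir]],
                           alpha = cfg$enrichment$alpha,
                           test = cfg$enrichment$test)
    state[[paste0("enrich_", dir)]] <- enr
    write_report_tsv(enr, file.path(intdir, sprintf("enrichment_%s.tsv", dir)))
    log_msg("stage enrich (%s): %d matrices, %d enriched", dir, nrow(enr),
            sum(enr$enriched))
  }
}

#' @noRd
ensure_enrich <- function(cfg, state, intdir) {
  if (is.null(state$library))
    state$library <- read_pwm_library(cfg$inputs$pwm_library)
  for (dir in c("up", "down")) {
    key <- paste0("enrich_", dir)
    if (is.null(state[[key]])) {
      x <- read_report_tsv(file.path(intdir, sprintf("enrichment_%s.tsv", dir)))
      x$enriched <- as.logical(x$enriched)
      class(x) <- c("EnrichmentResult", "data.frame")
      state[[key]] <- x
    }
  }
  invisible(NULL)
}

#' @noRd
stage_cma <- function(cfg, state, out, intdir) {
  state$last_files <- character()
  ensure_diff(cfg, state, intdir)
  ensure_enrich(cfg, state, intdir)
  direction_promoters(cfg, state)
  for (di in 1:2) {
    dir <- c("up", "down")[di]
    gacfg <- config_cma(cfg, child_seed(cfg$seed, 10L + di))
    res <- fit_cma(state$library, state$promoters[[dir]], gacfg)
    state[[paste0("cma_", dir)]] <- res
    write_module_json(res$module,
                      file.path(intdir, sprintf("module_%s.json", dir)))
    jsonlite::write_json(
      list(wilcoxon_p = res$wilcoxon_p,
           tf_regulatory_scores = as.list(res$tf_regulatory_scores)),
      file.path(intdir, sprintf("cma_%s.json", dir)),
      auto_unbox = TRUE, digits = NA)
    # per-TF report in the shape of the published TF tables
    enr <- state[[paste0("enrich_", dir)]]
    tfs <- names(res$tf_regulatory_scores)
    ratio <- vapply(tfs, function(tf) {
      rows <- enr[vapply(strsplit(enr$tf_symbols, ",", fixed = TRUE),
                         function(s) tf %in% s, logical(1)), , drop = FALSE]
      if (!nrow(rows)) NA_real_ else
        rows$yes_no_ratio[which.min(rows$adj_p)]
    }, numeric(1))
    tf_report <- data.frame(gene_symbol = tfs,
                            regulatory_score =
                              round(unname(res$tf_regulatory_scores), 4),
                            yes_no_ratio = round(unname(ratio), 4),
                            stringsAsFactors = FALSE)
    tf_report <- tf_report[order(-tf_report$regulatory_score,
                                 tf_report$gene_symbol), , drop = FALSE]
    rep_path <- file.path(out, sprintf("tf_report_%s.tsv", dir))
    write_report_tsv(tf_report, rep_path, seed = cfg$seed,
                     config_hash = cfg$hash)
    note_report(state, rep_path, nrow(tf_report))
    log_msg("stage cma (%s): p = %.3g, %d slots", dir, res$wilcoxon_p,
            nrow(res$module$slots))
  }
}

#' @noRd
ensure_cma <- function(cfg, state, intdir) {
  for (dir in c("up", "down")) {
    key <- paste0("cma_", dir)
    if (is.null(state[[key]])) {
      x <- jsonlite::read_json(file.path(intdir, sprintf("cma_%s.json", dir)),
                               simplifyVector = TRUE)
      state[[key]] <- list(tf_regulatory_scores =
                             unlist(x$tf_regulatory_scores))
    }
  }
  invisible(NULL)
}

# Regulatory scores of a stage result (CMAResult or resumed stub).
#' @noRd
cma_scores_of <- function(x) {
  if (inherits(x, "CMAResult")) x$tf_regulatory_scores else
    x$tf_regulatory_scores
}

#' @noRd
stage_master <- function(cfg, state, out, intdir) {
  state$last_files <- character()
  ensure_diff(cfg, state, intdir)
  ensure_enrich(cfg, state, intdir)
  ensure_cma(cfg, state, intdir)
  net <- read_network(cfg$inputs$network_edges, cfg$inputs$network_nodes)
  state$network <- net
  for (di in 1:2) {
    dir <- c("up", "down")[di]
    enr <- state[[paste0("enrich_", dir)]]
    tf_syms <- unique(unlist(strsplit(
      enr$tf_symbols[enr$enriched], ",", fixed = TRUE)))
    if (!length(tf_syms)) {
      log_msg("stage master (%s): no enriched matrix; using top 3 by p", dir)
      tf_syms <- unique(unlist(strsplit(utils::head(enr$tf_symbols, 3),
                                        ",", fixed = TRUE)))
    }
    # map TF gene symbols to TF-annotated network nodes
    tf_nodes <- net$nodes$node[net$nodes$is_tf &
      vapply(net$nodes$node, function(nd)
        any(node_symbols(net, nd) %in% tf_syms), logical(1))]
    assert_that(length(tf_nodes) > 0,
                "no enriched TF maps to a network node (%s)", dir)
    kn <- keynode_search(net, tf_nodes, max_radius = cfg$master$radius,
                         n_runs = cfg$master$n_runs,
                         seed = child_seed(cfg$seed, 20L + di),
                         fdr_threshold = cfg$master$fdr)
    write_report_tsv(kn, file.path(intdir, sprintf("keynode_%s.tsv", dir)))
    cand <- kn[kn$significant, , drop = FALSE]
    if (!nrow(cand)) cand <- utils::head(kn, 10)
    class(cand) <- class(kn)
    ranked <- total_rank(cand, net, cma_scores_of(state[[paste0("cma_", dir)]]),
                         state$tx_table, state$prot_table)
    state[[paste0("master_", dir)]] <- ranked
    report <- data.frame(master_molecule = ranked$node,
                         gene_symbols = ranked$gene_symbols,
                         total_rank = ranked$total_rank,
                         keynode_score = round(ranked$keynode_score, 4),
                         log_fc_transcriptome = round(ranked$log_fc_tx, 4),
                         log_fc_proteome = round(ranked$log_fc_prot, 4),
                         stringsAsFactors = FALSE)
    rep_path <- file.path(out, sprintf("master_regulators_%s.tsv", dir))
    write_report_tsv(report, rep_path, seed = cfg$seed,
                     config_hash = cfg$hash)
    note_report(state, rep_path, nrow(report))
    log_msg("stage master (%s): %d input TFs, %d candidates reported",
            dir, length(tf_nodes), nrow(report))
  }
}

#' @noRd
ensure_master <- function(cfg, state, intdir) {
  if (is.null(state$network))
    state$network <- read_network(cfg$inputs$network_edges,
                                  cfg$inputs$network_nodes)
  for (dir in c("up", "down")) {
    key <- paste0("master_", dir)
    if (is.null(state[[key]])) {
      x <- read_report_tsv(file.path(cfg$out_dir,
                                     sprintf("master_regulators_%s.tsv", dir)))
      state[[key]] <- data.frame(node = x$master_molecule,
                                 gene_symbols = x$gene_symbols,
                                 total_rank = x$total_rank,
                                 log_fc_tx = x$log_fc_transcriptome,
                                 log_fc_prot = x$log_fc_proteome,
                                 stringsAsFactors = FALSE)
    }
  }
  invisible(NULL)
}

#' @noRd
stage_drugs <- function(cfg, state, out, intdir) {
  state$last_files <- character()
  ensure_diff(cfg, state, intdir)
  ensure_master(cfg, state, intdir)
  have_drugs <- !is.null(cfg$inputs$drug_targets)
  have_cpd <- !is.null(cfg$inputs$compound_activities)
  assert_that(have_drugs || have_cpd,
              "no drug-target or compound-activity input configured")
  cand <- rbind(state$master_up[, c("node", "gene_symbols", "total_rank",
                                    "log_fc_tx", "log_fc_prot")],
                state$master_down[, c("node", "gene_symbols", "total_rank",
                                      "log_fc_tx", "log_fc_prot")])
  genes <- unique(unlist(strsplit(cand$gene_symbols, ",", fixed = TRUE)))
  genes <- genes[nzchar(genes)]
  gene_row <- function(g) {
    hit <- which(vapply(strsplit(cand$gene_symbols, ",", fixed = TRUE),
                        function(s) g %in% s, logical(1)))[1]
    cand[hit, , drop = FALSE]
  }
  rows <- list()
  if (have_drugs) {
    dt <- read_drug_table(cfg$inputs$drug_targets)
    for (g in genes) {
      score <- curated_druggability(g, dt)
      if (score == 0) next
      cr <- gene_row(g)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, mode = "curated", druggability_score = score,
        total_rank = cr$total_rank, log_fc_transcriptome = cr$log_fc_tx,
        log_fc_proteome = cr$log_fc_prot, stringsAsFactors = FALSE)
    }
  }
  if (have_cpd) {
    ct <- read_compound_table(cfg$inputs$compound_activities,
                              cfg$inputs$gene_weights)
    dg <- cfg$drugs
    flt <- filter_predicted(ct, dg$tox_threshold, dg$effect_threshold,
                            dg$target_threshold,
                            unlist(dg$diseases) %||% character())
    passing <- flt$compound_id[flt$passes_filter]
    for (g in genes) {
      score <- d_score_pass(g, ct, passing, dg$target_threshold)
      if (score == 0) next
      cr <- gene_row(g)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, mode = "predicted",
        druggability_score = round(score, 4),
        total_rank = cr$total_rank, log_fc_transcriptome = cr$log_fc_tx,
        log_fc_proteome = cr$log_fc_prot, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), mode = character(),
               druggability_score = numeric(), total_rank = numeric(),
               log_fc_transcriptome = numeric(),
               log_fc_proteome = numeric())
  report <- report[order(report$mode, report$total_rank, report$gene), ,
                   drop = FALSE]
  rownames(report) <- NULL
  rep_path <- file.path(out, "druggability.tsv")
  write_report_tsv(report, rep_path, seed = cfg$seed, config_hash = cfg$hash)
  note_report(state, rep_path, nrow(report))
  state$druggability <- report
  log_msg("stage drugs: %d target rows", nrow(report))
}
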