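# Readers and writers for every external format the pipeline touches:
# differential tables (TSV), promoter FASTA, TRANSFAC-style PWM flat files,
# signaling-network edge/node lists (TSV), drug-target tables (TSV) and
# compound-activity tables (TSV). Every reader validates strictly and every
# writer emits data its reader maps back to the same object.

# --- DiffTable --------------------------------------------------------------

#' Construct a differential-expression table
#'
#' A `DiffTable` holds one omics layer's differential statistics: one row per
#' feature with a log2 fold-change and a p-value. It is the entry point of
#' the pipeline: upstream normalisation and replicate-level testing are out
#' of scope and assumed done.
#'
#' @param feature_id Character vector of gene symbols; non-empty, unique.
#' @param log_fc Numeric log2 fold-changes; finite.
#' @param p_value Numeric p-values in `[0, 1]`.
#' @param layer `"transcriptome"` or `"proteome"`.
#' @return An object of class `DiffTable` (a data frame with a `layer`
#'   attribute).
#' @export
diff_table <- function(feature_id, log_fc, p_value,
                       layer = c("transcriptome", "proteome")) {
  layer <- match.arg(layer)
  feature_id <- as.character(feature_id)
  assert_that(length(feature_id) == length(log_fc) &&
              length(log_fc) == length(p_value),
              "feature_id, log_fc and p_value must have equal length")
  assert_that(all(nzchar(feature_id)), "feature_id must be non-empty")
  if (anyDuplicated(feature_id))
    to_abort("duplicate feature_id: %s",
             paste(unique(feature_id[duplicated(feature_id)]), collapse = ", "))
  assert_that(all(is.finite(log_fc)), "log_fc must be finite")
  bad <- which(!is.finite(p_value) | p_value < 0 | p_value > 1)
  if (length(bad))
    to_abort("p_value outside [0,1] for feature(s): %s",
             paste(feature_id[bad], collapse = ", "))
  out <- data.frame(feature_id = feature_id, log_fc = as.numeric(log_fc),
                    p_value = as.numeric(p_value), stringsAsFactors = FALSE)
  structure(out, layer = layer, class = c("DiffTable", "data.frame"))
}

#' Read a differential-expression table from TSV
#'
#' Duplicated feature IDs are collapsed to the row with the smallest p-value
#' (ties by first occurrence), with a warning naming the features collapsed.
#'
#' @param path Path to a tab-separated file with a header.
#' @param layer Omics layer of the table.
#' @param id_col,lfc_col,p_col Column names holding the feature ID, log
#'   fold-change and p-value.
#' @return A [diff_table()].
#' @export
read_diff_table <- function(path, layer = c("transcriptome", "proteome"),
                            id_col = "feature_id", lfc_col = "log_fc",
                            p_col = "p_value") {
  layer <- match.arg(layer)
  raw <- read_report_tsv(path)
  for (col in c(id_col, lfc_col, p_col))
    if (!col %in% names(raw))
      to_abort("file %s: missing required column '%s'", path, col)
  lfc <- suppressWarnings(as.numeric(raw[[lfc_col]]))
  p <- suppressWarnings(as.numeric(raw[[p_col]]))
  bad <- which(is.na(lfc) | is.na(p))
  if (length(bad))
    to_abort("file %s: non-numeric logFC/p at data row(s) %s", path,
             paste(bad, collapse = ", "))
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("collapsing %d duplicated feature ID(s) (%s) to min-p row",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    keep <- order(ids, p)           # within ID, smallest p first
    keep <- keep[!duplicated(ids[keep])]
    keep <- sort(keep)              # preserve original file order
    ids <- ids[keep]; lfc <- lfc[keep]; p <- p[keep]
  }
  n_in <- nrow(raw)
  tab <- diff_table(ids, lfc, p, layer = layer)
  log_msg("read_diff_table: %d rows parsed, %d kept, %d collapsed",
          n_in, nrow(tab), n_in - nrow(tab))
  tab
}

#' Write a differential table as TSV
#' @param x A `DiffTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(x, path) {
  stopifnot(inherits(x, "DiffTable"))
  write_report_tsv(as.data.frame(x), path)
}

# --- PromoterSet ------------------------------------------------------------

#' Construct a promoter set
#'
#' Promoters are fixed-length windows around the TSS: the closed interval
#' `[-1000, +100]` in TSS-relative coordinates, i.e. 1100 bp with the TSS at
#' offset 0 excluded from numbering. Internally sequences are 0-based.
#' Labels partition the set into the study ("yes") and background ("no")
#' promoters used by the enrichment contrast.
#'
#' @param gene_id Character vector of gene IDs.
#' @param sequence Character vector of equal-length sequences over
#'   `{A,C,G,T,N}`.
#' @param label `"yes"` / `"no"` per record.
#' @param width Expected sequence length (1100 for real promoter windows;
#'   relaxable for toy data).
#' @return An object of class `PromoterSet`.
#' @export
promoter_set <- function(gene_id, sequence, label, width = 1100L) {
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  label <- as.character(label)
  assert_that(length(gene_id) == length(sequence) &&
              length(sequence) == length(label),
              "gene_id, sequence and label must have equal length")
  assert_that(!anyDuplicated(gene_id), "gene_id must be unique")
  assert_that(all(label %in% c("yes", "no")), "labels must be 'yes' or 'no'")
  lens <- nchar(sequence)
  if (any(lens != width))
    to_abort("sequence length != %d for gene(s): %s", width,
             paste(gene_id[lens != width], collapse = ", "))
  if (any(grepl("[^ACGTN]", sequence)))
    to_abort("non-ACGTN character in sequence(s): %s",
             paste(gene_id[grepl("[^ACGTN]", sequence)], collapse = ", "))
  structure(list(gene_id = gene_id, sequence = sequence, label = label,
                 width = as.integer(width),
                 window = c(start_offset = -1000L, end_offset = 100L)),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet: %d promoters (%d yes / %d no), width %d bp\n",
              length(x$gene_id), sum(x$label == "yes"), sum(x$label == "no"),
              x$width))
  invisible(x)
}

# Integer-encoded sequence matrix (n_promoters x width), cached on the object.
#' @noRd
promoter_int_matrix <- function(ps) {
  cached <- attr(ps, "int_matrix")
  if (!is.null(cached)) return(cached)
  m <- t(vapply(ps$sequence, dna_to_int, integer(ps$width), USE.NAMES = FALSE))
  rownames(m) <- ps$gene_id
  m
}

#' @noRd
subset_promoters <- function(ps, idx) {
  out <- promoter_set(ps$gene_id[idx], ps$sequence[idx], ps$label[idx],
                      width = ps$width)
  out
}

#' Read promoters from FASTA with a yes/no label map
#'
#' @param path FASTA file, one record per gene.
#' @param label_map Named character vector mapping record IDs to `"yes"` or
#'   `"no"`. Every name must be present in the FASTA; unlabeled FASTA
#'   records are dropped with a log message.
#' @param pad If `TRUE`, records shorter than `width` are padded with `N` at
#'   the 5' end; otherwise (default) a short or long record is an error.
#' @param width Expected promoter length (default 1100).
#' @return A [promoter_set()].
#' @export
read_promoters_fasta <- function(path, label_map, pad = FALSE, width = 1100L) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  assert_that(length(label_map) > 0 && !is.null(names(label_map)),
              "label_map must be a named character vector")
  missing <- setdiff(names(label_map), ids)
  if (length(missing))
    to_abort("label_map record(s) absent from FASTA: %s",
             paste(missing, collapse = ", "))
  keep <- ids %in% names(label_map)
  if (any(!keep))
    log_msg("read_promoters_fasta: dropping %d unlabeled record(s)", sum(!keep))
  seqs <- seqs[keep]; ids <- ids[keep]
  chr <- toupper(as.character(seqs))
  lens <- nchar(chr)
  if (pad) {
    short <- lens < width
    chr[short] <- paste0(strrep("N", width - lens[short]), chr[short])
  }
  promoter_set(ids, chr, unname(label_map[ids]), width = width)
}

#' Write a promoter set as FASTA
#' @param ps A `PromoterSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly. Labels are not stored in the FASTA; use
#'   [promoter_label_map()] to persist them alongside.
#' @export
write_promoters_fasta <- function(ps, path) {
  stopifnot(inherits(ps, "PromoterSet"))
  x <- Biostrings::DNAStringSet(ps$sequence)
  names(x) <- ps$gene_id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Extract the yes/no label map of a promoter set
#' @param ps A `PromoterSet`.
#' @return Named character vector suitable for [read_promoters_fasta()].
#' @export
promoter_label_map <- function(ps) {
  stats::setNames(ps$label, ps$gene_id)
}

# --- PWMatrix / TRANSFAC-style library --------------------------------------

#' Construct a position weight matrix
#'
#' @param matrix_id Identifier of the matrix.
#' @param counts Numeric L x 4 matrix (rows = positions, columns = A,C,G,T)
#'   of counts or frequencies; each row must have a positive entry and L >= 4.
#' @param tf_symbols Gene symbols of the transcription factor(s) the matrix
#'   models.
#' @param cutoff Default normalized-score cutoff in `[0, 1]` used when
#'   scanning with this matrix.
#' @return Object of class `PWMatrix`.
#' @export
pw_matrix <- function(matrix_id, counts, tf_symbols = character(),
                      cutoff = 0.85) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) == 4, "counts must have 4 columns (A,C,G,T)")
  assert_that(nrow(counts) >= 4, "matrix %s: length must be >= 4", matrix_id)
  assert_that(all(is.finite(counts)) && all(counts >= 0),
              "matrix %s: counts must be non-negative and finite", matrix_id)
  assert_that(all(rowSums(counts) > 0),
              "matrix %s: every position needs a positive entry", matrix_id)
  assert_that(is.numeric(cutoff) && cutoff >= 0 && cutoff <= 1,
              "matrix %s: cutoff must be in [0,1]", matrix_id)
  colnames(counts) <- c("A", "C", "G", "T")
  rownames(counts) <- NULL
  structure(list(matrix_id = as.character(matrix_id), counts = counts,
                 tf_symbols = as.character(tf_symbols),
                 cutoff = as.numeric(cutoff)),
            class = "PWMatrix")
}

#' @export
print.PWMatrix <- function(x, ...) {
  cat(sprintf("PWMatrix %s: L=%d, TFs: %s, cutoff=%.2f\n", x$matrix_id,
              nrow(x$counts),
              if (length(x$tf_symbols)) paste(x$tf_symbols, collapse = ",")
              else "<none>", x$cutoff))
  invisible(x)
}

#' Read a TRANSFAC-style matrix flat file
#'
#' Blocks are delimited by `//`. Within a block: an `ID` line, optional `BF`
#' lines naming TF gene symbols (one symbol per line in this dialect), an
#' optional `CO` line giving the matrix cutoff, an optional `P0` column
#' header, and numbered count rows of 4 numeric fields (a trailing consensus
#' letter is tolerated). Both raw count matrices and pre-normalized
#' frequency matrices (row sums about 1) are accepted; counts are preserved
#' exactly as printed. A final block lacking its `//` terminator at EOF is
#' accepted with a log message.
#'
#' @param path Path to the flat file.
#' @param default_cutoff Cutoff assigned to matrices without a `CO` line.
#' @return List of [pw_matrix()] objects.
#' @export
read_pwm_library <- function(path, default_cutoff = 0.85) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  terms <- grep("^//", lines)
  if (length(terms) == 0 || utils::tail(terms, 1) < length(lines)) {
    log_msg("read_pwm_library: final block not //-terminated; accepting")
    lines <- c(lines, "//")
    terms <- grep("^//", lines)
  }
  starts <- c(1L, utils::head(terms, -1) + 1L)
  out <- list()
  for (b in seq_along(terms)) {
    if (terms[b] <= starts[b]) next
    block <- lines[starts[b]:(terms[b] - 1L)]
    id_line <- grep("^ID\\b", block, value = TRUE)
    mid <- if (length(id_line)) sub("^ID\\s+", "", id_line[1]) else
      sprintf("M%04d", b)
    bf <- sub("^BF\\s+", "", grep("^BF\\b", block, value = TRUE))
    co <- grep("^CO\\b", block, value = TRUE)
    cutoff <- if (length(co)) as.numeric(sub("^CO\\s+", "", co[1])) else
      default_cutoff
    rows <- grep("^\\d+\\s", block, value = TRUE)
    if (!length(rows)) to_abort("block %s: no count rows", mid)
    counts <- matrix(NA_real_, nrow = length(rows), ncol = 4)
    for (i in seq_along(rows)) {
      f <- strsplit(trimws(rows[i]), "\\s+")[[1]][-1]
      # tolerate a trailing consensus letter column
      if (length(f) == 5 && is.na(suppressWarnings(as.numeric(f[5]))))
        f <- f[1:4]
      v <- suppressWarnings(as.numeric(f))
      if (length(v) != 4 || anyNA(v))
        to_abort("block %s: count row %d does not have 4 numeric fields",
                 mid, i)
      counts[i, ] <- v
    }
    out[[length(out) + 1L]] <- pw_matrix(mid, counts, tf_symbols = bf,
                                         cutoff = cutoff)
  }
  if (!length(out)) to_abort("empty PWM library: %s", path)
  log_msg("read_pwm_library: %d matrices", length(out))
  out
}

#' Write a PWM library in the TRANSFAC-style dialect read by
#' [read_pwm_library()]
#' @param library List of `PWMatrix` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in library) {
    stopifnot(inherits(m, "PWMatrix"))
    writeLines(sprintf("ID %s", m$matrix_id), con)
    for (s in m$tf_symbols) writeLines(sprintf("BF %s", s), con)
    writeLines(sprintf("CO %s", format(m$cutoff, digits = 15)), con)
    writeLines("P0      A      C      G      T", con)
    for (i in seq_len(nrow(m$counts)))
      writeLines(paste0(sprintf("%02d ", i),
                        paste(format(m$counts[i, ], digits = 15),
                              collapse = " ")), con)
    writeLines("//", con)
  }
  invisible(path)
}

# Map TF symbol -> matrix ids for a library.
#' @noRd
library_tf_map <- function(library) {
  ids <- vapply(library, `[[`, "", "matrix_id")
  syms <- lapply(library, `[[`, "tf_symbols")
  df <- data.frame(matrix_id = rep(ids, lengths(syms)),
                   tf_symbol = unlist(syms, use.names = FALSE),
                   stringsAsFactors = FALSE)
  df
}

# --- SignalingNetwork -------------------------------------------------------

#' Construct a directed signaling network
#'
#' Node annotations attach gene symbols and a transcription-factor flag to
#' each molecule node; master-regulator search samples its resampling null
#' from the TF-flagged nodes. Self-loops are removed with a log message.
#'
#' @param edges Data frame with columns `source`, `target`,
#'   `interaction` (label; free text).
#' @param nodes Optional data frame with columns `node`, `gene_symbols`
#'   (comma-separated string, possibly empty) and `is_tf` (logical). Nodes
#'   referenced by edges but absent here get an empty annotation.
#' @return Object of class `SignalingNetwork` wrapping an igraph.
#' @export
signaling_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  assert_that(all(c("source", "target") %in% names(edges)),
              "edges must have 'source' and 'target' columns")
  if (is.null(edges$interaction)) edges$interaction <- "interaction"
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  self <- edges$source == edges$target
  if (any(self)) {
    log_msg("signaling_network: removing %d self-loop(s)", sum(self))
    edges <- edges[!self, , drop = FALSE]
  }
  all_nodes <- unique(c(edges$source, edges$target,
                        if (!is.null(nodes)) as.character(nodes$node)))
  ann <- data.frame(node = all_nodes, gene_symbols = "", is_tf = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    assert_that(all(c("node") %in% names(nodes)), "nodes must have 'node'")
    i <- match(as.character(nodes$node), ann$node)
    if (!is.null(nodes$gene_symbols))
      ann$gene_symbols[i] <- as.character(nodes$gene_symbols)
    if (!is.null(nodes$is_tf)) ann$is_tf[i] <- as.logical(nodes$is_tf)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "interaction")],
    directed = TRUE,
    vertices = ann)
  structure(list(graph = g, edges = edges, nodes = ann),
            class = "SignalingNetwork")
}

#' @export
print.SignalingNetwork <- function(x, ...) {
  cat(sprintf("SignalingNetwork: %d nodes (%d TFs), %d directed edges\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges)))
  invisible(x)
}

#' Read a signaling network from edge-list and node-annotation TSVs
#' @param edge_path TSV with columns source, target, interaction.
#' @param node_path Optional TSV with columns node, gene_symbols, is_tf.
#' @return A [signaling_network()].
#' @export
read_network <- function(edge_path, node_path = NULL) {
  edges <- read_report_tsv(edge_path)
  nodes <- if (!is.null(node_path)) {
    n <- read_report_tsv(node_path, colClasses = "character")
    n$is_tf <- toupper(n$is_tf) %in% c("TRUE", "T", "1")
    n$gene_symbols[is.na(n$gene_symbols)] <- ""
    n
  } else NULL
  signaling_network(edges, nodes)
}

#' Write a signaling network as edge-list and node-annotation TSVs
#' @param net A `SignalingNetwork`.
#' @param edge_path,node_path Output paths.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, node_path) {
  stopifnot(inherits(net, "SignalingNetwork"))
  write_report_tsv(net$edges, edge_path)
  write_report_tsv(net$nodes, node_path)
  invisible(edge_path)
}

# Gene symbols of a node as a character vector.
#' @noRd
node_symbols <- function(net, node) {
  s <- net$nodes$gene_symbols[match(node, net$nodes$node)]
  if (is.na(s) || !nzchar(s)) character() else
    trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}

# --- DrugTargetTable --------------------------------------------------------

#' Construct a curated drug-target table
#'
#' One row per (compound, target gene, disease) with the maximum clinical
#' trial phase (0 = never in trials, 4 = phase IV) observed for that triple.
#'
#' @param rows Data frame with columns `compound_id`, `target_gene`,
#'   `disease_id`, `max_trial_phase`.
#' @return Object of class `DrugTargetTable`.
#' @export
drug_target_table <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_gene", "disease_id", "max_trial_phase")
  assert_that(all(need %in% names(rows)), "missing columns: %s",
              paste(setdiff(need, names(rows)), collapse = ", "))
  rows$max_trial_phase <- as.integer(rows$max_trial_phase)
  assert_that(all(rows$max_trial_phase %in% 0:4),
              "max_trial_phase must be in 0..4")
  key <- paste(rows$compound_id, rows$target_gene, rows$disease_id)
  assert_that(!anyDuplicated(key),
              "(compound, target) pairs must be unique per disease")
  structure(rows, class = c("DrugTargetTable", "data.frame"))
}

#' Read a curated drug-target table from TSV
#' @param path TSV path.
#' @return A [drug_target_table()].
#' @export
read_drug_table <- function(path) {
  drug_target_table(read_report_tsv(path))
}

#' Write a curated drug-target table as TSV
#' @param x A `DrugTargetTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_table <- function(x, path) {
  stopifnot(inherits(x, "DrugTargetTable"))
  write_report_tsv(as.data.frame(x), path)
}

# --- CompoundActivityTable --------------------------------------------------

#' Construct a compound-activity table
#'
#' Holds precomputed probability-of-activity (Pa) values per compound and
#' activity. Activities are classed as `mechanism` (target-mediated; must
#' carry mapped genes), `disease_effect` or `toxicity`. Per-gene reliability
#' weights -- IAP (invariant accuracy of prediction) and an optional extra
#' weight -- are carried alongside.
#'
#' @param rows Data frame with columns `compound_id`, `activity_name`,
#'   `activity_class`, `pa`, `mapped_genes` (comma-separated, may be empty
#'   for non-mechanism rows).
#' @param gene_weights Data frame with columns `gene`, `iap` in `[0,1]`,
#'   `opt_weight` (> 0). Genes absent here default to iap 1, weight 1.
#' @return Object of class `CompoundActivityTable`.
#' @export
compound_activity_table <- function(rows, gene_weights = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("compound_id", "activity_name", "activity_class", "pa",
            "mapped_genes")
  assert_that(all(need %in% names(rows)), "missing columns: %s",
              paste(setdiff(need, names(rows)), collapse = ", "))
  assert_that(all(rows$activity_class %in%
                    c("mechanism", "disease_effect", "toxicity")),
              "activity_class must be mechanism/disease_effect/toxicity")
  rows$pa <- as.numeric(rows$pa)
  assert_that(all(rows$pa >= 0 & rows$pa <= 1), "pa must be in [0,1]")
  rows$mapped_genes[is.na(rows$mapped_genes)] <- ""
  mech <- rows$activity_class == "mechanism"
  assert_that(all(nzchar(rows$mapped_genes[mech])),
              "mechanism rows must have non-empty mapped_genes")
  if (is.null(gene_weights)) {
    gene_weights <- data.frame(gene = character(), iap = numeric(),
                               opt_weight = numeric())
  } else {
    gene_weights <- as.data.frame(gene_weights, stringsAsFactors = FALSE)
    assert_that(all(c("gene", "iap", "opt_weight") %in% names(gene_weights)),
                "gene_weights needs columns gene, iap, opt_weight")
    assert_that(all(gene_weights$iap >= 0 & gene_weights$iap <= 1),
                "iap must be in [0,1]")
    assert_that(all(gene_weights$opt_weight > 0), "opt_weight must be > 0")
  }
  structure(list(rows = rows, gene_weights = gene_weights),
            class = "CompoundActivityTable")
}

#' Read a compound-activity table (and optional gene weights) from TSV
#' @param path Activity TSV path.
#' @param weights_path Optional gene-weight TSV path.
#' @return A [compound_activity_table()].
#' @export
read_compound_table <- function(path, weights_path = NULL) {
  rows <- read_report_tsv(path)
  rows$mapped_genes <- as.character(rows$mapped_genes)
  rows$mapped_genes[is.na(rows$mapped_genes)] <- ""
  w <- if (!is.null(weights_path)) read_report_tsv(weights_path) else NULL
  compound_activity_table(rows, w)
}

#' Write a compound-activity table (and gene weights) as TSV
#' @param x A `CompoundActivityTable`.
#' @param path Activity TSV path.
#' @param weights_path Optional gene-weight TSV path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(x, path, weights_path = NULL) {
  stopifnot(inherits(x, "CompoundActivityTable"))
  write_report_tsv(x$rows, path)
  if (!is.null(weights_path)) write_report_tsv(x$gene_weights, weights_path)
  invisible(path)
}

# IAP / optWeight lookup with default 1.
#' @noRd
gene_weight_lookup <- function(cat_tab, gene, what = c("iap", "opt_weight")) {
  what <- match.arg(what)
  i <- match(gene, cat_tab$gene_weights$gene)
  w <- cat_tab$gene_weights[[what]][i]
  w[is.na(w)] <- 1
  w
}

#' @noRd
split_genes <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE),
         function(v) trimws(v[nzchar(trimws(v))]))
}
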