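# Significance calling per omics layer, transcript-protein concordance
# classification, and top-N input-gene selection.

#' Call significant features in one omics layer
#'
#' Benjamini-Hochberg adjusted p-values are computed over all rows of the
#' table; a feature is significant when `adj_p <= alpha` and
#' `|log_fc| >= lfc_min`. Direction follows the sign of the log
#' fold-change; a feature with `log_fc == 0` is `unchanged` and never
#' flagged significant (no direction can be assigned).
#'
#' @param table A [diff_table()].
#' @param alpha FDR threshold in (0, 1).
#' @param lfc_min Minimum absolute log2 fold-change (>= 0).
#' @return Data frame of class `SignificanceCalls` with columns
#'   `feature_id`, `layer`, `log_fc`, `p_value`, `adj_p`, `direction`
#'   (`up`/`down`/`unchanged`), `significant`.
#' @export
call_significance <- function(table, alpha = 0.05, lfc_min = 0) {
  stopifnot(inherits(table, "DiffTable"))
  assert_that(nrow(table) > 0, "empty differential table")
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  assert_that(lfc_min >= 0, "lfc_min must be >= 0")
  adj <- stats::p.adjust(table$p_value, method = "BH")
  direction <- ifelse(table$log_fc > 0, "up",
                      ifelse(table$log_fc < 0, "down", "unchanged"))
  sig <- adj <= alpha & abs(table$log_fc) >= lfc_min &
    direction != "unchanged"
  out <- data.frame(feature_id = table$feature_id,
                    layer = attr(table, "layer"),
                    log_fc = table$log_fc, p_value = table$p_value,
                    adj_p = adj, direction = direction, significant = sig,
                    stringsAsFactors = FALSE)
  class(out) <- c("SignificanceCalls", "data.frame")
  out
}

#' Classify transcript-protein concordance
#'
#' Features significant in both layers are `concordant_up` /
#' `concordant_down` when the fold-change signs agree, and fall in one of
#' the two discordant classes when they disagree
#' (`discordant_up_gene_down_protein`, `discordant_down_gene_up_protein`).
#' Features significant in exactly one layer are `single_layer_only`.
#' Features carrying no significant call in either layer receive no class
#' record but are counted in the summary (`n_not_significant`), so nothing
#' is silently dropped.
#'
#' @param tx_calls,prot_calls `SignificanceCalls` for the transcriptome and
#'   proteome layers.
#' @return List with `records` (data frame feature_id, class) and `summary`
#'   (named integer vector of the five class counts plus
#'   `n_not_significant`).
#' @export
classify_concordance <- function(tx_calls, prot_calls) {
  stopifnot(inherits(tx_calls, "SignificanceCalls"),
            inherits(prot_calls, "SignificanceCalls"))
  tx_sig <- tx_calls[tx_calls$significant, , drop = FALSE]
  pr_sig <- prot_calls[prot_calls$significant, , drop = FALSE]
  feats <- union(tx_sig$feature_id, pr_sig$feature_id)
  ti <- match(feats, tx_sig$feature_id)
  pi <- match(feats, pr_sig$feature_id)
  cls <- character(length(feats))
  for (k in seq_along(feats)) {
    in_tx <- !is.na(ti[k]); in_pr <- !is.na(pi[k])
    if (in_tx && in_pr) {
      dt <- tx_sig$direction[ti[k]]; dp <- pr_sig$direction[pi[k]]
      cls[k] <- if (dt == dp) paste0("concordant_", dt)
      else if (dt == "up") "discordant_up_gene_down_protein"
      else "discordant_down_gene_up_protein"
    } else {
      cls[k] <- "single_layer_only"
    }
  }
  classes <- c("concordant_up", "concordant_down",
               "discordant_up_gene_down_protein",
               "discordant_down_gene_up_protein", "single_layer_only")
  counts <- stats::setNames(integer(5), classes)
  tab <- table(factor(cls, levels = classes))
  counts[names(tab)] <- as.integer(tab)
  detected <- union(tx_calls$feature_id, prot_calls$feature_id)
  summary <- c(counts,
               n_not_significant = length(detected) - length(feats))
  list(records = data.frame(feature_id = feats, class = cls,
                            stringsAsFactors = FALSE),
       summary = summary)
}

#' Select the top-N most significant features
#'
#' Significant features are ordered by ascending p-value, ties broken by
#' descending absolute log fold-change, then lexicographic feature ID; the
#' first `n` IDs are returned (fewer if fewer are significant).
#'
#' @param calls A `SignificanceCalls` data frame.
#' @param n Number of features to keep (default 300).
#' @param direction Optional filter: `"up"` or `"down"`.
#' @return Character vector of feature IDs.
#' @export
top_n_by_significance <- function(calls, n = 300, direction = NULL) {
  stopifnot(inherits(calls, "SignificanceCalls"))
  assert_that(n >= 1, "n must be >= 1")
  x <- calls[calls$significant, , drop = FALSE]
  if (!is.null(direction)) {
    assert_that(direction %in% c("up", "down"), "direction must be up/down")
    x <- x[x$direction == direction, , drop = FALSE]
  }
  ord <- order(x$p_value, -abs(x$log_fc), x$feature_id)
  utils::head(x$feature_id[ord], n)
}
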