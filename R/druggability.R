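# Druggability scoring: curated-evidence compound ranking (target /
# disease / clinical-validity components), predicted-compound filtering on
# probability-of-activity (Pa) values, and per-gene druggability scores.

#' Curated target-activity score of a compound
#'
#' With `T` the compound's targets intersected with the input target list,
#' `AT` all of the compound's targets, `rank(t)` the externally supplied
#' rank of target `t` (from the master-regulator stage; rank 1 = best) and
#' `maxRank(T)` the largest rank in `T`:
#' `-(|T| / (|T| + w (|AT| - |T|))) * sum_t log10(rank(t) / (1 + maxRank(T)))`.
#' Every log term is negative (each ratio < 1), so the score is positive
#' whenever `T` is non-empty; `T` empty means the compound is not
#' applicable and is an error (callers exclude such compounds).
#'
#' @param compound_targets Character vector: all targets of the compound
#'   (`AT`).
#' @param input_targets Character vector: the input target list.
#' @param target_ranks Named numeric vector of ranks (must cover `T`).
#' @param w Weight multiplier penalising off-list targets (default 1).
#' @return Positive numeric score.
#' @export
t_score_psd <- function(compound_targets, input_targets, target_ranks,
                        w = 1) {
  T_set <- intersect(compound_targets, input_targets)
  if (!length(T_set))
    to_abort("compound has no target in the input list (T empty)")
  r <- target_ranks[T_set]
  assert_that(!anyNA(r), "target_ranks must cover every target in T")
  nT <- length(T_set); nAT <- length(unique(compound_targets))
  -(nT / (nT + w * (nAT - nT))) * sum(log10(r / (1 + max(r))))
}

#' Curated disease-activity score of a compound
#'
#' `sum over selected diseases d, sum over phases p of phase(d, p)` where
#' `phase(d, p) = p` if the compound has a known trial in phase `p` for
#' disease `d` and 0 otherwise; 0 when no disease is selected.
#'
#' @param compound_id Compound to score.
#' @param selected_diseases Character vector of disease IDs (`D`).
#' @param trial_table A [drug_target_table()]; the known phases of a
#'   (compound, disease) pair are the distinct `max_trial_phase` values
#'   over its rows (phase 0 = no trial contributes nothing).
#' @return Non-negative numeric score.
#' @export
d_score_psd <- function(compound_id, selected_diseases, trial_table) {
  stopifnot(inherits(trial_table, "DrugTargetTable"))
  if (!length(selected_diseases)) return(0)
  rows <- trial_table[trial_table$compound_id == compound_id &
                        trial_table$disease_id %in% selected_diseases, ,
                      drop = FALSE]
  if (!nrow(rows)) return(0)
  sum(vapply(split(rows$max_trial_phase, rows$disease_id),
             function(p) sum(unique(p)), numeric(1)))
}

#' Clinical validity of a compound
#'
#' The highest clinical-trial phase (1-4) the compound ever reached for
#' any pathology; 0 if never tested.
#'
#' @param compound_id Compound to score.
#' @param trial_table A [drug_target_table()].
#' @return Integer in 0..4.
#' @export
clinical_validity <- function(compound_id, trial_table) {
  stopifnot(inherits(trial_table, "DrugTargetTable"))
  rows <- trial_table[trial_table$compound_id == compound_id, , drop = FALSE]
  if (!nrow(rows)) return(0L)
  as.integer(max(rows$max_trial_phase))
}

#' Rank curated compounds by summed component ranks
#'
#' Each of the three component scores is ranked descending (higher score =
#' rank 1, ties share the smallest rank); the drug rank is their sum and
#' the output is ordered by ascending drug rank, ties broken by compound
#' ID.
#'
#' @param scores Data frame with columns `compound_id`, `t_score_psd`,
#'   `d_score_psd`, `clinical_validity`.
#' @return The input with `t_rank`, `d_rank`, `cv_rank` and `drug_rank`
#'   columns appended, reordered.
#' @export
drug_rank <- function(scores) {
  scores <- as.data.frame(scores, stringsAsFactors = FALSE)
  need <- c("compound_id", "t_score_psd", "d_score_psd", "clinical_validity")
  assert_that(all(need %in% names(scores)), "missing columns: %s",
              paste(setdiff(need, names(scores)), collapse = ", "))
  scores$t_rank <- rank(-scores$t_score_psd, ties.method = "min")
  scores$d_rank <- rank(-scores$d_score_psd, ties.method = "min")
  scores$cv_rank <- rank(-scores$clinical_validity, ties.method = "min")
  scores$drug_rank <- scores$t_rank + scores$d_rank + scores$cv_rank
  scores <- scores[order(scores$drug_rank, scores$compound_id), ,
                   drop = FALSE]
  rownames(scores) <- NULL
  scores
}

#' Filter predicted compounds on Pa thresholds
#'
#' A compound passes when (i) its toxicity score -- the maximum Pa over its
#' toxicity activities, 0 if it has none -- is strictly below
#' `tox_threshold`; (ii) every predicted effect matching a selected disease
#' has Pa strictly above `effect_threshold` (vacuously true with no
#' matching effect rows); and (iii) it has at least 2 distinct target genes
#' on mechanism rows with Pa strictly above `target_threshold`. The
#' disease-activity score is the maximum Pa over disease-matched effects.
#'
#' @param compound_table A [compound_activity_table()].
#' @param tox_threshold,effect_threshold,target_threshold Pa thresholds in
#'   `[0, 1]`.
#' @param diseases Character vector of disease activity names to match
#'   against `activity_name` of `disease_effect` rows.
#' @return Data frame, one row per compound: `compound_id`,
#'   `toxicity_score`, `disease_activity_score`, `n_targets`,
#'   `passes_filter`.
#' @export
filter_predicted <- function(compound_table, tox_threshold = 0.5,
                             effect_threshold = 0.5,
                             target_threshold = 0.5,
                             diseases = character()) {
  stopifnot(inherits(compound_table, "CompoundActivityTable"))
  for (th in c(tox_threshold, effect_threshold, target_threshold))
    assert_that(th >= 0 && th <= 1, "thresholds must be in [0,1]")
  rows <- compound_table$rows
  ids <- unique(rows$compound_id)
  out <- lapply(ids, function(cid) {
    cr <- rows[rows$compound_id == cid, , drop = FALSE]
    tox <- cr$pa[cr$activity_class == "toxicity"]
    tox_score <- if (length(tox)) max(tox) else 0
    eff <- cr[cr$activity_class == "disease_effect" &
                cr$activity_name %in% diseases, , drop = FALSE]
    dis_score <- if (nrow(eff)) max(eff$pa) else 0
    mech <- cr[cr$activity_class == "mechanism" &
                 cr$pa > target_threshold, , drop = FALSE]
    targets <- unique(unlist(split_genes(mech$mapped_genes)))
    passes <- tox_score < tox_threshold &&
      (nrow(eff) == 0 || all(eff$pa > effect_threshold)) &&
      length(targets) >= 2
    data.frame(compound_id = cid, toxicity_score = tox_score,
               disease_activity_score = dis_score,
               n_targets = length(targets), passes_filter = passes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Predicted target-activity score of one compound (structure)
#'
#' Over the compound's mechanism activities passing the target threshold
#' (`M(s)`), with `G(m)` the genes mapped to mechanism `m`:
#' `(|T| / (|T| + w (|AT| - |T|))) * sum_m pa(m) * sum_g IAP(g) optWeight(g)`
#' where `T` is the compound's target genes intersected with the input
#' list and `AT` all its target genes.
#'
#' @param compound_id Compound (structure) to score.
#' @param compound_table A [compound_activity_table()] (supplies Pa, gene
#'   maps, IAP and optWeight).
#' @param input_targets Character vector: the input target gene list.
#' @param target_threshold Pa threshold defining `M(s)` (strict `>`).
#' @param w Weight multiplier (default 1).
#' @return Non-negative score; error if `T` is empty (compound excluded).
#' @export
t_score_pass <- function(compound_id, compound_table, input_targets,
                         target_threshold = 0.5, w = 1) {
  stopifnot(inherits(compound_table, "CompoundActivityTable"))
  rows <- compound_table$rows
  mech <- rows[rows$compound_id == compound_id &
                 rows$activity_class == "mechanism" &
                 rows$pa > target_threshold, , drop = FALSE]
  genes_per_mech <- split_genes(mech$mapped_genes)
  AT <- unique(unlist(genes_per_mech))
  T_set <- intersect(AT, input_targets)
  if (!length(T_set))
    to_abort("compound %s has no target in the input list (T empty)",
             compound_id)
  inner <- vapply(seq_len(nrow(mech)), function(i) {
    g <- genes_per_mech[[i]]
    mech$pa[i] * sum(gene_weight_lookup(compound_table, g, "iap") *
                       gene_weight_lookup(compound_table, g, "opt_weight"))
  }, numeric(1))
  (length(T_set) / (length(T_set) + w * (length(AT) - length(T_set)))) *
    sum(inner)
}

#' Predicted druggability score of one gene
#'
#' `IAP(g) * sum over passing structures s targeting g, sum over their
#' mechanisms mapped to g of pa(m)`.
#'
#' @param gene Gene symbol.
#' @param compound_table A [compound_activity_table()].
#' @param passing_compounds Character vector of compound IDs that passed
#'   [filter_predicted()] (`S(g)` is its subset targeting `gene`).
#' @param target_threshold Pa threshold defining counted mechanisms
#'   (strict `>`), matching the filter.
#' @return Non-negative numeric score (0 when `S(g)` is empty).
#' @export
d_score_pass <- function(gene, compound_table, passing_compounds,
                         target_threshold = 0.5) {
  stopifnot(inherits(compound_table, "CompoundActivityTable"))
  rows <- compound_table$rows
  mech <- rows[rows$compound_id %in% passing_compounds &
                 rows$activity_class == "mechanism" &
                 rows$pa > target_threshold, , drop = FALSE]
  if (!nrow(mech)) return(0)
  has_gene <- vapply(split_genes(mech$mapped_genes),
                     function(g) gene %in% g, logical(1))
  if (!any(has_gene)) return(0)
  gene_weight_lookup(compound_table, gene, "iap") * sum(mech$pa[has_gene])
}

#' Curated druggability of one gene
#'
#' The number of distinct known compounds targeting the gene.
#'
#' @param gene Gene symbol.
#' @param drug_table A [drug_target_table()].
#' @return Non-negative integer count.
#' @export
curated_druggability <- function(gene, drug_table) {
  stopifnot(inherits(drug_table, "DrugTargetTable"))
  length(unique(drug_table$compound_id[drug_table$target_gene == gene]))
}
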