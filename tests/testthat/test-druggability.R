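# Druggability formulas: hand-computed toys at tight tolerance.

trial_fixture <- function() {
  drug_target_table(data.frame(
    compound_id = c("c1", "c1", "c2", "c2", "c2", "c3"),
    target_gene = c("PRMT1", "STAT3", "PRMT1", "ITGAV", "ITGB6", "SIRT2"),
    disease_id = c("d1", "d1", "d1", "d2", "d2", "d1"),
    max_trial_phase = c(1L, 3L, 2L, 1L, 3L, 0L)))
}

test_that("t_score_psd evaluates the reconstructed formula", {
  expect_equal(t_score_psd("PRMT1", "PRMT1", c(PRMT1 = 1)),
               -log10(1 / 2), tolerance = 1e-12)
  # doubling w strictly decreases the score when |AT| > |T|
  s1 <- t_score_psd(c("PRMT1", "OFF1", "OFF2"), "PRMT1", c(PRMT1 = 2), w = 1)
  s2 <- t_score_psd(c("PRMT1", "OFF1", "OFF2"), "PRMT1", c(PRMT1 = 2), w = 2)
  expect_lt(s2, s1)
  expect_gt(s2, 0)

  # 3-target toy vs spreadsheet-style recomputation
  at <- c("A", "B", "C", "X", "Y")
  ranks <- c(A = 2, B = 5, C = 9)
  got <- t_score_psd(at, c("A", "B", "C"), ranks, w = 1.5)
  want <- -(3 / (3 + 1.5 * 2)) *
    (log10(2 / 10) + log10(5 / 10) + log10(9 / 10))
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(t_score_psd(c("X", "Y"), "PRMT1", c(PRMT1 = 1)), "T empty")
})

test_that("d_score_psd sums observed phases over selected diseases", {
  tt <- trial_fixture()
  expect_equal(d_score_psd("c1", character(), tt), 0)
  # c1 in d1 with phases {1, 3} -> 4
  expect_equal(d_score_psd("c1", "d1", tt), 4)
  # phases {2} in d1 plus untested d2 -> 2
  expect_equal(d_score_psd("c2", c("d1", "d2"), tt), 2 + 1 + 3)
  expect_equal(d_score_psd("c3", "d1", tt), 0)  # phase 0 contributes 0
  expect_equal(d_score_psd("nope", "d1", tt), 0)
  # two diseases with phases {2} and {1,2,3,4} -> 12
  tt2 <- drug_target_table(data.frame(
    compound_id = "c9", target_gene = paste0("g", 1:5),
    disease_id = c("dA", "dB", "dB", "dB", "dB"),
    max_trial_phase = c(2L, 1L, 2L, 3L, 4L)))
  expect_equal(d_score_psd("c9", c("dA", "dB"), tt2), 12)
})

test_that("clinical validity is the max phase over any pathology", {
  tt <- trial_fixture()
  expect_equal(clinical_validity("c1", tt), 3L)
  expect_equal(clinical_validity("c3", tt), 0L)
  expect_equal(clinical_validity("ghost", tt), 0L)
  expect_true(all(vapply(unique(tt$compound_id), clinical_validity,
                         integer(1), trial_table = tt) <= 4L))
})

test_that("drug_rank sums descending component ranks deterministically", {
  one <- data.frame(compound_id = "c1", t_score_psd = 1, d_score_psd = 2,
                    clinical_validity = 3)
  expect_equal(drug_rank(one)$drug_rank, 3)

  two <- data.frame(compound_id = c("best", "worst"),
                    t_score_psd = c(2, 1), d_score_psd = c(8, 0),
                    clinical_validity = c(4, 1))
  r <- drug_rank(two)
  expect_equal(r$drug_rank, c(3, 6))
  expect_equal(r$compound_id, c("best", "worst"))
  # invariant to input order
  expect_equal(drug_rank(two[2:1, ])$drug_rank, c(3, 6))
})

pass_fixture <- function() {
  rows <- rbind(
    data.frame(compound_id = "ok", activity_name = c("m1", "m2", "eff", "tox"),
               activity_class = c("mechanism", "mechanism", "disease_effect",
                                  "toxicity"),
               pa = c(0.8, 0.7, 0.6, 0.2),
               mapped_genes = c("PRMT1", "ITGAV", "", "")),
    data.frame(compound_id = "one_target",
               activity_name = c("m1", "eff"),
               activity_class = c("mechanism", "disease_effect"),
               pa = c(0.9, 0.9), mapped_genes = c("PRMT1", "")),
    data.frame(compound_id = "toxic", activity_name = c("m1", "m2", "tox"),
               activity_class = c("mechanism", "mechanism", "toxicity"),
               pa = c(0.9, 0.9, 0.95), mapped_genes = c("PRMT1", "STAT3", "")),
    data.frame(compound_id = "weak_eff",
               activity_name = c("m1", "m2", "eff"),
               activity_class = c("mechanism", "mechanism", "disease_effect"),
               pa = c(0.9, 0.8, 0.2), mapped_genes = c("PRMT1", "STAT3", "")),
    data.frame(compound_id = "no_tox_row",
               activity_name = c("m1", "m2"),
               activity_class = "mechanism",
               pa = c(0.6, 0.9), mapped_genes = c("ITGAV", "ITGB6")))
  rows$activity_name[rows$activity_name == "eff"] <- "nephropathy"
  compound_activity_table(rows,
                          data.frame(gene = c("PRMT1", "ITGAV"),
                                     iap = c(0.9, 1), opt_weight = c(1, 2)))
}

test_that("filter_predicted applies the three strict-threshold clauses", {
  ct <- pass_fixture()
  res <- filter_predicted(ct, tox_threshold = 0.5, effect_threshold = 0.5,
                          target_threshold = 0.5, diseases = "nephropathy")
  got <- setNames(res$passes_filter, res$compound_id)
  expect_true(got[["ok"]])
  expect_false(got[["one_target"]])     # fewer than 2 targets
  expect_false(got[["toxic"]])          # toxicity 0.95 >= 0.5
  expect_false(got[["weak_eff"]])       # matched effect Pa 0.2 <= 0.5
  expect_true(got[["no_tox_row"]])      # toxicity score 0 < any threshold > 0
  expect_equal(res$toxicity_score[res$compound_id == "no_tox_row"], 0)
  expect_equal(res$disease_activity_score[res$compound_id == "ok"], 0.6)

  # boundary semantics: permissive thresholds pass every >=2-target compound
  all_pass <- filter_predicted(ct, 1, 0, 0, diseases = "nephropathy")
  expect_equal(setNames(all_pass$passes_filter, all_pass$compound_id)[
    c("ok", "toxic", "weak_eff", "no_tox_row")],
    c(ok = TRUE, toxic = TRUE, weak_eff = TRUE, no_tox_row = TRUE))
  expect_false(all_pass$passes_filter[all_pass$compound_id == "one_target"])
})

test_that("t_score_pass and d_score_pass evaluate the printed formulas", {
  # one mechanism pa .5, gene iap 1, weight 1, |T| = |AT| -> 0.5
  simple <- compound_activity_table(
    data.frame(compound_id = "s", activity_name = "m",
               activity_class = "mechanism", pa = 0.5, mapped_genes = "G"),
    data.frame(gene = "G", iap = 1, opt_weight = 1))
  expect_equal(t_score_pass("s", simple, "G", target_threshold = 0.2), 0.5,
               tolerance = 1e-12)
  # pa == threshold is excluded (strict inequality as printed)
  expect_error(t_score_pass("s", simple, "G", target_threshold = 0.5),
               "T empty")

  zero_iap <- compound_activity_table(
    simple$rows, data.frame(gene = "G", iap = 0, opt_weight = 1))
  expect_equal(t_score_pass("s", zero_iap, "G", target_threshold = 0.2), 0)

  # 2-mechanism toy vs hand recomputation
  ct <- pass_fixture()
  got <- t_score_pass("ok", ct, c("PRMT1", "ITGAV"), target_threshold = 0.5,
                      w = 1)
  want <- (2 / 2) * (0.8 * (0.9 * 1) + 0.7 * (1 * 2))
  expect_equal(got, want, tolerance = 1e-9)
  expect_error(t_score_pass("ok", ct, "UNRELATED"), "T empty")

  # d_score_pass: IAP * sum of mechanism Pa over passing structures
  expect_equal(d_score_pass("PRMT1", ct, c("ok", "toxic")),
               0.9 * (0.8 + 0.9), tolerance = 1e-9)
  expect_equal(d_score_pass("PRMT1", ct, character()), 0)
  # additivity over disjoint structure sets
  expect_equal(d_score_pass("PRMT1", ct, "ok") +
                 d_score_pass("PRMT1", ct, "toxic"),
               d_score_pass("PRMT1", ct, c("ok", "toxic")),
               tolerance = 1e-12)
})

test_that("curated druggability counts distinct compounds", {
  tt <- trial_fixture()
  expect_equal(curated_druggability("PRMT1", tt), 2L)
  expect_equal(curated_druggability("ITGAL", tt), 0L)
})
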