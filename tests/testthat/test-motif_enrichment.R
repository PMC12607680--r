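# PWM scoring, scanning, and Yes/No enrichment.

test_that("normalized score hits its extremes and matches the oracle", {
  withr::local_seed(21)
  counts <- matrix(sample(1:30, 32, replace = TRUE), 8, 4)
  m <- pw_matrix("M1", counts, "TFX")
  bases <- c("A", "C", "G", "T")
  cons <- paste(bases[apply(m$counts, 1, which.max)], collapse = "")
  anti <- paste(bases[apply(m$counts, 1, which.min)], collapse = "")
  expect_equal(normalized_pwm_score(m, cons), 1.0)
  expect_equal(normalized_pwm_score(m, anti), 0.0)
  for (w in random_dna(10, 8))
    expect_equal(normalized_pwm_score(m, w), oracle_pwm_score(m, w))
  # N contributes the expected weight; score stays in [0, 1]
  withN <- random_dna(1, 8); substr(withN, 3, 3) <- "N"
  sN <- normalized_pwm_score(m, withN)
  expect_gte(sN, 0); expect_lte(sN, 1)
  expect_equal(sN, oracle_pwm_score(m, withN))
  expect_error(normalized_pwm_score(m, "ACGT"), "length")
})

test_that("scanning counts windows and matches the exhaustive oracle", {
  withr::local_seed(22)
  m <- toy_pwm("M1", "ACGTACGTAC")
  seq1100 <- random_dna(1, 1100)
  hits <- scan_promoter(m, seq1100, cutoff = 0)
  expect_equal(nrow(hits), 2L * (1100L - 10L + 1L))
  expect_true(all(hits$start + 10 <= 1100))

  allN <- strrep("N", 1100)
  expect_equal(nrow(scan_promoter(m, allN, cutoff = 1.0)), 0L)

  for (i in 1:5) {
    s <- random_dna(1, 60)
    got <- scan_promoter(m, s, cutoff = 0.6)
    want <- oracle_scan(m, s, 0.6)
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$norm_score, want$norm_score)
  }
})

test_that("raising the cutoff never increases match counts", {
  withr::local_seed(23)
  m <- toy_pwm("M1", "TTGACA")
  s <- random_dna(1, 500)
  counts <- vapply(seq(0.5, 0.95, by = 0.05),
                   function(co) nrow(scan_promoter(m, s, cutoff = co)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("enrichment: identical sets are null, Fisher matches hypergeometric", {
  withr::local_seed(24)
  lib <- list(toy_pwm("M1", "ACGTAC"), toy_pwm("M2", "GGATCC"))
  seqs <- random_dna(6, 1100)
  same <- promoter_set(sprintf("g%d", 1:12), rep(seqs, 2),
                       rep(c("yes", "no"), each = 6))
  enr <- enrich_matrices(lib, same)
  expect_true(all(enr$yes_no_ratio[is.finite(enr$yes_no_ratio)] == 1))
  expect_true(all(!enr$enriched))
  expect_true(all(enr$adj_p >= enr$p_value))

  # toy 2x2: 8 sites / 1000 windows yes vs 1 / 1000 no
  p_pkg <- phyper(8 - 1, 9, 1991, 1000, lower.tail = FALSE)
  p_orc <- oracle_fisher_greater(8, 992, 1, 999)
  expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  expect_equal(p_pkg, fisher.test(matrix(c(8, 992, 1, 999), 2, byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-9)
})

test_that("enrichment is strand-symmetric and recovers implants", {
  spec <- synthetic_spec(seed = 31)          # stated world: 50 yes / 50 no
  lib <- gen_pwm_library(spec)
  ps <- gen_promoters(spec, lib)
  enr <- enrich_matrices(lib, ps)
  planted <- paste0("M_", spec$planted_tfs)
  expect_true(all(enr$enriched[enr$matrix_id %in% planted]))
  expect_true(all(enr$yes_no_ratio[enr$matrix_id %in% planted] > 1))

  rc <- promoter_set(ps$gene_id,
                     vapply(ps$sequence, oracle_revcomp, "",
                            USE.NAMES = FALSE),
                     ps$label)
  enr_rc <- enrich_matrices(lib, rc)
  ord <- order(enr$matrix_id); ord_rc <- order(enr_rc$matrix_id)
  expect_equal(enr$yes_sites[ord], enr_rc$yes_sites[ord_rc])
  expect_equal(enr$p_value[ord], enr_rc$p_value[ord_rc])

  # binomial alternative agrees on direction
  enb <- enrich_matrices(lib, ps, test = "binomial")
  expect_true(all(enb$enriched[enb$matrix_id %in% planted]))

  # background set replaces the No contrast for testing only
  bg <- promoter_set(paste0("b", seq_len(sum(ps$label == "no"))),
                     ps$sequence[ps$label == "no"],
                     rep("no", sum(ps$label == "no")))
  enr_bg <- enrich_matrices(lib, ps, background = bg)
  expect_true(all(enr_bg$enriched[enr_bg$matrix_id %in% planted]))
})

test_that("site_dump reports 0-based half-open intervals", {
  m <- toy_pwm("M1", "ACGTACG")
  ps <- promoter_set("g1", paste0(strrep("T", 40), "ACGTACG",
                                  strrep("T", 1053)), "yes")
  dump <- site_dump(list(m), ps, cutoff = 0.99)
  expect_true(any(dump$start == 40 & dump$end == 47 & dump$strand == "+"))
})
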