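# Composite modules: scoring, Wilcoxon separation, GA search.

toy_lib <- function() list(toy_pwm("MA", "ACGTCA", tf = "TFA"),
                           toy_pwm("MB", "GGATCC", tf = "TFB"),
                           toy_pwm("MC", "TTAACG", tf = "TFC"))

test_that("composite_module validates its invariants", {
  slots <- data.frame(matrix_id = "MA", weight = 1, slot_cutoff = 0.8,
                      max_sites = 1)
  expect_s3_class(composite_module(slots, 200), "CompositeModule")
  expect_error(composite_module(slots, 150), "window_len")
  expect_error(composite_module(slots[0, ], 250), "slots")
  expect_error(composite_module(do.call(rbind, replicate(11, slots,
                                                         simplify = FALSE)),
                                250), "slots")
  bad <- slots; bad$weight <- -1
  expect_error(composite_module(bad, 250), "weight")
})

test_that("module_score matches direct site arithmetic and the oracle", {
  withr::local_seed(41)
  lib <- toy_lib()
  # single slot, weight 1: score equals the best single-site norm score
  s <- random_dna(1, 400)
  mod1 <- composite_module(data.frame(matrix_id = "MA", weight = 1,
                                      slot_cutoff = 0.5, max_sites = 1), 250)
  hits <- scan_promoter(lib[[1]], s, cutoff = 0.5)
  expect_equal(module_score(mod1, s, lib), max(hits$norm_score))

  # all weights zero: score 0
  mod0 <- composite_module(data.frame(matrix_id = c("MA", "MB"), weight = 0,
                                      slot_cutoff = 0.5, max_sites = 2), 250)
  expect_equal(module_score(mod0, s, lib), 0)

  # 3-slot module on 400 bp toys: equals exhaustive window enumeration
  mod3 <- composite_module(data.frame(matrix_id = c("MA", "MB", "MC"),
                                      weight = c(1, 0.5, 2),
                                      slot_cutoff = c(0.6, 0.7, 0.65),
                                      max_sites = c(2, 1, 3)), 220)
  for (i in 1:4) {
    si <- random_dna(1, 400)
    expect_equal(module_score(mod3, si, lib),
                 oracle_module_score(mod3, si, lib))
  }
  expect_error(module_score(mod3, random_dna(1, 100), lib), "shorter")
})

test_that("cached GA scoring equals the public module_score", {
  withr::local_seed(42)
  lib <- toy_lib()
  ps <- toy_promoter_set(lib, n_yes = 6, n_no = 6, width = 400)
  cfg <- cma_config(seed = 1, cutoff_grid = c(0.6, 0.8),
                    window_grid = c(200L, 250L), init_cutoff = 0.8,
                    init_window = 250L)
  ctx <- transomic:::cma_context(lib, ps, cfg)
  mod <- composite_module(data.frame(matrix_id = c("MA", "MC"),
                                     weight = c(1.5, 1),
                                     slot_cutoff = c(0.6, 0.8),
                                     max_sites = c(2, 1)), 200)
  cached <- transomic:::module_scores_ctx(ctx, mod)
  direct <- vapply(ps$sequence, function(s) module_score(mod, s, lib), 1,
                   USE.NAMES = FALSE)
  expect_equal(cached, direct)
})

test_that("separation_p: exact enumeration, ties, approximation, null", {
  expect_equal(separation_p(c(3, 4, 5), c(0, 1, 2)), 1 / 20)
  expect_equal(separation_p(c(0, 1, 2), c(3, 4, 5)), 1)
  expect_gte(separation_p(c(1, 2, 3), c(1, 2, 3)), 0.5)

  # exact path agrees with wilcox.test where the latter is exact (no ties)
  withr::local_seed(43)
  for (i in 1:5) {
    y <- rnorm(6); n <- rnorm(8)
    expect_equal(separation_p(y, n),
                 wilcox.test(y, n, alternative = "greater",
                             exact = TRUE)$p.value)
  }

  # permutation null of the approximate path is near-uniform
  pooled <- rnorm(40)
  ps <- vapply(1:400, function(i) {
    lab <- sample(rep(c(TRUE, FALSE), 20))
    separation_p(pooled[lab], pooled[!lab])
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
})

test_that("GA is deterministic, elite-monotone, and beats its baselines", {
  withr::local_seed(44)
  lib <- toy_lib()
  ps <- toy_promoter_set(lib, n_yes = 8, n_no = 8, width = 400)
  cfg <- cma_config(population_size = 14, n_generations = 6, seed = 9,
                    window_grid = c(200L, 250L), init_window = 250L)
  r1 <- fit_cma(lib, ps, cfg)
  r2 <- fit_cma(lib, ps, cfg)
  expect_identical(r1$module, r2$module)
  expect_identical(r1$wilcoxon_p, r2$wilcoxon_p)
  expect_true(all(diff(r1$fitness_trace) >= 0))
  expect_equal(length(r1$yes_scores), 8L)
  expect_lte(r1$wilcoxon_p,
             min(single_matrix_separation(lib, ps, cfg)))
  expect_error(fit_cma(list(), ps, cfg), "non-empty")
})

test_that("regulatory scores are drop-one contributions", {
  withr::local_seed(45)
  lib <- toy_lib()
  ps <- toy_promoter_set(lib, n_yes = 8, n_no = 8, width = 400)
  cfg <- cma_config(population_size = 12, n_generations = 4, seed = 2,
                    window_grid = c(200L, 250L), init_window = 250L)
  res <- fit_cma(lib, ps, cfg)
  in_mod <- unique(res$module$slots$matrix_id)
  tf_in <- c(TFA = "MA", TFB = "MB", TFC = "MC")
  for (tf in names(tf_in)) {
    if (!tf_in[[tf]] %in% in_mod)
      expect_equal(regulatory_score(res, tf), 0)
    else
      expect_gte(regulatory_score(res, tf), 0)
  }
  expect_error(regulatory_score(res, "NOPE"), "unknown TF")

  # single-slot module: drop-one equals full -log10 p minus empty baseline
  ctx <- transomic:::cma_context(lib, ps, cfg)
  mod1 <- composite_module(data.frame(matrix_id = "MA", weight = 1,
                                      slot_cutoff = 0.85, max_sites = 3), 250)
  full <- transomic:::module_neglogp(ctx, mod1)
  empty <- -log10(separation_p(rep(0, 8), rep(0, 8)))
  reg <- transomic:::tf_regulatory_scores(ctx, mod1)
  expect_equal(unname(reg["TFA"]), max(0, full - empty))
})

test_that("module JSON round-trips", {
  mod <- composite_module(data.frame(matrix_id = c("MA", "MB"),
                                     weight = c(1, 0.25),
                                     slot_cutoff = c(0.8, 0.9),
                                     max_sites = c(1L, 3L)), 300)
  f <- withr::local_tempfile(fileext = ".json")
  write_module_json(mod, f)
  back <- read_module_json(f)
  expect_equal(back$slots$weight, mod$slots$weight)
  expect_equal(back$window_len, mod$window_len)
})
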