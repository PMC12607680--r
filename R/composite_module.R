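# Composite-module search: a weighted cluster of up to 10 PWM slots
# constrained to co-occur inside a sliding window, optimized by a genetic
# algorithm to separate Yes from No promoter score distributions
# (minimizing a one-sided Wilcoxon rank-sum p-value).

#' Construct a composite module
#'
#' A module is a set of 1-10 slots, each naming a matrix with a non-negative
#' weight, its own score cutoff and a cap on how many matches are counted,
#' plus a window length in 200-300 bp. A promoter's module score is the
#' best window score over all window placements; a window scores the
#' weighted sum over slots of the top `max_sites` match scores inside it.
#'
#' @param slots Data frame with columns `matrix_id`, `weight` (>= 0),
#'   `slot_cutoff` in `[0,1]`, `max_sites` (>= 1).
#' @param window_len Integer window length in `[200, 300]`.
#' @return Object of class `CompositeModule`.
#' @export
composite_module <- function(slots, window_len = 250L) {
  slots <- as.data.frame(slots, stringsAsFactors = FALSE)
  need <- c("matrix_id", "weight", "slot_cutoff", "max_sites")
  assert_that(all(need %in% names(slots)), "slots needs columns: %s",
              paste(need, collapse = ", "))
  assert_that(nrow(slots) >= 1 && nrow(slots) <= 10,
              "a module has between 1 and 10 slots")
  assert_that(all(slots$weight >= 0), "slot weights must be >= 0")
  assert_that(all(slots$slot_cutoff >= 0 & slots$slot_cutoff <= 1),
              "slot cutoffs must be in [0,1]")
  assert_that(all(slots$max_sites >= 1), "max_sites must be >= 1")
  window_len <- as.integer(window_len)
  assert_that(window_len >= 200 && window_len <= 300,
              "window_len must be in [200, 300]")
  structure(list(slots = slots, window_len = window_len),
            class = "CompositeModule")
}

#' @export
print.CompositeModule <- function(x, ...) {
  cat(sprintf("CompositeModule: %d slot(s), window %d bp\n",
              nrow(x$slots), x$window_len))
  print(x$slots)
  invisible(x)
}

#' Serialize / deserialize a composite module as JSON
#' @param module A `CompositeModule`.
#' @param path Output path.
#' @return `path` invisibly (write) or the module (read).
#' @export
write_module_json <- function(module, path) {
  stopifnot(inherits(module, "CompositeModule"))
  jsonlite::write_json(list(slots = module$slots,
                            window_len = module$window_len),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_module_json
#' @export
read_module_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  composite_module(x$slots, x$window_len)
}

# Sum of the top-k values of a numeric vector.
#' @noRd
top_k_sum <- function(x, k) {
  if (length(x) <= k) sum(x) else
    sum(sort(x, decreasing = TRUE, method = "quick")[seq_len(k)])
}

#' Score one promoter with a composite module
#'
#' Window starts slide from the 5' end by `stride` bp; each window scores
#' `sum_slots weight * top_max_sites(matches fully inside window)` and the
#' promoter score is the maximum over windows. A site counts for a window
#' only when the full match interval lies inside it.
#'
#' @param module A [composite_module()].
#' @param sequence Promoter sequence (length >= `window_len`).
#' @param pwm_library Library containing every slot's matrix.
#' @param stride Window stride in bp (default 10).
#' @param pseudocount PWM smoothing constant.
#' @return Numeric promoter score (>= 0).
#' @export
module_score <- function(module, sequence, pwm_library, stride = 10L,
                         pseudocount = 0.01) {
  stopifnot(inherits(module, "CompositeModule"))
  len <- nchar(sequence)
  assert_that(len >= module$window_len,
              "sequence shorter than module window")
  lib_ids <- vapply(pwm_library, `[[`, "", "matrix_id")
  ws <- seq.int(0L, len - module$window_len, by = stride)
  win_scores <- numeric(length(ws))
  for (si in seq_len(nrow(module$slots))) {
    slot <- module$slots[si, ]
    if (slot$weight == 0) next
    mi <- match(slot$matrix_id, lib_ids)
    if (is.na(mi)) to_abort("slot matrix %s not in library", slot$matrix_id)
    L <- nrow(pwm_library[[mi]]$counts)
    hits <- scan_promoter(pwm_library[[mi]], sequence,
                          cutoff = slot$slot_cutoff,
                          pseudocount = pseudocount)
    for (wi in seq_along(ws)) {
      w <- ws[wi]
      inside <- hits$start >= w & hits$start + L <= w + module$window_len
      if (any(inside))
        win_scores[wi] <- win_scores[wi] +
          slot$weight * top_k_sum(hits$norm_score[inside], slot$max_sites)
    }
  }
  if (!length(win_scores)) 0 else max(win_scores)
}

#' One-sided Wilcoxon rank-sum separation p-value (Yes > No)
#'
#' Mid-ranks are used for ties. When the pooled sample size is at most 20
#' the exact permutation distribution of the rank sum is enumerated;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param yes_scores,no_scores Non-empty numeric vectors.
#' @return p-value in `(0, 1]`.
#' @export
separation_p <- function(yes_scores, no_scores) {
  assert_that(length(yes_scores) > 0 && length(no_scores) > 0,
              "both score vectors must be non-empty")
  ny <- length(yes_scores); nn <- length(no_scores); N <- ny + nn
  pooled <- c(yes_scores, no_scores)
  r <- rank(pooled)
  W <- sum(r[seq_len(ny)])
  if (N <= 20) {
    combos <- utils::combn(N, ny)
    wnull <- colSums(matrix(r[combos], nrow = ny))
    p <- mean(wnull >= W - 1e-9)
  } else {
    mu <- ny * (N + 1) / 2
    ties <- table(r)
    corr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- ny * nn / 12 * ((N + 1) - corr)
    if (sigma2 <= 0) return(1)
    p <- stats::pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Genetic-algorithm configuration for the composite-module search
#'
#' @param population_size,n_generations GA schedule (defaults 100 x 50).
#' @param mutation_prob Per-field mutation probability (default 0.2).
#' @param crossover_prob Probability a child is bred by slot-level uniform
#'   crossover of two tournament winners (default 0.4); otherwise it is a
#'   mutated copy of one winner.
#' @param immigration_prob Probability a child is a fresh random module
#'   (default 0.1), keeping the population diverse.
#' @param tournament_size Tournament selection size (default 3).
#' @param lambda Parsimony penalty per slot on the fitness
#'   `-log10(p) - lambda * n_slots` (default 0.1).
#' @param stride Window stride in bp (default 10).
#' @param max_slots Slot ceiling (default 10).
#' @param cutoff_grid,window_grid,max_sites_grid Discrete grids explored by
#'   mutation for slot cutoffs, window lengths and per-slot site caps.
#' @param init_cutoff,init_window,init_max_sites Slot defaults used for the
#'   deterministic single-matrix individuals seeded into the initial
#'   population (and by [single_matrix_separation()]).
#' @param seed RNG seed; recorded in the result.
#' @param pseudocount PWM smoothing constant.
#' @return List of class `cma_config`.
#' @export
cma_config <- function(population_size = 100L, n_generations = 50L,
                       mutation_prob = 0.2, crossover_prob = 0.4,
                       immigration_prob = 0.1, tournament_size = 3L,
                       lambda = 0.1, stride = 10L, max_slots = 10L,
                       cutoff_grid = seq(0.75, 0.95, by = 0.05),
                       window_grid = c(200L, 250L, 300L),
                       max_sites_grid = 1:3,
                       init_cutoff = 0.85, init_window = 250L,
                       init_max_sites = 3L, seed = 1L, pseudocount = 0.01) {
  assert_that(all(window_grid >= 200 & window_grid <= 300),
              "window_grid must lie in [200, 300]")
  assert_that(init_cutoff %in% cutoff_grid && init_window %in% window_grid &&
              init_max_sites %in% max_sites_grid,
              "init slot parameters must lie on the mutation grids")
  assert_that(crossover_prob + immigration_prob <= 1,
              "crossover_prob + immigration_prob must be <= 1")
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 mutation_prob = mutation_prob,
                 crossover_prob = crossover_prob,
                 immigration_prob = immigration_prob,
                 tournament_size = as.integer(tournament_size),
                 lambda = lambda, stride = as.integer(stride),
                 max_slots = as.integer(max_slots),
                 cutoff_grid = cutoff_grid,
                 window_grid = as.integer(window_grid),
                 max_sites_grid = as.integer(max_sites_grid),
                 init_cutoff = init_cutoff,
                 init_window = as.integer(init_window),
                 init_max_sites = as.integer(init_max_sites),
                 seed = as.integer(seed), pseudocount = pseudocount),
            class = "cma_config")
}

# --- evaluation context with memoised slot-score matrices -------------------

# Pre-scans every matrix over every promoter once (at the lowest grid
# cutoff) and memoises, per (matrix, cutoff, max_sites, window_len), the
# n_promoters x n_windows matrix of top-k in-window score sums. Module
# fitness then reduces to a weighted sum of cached matrices plus a row max.
#' @noRd
cma_context <- function(pwm_library, promoters, config) {
  stopifnot(inherits(promoters, "PromoterSet"))
  int_mat <- promoter_int_matrix(promoters)
  base_cut <- min(config$cutoff_grid)
  lib_ids <- vapply(pwm_library, `[[`, "", "matrix_id")
  prescan <- lapply(pwm_library, function(m) {
    cp <- compile_pwm(m, config$pseudocount)
    per_prom <- vector("list", nrow(int_mat))
    for (strand in c("+", "-")) {
      sc <- scan_scores_matrix(cp, int_mat, strand)
      hit <- which(sc >= base_cut, arr.ind = TRUE)
      if (nrow(hit)) {
        sp <- split(data.frame(start = hit[, 2] - 1L,
                               score = sc[hit]), hit[, 1])
        for (nm in names(sp)) {
          i <- as.integer(nm)
          per_prom[[i]] <- rbind(per_prom[[i]], sp[[nm]])
        }
      }
    }
    per_prom <- lapply(per_prom, function(d) {
      if (is.null(d)) data.frame(start = integer(), score = numeric()) else
        d[order(d$start), , drop = FALSE]
    })
    list(L = cp$L, matches = per_prom)
  })
  names(prescan) <- lib_ids
  list(library = pwm_library, lib_ids = lib_ids,
       tf_map = library_tf_map(pwm_library),
       yes = which(promoters$label == "yes"),
       no = which(promoters$label == "no"),
       gene_id = promoters$gene_id,
       n_prom = length(promoters$gene_id), width = promoters$width,
       prescan = prescan, config = config, cache = new.env(parent = emptyenv()))
}

#' @noRd
slot_score_matrix <- function(ctx, matrix_id, cutoff, k, wlen) {
  key <- paste(matrix_id, format(cutoff), k, wlen, sep = "|")
  cached <- ctx$cache[[key]]
  if (!is.null(cached)) return(cached)
  ps <- ctx$prescan[[matrix_id]]
  if (is.null(ps)) to_abort("matrix %s not in CMA context", matrix_id)
  ws <- seq.int(0L, ctx$width - wlen, by = ctx$config$stride)
  S <- matrix(0, ctx$n_prom, length(ws))
  for (i in seq_len(ctx$n_prom)) {
    m <- ps$matches[[i]]
    if (!nrow(m)) next
    keep <- m$score >= cutoff
    if (!any(keep)) next
    s0 <- m$start[keep]; sc <- m$score[keep]
    lo <- findInterval(ws - 0.5, s0) + 1L
    hi <- findInterval(ws + wlen - ps$L + 0.5, s0)
    for (wi in which(hi >= lo)) {
      S[i, wi] <- top_k_sum(sc[lo[wi]:hi[wi]], k)
    }
  }
  ctx$cache[[key]] <- S
  S
}

# Promoter scores of a module under a context: weighted slot matrices
# summed, then row max over window starts.
#' @noRd
module_scores_ctx <- function(ctx, module) {
  acc <- NULL
  for (si in seq_len(nrow(module$slots))) {
    slot <- module$slots[si, ]
    if (slot$weight == 0) next
    S <- slot_score_matrix(ctx, slot$matrix_id, slot$slot_cutoff,
                           slot$max_sites, module$window_len)
    acc <- if (is.null(acc)) slot$weight * S else acc + slot$weight * S
  }
  if (is.null(acc)) return(numeric(ctx$n_prom))
  apply(acc, 1, max)
}

#' @noRd
module_neglogp <- function(ctx, module) {
  sc <- module_scores_ctx(ctx, module)
  -log10(separation_p(sc[ctx$yes], sc[ctx$no]))
}

# --- GA machinery -----------------------------------------------------------

#' @noRd
random_slot <- function(ctx) {
  cfg <- ctx$config
  data.frame(matrix_id = sample(ctx$lib_ids, 1),
             weight = stats::runif(1, 0.2, 2),
             slot_cutoff = sample(cfg$cutoff_grid, 1),
             max_sites = sample(cfg$max_sites_grid, 1),
             stringsAsFactors = FALSE)
}

#' @noRd
random_module <- function(ctx) {
  cfg <- ctx$config
  n <- sample(seq_len(min(4L, cfg$max_slots)), 1)
  composite_module(do.call(rbind, replicate(n, random_slot(ctx),
                                            simplify = FALSE)),
                   sample(cfg$window_grid, 1))
}

#' @noRd
mutate_module <- function(ctx, module) {
  cfg <- ctx$config
  slots <- module$slots
  wlen <- module$window_len
  for (si in seq_len(nrow(slots))) {
    if (stats::runif(1) < cfg$mutation_prob)
      slots$weight[si] <- slots$weight[si] * exp(stats::rnorm(1, 0, 0.4))
    if (stats::runif(1) < cfg$mutation_prob)
      slots$slot_cutoff[si] <- sample(cfg$cutoff_grid, 1)
    if (stats::runif(1) < cfg$mutation_prob)
      slots$max_sites[si] <- sample(cfg$max_sites_grid, 1)
    if (stats::runif(1) < cfg$mutation_prob / 2)
      slots$matrix_id[si] <- sample(ctx$lib_ids, 1)
  }
  if (stats::runif(1) < cfg$mutation_prob)
    wlen <- sample(cfg$window_grid, 1)
  if (stats::runif(1) < cfg$mutation_prob && nrow(slots) < cfg$max_slots)
    slots <- rbind(slots, random_slot(ctx))
  if (stats::runif(1) < cfg$mutation_prob && nrow(slots) > 1)
    slots <- slots[-sample(nrow(slots), 1), , drop = FALSE]
  composite_module(slots, wlen)
}

# Slot-level uniform crossover: the child inherits each slot of the
# pooled parents with probability 1/2 (at least one, at most max_slots)
# and one parent's window length. This is the operator that combines two
# good single-motif individuals into a composite module.
#' @noRd
crossover_modules <- function(ctx, a, b) {
  pool <- rbind(a$slots, b$slots)
  keep <- stats::runif(nrow(pool)) < 0.5
  if (!any(keep)) keep[sample.int(nrow(pool), 1)] <- TRUE
  if (sum(keep) > ctx$config$max_slots)
    keep[sample(which(keep), sum(keep) - ctx$config$max_slots)] <- FALSE
  composite_module(pool[keep, , drop = FALSE],
                   if (stats::runif(1) < 0.5) a$window_len else b$window_len)
}

#' Fit a composite module by genetic-algorithm search
#'
#' The GA evolves `CompositeModule` genomes by tournament selection,
#' slot-level uniform crossover, per-field mutation, random immigration
#' and single-individual elitism; fitness is
#' `-log10(separation p) - lambda * n_slots`. The initial population is
#' seeded with one deterministic single-slot individual per library matrix
#' (at the init slot defaults), so the best module found can never be worse
#' than the best single matrix under those defaults. The best individual
#' ever seen is returned together with its per-promoter scores and per-TF
#' regulatory scores (drop-one contribution to `-log10 p`, floored at 0).
#'
#' @param pwm_library List of [pw_matrix()] objects (the slot alphabet).
#' @param promoters A [promoter_set()] with non-empty Yes and No subsets.
#' @param ga_config A [cma_config()].
#' @return Object of class `CMAResult`: `module`, `wilcoxon_p`,
#'   `yes_scores`, `no_scores` (named by gene), `tf_regulatory_scores`,
#'   `fitness_trace`, `generations_run`, `seed`.
#' @export
fit_cma <- function(pwm_library, promoters, ga_config = cma_config()) {
  stopifnot(inherits(ga_config, "cma_config"))
  assert_that(length(pwm_library) >= 1, "library must be non-empty")
  assert_that(any(promoters$label == "yes") && any(promoters$label == "no"),
              "Yes and No subsets must be non-empty")
  withr::with_seed(ga_config$seed, {
    ctx <- cma_context(pwm_library, promoters, ga_config)
    cfg <- ga_config
    # deterministic single-matrix individuals first, then random fill
    pop <- lapply(ctx$lib_ids, function(id)
      composite_module(data.frame(matrix_id = id, weight = 1,
                                  slot_cutoff = cfg$init_cutoff,
                                  max_sites = cfg$init_max_sites,
                                  stringsAsFactors = FALSE),
                       cfg$init_window))
    if (length(pop) > cfg$population_size)
      pop <- pop[seq_len(cfg$population_size)]
    while (length(pop) < cfg$population_size)
      pop[[length(pop) + 1L]] <- random_module(ctx)
    fitness_of <- function(mod)
      module_neglogp(ctx, mod) - cfg$lambda * nrow(mod$slots)
    fit <- vapply(pop, fitness_of, numeric(1))
    best_i <- which.max(fit)
    best <- list(module = pop[[best_i]], fitness = fit[best_i])
    trace <- numeric(cfg$n_generations)
    tournament <- function() {
      cand <- sample.int(length(pop), cfg$tournament_size)
      pop[[cand[which.max(fit[cand])]]]
    }
    for (gen in seq_len(cfg$n_generations)) {
      nxt <- list(best$module)                     # elitism of 1
      while (length(nxt) < cfg$population_size) {
        u <- stats::runif(1)
        child <- if (u < cfg$crossover_prob) {
          crossover_modules(ctx, tournament(), tournament())
        } else if (u < cfg$crossover_prob + cfg$immigration_prob) {
          random_module(ctx)
        } else {
          tournament()
        }
        nxt[[length(nxt) + 1L]] <- mutate_module(ctx, child)
      }
      pop <- nxt
      fit <- vapply(pop, fitness_of, numeric(1))
      gi <- which.max(fit)
      if (fit[gi] > best$fitness)
        best <- list(module = pop[[gi]], fitness = fit[gi])
      trace[gen] <- best$fitness
    }
    scores <- module_scores_ctx(ctx, best$module)
    p <- separation_p(scores[ctx$yes], scores[ctx$no])
    reg <- tf_regulatory_scores(ctx, best$module)
    structure(list(module = best$module, wilcoxon_p = p,
                   yes_scores = stats::setNames(scores[ctx$yes],
                                                ctx$gene_id[ctx$yes]),
                   no_scores = stats::setNames(scores[ctx$no],
                                               ctx$gene_id[ctx$no]),
                   tf_regulatory_scores = reg,
                   fitness = best$fitness, fitness_trace = trace,
                   generations_run = cfg$n_generations,
                   seed = cfg$seed, config = cfg,
                   library_tfs = unique(ctx$tf_map$tf_symbol)),
              class = "CMAResult")
  })
}

#' @export
print.CMAResult <- function(x, ...) {
  cat(sprintf(
    "CMAResult: %d-slot module, window %d bp, Wilcoxon p = %.3g (seed %d)\n",
    nrow(x$module$slots), x$module$window_len, x$wilcoxon_p, x$seed))
  invisible(x)
}

# Drop-one regulatory score per TF symbol of the library: the loss in
# -log10(separation p) when all slots whose matrix maps to the TF are
# removed, floored at 0. A module stripped of all slots scores every
# promoter 0 (no separation).
#' @noRd
tf_regulatory_scores <- function(ctx, module) {
  full <- module_neglogp(ctx, module)
  baseline_p <- separation_p(rep(0, length(ctx$yes)), rep(0, length(ctx$no)))
  empty_neglogp <- -log10(baseline_p)
  tf_all <- unique(ctx$tf_map$tf_symbol)
  out <- stats::setNames(numeric(length(tf_all)), tf_all)
  for (tf in tf_all) {
    mats <- ctx$tf_map$matrix_id[ctx$tf_map$tf_symbol == tf]
    drop <- module$slots$matrix_id %in% mats
    if (!any(drop)) next
    reduced <- if (all(drop)) empty_neglogp else
      module_neglogp(ctx, composite_module(
        module$slots[!drop, , drop = FALSE], module$window_len))
    out[tf] <- max(0, full - reduced)
  }
  out
}

#' Regulatory score of one transcription factor in a fitted module
#'
#' The drop-one contribution of the TF to the module's separation: the
#' decrease in `-log10(Wilcoxon p)` when every slot whose matrix maps to
#' the TF is removed, floored at 0. TFs in the library but absent from the
#' module score 0; a TF unknown to the library is an error.
#'
#' @param cma_result A `CMAResult` from [fit_cma()].
#' @param tf_symbol Gene symbol of the TF.
#' @return Non-negative numeric score.
#' @export
regulatory_score <- function(cma_result, tf_symbol) {
  stopifnot(inherits(cma_result, "CMAResult"))
  if (!tf_symbol %in% cma_result$library_tfs)
    to_abort("unknown TF symbol: %s", tf_symbol)
  unname(cma_result$tf_regulatory_scores[tf_symbol])
}

#' Separation p-value of every single matrix used alone
#'
#' Scores each promoter with a one-slot module (weight 1, the init slot
#' defaults of `ga_config`) per library matrix and returns the Wilcoxon
#' separation p-values. This is the baseline the GA initial population is
#' seeded from.
#'
#' @param pwm_library Matrix library.
#' @param promoters A `PromoterSet`.
#' @param ga_config A [cma_config()].
#' @return Named numeric vector of p-values (by matrix_id).
#' @export
single_matrix_separation <- function(pwm_library, promoters,
                                     ga_config = cma_config()) {
  ctx <- cma_context(pwm_library, promoters, ga_config)
  ps <- vapply(ctx$lib_ids, function(id) {
    mod <- composite_module(data.frame(matrix_id = id, weight = 1,
                                       slot_cutoff = ga_config$init_cutoff,
                                       max_sites = ga_config$init_max_sites,
                                       stringsAsFactors = FALSE),
                            ga_config$init_window)
    sc <- module_scores_ctx(ctx, mod)
    separation_p(sc[ctx$yes], sc[ctx$no])
  }, numeric(1))
  ps
}

#' Label-permutation null of the optimized separation statistic
#'
#' Optimizing a module and then testing it on the same promoters inflates
#' the nominal Wilcoxon p; this calibration refits the GA on
#' label-permuted copies of the promoter set and returns the null
#' distribution of the optimized `-log10 p`, plus a smoothed empirical p
#' for the observed statistic.
#'
#' @param pwm_library Matrix library.
#' @param promoters A `PromoterSet`.
#' @param ga_config A [cma_config()]; permutation `i` runs with seed
#'   derived from `ga_config$seed` and `i`.
#' @param n_permutations Number of label permutations (default 50).
#' @param observed Optional observed `-log10 p` to calibrate (e.g.
#'   `-log10(result$wilcoxon_p)`).
#' @return List with `null_stats` (numeric vector) and, when `observed` is
#'   given, `calibrated_p = (1 + #null >= observed) / (1 + n)`.
#' @export
cma_permutation_null <- function(pwm_library, promoters,
                                 ga_config = cma_config(),
                                 n_permutations = 50L, observed = NULL) {
  null_stats <- vapply(seq_len(n_permutations), function(i) {
    perm_seed <- child_seed(ga_config$seed, i)
    perm <- withr::with_seed(perm_seed, sample(promoters$label))
    pp <- promoter_set(promoters$gene_id, promoters$sequence, perm,
                       width = promoters$width)
    cfg <- ga_config
    cfg$seed <- perm_seed
    res <- fit_cma(pwm_library, pp, cfg)
    -log10(res$wilcoxon_p)
  }, numeric(1))
  out <- list(null_stats = null_stats)
  if (!is.null(observed))
    out$calibrated_p <- (1 + sum(null_stats >= observed)) /
      (1 + n_permutations)
  out
}
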