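# PWM scoring and promoter scanning, plus Yes-versus-No binding-site
# enrichment with Benjamini-Hochberg control.
#
# Scoring scheme (Match-style): per-position log-odds weights against a
# uniform 0.25 background, pseudocount-smoothed, then min-max normalized so
# the consensus scores 1 and the anti-consensus 0. An N base contributes the
# position's expected weight under the background.

# Compile a PWMatrix into a 5-row weight lookup (A,C,G,T,N) plus the
# min/max possible raw sums. Frequency matrices (row sums ~ 1) and count
# matrices are treated identically because rows are normalized first.
#' @noRd
compile_pwm <- function(m, pseudocount = 0.01) {
  stopifnot(inherits(m, "PWMatrix"))
  f <- m$counts / rowSums(m$counts)
  f <- (f + pseudocount) / (1 + 4 * pseudocount)
  w <- log2(f / 0.25)                      # L x 4
  wn <- rowMeans(w)                        # expected weight at N
  W <- cbind(w, wn)
  colnames(W) <- DNA_LEVELS
  min_sum <- sum(apply(w, 1, min))
  max_sum <- sum(apply(w, 1, max))
  if (max_sum <= min_sum)
    to_abort("matrix %s is uninformative (flat weights)", m$matrix_id)
  # reverse-complement weights: position L+1-j, complementary base
  Wrc <- W[rev(seq_len(nrow(W))), c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
  colnames(Wrc) <- DNA_LEVELS
  list(matrix_id = m$matrix_id, L = nrow(W), W = W, Wrc = Wrc,
       min_sum = min_sum, max_sum = max_sum, cutoff = m$cutoff)
}

# Normalized scores of every window on every row of an integer-encoded
# sequence matrix (n x len). Returns n x (len - L + 1).
#' @noRd
scan_scores_matrix <- function(cp, int_mat, strand = "+") {
  W <- if (strand == "+") cp$W else cp$Wrc
  n <- nrow(int_mat); len <- ncol(int_mat); L <- cp$L
  if (len < L) return(matrix(numeric(0), nrow = n, ncol = 0))
  nw <- len - L + 1L
  acc <- matrix(0, n, nw)
  for (j in seq_len(L)) {
    idx <- int_mat[, j:(j + nw - 1L), drop = FALSE]
    acc <- acc + matrix(W[j, idx], n, nw)
  }
  (acc - cp$min_sum) / (cp$max_sum - cp$min_sum)
}

#' Normalized PWM score of a single window
#'
#' The raw score is the sum over positions of the log-odds weight of the
#' observed base (pseudocount-smoothed frequencies against a uniform 0.25
#' background); the normalized score is `(raw - min) / (max - min)` where
#' min/max are the worst/best achievable raw sums, so the consensus sequence
#' scores exactly 1 and the anti-consensus exactly 0. `N` contributes the
#' position's background-expected weight.
#'
#' @param matrix A [pw_matrix()].
#' @param window_sequence Character sequence of length equal to the matrix
#'   length, over `{A,C,G,T,N}`.
#' @param pseudocount Smoothing constant added to normalized frequencies.
#' @return Normalized score in `[0, 1]` (the background-expected weight of
#'   an `N` lies between the position's minimum and maximum, so `N` windows
#'   stay in range too).
#' @export
normalized_pwm_score <- function(matrix, window_sequence, pseudocount = 0.01) {
  cp <- compile_pwm(matrix, pseudocount)
  v <- dna_to_int(window_sequence)
  if (length(v) != cp$L)
    to_abort("window length %d != matrix length %d", length(v), cp$L)
  raw <- sum(cp$W[cbind(seq_len(cp$L), v)])
  (raw - cp$min_sum) / (cp$max_sum - cp$min_sum)
}

#' Scan one promoter sequence with a PWM on both strands
#'
#' The reverse strand is scanned as the matrix's reverse complement against
#' the forward sequence, which is equivalent to scanning the
#' reverse-complemented sequence. All matches with normalized score at or
#' above the cutoff are returned; `start` is the 0-based forward-strand
#' coordinate of the leftmost base of the matched window (BED-like), for
#' either strand, so `start + L <= nchar(sequence)` always holds.
#'
#' @param matrix A [pw_matrix()].
#' @param sequence Character promoter sequence (any length >= matrix length).
#' @param cutoff Normalized-score cutoff; defaults to the matrix's own.
#' @param pseudocount Smoothing constant (see [normalized_pwm_score()]).
#' @return Data frame `matrix_id`, `start`, `strand`, `norm_score`, sorted
#'   by `start` then strand.
#' @export
scan_promoter <- function(matrix, sequence, cutoff = NULL,
                          pseudocount = 0.01) {
  cp <- compile_pwm(matrix, pseudocount)
  cutoff <- cutoff %||% cp$cutoff
  v <- matrix(dna_to_int(sequence), nrow = 1)
  hits <- list()
  for (strand in c("+", "-")) {
    sc <- scan_scores_matrix(cp, v, strand)
    keep <- which(sc[1, ] >= cutoff)
    if (length(keep))
      hits[[strand]] <- data.frame(matrix_id = cp$matrix_id,
                                   start = keep - 1L, strand = strand,
                                   norm_score = sc[1, keep],
                                   stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(matrix_id = character(), start = integer(),
               strand = character(), norm_score = numeric())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count matches >= cutoff per promoter over both strands for one compiled
# matrix; returns integer vector (n promoters).
#' @noRd
count_sites_set <- function(cp, int_mat, cutoff) {
  n <- nrow(int_mat)
  if (ncol(int_mat) < cp$L) return(integer(n))
  cnt <- integer(n)
  for (strand in c("+", "-")) {
    sc <- scan_scores_matrix(cp, int_mat, strand)
    cnt <- cnt + as.integer(rowSums(sc >= cutoff))
  }
  cnt
}

#' Test each matrix for binding-site enrichment in Yes vs No promoters
#'
#' Site counts are compared between the Yes and No sets on a 2x2 table of
#' matched windows versus scanned windows (both strands), with a one-sided
#' Fisher exact test for Yes excess (hypergeometric tail; a binomial
#' alternative is available). P-values are Benjamini-Hochberg adjusted
#' across matrices and rows are flagged `enriched` when `adj_p < alpha`.
#' Site densities are reported per kilobase of promoter sequence, and the
#' Yes-No ratio is their quotient.
#'
#' @param pwm_library List of [pw_matrix()] objects.
#' @param promoters A [promoter_set()] with non-empty Yes and No subsets.
#' @param alpha Adjusted-p threshold for the `enriched` flag (default 0.01).
#' @param cutoff Optional single cutoff overriding every matrix's own.
#' @param test `"fisher"` (default) or `"binomial"`.
#' @param background Optional second [promoter_set()] used in place of the
#'   No set for the significance test only (e.g. promoters sampled from
#'   random genomic regions); densities and the Yes-No ratio still contrast
#'   Yes against No.
#' @param pseudocount Smoothing constant for PWM scoring.
#' @return Data frame of class `EnrichmentResult`: `matrix_id`,
#'   `tf_symbols`, `yes_sites`, `no_sites`, `yes_site_density`,
#'   `no_site_density`, `yes_no_ratio`, `p_value`, `adj_p`, `enriched`.
#' @export
enrich_matrices <- function(pwm_library, promoters, alpha = 0.01,
                            cutoff = NULL, test = c("fisher", "binomial"),
                            background = NULL, pseudocount = 0.01) {
  test <- match.arg(test)
  stopifnot(inherits(promoters, "PromoterSet"))
  yes_idx <- which(promoters$label == "yes")
  no_idx <- which(promoters$label == "no")
  assert_that(length(yes_idx) > 0 && length(no_idx) > 0,
              "both Yes and No subsets must be non-empty")
  int_all <- promoter_int_matrix(promoters)
  yes_mat <- int_all[yes_idx, , drop = FALSE]
  no_mat <- int_all[no_idx, , drop = FALSE]
  test_mat <- if (!is.null(background)) {
    stopifnot(inherits(background, "PromoterSet"))
    assert_that(background$width == promoters$width,
                "background width must match promoter width")
    promoter_int_matrix(background)
  } else no_mat
  width <- promoters$width
  rows <- lapply(pwm_library, function(m) {
    cp <- compile_pwm(m, pseudocount)
    co <- cutoff %||% cp$cutoff
    nw <- width - cp$L + 1L
    assert_that(nw > 0, "matrix %s longer than promoters", cp$matrix_id)
    ys <- sum(count_sites_set(cp, yes_mat, co))
    ns <- sum(count_sites_set(cp, no_mat, co))
    ts <- if (is.null(background)) ns else
      sum(count_sites_set(cp, test_mat, co))
    wy <- 2 * nrow(yes_mat) * nw          # scanned windows, Yes
    wt <- 2 * nrow(test_mat) * nw         # scanned windows, contrast set
    p <- if (test == "fisher") {
      # one-sided hypergeometric tail: P(X >= ys)
      stats::phyper(ys - 1, ys + ts, wy + wt - ys - ts, wy,
                    lower.tail = FALSE)
    } else {
      stats::pbinom(ys - 1, ys + ts, wy / (wy + wt), lower.tail = FALSE)
    }
    dy <- ys / (nrow(yes_mat) * width) * 1000
    dn <- ns / (nrow(no_mat) * width) * 1000
    data.frame(matrix_id = cp$matrix_id,
               tf_symbols = paste(m$tf_symbols, collapse = ","),
               yes_sites = ys, no_sites = ns,
               yes_site_density = dy, no_site_density = dn,
               yes_no_ratio = if (dn > 0) dy / dn else
                 if (dy > 0) Inf else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out$enriched <- out$adj_p < alpha
  out <- out[order(out$p_value, out$matrix_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Dump all binding sites of a library over a promoter set (BED-like)
#'
#' @param pwm_library List of matrices.
#' @param promoters A `PromoterSet`.
#' @param cutoff Optional cutoff override.
#' @return Data frame `gene_id`, `start`, `end` (0-based half-open),
#'   `matrix_id`, `norm_score`, `strand`.
#' @export
site_dump <- function(pwm_library, promoters, cutoff = NULL) {
  stopifnot(inherits(promoters, "PromoterSet"))
  out <- lapply(pwm_library, function(m) {
    res <- lapply(seq_along(promoters$gene_id), function(i) {
      h <- scan_promoter(m, promoters$sequence[i], cutoff = cutoff)
      if (!nrow(h)) return(NULL)
      data.frame(gene_id = promoters$gene_id[i], start = h$start,
                 end = h$start + nrow(m$counts), matrix_id = h$matrix_id,
                 norm_score = h$norm_score, strand = h$strand,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), matrix_id = character(),
                      norm_score = numeric(), strand = character())
  rownames(out) <- NULL
  out
}
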