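# Independent oracles and tiny fixture builders shared across tests.
# Every oracle is a deliberately naive reimplementation, kept free of the
# package's vectorised code paths.

# Naive PWM scoring from the formula: row-normalise, pseudocount-smooth,
# log-odds vs uniform background, min-max normalise.
oracle_pwm_score <- function(m, window, pc = 0.01) {
  f <- m$counts / rowSums(m$counts)
  f <- (f + pc) / (1 + 4 * pc)
  W <- log2(f / 0.25)
  wn <- rowMeans(W)
  v <- match(strsplit(toupper(window), "")[[1]], c("A", "C", "G", "T", "N"))
  raw <- sum(vapply(seq_along(v), function(i)
    if (v[i] == 5) wn[i] else W[i, v[i]], numeric(1)))
  (raw - sum(apply(W, 1, min))) / (sum(apply(W, 1, max)) - sum(apply(W, 1, min)))
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Exhaustive per-window scan over both strands; leftmost forward start.
oracle_scan <- function(m, sequence, cutoff) {
  L <- nrow(m$counts)
  len <- nchar(sequence)
  out <- list()
  for (s0 in 0:(len - L)) {
    win <- substr(sequence, s0 + 1, s0 + L)
    for (strand in c("+", "-")) {
      sc <- oracle_pwm_score(m, if (strand == "+") win else
        oracle_revcomp(win))
      if (sc >= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          start = s0, strand = strand, norm_score = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) data.frame(start = integer(), strand = character(),
                               norm_score = numeric()) else
    do.call(rbind, out)
}

# Exhaustive module scoring: every window start, naive per-slot top-k.
oracle_module_score <- function(module, sequence, library, stride = 10L) {
  lib_ids <- vapply(library, function(m) m$matrix_id, "")
  len <- nchar(sequence)
  ws <- seq.int(0L, len - module$window_len, by = stride)
  best <- 0
  for (w in ws) {
    total <- 0
    for (si in seq_len(nrow(module$slots))) {
      slot <- module$slots[si, ]
      m <- library[[match(slot$matrix_id, lib_ids)]]
      L <- nrow(m$counts)
      hits <- oracle_scan(m, sequence, slot$slot_cutoff)
      inside <- hits$norm_score[hits$start >= w &
                                  hits$start + L <= w + module$window_len]
      if (length(inside)) {
        k <- min(slot$max_sites, length(inside))
        total <- total + slot$weight *
          sum(sort(inside, decreasing = TRUE)[seq_len(k)])
      }
    }
    best <- max(best, total)
  }
  best
}

# All-pairs shortest directed path lengths by boolean matrix powers
# (independent of igraph). adj: n x n 0/1 matrix, adj[i, j] = edge i -> j.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0)
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# Fisher one-sided p for a 2x2 (a successes of m draws from a+b successes
# in N) via explicit hypergeometric summation.
oracle_fisher_greater <- function(a, b, c, d) {
  # table: [a, b; c, d]; one-sided P(X >= a), X ~ Hypergeom
  m <- a + b; n <- c + d; k <- a + c
  hi <- min(m, k)
  sum(vapply(a:hi, function(x) stats::dhyper(x, m, n, k), numeric(1)))
}

# Deterministic toy PWM from a consensus string: dominant count 70,
# others 10 (heterogeneity not needed for oracle tests).
toy_pwm <- function(id, consensus, tf = id, cutoff = 0.8) {
  v <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  counts <- matrix(10, length(v), 4)
  counts[cbind(seq_along(v), v)] <- 70
  pw_matrix(id, counts, tf_symbols = tf, cutoff = cutoff)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# Small promoter set with optional implanted consensus sites, for CMA
# unit tests (width kept small for speed).
toy_promoter_set <- function(library, n_yes = 10, n_no = 10, width = 400,
                             implant = TRUE) {
  seqs <- random_dna(n_yes + n_no, width)
  if (implant) {
    for (i in seq_len(n_yes)) {
      pos <- 50
      for (m in library) {
        cons <- paste(c("A", "C", "G", "T")[apply(m$counts, 1, which.max)],
                      collapse = "")
        substr(seqs[i], pos, pos + nchar(cons) - 1L) <- cons
        pos <- pos + nchar(cons) + 15L
      }
    }
  }
  promoter_set(sprintf("P%02d", seq_len(n_yes + n_no)), seqs,
               rep(c("yes", "no"), c(n_yes, n_no)), width = width)
}
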