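# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
to_abort <- function(fmt, ..., class = "transomic_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @noRd
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) to_abort(fmt, ...)
  invisible(TRUE)
}

#' @noRd
log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[transomic] ", fmt), ...))
}

# Derive a child seed from a base seed and a small stream offset, kept
# within 32-bit integer range.
#' @noRd
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + stream) %% 2147483587L)
}

# Nucleotide alphabet used throughout: A=1, C=2, G=3, T=4, N=5.
DNA_LEVELS <- c("A", "C", "G", "T", "N")

#' @noRd
dna_to_int <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_LEVELS)
  if (anyNA(m)) to_abort("sequence contains characters outside {A,C,G,T,N}")
  m
}

#' @noRd
int_to_dna <- function(v) paste(DNA_LEVELS[v], collapse = "")

#' @noRd
revcomp_int <- function(v) {
  comp <- c(4L, 3L, 2L, 1L, 5L)
  rev(comp[v])
}

#' @noRd
revcomp_chr <- function(x) int_to_dna(revcomp_int(dna_to_int(x)))

# --- TSV plumbing -----------------------------------------------------------

# All pipeline writers emit a single commented header line recording the
# package version and (optionally) seed and config hash, then a TSV with
# column names. Readers skip '#' lines.

#' @noRd
report_header <- function(seed = NULL, config_hash = NULL) {
  parts <- c(sprintf("transomic %s",
                     as.character(utils::packageVersion("transomic"))))
  if (!is.null(seed)) parts <- c(parts, sprintf("seed=%s", seed))
  if (!is.null(config_hash)) parts <- c(parts, sprintf("config=%s", config_hash))
  paste0("# ", paste(parts, collapse = "; "))
}

#' @noRd
write_report_tsv <- function(df, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed = seed, config_hash = config_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' @noRd
read_report_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", colClasses = colClasses)
}

# md5 of a canonical JSON rendering of an R object (used for config hashes;
# written to a temp file because tools::md5sum hashes files).
#' @noRd
object_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}
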