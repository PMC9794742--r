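# Shared internal helpers: RNG hygiene, alphabets, alignment wrappers.

# The 20 standard amino acids, fixed order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All user-facing stochastic functions funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed; keeps derived seeds
# inside the 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 48271 + as.integer(k)) %% .Machine$integer.max
}

.pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

# Alignment parameter set used everywhere (tBLASTn defaults): BLOSUM62,
# gap open 11, gap extend 1.
align_params <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
       lambda = 0.267, K = 0.041)
}

# Global (Needleman-Wunsch, end gaps penalised) alignment of one or more
# patterns against a single subject.
pw_global <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
}

# Local (Smith-Waterman) alignment of one or more patterns vs a subject.
pw_local <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
}

assert_protein <- function(x, what = "sequence", allow_stop = FALSE) {
  ok_chars <- c(AA20, "X", if (allow_stop) "*")
  bad <- setdiff(unique(strsplit(paste(x, collapse = ""), "")[[1]]), ok_chars)
  if (length(bad) > 0)
    stop(what, " contains invalid characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

random_peptide <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Substitute exactly n_subs positions of a peptide with a different
# residue (uniform over the 19 alternatives); positions in `protect`
# (1-based) are never touched.
mutate_peptide <- function(aa, n_subs, protect = integer(0)) {
  v <- strsplit(aa, "")[[1]]
  free <- setdiff(seq_along(v), protect)
  n_subs <- min(n_subs, length(free))
  if (n_subs == 0) return(aa)
  pos <- sample(free, n_subs)
  for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1)
  paste(v, collapse = "")
}

read_tsv_strict <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0)
      stop(basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
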