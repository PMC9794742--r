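# Shared fixtures and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

# default simulated reference library, built once per test run
tiny_library <- function() {
  if (is.null(.fixture_cache$lib))
    .fixture_cache$lib <- simulate_reference_library(seed = 2024)
  .fixture_cache$lib
}

# write a divergence table TSV and load it
make_divtable <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("taxonA\ttaxonB\tdivergence_my",
               vapply(rows, function(r)
                 paste(r[[1]], r[[2]], r[[3]], sep = "\t"), "")), path)
  load_divergence_table(path)
}

# exact-count mutant: substitute exactly n positions of a peptide
exact_mutant <- function(aa, n, seed = 1) {
  v <- strsplit(aa, "")[[1]]
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  pos <- sample(length(v), n)
  for (p in pos) v[p] <- sample(setdiff(aa20, v[p]), 1)
  paste(v, collapse = "")
}

rand_pep <- function(n, seed) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

# Independent quadratic Smith-Waterman oracle (affine gaps; a gap of
# length g costs open + g * extend, matching the package's alignment
# parameters).  Returns the optimal local score.
sw_score_oracle <- function(a, b, open = 11, extend = 1) {
  B <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    s <- B[av[i - 1], bv]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - extend, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open - extend, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s[j - 1], E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

get_blosum62 <- function() {
  if (is.null(.fixture_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fixture_cache$B62 <- e$BLOSUM62
  }
  .fixture_cache$B62
}

# best internal-search score of a query against a DNA sequence, using the
# exhaustive full-alignment path
search_best_score <- function(query, dna, min_seg_aa = 10) {
  h <- eprv_search(c(q = query), dna, evalue_max = Inf,
                   min_seg_aa = min_seg_aa, exhaustive = TRUE)
  if (nrow(h) == 0) 0 else max(h$score_raw)
}

# oracle counterpart: max brute-force SW score over the same stop-free
# segmentation of the six-frame translation
oracle_best_score <- function(query, dna, min_seg_aa = 10) {
  frames <- six_frame_translate(dna)
  best <- 0
  for (pep in frames) {
    for (seg in strsplit(pep, "*", fixed = TRUE)[[1]]) {
      if (nchar(seg) < min_seg_aa) next
      sc <- sw_score_oracle(seg, query)
      if (sc > best) best <- sc
    }
  }
  best
}

# shared default-scenario pipeline run (expensive; built on demand once)
scenario_run <- function() {
  if (is.null(.fixture_cache$scenario_run)) {
    sc <- simulate_scenario(seed = 42)
    out <- suppressWarnings(run_pipeline(
      genomes = setNames(list(sc$assembly), sc$genome_id),
      taxonomy = sc$taxonomy, library = sc$library,
      config = pipeline_config(seed = 42),
      out_dir = tempfile("eprvrun"), annotate = FALSE))
    .fixture_cache$scenario_run <- list(scenario = sc, result = out)
  }
  .fixture_cache$scenario_run
}
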