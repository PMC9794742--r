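# Translated search: six-frame translation, internal search engine,
# external-hit adapter.

test_that("six-frame translation follows the canonical conventions", {
  fr <- six_frame_translate("ATGTAA")
  expect_equal(fr[["frame0"]], "M*")
  # reverse complement of TTACAT is ATGTAA
  fr2 <- six_frame_translate("TTACAT")
  expect_equal(fr2[["frame3"]], "M*")
  expect_equal(six_frame_translate("ATGNAA")[["frame0"]], "MX")
  # frames 1/2 shift by one base
  expect_equal(six_frame_translate("AATGTAA")[["frame1"]], "M*")
})

test_that("a verbatim planted query is recovered at its exact interval", {
  lib <- tiny_library()
  bg <- generate_background(1, 50000, seed = 21)
  for (strand in c("plus", "minus")) {
    im <- implant(bg, lib, implant_spec(lib$id[1],
                                        strand_policy = strand),
                  seed = 22)
    h <- eprv_search(setNames(lib$aa_seq[1], lib$id[1]), im$assembly)
    expect_gte(nrow(h), 1)
    expect_equal(h$start_bp[1], im$truth$start[1])
    expect_equal(h$end_bp[1], im$truth$end[1])
    expect_equal(h$strand[1], im$truth$strand[1])
    expect_equal(h$matched_peptide[1], lib$aa_seq[1])
    # interval length ties to the ungapped peptide
    expect_equal(h$end_bp[1] - h$start_bp[1],
                 3 * nchar(h$matched_peptide[1]))
  }
})

test_that("random background yields no hits at the E-value threshold", {
  q <- setNames(rand_pep(320, 31), "probe")
  for (s in c(101, 102, 103)) {
    bg <- generate_background(1, 50000, seed = s)
    expect_equal(nrow(eprv_search(q, bg, evalue_max = 1e-10)), 0)
  }
})

test_that("degenerate assemblies are handled", {
  q <- setNames(rand_pep(100, 1), "probe")
  expect_equal(nrow(eprv_search(q, Biostrings::DNAStringSet())), 0)
  tiny <- Biostrings::DNAStringSet(c(short = "AT"))
  expect_warning(h <- eprv_search(q, tiny), "skipped")
  expect_equal(nrow(h), 0)
})

test_that("internal search matches the brute-force Smith-Waterman oracle", {
  lib <- tiny_library()
  q60 <- substr(lib$aa_seq[1], 1, 60)
  for (s in 1:4) {
    bg <- as.character(generate_background(1, 2000, seed = 200 + s)[[1]])
    # plant a mutated fragment in half the instances
    if (s %% 2 == 0) {
      frag <- reverse_translate(exact_mutant(q60, 9, seed = s), seed = s)
      substr(bg, 601, 600 + nchar(frag)) <- frag
    }
    expect_equal(search_best_score(q60, bg), oracle_best_score(q60, bg))
  }
})

test_that("self-score dominates scores of mutated copies", {
  pep <- rand_pep(120, 55)
  dna <- reverse_translate(pep, seed = 1)
  self <- search_best_score(pep, dna)
  for (s in 1:20) {
    mut <- mutate_coding(dna, runif(1, 0.05, 0.5), seed = 300 + s)
    expect_lte(search_best_score(pep, mut), self)
  }
})

test_that("reported intervals translate back to the matched peptide", {
  run <- scenario_run()
  h <- run$result$hits
  asm <- run$scenario$assembly
  set.seed(1)
  for (r in sample(nrow(h), 20)) {
    d <- substr(as.character(asm[[h$contig[r]]]), h$start_bp[r] + 1,
                h$end_bp[r])
    if (h$strand[r] == "-")
      d <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(d)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(d),
                                             if.fuzzy.codon = "solve"))
    # ungapped hits cover the interval exactly; gapped hits still
    # translate to a peptide containing every ungapped block
    if (!grepl("-", h$aligned_subject_aa[r], fixed = TRUE)) {
      expect_equal(aa, h$matched_peptide[r])
    } else {
      blocks <- strsplit(h$aligned_subject_aa[r], "-+")[[1]]
      expect_true(all(vapply(blocks, grepl, TRUE, x = aa,
                             fixed = TRUE)))
    }
  }
})

test_that("external tabular hits are normalised to forward-strand intervals", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# tblastn tabular output",
               paste("q1", "ctgA", "95.0", "300", "15", "0", "1", "300",
                     "101", "400", "1e-50", "250", sep = "\t"),
               paste("q1", "ctgA", "90.0", "100", "10", "0", "1", "100",
                     "400", "101", "2e-20", "120", "MKVLHEW", sep = "\t")),
             path)
  h <- parse_external_hits(path)
  expect_equal(nrow(h), 2)
  expect_equal(h$start_bp[1], 100)
  expect_equal(h$end_bp[1], 400)
  expect_equal(h$strand[1], "+")
  expect_equal(h$start_bp[2], 100)
  expect_equal(h$end_bp[2], 400)
  expect_equal(h$strand[2], "-")
  expect_equal(h$matched_peptide[2], "MKVLHEW")

  bad <- tempfile()
  writeLines("q1\tctgA\tnot-enough-fields", bad)
  expect_error(parse_external_hits(bad), "line 1")
})
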