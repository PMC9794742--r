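# Synthetic-genome generator: background, coding mutations, implants,
# truth ledger.

test_that("background generation is seeded and hits its GC target", {
  a <- generate_background(2, 5000, seed = 1)
  b <- generate_background(2, 5000, seed = 1)
  expect_identical(as.character(a), as.character(b))

  at_only <- generate_background(1, 2000, gc_fraction = 0, seed = 2)
  expect_false(grepl("[GC]", as.character(at_only[[1]])))

  g <- as.character(generate_background(1, 100000, gc_fraction = 0.40,
                                        seed = 3)[[1]])
  counts <- table(strsplit(g, "")[[1]])
  gc <- sum(counts[c("G", "C")]) / sum(counts[c("A", "C", "G", "T")])
  expect_gte(gc, 0.38); expect_lte(gc, 0.42)

  nr <- as.character(generate_background(1, 50000, n_run_rate = 1e-3,
                                         seed = 4)[[1]])
  expect_true(grepl("N", nr))
})

test_that("reverse translation is faithful and codon-diverse", {
  expect_equal(reverse_translate("M"), "ATG")
  aa <- tiny_library()$aa_seq[1]
  dna <- reverse_translate(aa, seed = 9)
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(dna))), aa)
  dna2 <- reverse_translate(aa, seed = 10)
  expect_false(dna == dna2)   # same protein, different codons
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(dna2))), aa)
  expect_error(reverse_translate("MA*K"), "\\*")
})

test_that("coding mutation realises its target divergence without stops", {
  aa <- rand_pep(300, 77)
  dna <- reverse_translate(aa, seed = 1)
  expect_identical(mutate_coding(dna, 0, seed = 1), dna)

  m <- mutate_coding(dna, 0.05, seed = 2)
  aam <- as.character(Biostrings::translate(Biostrings::DNAString(m)))
  ndiff <- sum(strsplit(aa, "")[[1]] != strsplit(aam, "")[[1]])
  expect_gte(ndiff, 11); expect_lte(ndiff, 19)
  expect_false(grepl("*", aam, fixed = TRUE))

  # no stop codon under many seeds
  for (s in 1:100) {
    aam <- as.character(Biostrings::translate(Biostrings::DNAString(
      mutate_coding(dna, 0.3, seed = s))))
    expect_false(grepl("*", aam, fixed = TRUE))
  }
  expect_error(mutate_coding(dna, 0.99), "0.95")
})

test_that("implants honour their degeneration and placement contracts", {
  lib <- tiny_library()
  bg <- generate_background(2, 60000, seed = 5)
  extract_aa <- function(asm, tr) {
    d <- substr(as.character(asm[[tr$contig]]), tr$start + 1, tr$end)
    if (tr$strand == "-")
      d <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(d)))
    n <- (nchar(d) %/% 3) * 3
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(d, 1, n))))
  }

  one <- implant(bg, lib, implant_spec(lib$id[1]), seed = 6)
  expect_equal(nrow(one$truth), 1)
  expect_false(grepl("*", extract_aa(one$assembly, one$truth[1, ]),
                     fixed = TRUE))

  burst <- implant(bg, lib, implant_spec(lib$id[2], n_copies = 12,
                                         aa_divergence = 0), seed = 7)
  peps <- vapply(seq_len(12), function(i)
    extract_aa(burst$assembly, burst$truth[i, ]), "")
  expect_equal(length(unique(peps)), 1)
  expect_equal(length(unique(burst$truth$copy_group_id)), 1)

  tand <- implant(bg, lib, implant_spec(lib$id[3], n_copies = 2,
                                        placement = "tandem",
                                        tandem_gap_bp = 800), seed = 8)
  expect_equal(tand$truth$start[2] - tand$truth$end[1], 800)

  stp <- implant(bg, lib, implant_spec(lib$id[4],
                                       degeneration = "internal_stop"),
                 seed = 9)
  expect_true(grepl("*", extract_aa(stp$assembly, stp$truth[1, ]),
                    fixed = TRUE))

  fs <- implant(bg, lib, implant_spec(lib$id[5],
                                      degeneration = "frameshift"),
                seed = 10)
  expect_false((fs$truth$end[1] - fs$truth$start[1]) %% 3 == 0)

  minus <- implant(bg, lib, implant_spec(lib$id[6],
                                         strand_policy = "minus"),
                   seed = 11)
  expect_equal(minus$truth$strand[1], "-")
  expect_equal(extract_aa(minus$assembly, minus$truth[1, ]),
               lib$aa_seq[6])
})

test_that("truth ledger round-trips through GFF3 losslessly", {
  lib <- tiny_library()
  bg <- generate_background(1, 50000, seed = 12)
  im <- implant(bg, lib,
                list(implant_spec(lib$id[1], n_copies = 2),
                     implant_spec(lib$id[2], strand_policy = "minus")),
                seed = 13)
  path <- tempfile(fileext = ".gff3")
  write_truth_gff3(im$truth, path)
  back <- read_truth_gff3(path)
  ord <- function(df) {
    df <- df[order(df$contig, df$start), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(back), ord(im$truth[, names(back)]))
})

test_that("the default scenario is deterministic under its seed", {
  a <- simulate_scenario(seed = 5, n_contigs = 1, contig_bp = 60000,
                        n_intact = 2, n_stop = 1, n_frameshift = 1,
                        n_decoy = 1, burst_copies = 0, tandem_copies = 0)
  b <- simulate_scenario(seed = 5, n_contigs = 1, contig_bp = 60000,
                        n_intact = 2, n_stop = 1, n_frameshift = 1,
                        n_decoy = 1, burst_copies = 0, tandem_copies = 0)
  expect_identical(as.character(a$assembly), as.character(b$assembly))
  expect_identical(a$truth, b$truth)
})
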