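# Screening rules: intactness, proximity dedup, lineage triage.

fake_hit <- function(contig = "c1", start = 0, len_aa = 300, score = 100,
                     pep = NULL, gapped = FALSE) {
  pep <- pep %||% strrep("K", len_aa)
  data.frame(contig = contig, start_bp = start,
             end_bp = start + 3 * nchar(gsub("-", "", pep)),
             strand = "+", frame = 0L, query_id = "q",
             aligned_query_aa = pep,
             aligned_subject_aa = if (gapped) sub("K", "-", pep) else pep,
             matched_peptide = gsub("-", "", pep),
             score_raw = score * 2, score_bits = score, evalue = 0,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("intactness screen enforces length, stops and indel-freedom", {
  h <- rbind(fake_hit(len_aa = 299), fake_hit(len_aa = 300))
  expect_equal(nrow(filter_intact(h)), 1)
  expect_equal(nchar(filter_intact(h)$matched_peptide), 300)

  stopped <- fake_hit(pep = paste0(strrep("K", 150), "*", strrep("K", 150)))
  expect_equal(nrow(filter_intact(stopped)), 0)

  gapped <- fake_hit(len_aa = 320, gapped = TRUE)
  expect_equal(nrow(filter_intact(gapped)), 0)
})

test_that("proximity dedup keeps one best hit per tandem chain", {
  # two hits, gap 800, scores 120 vs 90 -> the 120 survives
  h <- rbind(fake_hit(start = 0, score = 120),
             fake_hit(start = 900 + 800, score = 90))
  out <- dedup_proximity(h)
  expect_equal(nrow(out), 1)
  expect_equal(out$score_bits, 120)

  # gap exactly 1500 is allowed ("less than" is strict)
  h2 <- rbind(fake_hit(start = 0), fake_hit(start = 900 + 1500))
  expect_equal(nrow(dedup_proximity(h2)), 2)

  # 5-copy tandem array with 200 bp gaps collapses to one survivor,
  # regardless of where the best copy sits
  starts <- cumsum(c(0, rep(900 + 200, 4)))
  h3 <- do.call(rbind, lapply(seq_along(starts), function(i)
    fake_hit(start = starts[i], score = c(100, 90, 95, 110, 80)[i])))
  out3 <- dedup_proximity(h3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$score_bits, 110)

  # ties go to the leftmost
  h4 <- rbind(fake_hit(start = 0, score = 100),
              fake_hit(start = 1000, score = 100))
  expect_equal(dedup_proximity(h4)$start_bp, 0)

  # different contigs never conflict
  h5 <- rbind(fake_hit(contig = "c1"), fake_hit(contig = "c2"))
  expect_equal(nrow(dedup_proximity(h5)), 2)
})

test_that("lineage triage keeps Caulimoviridae-class hits and drops decoys", {
  lib <- tiny_library()
  caulimo <- lib$aa_seq[match("Florendovirus_01", lib$id)]
  decoy <- lib$aa_seq[match("Tekay_01", lib$id)]

  h <- rbind(fake_hit(pep = exact_mutant(caulimo, 16, seed = 3)),
             fake_hit(start = 10000,
                      pep = exact_mutant(decoy, 16, seed = 4)))
  cand <- triage_lineage(h, lib)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$provisional_class, "caulimoviridae")
  expect_equal(cand$best_ref_otu, "Florendovirus")

  one_class <- lib[lib$lineage_class == "caulimoviridae", ]
  class(one_class) <- class(lib)
  expect_error(triage_lineage(h, one_class), "cannot triage")
})

test_that("the screen composition is idempotent", {
  run <- scenario_run()
  h <- run$result$hits
  lib <- run$scenario$library
  once <- screen_hits(h, lib)
  twice <- screen_hits(once, lib)
  expect_equal(twice$candidate_id, once$candidate_id)
  expect_equal(twice$aa_seq, once$aa_seq)
  expect_equal(twice$best_ref_id, once$best_ref_id)
})

test_that("planted degenerate copies are absent from the screened output", {
  sc <- simulate_scenario(seed = 7, n_contigs = 1, contig_bp = 120000,
                          n_intact = 2, n_stop = 2, n_frameshift = 2,
                          n_decoy = 2, burst_copies = 0,
                          tandem_copies = 3)
  q <- eprvscan:::.select_queries(sc$library, 1)
  h <- eprv_search(q, sc$assembly)
  cand <- screen_hits(h, sc$library)
  rec <- evaluate_recovery(sc$truth, cand, library = sc$library)
  pc <- rec$per_class
  expect_equal(pc$sensitivity[pc$class == "intact" &
                                pc$placement == "dispersed"], 1)
  for (cl in c("internal_stop", "frameshift", "decoy"))
    if (cl %in% pc$class)
      expect_equal(pc$sensitivity[pc$class == cl], 0)
  # the tandem array contributes exactly one candidate
  tandem_grp <- unique(sc$truth$copy_group_id[sc$truth$placement ==
                                                "tandem"])
  expect_equal(unname(rec$copy_group_candidates[tandem_grp]), 1)
})
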