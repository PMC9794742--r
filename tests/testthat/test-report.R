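# Published-table consistency arithmetic and recovery scoring.

test_that("cluster60 table arithmetic reproduces the printed totals", {
  chk <- check_published_tables()
  expect_equal(chk$table1$n_clusters, 57)
  expect_equal(chk$table1$n_otus, 13)
  expect_equal(chk$table1$n_episomal_clusters, 30)
  expect_equal(unname(chk$table1$clusters_per_otu[["Florendovirus"]]), 11)

  pg <- chk$table1$per_genus
  consistent <- c(Badnavirus = 80, Caulimovirus = 38, Dioscovirus = 144,
                  Petuvirus = 1693, Solendovirus = 1124, Soymovirus = 454,
                  Gymnendovirus = 95, Wendovirus = 282, Xendovirus = 65,
                  Zendovirus = 781)
  for (g in names(consistent)) {
    row <- pg[pg$otu == g, ]
    expect_equal(row$computed_n_seqs, unname(consistent[g]))
    expect_false(row$discrepant)
  }
})

test_that("known discrepant genus totals are flagged, not asserted", {
  chk <- check_published_tables()
  flagged <- chk$genus_consistency
  expect_setequal(flagged$otu,
                  c("Florendovirus", "Yendovirus", "Tungrovirus"))
  # both numbers are reported for each flagged genus
  expect_equal(flagged$printed_n_seqs[flagged$otu == "Florendovirus"], 6162)
  expect_equal(flagged$computed_n_seqs[flagged$otu == "Florendovirus"], 6138)
  expect_equal(flagged$printed_n_seqs[flagged$otu == "Yendovirus"], 334)
  expect_equal(flagged$computed_n_seqs[flagged$otu == "Yendovirus"], 335)
  expect_equal(flagged$printed_n_seqs[flagged$otu == "Tungrovirus"], 308)
  expect_equal(flagged$computed_n_seqs[flagged$otu == "Tungrovirus"], 298)
})

test_that("cluster100 table arithmetic reproduces the printed totals", {
  chk <- check_published_tables()
  expect_equal(chk$table3$n_clusters, 31)
  expect_equal(chk$table3$total_seqs, 1534)
  expect_equal(chk$table3$max_copies, 951)
  expect_equal(unname(chk$table3$per_genome[["Capsicum annuum"]]), 1014)
  pgg <- chk$table3$per_genome_group
  expect_equal(pgg$n_seqs[pgg$genome_species == "Capsicum annuum" &
                            pgg$otu_group == "Solendovirus"], 962)
})

test_that("cluster summaries count taxonomic breadth over member hosts", {
  taxonomy <- data.frame(
    genome_id = c("g1", "g2", "g3"),
    species = c("Aus unus", "Aus duo", "Bus tres"),
    genus = c("Aus", "Aus", "Bus"),
    family = c("Aceae", "Aceae", "Bceae"),
    order = c("Aales", "Aales", "Bales"),
    class_ = rep("Magnoliopsida", 3),
    kingdom = rep("Plantae", 3), stringsAsFactors = FALSE)
  pep <- rand_pep(310, 500)
  cand <- data.frame(candidate_id = c("c1", "c2", "c3"),
                     aa_seq = c(pep, pep, exact_mutant(pep, 30, 1)),
                     genome_id = c("g1", "g2", "g3"),
                     stringsAsFactors = FALSE)
  cs <- greedy_cluster(cand, 0.6)
  dt <- make_divtable(list(list("Aus", "Bus", 120)))
  tab <- build_cluster_table(cs, cand, taxonomy, divergence_table = dt)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_seqs, 3)
  expect_equal(tab$n_species, 3)
  expect_equal(tab$n_genera, 2)
  expect_equal(tab$max_age_my, 120)

  # single-genome cluster: breadth 1 everywhere, age 0
  cs1 <- greedy_cluster(cand[1, ], 0.6)
  tab1 <- build_cluster_table(cs1, cand[1, ], taxonomy,
                              divergence_table = dt)
  expect_true(all(unlist(tab1[, c("n_classes", "n_orders", "n_families",
                                  "n_genera", "n_species")]) == 1))
  expect_equal(tab1$max_age_my, 0)

  # a member without taxonomy is an error naming the member
  cand_bad <- cand
  cand_bad$genome_id[2] <- "gX"
  expect_error(build_cluster_table(cs, cand_bad, taxonomy,
                                   divergence_table = dt), "c2")
})

test_that("recovery scoring handles the oracle and degenerate cases", {
  truth <- data.frame(contig = c("c1", "c1"), start = c(100, 5000),
                      end = c(1060, 5960), strand = "+",
                      source_ref_id = "x", degeneration = "intact",
                      placement = "dispersed",
                      copy_group_id = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  # oracle injection: candidates exactly equal truth
  cand <- data.frame(candidate_id = c("a", "b"), contig = "c1",
                     start_bp = c(100, 5000), end_bp = c(1060, 5960),
                     stringsAsFactors = FALSE)
  rec <- evaluate_recovery(truth, cand)
  expect_equal(rec$per_class$sensitivity, 1)
  expect_equal(rec$precision, 1)

  # empty predictions: zero sensitivity, NA precision
  rec0 <- evaluate_recovery(truth, cand[0, ])
  expect_equal(rec0$per_class$sensitivity, 0)
  expect_true(is.na(rec0$precision))
})
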