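# Distances, neighbor joining, bootstrap, OTU assignment, minimum ages.

test_that("Poisson-corrected distances match the closed form", {
  a <- rand_pep(300, 61)
  b <- exact_mutant(a, 30, seed = 62)   # p = 0.10
  d <- pairwise_distances(setNames(c(a, b), c("a", "b")))
  expect_equal(d["a", "b"], -log(0.9), tolerance = 1e-6)
  expect_equal(d["a", "b"], 0.10536, tolerance = 1e-4)
  expect_equal(d["a", "a"], 0)

  # symmetry over random pairs
  peps <- setNames(vapply(1:6, function(i) rand_pep(150, 70 + i), ""),
                   paste0("s", 1:6))
  dm <- pairwise_distances(peps)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))

  expect_warning(poisson_distance(0.97), "clamped")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4 taxa with hand-built additive distances:
  # ((A:1,B:2):1.5,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 1 + 1.5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 1.5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 1.5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 1.5 + 4
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[
    rownames(d), colnames(d)]), unname(d), tolerance = 1e-9)
  # AB|CD is the internal split
  expect_equal(as.numeric(ape::dist.topo(tr, ape::read.tree(
    text = "((A:1,B:2):1.5,C:3,D:4);"))), 0)

  # random additive trees up to 8 taxa: topology and patristic distances
  for (n in 5:8) {
    set.seed(100 + n)
    true <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    dm <- ape::cophenetic.phylo(true)
    got <- nj_tree(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), got)), 0)
    expect_equal(unname(as.matrix(ape::cophenetic.phylo(got))[
      rownames(dm), colnames(dm)]), unname(dm), tolerance = 1e-9)
  }

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(rbind(cbind(bad, 1), 1)), "symmetric")
})

test_that("three-taxon branch lengths follow the three-point formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (5 + 9 - 10) / 2)   # 2
  expect_equal(bl[["b"]], (5 + 10 - 9) / 2)   # 3
  expect_equal(bl[["c"]], (9 + 10 - 5) / 2)   # 7
})

test_that("NJ topology matches exhaustive least-squares enumeration on
           additive matrices", {
  for (n in 5:6) {
    set.seed(200 + n)
    true <- ape::rtree(n, br = function(k) runif(k, 0.2, 1))
    dm <- ape::cophenetic.phylo(true)
    got <- nj_tree(dm)
    # oracle: among all unrooted topologies, least-squares edge fitting
    # gives residual ~0 only for the generating topology
    all_t <- phangorn::allTrees(n, tip.label = rownames(dm))
    rss <- vapply(all_t, function(tt) {
      X <- phangorn::designTree(tt)
      # designTree rows follow as.dist() over the tip order passed to
      # allTrees, which is rownames(dm)
      y <- as.vector(as.dist(dm))
      fit <- stats::lm.fit(as.matrix(X), y)
      sum(fit$residuals^2)
    }, 0)
    best <- all_t[[which.min(rss)]]
    expect_lt(min(rss), 1e-12)
    expect_equal(as.numeric(ape::dist.topo(best, got)), 0)
  }
})

test_that("bootstrap supports separate well-resolved clades", {
  set.seed(77)
  anc1 <- rand_pep(200, 81)
  anc2 <- exact_mutant(anc1, 100, seed = 82)    # 50% diverged clades
  peps <- setNames(c(vapply(1:4, function(i) exact_mutant(anc1, 6, i), ""),
                     vapply(1:4, function(i) exact_mutant(anc2, 6, 10 + i),
                            "")),
                   c(paste0("x", 1:4), paste0("y", 1:4)))
  tr <- bootstrap_support(peps, n_reps = 100, seed = 5)
  sup <- tr$node.label[!is.na(tr$node.label)]
  # the clade-separating split is recovered essentially always
  expect_gte(max(sup), 95)

  # n_reps = 1 gives all-or-nothing supports
  tr1 <- bootstrap_support(peps, n_reps = 1, seed = 6)
  expect_true(all(tr1$node.label[!is.na(tr1$node.label)] %in% c(0, 100)))

  # reproducibility under a fixed seed
  tr2 <- bootstrap_support(peps, n_reps = 20, seed = 9)
  tr3 <- bootstrap_support(peps, n_reps = 20, seed = 9)
  expect_identical(tr2$node.label, tr3$node.label)
})

test_that("nearest-reference classification recovers source OTUs", {
  lib <- tiny_library()
  flo <- lib[lib$id == "Florendovirus_01", ]
  mut <- exact_mutant(flo$aa_seq, 16, seed = 91)   # 5% divergence
  a <- assign_otu(c(m = mut), lib)
  expect_equal(a$otu, "Florendovirus")
  expect_gt(a$support, 0.5)

  exact <- assign_otu(c(e = flo$aa_seq), lib)
  expect_equal(exact$otu, "Florendovirus")
  expect_equal(exact$support, 1)
  expect_equal(exact$d1, 0)

  # far-from-everything queries stay unclassified
  randoms <- setNames(vapply(1:10, function(i) rand_pep(300, 900 + i), ""),
                      paste0("r", 1:10))
  ar <- suppressWarnings(assign_otu(randoms, lib))
  expect_true(all(ar$otu == "unclassified"))

  # clade method agrees on a clear-cut case
  ac <- assign_otu(c(m = mut), lib, method = "clade")
  expect_equal(ac$otu, "Florendovirus")
})

test_that("minimum ages use the most distant resolvable host pair", {
  dt <- make_divtable(list(list("Dioscorea", "Amborella", 191),
                           list("Dioscorea", "Musa", 117),
                           list("Amborella", "Musa", 191)))
  # single-genus cluster
  one <- min_age(c("Dioscorea", "Dioscorea"), dt)
  expect_equal(one$age_my, 0)

  three <- min_age(c("Dioscorea", "Amborella", "Musa"), dt)
  expect_equal(three$age_my, 191)
  # first maximizing pair in sorted order
  expect_equal(three$pair, c("Amborella", "Dioscorea"))

  # invariant to duplication and order
  expect_equal(min_age(c("Musa", "Dioscorea", "Musa", "Amborella"),
                       dt)$age_my, 191)

  # missing pairs are reported, not zeroed
  dt2 <- make_divtable(list(list("Dioscorea", "Musa", 117)))
  res <- min_age(c("Dioscorea", "Musa", "Oryza"), dt2)
  expect_equal(res$age_my, 117)
  expect_equal(nrow(res$unresolved), 2)
})
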