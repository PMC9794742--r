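# Distance-based phylogeny of cluster representatives: Poisson-corrected
# distances from pairwise global alignments, neighbor-joining trees,
# bootstrap support from a reference-anchored alignment, OTU assignment
# by nearest reference, and minimum insertion-age inference.

#' Poisson-corrected amino-acid distance
#'
#' `d = -ln(1 - p)` for a mismatch fraction `p`; corrects the observed
#' proportion of differing sites for multiple hits under a Poisson model
#' of substitution.  `p >= 0.95` is clamped (with a warning) to keep the
#' distance finite.
#'
#' @param p Mismatch fraction(s) in [0, 1].
#' @return Distance(s).
#' @export
poisson_distance <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p >= 0.95)) {
    warning("mismatch fraction >= 0.95 clamped for Poisson correction")
    p <- pmin(p, 0.95)
  }
  -log(1 - p)
}

# mismatch fraction over a gapped alignment pair, gap columns excluded
.p_mismatch <- function(arow, brow) {
  a <- strsplit(arow, "")[[1]]
  b <- strsplit(brow, "")[[1]]
  use <- a != "-" & b != "-"
  if (!any(use)) stop("alignment pair has no shared (gap-free) columns",
                      call. = FALSE)
  mean(a[use] != b[use])
}

#' Pairwise Poisson-corrected distance matrix
#'
#' Distances come from pairwise global alignments (BLOSUM62, 11/1) of
#' every sequence pair -- not from one multiple alignment -- with the
#' mismatch fraction taken over columns where neither sequence is
#' gapped, then Poisson-corrected ([poisson_distance()]).
#'
#' @param peptides Named character vector (>= 2 sequences).
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence name.
#' @export
pairwise_distances <- function(peptides) {
  n <- length(peptides)
  stopifnot(n >= 2, !is.null(names(peptides)))
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- pw_global(peptides[js], peptides[[i]])
    arow <- as.character(Biostrings::pattern(aln))
    brow <- as.character(Biostrings::subject(aln))
    for (k in seq_along(js)) {
      p <- .p_mismatch(arow[k], brow[k])
      d[i, js[k]] <- d[js[k], i] <- poisson_distance(p)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]); negative
#' branch lengths arising from non-additive noise are clamped to zero.
#' For exactly three taxa the unique unrooted topology with the classic
#' three-point branch lengths is returned.
#'
#' @param dist Symmetric matrix (zero diagonal, finite entries) or
#'   [stats::dist].
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# -- reference-anchored multiple alignment ----------------------------------

#' Reference-anchored multiple alignment
#'
#' A lightweight MSA for column resampling: every sequence is globally
#' aligned to the longest sequence (the anchor) and projected onto the
#' anchor's coordinates; insertions relative to the anchor are dropped.
#' Adequate for bootstrap resampling of well-conserved domains; users
#' with an externally computed alignment can supply it to
#' [bootstrap_support()] directly as a character matrix.
#'
#' @param peptides Named character vector.
#' @return Character matrix (rows = sequences, columns = anchor
#'   positions, `-` for gaps).
#' @export
anchor_alignment <- function(peptides) {
  stopifnot(length(peptides) >= 2, !is.null(names(peptides)))
  ord <- order(-nchar(peptides), names(peptides))
  anchor_name <- names(peptides)[ord[1]]
  anchor <- peptides[[anchor_name]]
  ncol <- nchar(anchor)
  mat <- matrix("-", nrow = length(peptides), ncol = ncol,
                dimnames = list(names(peptides), NULL))
  mat[anchor_name, ] <- strsplit(anchor, "")[[1]]
  others <- setdiff(names(peptides), anchor_name)
  if (length(others) > 0) {
    aln <- pw_global(peptides[others], anchor)
    prow <- as.character(Biostrings::pattern(aln))
    srow <- as.character(Biostrings::subject(aln))
    for (k in seq_along(others)) {
      pv <- strsplit(prow[k], "")[[1]]
      sv <- strsplit(srow[k], "")[[1]]
      mat[others[k], ] <- pv[sv != "-"]
    }
  }
  mat
}

# p-distance matrix from an alignment matrix restricted to columns `cols`
.aln_dist <- function(mat, cols) {
  sub <- mat[, cols, drop = FALSE]
  n <- nrow(sub)
  d <- matrix(0, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- sub[i, ] != "-" & sub[j, ] != "-"
    p <- if (any(use)) mean(sub[i, use] != sub[j, use]) else 0.95
    d[i, j] <- d[j, i] <- poisson_distance(min(p, 0.9499))
  }
  d
}

# canonical bipartition keys of the internal nodes of a tree, in node
# order; trivial splits get NA
.split_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  n <- length(labs)
  vapply(pp, function(idx) {
    side <- labs[idx]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, "")
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from Poisson-corrected distances over an
#' alignment, then resamples alignment columns with replacement
#' `n_reps` times; the support of each internal split is the percentage
#' of replicate NJ trees containing it, stored in `tree$node.label`
#' (trivial splits get `NA`).
#'
#' @param x Named peptide vector (aligned internally with
#'   [anchor_alignment()]) or an alignment character matrix.
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; supports are reproducible under a fixed seed.
#' @return An [ape::phylo] tree with `node.label` support values in
#'   [0, 100].
#' @export
bootstrap_support <- function(x, n_reps = 100, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  mat <- if (is.matrix(x)) x else anchor_alignment(x)
  main <- nj_tree(.aln_dist(mat, seq_len(ncol(mat))))
  keys <- .split_keys(main)
  counts <- setNames(numeric(length(keys)), keys)
  suppressWarnings(with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample(ncol(mat), ncol(mat), replace = TRUE)
      bt <- nj_tree(.aln_dist(mat, cols))
      bk <- .split_keys(bt)
      hit <- keys %in% bk[!is.na(bk)]
      counts[hit] <- counts[hit] + 1
    }
  }))
  support <- 100 * counts / n_reps
  support[is.na(keys)] <- NA_real_
  main$node.label <- unname(support)
  main
}

# -- OTU assignment ----------------------------------------------------------

#' Classify peptides into OTUs against the reference library
#'
#' Default method `nearest_reference`: each peptide takes the OTU of the
#' reference at minimal Poisson-corrected distance; the support margin
#' is `(d2 - d1) / d2` where `d1`/`d2` are the best distances to
#' references of two *different* OTUs (1 = unambiguous, 0 = tie).  A
#' peptide farther than `max_distance` from every reference is
#' `"unclassified"`.  Method `clade` reads the assignment off an NJ tree
#' of the peptide with all references: the OTU is assigned only when the
#' peptide's smallest enclosing clade is OTU-pure.
#'
#' @param peptides Named character vector of query peptides.
#' @param library An `eprv_reflib`.
#' @param max_distance Classification ceiling on `d1` (default 1.0,
#'   i.e. ~63% observed mismatch).
#' @param method `"nearest_reference"` (default) or `"clade"`.
#' @return Data.frame with `id`, `otu`, `support`, `method`, `d1`,
#'   `best_ref_id`.
#' @export
assign_otu <- function(peptides, library, max_distance = 1.0,
                       method = c("nearest_reference", "clade")) {
  method <- match.arg(method)
  stopifnot(inherits(library, "eprv_reflib"), nrow(library) > 0)
  if (is.null(names(peptides)))
    names(peptides) <- sprintf("query_%03d", seq_along(peptides))
  lib <- library[order(library$id), ]
  refs <- setNames(lib$aa_seq, lib$id)
  out <- list()
  for (qi in seq_along(peptides)) {
    aln <- pw_global(refs, peptides[[qi]])
    prow <- as.character(Biostrings::pattern(aln))
    srow <- as.character(Biostrings::subject(aln))
    dd <- suppressWarnings(vapply(seq_along(refs), function(k)
      poisson_distance(min(.p_mismatch(prow[k], srow[k]), 0.9499)), 0))
    best <- which.min(dd)
    d1 <- dd[best]
    other <- lib$otu != lib$otu[best]
    d2 <- if (any(other)) min(dd[other]) else NA_real_
    support <- if (is.na(d2) || d2 == 0) 0 else max(0, (d2 - d1) / d2)
    otu <- lib$otu[best]
    if (method == "clade" && d1 <= max_distance) {
      qname <- names(peptides)[qi]
      dmat <- pairwise_distances(c(setNames(peptides[qi], qname), refs))
      tr <- nj_tree(dmat)
      otu <- .clade_otu(tr, qname, setNames(lib$otu, lib$id))
      if (is.na(otu)) otu <- "unclassified"
    }
    if (d1 > max_distance) {
      otu <- "unclassified"
      support <- NA_real_
    }
    out[[qi]] <- data.frame(id = names(peptides)[qi], otu = otu,
                            support = support, method = method, d1 = d1,
                            best_ref_id = lib$id[best],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# OTU of the smallest OTU-pure clade containing tip `qname`, else NA
.clade_otu <- function(tree, qname, ref_otus) {
  tip <- match(qname, tree$tip.label)
  node <- tree$edge[tree$edge[, 2] == tip, 1]
  repeat {
    tips <- tree$tip.label[.descendant_tips(tree, node)]
    otus <- unique(ref_otus[setdiff(tips, qname)])
    otus <- otus[!is.na(otus)]
    if (length(otus) == 1) return(otus)
    up <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(up) == 0) return(NA_character_)
    node <- up
  }
}

.descendant_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .descendant_tips, tree = tree))
}

# -- minimum insertion age ---------------------------------------------------

#' Minimum insertion age of a cluster from its host taxa
#'
#' The minimum age of the insertion event behind a cluster of EPRVs is
#' the divergence time of the most distantly related pair of host taxa
#' sharing the cluster.  A cluster confined to a single taxon has age 0.
#' Pairs absent from the divergence table are collected and reported --
#' never silently treated as 0.
#'
#' @param hosts Character vector of host taxon names (genus or species,
#'   matching the table's rank) of the cluster members; duplicates and
#'   ordering are irrelevant.
#' @param divergence_table An `eprv_divtable`
#'   ([load_divergence_table()]).
#' @return List with `age_my`, `pair` (the first maximizing pair in
#'   sorted order), and `unresolved` (data.frame of unresolvable pairs;
#'   the age is computed over the resolvable ones, and is `NA` if none
#'   are resolvable but distinct hosts exist).
#' @export
min_age <- function(hosts, divergence_table) {
  stopifnot(length(hosts) >= 1)
  h <- sort(unique(hosts))
  if (length(h) == 1)
    return(list(age_my = 0, pair = c(h, h),
                unresolved = data.frame(taxonA = character(0),
                                        taxonB = character(0))))
  pairs <- utils::combn(h, 2)
  ages <- numeric(ncol(pairs))
  bad <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    v <- divergence_lookup(divergence_table, pairs[1, k], pairs[2, k],
                           strict = FALSE)
    if (is.na(v)) bad[k] <- TRUE else ages[k] <- v
  }
  unresolved <- data.frame(taxonA = pairs[1, bad], taxonB = pairs[2, bad],
                           stringsAsFactors = FALSE)
  if (all(bad))
    return(list(age_my = NA_real_, pair = c(NA_character_, NA_character_),
                unresolved = unresolved))
  ages[bad] <- -Inf
  best <- which.max(ages)  # pairs are generated in sorted order
  list(age_my = ages[best], pair = c(pairs[1, best], pairs[2, best]),
       unresolved = unresolved)
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param d Labelled symmetric matrix.
#' @param path Output path.
#' @export
write_phylip <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -12),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}
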