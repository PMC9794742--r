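# Synthetic genome assemblies with a planted-element truth ledger.
#
# The simulator emulates the statistical structure the discovery pipeline
# assumes: random host background, recently inserted (hence intact and
# weakly diverged) Caulimoviridae RT domains, degenerate copies carrying
# internal stops or frameshifts, tandem arrays, amplification bursts of
# identical copies, and Ty3/Gypsy retrotransposon decoys.

# -- genetic-code helpers ----------------------------------------------------

codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    by_aa <- split(names(gc), unname(gc))
    by_aa[["*"]] <- NULL
    # deterministic order within each synonymous family
    .pkg_cache$codons <- lapply(by_aa, sort)
  }
  .pkg_cache$codons
}

#' Reverse-translate a peptide into DNA
#'
#' @param aa_seq Peptide (no `'*'`).
#' @param codon_policy `"uniform"` samples uniformly over synonymous
#'   codons (the pipeline is codon-usage agnostic); `"first"` always
#'   takes the alphabetically first codon (deterministic).
#' @param seed RNG seed for the uniform policy.
#' @return DNA string; translating it in frame 0 reproduces `aa_seq`.
#' @export
reverse_translate <- function(aa_seq, codon_policy = c("uniform", "first"),
                              seed = NULL) {
  codon_policy <- match.arg(codon_policy)
  if (grepl("\\*", aa_seq)) stop("aa_seq must not contain '*'", call. = FALSE)
  assert_protein(aa_seq, "aa_seq")
  tab <- codon_table()
  v <- strsplit(aa_seq, "")[[1]]
  if (any(v == "X")) stop("cannot reverse-translate 'X'", call. = FALSE)
  with_seed(seed, {
    codons <- vapply(v, function(a) {
      opts <- tab[[a]]
      if (codon_policy == "first") opts[[1]] else sample(opts, 1)
    }, "", USE.NAMES = FALSE)
    paste(codons, collapse = "")
  })
}

#' Mutate a coding sequence to a target amino-acid divergence
#'
#' Substitutes exactly `round(target * n_aa)` codons so that each encodes
#' a different residue; no stop codon is ever introduced, and for
#' proteins of >= 50 aa the realised amino-acid divergence is within
#' 1/n of the target (well inside the +/-0.02 contract for >= 300 aa).
#'
#' @param dna In-frame coding DNA (length divisible by 3, no stop).
#' @param target_aa_divergence Fraction in `[0, 0.95]`.
#' @param seed RNG seed.
#' @return Mutated DNA string of the same length.
#' @export
mutate_coding <- function(dna, target_aa_divergence, seed = NULL) {
  if (nchar(dna) %% 3 != 0)
    stop("dna length must be divisible by 3", call. = FALSE)
  if (target_aa_divergence < 0 || target_aa_divergence > 0.95)
    stop("target divergence must be in [0, 0.95]", call. = FALSE)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna)))
  if (grepl("\\*", aa)) stop("dna must not encode a stop", call. = FALSE)
  n <- nchar(aa)
  m <- round(target_aa_divergence * n)
  if (m == 0) return(dna)
  tab <- codon_table()
  with_seed(seed, {
    pos <- sample(n, m)
    codons <- substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))
    av <- strsplit(aa, "")[[1]]
    for (p in pos) {
      new_aa <- sample(setdiff(AA20, av[p]), 1)
      codons[p] <- sample(tab[[new_aa]], 1)
    }
    paste(codons, collapse = "")
  })
}

# -- background --------------------------------------------------------------

#' Generate random background contigs
#'
#' I.i.d. nucleotides at a target GC fraction, with optional runs of `N`
#' (assembly gaps): each base starts an N run with probability
#' `n_run_rate`; run lengths are geometric with mean 100 bp.
#'
#' @param n_contigs,length_bp Number of contigs and length of each.
#' @param gc_fraction Target GC in `[0,1]`.
#' @param n_run_rate Per-base probability of initiating an N run.
#' @param seed RNG seed; output is byte-identical under a fixed seed.
#' @return A [Biostrings::DNAStringSet] named `contig_01`, ...
#' @export
generate_background <- function(n_contigs = 1, length_bp = 100000,
                                gc_fraction = 0.36, n_run_rate = 0,
                                seed = NULL) {
  stopifnot(length_bp >= 1, gc_fraction >= 0, gc_fraction <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    seqs <- vapply(seq_len(n_contigs), function(i) {
      v <- sample(names(p), length_bp, replace = TRUE, prob = p)
      if (n_run_rate > 0) {
        starts <- which(runif(length_bp) < n_run_rate)
        for (s in starts) {
          len <- 1 + stats::rgeom(1, 1 / 100)
          v[s:min(length_bp, s + len - 1)] <- "N"
        }
      }
      paste(v, collapse = "")
    }, "")
    Biostrings::DNAStringSet(
      setNames(seqs, sprintf("contig_%02d", seq_len(n_contigs))))
  })
}

# -- implanting --------------------------------------------------------------

#' Describe a batch of element copies to implant
#'
#' @param source_ref_id Reference-library id the copies derive from.
#' @param n_copies Number of copies.
#' @param aa_divergence Target amino-acid divergence of each copy from
#'   the source (applied independently per copy; 0 gives identical
#'   copies, the signature of a recent amplification burst).
#' @param degeneration `"intact"`, `"internal_stop"` (a stop codon
#'   planted in the middle of the domain) or `"frameshift"` (a 1- or
#'   2-bp deletion in the middle 60% of the element, so neither
#'   in-frame piece can satisfy the intactness criterion).
#' @param placement `"dispersed"` (random, mutually distant loci) or
#'   `"tandem"` (consecutive copies separated by `tandem_gap_bp`).
#' @param tandem_gap_bp Exact inter-copy gap for tandem placement.
#' @param strand_policy `"random"`, `"plus"` or `"minus"`.
#' @return An `eprv_implant_spec` list.
#' @export
implant_spec <- function(source_ref_id, n_copies = 1, aa_divergence = 0,
                         degeneration = c("intact", "internal_stop",
                                          "frameshift"),
                         placement = c("dispersed", "tandem"),
                         tandem_gap_bp = 200,
                         strand_policy = c("random", "plus", "minus")) {
  degeneration <- match.arg(degeneration)
  placement <- match.arg(placement)
  strand_policy <- match.arg(strand_policy)
  stopifnot(n_copies >= 1, tandem_gap_bp >= 0,
            aa_divergence >= 0, aa_divergence <= 0.95)
  structure(list(source_ref_id = source_ref_id, n_copies = n_copies,
                 aa_divergence = aa_divergence, degeneration = degeneration,
                 placement = placement, tandem_gap_bp = tandem_gap_bp,
                 strand_policy = strand_policy),
            class = "eprv_implant_spec")
}

# Build the (possibly degenerate) DNA of one element copy.
.make_copy_dna <- function(aa, spec, seed) {
  with_seed(seed, {
    dna <- reverse_translate(aa, "uniform")
    dna <- mutate_coding(dna, spec$aa_divergence)
    if (spec$degeneration == "internal_stop") {
      n <- nchar(dna) / 3
      p <- sample(seq(ceiling(0.35 * n), floor(0.65 * n)), 1)
      substr(dna, 3 * p - 2, 3 * p) <- "TAA"
    } else if (spec$degeneration == "frameshift") {
      # deletion constrained to the middle 60% so that neither in-frame
      # piece (nor a short lucky read-through extension) can reach the
      # 300-aa intactness threshold for domains of ~320 aa
      L <- nchar(dna)
      del <- sample(1:2, 1)
      at <- sample(seq(ceiling(0.2 * L), floor(0.8 * L) - del), 1)
      dna <- paste0(substr(dna, 1, at - 1), substr(dna, at + del, L))
    }
    dna
  })
}

#' Implant element copies into a background assembly
#'
#' Copies never overlap one another (a 2 kb exclusion zone keeps
#' dispersed copies clear of the 1500 bp tandem-collapse rule) and never
#' touch contig ends; placement is rejection-sampled with 100 retries.
#' Minus-strand copies store the reverse complement; truth coordinates
#' are always forward-strand, 0-based, half-open.
#'
#' @param assembly A [Biostrings::DNAStringSet].
#' @param library An `eprv_reflib` (see [load_reference_library()]) or a
#'   named character vector of peptides.
#' @param specs A list of [implant_spec()] objects.
#' @param seed RNG seed.
#' @param min_gap_bp Exclusion zone around each implanted interval.
#' @param margin_bp Minimum distance from contig ends.
#' @return A list with `assembly` (modified copy) and `truth`, a
#'   data.frame ledger with columns `contig`, `start`, `end`, `strand`,
#'   `source_ref_id`, `degeneration`, `placement`, `copy_group_id`.
#' @export
implant <- function(assembly, library, specs, seed = NULL,
                    min_gap_bp = 2000, margin_bp = 1000) {
  if (inherits(library, "eprv_reflib"))
    lib <- setNames(library$aa_seq, library$id)
  else lib <- library
  if (inherits(specs, "eprv_implant_spec")) specs <- list(specs)
  seqs <- as.character(assembly)
  lens <- nchar(seqs)
  occupied <- lapply(seqs, function(x) NULL)  # per-contig interval list
  truth <- list()

  place_block <- function(block_len, rng_k) {
    # returns c(contig_index, start0) or errors after 100 retries
    for (try in seq_len(100)) {
      ci <- sample(length(seqs), 1)
      if (lens[ci] < block_len + 2 * margin_bp) next
      s0 <- sample(lens[ci] - block_len - 2 * margin_bp, 1) + margin_bp
      iv <- c(s0 - min_gap_bp, s0 + block_len + min_gap_bp)
      occ <- occupied[[ci]]
      clash <- FALSE
      if (!is.null(occ))
        clash <- any(occ[, 1] < iv[2] & occ[, 2] > iv[1])
      if (!clash) {
        occupied[[ci]] <<- rbind(occ, c(s0, s0 + block_len))
        return(c(ci, s0))
      }
    }
    stop("could not place implant without overlap after 100 retries",
         call. = FALSE)
  }

  with_seed(seed, {
    for (g in seq_along(specs)) {
      spec <- specs[[g]]
      aa <- lib[[spec$source_ref_id]]
      if (is.null(aa)) stop("unknown source_ref_id: ", spec$source_ref_id,
                            call. = FALSE)
      grp <- sprintf("grp_%03d", g)
      strands <- switch(spec$strand_policy,
                        plus = rep("+", spec$n_copies),
                        minus = rep("-", spec$n_copies),
                        random = sample(c("+", "-"), spec$n_copies,
                                        replace = TRUE))
      dnas <- lapply(seq_len(spec$n_copies), function(i)
        .make_copy_dna(aa, spec, seed = NULL))
      if (spec$placement == "tandem") {
        block_len <- sum(nchar(unlist(dnas))) +
          spec$tandem_gap_bp * (spec$n_copies - 1)
        at <- place_block(block_len, g)
        ci <- at[1]; pos <- at[2]
        for (i in seq_len(spec$n_copies)) {
          d <- dnas[[i]]
          ins <- if (strands[i] == "-")
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(d))) else d
          substr(seqs[ci], pos + 1, pos + nchar(d)) <- ins
          truth[[length(truth) + 1]] <- data.frame(
            contig = names(assembly)[ci], start = pos, end = pos + nchar(d),
            strand = strands[i], source_ref_id = spec$source_ref_id,
            degeneration = spec$degeneration, placement = "tandem",
            copy_group_id = grp, stringsAsFactors = FALSE)
          pos <- pos + nchar(d) + spec$tandem_gap_bp
        }
      } else {
        for (i in seq_len(spec$n_copies)) {
          d <- dnas[[i]]
          at <- place_block(nchar(d), g)
          ci <- at[1]; pos <- at[2]
          ins <- if (strands[i] == "-")
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(d))) else d
          substr(seqs[ci], pos + 1, pos + nchar(d)) <- ins
          truth[[length(truth) + 1]] <- data.frame(
            contig = names(assembly)[ci], start = pos, end = pos + nchar(d),
            strand = strands[i], source_ref_id = spec$source_ref_id,
            degeneration = spec$degeneration, placement = "dispersed",
            copy_group_id = grp, stringsAsFactors = FALSE)
        }
      }
    }
  })
  truth <- do.call(rbind, truth)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(assembly)
  list(assembly = out, truth = truth)
}

#' Write / read a truth ledger as GFF3
#'
#' Intervals are stored 0-based half-open in memory and 1-based closed in
#' the GFF3 file (type `EPRV_truth`, attributes `source_ref_id`,
#' `degeneration`, `placement`, `copy_group_id`).  The round trip is
#' lossless.
#'
#' @param truth Truth data.frame from [implant()].
#' @param path GFF3 path.
#' @return `write_truth_gff3()` returns the path; `read_truth_gff3()`
#'   the reconstructed data.frame.
#' @export
write_truth_gff3 <- function(truth, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$contig,
    ranges = IRanges::IRanges(start = truth$start + 1, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "eprvscan", type = "EPRV_truth",
    ID = sprintf("truth_%04d", seq_len(nrow(truth))),
    source_ref_id = truth$source_ref_id,
    degeneration = truth$degeneration,
    placement = truth$placement,
    copy_group_id = truth$copy_group_id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_truth_gff3
#' @export
read_truth_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             source_ref_id = m$source_ref_id,
             degeneration = m$degeneration,
             placement = m$placement,
             copy_group_id = m$copy_group_id,
             stringsAsFactors = FALSE)
}

# -- synthetic reference library --------------------------------------------

#' Simulate a labelled reference RT-domain library
#'
#' Generates a star-shaped family of RT central domains: a root peptide
#' with the canonical RT catalytic box (YxDD region) held invariant, OTU
#' ancestors diverged from the root, members diverged from their
#' ancestor, and retroelement decoy families diverged further from the
#' root.  The geometry makes OTUs mutually ~50% diverged (so 60%
#' identity clustering separates them), members ~20% diverged within an
#' OTU, and decoys distant enough to triage yet close enough for a
#' translated search with Caulimoviridae probes to pick up.
#'
#' @param seed RNG seed.
#' @param composition Optional data.frame with columns `otu`,
#'   `lineage_class`, `n` fixing the record count per OTU (see
#'   [paper_library_composition()]); defaults to 2 members of every OTU
#'   in [caulimoviridae_otus()], 2 per decoy family and 1 Retroviridae.
#' @param length_aa Domain length (default 320 aa).
#' @param otu_divergence,member_divergence,decoy_divergence Fractional
#'   amino-acid divergences ancestor-from-root, member-from-ancestor and
#'   decoy-family-from-root.
#' @return An `eprv_reflib` data.frame.
#' @export
simulate_reference_library <- function(seed = 1, composition = NULL,
                                       length_aa = 320,
                                       otu_divergence = 0.30,
                                       member_divergence = 0.10,
                                       decoy_divergence = 0.45) {
  voc <- caulimoviridae_otus()
  if (is.null(composition)) {
    composition <- rbind(
      data.frame(otu = voc$caulimoviridae, lineage_class = "caulimoviridae",
                 n = 2, stringsAsFactors = FALSE),
      data.frame(otu = setdiff(voc$decoy, "Retroviridae"),
                 lineage_class = "retroelement", n = 2,
                 stringsAsFactors = FALSE),
      data.frame(otu = "Retroviridae", lineage_class = "retroelement",
                 n = 1, stringsAsFactors = FALSE))
  }
  rt_box <- "YVDDILVFSA"
  box_at <- min(150, length_aa - nchar(rt_box) - 10)
  protect <- seq(box_at, box_at + nchar(rt_box) - 1)
  with_seed(seed, {
    root <- random_peptide(length_aa)
    substr(root, box_at, box_at + nchar(rt_box) - 1) <- rt_box
    recs <- list()
    for (r in seq_len(nrow(composition))) {
      otu <- composition$otu[r]
      cls <- composition$lineage_class[r]
      div0 <- if (cls == "retroelement") decoy_divergence else otu_divergence
      anc <- mutate_peptide(root, round(div0 * length_aa), protect)
      for (i in seq_len(composition$n[r])) {
        recs[[length(recs) + 1]] <- data.frame(
          id = sprintf("%s_%02d", otu, i), lineage_class = cls, otu = otu,
          aa_seq = mutate_peptide(anc, round(member_divergence * length_aa),
                                  protect),
          stringsAsFactors = FALSE)
      }
    }
    lib <- do.call(rbind, recs)
    class(lib) <- c("eprv_reflib", "data.frame")
    lib
  })
}

#' Library composition emulating the published 182-sequence collection
#'
#' 104 sequences over the eleven episomal Caulimoviridae genera, 63 over
#' the six exclusively endogenous OTUs, 14 Ty3/Gypsy decoys over seven
#' families, and one Retroviridae outgroup.
#'
#' @return A data.frame usable as the `composition` argument of
#'   [simulate_reference_library()].
#' @export
paper_library_composition <- function() {
  voc <- caulimoviridae_otus()
  endo6 <- setdiff(voc$endogenous, "Wendovirus")
  rbind(
    data.frame(otu = voc$episomal, lineage_class = "caulimoviridae",
               n = c(10, 10, 10, 10, 10, 9, 9, 9, 9, 9, 9),
               stringsAsFactors = FALSE),
    data.frame(otu = endo6, lineage_class = "caulimoviridae",
               n = c(11, 11, 11, 10, 10, 10), stringsAsFactors = FALSE),
    data.frame(otu = setdiff(voc$decoy, "Retroviridae"),
               lineage_class = "retroelement", n = 2,
               stringsAsFactors = FALSE),
    data.frame(otu = "Retroviridae", lineage_class = "retroelement", n = 1,
               stringsAsFactors = FALSE))
}

# -- the default validation scenario ----------------------------------------

#' Simulate the default planted-element validation scenario
#'
#' The reference conditions used to validate the pipeline: 2 Mb of
#' background over 5 contigs carrying 20 intact dispersed Caulimoviridae
#' RT implants at 0-10% amino-acid divergence, 10 internal-stop and 10
#' frameshift degenerate copies, 10 Ty3/Gypsy decoy implants, one
#' 12-copy identical amplification burst, and one 5-copy tandem array
#' with 200 bp gaps.
#'
#' @param seed RNG seed driving every stochastic choice.
#' @param n_contigs,contig_bp Assembly shape (default 5 x 400 kb).
#' @param n_intact,n_stop,n_frameshift,n_decoy Dispersed implant counts.
#' @param burst_copies,tandem_copies,tandem_gap_bp Burst/array geometry.
#' @param max_divergence Upper end of the per-implant divergence draw.
#' @param library Optional pre-built `eprv_reflib`; defaults to
#'   [simulate_reference_library()] under a seed derived from `seed`.
#' @return A list with `assembly`, `truth`, `library`, `taxonomy` (a
#'   one-row host-taxonomy table for the simulated genome) and
#'   `genome_id`.
#' @export
simulate_scenario <- function(seed = 1, n_contigs = 5, contig_bp = 400000,
                              n_intact = 20, n_stop = 10, n_frameshift = 10,
                              n_decoy = 10, burst_copies = 12,
                              tandem_copies = 5, tandem_gap_bp = 200,
                              max_divergence = 0.10, library = NULL) {
  if (is.null(library))
    library <- simulate_reference_library(seed = child_seed(seed, 1))
  caulimo <- library$id[library$lineage_class == "caulimoviridae"]
  decoys <- library$id[library$lineage_class == "retroelement"]
  bg <- generate_background(n_contigs, contig_bp, gc_fraction = 0.36,
                            n_run_rate = 1e-5, seed = child_seed(seed, 2))
  specs <- with_seed(child_seed(seed, 3), {
    burst_src <- sample(caulimo, 1)
    tandem_src <- sample(setdiff(caulimo, burst_src), 1)
    pool <- setdiff(caulimo, c(burst_src, tandem_src))
    sp <- list()
    for (i in seq_len(n_intact))
      sp[[length(sp) + 1]] <- implant_spec(sample(pool, 1),
        aa_divergence = runif(1, 0, max_divergence))
    for (i in seq_len(n_stop))
      sp[[length(sp) + 1]] <- implant_spec(sample(pool, 1),
        aa_divergence = runif(1, 0, max_divergence),
        degeneration = "internal_stop")
    for (i in seq_len(n_frameshift))
      sp[[length(sp) + 1]] <- implant_spec(sample(pool, 1),
        aa_divergence = runif(1, 0, max_divergence),
        degeneration = "frameshift")
    for (i in seq_len(n_decoy))
      sp[[length(sp) + 1]] <- implant_spec(sample(decoys, 1),
        aa_divergence = runif(1, 0, max_divergence))
    if (burst_copies > 0)
      sp[[length(sp) + 1]] <- implant_spec(burst_src,
        n_copies = burst_copies, aa_divergence = 0)
    if (tandem_copies > 0)
      sp[[length(sp) + 1]] <- implant_spec(tandem_src,
        n_copies = tandem_copies, aa_divergence = 0, placement = "tandem",
        tandem_gap_bp = tandem_gap_bp)
    sp
  })
  imp <- implant(bg, library, specs, seed = child_seed(seed, 4))
  taxonomy <- data.frame(
    genome_id = "simgenome_01", species = "Simulatus unus",
    genus = "Simulatus", family = "Simulataceae", order = "Simulatales",
    class_ = "Magnoliopsida", kingdom = "Plantae", stringsAsFactors = FALSE)
  list(assembly = imp$assembly, truth = imp$truth, library = library,
       taxonomy = taxonomy, genome_id = "simgenome_01")
}
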