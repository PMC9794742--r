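# Element architecture around candidate RT loci: ORF prediction,
# domain-motif annotation, and the Wendovirus diagnostic rule
# (four partially overlapping ORFs with two aspartic-proteinase domains
# in different ORFs).

#' Predict ORFs in an element window
#'
#' Scans the three forward frames (the element is expected to be
#' oriented with the RT on the forward strand).  An ORF runs from the
#' first ATG after a stop codon (or the element start) to the next stop
#' codon or the element end; out-of-frame overlapping ORFs are all
#' reported.
#'
#' @param element_dna DNA string of the element window.
#' @param min_orf_aa Minimum peptide length (default 100 aa).
#' @return Data.frame with element-relative `start`/`end` (0-based
#'   half-open nucleotides; the terminating stop codon is included in
#'   the interval), `frame`, `aa_len` and `peptide` (no stop character).
#' @export
find_orfs <- function(element_dna, min_orf_aa = 100) {
  dna <- as.character(element_dna)
  out <- list()
  for (off in 0:2) {
    n <- ((nchar(dna) - off) %/% 3) * 3
    if (n < 3) next
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, off + 1, off + n)),
      if.fuzzy.codon = "solve"))
    m <- gregexpr("[^*]+", pep)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      r1 <- as.integer(m[k]); r2 <- r1 + len[k] - 1L
      region <- substr(pep, r1, r2)
      mpos <- regexpr("M", region, fixed = TRUE)
      if (mpos == -1) next
      a1 <- r1 + as.integer(mpos) - 1L   # aa position of the ATG
      orf_pep <- substr(pep, a1, r2)
      if (nchar(orf_pep) < min_orf_aa) next
      has_stop <- r2 < nchar(pep)        # terminated by a stop codon?
      out[[length(out) + 1]] <- data.frame(
        start = off + 3L * (a1 - 1L),
        end = off + 3L * r2 + if (has_stop) 3L else 0L,
        frame = off, aa_len = nchar(orf_pep), peptide = orf_pep,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), aa_len = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$frame), ]
  rownames(res) <- NULL
  res
}

#' Scan a peptide for domain motifs
#'
#' Finds all occurrences of each packaged motif pattern
#' ([load_motifs()]) and keeps those whose BLOSUM62 similarity to the
#' motif consensus reaches the motif's `min_score`; multiple motifs per
#' peptide (and multiple hits per motif) are allowed.
#'
#' @param peptide Peptide string.
#' @param motifs An `eprv_motifs` set.
#' @return Data.frame with `motif`, `offset_aa` (0-based), `score`.
#' @export
scan_domains <- function(peptide, motifs = load_motifs()) {
  out <- list()
  for (m in motifs) {
    g <- gregexpr(m$pattern, peptide)[[1]]
    if (g[1] == -1) next
    w <- nchar(m$consensus)
    for (s in as.integer(g)) {
      sc <- motif_match_score(substr(peptide, s, s + w - 1), m)
      if (!is.na(sc) && sc >= m$min_score)
        out[[length(out) + 1]] <- data.frame(
          motif = m$name, offset_aa = s - 1L, width_aa = w, score = sc,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(0), offset_aa = integer(0),
                      width_aa = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Annotate an element window (ORFs + domains + architecture call)
#'
#' @param element_dna DNA string of the window.
#' @param motifs Motif set.
#' @param min_orf_aa Minimum ORF length for architecture calls.
#' @return A list of class `eprv_annotation`: `orfs` (see
#'   [find_orfs()]), `domains` (one row per motif hit, with `orf_index`
#'   into `orfs`), `architecture_call`.
#' @export
annotate_element <- function(element_dna, motifs = load_motifs(),
                             min_orf_aa = 100) {
  orfs <- find_orfs(element_dna, min_orf_aa)
  doms <- list()
  for (i in seq_len(nrow(orfs))) {
    d <- scan_domains(orfs$peptide[i], motifs)
    if (nrow(d) > 0) {
      d$orf_index <- i
      doms[[length(doms) + 1]] <- d
    }
  }
  domains <- if (length(doms) > 0) do.call(rbind, doms) else
    data.frame(motif = character(0), offset_aa = integer(0),
               width_aa = integer(0), score = numeric(0),
               orf_index = integer(0), stringsAsFactors = FALSE)
  ann <- structure(list(orfs = orfs, domains = domains,
                        architecture_call = NA_character_),
                   class = "eprv_annotation")
  ann$architecture_call <- classify_architecture(ann)
  ann
}

#' Classify the architecture of an annotated element
#'
#' `wendovirus_like` requires, on the annotated ORFs: at least four
#' ORFs; a zinc-finger-bearing ORF (the coat-protein signature); an ORF
#' carrying a movement protein together with an aspartic proteinase; a
#' *distinct, downstream* ORF carrying a second aspartic proteinase
#' followed (in peptide order) by the reverse transcriptase and then the
#' RNase H; and at least two distinct aspartic-proteinase-bearing ORFs
#' in total.  Either proteinase motif family may occupy either position
#' (the packaged motifs are family surrogates).  Elements whose full
#' domain repertoire is present but arranged differently (e.g. the RT
#' ORF split in two) are `unresolved`; anything else is `other`.
#'
#' @param annotation An `eprv_annotation` (or a list with `orfs` and
#'   `domains` in the same layout).
#' @return `"wendovirus_like"`, `"unresolved"` or `"other"`.
#' @export
classify_architecture <- function(annotation) {
  orfs <- annotation$orfs
  dom <- annotation$domains
  ap <- c("aspartic_proteinase_1", "aspartic_proteinase_2")
  has <- function(i, what) any(dom$orf_index == i & dom$motif %in% what)
  first_off <- function(i, what) {
    v <- dom$offset_aa[dom$orf_index == i & dom$motif %in% what]
    if (length(v) == 0) NA_integer_ else min(v)
  }
  n_ap_orfs <- length(unique(dom$orf_index[dom$motif %in% ap]))
  mp_orfs <- which(vapply(seq_len(nrow(orfs)), function(i)
    has(i, "movement_protein") && has(i, ap), TRUE))
  rt_ok <- function(i) {
    a <- first_off(i, ap)
    r <- dom$offset_aa[dom$orf_index == i &
                         dom$motif == "reverse_transcriptase"]
    h <- dom$offset_aa[dom$orf_index == i & dom$motif == "rnaseh"]
    !is.na(a) && length(r) > 0 && length(h) > 0 &&
      any(r > a) && any(h > min(r[r > a]))
  }
  full_rule <- nrow(orfs) >= 4 &&
    any(vapply(seq_len(nrow(orfs)), has, TRUE, what = "zinc_finger")) &&
    length(mp_orfs) > 0 &&
    n_ap_orfs >= 2 &&
    any(vapply(seq_len(nrow(orfs)), function(j)
      j %in% setdiff(seq_len(nrow(orfs)), mp_orfs) &&
        any(orfs$start[j] > orfs$start[mp_orfs]) && rt_ok(j), TRUE))
  if (full_rule) return("wendovirus_like")
  # full repertoire present but arranged differently -> unresolved
  repertoire <- nrow(orfs) >= 4 &&
    all(c("zinc_finger", "movement_protein", "reverse_transcriptase",
          "rnaseh") %in% dom$motif) && n_ap_orfs >= 2
  if (repertoire) return("unresolved")
  "other"
}

# -- constructive Wendovirus-like fixture -----------------------------------

# Junction cassette: read in the current ORF's frame it contributes
# N,E,G and the terminating TAA; shifted one base, it opens the next
# ORF (M,K,D) which continues past the stop.  Appending "G" completes
# the next ORF's fourth codon (K).
.WENDO_JUNCTION <- "AATGAAGGATAA"

#' Construct a synthetic Wendovirus-like element
#'
#' Builds, deterministically under `seed`, a ~7.7 kb element with four
#' partially overlapping ORFs laid out as in the Wendovirus genome
#' organisation: ORF1 zinc finger | ORF2 movement protein + aspartic
#' proteinase | ORF3 second aspartic proteinase + RT + RNase H | ORF4
#' without known domains.  Consecutive ORFs overlap by 11 bp through a
#' shared junction cassette that encodes the upstream stop codon and the
#' downstream start codon in shifted frames.  The `include_*` switches
#' ablate individual motifs (for rule-negative controls); with all
#' motifs included the construction is verified to annotate as
#' `wendovirus_like`.
#'
#' @param seed RNG seed.
#' @param orf_aa Payload lengths (aa) of the four ORFs.
#' @param flank_bp Random flank added on each side.
#' @param include_zf,include_mp,include_ap1,include_ap2,include_rt,include_rh
#'   Motif inclusion switches.
#' @param motifs Motif set supplying the consensus sequences.
#' @return DNA string of the element.
#' @export
simulate_wendovirus_element <- function(seed = 1,
                                        orf_aa = c(200, 420, 700, 150),
                                        flank_bp = 1600,
                                        include_zf = TRUE,
                                        include_mp = TRUE,
                                        include_ap1 = TRUE,
                                        include_ap2 = TRUE,
                                        include_rt = TRUE,
                                        include_rh = TRUE,
                                        motifs = load_motifs()) {
  stopifnot(length(orf_aa) == 4, all(orf_aa >= 120))
  embed <- function(pep, consensus, at) {
    substr(pep, at, at + nchar(consensus) - 1) <- consensus
    pep
  }
  build <- function() {
    p1 <- random_peptide(orf_aa[1])
    if (include_zf) p1 <- embed(p1, motifs$zinc_finger$consensus, 80)
    p2 <- random_peptide(orf_aa[2])
    if (include_mp) p2 <- embed(p2, motifs$movement_protein$consensus, 60)
    if (include_ap1)
      p2 <- embed(p2, motifs$aspartic_proteinase_1$consensus, 300)
    p3 <- random_peptide(orf_aa[3])
    if (include_ap2)
      p3 <- embed(p3, motifs$aspartic_proteinase_2$consensus, 60)
    if (include_rt)
      p3 <- embed(p3, motifs$reverse_transcriptase$consensus, 300)
    if (include_rh) p3 <- embed(p3, motifs$rnaseh$consensus, 620)
    p4 <- random_peptide(orf_aa[4])
    flank5 <- paste(sample(c("A", "C", "G", "T"), flank_bp, TRUE),
                    collapse = "")
    flank3 <- paste(sample(c("A", "C", "G", "T"), flank_bp, TRUE),
                    collapse = "")
    paste0(flank5,
           "ATG", reverse_translate(p1, "uniform"), .WENDO_JUNCTION, "G",
           reverse_translate(p2, "uniform"), .WENDO_JUNCTION, "G",
           reverse_translate(p3, "uniform"), .WENDO_JUNCTION, "G",
           reverse_translate(p4, "uniform"), "TAA",
           flank3)
  }
  all_in <- include_zf && include_mp && include_ap1 && include_ap2 &&
    include_rt && include_rh
  with_seed(seed, {
    for (attempt in 1:20) {
      dna <- build()
      if (!all_in) return(dna)
      call <- annotate_element(dna, motifs)$architecture_call
      if (call == "wendovirus_like") return(dna)
    }
    stop("failed to construct a verifiable Wendovirus-like element",
         call. = FALSE)
  })
}

#' Write an element annotation as GFF3
#'
#' ORFs become `CDS` features; motif hits become `protein_match`
#' children with protein offsets converted to element nucleotides.
#'
#' @param annotation An `eprv_annotation`.
#' @param seqname Contig/element name for column 1.
#' @param path Output path.
#' @param offset_bp Added to all coordinates (window placement on the
#'   parent contig).
#' @export
write_annotation_gff3 <- function(annotation, seqname, path,
                                  offset_bp = 0) {
  orfs <- annotation$orfs
  dom <- annotation$domains
  rows <- character(0)
  for (i in seq_len(nrow(orfs))) {
    oid <- sprintf("orf_%02d", i)
    rows <- c(rows, paste(seqname, "eprvscan", "CDS",
                          offset_bp + orfs$start[i] + 1,
                          offset_bp + orfs$end[i], ".", "+",
                          orfs$frame[i],
                          paste0("ID=", oid), sep = "\t"))
    dd <- dom[dom$orf_index == i, , drop = FALSE]
    for (k in seq_len(nrow(dd))) {
      s <- orfs$start[i] + 3 * dd$offset_aa[k]
      w <- 3 * dd$width_aa[k]
      rows <- c(rows, paste(seqname, "eprvscan", "protein_match",
                            offset_bp + s + 1, offset_bp + s + w, ".",
                            "+", ".",
                            paste0("Parent=", oid, ";Name=", dd$motif[k],
                                   ";score=", dd$score[k]), sep = "\t"))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
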