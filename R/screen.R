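# Screening raw hits down to intact, non-redundant, Caulimoviridae-class
# candidate RT domains.  The pipeline order is fixed: intactness ->
# proximity dedup -> lineage triage; the composition is idempotent.

#' Keep only intact RT-domain hits
#'
#' A hit is intact when its ungapped genomic peptide is at least
#' `min_aa` residues, contains no stop codon, and its subject alignment
#' row carries no gap (a single-frame, indel-free alignment is the
#' operational "no frameshifts": a frameshift splits a domain across
#' frames and can never satisfy this).
#'
#' @param hits Hit data.frame from [eprv_search()] or
#'   [parse_external_hits()].
#' @param min_aa Minimum peptide length (default 300 aa).
#' @return The surviving rows.
#' @export
filter_intact <- function(hits, min_aa = 300) {
  if (nrow(hits) == 0) return(hits)
  pep <- hits$matched_peptide
  if (anyNA(pep)) {
    warning(sum(is.na(pep)),
            " hit(s) without a subject peptide dropped from the ",
            "intactness screen")
  }
  keep <- !is.na(pep) &
    nchar(pep) >= min_aa &
    !grepl("*", pep, fixed = TRUE) &
    !grepl("-", hits$aligned_subject_aa, fixed = TRUE)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse proximal hits (tandem-array rule)
#'
#' Hits on the same contig lying less than `window_bp` apart (strict
#' inter-interval gap, strand-agnostic; overlapping hits always
#' conflict) are treated as one tandem/nested array: the proximity
#' relation is chained transitively left to right, and each resulting
#' chain keeps exactly one survivor -- its highest bit score, ties going
#' to the leftmost.  A tandem array of any size therefore collapses to
#' a single representative hit, and no two survivors lie closer than
#' `window_bp`.
#'
#' @param hits Hit data.frame.
#' @param window_bp Minimum allowed gap (default 1500 bp; a gap of
#'   exactly `window_bp` is allowed -- "less than" is strict).
#' @return The surviving rows, sorted by position.
#' @export
dedup_proximity <- function(hits, window_bp = 1500) {
  if (nrow(hits) == 0) return(hits)
  parts <- split(seq_len(nrow(hits)), hits$contig)
  surv_idx <- integer(0)
  for (idx in parts) {
    idx <- idx[order(hits$start_bp[idx], hits$end_bp[idx])]
    # chain hits whose gap to the running right edge is < window_bp
    chain_of <- integer(length(idx))
    chain <- 1L
    right <- hits$end_bp[idx[1]]
    chain_of[1] <- 1L
    for (k in seq_along(idx)[-1]) {
      if (hits$start_bp[idx[k]] - right >= window_bp) chain <- chain + 1L
      chain_of[k] <- chain
      right <- max(right, hits$end_bp[idx[k]])
    }
    for (ch in unique(chain_of)) {
      members <- idx[chain_of == ch]
      best <- members[which.max(hits$score_bits[members])]  # leftmost tie
      surv_idx <- c(surv_idx, best)
    }
  }
  out <- hits[sort(surv_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Triage hits by lineage and emit candidate RT domains
#'
#' Every hit peptide is scored by global alignment (same BLOSUM62/11/1
#' parameters as the search) against every reference in the library; its
#' provisional class is the lineage class of the best-scoring reference.
#' Hits closer to retroelement (Ty3/Gypsy) references are removed; only
#' Caulimoviridae-class hits become candidates.  An exact score tie
#' between classes is resolved by the higher summed top-3 score per
#' class (then Caulimoviridae, for full determinism).
#'
#' @param hits Hit data.frame (peptides required).
#' @param library An `eprv_reflib` containing both lineage classes.
#' @return A data.frame of class `eprv_candidates`: the hit fields plus
#'   `candidate_id`, `aa_seq`, `best_ref_id`, `best_ref_otu`,
#'   `provisional_class` (only `caulimoviridae` rows are returned).
#' @export
triage_lineage <- function(hits, library) {
  stopifnot(inherits(library, "eprv_reflib"))
  for (cls in c("caulimoviridae", "retroelement"))
    if (!any(library$lineage_class == cls))
      stop("cannot triage: library has no '", cls, "' references",
           call. = FALSE)
  lib <- library[order(library$id), ]
  out <- hits
  out$candidate_id <- sprintf("%s:%d-%d:%s", hits$contig, hits$start_bp,
                              hits$end_bp, hits$strand)
  out$aa_seq <- hits$matched_peptide
  out$best_ref_id <- NA_character_
  out$best_ref_otu <- NA_character_
  out$provisional_class <- NA_character_
  if (nrow(hits) > 0) {
    pats <- Biostrings::AAStringSet(setNames(lib$aa_seq, lib$id))
    for (r in seq_len(nrow(hits))) {
      sc <- Biostrings::score(Biostrings::pairwiseAlignment(
        pattern = pats, subject = Biostrings::AAString(out$aa_seq[r]),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1))
      top <- which(sc == max(sc))
      classes_at_top <- unique(lib$lineage_class[top])
      if (length(classes_at_top) == 1) {
        cls <- classes_at_top
      } else {
        sum3 <- vapply(c("caulimoviridae", "retroelement"), function(cl) {
          s <- sort(sc[lib$lineage_class == cl], decreasing = TRUE)
          sum(utils::head(s, 3))
        }, 0)
        cls <- if (sum3[["retroelement"]] > sum3[["caulimoviridae"]])
          "retroelement" else "caulimoviridae"
      }
      best <- top[lib$lineage_class[top] == cls][1]
      out$best_ref_id[r] <- lib$id[best]
      out$best_ref_otu[r] <- lib$otu[best]
      out$provisional_class[r] <- cls
    }
  }
  out <- out[!is.na(out$provisional_class) &
               out$provisional_class == "caulimoviridae", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eprv_candidates", "data.frame")
  out
}

#' Run the complete screen (intactness, dedup, triage)
#'
#' @param hits Hit data.frame.
#' @param library Reference library with both lineage classes.
#' @param min_aa,window_bp Thresholds passed to [filter_intact()] and
#'   [dedup_proximity()].
#' @return Candidate data.frame (see [triage_lineage()]).
#' @export
screen_hits <- function(hits, library, min_aa = 300, window_bp = 1500) {
  triage_lineage(dedup_proximity(filter_intact(hits, min_aa), window_bp),
                 library)
}

#' Write candidates as FASTA / GFF3 / TSV
#'
#' @param candidates `eprv_candidates` data.frame.
#' @param fasta_path,gff3_path,tsv_path Output paths (any may be `NULL`).
#' @export
write_candidates <- function(candidates, fasta_path = NULL,
                             gff3_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(
        setNames(candidates$aa_seq, candidates$candidate_id)),
      fasta_path)
  }
  if (!is.null(gff3_path)) {
    if (nrow(candidates) > 0) {
      gr <- GenomicRanges::GRanges(
        seqnames = candidates$contig,
        ranges = IRanges::IRanges(candidates$start_bp + 1,
                                  candidates$end_bp),
        strand = candidates$strand)
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        source = "eprvscan", type = "EPRV_RT_candidate",
        ID = candidates$candidate_id,
        best_ref_id = candidates$best_ref_id)
      rtracklayer::export(gr, gff3_path, format = "gff3")
    } else writeLines("##gff-version 3", gff3_path)
  }
  if (!is.null(tsv_path)) {
    cols <- c("candidate_id", "contig", "start_bp", "end_bp", "strand",
              "frame", "query_id", "score_bits", "evalue", "best_ref_id",
              "best_ref_otu", "aa_seq")
    write_tsv(candidates[, intersect(cols, names(candidates))], tsv_path)
  }
  invisible(candidates)
}
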