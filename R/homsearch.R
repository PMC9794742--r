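# Translated homology search: a self-contained tBLASTn surrogate.
#
# Each contig is translated in all six frames; frame translations are cut
# at stop codons into stop-free segments, candidate query/segment pairs
# are pre-filtered by an exact k-mer seed, and surviving pairs are scored
# by local Smith-Waterman alignment (BLOSUM62, gap open 11 / extend 1 --
# the tBLASTn defaults).  E-values use Karlin-Altschul statistics with
# the published gapped BLOSUM62 parameters (lambda = 0.267, K = 0.041)
# and search space m x n = query length x total translated length;
# agreement with NCBI's edge-corrected E-values is not claimed, only the
# functional role of the threshold.

#' Translate a DNA sequence in all six reading frames
#'
#' Standard genetic code; codons containing `N` become `X`; stop codons
#' are rendered `*`.  Frames 0-2 read the forward strand at offsets
#' 0/1/2, frames 3-5 read the reverse complement at offsets 0/1/2.
#' Trailing partial codons are dropped.
#'
#' @param dna A DNA string or [Biostrings::DNAString] over `{A,C,G,T,N}`.
#' @return Named character vector `frame0` ... `frame5`.
#' @export
six_frame_translate <- function(dna) {
  d <- if (inherits(dna, "DNAString")) dna else Biostrings::DNAString(dna)
  rc <- Biostrings::reverseComplement(d)
  tr <- function(x, off) {
    n <- ((length(x) - off) %/% 3) * 3
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1, off + n), if.fuzzy.codon = "solve"))
  }
  c(frame0 = tr(d, 0), frame1 = tr(d, 1), frame2 = tr(d, 2),
    frame3 = tr(rc, 0), frame4 = tr(rc, 1), frame5 = tr(rc, 2))
}

# Maximal stop-free segments of a frame translation.
# Returns data.frame(start_aa [0-based], seq).
.stop_free_segments <- function(pep, min_aa) {
  if (!nzchar(pep)) return(NULL)
  m <- gregexpr("[^*]+", pep)[[1]]
  if (m[1] == -1) return(NULL)
  len <- attr(m, "match.length")
  keep <- len >= min_aa
  if (!any(keep)) return(NULL)
  data.frame(start_aa = as.integer(m[keep]) - 1L,
             seq = substring(pep, m[keep], m[keep] + len[keep] - 1L),
             stringsAsFactors = FALSE)
}

.kmer_set <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

.empty_hits <- function() {
  data.frame(contig = character(0), start_bp = integer(0),
             end_bp = integer(0), strand = character(0), frame = integer(0),
             query_id = character(0), aligned_query_aa = character(0),
             aligned_subject_aa = character(0),
             matched_peptide = character(0), score_raw = numeric(0),
             score_bits = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Search genome assemblies for protein-level matches to reference RTs
#'
#' Internal translated search (see the file-level notes): locates local
#' alignments of each query peptide within the six-frame translation of
#' each contig and maps them back to forward-strand nucleotide
#' coordinates.  Alignments are strictly single-frame -- a frameshifted
#' element can only be recovered as two independent partial hits.
#'
#' @param queries Named character vector / [Biostrings::AAStringSet] of
#'   query peptides, or an `eprv_reflib` (all rows are used).
#' @param assembly A [Biostrings::DNAStringSet] (or single DNA string).
#' @param evalue_max Report hits with E-value at or below this (default
#'   `1e-10`).
#' @param score_min Additional bit-score floor (default 0).
#' @param min_seg_aa Stop-free segments shorter than this are never
#'   examined; 60 aa keeps partial fragments of degenerate elements
#'   visible while skipping the bulk of random translation.
#' @param seed_k Exact k-mer seed length for the pre-filter (default 4).
#' @param exhaustive If `TRUE`, skip the seed pre-filter and align every
#'   query against every segment (the full Smith-Waterman reference
#'   path used by the test oracles).
#' @return A data.frame of raw hits, one row per (query, segment) local
#'   alignment: `contig`, `start_bp`/`end_bp` (0-based half-open,
#'   forward strand), `strand`, `frame` (offset 0-2 within the strand),
#'   `query_id`, `aligned_query_aa`/`aligned_subject_aa` (gapped rows),
#'   `matched_peptide` (ungapped genomic peptide), `score_raw`,
#'   `score_bits`, `evalue`.
#' @export
eprv_search <- function(queries, assembly, evalue_max = 1e-10,
                        score_min = 0, min_seg_aa = 60, seed_k = 4,
                        exhaustive = FALSE) {
  if (inherits(queries, "eprv_reflib"))
    queries <- setNames(queries$aa_seq, queries$id)
  if (inherits(queries, "AAStringSet"))
    queries <- setNames(as.character(queries), names(queries))
  if (length(queries) == 0) stop("no query sequences", call. = FALSE)
  if (is.null(names(queries)) || any(!nzchar(names(queries))))
    stop("queries must be named", call. = FALSE)
  if (is.character(assembly) || inherits(assembly, "DNAString"))
    assembly <- Biostrings::DNAStringSet(
      setNames(as.character(assembly), "contig_01"))
  if (length(assembly) == 0) return(.empty_hits())

  params <- align_params()
  # translate everything first: the E-value search space needs the total
  contig_frames <- vector("list", length(assembly))
  n_total <- 0
  for (i in seq_along(assembly)) {
    if (Biostrings::width(assembly)[i] < 3) {
      warning("contig '", names(assembly)[i],
              "' shorter than one codon; skipped")
      next
    }
    fr <- six_frame_translate(assembly[[i]])
    contig_frames[[i]] <- fr
    n_total <- n_total + sum(nchar(fr))
  }
  if (n_total == 0) return(.empty_hits())

  # collect candidate segments
  segs <- list()
  for (i in seq_along(assembly)) {
    fr <- contig_frames[[i]]
    if (is.null(fr)) next
    for (f in 0:5) {
      s <- .stop_free_segments(fr[[f + 1]], min_seg_aa)
      if (is.null(s)) next
      s$contig_i <- i
      s$frame6 <- f
      segs[[length(segs) + 1]] <- s
    }
  }
  if (length(segs) == 0) return(.empty_hits())
  segs <- do.call(rbind, segs)
  seg_kmers <- lapply(segs$seq, .kmer_set, k = seed_k)

  contig_len <- Biostrings::width(assembly)
  hits <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qid <- names(queries)[qi]
    m <- nchar(q)
    idx <- if (exhaustive) seq_len(nrow(segs)) else {
      qk <- .kmer_set(q, seed_k)
      which(vapply(seg_kmers, function(s) any(s %in% qk), TRUE))
    }
    if (length(idx) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(segs$seq[idx]),
      subject = Biostrings::AAString(q),
      type = "local", substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    raw <- Biostrings::score(aln)
    bits <- (params$lambda * raw - log(params$K)) / log(2)
    ev <- m * n_total * 2^(-bits)
    keep <- which(ev <= evalue_max & bits >= score_min)
    if (length(keep) == 0) next
    p1 <- segs$start_aa[idx][keep] +
      IRanges::start(Biostrings::pattern(aln))[keep]  # 1-based aa in frame
    p2 <- segs$start_aa[idx][keep] +
      IRanges::end(Biostrings::pattern(aln))[keep]
    f6 <- segs$frame6[idx][keep]
    ci <- segs$contig_i[idx][keep]
    off <- f6 %% 3
    L <- contig_len[ci]
    fwd <- f6 < 3
    start_bp <- ifelse(fwd, off + 3 * (p1 - 1), L - (off + 3 * p2))
    end_bp <- ifelse(fwd, off + 3 * p2, L - (off + 3 * (p1 - 1)))
    sub_rows <- as.character(Biostrings::pattern(aln))[keep]
    hits[[length(hits) + 1]] <- data.frame(
      contig = names(assembly)[ci],
      start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
      strand = ifelse(fwd, "+", "-"), frame = off,
      query_id = qid,
      aligned_query_aa = as.character(Biostrings::subject(aln))[keep],
      aligned_subject_aa = sub_rows,
      matched_peptide = gsub("-", "", sub_rows, fixed = TRUE),
      score_raw = raw[keep], score_bits = bits[keep], evalue = ev[keep],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(.empty_hits())
  out <- do.call(rbind, hits)
  out <- out[order(out$contig, out$start_bp, out$end_bp, out$query_id), ]
  rownames(out) <- NULL
  out
}

#' Import hits from an external tabular translated search
#'
#' Adapter for users who run tBLASTn themselves: reads 12+-column BLAST
#' tabular output (`qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore [sseq]`), skipping `#` comment
#' lines, and normalises subject coordinates to 0-based half-open
#' forward-strand intervals; the strand is inferred from
#' `sstart > send`.  When a 13th column with the aligned subject
#' peptide is present it feeds the downstream intactness screen.
#'
#' @param tabular_path Path to the tabular file.
#' @return A hit data.frame in the same layout as [eprv_search()]
#'   (alignment rows `NA` when the file does not carry them).
#' @export
parse_external_hits <- function(tabular_path) {
  lines <- readLines(tabular_path)
  lines <- lines[nzchar(lines)]
  is_data <- !startsWith(lines, "#")
  rows <- lapply(which(is_data), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12)
      stop("line ", i, ": expected >= 12 tab-separated fields, got ",
           length(f), call. = FALSE)
    sstart <- suppressWarnings(as.numeric(f[9]))
    send <- suppressWarnings(as.numeric(f[10]))
    ev <- suppressWarnings(as.numeric(f[11]))
    bs <- suppressWarnings(as.numeric(f[12]))
    if (anyNA(c(sstart, send, ev, bs)))
      stop("line ", i, ": malformed numeric field", call. = FALSE)
    sseq <- if (length(f) >= 13) f[13] else NA_character_
    data.frame(contig = f[2],
               start_bp = as.integer(min(sstart, send) - 1),
               end_bp = as.integer(max(sstart, send)),
               strand = if (sstart > send) "-" else "+",
               frame = NA_integer_, query_id = f[1],
               aligned_query_aa = NA_character_,
               aligned_subject_aa = sseq,
               matched_peptide = if (is.na(sseq)) NA_character_ else
                 gsub("-", "", sseq, fixed = TRUE),
               score_raw = NA_real_, score_bits = bs, evalue = ev,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) return(.empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export hits as TSV or BED6
#'
#' @param hits Hit data.frame from [eprv_search()].
#' @param path Output path.
#' @param header_comment Optional `#` header line for provenance.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path, header_comment = NULL) {
  write_tsv(hits, path, header_comment)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start_bp, hits$end_bp,
                    hits$query_id, round(hits$score_bits), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
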