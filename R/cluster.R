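# Greedy identity clustering of candidate RT peptides (CD-HIT
# semantics) and detection of recent amplification bursts.

#' Pairwise amino-acid identity (CD-HIT convention)
#'
#' Identity is the number of identical aligned positions divided by the
#' length of the *shorter* sequence, computed on a global alignment of
#' the pair (BLOSUM62, gap open 11 / extend 1).  Symmetric, in [0, 1].
#'
#' @param a_peptide,b_peptide Non-empty peptides.
#' @return Identity fraction.
#' @export
pairwise_identity <- function(a_peptide, b_peptide) {
  stopifnot(nzchar(a_peptide), nzchar(b_peptide))
  if (a_peptide == b_peptide) return(1)
  aln <- pw_global(a_peptide, b_peptide)
  Biostrings::pid(aln, type = "PID3") / 100
}

# identities of one sequence against several representatives (vectorised)
.identity_to_reps <- function(seqs, subject) {
  exact <- seqs == subject
  out <- as.numeric(exact)
  todo <- which(!exact)
  if (length(todo) > 0) {
    aln <- pw_global(seqs[todo], subject)
    out[todo] <- Biostrings::pid(aln, type = "PID3") / 100
  }
  out
}

#' Greedy incremental clustering at an identity threshold
#'
#' CD-HIT semantics: sequences are sorted by decreasing length (ties
#' broken by id, lexicographically); the first sequence founds cluster
#' 1; every subsequent sequence joins the first existing cluster whose
#' representative it matches at `>= threshold` identity
#' ([pairwise_identity()]), otherwise it founds a new cluster.  The
#' representative is always the founding (longest) member.  Unlike
#' CD-HIT itself, no short-word pre-filter is used -- every comparison is
#' an exact pairwise alignment.
#'
#' @param candidates An `eprv_candidates` data.frame, or a named
#'   character vector of peptides.
#' @param threshold Identity threshold in (0, 1]; 0.60 and 1.00
#'   correspond to the cluster60 / cluster100 analyses.
#' @param allow_split_representatives If `TRUE`, a cluster whose members
#'   are not all within `threshold` identity of *each other* (the greedy
#'   rule only guarantees identity to the representative) gains a second
#'   representative: the member least similar to the founder.  Off by
#'   default.
#' @return An object of class `eprv_clusterset`: list with `threshold`
#'   and `membership`, a data.frame (`member_id`, `cluster_id`,
#'   `representative`, `identity_to_rep`).
#' @export
greedy_cluster <- function(candidates, threshold,
                           allow_split_representatives = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- if (inherits(candidates, "data.frame"))
    setNames(candidates$aa_seq, candidates$candidate_id) else candidates
  if (length(seqs) == 0) stop("no sequences to cluster", call. = FALSE)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  eps <- 1e-9
  rep_ids <- character(0)
  assign_cluster <- integer(length(seqs))
  ident <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    if (length(rep_ids) > 0) {
      ids <- .identity_to_reps(seqs[rep_ids], seqs[[i]])
      hit <- which(ids >= threshold - eps)
    } else hit <- integer(0)
    if (length(hit) > 0) {
      assign_cluster[i] <- hit[1]
      ident[i] <- ids[hit[1]]
    } else {
      rep_ids <- c(rep_ids, names(seqs)[i])
      assign_cluster[i] <- length(rep_ids)
      ident[i] <- 1
    }
  }
  membership <- data.frame(member_id = names(seqs),
                           cluster_id = sprintf("cluster_%03d",
                                                assign_cluster),
                           representative = names(seqs) ==
                             rep_ids[assign_cluster],
                           identity_to_rep = ident,
                           stringsAsFactors = FALSE)
  if (allow_split_representatives) {
    for (cl in unique(membership$cluster_id)) {
      mem <- membership$member_id[membership$cluster_id == cl]
      if (length(mem) < 3) next
      founder <- mem[membership$representative[match(mem,
                                                     membership$member_id)]]
      others <- setdiff(mem, founder)
      ids <- .identity_to_reps(seqs[others], seqs[[founder]])
      # check within-cluster diameter via the weakest member
      weakest <- others[which.min(ids)]
      pairwise_min <- min(vapply(others, function(o)
        pairwise_identity(seqs[[o]], seqs[[weakest]]), 0))
      if (pairwise_min < threshold - eps)
        membership$representative[membership$member_id == weakest] <- TRUE
    }
  }
  structure(list(threshold = threshold, membership = membership),
            class = "eprv_clusterset")
}

#' @export
print.eprv_clusterset <- function(x, ...) {
  n <- length(unique(x$membership$cluster_id))
  cat("eprv_clusterset: ", nrow(x$membership), " sequences in ", n,
      " cluster(s) at >= ", 100 * x$threshold, "% identity\n", sep = "")
  invisible(x)
}

#' Cluster sizes of a cluster set
#'
#' @param clusterset An `eprv_clusterset`.
#' @return Named integer vector (cluster id -> size).
#' @export
cluster_sizes <- function(clusterset) {
  tab <- table(clusterset$membership$cluster_id)
  setNames(as.integer(tab), names(tab))
}

#' Detect recent amplification (cluster100 bursts)
#'
#' Multiple copies of a 100% identical RT domain in one genome indicate
#' amplification after insertion.  Candidates are clustered per genome
#' at threshold 1.0 and only clusters with at least `min_copies` members
#' are reported.
#'
#' @param candidates `eprv_candidates` with a `genome_id` column (a
#'   missing column is treated as a single genome).
#' @param min_copies Minimum burst size (default 10; clusters of 9 or
#'   fewer identical copies are not reported).
#' @return Data.frame with one row per amplification cluster:
#'   `genome_id`, `cluster_id`, `n_copies`, `representative_id`.
#' @export
find_amplification <- function(candidates, min_copies = 10) {
  if (nrow(candidates) == 0)
    return(data.frame(genome_id = character(0), cluster_id = character(0),
                      n_copies = integer(0),
                      representative_id = character(0),
                      stringsAsFactors = FALSE))
  gid <- if ("genome_id" %in% names(candidates))
    candidates$genome_id else rep("genome_01", nrow(candidates))
  out <- list()
  for (g in unique(gid)) {
    sub <- candidates[gid == g, , drop = FALSE]
    cs <- greedy_cluster(sub, threshold = 1.0)
    sizes <- cluster_sizes(cs)
    big <- names(sizes)[sizes >= min_copies]
    for (cl in big) {
      mem <- cs$membership[cs$membership$cluster_id == cl, ]
      out[[length(out) + 1]] <- data.frame(
        genome_id = g, cluster_id = paste0(g, ":", cl),
        n_copies = nrow(mem),
        representative_id = mem$member_id[mem$representative][1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(genome_id = character(0), cluster_id = character(0),
                      n_copies = integer(0),
                      representative_id = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write cluster membership as TSV and representatives as FASTA
#'
#' @param clusterset An `eprv_clusterset`.
#' @param seqs Named peptide vector covering all member ids.
#' @param tsv_path,rep_fasta_path Output paths (either may be `NULL`).
#' @export
write_clusters <- function(clusterset, seqs = NULL, tsv_path = NULL,
                           rep_fasta_path = NULL) {
  if (!is.null(tsv_path)) write_tsv(clusterset$membership, tsv_path)
  if (!is.null(rep_fasta_path)) {
    stopifnot(!is.null(seqs))
    reps <- clusterset$membership$member_id[
      clusterset$membership$representative]
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(seqs[reps]), rep_fasta_path)
  }
  invisible(clusterset)
}
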