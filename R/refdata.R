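# Reference data: the labelled RT-domain library, host taxonomy,
# divergence-time table and the packaged domain-motif set.

#' Controlled vocabulary of Caulimoviridae OTUs and retroelement decoys
#'
#' The classification labels used throughout the package: the eleven
#' episomal genera of Caulimoviridae, the six exclusively endogenous
#' OTUs, the endogenous-only Wendovirus group, and the Ty3/Gypsy
#' retrotransposon decoy families carried in the reference library to
#' absorb cross-hits.
#'
#' @return A list with character vectors `episomal`, `endogenous`,
#'   `decoy`, plus `caulimoviridae` (episomal + endogenous).
#' @export
#' @examples
#' caulimoviridae_otus()$episomal
caulimoviridae_otus <- function() {
  episomal <- c("Badnavirus", "Caulimovirus", "Vaccinivirus", "Soymovirus",
                "Cavemovirus", "Solendovirus", "Dioscovirus", "Rosadnavirus",
                "Tungrovirus", "Petuvirus", "Ruflodivirus")
  endogenous <- c("Florendovirus", "Xendovirus", "Yendovirus", "Zendovirus",
                  "Gymnendovirus", "Fernendovirus", "Wendovirus")
  decoy <- c("Athila", "CRM", "Galadriel", "Ogre", "Reina", "Retand",
             "Tekay", "Retroviridae")
  list(episomal = episomal, endogenous = endogenous, decoy = decoy,
       caulimoviridae = c(episomal, endogenous))
}

#' Load the labelled reference RT-domain library
#'
#' Reads a protein FASTA of RT central-domain sequences together with a
#' tab-separated metadata table assigning each sequence a lineage class
#' (`caulimoviridae` or `retroelement`) and an OTU label (a
#' Caulimoviridae genus/OTU, or a retroelement family for decoys).
#'
#' @param fasta_path Protein FASTA; record ids must match metadata ids 1:1.
#' @param metadata_path TSV with columns `id`, `lineage_class`, `otu`.
#' @return A data.frame of class `eprv_reflib` with columns `id`,
#'   `lineage_class`, `otu`, `aa_seq`.  Per-class counts are reported via
#'   a message.
#' @export
load_reference_library <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0) stop("no records in ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  meta <- read_tsv_strict(metadata_path,
                          required = c("id", "lineage_class", "otu"))
  if (anyDuplicated(meta$id))
    stop("duplicate metadata ids", call. = FALSE)
  no_meta <- setdiff(ids, meta$id)
  if (length(no_meta) > 0)
    stop("sequence id(s) without metadata: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  no_seq <- setdiff(meta$id, ids)
  if (length(no_seq) > 0)
    stop("metadata id(s) without sequence: ",
         paste(no_seq, collapse = ", "), call. = FALSE)
  aa <- as.character(seqs)
  names(aa) <- ids
  if (any(grepl("\\*", aa)))
    stop("reference sequences must not contain stop characters ('*')",
         call. = FALSE)
  assert_protein(aa, "reference library")
  bad_class <- setdiff(unique(meta$lineage_class),
                       c("caulimoviridae", "retroelement"))
  if (length(bad_class) > 0)
    stop("unknown lineage_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(meta$otu))) stop("empty otu label", call. = FALSE)
  lib <- data.frame(id = meta$id, lineage_class = meta$lineage_class,
                    otu = meta$otu, aa_seq = unname(aa[meta$id]),
                    stringsAsFactors = FALSE)
  short <- lib$id[nchar(lib$aa_seq) < 100]
  if (length(short) > 0)
    stop("reference sequence(s) shorter than 100 aa: ",
         paste(short, collapse = ", "), call. = FALSE)
  class(lib) <- c("eprv_reflib", "data.frame")
  counts <- table(lib$lineage_class)
  message("reference library: ", nrow(lib), " records (",
          paste(names(counts), unname(counts), sep = "=", collapse = ", "),
          ")")
  lib
}

#' Write a reference library to FASTA + metadata TSV
#'
#' @param lib An `eprv_reflib` data.frame.
#' @param fasta_path,metadata_path Output paths.
#' @export
write_reference_library <- function(lib, fasta_path, metadata_path) {
  seqs <- Biostrings::AAStringSet(setNames(lib$aa_seq, lib$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(lib[, c("id", "lineage_class", "otu")], metadata_path)
  invisible(list(fasta = fasta_path, metadata = metadata_path))
}

#' Load a species/genus divergence-time table
#'
#' Reads a three-column TSV (`taxonA`, `taxonB`, `divergence_my`) of
#' pairwise divergence times in million years (a local stand-in for
#' TimeTree lookups).  Lookups are symmetric and self-pairs are 0.
#'
#' @param tsv_path Path to the table.
#' @return An object of class `eprv_divtable`.
#' @seealso [divergence_lookup()]
#' @export
load_divergence_table <- function(tsv_path) {
  df <- read_tsv_strict(tsv_path,
                        required = c("taxonA", "taxonB", "divergence_my"))
  df$divergence_my <- as.numeric(df$divergence_my)
  if (any(is.na(df$divergence_my)))
    stop("non-numeric divergence values", call. = FALSE)
  if (any(df$divergence_my < 0))
    stop("negative divergence ages are not allowed", call. = FALSE)
  key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "\t"),
                df$taxonA, df$taxonB, USE.NAMES = FALSE)
  # conflicting duplicates are an error; consistent duplicates collapse
  tab <- tapply(df$divergence_my, key, function(v) {
    if (length(unique(v)) > 1) NA_real_ else v[[1]]
  })
  if (any(is.na(tab))) {
    bad <- names(tab)[is.na(tab)]
    stop("conflicting duplicate pair(s): ",
         paste(gsub("\t", "/", bad), collapse = ", "), call. = FALSE)
  }
  obj <- list(entries = setNames(as.numeric(tab), names(tab)))
  class(obj) <- "eprv_divtable"
  obj
}

#' Look up the divergence time of a pair of taxa
#'
#' Symmetric lookup; a self-pair returns 0 regardless of table content.
#' A missing pair is a reportable condition (class
#' `eprv_missing_pair`), never a silent zero.
#'
#' @param table An `eprv_divtable`.
#' @param a,b Taxon names (genus or species rank, matching the table).
#' @param strict If `TRUE` (default) a missing pair raises a condition;
#'   if `FALSE` it returns `NA_real_`.
#' @return Divergence time in million years.
#' @export
divergence_lookup <- function(table, a, b, strict = TRUE) {
  stopifnot(inherits(table, "eprv_divtable"))
  if (a == b) return(0)
  key <- paste(sort(c(a, b)), collapse = "\t")
  v <- unname(table$entries[key])
  if (is.na(v)) {
    if (strict)
      stop(structure(class = c("eprv_missing_pair", "error", "condition"),
                     list(message = paste0("no divergence entry for pair (",
                                           a, ", ", b, ")"),
                          call = sys.call())))
    return(NA_real_)
  }
  v
}

#' Load the packaged domain-motif set
#'
#' Motifs are simplified position-constrained patterns (fixed-width
#' regular expressions) with a per-motif score threshold; matches are
#' scored by their BLOSUM62 similarity to the motif consensus.  These are
#' surrogates for profile-HMM domain models (e.g. the two aspartic
#' proteinase families PF13975/PF00077): they assert domain presence and
#' order, not calibrated bit scores.
#'
#' @param path Optional YAML file; defaults to the packaged set covering
#'   the six roles `zinc_finger`, `movement_protein`,
#'   `aspartic_proteinase_1`, `aspartic_proteinase_2`,
#'   `reverse_transcriptase`, `rnaseh`.
#' @return A list of motifs (class `eprv_motifs`); each motif has fields
#'   `name`, `pattern`, `consensus`, `min_score`.
#' @export
load_motifs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs.yaml", package = "eprvscan",
                        mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  motifs <- lapply(raw$motifs, function(m) {
    m$min_score <- as.numeric(m$min_score)
    m
  })
  names(motifs) <- vapply(motifs, `[[`, "", "name")
  roles <- c("zinc_finger", "movement_protein", "aspartic_proteinase_1",
             "aspartic_proteinase_2", "reverse_transcriptase", "rnaseh")
  miss <- setdiff(roles, names(motifs))
  if (length(miss) > 0)
    stop("motif set is missing role(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (m in motifs) {
    sc <- motif_match_score(m$consensus, m)
    if (!grepl(m$pattern, m$consensus) || is.na(sc) || sc < m$min_score)
      stop("motif '", m$name, "' fails to match its own consensus",
           call. = FALSE)
  }
  class(motifs) <- c("eprv_motifs", class(motifs))
  motifs
}

# BLOSUM62 similarity of a fixed-width match to the motif consensus.
motif_match_score <- function(match, motif) {
  if (nchar(match) != nchar(motif$consensus)) return(NA_real_)
  b <- blosum62()
  a <- strsplit(match, "")[[1]]
  c0 <- strsplit(motif$consensus, "")[[1]]
  if (!all(a %in% rownames(b))) return(NA_real_)
  sum(b[cbind(a, c0)])
}
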