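# Summary tables, consistency checks on the published cluster tables,
# and recovery metrics against the simulation truth ledger.

#' Per-cluster summary table (cluster60-statistics analog)
#'
#' One row per cluster with the number of member sequences, the
#' taxonomic breadth of the member hosts (distinct classes, orders,
#' families, genera, species -- independent distinct-value counts), the
#' OTU assigned to the cluster representative, and the minimum
#' insertion age with its maximizing host pair.
#'
#' @param clusterset An `eprv_clusterset`.
#' @param candidates `eprv_candidates` covering all member ids (used
#'   for the genome of each member; a missing `genome_id` column means
#'   a single genome).
#' @param taxonomy Data.frame with `genome_id`, `species`, `genus`,
#'   `family`, `order`, `class_`, `kingdom`.
#' @param assignments Optional output of [assign_otu()] keyed by
#'   representative id.
#' @param divergence_table Optional `eprv_divtable`; ages are `NA`
#'   without it.  Ages use genus-rank lookups (the published maximum
#'   ages are quoted between genera).
#' @return Data.frame with one row per cluster.
#' @export
build_cluster_table <- function(clusterset, candidates, taxonomy,
                                assignments = NULL,
                                divergence_table = NULL) {
  mem <- clusterset$membership
  if (nrow(mem) == 0)
    return(data.frame(otu = character(0), cluster_id = character(0),
                      n_seqs = integer(0), stringsAsFactors = FALSE))
  gid <- if ("genome_id" %in% names(candidates))
    setNames(candidates$genome_id, candidates$candidate_id)
  else setNames(rep(taxonomy$genome_id[1], nrow(candidates)),
                candidates$candidate_id)
  rows <- list()
  for (cl in unique(mem$cluster_id)) {
    ids <- mem$member_id[mem$cluster_id == cl]
    g <- gid[ids]
    if (anyNA(g))
      stop("member(s) without genome id: ",
           paste(ids[is.na(g)], collapse = ", "), call. = FALSE)
    tx <- taxonomy[match(g, taxonomy$genome_id), , drop = FALSE]
    if (anyNA(tx$species))
      stop("member(s) without taxonomy: ",
           paste(ids[is.na(tx$species)], collapse = ", "), call. = FALSE)
    rep_id <- mem$member_id[mem$cluster_id == cl & mem$representative][1]
    otu <- NA_character_
    if (!is.null(assignments)) {
      hit <- match(rep_id, assignments$id)
      if (!is.na(hit)) otu <- assignments$otu[hit]
    }
    age <- list(age_my = NA_real_, pair = c(NA_character_, NA_character_))
    if (!is.null(divergence_table))
      age <- min_age(tx$genus, divergence_table)
    rows[[length(rows) + 1]] <- data.frame(
      otu = otu, cluster_id = cl, n_seqs = length(ids),
      n_classes = length(unique(tx$class_)),
      n_orders = length(unique(tx$order)),
      n_families = length(unique(tx$family)),
      n_genera = length(unique(tx$genus)),
      n_species = length(unique(tx$species)),
      host_a = age$pair[1], host_b = age$pair[2],
      max_age_my = age$age_my, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(-out$n_seqs), ]
}

#' Consistency checks over the packaged published cluster tables
#'
#' Recomputes, from the packaged transcriptions of the published
#' cluster60 and cluster100 tables, the summary quantities the text
#' reports -- total cluster and OTU-group counts, per-genus sequence
#' sums, the episomal/endogenous split, cluster100 totals, per-genome
#' sums and the maximum burst -- and compares per-genus sums against the
#' printed genus totals.  Rows where the printed total disagrees with
#' the column sum (a known feature of three genera in the source) are
#' *flagged*, not asserted either way.
#'
#' @param table1_path,totals_path,table3_path Optional overrides for
#'   the packaged transcriptions.
#' @return A list of class `eprv_table_check`; see the elements
#'   `table1`, `table3` and `genus_consistency`.
#' @export
check_published_tables <- function(table1_path = NULL, totals_path = NULL,
                                   table3_path = NULL) {
  pkgfile <- function(x) system.file("extdata", x, package = "eprvscan",
                                     mustWork = TRUE)
  t1 <- read_tsv_strict(table1_path %||% pkgfile("table1_cluster60.tsv"),
                        required = c("otu", "cluster_label", "n_seqs"))
  tot <- read_tsv_strict(totals_path %||% pkgfile("table1_genus_totals.tsv"),
                         required = c("otu", "printed_n_seqs"))
  t3 <- read_tsv_strict(table3_path %||% pkgfile("table3_cluster100.tsv"),
                        required = c("cluster100", "n_seqs",
                                     "genome_species", "eprv_group"))
  voc <- caulimoviridae_otus()
  computed <- tapply(t1$n_seqs, t1$otu, sum)
  genus <- data.frame(otu = tot$otu,
                      printed_n_seqs = tot$printed_n_seqs,
                      computed_n_seqs = as.integer(computed[tot$otu]),
                      stringsAsFactors = FALSE)
  genus$discrepant <- genus$printed_n_seqs != genus$computed_n_seqs
  t3$otu_group <- sub("-[0-9]+$", "", t3$eprv_group)
  per_genome <- tapply(t3$n_seqs, t3$genome_species, sum)
  per_genome_group <- stats::aggregate(
    n_seqs ~ genome_species + otu_group, data = t3, FUN = sum)
  out <- list(
    table1 = list(
      n_clusters = nrow(t1),
      n_otus = length(unique(t1$otu)),
      n_episomal_clusters = sum(t1$otu %in% voc$episomal),
      n_endogenous_clusters = sum(!t1$otu %in% voc$episomal),
      clusters_per_otu = table(t1$otu),
      per_genus = genus),
    table3 = list(
      n_clusters = nrow(t3),
      total_seqs = sum(t3$n_seqs),
      max_copies = max(t3$n_seqs),
      n_genomes = length(unique(t3$genome_species)),
      n_otu_groups = length(unique(t3$otu_group)),
      per_genome = setNames(as.integer(per_genome), names(per_genome)),
      per_genome_group = per_genome_group),
    genus_consistency = genus[genus$discrepant, , drop = FALSE])
  class(out) <- c("eprv_table_check", "list")
  out
}

#' @export
print.eprv_table_check <- function(x, ...) {
  cat("published-table consistency check\n")
  cat("  cluster60: ", x$table1$n_clusters, " clusters, ",
      x$table1$n_otus, " OTU groups (",
      x$table1$n_episomal_clusters, " episomal / ",
      x$table1$n_endogenous_clusters, " endogenous-only)\n", sep = "")
  cat("  cluster100: ", x$table3$n_clusters, " clusters, ",
      x$table3$total_seqs, " sequences, max burst ",
      x$table3$max_copies, "\n", sep = "")
  if (nrow(x$genus_consistency) > 0) {
    cat("  flagged genus totals (printed vs column sum):\n")
    for (i in seq_len(nrow(x$genus_consistency)))
      cat("    ", x$genus_consistency$otu[i], ": ",
          x$genus_consistency$printed_n_seqs[i], " vs ",
          x$genus_consistency$computed_n_seqs[i], "\n", sep = "")
  }
  invisible(x)
}

# reciprocal overlap fraction of [a1,a2) and [b1,b2)
.recip_overlap <- function(a1, a2, b1, b2) {
  ov <- max(0, min(a2, b2) - max(a1, b1))
  min(ov / (a2 - a1), ov / (b2 - b1))
}

#' Score pipeline output against the simulation truth ledger
#'
#' A truth element is recovered when some candidate interval overlaps it
#' reciprocally by at least `min_overlap` on the same contig.  Truth
#' records derived from retroelement references are scored as class
#' `decoy` regardless of their degeneration label; sensitivity is
#' reported per class and per placement, and OTU-label accuracy over the
#' recovered intact elements when assignments are supplied.
#'
#' @param truth Truth ledger from [implant()].
#' @param candidates `eprv_candidates`.
#' @param library Optional `eprv_reflib` (needed to recognise decoy
#'   truth records and score OTU labels).
#' @param assignments Optional [assign_otu()] output keyed by candidate
#'   id.
#' @param min_overlap Reciprocal overlap threshold (default 0.5).
#' @return A list of class `eprv_recovery`: `per_class` (class,
#'   placement, n_truth, n_recovered, sensitivity), `precision`
#'   (`NA` when there are no candidates), `otu_accuracy` (`NA` without
#'   assignments), `copy_group_candidates` (candidates matching each
#'   truth copy group), and `matches` (truth row -> candidate id).
#' @export
evaluate_recovery <- function(truth, candidates, library = NULL,
                              assignments = NULL, min_overlap = 0.5) {
  cls <- truth$degeneration
  if (!is.null(library)) {
    decoy <- library$lineage_class[match(truth$source_ref_id,
                                         library$id)] == "retroelement"
    cls[which(decoy)] <- "decoy"
  }
  match_id <- rep(NA_character_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    on_ctg <- which(candidates$contig == truth$contig[i])
    for (j in on_ctg) {
      if (.recip_overlap(truth$start[i], truth$end[i],
                         candidates$start_bp[j],
                         candidates$end_bp[j]) >= min_overlap) {
        match_id[i] <- candidates$candidate_id[j]
        break
      }
    }
  }
  recovered <- !is.na(match_id)
  key <- paste(cls, truth$placement)
  per_class <- do.call(rbind, lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(class = cls[sel][1], placement = truth$placement[sel][1],
               n_truth = sum(sel), n_recovered = sum(recovered[sel]),
               sensitivity = mean(recovered[sel]),
               stringsAsFactors = FALSE)
  }))
  # precision: candidates explained by an intact, non-decoy truth element
  precision <- NA_real_
  if (nrow(candidates) > 0) {
    good <- candidates$candidate_id %in%
      match_id[cls == "intact" & recovered]
    precision <- mean(good)
  }
  otu_accuracy <- NA_real_
  if (!is.null(assignments) && !is.null(library)) {
    sel <- which(cls == "intact" & recovered)
    if (length(sel) > 0) {
      truth_otu <- library$otu[match(truth$source_ref_id[sel], library$id)]
      called <- assignments$otu[match(match_id[sel], assignments$id)]
      otu_accuracy <- mean(called == truth_otu, na.rm = FALSE)
    }
  }
  cg <- tapply(match_id, truth$copy_group_id, function(v)
    length(unique(v[!is.na(v)])))
  out <- list(per_class = per_class, precision = precision,
              otu_accuracy = otu_accuracy,
              copy_group_candidates = setNames(as.integer(cg), names(cg)),
              matches = data.frame(truth_row = seq_len(nrow(truth)),
                                   class = cls,
                                   candidate_id = match_id,
                                   stringsAsFactors = FALSE))
  class(out) <- c("eprv_recovery", "list")
  out
}

#' @export
print.eprv_recovery <- function(x, ...) {
  cat("planted-element recovery\n")
  print(x$per_class, row.names = FALSE)
  cat("precision:", format(x$precision), " otu accuracy:",
      format(x$otu_accuracy), "\n")
  invisible(x)
}

#' Render a data.frame as a Markdown table
#'
#' @param df Data.frame.
#' @return Character vector of Markdown lines.
#' @export
render_markdown_table <- function(df) {
  hdr <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  body <- apply(df, 1, function(r)
    paste("|", paste(as.character(r), collapse = " | "), "|"))
  c(hdr, sep, body)
}
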