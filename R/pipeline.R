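# End-to-end orchestration: search -> screen -> cluster -> classify ->
# age -> annotate -> report, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Defaults are the discovery parameters of the published analysis:
#' E-value cutoff 1e-10, minimum intact RT length 300 aa, 1500 bp
#' proximity dedup, clustering thresholds 60% and 100%, and
#' amplification bursts of at least 10 identical copies.
#'
#' @param evalue_max,score_min,min_aa,dedup_bp,cluster_thresholds,min_copies
#'   Stage thresholds (see the stage functions).
#' @param bootstrap_reps Bootstrap replicates for the classification
#'   tree; 0 (default) writes the tree without support values.
#' @param seed Run seed.
#' @param window_bp Element window half-width around a candidate RT for
#'   architecture annotation.
#' @param min_seg_aa,seed_k Internal search engine knobs
#'   ([eprv_search()]).
#' @param otu_max_distance Classification ceiling ([assign_otu()]).
#' @param queries_per_otu Number of library references per
#'   Caulimoviridae OTU used as search probes (representative-probe
#'   strategy).
#' @return A named list of class `eprv_config`.
#' @export
pipeline_config <- function(evalue_max = 1e-10, score_min = 0,
                            min_aa = 300, dedup_bp = 1500,
                            cluster_thresholds = c(0.60, 1.00),
                            min_copies = 10, bootstrap_reps = 0,
                            seed = 1, window_bp = 5000, min_seg_aa = 60,
                            seed_k = 4, otu_max_distance = 1.0,
                            queries_per_otu = 1) {
  cfg <- list(evalue_max = evalue_max, score_min = score_min,
              min_aa = min_aa, dedup_bp = dedup_bp,
              cluster_thresholds = cluster_thresholds,
              min_copies = min_copies, bootstrap_reps = bootstrap_reps,
              seed = seed, window_bp = window_bp,
              min_seg_aa = min_seg_aa, seed_k = seed_k,
              otu_max_distance = otu_max_distance,
              queries_per_otu = queries_per_otu)
  stopifnot(evalue_max > 0, min_aa > 0, dedup_bp > 0, min_copies > 0,
            all(cluster_thresholds > 0 & cluster_thresholds <= 1))
  class(cfg) <- c("eprv_config", "list")
  cfg
}

# default probe set: the first `k` references (by id) of every
# Caulimoviridae OTU
.select_queries <- function(library, k) {
  lib <- library[library$lineage_class == "caulimoviridae", ]
  lib <- lib[order(lib$otu, lib$id), ]
  picks <- unlist(lapply(split(lib$id, lib$otu), utils::head, k))
  setNames(lib$aa_seq[match(picks, lib$id)], picks)
}

#' Run the full discovery-and-classification pipeline
#'
#' Executes, for one or more genome assemblies: translated search,
#' intactness/proximity/lineage screening, global clustering at the
#' configured thresholds, per-genome amplification detection, OTU
#' assignment of cluster representatives, minimum insertion-age
#' inference, element-architecture annotation, and the summary table.
#' All outputs are written under `out_dir` together with a YAML run
#' manifest (configuration, seed, package version, input checksums,
#' per-stage counts).  A stage failure aborts with the stage name;
#' outputs of completed stages are retained.
#'
#' @param genomes Named list of [Biostrings::DNAStringSet] (name =
#'   genome id) or a data.frame with columns `genome_id`, `fasta`.
#' @param taxonomy Host taxonomy data.frame (`genome_id`, `species`,
#'   `genus`, `family`, `order`, `class_`, `kingdom`).
#' @param library Reference library (`eprv_reflib`).
#' @param divergence_table Optional `eprv_divtable`; when absent the
#'   age stage is skipped with a warning and `ages.tsv` is not written.
#' @param config [pipeline_config()].
#' @param out_dir Run directory (created).
#' @param queries Optional explicit probe set (named peptides);
#'   defaults to `queries_per_otu` references per OTU.
#' @param annotate If `FALSE`, skip the per-candidate architecture
#'   annotation stage.
#' @return Invisibly, a list with the main in-memory results
#'   (`hits`, `candidates`, `clusters`, `assignments`, `ages`,
#'   `amplification`, `cluster_table`, `manifest`).
#' @export
run_pipeline <- function(genomes, taxonomy, library,
                         divergence_table = NULL,
                         config = pipeline_config(), out_dir,
                         queries = NULL, annotate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # run id is derived from the configuration only, so that identical runs
  # produce byte-identical outputs
  run_id <- sprintf("eprvscan-seed%03d", as.integer(config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  checksums <- list()
  if (is.data.frame(genomes)) {
    paths <- genomes$fasta
    checksums <- as.list(tools::md5sum(paths))
    gs <- lapply(paths, Biostrings::readDNAStringSet)
    names(gs) <- genomes$genome_id
    genomes <- gs
  }
  if (is.null(queries))
    queries <- .select_queries(library, config$queries_per_otu)

  counts <- list()
  # -- search ---------------------------------------------------------------
  hits <- stage("search", {
    hl <- lapply(names(genomes), function(g) {
      h <- eprv_search(queries, genomes[[g]],
                       evalue_max = config$evalue_max,
                       score_min = config$score_min,
                       min_seg_aa = config$min_seg_aa,
                       seed_k = config$seed_k)
      if (nrow(h) > 0) h$genome_id <- g
      h
    })
    do.call(rbind, hl[vapply(hl, nrow, 0L) > 0])
  })
  if (is.null(hits)) hits <- .empty_hits()
  counts$raw_hits <- nrow(hits)
  write_hits_tsv(hits, file.path(out_dir, "hits.tsv"),
                 header_comment = paste("run:", run_id))

  # -- screen ---------------------------------------------------------------
  candidates <- stage("screen", {
    if (nrow(hits) == 0) {
      out <- triage_lineage(hits, library)
    } else {
      parts <- lapply(split(seq_len(nrow(hits)), hits$genome_id),
                      function(ix) {
        cc <- screen_hits(hits[ix, , drop = FALSE], library,
                          min_aa = config$min_aa,
                          window_bp = config$dedup_bp)
        if (nrow(cc) > 0)
          cc$candidate_id <- paste0(cc$genome_id, ":", cc$candidate_id)
        cc
      })
      out <- do.call(rbind, parts)
      rownames(out) <- NULL
      class(out) <- c("eprv_candidates", "data.frame")
    }
    out
  })
  counts$candidates <- nrow(candidates)
  write_candidates(candidates,
                   fasta_path = file.path(out_dir, "candidates.fa"),
                   gff3_path = file.path(out_dir, "candidates.gff3"),
                   tsv_path = file.path(out_dir, "candidates.tsv"))

  # -- cluster --------------------------------------------------------------
  clusters <- list()
  amplification <- NULL
  if (nrow(candidates) > 0) {
    clusters <- stage("cluster", {
      cl <- lapply(config$cluster_thresholds, function(th)
        greedy_cluster(candidates, th))
      names(cl) <- sprintf("clusters%02.0f", 100 * config$cluster_thresholds)
      cl
    })
    for (nm in names(clusters))
      write_tsv(clusters[[nm]]$membership,
                file.path(out_dir, paste0(nm, ".tsv")),
                header_comment = paste("run:", run_id))
    amplification <- stage("amplification",
                           find_amplification(candidates,
                                              config$min_copies))
    write_tsv(amplification, file.path(out_dir, "amplification.tsv"),
              header_comment = paste("run:", run_id))
    counts$clusters60 <- length(unique(
      clusters[[1]]$membership$cluster_id))
    counts$amplification_clusters <- nrow(amplification)
  }

  # -- classify -------------------------------------------------------------
  assignments <- NULL
  if (nrow(candidates) > 0) {
    assignments <- stage("classify", {
      main <- clusters[[1]]$membership
      reps <- main$member_id[main$representative]
      peps <- setNames(candidates$aa_seq[match(reps,
                                               candidates$candidate_id)],
                       reps)
      a <- assign_otu(peps, library,
                      max_distance = config$otu_max_distance)
      # propagate the representative's OTU to all cluster members
      rep_of <- setNames(main$cluster_id, main$member_id)
      cluster_otu <- setNames(a$otu, rep_of[a$id])
      full <- data.frame(id = main$member_id,
                         cluster_id = main$cluster_id,
                         otu = unname(cluster_otu[main$cluster_id]),
                         stringsAsFactors = FALSE)
      attr(full, "representatives") <- a
      full
    })
    write_tsv(assignments, file.path(out_dir, "assignments.tsv"),
              header_comment = paste("run:", run_id))
    stage("tree", {
      main <- clusters[[1]]$membership
      reps <- main$member_id[main$representative]
      peps <- c(setNames(candidates$aa_seq[match(reps,
                                                 candidates$candidate_id)],
                         reps),
                setNames(library$aa_seq, library$id))
      if (length(peps) >= 3) {
        tr <- if (config$bootstrap_reps > 0)
          bootstrap_support(peps, n_reps = config$bootstrap_reps,
                            seed = child_seed(config$seed, 99))
        else nj_tree(pairwise_distances(peps))
        ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
      }
    })
  }

  # -- age ------------------------------------------------------------------
  ages <- NULL
  if (!is.null(divergence_table) && nrow(candidates) > 0) {
    ages <- stage("age", {
      main <- clusters[[1]]$membership
      gid <- setNames(candidates$genome_id %||%
                        rep(taxonomy$genome_id[1], nrow(candidates)),
                      candidates$candidate_id)
      do.call(rbind, lapply(unique(main$cluster_id), function(cl) {
        g <- gid[main$member_id[main$cluster_id == cl]]
        genera <- taxonomy$genus[match(g, taxonomy$genome_id)]
        a <- min_age(genera, divergence_table)
        data.frame(cluster_id = cl, host_a = a$pair[1],
                   host_b = a$pair[2], max_age_my = a$age_my,
                   n_unresolved_pairs = nrow(a$unresolved),
                   stringsAsFactors = FALSE)
      }))
    })
    write_tsv(ages, file.path(out_dir, "ages.tsv"),
              header_comment = paste("run:", run_id))
  } else if (is.null(divergence_table)) {
    warning("no divergence table supplied; insertion-age stage skipped")
  }

  # -- annotate -------------------------------------------------------------
  if (annotate && nrow(candidates) > 0) {
    stage("annotate", {
      motifs <- load_motifs()
      gff <- file.path(out_dir, "annotations.gff3")
      unlink(gff)
      first <- TRUE
      for (r in seq_len(nrow(candidates))) {
        g <- candidates$genome_id[r] %||% names(genomes)[1]
        contig <- genomes[[g]][[candidates$contig[r]]]
        w0 <- max(0, candidates$start_bp[r] - config$window_bp)
        w1 <- min(length(contig), candidates$end_bp[r] + config$window_bp)
        win <- as.character(Biostrings::subseq(contig, w0 + 1, w1))
        if (candidates$strand[r] == "-")
          win <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(win)))
        ann <- annotate_element(win, motifs)
        tmp <- tempfile()
        write_annotation_gff3(ann, candidates$candidate_id[r], tmp,
                              offset_bp = 0)
        lines <- readLines(tmp)
        if (!first) lines <- lines[-1]
        cat(lines, file = gff, sep = "\n", append = !first)
        cat("\n", file = gff, append = TRUE)
        first <- FALSE
      }
    })
  }

  # -- report ---------------------------------------------------------------
  cluster_table <- NULL
  if (nrow(candidates) > 0) {
    cluster_table <- stage("report", {
      build_cluster_table(clusters[[1]], candidates, taxonomy,
                          assignments = attr(assignments,
                                             "representatives"),
                          divergence_table = divergence_table)
    })
    write_tsv(cluster_table, file.path(out_dir, "table1_analog.tsv"),
              header_comment = paste("run:", run_id))
  }

  manifest <- list(run_id = run_id,
                   package_version =
                     as.character(utils::packageVersion("eprvscan")),
                   seed = config$seed,
                   config = unclass(config),
                   genomes = names(genomes),
                   n_queries = length(queries),
                   input_checksums = checksums,
                   counts = counts,
                   outputs = list.files(out_dir))
  yaml::write_yaml(manifest, file.path(out_dir, "run-manifest.yaml"))
  invisible(list(hits = hits, candidates = candidates,
                 clusters = clusters, assignments = assignments,
                 ages = ages, amplification = amplification,
                 cluster_table = cluster_table, manifest = manifest))
}
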