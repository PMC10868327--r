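# ---------------------------------------------------------------------------
# End-to-end assembly driver: one global graph, then barcode-by-barcode
# subgraph derivation, simplification, path extraction and clustering.
# ---------------------------------------------------------------------------

#' Assemble read clouds into isoform clusters
#'
#' Runs the full pipeline: builds the global compacted de Bruijn graph from
#' all reads combined, prunes extremely low-coverage edges, then for every
#' read cloud aligns its reads to the graph, derives and simplifies the
#' barcode-specific subgraph, extracts transcript paths using read-pair
#' linkage and inserts them into the cross-barcode cluster store.
#'
#' @param clouds named list of `read_cloud` objects (see
#'   [read_clouds_fastq()] or [simulate_clouds()]).
#' @param k odd k-mer size (55 for real-scale data; 21 suits small examples).
#' @param double_stranded build the graph on both strands (default).
#' @param prune_cutoff,tip_length,bulge_frac global simplification
#'   parameters, see [prune_low_coverage()].
#' @param max_tip_len,rel_cov,min_len_diff,len_diff_frac,max_gap_edge_len,max_gap_edges
#'   subgraph simplification parameters, see [simplify_subgraph()];
#'   `max_gap_edge_len = NULL` bounds gap-closing edges by the estimated
#'   insert length (coverage holes in a cloud are missing fragments).
#' @param endpoint_tol clustering endpoint window, see [path_cluster_store()].
#' @param min_support,support_ratio path extension margin, see
#'   [extract_paths()].
#' @param graph optionally, a prebuilt `assembly_graph` to reuse (skips
#'   graph construction and pruning).
#' @param verbose print progress.
#' @return list with `graph`, `store` (a `path_cluster_store`), `paths`
#'   (per-barcode list of `transcript_path`), `insert` (insert-size stats)
#'   and `empty_clouds` (barcodes with no aligned reads, skipped).
#' @export
assemble_clouds <- function(clouds, k = 55L, double_stranded = TRUE,
                            prune_cutoff = 2.0, tip_length = NULL,
                            bulge_frac = 0.2,
                            max_tip_len = 100L, rel_cov = 0.5,
                            min_len_diff = 50L, len_diff_frac = 0.1,
                            max_gap_edge_len = NULL, max_gap_edges = 6L,
                            endpoint_tol = 30L,
                            min_support = 2L, support_ratio = 2,
                            graph = NULL, verbose = FALSE) {
  if (is.null(graph)) {
    reads <- unlist(lapply(clouds, function(cl) {
      c(cl$read1, cl$read2[!is.na(cl$read2)])
    }), use.names = FALSE)
    if (verbose) message("building graph from ", length(reads), " reads")
    graph <- build_graph(reads, k, double_stranded)
    graph <- prune_low_coverage(graph, prune_cutoff, tip_length, bulge_frac)
  }
  if (verbose) message("graph: ", nrow(graph$edges), " edges")
  index <- graph_kmer_index(graph)
  aligned <- lapply(clouds, align_cloud, graph = graph, index = index)
  ins <- estimate_insert_stats(aligned, graph)
  if (is.null(max_gap_edge_len)) {
    # coverage holes in a read cloud are missing fragments, so the edges
    # worth re-inserting are up to a fragment length (mean + 3 SD, the same
    # window the pair-linkage logic uses)
    max_gap_edge_len <- max(100L, as.integer(round(ins$mean + 3 * ins$sd)))
  }
  store <- path_cluster_store(graph, endpoint_tol)
  paths <- vector("list", length(clouds))
  names(paths) <- names(clouds)
  empty <- character(0)
  for (bi in seq_along(clouds)) {
    bc <- names(clouds)[bi] %||% clouds[[bi]]$barcode
    sub <- derive_subgraph(aligned[[bi]], graph, bc)
    if (length(sub$edges) == 0L) {
      empty <- c(empty, bc)
      next
    }
    sub <- simplify_subgraph(sub, graph,
                             max_tip_len = max_tip_len, rel_cov = rel_cov,
                             min_len_diff = min_len_diff,
                             len_diff_frac = len_diff_frac,
                             max_gap_edge_len = max_gap_edge_len,
                             max_gap_edges = max_gap_edges)
    ps <- extract_paths(sub, graph, aligned[[bi]], ins,
                        min_support = min_support,
                        support_ratio = support_ratio)
    for (p in ps) insert_path(store, p)
    paths[[bi]] <- ps
    if (verbose && bi %% 100L == 0L) {
      message("processed ", bi, "/", length(clouds), " clouds")
    }
  }
  list(graph = graph, store = store, paths = paths, insert = ins,
       empty_clouds = empty)
}

#' Turn assembled clusters into a contig table for evaluation
#'
#' Expands the filtered clusters into one contig row per (cluster, barcode),
#' matching the per-barcode semantics of the assembler: each barcode that
#' supports a cluster is credited with the cluster's representative contig.
#'
#' @param clusters data.frame from [filter_clusters()].
#' @return data.frame with columns `contig`, `barcode`, `seq` suitable for
#'   [assign_contigs()].
#' @export
clusters_to_contigs <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(contig = character(0), barcode = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    bcs <- clusters$barcodes[[i]]
    data.frame(
      contig = sprintf("cluster_%d.%s", clusters$cluster[i],
                       seq_along(bcs)),
      barcode = bcs,
      seq = clusters$seq[i],
      stringsAsFactors = FALSE)
  }))
}
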