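# ---------------------------------------------------------------------------
# Cross-barcode path clustering. Extracted paths are grouped by the exact
# sequence of edges they traverse plus a tolerance window on the leftmost
# position of the first edge and the rightmost position of the last edge;
# the barcodes recorded per cluster give isoform abundances.
# ---------------------------------------------------------------------------

#' Create an empty path cluster store
#'
#' @param graph the `assembly_graph` paths refer to.
#' @param endpoint_tol endpoint window in bp: a new path joins an existing
#'   cluster with the same edge chain when both endpoint disparities are
#'   strictly below this value (default 30).
#' @return a `path_cluster_store`.
#' @export
path_cluster_store <- function(graph, endpoint_tol = 30L) {
  st <- new.env(parent = emptyenv())
  st$graph <- graph
  st$endpoint_tol <- as.integer(endpoint_tol)
  st$clusters <- list()
  st$index <- new.env(hash = TRUE, parent = emptyenv())
  class(st) <- "path_cluster_store"
  st
}

#' @export
print.path_cluster_store <- function(x, ...) {
  cat(sprintf("path_cluster_store: %d clusters, %d paths\n",
              length(x$clusters),
              sum(vapply(x$clusters, function(cl) length(cl$barcodes),
                         integer(1)))))
  invisible(x)
}

# canonical orientation of a path in a double-stranded graph: the
# lexicographically smaller of the edge chain and its reverse-complement twin
# chain (a chain-level rule, so endpoint offsets cannot flip the choice);
# offsets are mirrored when flipped
canonical_path <- function(path, graph) {
  if (!graph$double_stranded) return(path)
  tw <- graph$twin[path$edges]
  if (anyNA(tw)) return(path)
  fwd_key <- paste(path$edges, collapse = ",")
  rev_key <- paste(rev(unname(tw)), collapse = ",")
  if (fwd_key <= rev_key) return(path)
  lens <- unname(graph$elen[path$edges])
  n <- length(path$edges)
  new_transcript_path(
    path$barcode,
    rev(unname(tw)),
    start = lens[n] - path$end,
    end = lens[1L] - path$start,
    graph
  )
}

#' Insert a transcript path into the cluster store
#'
#' If no cluster shares the path's (canonicalised) edge chain a new cluster
#' is founded. Otherwise the path joins the first existing cluster of that
#' chain whose leftmost and rightmost endpoint disparities are both strictly
#' below the store's endpoint tolerance; if none qualifies, a new cluster is
#' founded. Representative endpoints and sequence are the founding path's.
#'
#' @param store a `path_cluster_store`.
#' @param path a `transcript_path`.
#' @return the cluster id (integer), invisibly the store is updated.
#' @export
insert_path <- function(store, path) {
  graph <- store$graph
  path <- canonical_path(path, graph)
  key <- paste(path$edges, collapse = ",")
  tol <- store$endpoint_tol
  ids <- store$index[[key]]
  for (cid in ids) {
    cl <- store$clusters[[cid]]
    if (abs(cl$left - path$start) < tol && abs(cl$right - path$end) < tol) {
      cl$barcodes <- c(cl$barcodes, path$barcode)
      store$clusters[[cid]] <- cl
      return(cid)
    }
  }
  cid <- length(store$clusters) + 1L
  store$clusters[[cid]] <- list(
    id = cid,
    edges = path$edges,
    left = path$start,
    right = path$end,
    barcodes = path$barcode,
    seq = path_sequence(path, graph)
  )
  store$index[[key]] <- c(ids, cid)
  cid
}

#' Filter and rank clusters
#'
#' Keeps clusters whose representative sequence is strictly longer than
#' `min_length` bp and which carry at least `min_barcodes` distinct barcodes,
#' sorted by distinct-barcode count (descending), then length (descending).
#'
#' @param store a `path_cluster_store`.
#' @param min_length minimal representative length, exclusive (default 300).
#' @param min_barcodes minimal number of distinct barcodes (default 1).
#' @return data.frame with columns `cluster`, `n_barcodes`, `length`,
#'   `edges`, `seq`, plus a `barcodes` list column.
#' @export
filter_clusters <- function(store, min_length = 300L, min_barcodes = 1L) {
  cls <- store$clusters
  if (length(cls) == 0L) {
    return(data.frame(cluster = integer(0), n_barcodes = integer(0),
                      length = integer(0), edges = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    cluster = vapply(cls, `[[`, integer(1), "id"),
    n_barcodes = vapply(cls, function(cl) length(unique(cl$barcodes)),
                        integer(1)),
    length = vapply(cls, function(cl) nchar(cl$seq), integer(1)),
    edges = vapply(cls, function(cl) paste(cl$edges, collapse = ","),
                   character(1)),
    seq = vapply(cls, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE
  )
  df$barcodes <- lapply(cls, function(cl) unique(cl$barcodes))
  df <- df[df$length > min_length & df$n_barcodes >= min_barcodes, ,
           drop = FALSE]
  df[order(-df$n_barcodes, -df$length), , drop = FALSE]
}

#' Write clusters as FASTA
#'
#' Headers carry the barcode count, length and edge chain:
#' `>cluster_<id> barcodes=<n> length=<bp> edges=<e1,e2,...>`.
#'
#' @param clusters data.frame from [filter_clusters()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clusters_fasta <- function(clusters, path) {
  seqs <- Biostrings::DNAStringSet(clusters$seq)
  names(seqs) <- sprintf("cluster_%d barcodes=%d length=%d edges=%s",
                         clusters$cluster, clusters$n_barcodes,
                         clusters$length, clusters$edges)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write per-(cluster, barcode) assignments as TSV
#'
#' One row per (cluster, barcode) incidence, with the representative path
#' length and edge chain.
#'
#' @inheritParams write_clusters_fasta
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    data.frame(cluster = clusters$cluster[i],
               barcode = clusters$barcodes[[i]],
               length = clusters$length[i],
               edges = clusters$edges[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster = integer(0), barcode = character(0),
                       length = integer(0), edges = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
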