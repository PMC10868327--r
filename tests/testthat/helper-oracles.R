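# Independent brute-force oracles used to validate the implementation.

# all k-mers of a string (no N handling needed for synthetic fixtures)
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# Brute-force compacted de Bruijn graph: builds the uncompacted k-mer graph
# as plain tables and enumerates maximal unbranched paths by walking.
# Returns a data.frame (seq, cov) sorted by sequence.
oracle_unitigs <- function(reads, k, double_stranded = FALSE) {
  kms <- unlist(lapply(reads, oracle_kmers, k = k))
  if (double_stranded) {
    kms <- c(kms, unlist(lapply(rc_dna(reads), oracle_kmers, k = k)))
  }
  kms <- kms[!grepl("N", kms, fixed = TRUE)]
  if (length(kms) == 0L) {
    return(data.frame(seq = character(0), cov = numeric(0)))
  }
  cnt <- table(kms)
  kmers <- names(cnt)
  pre <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  outdeg <- table(pre)
  indeg <- table(suf)
  deg <- function(v, tab) if (v %in% names(tab)) tab[[v]] else 0L
  is_branch <- function(v) deg(v, outdeg) != 1L || deg(v, indeg) != 1L
  by_pre <- split(kmers, pre)
  used <- stats::setNames(rep(FALSE, length(kmers)), kmers)
  res_seq <- character(0)
  res_cov <- numeric(0)
  walk <- function(start) {
    km <- start
    seqs <- km
    covs <- cnt[[km]]
    used[[km]] <<- TRUE
    repeat {
      v <- substr(km, 2L, k)
      if (is_branch(v)) break
      nxt <- by_pre[[v]]
      if (is.null(nxt) || used[[nxt[1L]]]) break
      km <- nxt[1L]
      used[[km]] <<- TRUE
      seqs <- c(seqs, substr(km, k, k))
      covs <- c(covs, cnt[[km]])
    }
    res_seq <<- c(res_seq, paste(seqs, collapse = ""))
    res_cov <<- c(res_cov, mean(covs))
  }
  for (km in kmers) {
    if (!used[[km]] && is_branch(substr(km, 1L, k - 1L))) walk(km)
  }
  for (km in sort(kmers)) {          # isolated cycles
    if (!used[[km]]) walk(km)
  }
  ord <- order(res_seq)
  data.frame(seq = res_seq[ord], cov = res_cov[ord],
             stringsAsFactors = FALSE)
}

# per-base depth oracle for barcode-specific coverage of one edge: lays every
# alignment footprint onto a depth array and averages
oracle_edge_cov <- function(footprints, edge_len) {
  depth <- integer(edge_len)
  for (fp in footprints) {
    if (fp[2L] > fp[1L]) {
      idx <- (fp[1L] + 1L):fp[2L]
      depth[idx] <- depth[idx] + 1L
    }
  }
  sum(depth) / edge_len
}

# exhaustive enumeration of walks in a small graph from dead-start edges to
# dead-end edges with a per-edge visit cap; used as the oracle for
# pair-guided repeat traversal
oracle_walks <- function(graph, max_visits = 2L, max_len = 20L) {
  e <- graph$edges
  dead_start <- e$id[!(e$from %in% e$to)]
  walks <- list()
  grow <- function(w) {
    last <- w[length(w)]
    outs <- out_edges(graph, graph$eto[[last]])
    outs <- outs[vapply(outs, function(x) sum(w == x), integer(1)) <
                   max_visits]
    if (length(outs) == 0L) {
      walks[[length(walks) + 1L]] <<- w
      return(invisible())
    }
    for (o in outs) {
      if (length(w) < max_len) grow(c(w, o))
    }
  }
  for (s in dead_start) grow(s)
  walks
}

# small convenience: single-stranded toy graph from transcripts
toy_graph <- function(..., k = 21L) {
  build_graph(c(...), k = k, double_stranded = FALSE)
}

# manual cloud subgraph constructor for simplifier unit tests
toy_subgraph <- function(graph, edges, cov = NULL, barcode = "BC") {
  edges <- sort(edges)
  lens <- unname(graph$elen[edges])
  if (is.null(cov)) cov <- rep(1, length(edges))
  if (!is.null(names(cov))) cov <- unname(cov[edges])
  structure(list(
    barcode = barcode,
    edges = edges,
    bc_cov = stats::setNames(rep_len(cov, length(edges)), edges),
    left = stats::setNames(rep(0L, length(edges)), edges),
    right = stats::setNames(as.integer(lens), edges)
  ), class = "cloud_subgraph")
}
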