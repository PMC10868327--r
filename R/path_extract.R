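# ---------------------------------------------------------------------------
# Transcript path extraction from a simplified cloud subgraph. A restricted
# path-extension procedure in the spirit of pair-end-aware repeat resolution:
# seeds one path per maximal simple chain (longest first) and extends across
# branch vertices along the candidate best supported by read-pair linkage.
# ---------------------------------------------------------------------------

#' Construct a transcript path
#'
#' An ordered chain of adjacent graph edges with a start offset on the first
#' edge and an exclusive end offset on the last edge; spellable to a
#' nucleotide sequence with [path_sequence()].
#'
#' @param barcode owning barcode.
#' @param edges ordered edge-id vector (consecutive edges must be adjacent).
#' @param start 0-based start offset on the first edge.
#' @param end exclusive end offset on the last edge.
#' @param graph the `assembly_graph`.
#' @return a `transcript_path`.
#' @export
new_transcript_path <- function(barcode, edges, start, end, graph) {
  lens <- unname(graph$elen[edges])
  total <- sum(lens) - (length(edges) - 1L) * (graph$k - 1L)
  spelled <- total - start - (lens[length(edges)] - end)
  structure(list(barcode = barcode, edges = edges,
                 start = as.integer(start), end = as.integer(end),
                 length = as.integer(spelled)),
            class = "transcript_path")
}

#' @export
print.transcript_path <- function(x, ...) {
  cat(sprintf("transcript_path [%s]: %d edges, %d bp\n",
              x$barcode, length(x$edges), x$length))
  invisible(x)
}

#' Spell the nucleotide sequence of a transcript path
#'
#' Concatenates the path's edge sequences collapsing the k-1 overlaps, then
#' trims to the path's start/end offsets.
#'
#' @param path a `transcript_path`.
#' @param graph the `assembly_graph`.
#' @return DNA string of length `path$length`.
#' @export
path_sequence <- function(path, graph) {
  seqs <- unname(graph$eseq[path$edges])
  lens <- unname(graph$elen[path$edges])
  n <- length(seqs)
  s <- seqs[1L]
  if (n > 1L) {
    s <- paste0(s, paste(substr(seqs[-1L], graph$k, lens[-1L]),
                         collapse = ""))
  }
  total <- nchar(s)
  from <- path$start + 1L
  to <- total - (lens[n] - path$end)
  if (from > to) stop("inconsistent path offsets: empty sequence")
  substr(s, from, to)
}

# undirected connected components over subgraph edges
sub_components <- function(sub, graph) {
  ids <- sort(sub$edges)
  if (length(ids) == 0L) return(list())
  efrom <- unname(graph$efrom[ids])
  eto <- unname(graph$eto[ids])
  verts <- unique(c(efrom, eto))
  comp <- stats::setNames(seq_along(verts), verts)
  repeat {
    new <- pmin(comp[efrom], comp[eto])
    changed <- any(comp[efrom] != new) || any(comp[eto] != new)
    comp[efrom] <- new
    comp[eto] <- new
    if (!changed) break
  }
  split(ids, comp[efrom])
}

# pairs of edge sets touched by the two mates of each read pair (twin-closed)
pair_edge_sets <- function(alignments, graph) {
  out <- list()
  for (pair in alignments) {
    e1 <- unique(unlist(lapply(pair$m1, `[[`, "edges")))
    e2 <- unique(unlist(lapply(pair$m2, `[[`, "edges")))
    if (is.null(e1)) e1 <- character(0)
    if (is.null(e2)) e2 <- character(0)
    out[[length(out) + 1L]] <- list(e1 = twin_closure(graph, e1),
                                    e2 = twin_closure(graph, e2))
  }
  out
}

# support for candidate chain given the tail edges of the growing path:
# read pairs with one mate on the tail and the other on the candidate, plus
# single alignments spanning both
link_support <- function(pairs, tail_edges, cand_edges) {
  s <- 0L
  for (p in pairs) {
    spans1 <- length(intersect(p$e1, tail_edges)) > 0L
    spans2 <- length(intersect(p$e2, tail_edges)) > 0L
    hits1 <- length(intersect(p$e1, cand_edges)) > 0L
    hits2 <- length(intersect(p$e2, cand_edges)) > 0L
    # pair evidence: mates on different loci bridging tail and candidate
    # (two mates co-located on one edge carry no junction information)
    colocated <- identical(sort(p$e1), sort(p$e2))
    pair_link <- !colocated &&
      ((spans1 && hits2) || (spans2 && hits1))
    # single-read evidence: one alignment walking from the tail into the
    # candidate (it must touch at least two edges to span a junction)
    single_link <- (length(p$e1) >= 2L && spans1 && hits1) ||
      (length(p$e2) >= 2L && spans2 && hits2)
    if (pair_link || single_link) s <- s + 1L
  }
  s
}

# edges within the last `window` bp of a path (edge chain)
path_tail <- function(edges, graph, window) {
  lens <- unname(graph$elen[edges]) - graph$k + 1L
  cum <- rev(cumsum(rev(lens)))
  edges[cum <= window + lens]
}

#' Extract transcript paths from a simplified cloud subgraph
#'
#' Seeds one path per unvisited maximal simple chain, longest first, and
#' extends it across branch vertices of the induced subgraph. At a branch
#' with several candidate continuations, the candidate supported by the most
#' read-pair links (mates placed across the junction) wins if its support is
#' at least `min_support` and at least `support_ratio` times the runner-up;
#' otherwise extension stops (conservative fragmentation over chimerism).
#' Revisiting an edge (short repeat traversal) is allowed when pair links
#' demand it, up to `max_visits` per edge. In a double-stranded graph the
#' mirror copies of each path are deduplicated via canonical sequences.
#'
#' @param sub a simplified `cloud_subgraph`.
#' @param graph the global `assembly_graph`.
#' @param alignments [align_cloud()] output for this cloud (used for pair
#'   linkage); may be `NULL`, in which case branches are never crossed.
#' @param insert_stats list with `mean` and `sd`, as from
#'   [estimate_insert_stats()]; sets the linkage window.
#' @param min_support,support_ratio extension margin rule.
#' @param max_visits per-edge traversal cap within one path.
#' @return list of `transcript_path` objects.
#' @export
extract_paths <- function(sub, graph, alignments = NULL, insert_stats = NULL,
                          min_support = 2L, support_ratio = 2,
                          max_visits = 2L) {
  if (length(sub$edges) == 0L) return(list())
  if (is.null(insert_stats)) insert_stats <- list(mean = 250, sd = 50)
  window <- insert_stats$mean + 3 * insert_stats$sd
  pairs <- if (is.null(alignments)) list() else
    pair_edge_sets(alignments, graph)
  chains <- sub_chains(sub, graph)
  chain_of <- new.env(hash = TRUE)
  for (ci in seq_along(chains)) {
    for (eid in chains[[ci]]) assign(eid, ci, envir = chain_of)
  }
  lens <- vapply(chains, chain_bp, numeric(1), graph = graph)
  sigs <- vapply(chains, paste, character(1), collapse = ",")
  order_seed <- order(-lens, sigs)
  visited <- character(0)
  paths <- list()

  ext_candidates <- function(vertex, dir) {
    cand <- if (dir == "right") {
      intersect(out_edges(graph, vertex), sub$edges)
    } else {
      intersect(in_edges(graph, vertex), sub$edges)
    }
    sort(cand)
  }

  for (si in order_seed) {
    seed <- chains[[si]]
    if (any(seed %in% visited)) next
    path <- seed
    # grow in each direction
    for (dir in c("right", "left")) {
      repeat {
        term_edge <- if (dir == "right") path[length(path)] else path[1L]
        vertex <- if (dir == "right") graph$eto[[term_edge]] else
          graph$efrom[[term_edge]]
        cand <- ext_candidates(vertex, dir)
        # paths are edge-disjoint: never grow into another path's territory;
        # within the current path, short-repeat revisits are capped
        cand <- setdiff(cand, setdiff(visited, path))
        cand <- cand[vapply(cand, function(e) sum(path == e), integer(1)) <
                       max_visits]
        if (length(cand) == 0L) break
        tail_e <- if (dir == "right") path_tail(path, graph, window) else
          path_tail(rev(path), graph, window)
        supp <- vapply(cand, function(e) {
          ch <- chains[[get(e, envir = chain_of)]]
          link_support(pairs, tail_e, twin_closure(graph, ch))
        }, integer(1))
        revisit <- cand %in% path
        if (length(cand) == 1L) {
          # unambiguous continuation; a revisit still needs pair evidence
          if (revisit[1L] && supp[1L] < 1L) break
          winner <- 1L
        } else {
          ord <- order(-supp, cand)
          winner <- ord[1L]
          runner <- supp[ord[2L]]
          if (supp[winner] < min_support ||
              supp[winner] < support_ratio * max(runner, 1L)) break
          if (revisit[winner] && supp[winner] < 1L) break
        }
        wch <- chains[[get(cand[winner], envir = chain_of)]]
        # enter the chain at the matching end
        if (dir == "right") {
          if (wch[1L] != cand[winner]) wch <- rev(wch)
          path <- c(path, wch)
        } else {
          if (wch[length(wch)] != cand[winner]) wch <- rev(wch)
          path <- c(wch, path)
        }
        if (length(path) > 200L) break  # safety
      }
    }
    visited <- c(visited, unique(path))
    if (graph$double_stranded) {
      visited <- twin_closure(graph, visited)
    }
    first <- path[1L]; last <- path[length(path)]
    start <- unname(sub$left[first] %||% 0L)
    if (is.na(start)) start <- 0L
    end <- unname(sub$right[last] %||% graph$elen[[last]])
    if (is.na(end)) end <- graph$elen[[last]]
    # offsets must leave a positive spelled length
    if (length(path) == 1L && end <= start) {
      start <- 0L
      end <- graph$elen[[last]]
    }
    paths[[length(paths) + 1L]] <-
      new_transcript_path(sub$barcode, path, start, end, graph)
  }
  # deduplicate reverse-complement mirror paths
  if (graph$double_stranded && length(paths) > 1L) {
    seqs <- vapply(paths, path_sequence, character(1), graph = graph)
    canon <- pmin(seqs, rc_dna(seqs))
    paths <- paths[!duplicated(canon)]
  }
  paths
}
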