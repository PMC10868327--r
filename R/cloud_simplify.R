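# ---------------------------------------------------------------------------
# Barcode-aware subgraph simplification: tip clipping, bulge removal and gap
# closing, operating on *sequences of global edges* in the induced subgraph
# with barcode-specific coverage. The global graph is never modified: an edge
# that is noise in one cloud can carry another cloud's isoform.
# ---------------------------------------------------------------------------

# induced degrees: list(in, out) named by vertex, counting only subgraph edges
sub_degrees <- function(sub, graph) {
  efrom <- unname(graph$efrom[sub$edges])
  eto <- unname(graph$eto[sub$edges])
  verts <- unique(c(efrom, eto))
  indeg <- table(factor(eto, levels = verts))
  outdeg <- table(factor(efrom, levels = verts))
  list(vertices = verts,
       indeg = as.integer(indeg), outdeg = as.integer(outdeg),
       names = verts)
}

sub_deg_lookup <- function(sub, graph) {
  d <- sub_degrees(sub, graph)
  indeg <- stats::setNames(d$indeg, d$vertices)
  outdeg <- stats::setNames(d$outdeg, d$vertices)
  list(indeg = indeg, outdeg = outdeg)
}

# maximal non-branching chains of the induced subgraph (list of edge-id
# vectors, deterministic order); internal vertices have induced in=out=1
sub_chains <- function(sub, graph) {
  ids <- sort(sub$edges)
  if (length(ids) == 0L) return(list())
  dg <- sub_deg_lookup(sub, graph)
  out_at <- split(ids, unname(graph$efrom[ids]))
  in_at <- split(ids, unname(graph$eto[ids]))
  mergeable <- function(v) dg$indeg[[v]] == 1L && dg$outdeg[[v]] == 1L
  nxt <- function(id) {
    v <- graph$eto[[id]]
    if (!mergeable(v)) return(NA_character_)
    out_at[[v]][1L]
  }
  prv <- function(id) {
    v <- graph$efrom[[id]]
    if (!mergeable(v)) return(NA_character_)
    in_at[[v]][1L]
  }
  assigned <- character(0)
  chains <- list()
  for (id in ids) {
    if (id %in% assigned) next
    p <- prv(id)
    if (!is.na(p) && !(p %in% assigned)) next
    ch <- id
    cur <- id
    repeat {
      nx <- nxt(cur)
      if (is.na(nx) || nx %in% ch || nx %in% assigned) break
      ch <- c(ch, nx)
      cur <- nx
    }
    chains[[length(chains) + 1L]] <- ch
    assigned <- c(assigned, ch)
  }
  for (id in ids) {  # isolated cycles
    if (id %in% assigned) next
    ch <- id
    cur <- id
    repeat {
      nx <- nxt(cur)
      if (is.na(nx) || nx %in% ch) break
      ch <- c(ch, nx)
      cur <- nx
    }
    chains[[length(chains) + 1L]] <- ch
    assigned <- c(assigned, ch)
  }
  chains
}

# spelled length of an edge chain (k-1 overlaps collapsed)
chain_bp <- function(chain, graph) {
  sum(graph$elen[chain]) - (length(chain) - 1L) * (graph$k - 1L)
}

# length-weighted mean barcode coverage of a chain
chain_cov <- function(sub, chain, graph) {
  lens <- unname(graph$elen[chain])
  sum(sub$bc_cov[chain] * lens) / sum(lens)
}

sub_remove_edges <- function(sub, ids) {
  keep <- setdiff(sub$edges, ids)
  sub$edges <- keep
  sub$bc_cov <- sub$bc_cov[keep]
  sub$left <- sub$left[keep]
  sub$right <- sub$right[keep]
  sub
}

sub_add_edges <- function(sub, ids, cov, graph) {
  ids <- setdiff(ids, sub$edges)
  if (length(ids) == 0L) return(sub)
  lens <- unname(graph$elen[ids])
  sub$edges <- sort(c(sub$edges, ids))
  add_cov <- stats::setNames(rep_len(cov, length(ids)), ids)
  add_l <- stats::setNames(rep(0L, length(ids)), ids)
  add_r <- stats::setNames(as.integer(lens), ids)
  sub$bc_cov <- c(sub$bc_cov, add_cov)[sub$edges]
  sub$left <- c(sub$left, add_l)[sub$edges]
  sub$right <- c(sub$right, add_r)[sub$edges]
  sub
}

# twin closure of an edge-id set
twin_closure <- function(graph, ids) {
  if (!graph$double_stranded) return(ids)
  unique(c(ids, stats::na.omit(graph$twin[ids])))
}

#' Clip tips from a cloud subgraph
#'
#' A tip is a maximal chain of subgraph edges hanging off a branching vertex:
#' internal vertices have induced degree two, the far vertex has degree one
#' (dead end or dead start), and the anchoring vertex has induced degree
#' greater than two. A tip is clipped when its spelled length is at most
#' `max_tip_len` bp, or when its mean barcode-specific coverage is below
#' `rel_cov` times the coverage of the best through-going chain at the
#' anchoring vertex. Applied iteratively to a fixpoint.
#'
#' @param sub a `cloud_subgraph`.
#' @param graph the global `assembly_graph` (read-only).
#' @param max_tip_len maximal tip length in bp (default 100).
#' @param rel_cov relative coverage threshold (default 0.5).
#' @return the simplified `cloud_subgraph`.
#' @export
clip_tips <- function(sub, graph, max_tip_len = 100L, rel_cov = 0.5) {
  repeat {
    if (length(sub$edges) == 0L) break
    chains <- sub_chains(sub, graph)
    dg <- sub_deg_lookup(sub, graph)
    deg <- function(v) dg$indeg[[v]] + dg$outdeg[[v]]
    covs <- vapply(chains, chain_cov, numeric(1), sub = sub, graph = graph)
    remove <- character(0)
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      v1 <- graph$efrom[[ch[1L]]]
      v2 <- graph$eto[[ch[length(ch)]]]
      anchor <- NULL
      if (deg(v2) == 1L && deg(v1) > 2L) anchor <- v1        # dead end
      else if (deg(v1) == 1L && deg(v2) > 2L) anchor <- v2   # dead start
      if (is.null(anchor)) next
      short <- chain_bp(ch, graph) <= max_tip_len
      low <- FALSE
      if (!short) {
        others <- covs[vapply(chains, function(o) {
          !identical(o, ch) &&
            (anchor %in% graph$efrom[o] || anchor %in% graph$eto[o])
        }, logical(1))]
        if (length(others)) {
          low <- covs[ci] < rel_cov * max(others)
        }
      }
      if (short || low) remove <- c(remove, ch)
    }
    remove <- twin_closure(graph, intersect(remove, sub$edges))
    if (length(remove) == 0L) break
    sub <- sub_remove_edges(sub, remove)
  }
  sub
}

#' Remove bulges from a cloud subgraph
#'
#' Finds pairs of simple non-branching chains that share their start and end
#' vertices (parallel alternatives) and whose spelled lengths differ by less
#' than `max(min_len_diff, len_diff_frac *` longer length`)`, and removes the
#' chain with the lower length-weighted mean barcode coverage. Ties are broken
#' deterministically: the lexicographically smaller edge-id chain is kept.
#' Applied to a fixpoint.
#'
#' @inheritParams clip_tips
#' @param min_len_diff,len_diff_frac length-similarity bound for a pair of
#'   parallel chains to count as a bulge.
#' @return the simplified `cloud_subgraph`.
#' @export
remove_bulges <- function(sub, graph, min_len_diff = 50L,
                          len_diff_frac = 0.1) {
  repeat {
    if (length(sub$edges) == 0L) break
    chains <- sub_chains(sub, graph)
    if (length(chains) < 2L) break
    key <- vapply(chains, function(ch) {
      paste(graph$efrom[[ch[1L]]], graph$eto[[ch[length(ch)]]], sep = "\r")
    }, character(1))
    remove <- character(0)
    for (kk in unique(key[duplicated(key)])) {
      grp <- chains[key == kk]
      lens <- vapply(grp, chain_bp, numeric(1), graph = graph)
      covs <- vapply(grp, chain_cov, numeric(1), sub = sub, graph = graph)
      sig <- vapply(grp, paste, character(1), collapse = ",")
      # keep the best chain (highest coverage, ties: smaller edge-id chain)
      ord <- order(-covs, sig)
      best <- ord[1L]
      for (j in ord[-1L]) {
        tol <- max(min_len_diff, len_diff_frac * max(lens[best], lens[j]))
        if (abs(lens[best] - lens[j]) < tol) {
          remove <- c(remove, grp[[j]])
        }
      }
    }
    remove <- twin_closure(graph, intersect(remove, sub$edges))
    if (length(remove) == 0L) break
    # never drop a chain whose twin was selected as kept: the twin closure
    # above already keeps decisions mirror-consistent for disjoint twins
    sub <- sub_remove_edges(sub, remove)
  }
  sub
}

# BFS over the global graph for a short connecting walk from vertex `vfrom`
# to vertex `vto`; every walk edge must be <= max_len bp; at most max_edges
# edges. Returns list(edges, bp) or NULL.
.find_gap_walk <- function(graph, vfrom, vto, max_len, max_edges = 6L) {
  best <- NULL
  frontier <- list(list(v = vfrom, edges = character(0), bp = 0L))
  for (depth in seq_len(max_edges)) {
    nxt <- list()
    for (st in frontier) {
      for (eid in sort(out_edges(graph, st$v))) {
        elen <- graph$elen[[eid]]
        if (elen > max_len) next
        if (eid %in% st$edges) next
        bp <- st$bp + (elen - graph$k + 1L)
        walk <- c(st$edges, eid)
        tov <- graph$eto[[eid]]
        if (tov == vto) {
          cand <- list(edges = walk, bp = bp)
          if (is.null(best) || cand$bp < best$bp ||
              (cand$bp == best$bp &&
               (length(cand$edges) < length(best$edges) ||
                (length(cand$edges) == length(best$edges) &&
                 paste(cand$edges, collapse = ",") <
                 paste(best$edges, collapse = ","))))) {
            best <- cand
          }
        } else if (length(nxt) < 200L) {
          nxt[[length(nxt) + 1L]] <- list(v = tov, edges = walk, bp = bp)
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  best
}

#' Close coverage gaps in a cloud subgraph
#'
#' Adds short edges of the global assembly graph back into the subgraph when
#' they merge two maximal simple paths into one: for each pair of paths
#' (dead end of one, dead start of the other) the shortest connecting walk of
#' global edges each at most `max_gap_edge_len` bp (at most `max_gap_edges`
#' edges; splice hubs chain several near-k-sized connector edges, so the
#' count cap is generous and the per-edge length bound does the real work)
#' is inserted. Added edges receive the mean barcode coverage of the
#' two flanking edges and full-span extreme positions. Applied greedily,
#' best (shortest) connection first, to a fixpoint.
#'
#' @inheritParams clip_tips
#' @param max_gap_edge_len maximal length of an inserted edge in bp.
#' @param max_gap_edges maximal number of edges in a connecting walk.
#' @return the `cloud_subgraph` with gaps closed.
#' @export
close_gaps <- function(sub, graph, max_gap_edge_len = 100L,
                       max_gap_edges = 6L) {
  repeat {
    if (length(sub$edges) == 0L) break
    chains <- sub_chains(sub, graph)
    if (length(chains) < 2L) break
    dg <- sub_deg_lookup(sub, graph)
    ends <- vapply(chains, function(ch) graph$eto[[ch[length(ch)]]],
                   character(1))
    starts <- vapply(chains, function(ch) graph$efrom[[ch[1L]]],
                     character(1))
    dead_end <- dg$outdeg[ends] == 0L
    dead_start <- dg$indeg[starts] == 0L
    best <- NULL
    for (i in which(dead_end)) {
      for (j in which(dead_start)) {
        if (i == j) next
        walk <- .find_gap_walk(graph, ends[i], starts[j], max_gap_edge_len,
                               max_gap_edges)
        if (is.null(walk)) next
        cand <- list(walk = walk, i = i, j = j)
        if (is.null(best) || walk$bp < best$walk$bp ||
            (walk$bp == best$walk$bp &&
             paste(walk$edges, collapse = ",") <
             paste(best$walk$edges, collapse = ","))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    flank_cov <- mean(c(
      sub$bc_cov[[chains[[best$i]][length(chains[[best$i]])]]],
      sub$bc_cov[[chains[[best$j]][1L]]]))
    add <- twin_closure(graph, best$walk$edges)
    sub <- sub_add_edges(sub, add, flank_cov, graph)
  }
  sub
}

#' Simplify a cloud subgraph
#'
#' Composition of the three per-barcode correction passes in order — tip
#' clipping, bulge removal, gap closing — iterated until the subgraph stops
#' changing (bounded number of rounds). On an error-free, gap-free
#' single-isoform cloud the composition is the identity.
#'
#' @inheritParams clip_tips
#' @inheritParams remove_bulges
#' @inheritParams close_gaps
#' @param max_rounds safety bound on the number of composition rounds.
#' @return the simplified `cloud_subgraph`.
#' @export
simplify_subgraph <- function(sub, graph, max_tip_len = 100L, rel_cov = 0.5,
                              min_len_diff = 50L, len_diff_frac = 0.1,
                              max_gap_edge_len = 100L, max_gap_edges = 6L,
                              max_rounds = 10L) {
  for (round in seq_len(max_rounds)) {
    before <- sub$edges
    sub <- clip_tips(sub, graph, max_tip_len, rel_cov)
    sub <- remove_bulges(sub, graph, min_len_diff, len_diff_frac)
    sub <- close_gaps(sub, graph, max_gap_edge_len, max_gap_edges)
    if (identical(sub$edges, before)) break
  }
  sub
}
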