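#' @useDynLib isocloud, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Compacted de Bruijn assembly graph
#
# Vertices are (k-1)-mers (stored as strings), edges are maximal unbranched
# sequences with a mean k-mer coverage. In double-stranded mode every edge has
# a reverse-complement twin and the twin map is an involution. The graph is
# the single global object all read clouds share; per-barcode processing never
# mutates it.
# ---------------------------------------------------------------------------

new_assembly_graph <- function(seq, cov, k, double_stranded) {
  ord <- order(seq)
  seq <- seq[ord]
  cov <- cov[ord]
  n <- length(seq)
  id <- if (n) sprintf("E%05d", seq_len(n)) else character(0)
  len <- nchar(seq)
  edges <- data.frame(
    id = id,
    seq = seq,
    from = substr(seq, 1L, k - 1L),
    to = substr(seq, len - k + 2L, len),
    length = len,
    cov = cov,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- id
  twin <- rep(NA_character_, n)
  names(twin) <- id
  if (double_stranded && n) {
    m <- match(rc_dna(seq), seq)
    twin[] <- id[m]
    # cycle edges (from == to) may pair up to rotation only
    miss <- which(is.na(twin))
    if (length(miss)) {
      cyc <- which(edges$from == edges$to)
      for (i in miss) {
        rcs <- rc_dna(seq[i])
        cand <- cyc[edges$length[cyc] == edges$length[i]]
        for (j in cand) {
          dbl <- paste0(substr(seq[j], k, edges$length[j]),
                        substr(seq[j], k, edges$length[j]))
          if (grepl(substr(rcs, k, edges$length[i]), dbl, fixed = TRUE)) {
            twin[i] <- id[j]
            break
          }
        }
      }
    }
  }
  g <- list(
    k = k,
    double_stranded = double_stranded,
    edges = edges,
    twin = twin,
    out_adj = split(id, edges$from),
    in_adj = split(id, edges$to),
    # named-vector views of the edge table for fast lookups in hot paths
    eseq = stats::setNames(edges$seq, id),
    efrom = stats::setNames(edges$from, id),
    eto = stats::setNames(edges$to, id),
    elen = stats::setNames(edges$length, id),
    ecov = stats::setNames(edges$cov, id)
  )
  class(g) <- "assembly_graph"
  g
}

#' Build the global compacted de Bruijn graph
#'
#' Constructs the de Bruijn graph of all `k`-mers present in `reads` (k-mers
#' containing N are skipped) and compacts every maximal unbranched path into a
#' single edge. Edge coverage is the mean multiplicity of its constituent
#' k-mers. In double-stranded mode (the default, as for real sequencing data)
#' the reverse complement of every read is included, so every edge has a twin.
#'
#' @param reads character vector of DNA reads.
#' @param k odd k-mer size, at least 3.
#' @param double_stranded include reverse complements and maintain the twin
#'   map. Single-stranded graphs are convenient for small worked examples.
#' @return an `assembly_graph` object.
#' @export
#' @examples
#' g <- build_graph("ACGTACGGTT", k = 5, double_stranded = FALSE)
#' g$edges$seq
build_graph <- function(reads, k = 55L, double_stranded = TRUE) {
  k <- as.integer(k)
  stopifnot(k >= 3L, k %% 2L == 1L)
  reads <- toupper(as.character(reads))
  if (length(reads) == 0L) {
    return(new_assembly_graph(character(0), numeric(0), k, double_stranded))
  }
  raw <- .dbg_build_cpp(reads, k, double_stranded)
  new_assembly_graph(raw$seq, raw$cov, k, double_stranded)
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat(sprintf(
    "assembly_graph: k=%d, %d edges, %d vertices, %s, total %d bp\n",
    x$k, nrow(x$edges),
    length(unique(c(x$edges$from, x$edges$to))),
    if (x$double_stranded) "double-stranded" else "single-stranded",
    sum(x$edges$length)
  ))
  invisible(x)
}

out_edges <- function(graph, vertex) graph$out_adj[[vertex]] %||% character(0)
in_edges <- function(graph, vertex) graph$in_adj[[vertex]] %||% character(0)

edge_field <- function(graph, ids, field) graph$edges[ids, field]

# number of k-mers spelled by an edge
edge_nkmers <- function(graph, ids) graph$edges[ids, "length"] - graph$k + 1L

# ---------------------------------------------------------------------------
# Re-compaction: merge chains of edges through vertices of in/out degree 1.
# Needed after any edge removal so the compaction invariant keeps holding.
# ---------------------------------------------------------------------------

re_compact <- function(graph) {
  if (nrow(graph$edges) <= 1L) return(graph)
  k <- graph$k
  ids <- graph$edges$id
  efrom <- graph$efrom; eto <- graph$eto
  elen <- graph$elen; ecov <- graph$ecov; eseq <- graph$eseq
  indeg <- table(graph$edges$to)
  outdeg <- table(graph$edges$from)
  merge_v <- intersect(names(indeg)[indeg == 1L], names(outdeg)[outdeg == 1L])
  mergeable <- new.env(hash = TRUE, parent = emptyenv())
  for (v in merge_v) assign(v, TRUE, envir = mergeable)
  out_at <- split(ids, graph$edges$from)
  in_at <- split(ids, graph$edges$to)
  nxt <- function(id) {
    v <- eto[[id]]
    if (is.null(mergeable[[v]])) return(NA_character_)
    out_at[[v]]
  }
  prv <- function(id) {
    v <- efrom[[id]]
    if (is.null(mergeable[[v]])) return(NA_character_)
    in_at[[v]]
  }
  assigned <- new.env(hash = TRUE, parent = emptyenv())
  chains <- list()
  # chains starting at non-mergeable boundaries, edge ids in sorted order
  for (id in ids) {
    if (!is.null(assigned[[id]])) next
    p <- prv(id)
    if (!is.na(p) && is.null(assigned[[p]])) next  # not a chain head (yet)
    ch <- id
    cur <- id
    assigned[[id]] <- TRUE
    repeat {
      nx <- nxt(cur)
      if (is.na(nx) || !is.null(assigned[[nx]])) break
      ch <- c(ch, nx)
      assigned[[nx]] <- TRUE
      cur <- nx
    }
    chains[[length(chains) + 1L]] <- ch
  }
  # leftover: isolated cycles where every vertex is mergeable
  for (id in ids) {
    if (!is.null(assigned[[id]])) next
    ch <- id
    cur <- id
    assigned[[id]] <- TRUE
    repeat {
      nx <- nxt(cur)
      if (is.na(nx) || !is.null(assigned[[nx]])) break
      ch <- c(ch, nx)
      assigned[[nx]] <- TRUE
      cur <- nx
    }
    chains[[length(chains) + 1L]] <- ch
  }
  seqs <- character(length(chains))
  covs <- numeric(length(chains))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    s <- eseq[[ch[1L]]]
    if (length(ch) > 1L) {
      tails <- substr(eseq[ch[-1L]], k, elen[ch[-1L]])
      s <- paste0(s, paste(tails, collapse = ""))
    }
    nk <- elen[ch] - k + 1L
    seqs[i] <- s
    covs[i] <- sum(ecov[ch] * nk) / sum(nk)
  }
  new_assembly_graph(seqs, covs, k, graph$double_stranded)
}

# drop edges by id and re-compact (twin-closed in double-stranded mode)
drop_edges <- function(graph, ids) {
  if (length(ids) == 0L) return(graph)
  if (graph$double_stranded) {
    ids <- unique(c(ids, stats::na.omit(graph$twin[ids])))
  }
  keep <- !(graph$edges$id %in% ids)
  g2 <- new_assembly_graph(graph$edges$seq[keep], graph$edges$cov[keep],
                           graph$k, graph$double_stranded)
  re_compact(g2)
}

# integer-indexed view of the edge table with hashed vertex adjacency,
# built once per pruning iteration (plain named-vector lookups are linear
# scans and far too slow on the raw, error-laden graph)
.prune_ctx <- function(graph) {
  e <- graph$edges
  out_at <- new.env(hash = TRUE, parent = emptyenv())
  in_at <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(e))) {
    out_at[[e$from[i]]] <- c(out_at[[e$from[i]]], i)
    in_at[[e$to[i]]] <- c(in_at[[e$to[i]]], i)
  }
  list(from = e$from, to = e$to, len = e$length, cov = e$cov, id = e$id,
       out_at = out_at, in_at = in_at, k = graph$k)
}

# minimal coverage along the best path vfrom -> vto avoiding edges in
# `exclude` (integer indices), spelled span at most `limit` bp; NA if none
.alt_path_cov <- function(ctx, vfrom, vto, limit, exclude) {
  best <- NA_real_
  frontier <- list(list(v = vfrom, bp = 0L, mincov = Inf))
  for (depth in 1:8) {
    nxt <- list()
    for (st in frontier) {
      for (f in ctx$out_at[[st$v]]) {
        if (f %in% exclude) next
        bp <- st$bp + ctx$len[f] - ctx$k + 1L
        if (bp > limit) next
        mc <- min(st$mincov, ctx$cov[f])
        if (ctx$to[f] == vto) {
          if (is.na(best) || mc > best) best <- mc
        } else if (length(nxt) < 64L) {
          nxt[[length(nxt) + 1L]] <- list(v = ctx$to[f], bp = bp,
                                          mincov = mc)
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  best
}

# bulge candidates: simple paths made entirely of low-coverage edges, running
# from one backbone anchor vertex to another. Sequencing errors typically
# spawn such paths parallel to a high-coverage alternative; overlapping
# errors fragment them into several edges, so single-edge parallelism is not
# enough. Returns a list of integer edge-index vectors.
.low_cov_paths <- function(ctx, low, max_bp, max_edges = 6L) {
  # anchors: vertices incident to at least one high-coverage edge
  anchor <- new.env(hash = TRUE, parent = emptyenv())
  for (i in which(!low)) {
    anchor[[ctx$from[i]]] <- TRUE
    anchor[[ctx$to[i]]] <- TRUE
  }
  out <- list()
  for (s in which(low)) {
    if (is.null(anchor[[ctx$from[s]]])) next
    stack <- list(list(edges = s, bp = ctx$len[s] - ctx$k + 1L))
    while (length(stack)) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      lastv <- ctx$to[st$edges[length(st$edges)]]
      if (!is.null(anchor[[lastv]])) {
        out[[length(out) + 1L]] <- st$edges
        next
      }
      if (length(st$edges) >= max_edges) next
      for (f in ctx$out_at[[lastv]]) {
        if (!low[f] || f %in% st$edges) next
        bp <- st$bp + ctx$len[f] - ctx$k + 1L
        if (bp > max_bp) next
        stack[[length(stack) + 1L]] <- list(edges = c(st$edges, f), bp = bp)
      }
    }
  }
  out
}

#' Remove extremely low-coverage edges from the global graph
#'
#' Light global simplification applied once after graph construction: prunes
#' obvious sequencing-error artifacts while leaving everything else intact, so
#' that an edge that is noise for one barcode can still serve another.
#' Two removal rules, iterated to a fixpoint with re-compaction in between:
#'
#' * tips: edges with a dead source or dead target vertex, shorter than
#'   `tip_length` and with coverage strictly below `cutoff`;
#' * bulges: paths of edges below `bulge_cutoff` (default `5 * cutoff`)
#'   whose coverage is below `bulge_frac` of an alternative path of similar
#'   length between the same two vertices. Both sides may span several edges
#'   when nearby sequencing-error bubbles interrupt them; the relative
#'   condition catches recurrent errors that rise above the absolute cutoff
#'   at deep coverage while sparing genuine low-coverage junctions, which
#'   have no similar-length alternative.
#'
#' No edge with coverage at or above `cutoff` is ever removed, and
#' `cutoff = 0` is the identity.
#'
#' @param graph an `assembly_graph`.
#' @param cutoff absolute coverage cutoff (default 2.0).
#' @param tip_length maximal tip length in bp; default `2 * k`.
#' @param bulge_frac relative coverage threshold for bulge branches
#'   (default 0.2 of the alternative's coverage).
#' @param bulge_cutoff absolute ceiling for bulge-candidate coverage;
#'   default `5 * cutoff`.
#' @return the pruned, re-compacted `assembly_graph`.
#' @export
prune_low_coverage <- function(graph, cutoff = 2.0, tip_length = NULL,
                               bulge_frac = 0.2, bulge_cutoff = NULL) {
  if (is.null(tip_length)) tip_length <- 2L * graph$k
  if (is.null(bulge_cutoff)) bulge_cutoff <- 5 * cutoff
  repeat {
    e <- graph$edges
    if (nrow(e) == 0L) break
    ctx <- .prune_ctx(graph)
    has_in <- e$from %in% e$to
    has_out <- e$to %in% e$from
    low <- e$cov < cutoff
    tip <- (!has_in | !has_out) & e$length < tip_length & low
    # dominated sub-cutoff edges: error paths sit next to their much deeper
    # true alternative, while genuine low-coverage junctions keep a sizeable
    # share of their neighborhood's depth
    max_at <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(e))) {
      for (v in c(e$from[i], e$to[i])) {
        cur <- max_at[[v]]
        if (is.null(cur) || e$cov[i] > cur) max_at[[v]] <- e$cov[i]
      }
    }
    # two tiers: sub-cutoff edges dominated 20-fold, and (independently of
    # the absolute cutoff, which recurrent errors outgrow at deep coverage)
    # short edges dominated 50-fold -- a genuine junction private to one
    # isoform keeps a far larger share of its neighborhood's depth
    dom <- vapply(seq_len(nrow(e)), function(i) {
      if (tip[i]) return(FALSE)
      nb <- max(max_at[[e$from[i]]], max_at[[e$to[i]]])
      (low[i] && e$cov[i] < 0.05 * nb) ||
        (cutoff > 0 && e$length[i] < 3L * graph$k &&
           e$cov[i] < 0.02 * nb)
    }, logical(1))
    # bulges: low-coverage paths parallel to an alternative path of similar
    # length and substantially higher coverage (both sides may span several
    # edges when nearby error bubbles interrupt them)
    bulge_idx <- integer(0)
    cand <- e$cov < bulge_cutoff & !tip & !dom
    if (any(cand)) {
      for (p in .low_cov_paths(ctx, cand, max_bp = 3L * graph$k)) {
        if (any(p %in% bulge_idx)) next
        pbp <- sum(ctx$len[p]) - (length(p) - 1L) * (graph$k - 1L) -
          graph$k + 1L
        alt <- .alt_path_cov(ctx, ctx$from[p[1L]], ctx$to[p[length(p)]],
                             limit = pbp + 2L * graph$k, exclude = p)
        if (!is.na(alt) && max(ctx$cov[p]) < bulge_frac * alt) {
          bulge_idx <- c(bulge_idx, p)
        }
      }
    }
    remove <- unique(c(e$id[tip | dom], e$id[bulge_idx]))
    if (graph$double_stranded) {
      remove <- unique(c(remove, stats::na.omit(graph$twin[remove])))
    }
    if (length(remove) == 0L) break
    graph <- drop_edges(graph, remove)
  }
  graph
}

# ---------------------------------------------------------------------------
# GFA1 import/export. Segments carry sequences and dp:f: coverage; links carry
# the (k-1)M overlap. In double-stranded mode one segment represents a twin
# pair and links use +/- orientations.
# ---------------------------------------------------------------------------

#' Write an assembly graph as GFA1
#'
#' @param graph an `assembly_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  e <- graph$edges
  k <- graph$k
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  if (nrow(e) == 0L) return(invisible(path))
  if (graph$double_stranded) {
    # canonical representative of each twin pair: lexicographically smaller seq
    rep_id <- ifelse(is.na(graph$twin) | e$seq <= e[graph$twin, "seq"],
                     e$id, graph$twin)
    names(rep_id) <- e$id
    segs <- unique(rep_id)
    writeLines(sprintf("S\t%s\t%s\tdp:f:%g", segs, e[segs, "seq"],
                       e[segs, "cov"]), con)
    ori <- ifelse(e$id == rep_id, "+", "-")
    names(ori) <- e$id
    links <- character(0)
    seen <- character(0)
    for (i in seq_len(nrow(e))) {
      for (f in out_edges(graph, e$to[i])) {
        a <- rep_id[[e$id[i]]]; oa <- ori[[e$id[i]]]
        b <- rep_id[[f]]; ob <- ori[[f]]
        fwd <- paste(a, oa, b, ob)
        mir <- paste(b, if (ob == "+") "-" else "+",
                     a, if (oa == "+") "-" else "+")
        key <- min(fwd, mir)
        if (key %in% seen) next
        seen <- c(seen, key)
        links <- c(links, sprintf("L\t%s\t%s\t%s\t%s\t%dM", a, oa, b, ob, k - 1L))
      }
    }
    if (length(links)) writeLines(links, con)
  } else {
    writeLines(sprintf("S\t%s\t%s\tdp:f:%g", e$id, e$seq, e$cov), con)
    links <- character(0)
    for (i in seq_len(nrow(e))) {
      fs <- out_edges(graph, e$to[i])
      if (length(fs)) {
        links <- c(links, sprintf("L\t%s\t+\t%s\t+\t%dM", e$id[i], fs, k - 1L))
      }
    }
    if (length(links)) writeLines(links, con)
  }
  invisible(path)
}

#' Read an assembly graph from GFA1
#'
#' Reconstructs the graph from S-line sequences; in double-stranded mode the
#' reverse complement of every segment is added back as its twin. The k-mer
#' size is inferred from the first link overlap unless given.
#'
#' @param path GFA file path.
#' @param k k-mer size; inferred from L-line overlaps when `NULL`.
#' @param double_stranded whether to restore twin edges.
#' @return an `assembly_graph`.
#' @export
read_gfa <- function(path, k = NULL, double_stranded = TRUE) {
  lines <- readLines(path)
  stype <- substr(lines, 1L, 1L)
  sl <- strsplit(lines[stype == "S"], "\t", fixed = TRUE)
  seqs <- vapply(sl, `[[`, character(1), 3L)
  covs <- vapply(sl, function(f) {
    dp <- grep("^dp:f:", f[-(1:3)], value = TRUE)
    if (length(dp)) as.numeric(sub("^dp:f:", "", dp[1L])) else 1.0
  }, numeric(1))
  if (is.null(k)) {
    ll <- strsplit(lines[stype == "L"], "\t", fixed = TRUE)
    if (length(ll) == 0L) stop("cannot infer k: no L lines; pass k explicitly")
    k <- as.integer(sub("M$", "", ll[[1L]][[6L]])) + 1L
  }
  if (double_stranded) {
    rcs <- rc_dna(seqs)
    add <- !(rcs %in% seqs)
    covs <- c(covs, covs[add])
    seqs <- c(seqs, rcs[add])
  }
  dedup <- !duplicated(seqs)
  new_assembly_graph(seqs[dedup], covs[dedup], k, double_stranded)
}
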