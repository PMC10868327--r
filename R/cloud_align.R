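# ---------------------------------------------------------------------------
# Read clouds: grouping barcoded reads, aligning them to the assembly graph,
# and deriving the per-barcode subgraph with barcode-specific coverage and
# extreme alignment positions.
# ---------------------------------------------------------------------------

#' Create a read cloud
#'
#' @param barcode non-empty barcode string.
#' @param read1 character vector of first mates.
#' @param read2 character vector of second mates, or `NULL` for single reads.
#'   `NA` entries mark pairs whose mate is missing.
#' @return a `read_cloud` object.
#' @export
read_cloud <- function(barcode, read1, read2 = NULL) {
  stopifnot(nzchar(barcode), all(nzchar(read1)))
  if (!is.null(read2)) stopifnot(length(read2) == length(read1))
  structure(list(barcode = barcode, read1 = as.character(read1),
                 read2 = if (is.null(read2)) NULL else as.character(read2)),
            class = "read_cloud")
}

#' @export
print.read_cloud <- function(x, ...) {
  cat(sprintf("read_cloud %s: %d read pairs\n", x$barcode, length(x$read1)))
  invisible(x)
}

cloud_size <- function(cloud) length(cloud$read1)

extract_barcode <- function(ids, comments, read1, mode, delim = "#",
                            inline_len = 16L) {
  switch(mode,
    bx = {
      m <- regmatches(comments, regexpr("BX:Z:[^[:space:]]+", comments))
      bc <- rep(NA_character_, length(comments))
      has <- grepl("BX:Z:", comments, fixed = TRUE)
      bc[has] <- sub("^.*BX:Z:([^[:space:]]+).*$", "\\1", comments[has])
      bc
    },
    suffix = {
      has <- grepl(delim, ids, fixed = TRUE)
      bc <- rep(NA_character_, length(ids))
      bc[has] <- sub(paste0("^.*", delim), "", ids[has])
      bc
    },
    inline = substr(read1, 1L, inline_len),
    stop("unknown barcode mode: ", mode)
  )
}

#' Group barcoded read pairs into read clouds
#'
#' One cloud per distinct barcode; records without a parseable barcode are
#' collected into a reject bin. Barcodes come from a SAM-style `BX:Z:` tag in
#' the read comment, from a read-name suffix after `delim`, or inline from
#' the first `inline_len` bases of read 1 (which are then trimmed off).
#'
#' @param ids read-pair identifiers.
#' @param read1,read2 mate sequences (`read2` may be `NULL`; `NA` entries in
#'   `read2` are treated as missing mates, with a warning).
#' @param comments FASTQ comment strings (needed for `mode = "bx"`).
#' @param mode one of `"bx"`, `"suffix"`, `"inline"`.
#' @param delim delimiter for `mode = "suffix"`.
#' @param inline_len barcode length for `mode = "inline"`.
#' @return list with `clouds` (named list of `read_cloud`) and `rejected`
#'   (ids without a barcode).
#' @export
group_by_barcode <- function(ids, read1, read2 = NULL, comments = NULL,
                             mode = c("bx", "suffix", "inline"),
                             delim = "#", inline_len = 16L) {
  mode <- match.arg(mode)
  if (is.null(comments)) comments <- rep("", length(ids))
  bc <- extract_barcode(ids, comments, read1, mode, delim, inline_len)
  if (mode == "inline") {
    read1 <- substr(read1, inline_len + 1L, nchar(read1))
  }
  ok <- !is.na(bc) & nzchar(bc)
  rejected <- ids[!ok]
  if (!is.null(read2) && anyNA(read2[ok])) {
    warning(sum(is.na(read2[ok])), " read(s) without a mate; kept as single")
  }
  clouds <- lapply(split(which(ok), bc[ok]), function(i) {
    read_cloud(bc[i[1L]], read1[i], if (is.null(read2)) NULL else read2[i])
  })
  list(clouds = clouds, rejected = rejected)
}

#' Read barcoded paired FASTQ files into read clouds
#'
#' @param r1,r2 FASTQ paths (optionally gzipped); `r2` may be `NULL`.
#' @inheritParams group_by_barcode
#' @return as [group_by_barcode()].
#' @export
read_clouds_fastq <- function(r1, r2 = NULL, mode = c("bx", "suffix", "inline"),
                              delim = "#", inline_len = 16L) {
  mode <- match.arg(mode)
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq")
  hdr <- names(x1)
  ids <- sub("[[:space:]].*$", "", hdr)
  comments <- ifelse(grepl("[[:space:]]", hdr),
                     sub("^[^[:space:]]+[[:space:]]+", "", hdr), "")
  s1 <- as.character(x1)
  s2 <- NULL
  if (!is.null(r2)) {
    x2 <- Biostrings::readDNAStringSet(r2, format = "fastq")
    ids2 <- sub("[[:space:]].*$", "", names(x2))
    m <- match(ids, ids2)
    s2 <- rep(NA_character_, length(ids))
    s2[!is.na(m)] <- as.character(x2)[m[!is.na(m)]]
  }
  group_by_barcode(ids, s1, s2, comments, mode, delim, inline_len)
}

# ---------------------------------------------------------------------------
# Seed-and-extend alignment to the graph: exact k-mer seeds, Hamming-distance
# extension that may walk across edges (collapsing the k-1 overlaps).
# Substitution-only by design: the graph was built from these same reads.
# ---------------------------------------------------------------------------

#' Build an exact k-mer index over the graph edges
#'
#' @param graph an `assembly_graph`.
#' @return an opaque index object for [align_read()].
#' @export
graph_kmer_index <- function(graph) {
  k <- graph$k
  env <- new.env(hash = TRUE, size = max(64L, sum(graph$edges$length)))
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    s <- e$seq[i]
    np <- e$length[i] - k + 1L
    kms <- substring(s, seq_len(np), seq_len(np) + k - 1L)
    for (p in seq_len(np)) {
      km <- kms[p]
      env[[km]] <- rbind(env[[km]], c(i, p))
    }
  }
  echars <- strsplit(e$seq, "", fixed = TRUE)
  list(k = k, map = env, echars = echars, ids = e$id, lens = e$length)
}

# recursive rightward extension; returns list of candidates
# (mm, edges = integer indices, end = 1-based inclusive position on last edge)
.ext_right <- function(graph, idx, rch, i, epos, rpos, mm, max_mm, depth = 0L) {
  L <- length(rch)
  len_i <- idx$lens[i]
  need <- L - rpos + 1L
  avail <- len_i - epos + 1L
  n <- min(need, avail)
  if (n > 0L) {
    mm <- mm + sum(idx$echars[[i]][epos:(epos + n - 1L)] !=
                   rch[rpos:(rpos + n - 1L)])
    if (mm > max_mm) return(list())
  }
  if (need <= avail) {
    return(list(list(mm = mm, edges = i, end = epos + n - 1L, rlen = need)))
  }
  if (depth < 16L) {
    outs <- out_edges(graph, graph$edges$to[i])
    res <- list()
    for (f in match(outs, idx$ids)) {
      sub <- .ext_right(graph, idx, rch, f, graph$k, rpos + n, mm, max_mm,
                        depth + 1L)
      for (s in sub) {
        s$edges <- c(i, s$edges)
        s$rlen <- s$rlen + n
        res[[length(res) + 1L]] <- s
      }
    }
    if (length(res)) return(res)
  }
  # dead end or budget exhausted on every continuation: clip here
  list(list(mm = mm, edges = i, end = len_i, rlen = n))
}

# leftward mirror: returns (mm, edges, start = 1-based position on first edge)
.ext_left <- function(graph, idx, rch, i, epos, rpos, mm, max_mm, depth = 0L) {
  need <- rpos
  avail <- epos
  n <- min(need, avail)
  if (n > 0L) {
    mm <- mm + sum(idx$echars[[i]][(epos - n + 1L):epos] !=
                   rch[(rpos - n + 1L):rpos])
    if (mm > max_mm) return(list())
  }
  if (need <= avail) {
    return(list(list(mm = mm, edges = i, start = epos - n + 1L, rlen = need)))
  }
  if (depth < 16L) {
    ins <- in_edges(graph, graph$edges$from[i])
    res <- list()
    for (f in match(ins, idx$ids)) {
      sub <- .ext_left(graph, idx, rch, f, idx$lens[f] - graph$k + 1L,
                       rpos - n, mm, max_mm, depth + 1L)
      for (s in sub) {
        s$edges <- c(s$edges, i)
        s$rlen <- s$rlen + n
        res[[length(res) + 1L]] <- s
      }
    }
    if (length(res)) return(res)
  }
  list(list(mm = mm, edges = i, start = 1L, rlen = n))
}

#' Align one read to the assembly graph
#'
#' Seeds by exact k-mer lookup, then extends in both directions with
#' substitution-only (Hamming) scoring, walking across adjacent edges where
#' the read spans junctions. All co-optimal alignments are returned, so a
#' read from a repeat contributes to every best-scoring locus.
#'
#' @param read DNA string.
#' @param graph an `assembly_graph`.
#' @param index index from [graph_kmer_index()] (built on the fly if `NULL`).
#' @param max_mm maximal mismatches; default `max(2, ceiling(0.05 * length))`.
#' @param max_hits maximal seed loci examined per k-mer.
#' @return list of alignments, each
#'   `list(edges, start, end, mm, clipped)` with 0-based `start` on the first
#'   edge and exclusive `end` on the last edge, or `NULL` when unaligned.
#' @export
align_read <- function(read, graph, index = NULL, max_mm = NULL,
                       max_hits = 8L) {
  k <- graph$k
  L <- nchar(read)
  if (L < k) return(NULL)
  if (is.null(index)) index <- graph_kmer_index(graph)
  if (is.null(max_mm)) max_mm <- max(2L, ceiling(0.05 * L))
  rch <- chars(read)
  seeds <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
  best <- list()
  best_mm <- max_mm + 1L
  best_span <- 0L
  for (p in seeds) {
    km <- substr(read, p, p + k - 1L)
    hits <- index$map[[km]]
    if (is.null(hits)) next
    nh <- min(nrow(hits), max_hits)
    for (h in seq_len(nh)) {
      i <- hits[h, 1L]; off <- hits[h, 2L]
      lefts <- .ext_left(graph, index, rch, i, off - 1L, p - 1L, 0L, max_mm)
      for (lft in lefts) {
        rights <- .ext_right(graph, index, rch, i, off + k, p + k, lft$mm,
                             max_mm)
        for (rgt in rights) {
          path_l <- lft$edges
          path_r <- rgt$edges
          # both include the seed edge i at their junction
          edges <- c(path_l[-length(path_l)], path_r)
          span <- lft$rlen + k + rgt$rlen
          aln <- list(edges = index$ids[edges],
                      start = lft$start - 1L,
                      end = rgt$end,
                      mm = rgt$mm,
                      span = span)
          # longest aligned span wins; mismatches break ties
          if (span > best_span ||
              (span == best_span && aln$mm < best_mm)) {
            best <- list(aln)
            best_mm <- aln$mm
            best_span <- span
          } else if (span == best_span && aln$mm == best_mm) {
            best[[length(best) + 1L]] <- aln
          }
        }
      }
    }
    if (best_mm == 0L && best_span == L) break  # full-length exact
  }
  if (length(best) == 0L) return(NULL)
  # deduplicate co-optimal alignments found from different seeds
  sig <- vapply(best, function(a)
    paste(paste(a$edges, collapse = ","), a$start, a$end), character(1))
  best <- best[!duplicated(sig)]
  best
}

#' Align all reads of a cloud to the graph
#'
#' Second mates are aligned as their reverse complement, so in a
#' double-stranded graph both mates of a fragment report paths along the same
#' strand walk (or its twin). Reads shorter than k are skipped.
#'
#' @param cloud a `read_cloud`.
#' @inheritParams align_read
#' @return list of per-pair alignment sets:
#'   `list(m1 = <alignments>, m2 = <alignments>)` (each possibly `NULL`).
#' @export
align_cloud <- function(cloud, graph, index = NULL, max_mm = NULL) {
  if (is.null(index)) index <- graph_kmer_index(graph)
  lapply(seq_along(cloud$read1), function(i) {
    r1 <- cloud$read1[i]
    m1 <- if (nchar(r1) >= graph$k)
      align_read(r1, graph, index, max_mm) else NULL
    m2 <- NULL
    if (!is.null(cloud$read2) && !is.na(cloud$read2[i]) &&
        nchar(cloud$read2[i]) >= graph$k) {
      m2 <- align_read(rc_dna(cloud$read2[i]), graph, index, max_mm)
    }
    list(m1 = m1, m2 = m2)
  })
}

# per-edge footprint of one alignment: matrix (edge id, start0, end0)
alignment_footprint <- function(aln, graph) {
  n <- length(aln$edges)
  lens <- unname(graph$elen[aln$edges])
  start <- rep(0L, n)
  end <- lens
  start[1L] <- aln$start
  end[n] <- aln$end
  data.frame(edge = aln$edges, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Derive the barcode-specific subgraph of a cloud
#'
#' The subgraph is the subset of global edges touched by at least one
#' alignment of the cloud, with barcode-specific coverage (aligned bases of
#' the cloud on the edge divided by edge length) and the extreme (leftmost /
#' rightmost) alignment positions per edge. In a double-stranded graph every
#' contribution is mirrored onto the twin edge so the subgraph is closed
#' under reverse complement. The global graph is never modified.
#'
#' @param alignments output of [align_cloud()].
#' @param graph an `assembly_graph`.
#' @param barcode barcode string recorded on the subgraph.
#' @return a `cloud_subgraph` with fields `edges`, `bc_cov`, `left`, `right`.
#' @export
derive_subgraph <- function(alignments, graph, barcode = "") {
  fps <- list()
  for (pair in alignments) {
    for (side in c("m1", "m2")) {
      for (aln in pair[[side]]) {
        fp <- alignment_footprint(aln, graph)
        fps[[length(fps) + 1L]] <- fp
        if (graph$double_stranded) {
          tw <- graph$twin[fp$edge]
          lens <- unname(graph$elen[fp$edge])
          ok <- !is.na(tw)
          if (any(ok)) {
            fps[[length(fps) + 1L]] <- data.frame(
              edge = tw[ok],
              start = lens[ok] - fp$end[ok],
              end = lens[ok] - fp$start[ok],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(fps) == 0L) {
    return(structure(list(barcode = barcode, edges = character(0),
                          bc_cov = numeric(0), left = integer(0),
                          right = integer(0)),
                     class = "cloud_subgraph"))
  }
  fp <- do.call(rbind, fps)
  bases <- tapply(fp$end - fp$start, fp$edge, sum)
  left <- tapply(fp$start, fp$edge, min)
  right <- tapply(fp$end, fp$edge, max)
  edges <- sort(names(bases))
  bc_cov <- as.numeric(bases[edges]) / unname(graph$elen[edges])
  names(bc_cov) <- edges
  lf <- as.integer(left[edges]); names(lf) <- edges
  rt <- as.integer(right[edges]); names(rt) <- edges
  structure(list(barcode = barcode, edges = edges, bc_cov = bc_cov,
                 left = lf, right = rt),
            class = "cloud_subgraph")
}

#' @export
print.cloud_subgraph <- function(x, ...) {
  cat(sprintf("cloud_subgraph [%s]: %d edges, mean barcode coverage %.2f\n",
              x$barcode, length(x$edges),
              if (length(x$bc_cov)) mean(x$bc_cov) else 0))
  invisible(x)
}

#' Estimate insert-size statistics from pair alignments
#'
#' Uses pairs whose two mates align within a single shared edge (or twin
#' edges), where the implied fragment length is unambiguous.
#'
#' @param aligned_clouds list of [align_cloud()] results.
#' @param graph an `assembly_graph`.
#' @param default fallback `c(mean, sd)` when fewer than 5 pairs qualify.
#' @return list with `mean`, `sd` and `n` observations.
#' @export
estimate_insert_stats <- function(aligned_clouds, graph,
                                  default = c(250, 50)) {
  ins <- numeric(0)
  for (cl in aligned_clouds) {
    for (pair in cl) {
      if (length(pair$m1) != 1L || length(pair$m2) != 1L) next
      a <- pair$m1[[1L]]; b <- pair$m2[[1L]]
      if (length(a$edges) != 1L || length(b$edges) != 1L) next
      if (b$edges == a$edges) {
        ins <- c(ins, max(a$end, b$end) - min(a$start, b$start))
      } else if (graph$double_stranded &&
                 !is.na(graph$twin[a$edges]) &&
                 graph$twin[a$edges] == b$edges) {
        len <- graph$elen[[a$edges]]
        s2 <- len - b$end; e2 <- len - b$start
        ins <- c(ins, max(a$end, e2) - min(a$start, s2))
      }
    }
  }
  if (length(ins) < 5L) {
    return(list(mean = default[1L], sd = default[2L], n = length(ins)))
  }
  list(mean = mean(ins), sd = max(stats::sd(ins), 1), n = length(ins))
}
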