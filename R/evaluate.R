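# ---------------------------------------------------------------------------
# Isoform assignment of assembled contigs against a reference (a lightweight
# intron-chain classifier), the barcode-based "fixed" filter, and
# precision / recall / fixed-recall scoring against simulation ground truth.
# ---------------------------------------------------------------------------

ASSIGN_CATEGORIES <- c("unique", "unique_minor", "ambiguous", "inconsistent",
                       "non_informative", "intergenic")

# per-gene annotation tables used by the classifier
build_reference <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  ref <- list()
  for (g in genes) {
    txs <- transcript_seqs(g)
    iso <- names(g$isoforms)
    # genomic junction chain per isoform, cumulative exon lengths for
    # transcript -> genome coordinate mapping
    juncs <- lapply(g$isoforms, function(ch) {
      if (length(ch) < 2L) return(character(0))
      paste(g$exons[ch[-length(ch)], "end"],
            g$exons[ch[-1L], "start"], sep = "-")
    })
    cums <- lapply(g$isoforms, function(ch) {
      cumsum(g$exons[ch, "end"] - g$exons[ch, "start"])
    })
    gstart <- vapply(g$isoforms, function(ch) g$exons[ch[1L], "start"],
                     numeric(1))
    gend <- vapply(g$isoforms, function(ch)
      g$exons[ch[length(ch)], "end"], numeric(1))
    ref[[g$id]] <- list(gene = g, tx = txs, iso = iso, juncs = juncs,
                        cums = cums, gstart = gstart, gend = gend)
  }
  ref
}

# transcript coordinate (0-based) -> genomic coordinate for isoform `iso`
tx_to_genomic <- function(refg, iso, pos) {
  ch <- refg$gene$isoforms[[iso]]
  cum <- c(0, refg$cums[[iso]])
  i <- findInterval(pos, cum, rightmost.closed = FALSE, left.open = FALSE)
  i <- pmin(pmax(i, 1L), length(ch))
  refg$gene$exons[ch[i], "start"] + (pos - cum[i])
}

# contiguous-subchain test for junction chains
is_subchain <- function(sub, full) {
  if (length(sub) == 0L) return(TRUE)
  if (length(sub) > length(full)) return(FALSE)
  for (s in seq_len(length(full) - length(sub) + 1L)) {
    if (all(full[s:(s + length(sub) - 1L)] == sub)) return(TRUE)
  }
  FALSE
}

#' Assign one contig to a reference isoform
#'
#' A lightweight stand-in for annotation-based isoform assignment: the
#' contig (either strand) is aligned to the reference transcripts with
#' free-end-gap alignment, its splice-junction chain is derived from the
#' best-matching transcript's gene model, and the chain plus endpoints decide
#' the category:
#'
#' * `unique` — junction chain and endpoints (within `endpoint_tol` bp)
#'   match exactly one isoform;
#' * `unique_minor` — exactly one isoform matches with endpoint slack up to
#'   `minor_slack` bp;
#' * `ambiguous` — the chain is a contiguous subchain of two or more
#'   isoforms;
#' * `inconsistent` — the contig overlaps a gene but cannot be certified as
#'   any single isoform;
#' * `non_informative` — aligned span below `min_span` bp, or junction-free
#'   within a multi-isoform gene;
#' * `intergenic` — no acceptable reference alignment.
#'
#' @param contig DNA string (non-empty).
#' @param barcode barcode associated with the contig.
#' @param reference output of `build_reference()` or a list of `gene_model`s.
#' @param max_edit_frac maximal edit distance as a fraction of contig length
#'   for an alignment to be accepted (default 0.02).
#' @param endpoint_tol endpoint tolerance in bp for `unique` (default 30).
#' @param minor_slack endpoint slack in bp for `unique_minor` (default 100).
#' @param min_span minimal informative aligned span in bp (default 300).
#' @return one-row data.frame: contig id fields are filled by the caller;
#'   columns `barcode`, `category`, `gene`, `isoform`.
#' @export
assign_contig <- function(contig, barcode, reference,
                          max_edit_frac = 0.02, endpoint_tol = 30L,
                          minor_slack = 100L, min_span = 300L) {
  if (!nzchar(contig)) stop("empty contig")
  if (inherits(reference, "gene_model")) {
    reference <- build_reference(reference)
  } else if (is.list(reference[[1L]]) && !is.null(reference[[1L]]$exons)) {
    reference <- build_reference(reference)
  }
  Lc <- nchar(contig)
  res <- function(category, gene = NA_character_, iso = NA_character_) {
    data.frame(barcode = barcode, category = category, gene = gene,
               isoform = iso, stringsAsFactors = FALSE)
  }
  strands <- c(contig, rc_dna(contig))
  best <- NULL
  # exact-containment fast path
  for (gid in names(reference)) {
    refg <- reference[[gid]]
    for (ti in seq_along(refg$tx)) {
      tx <- refg$tx[[ti]]
      for (s in 1:2) {
        p <- regexpr(strands[s], tx, fixed = TRUE)
        if (p > 0L) {
          cand <- list(gene = gid, iso = refg$iso[ti], edit = 0L,
                       s0 = p - 1L, e0 = p - 1L + Lc)
          if (is.null(best)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    # k-mer vote to rank candidate transcripts, then free-end-gap alignment
    # of the few best ones
    np <- min(15L, max(3L, Lc %/% 80L))
    pos <- unique(pmax(1L, round(seq(1L, Lc - 20L, length.out = np))))
    cands <- list()
    for (s in 1:2) {
      probes <- substring(strands[s], pos, pos + 20L)
      for (gid in names(reference)) {
        refg <- reference[[gid]]
        for (ti in seq_along(refg$tx)) {
          votes <- sum(vapply(probes, function(pp)
            grepl(pp, refg$tx[[ti]], fixed = TRUE), logical(1)))
          if (votes > 0L) {
            cands[[length(cands) + 1L]] <-
              list(gid = gid, ti = ti, s = s, votes = votes)
          }
        }
      }
    }
    if (length(cands)) {
      ord <- order(-vapply(cands, `[[`, numeric(1), "votes"))
      for (ci in ord[seq_len(min(6L, length(ord)))]) {
        cd <- cands[[ci]]
        refg <- reference[[cd$gid]]
        al <- Biostrings::pairwiseAlignment(
          pattern = strands[cd$s], subject = refg$tx[[cd$ti]],
          type = "global-local")
        ed <- Biostrings::nedit(al)
        if (ed <= max_edit_frac * Lc &&
            (is.null(best) || ed < best$edit)) {
          best <- list(gene = cd$gid, iso = refg$iso[cd$ti], edit = ed,
                       s0 = Biostrings::start(Biostrings::subject(al)) - 1L,
                       e0 = Biostrings::end(Biostrings::subject(al)))
        }
        if (!is.null(best) && best$edit == 0L) break
      }
    }
  }
  if (is.null(best)) return(res("intergenic"))
  refg <- reference[[best$gene]]
  span <- best$e0 - best$s0
  if (span < min_span) return(res("non_informative", best$gene))
  # junction chain of the contig: junctions of the matched isoform strictly
  # inside the aligned span
  cum <- refg$cums[[best$iso]]
  inner <- cum[-length(cum)]
  sel <- inner > best$s0 & inner < best$e0
  J <- refg$juncs[[best$iso]][sel]
  multi_junction_gene <- any(lengths(refg$juncs) > 0L)
  if (length(J) == 0L && multi_junction_gene) {
    return(res("non_informative", best$gene))
  }
  g0 <- tx_to_genomic(refg, best$iso, best$s0)
  g1 <- tx_to_genomic(refg, best$iso, best$e0 - 1L) + 1L
  full <- vapply(refg$iso, function(i)
    identical(refg$juncs[[i]], J), logical(1))
  end_d <- pmax(abs(g0 - refg$gstart), abs(g1 - refg$gend))
  f_tol <- refg$iso[full & end_d <= endpoint_tol]
  f_minor <- refg$iso[full & end_d <= minor_slack]
  subc <- refg$iso[vapply(refg$iso, function(i)
    is_subchain(J, refg$juncs[[i]]), logical(1))]
  if (length(f_tol) == 1L) return(res("unique", best$gene, f_tol))
  if (length(f_minor) == 1L) return(res("unique_minor", best$gene, f_minor))
  if (length(subc) >= 2L) return(res("ambiguous", best$gene))
  res("inconsistent", best$gene)
}

#' Assign a table of contigs
#'
#' @param contigs data.frame with columns `contig` (id), `barcode`, `seq`.
#' @inheritParams assign_contig
#' @return data.frame of assignments, one row per contig.
#' @export
assign_contigs <- function(contigs, reference, ...) {
  if (inherits(reference, "gene_model") ||
      (is.list(reference[[1L]]) && !is.null(reference[[1L]]$exons))) {
    reference <- build_reference(reference)
  }
  # identical sequences (one cluster representative, many barcodes) are
  # classified once
  useq <- unique(contigs$seq)
  cache <- lapply(useq, function(s) assign_contig(s, "", reference, ...))
  names(cache) <- useq
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    a <- cache[[contigs$seq[i]]]
    a$barcode <- contigs$barcode[i]
    cbind(data.frame(contig = contigs$contig[i], stringsAsFactors = FALSE), a)
  })
  do.call(rbind, rows)
}

#' Barcode-based "fixed" filter of contig assignments
#'
#' Removes assignments produced by split or mixed read clouds:
#'
#' * `mode = "gene"`: drops every assignment whose (barcode, gene) pair
#'   occurs on more than one contig — the same cloud yielded several contigs
#'   for one gene;
#' * `mode = "barcode"`: drops every assignment of any barcode that carries
#'   more than one gene-assigned contig in total.
#'
#' Only gene-assigned categories (unique, unique with minor difference,
#' ambiguous, inconsistent) count towards multiplicity.
#'
#' @param assignments data.frame from [assign_contigs()].
#' @param mode `"gene"` or `"barcode"`.
#' @return the filtered assignments data.frame.
#' @export
fixed_filter <- function(assignments, mode = c("gene", "barcode")) {
  mode <- match.arg(mode)
  counted <- assignments$category %in%
    c("unique", "unique_minor", "ambiguous", "inconsistent")
  if (mode == "gene") {
    key <- paste(assignments$barcode, assignments$gene, sep = "\r")
    bad_keys <- names(which(table(key[counted]) > 1L))
    drop <- counted & key %in% bad_keys
  } else {
    bad_bc <- names(which(table(assignments$barcode[counted]) > 1L))
    drop <- assignments$barcode %in% bad_bc
  }
  assignments[!drop, , drop = FALSE]
}

#' Score an assembly against simulation ground truth
#'
#' Precision is computed over unique / unique-with-minor-difference
#' assignments: the fraction whose isoform equals the truth isoform of that
#' barcode (and gene). Recall is the fraction of truth barcodes in the
#' denominator set whose isoform was correctly recovered by such an
#' assignment. Fixed recall applies [fixed_filter()] first and removes the
#' filtered-out barcodes from both numerator and denominator.
#'
#' @param assignments data.frame from [assign_contigs()].
#' @param truth truth data.frame from [simulate_clouds()].
#' @param denominator `"all"` truth barcodes, or `"min_reads"` for barcodes
#'   with at least `min_reads` read pairs.
#' @param min_reads threshold for `denominator = "min_reads"`.
#' @param fixed_mode filter mode passed to [fixed_filter()] for the fixed
#'   recall (default `"barcode"`).
#' @return list with `precision`, `recall`, `fixed_recall`, `counts`
#'   (per-category contig counts) and `n_denominator`.
#' @export
score_assembly <- function(assignments, truth,
                           denominator = c("all", "min_reads"),
                           min_reads = 5L, fixed_mode = "barcode") {
  denominator <- match.arg(denominator)
  bc_reads <- tapply(truth$n_pairs, truth$barcode, sum)
  denom <- if (denominator == "all") unique(truth$barcode) else
    names(bc_reads)[bc_reads >= min_reads]
  if (length(denom) == 0L) stop("empty recall denominator")
  truth_key <- paste(truth$barcode, truth$gene, sep = "\r")
  truth_iso <- stats::setNames(truth$isoform, truth_key)
  correct_rows <- function(a) {
    uu <- a$category %in% c("unique", "unique_minor")
    key <- paste(a$barcode, a$gene, sep = "\r")
    uu & !is.na(a$isoform) & a$isoform == truth_iso[key] &
      key %in% names(truth_iso)
  }
  uu <- assignments$category %in% c("unique", "unique_minor")
  corr <- correct_rows(assignments)
  precision <- if (sum(uu) == 0L) NA_real_ else sum(corr & uu) / sum(uu)
  recall <- length(intersect(denom, assignments$barcode[corr])) /
    length(denom)
  fixed <- fixed_filter(assignments, fixed_mode)
  removed_bc <- setdiff(assignments$barcode, fixed$barcode)
  denom_fixed <- setdiff(denom, removed_bc)
  fixed_recall <- if (length(denom_fixed) == 0L) NA_real_ else
    length(intersect(denom_fixed, fixed$barcode[correct_rows(fixed)])) /
      length(denom_fixed)
  counts <- table(factor(assignments$category, levels = ASSIGN_CATEGORIES))
  list(precision = precision, recall = recall, fixed_recall = fixed_recall,
       counts = as.list(counts), n_denominator = length(denom))
}

#' Write evaluation outputs
#'
#' `eval.tsv` holds one row per contig with its category and truth
#' comparison; `metrics.json` holds precision / recall / fixed recall and
#' category counts.
#'
#' @param assignments data.frame from [assign_contigs()].
#' @param metrics list from [score_assembly()].
#' @param truth truth data.frame.
#' @param dir output directory.
#' @return paths written, invisibly.
#' @export
write_evaluation <- function(assignments, metrics, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(assignments$barcode, assignments$gene, sep = "\r")
  tkey <- paste(truth$barcode, truth$gene, sep = "\r")
  truth_iso <- stats::setNames(truth$isoform, tkey)
  out <- assignments
  out$truth_isoform <- unname(truth_iso[key])
  out$correct <- !is.na(out$isoform) & !is.na(out$truth_isoform) &
    out$isoform == out$truth_isoform
  tp <- file.path(dir, "eval.tsv")
  utils::write.table(out, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- file.path(dir, "metrics.json")
  jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tp, mp))
}
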