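# ---------------------------------------------------------------------------
# Synthetic multi-isoform genes and barcoded read clouds. The generator
# emulates SPIso-seq-style data: many small read clouds, one (or a few)
# mRNA molecules per barcode usually from distinct genes, per-molecule
# coverage down to ~1x, substitution sequencing errors.
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a random multi-isoform gene model
#'
#' Exons are laid out left to right with random intron spacing; isoforms are
#' distinct exon chains that always contain the first and the last exon
#' (treated as constitutive), mirroring exon-skipping alternative splicing.
#'
#' @param gene_id gene identifier.
#' @param n_exons number of exons (>= 2).
#' @param n_isoforms number of distinct isoforms; at most
#'   `2^(n_exons - 2)`.
#' @param exon_len_range,intron_len_range integer ranges for exon and intron
#'   lengths in bp.
#' @param min_tx_len minimal transcript length in bp; isoform chains are
#'   redrawn until all transcripts reach it.
#' @param seed optional RNG seed for a reproducible gene.
#' @return a `gene_model`: list with `id`, `seq` (genomic), `exons`
#'   (0-based half-open start/end matrix), `isoforms` (named list of exon
#'   index chains).
#' @export
make_gene <- function(gene_id = "gene1", n_exons = 8L, n_isoforms = 4L,
                      exon_len_range = c(120L, 240L),
                      intron_len_range = c(200L, 600L),
                      min_tx_len = 350L, seed = NULL) {
  stopifnot(n_exons >= 2L)
  if (n_isoforms > 2^(n_exons - 2L)) {
    stop("infeasible isoform count: at most 2^(n_exons-2) distinct chains")
  }
  with_seed(seed, {
    exon_len <- sample(exon_len_range[1L]:exon_len_range[2L], n_exons,
                       replace = TRUE)
    intron_len <- if (n_exons > 1L) {
      sample(intron_len_range[1L]:intron_len_range[2L], n_exons - 1L,
             replace = TRUE)
    } else integer(0)
    starts <- cumsum(c(0L, exon_len[-n_exons] + intron_len))
    exons <- cbind(start = starts, end = starts + exon_len)
    gseq <- random_dna(1L, max(exons[, "end"]))
    mid <- if (n_exons > 2L) 2:(n_exons - 1L) else integer(0)
    chains <- list()
    seen <- character(0)
    guard <- 0L
    while (length(chains) < n_isoforms) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not draw distinct isoform chains")
      keep <- if (length(mid)) mid[stats::runif(length(mid)) < 0.5] else
        integer(0)
      ch <- c(1L, keep, n_exons)
      sig <- paste(ch, collapse = ",")
      if (sig %in% seen) next
      if (sum(exon_len[ch]) < min_tx_len) next
      seen <- c(seen, sig)
      chains[[length(chains) + 1L]] <- ch
    }
    names(chains) <- sprintf("%s.i%d", gene_id, seq_along(chains))
    structure(list(id = gene_id, seq = gseq, exons = exons,
                   isoforms = chains),
              class = "gene_model")
  })
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %d exons, %d isoforms, locus %d bp\n",
              x$id, nrow(x$exons), length(x$isoforms), nchar(x$seq)))
  invisible(x)
}

#' Transcript sequences of a gene model
#'
#' @param gene a `gene_model`.
#' @return named character vector, one transcript per isoform.
#' @export
transcript_seqs <- function(gene) {
  vapply(gene$isoforms, function(ch) {
    paste(substring(gene$seq, gene$exons[ch, "start"] + 1L,
                    gene$exons[ch, "end"]), collapse = "")
  }, character(1))
}

# fragment a molecule of length L into consecutive fragments (partition
# model): cut spacings ~ N(insert_mean, insert_sd), truncated
partition_fragments <- function(L, insert_mean, insert_sd, min_frag) {
  cuts <- integer(0)
  pos <- 0L
  while (pos < L) {
    f <- max(min_frag, round(stats::rnorm(1L, insert_mean, insert_sd)))
    pos <- min(L, pos + f)
    cuts <- c(cuts, pos)
  }
  starts <- c(0L, cuts[-length(cuts)])
  ends <- cuts
  # merge a trailing sliver into the previous fragment
  n <- length(starts)
  if (n > 1L && (ends[n] - starts[n]) < min_frag) {
    starts <- starts[-n]
    ends <- ends[-(n - 1L)]
  }
  cbind(start = starts, end = ends)
}

add_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- chars(s)
    hit <- which(stats::runif(length(b)) < error_rate)
    if (length(hit)) {
      b[hit] <- vapply(b[hit], function(x) {
        sample(setdiff(c("A", "C", "G", "T"), x), 1L)
      }, character(1))
      s <- paste(b, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

draw_cloud_size <- function(model) {
  n <- switch(model$model %||% "nb",
    nb = stats::rnbinom(1L, size = model$size %||% 2,
                        mu = model$mu %||% 8),
    lognormal = round(stats::rlnorm(1L, model$meanlog, model$sdlog)),
    fixed = model$n,
    passes = NA_integer_,  # resolved per molecule
    empirical = sample(model$sizes, 1L,
                       prob = model$prob %||% NULL, replace = TRUE),
    stop("unknown cloud size model")
  )
  if (!is.na(n)) max(1L, as.integer(n)) else n
}

#' Simulate barcoded read clouds with ground truth
#'
#' Every barcode captures one mRNA molecule (or several, from distinct
#' genes), fragments it and sequences paired-end reads with substitution
#' errors. Two fragmentation models are available:
#'
#' * `"partition"` (default): random cut points tile the whole molecule, as
#'   in linked-read library preparation; a cloud of n pairs samples n
#'   fragments from the tiling (cycling additional tiling passes when n
#'   exceeds one pass), so molecule ends are reachable and small clouds
#'   leave interior coverage gaps;
#' * `"uniform"`: n independent fragments with uniform start positions.
#'
#' Cloud sizes (read pairs per barcode) come from `cloud_size_model`:
#' `list(model = "nb", mu, size)` (negative binomial, default mean 8 with
#' many 1-3 pair clouds), `"lognormal"`, `"fixed"` (`n`), `"empirical"`
#' (`sizes`, optional `prob`), or `"passes"` (`passes` full tilings of each
#' molecule, guaranteeing end-to-end coverage about
#' `passes * 2 * read_len / insert_mean` deep).
#'
#' @param genes list of `gene_model` objects.
#' @param n_barcodes number of read clouds.
#' @param cloud_size_model cloud-size distribution spec (see details).
#' @param isoform_weights optional named weights over isoform ids.
#' @param balance_isoforms assign isoforms round-robin across barcodes
#'   instead of sampling, guaranteeing every isoform of a gene receives a
#'   near-equal number of clouds (single-molecule clouds only).
#' @param mols_per_cloud mean number of molecules per barcode; molecules of
#'   one barcode come from distinct genes (1 = exactly one molecule).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-length distribution in bp.
#' @param error_rate per-base substitution probability (<= 0.1).
#' @param fragment_model `"partition"` or `"uniform"`.
#' @param seed optional RNG seed; the simulation is fully deterministic
#'   under it.
#' @return list with `clouds` (named list of `read_cloud`) and `truth`
#'   (data.frame: barcode, gene, isoform, n_pairs, coverage).
#' @export
simulate_clouds <- function(genes, n_barcodes,
                            cloud_size_model = list(model = "nb", mu = 8,
                                                    size = 2),
                            isoform_weights = NULL,
                            balance_isoforms = FALSE,
                            mols_per_cloud = 1,
                            read_len = 100L,
                            insert_mean = 220, insert_sd = 25,
                            error_rate = 0.001,
                            fragment_model = c("partition", "uniform"),
                            seed = NULL) {
  fragment_model <- match.arg(fragment_model)
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  if (inherits(genes, "gene_model")) genes <- list(genes)
  txs <- lapply(genes, transcript_seqs)
  names(txs) <- vapply(genes, `[[`, character(1), "id")
  all_tx_len <- nchar(unlist(txs))
  if (read_len > min(all_tx_len)) {
    stop("read_len exceeds the shortest transcript (", min(all_tx_len), " bp)")
  }
  min_frag <- max(read_len, 2L * 25L)
  with_seed(seed, {
    barcodes <- character(0)
    while (length(unique(barcodes)) < n_barcodes) {
      barcodes <- unique(c(barcodes, random_dna(n_barcodes, 16L)))
    }
    barcodes <- barcodes[seq_len(n_barcodes)]
    clouds <- vector("list", n_barcodes)
    truth <- vector("list", n_barcodes)
    iso_cycle <- if (balance_isoforms) {
      all_iso <- unlist(lapply(seq_along(genes), function(gi)
        paste(gi, names(txs[[gi]]), sep = "\r")))
      rep_len(all_iso, n_barcodes)
    } else NULL
    for (bi in seq_len(n_barcodes)) {
      bc <- barcodes[bi]
      m <- if (mols_per_cloud <= 1) 1L else
        min(length(genes), max(1L, stats::rpois(1L, mols_per_cloud)))
      gsel <- if (is.null(iso_cycle)) sample(seq_along(genes), m) else
        as.integer(sub("\r.*$", "", iso_cycle[bi]))
      r1 <- character(0); r2 <- character(0)
      rows <- list()
      for (gi in gsel) {
        tx_ids <- names(txs[[gi]])
        w <- if (is.null(isoform_weights)) rep(1, length(tx_ids)) else {
          ww <- isoform_weights[tx_ids]
          ww[is.na(ww)] <- 1
          as.numeric(ww)
        }
        iso <- if (is.null(iso_cycle)) sample(tx_ids, 1L, prob = w) else
          sub("^.*\r", "", iso_cycle[bi])
        tx <- txs[[gi]][[iso]]
        L <- nchar(tx)
        size <- draw_cloud_size(cloud_size_model)
        frags <- NULL
        if (fragment_model == "partition") {
          pool <- partition_fragments(L, insert_mean, insert_sd, min_frag)
          if (is.na(size)) {  # "passes" model: full tilings
            for (p in seq_len(max(1L, cloud_size_model$passes) - 1L)) {
              pool <- rbind(pool,
                            partition_fragments(L, insert_mean, insert_sd,
                                                min_frag))
            }
            frags <- pool
          } else {
            take <- NULL
            while (size > nrow(pool)) {
              take <- rbind(take, pool)
              size <- size - nrow(pool)
              pool <- partition_fragments(L, insert_mean, insert_sd,
                                          min_frag)
            }
            sel <- sort(sample(nrow(pool), size))
            frags <- rbind(take, pool[sel, , drop = FALSE])
          }
        } else {
          if (is.na(size)) stop("'passes' model requires partition fragments")
          flen <- pmax(min_frag,
                       pmin(L, round(stats::rnorm(size, insert_mean,
                                                  insert_sd))))
          fst <- vapply(flen, function(f)
            sample.int(L - f + 1L, 1L) - 1L, integer(1))
          frags <- cbind(start = fst, end = fst + flen)
        }
        n_pairs <- nrow(frags)
        rl1 <- pmin(read_len, frags[, "end"] - frags[, "start"])
        p1 <- substring(tx, frags[, "start"] + 1L, frags[, "start"] + rl1)
        p2 <- rc_dna(substring(tx, frags[, "end"] - rl1 + 1L,
                               frags[, "end"]))
        p1 <- add_substitutions(p1, error_rate)
        p2 <- add_substitutions(p2, error_rate)
        r1 <- c(r1, p1); r2 <- c(r2, p2)
        rows[[length(rows) + 1L]] <- data.frame(
          barcode = bc, gene = names(txs)[gi], isoform = iso,
          n_pairs = n_pairs,
          coverage = sum(2L * rl1) / L,
          stringsAsFactors = FALSE)
      }
      clouds[[bi]] <- read_cloud(bc, r1, r2)
      truth[[bi]] <- do.call(rbind, rows)
    }
    names(clouds) <- barcodes
    list(clouds = clouds, truth = do.call(rbind, truth))
  })
}

#' Write a simulation as paired FASTQ plus truth tables
#'
#' Produces `<prefix>_R1.fastq` / `<prefix>_R2.fastq` with `BX:Z:` barcode
#' comments and constant quality, `<prefix>_truth.tsv`, a GTF-like
#' `<prefix>_genes.gtf` with exon and transcript records, and
#' `<prefix>_transcripts.fasta` with the reference transcripts.
#'
#' @param sim output of [simulate_clouds()].
#' @param genes the `gene_model` list used for the simulation.
#' @param prefix output path prefix.
#' @return character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, genes, prefix) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  r1p <- paste0(prefix, "_R1.fastq")
  r2p <- paste0(prefix, "_R2.fastq")
  ids <- character(0); s1 <- character(0); s2 <- character(0)
  n <- 0L
  for (cl in sim$clouds) {
    m <- length(cl$read1)
    ids <- c(ids, sprintf("read%d BX:Z:%s", n + seq_len(m), cl$barcode))
    s1 <- c(s1, cl$read1)
    s2 <- c(s2, cl$read2)
    n <- n + m
  }
  w <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
  }
  w(s1, r1p); w(s2, r2p)
  tp <- paste0(prefix, "_truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gp <- paste0(prefix, "_genes.gtf")
  lines <- character(0)
  for (g in genes) {
    for (iso in names(g$isoforms)) {
      ch <- g$isoforms[[iso]]
      lines <- c(lines, sprintf(
        "%s\tisocloud\ttranscript\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
        g$id, g$exons[ch[1L], "start"] + 1L,
        g$exons[ch[length(ch)], "end"], g$id, iso))
      for (e in ch) {
        lines <- c(lines, sprintf(
          "%s\tisocloud\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          g$id, g$exons[e, "start"] + 1L, g$exons[e, "end"], g$id, iso))
      }
    }
  }
  writeLines(lines, gp)
  fp <- paste0(prefix, "_transcripts.fasta")
  tx <- unlist(lapply(genes, transcript_seqs))
  txs <- Biostrings::DNAStringSet(tx)
  Biostrings::writeXStringSet(txs, fp)
  invisible(c(r1p, r2p, tp, gp, fp))
}
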