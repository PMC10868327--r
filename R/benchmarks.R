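# ---------------------------------------------------------------------------
# Self-contained benchmark experiments: simulate, assemble, evaluate.
# These power the package's reproducibility checks; problem sizes are chosen
# to run on a single CPU in minutes.
# ---------------------------------------------------------------------------

#' Perfect-data recovery experiment
#'
#' Simulates noiseless read clouds from a panel of random multi-isoform
#' genes, with every molecule tiled end to end (several independent
#' fragmentation passes, so per-molecule coverage is well above 2x), then
#' assembles each gene's clouds and scores the result. With clean data the
#' assembler is expected to return, per barcode, exactly one contig identical
#' to the truth transcript.
#'
#' @param n_genes number of genes in the panel.
#' @param isoform_range range of isoform counts sampled per gene.
#' @param barcodes_per_isoform read clouds per isoform (round-robin).
#' @param passes tiling passes per molecule (per-molecule coverage is about
#'   `passes * 2 * read_len / insert_mean`).
#' @param read_len,insert_mean,insert_sd read and fragment geometry in bp.
#' @param k k-mer size for assembly.
#' @param seed RNG seed.
#' @return list with `n_barcodes`, `n_perfect` (barcodes whose single contig
#'   equals the truth transcript), `perfect_rate`, `precision`, `recall`,
#'   `fixed_recall` (pooled over genes) and `n_genes`.
#' @export
perfect_recovery_experiment <- function(n_genes = 50L,
                                        isoform_range = c(4L, 16L),
                                        barcodes_per_isoform = 3L,
                                        passes = 3L,
                                        read_len = 100L,
                                        insert_mean = 150, insert_sd = 35,
                                        k = 21L, seed = 1L) {
  n_bc <- 0L
  n_perfect <- 0L
  asn_all <- list()
  truth_all <- list()
  set.seed(seed)
  gene_seeds <- sample.int(1e6, n_genes)
  for (gi in seq_len(n_genes)) {
    n_iso <- sample(isoform_range[1]:isoform_range[2], 1L)
    gene <- make_gene(sprintf("g%03d", gi),
                      n_exons = max(6L, min(12L, n_iso %/% 2L + 4L)),
                      n_isoforms = n_iso, seed = gene_seeds[gi])
    tx <- transcript_seqs(gene)
    sim <- simulate_clouds(
      gene, n_barcodes = barcodes_per_isoform * n_iso,
      cloud_size_model = list(model = "passes", passes = passes),
      balance_isoforms = TRUE,
      read_len = read_len, insert_mean = insert_mean,
      insert_sd = insert_sd, error_rate = 0,
      seed = gene_seeds[gi] + 1L)
    res <- assemble_clouds(sim$clouds, k = k)
    truth_iso <- stats::setNames(sim$truth$isoform, sim$truth$barcode)
    for (bc in names(res$paths)) {
      n_bc <- n_bc + 1L
      ps <- res$paths[[bc]]
      if (length(ps) == 1L) {
        s <- path_sequence(ps[[1]], res$graph)
        t <- unname(tx[truth_iso[[bc]]])
        if (s == t || s == rc_dna(t)) n_perfect <- n_perfect + 1L
      }
    }
    cls <- filter_clusters(res$store, min_length = 300, min_barcodes = 1)
    contigs <- clusters_to_contigs(cls)
    if (nrow(contigs)) {
      asn_all[[gi]] <- assign_contigs(contigs, list(gene))
    }
    truth_all[[gi]] <- sim$truth
  }
  asn <- do.call(rbind, asn_all)
  truth <- do.call(rbind, truth_all)
  m <- score_assembly(asn, truth)
  list(n_genes = n_genes, n_barcodes = n_bc, n_perfect = n_perfect,
       perfect_rate = n_perfect / n_bc,
       precision = m$precision, recall = m$recall,
       fixed_recall = m$fixed_recall)
}

#' Low-coverage robustness experiment
#'
#' Simulates barcoded read clouds from a single high-complexity gene with
#' negative-binomial cloud sizes (many clouds at about 1x coverage),
#' substitution sequencing errors, and partition fragmentation; assembles all
#' clouds against one global graph and scores precision, recall and fixed
#' recall against the simulation truth.
#'
#' @param n_clouds number of read clouds (barcodes).
#' @param n_isoforms isoform count of the synthetic gene.
#' @param error_rate per-base substitution rate.
#' @param cloud_mu,cloud_size negative-binomial mean and dispersion of cloud
#'   sizes (read pairs per cloud).
#' @param read_len,insert_mean,insert_sd read and fragment geometry in bp.
#' @param k k-mer size for assembly.
#' @param seed RNG seed.
#' @return list with `precision`, `recall`, `fixed_recall`, per-category
#'   contig counts, `n_clusters`, `isoforms_recovered` and `n_isoforms`.
#' @export
robustness_experiment <- function(n_clouds = 1000L, n_isoforms = 16L,
                                  error_rate = 0.005,
                                  cloud_mu = 8, cloud_size = 2,
                                  read_len = 100L,
                                  insert_mean = 220, insert_sd = 25,
                                  k = 21L, seed = 1L) {
  set.seed(seed)
  gene_seed <- sample.int(1e6, 2)
  gene <- make_gene("geneX", n_exons = 12L, n_isoforms = n_isoforms,
                    exon_len_range = c(100L, 250L), seed = gene_seed[1])
  sim <- simulate_clouds(
    gene, n_barcodes = n_clouds,
    cloud_size_model = list(model = "nb", mu = cloud_mu, size = cloud_size),
    read_len = read_len, insert_mean = insert_mean, insert_sd = insert_sd,
    error_rate = error_rate, seed = gene_seed[2])
  res <- assemble_clouds(sim$clouds, k = k)
  cls <- filter_clusters(res$store, min_length = 300, min_barcodes = 1)
  contigs <- clusters_to_contigs(cls)
  asn <- assign_contigs(contigs, list(gene))
  m <- score_assembly(asn, sim$truth)
  truth_iso <- stats::setNames(sim$truth$isoform, sim$truth$barcode)
  uu <- asn$category %in% c("unique", "unique_minor")
  correct <- uu & !is.na(asn$isoform) &
    asn$isoform == truth_iso[asn$barcode]
  list(precision = m$precision, recall = m$recall,
       fixed_recall = m$fixed_recall, counts = m$counts,
       n_clusters = nrow(cls),
       isoforms_recovered = length(unique(asn$isoform[correct])),
       n_isoforms = n_isoforms)
}
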