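eval_fixture <- function() {
  g <- make_gene("gE", n_exons = 7, n_isoforms = 4,
                 exon_len_range = c(140, 220), seed = 90)
  list(g = g, tx = transcript_seqs(g), ref = isocloud:::build_reference(list(g)))
}

test_that("a contig identical to a reference transcript is unique", {
  fx <- eval_fixture()
  for (iso in names(fx$tx)) {
    a <- assign_contig(fx$tx[[iso]], "B", fx$ref)
    expect_equal(a$category, "unique")
    expect_equal(a$isoform, iso)
    expect_equal(a$gene, "gE")
  }
  # the reverse complement is handled too
  a <- assign_contig(rc_dna(fx$tx[[1]]), "B", fx$ref)
  expect_equal(a$category, "unique")
})

test_that("random sequence is intergenic; empty contig errors", {
  fx <- eval_fixture()
  set.seed(91)
  a <- assign_contig(random_dna(1, 500), "B", fx$ref)
  expect_equal(a$category, "intergenic")
  expect_error(assign_contig("", "B", fx$ref), "empty")
})

test_that("short aligned spans are non-informative", {
  fx <- eval_fixture()
  a <- assign_contig(substr(fx$tx[[1]], 1, 250), "B", fx$ref)
  expect_equal(a$category, "non_informative")
})

test_that("a shared junction-free segment in a multi-isoform gene is non-informative", {
  fx <- eval_fixture()
  ex1 <- fx$g$exons[1, ]
  # wholly inside the (constitutive, >300 bp only if long enough) first exon
  seg <- substr(fx$g$seq, ex1["start"] + 1, ex1["end"])
  if (nchar(seg) >= 300) {
    a <- assign_contig(seg, "B", fx$ref)
    expect_equal(a$category, "non_informative")
  }
  # a long junction-containing fragment shared by >= 2 isoforms is ambiguous
  chains <- vapply(fx$g$isoforms, paste, character(1), collapse = ",")
  # fragment of isoform 1 missing both terminal exons
  ch <- fx$g$isoforms[[1]]
  inner <- ch[-c(1, length(ch))]
  frag <- paste(substring(fx$g$seq, fx$g$exons[inner, "start"] + 1,
                          fx$g$exons[inner, "end"]), collapse = "")
  shared <- sum(vapply(fx$g$isoforms, function(other) {
    isocloud:::is_subchain(
      paste(fx$g$exons[inner[-length(inner)], "end"],
            fx$g$exons[inner[-1], "start"], sep = "-"),
      paste(fx$g$exons[other[-length(other)], "end"],
            fx$g$exons[other[-1], "start"], sep = "-"))
  }, logical(1)))
  a2 <- assign_contig(frag, "B", fx$ref)
  if (shared >= 2) {
    expect_equal(a2$category, "ambiguous")
  } else {
    expect_true(a2$category %in% c("inconsistent", "unique_minor"))
  }
})

test_that("small endpoint truncation downgrades unique to unique_minor", {
  fx <- eval_fixture()
  t1 <- fx$tx[[1]]
  a <- assign_contig(substr(t1, 50, nchar(t1)), "B", fx$ref)
  expect_equal(a$category, "unique_minor")
  expect_equal(a$isoform, names(fx$tx)[1])
})

test_that("the gene-mode fixed filter removes duplicated (barcode, gene) contigs", {
  asn <- data.frame(
    contig = sprintf("c%d", 1:10),
    barcode = c("B1", "B1", "B2", "B3", "B4", "B5", "B6", "B6", "B6", "B7"),
    category = c(rep("unique", 9), "non_informative"),
    gene = c("G", "G", "G", "G", "G", "G", "H", "H", "H", NA),
    isoform = "i1",
    stringsAsFactors = FALSE
  )
  out <- fixed_filter(asn, mode = "gene")
  # B1 (2 contigs on G) removed entirely; B6 (3 contigs on H) removed
  expect_false(any(out$barcode == "B1"))
  expect_false(any(out$barcode == "B6" & out$gene == "H"))
  expect_equal(nrow(out), 5L)   # 10 - 2 - 3 = 5 survive
  # barcode mode also removes multi-assignment barcodes
  out2 <- fixed_filter(asn, mode = "barcode")
  expect_false(any(out2$barcode %in% c("B1", "B6")))
  # single-contig barcodes are kept in both modes
  expect_true("B2" %in% out$barcode && "B2" %in% out2$barcode)
})

test_that("precision and recall match hand-computed confusion counts", {
  # 10 truth barcodes: 8 correct unique, 1 wrong unique, 1 unassembled
  truth <- data.frame(
    barcode = sprintf("B%02d", 1:10), gene = "G",
    isoform = rep(c("i1", "i2"), 5), n_pairs = 6, coverage = 2,
    stringsAsFactors = FALSE
  )
  asn <- data.frame(
    contig = sprintf("c%d", 1:9),
    barcode = sprintf("B%02d", 1:9),
    category = "unique",
    gene = "G",
    isoform = c(rep(c("i1", "i2"), 4), "i1"),  # B09 truth is i1 -> correct
    stringsAsFactors = FALSE
  )
  asn$isoform[9] <- "i2"                       # make B09 wrong
  m <- score_assembly(asn, truth)
  expect_equal(m$precision, 8 / 9, tolerance = 1e-12)
  expect_equal(m$recall, 8 / 10, tolerance = 1e-12)
  expect_equal(m$n_denominator, 10L)
  expect_equal(Reduce(`+`, m$counts), 9L)
  # all correct: precision = recall = 1
  asn2 <- asn[1:8, ]
  truth2 <- truth[1:8, ]
  m2 <- score_assembly(asn2, truth2)
  expect_equal(m2$precision, 1)
  expect_equal(m2$recall, 1)
  # precision unchanged by non-informative padding
  asn3 <- rbind(asn, data.frame(contig = "c10", barcode = "B10",
                                category = "non_informative", gene = NA,
                                isoform = NA))
  expect_equal(score_assembly(asn3, truth)$precision, 8 / 9)
})

test_that("fixed recall removes filtered barcodes from both sides", {
  truth <- data.frame(
    barcode = c("B1", "B2", "B3", "B4"), gene = "G",
    isoform = "i1", n_pairs = c(6, 2, 6, 6), coverage = 2,
    stringsAsFactors = FALSE
  )
  # B2's cloud split into two contigs, one correct and one inconsistent
  asn <- data.frame(
    contig = c("c1", "c2a", "c2b", "c3"),
    barcode = c("B1", "B2", "B2", "B3"),
    category = c("unique", "unique", "inconsistent", "unique"),
    gene = "G", isoform = c("i1", "i1", NA, "i1"),
    stringsAsFactors = FALSE
  )
  m <- score_assembly(asn, truth)
  expect_equal(m$recall, 3 / 4)
  # after filtering, B2 leaves the denominator: 2 correct of {B1, B3, B4}
  expect_equal(m$fixed_recall, 2 / 3, tolerance = 1e-12)
  # min-reads denominator mode
  m5 <- score_assembly(asn, truth, denominator = "min_reads", min_reads = 5)
  expect_equal(m5$n_denominator, 3L)
  expect_equal(m5$recall, 2 / 3, tolerance = 1e-12)
  expect_error(score_assembly(asn, truth[0, ]), "denominator")
})

test_that("evaluation writers produce eval.tsv and metrics.json", {
  truth <- data.frame(barcode = "B1", gene = "G", isoform = "i1",
                      n_pairs = 6, coverage = 2, stringsAsFactors = FALSE)
  asn <- data.frame(contig = "c1", barcode = "B1", category = "unique",
                    gene = "G", isoform = "i1", stringsAsFactors = FALSE)
  m <- score_assembly(asn, truth)
  d <- withr::local_tempdir()
  write_evaluation(asn, m, truth, d)
  tab <- read.delim(file.path(d, "eval.tsv"))
  expect_true(tab$correct[1])
  js <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(js$precision, 1)
})
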