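# A small double-stranded graph with a few linear transcripts gives realistic
# paths to cluster.
cluster_fixture <- function() {
  set.seed(60)
  t1 <- random_dna(1, 600)
  g <- build_graph(t1, k = 21, double_stranded = TRUE)
  eid <- g$edges$id[g$edges$seq == t1]
  list(g = g, eid = eid, len = nchar(t1))
}

test_that("paths with small endpoint shifts merge; shift of 30 does not", {
  fx <- cluster_fixture()
  st <- path_cluster_store(fx$g, endpoint_tol = 30)
  p0 <- new_transcript_path("B1", fx$eid, 50, 550, fx$g)
  id0 <- insert_path(st, p0)
  # +10 / -10 endpoint wobble joins the founding cluster
  id1 <- insert_path(st, new_transcript_path("B2", fx$eid, 60, 540, fx$g))
  expect_equal(id1, id0)
  # a 30 bp disparity on one endpoint founds a new cluster (strict < 30)
  id2 <- insert_path(st, new_transcript_path("B3", fx$eid, 80, 550, fx$g))
  expect_false(id2 == id0)
  # 29 bp still merges
  id3 <- insert_path(st, new_transcript_path("B4", fx$eid, 79, 550, fx$g))
  expect_equal(id3, id0)
})

test_that("identical paths from two barcodes give one cluster of count 2", {
  fx <- cluster_fixture()
  st <- path_cluster_store(fx$g)
  insert_path(st, new_transcript_path("B1", fx$eid, 0, fx$len, fx$g))
  insert_path(st, new_transcript_path("B2", fx$eid, 0, fx$len, fx$g))
  cl <- filter_clusters(st, min_length = 0)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_barcodes, 2L)
})

test_that("a path and its reverse complement land in one cluster", {
  fx <- cluster_fixture()
  st <- path_cluster_store(fx$g)
  twin <- fx$g$twin[fx$eid]
  p <- new_transcript_path("B1", fx$eid, 40, 560, fx$g)
  prc <- new_transcript_path("B2", unname(twin), fx$len - 560, fx$len - 40,
                             fx$g)
  expect_equal(rc_dna(path_sequence(prc, fx$g)), path_sequence(p, fx$g))
  i1 <- insert_path(st, p)
  i2 <- insert_path(st, prc)
  expect_equal(i1, i2)
})

test_that("barcode-multiset conservation across many inserts", {
  fx <- cluster_fixture()
  st <- path_cluster_store(fx$g)
  set.seed(61)
  n <- 60
  for (i in 1:n) {
    insert_path(st, new_transcript_path(
      sprintf("B%03d", i), fx$eid,
      sample(0:120, 1), fx$len - sample(0:120, 1), fx$g))
  }
  cl <- filter_clusters(st, min_length = 0)
  expect_equal(sum(vapply(st$clusters, function(x) length(x$barcodes),
                          integer(1))), n)
  # deterministic under a fixed insertion order
  st2 <- path_cluster_store(fx$g)
  set.seed(61)
  for (i in 1:n) {
    insert_path(st2, new_transcript_path(
      sprintf("B%03d", i), fx$eid,
      sample(0:120, 1), fx$len - sample(0:120, 1), fx$g))
  }
  expect_identical(lapply(st$clusters, `[[`, "barcodes"),
                   lapply(st2$clusters, `[[`, "barcodes"))
})

test_that("filtering is strict in length and monotone in barcode count", {
  fx <- cluster_fixture()
  # representative of exactly 300 bp: excluded by the strict > 300 rule
  st300 <- path_cluster_store(fx$g)
  insert_path(st300, new_transcript_path("B1", fx$eid, 0, 300, fx$g))
  expect_equal(nrow(filter_clusters(st300, min_length = 300)), 0L)
  # 301 bp: included
  st301 <- path_cluster_store(fx$g)
  insert_path(st301, new_transcript_path("B1", fx$eid, 0, 301, fx$g))
  insert_path(st301, new_transcript_path("B2", fx$eid, 0, 301, fx$g))
  out <- filter_clusters(st301, min_length = 300)
  expect_equal(nrow(out), 1L)
  expect_equal(out$length, 301L)
  expect_equal(out$n_barcodes, 2L)
  # two clusters with >= 30 bp endpoint disparity; min_barcodes filtering
  st <- path_cluster_store(fx$g)
  insert_path(st, new_transcript_path("B1", fx$eid, 0, 600, fx$g))
  insert_path(st, new_transcript_path("B2", fx$eid, 0, 600, fx$g))
  insert_path(st, new_transcript_path("B3", fx$eid, 100, 500, fx$g))
  all_cl <- filter_clusters(st, min_length = 0, min_barcodes = 1)
  expect_equal(nrow(all_cl), 2L)
  expect_equal(nrow(filter_clusters(st, 0, 2)), 1L)
})

test_that("cluster FASTA and TSV outputs round-trip the key fields", {
  fx <- cluster_fixture()
  st <- path_cluster_store(fx$g)
  insert_path(st, new_transcript_path("B1", fx$eid, 0, 400, fx$g))
  insert_path(st, new_transcript_path("B2", fx$eid, 5, 398, fx$g))
  cl <- filter_clusters(st, min_length = 0)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_clusters_fasta(cl, fa)
  write_clusters_tsv(cl, tsv)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), 1L)
  expect_match(names(seqs), "barcodes=2")
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$barcode), c("B1", "B2"))
})
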