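test_that("grouping by barcode forms one cloud per distinct barcode", {
  ids <- c("r1", "r2", "r3", "r4")
  cm <- paste0("BX:Z:", c("B1", "B1", "B2", "B3"))
  r1 <- rep("ACGTACGTACGT", 4)
  r2 <- rep("TTTTACGTACGT", 4)
  res <- group_by_barcode(ids, r1, r2, cm, mode = "bx")
  expect_equal(length(res$clouds), 3L)
  expect_equal(unname(sort(vapply(res$clouds, cloud_size, integer(1)))),
               c(1L, 1L, 2L))
  expect_equal(res$rejected, character(0))
})

test_that("records without a barcode go to the reject bin", {
  ids <- c("a", "b")
  cm <- c("BX:Z:B1", "no_tag_here")
  res <- group_by_barcode(ids, rep("ACGT", 2), comments = cm, mode = "bx")
  expect_equal(length(res$clouds), 1L)
  expect_equal(res$rejected, "b")
})

test_that("barcode modes: name suffix and inline bases", {
  res <- group_by_barcode(c("x#AAA", "y#AAA", "z#CCC"),
                          rep("ACGTACGT", 3), mode = "suffix")
  expect_equal(sort(names(res$clouds)), c("AAA", "CCC"))
  res2 <- group_by_barcode(c("x", "y"),
                           c("AAACCCGGGTTTAAACCCGT", "AAACCCGGGTTTAAACTGCA"),
                           mode = "inline", inline_len = 16L)
  # inline barcodes are trimmed off the read
  expect_equal(res2$clouds[[1]]$read1[1], "CCGT")
})

test_that("grouping conserves the number of barcoded pairs", {
  set.seed(20)
  n <- 500
  bcs <- sample(sprintf("B%02d", 1:40), n, replace = TRUE)
  res <- group_by_barcode(sprintf("r%d", 1:n), random_dna(n, 30),
                          comments = paste0("BX:Z:", bcs), mode = "bx")
  expect_equal(sum(vapply(res$clouds, cloud_size, integer(1))), n)
  expect_equal(sort(names(res$clouds)), sort(unique(bcs)))
})

test_that("a read inside one edge aligns with exact offsets", {
  set.seed(21)
  t1 <- random_dna(1, 400)
  g <- toy_graph(t1)
  idx <- graph_kmer_index(g)
  r <- substr(t1, 51, 150)
  a <- align_read(r, g, idx)
  expect_equal(length(a), 1L)
  expect_equal(length(a[[1]]$edges), 1L)
  expect_equal(a[[1]]$start, 50L)
  expect_equal(a[[1]]$end, 150L)
  expect_equal(a[[1]]$mm, 0L)
})

test_that("a junction-spanning read aligns across edges and spells itself", {
  set.seed(22)
  a_ <- random_dna(1, 120); s <- random_dna(1, 80)
  b <- random_dna(1, 120); c_ <- random_dna(1, 120)
  t1 <- paste0(a_, s, b); t2 <- paste0(c_, s, b)
  g <- toy_graph(t1, t2)
  idx <- graph_kmer_index(g)
  r <- substr(t1, 100, 199)  # spans the branch into the shared segment
  alns <- align_read(r, g, idx)
  expect_equal(length(alns), 1L)
  aln <- alns[[1]]
  expect_gt(length(aln$edges), 1L)
  p <- new_transcript_path("x", aln$edges, aln$start, aln$end, g)
  expect_equal(path_sequence(p, g), r)
  # one substitution is tolerated and counted
  r2 <- r; substr(r2, 40, 40) <- setdiff(c("A","C","G","T"),
                                         substr(r2, 40, 40))[1]
  a2 <- align_read(r2, g, idx)
  expect_equal(a2[[1]]$mm, 1L)
  expect_equal(a2[[1]]$edges, aln$edges)
})

test_that("a read sharing no k-mer with the graph is unaligned", {
  set.seed(23)
  g <- toy_graph(random_dna(1, 300))
  idx <- graph_kmer_index(g)
  expect_null(align_read(random_dna(1, 100), g, idx))
  # reads shorter than k are unalignable
  expect_null(align_read("ACGT", g, idx))
})

test_that("subgraph derivation records extremes and depth-oracle coverage", {
  set.seed(24)
  t1 <- random_dna(1, 500)
  g <- toy_graph(t1)
  cl <- read_cloud("BC1", c(substr(t1, 11, 60), substr(t1, 61, 110)))
  al <- align_cloud(cl, g)
  sub <- derive_subgraph(al, g, "BC1")
  expect_equal(sub$edges, g$edges$id)
  expect_equal(unname(sub$left), 10L)
  expect_equal(unname(sub$right), 110L)
  expect_equal(unname(sub$bc_cov), 100 / 500, tolerance = 1e-9)
})

test_that("barcode coverage equals the per-base depth oracle", {
  set.seed(25)
  for (rep_i in 1:5) {
    t1 <- random_dna(1, 400)
    g <- toy_graph(t1)
    n <- sample(3:10, 1)
    starts <- sample(1:(400 - 80), n, replace = TRUE)
    cl <- read_cloud("B", substring(t1, starts, starts + 79))
    al <- align_cloud(cl, g)
    sub <- derive_subgraph(al, g, "B")
    fps <- lapply(starts, function(s) c(s - 1L, s + 79L))
    expect_equal(unname(sub$bc_cov), oracle_edge_cov(fps, 400),
                 tolerance = 1e-9)
  }
})

test_that("an empty cloud yields an empty subgraph, graph untouched", {
  set.seed(26)
  g <- toy_graph(random_dna(1, 300))
  g0 <- g
  cl <- read_cloud("B", random_dna(2, 60))
  al <- align_cloud(cl, g)
  sub <- derive_subgraph(al, g, "B")
  expect_equal(length(sub$edges), 0L)
  expect_identical(g, g0)
})

test_that("an error-free single-transcript cloud induces one simple path", {
  set.seed(27)
  a_ <- random_dna(1, 150); s <- random_dna(1, 90); b <- random_dna(1, 150)
  t1 <- paste0(a_, s, b); t2 <- paste0(random_dna(1, 150), s, random_dna(1, 150))
  g <- toy_graph(t1, t2)
  starts <- seq(1, nchar(t1) - 80, by = 40)
  cl <- read_cloud("B", substring(t1, starts, starts + 79))
  sub <- derive_subgraph(align_cloud(cl, g), g, "B")
  chains <- isocloud:::sub_chains(sub, g)
  expect_equal(length(chains), 1L)
  comp <- isocloud:::sub_components(sub, g)
  expect_equal(length(comp), 1L)
})
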