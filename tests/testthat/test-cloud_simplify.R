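# Toy topologies are built from designed transcripts so that the global
# graph contains exactly the branches each pass must handle.

test_that("tip clipping leaves a simple path untouched", {
  set.seed(30)
  g <- toy_graph(random_dna(1, 300))
  sub <- toy_subgraph(g, g$edges$id, cov = 2)
  out <- clip_tips(sub, g, max_tip_len = 100, rel_cov = 0.5)
  expect_equal(out$edges, sub$edges)
})

test_that("a short spur at a branching vertex is clipped", {
  set.seed(31)
  x <- random_dna(1, 150); y <- random_dna(1, 150)
  w <- random_dna(1, 30)                      # short spur
  t1 <- paste0(x, y); t2 <- paste0(x, w)
  g <- toy_graph(t1, t2)
  expect_equal(nrow(g$edges), 3L)
  sub <- toy_subgraph(g, g$edges$id, cov = 2)
  out <- clip_tips(sub, g, max_tip_len = 100, rel_cov = 0.5)
  spur <- g$edges$id[g$edges$length == min(g$edges$length)]
  expect_false(spur %in% out$edges)
  expect_equal(length(isocloud:::sub_chains(out, g)), 1L)
  # oracle: the clipped chain is exactly the one matching the tip predicate
  # (dead far end, branching anchor, spelled length <= limit)
  expect_equal(setdiff(sub$edges, out$edges), spur)
})

test_that("a long spur with matching coverage is kept", {
  set.seed(32)
  x <- random_dna(1, 150); y <- random_dna(1, 150)
  w <- random_dna(1, 2000)
  g <- toy_graph(paste0(x, y), paste0(x, w))
  spur_id <- g$edges$id[which.max(g$edges$length)]
  sub <- toy_subgraph(g, g$edges$id, cov = 2)  # equal coverage everywhere
  out <- clip_tips(sub, g, max_tip_len = 100, rel_cov = 0.5)
  expect_true(spur_id %in% out$edges)
})

test_that("bulge removal drops the lower-coverage parallel chain", {
  set.seed(33)
  x <- random_dna(1, 120); y <- random_dna(1, 120)
  p <- random_dna(1, 60); q <- random_dna(1, 60)
  g <- toy_graph(paste0(x, p, y), paste0(x, q, y))
  expect_equal(nrow(g$edges), 4L)
  ids <- g$edges$id
  mids <- ids[g$edges$length == min(g$edges$length)]  # the parallel branches
  pid <- mids[grepl(substr(p, 10, 30), g$edges[mids, "seq"], fixed = TRUE)]
  qid <- setdiff(mids, pid)
  covs <- stats::setNames(rep(5, 4), ids)
  covs[qid] <- 0.5
  sub <- toy_subgraph(g, ids, cov = covs)
  out <- remove_bulges(sub, g)
  expect_false(qid %in% out$edges)
  expect_true(pid %in% out$edges)
})

test_that("bulge ties resolve deterministically, keeping one branch", {
  set.seed(34)
  x <- random_dna(1, 120); y <- random_dna(1, 120)
  p <- random_dna(1, 60); q <- random_dna(1, 60)
  g <- toy_graph(paste0(x, p, y), paste0(x, q, y))
  sub <- toy_subgraph(g, g$edges$id, cov = 2)   # exact coverage tie
  out1 <- remove_bulges(sub, g)
  out2 <- remove_bulges(sub, g)
  mids <- g$edges$id[g$edges$length == min(g$edges$length)]
  expect_equal(sum(mids %in% out1$edges), 1L)
  expect_identical(out1$edges, out2$edges)
  # the lexicographically smaller edge-id chain survives
  expect_true(sort(mids)[1] %in% out1$edges)
})

test_that("a subgraph without parallel chains is unchanged by bulge removal", {
  set.seed(35)
  g <- toy_graph(random_dna(1, 400))
  sub <- toy_subgraph(g, g$edges$id)
  expect_equal(remove_bulges(sub, g)$edges, sub$edges)
})

test_that("gap closing inserts a short global edge between two paths", {
  set.seed(36)
  x <- random_dna(1, 200); y <- random_dna(1, 200)
  gapseq <- random_dna(1, 40)
  u <- random_dna(1, 200); v <- random_dna(1, 200)
  g <- toy_graph(paste0(x, gapseq, y), paste0(u, gapseq, v))
  gap_id <- g$edges$id[g$edges$length == min(g$edges$length)]
  xid <- g$edges$id[startsWith(g$edges$seq, substr(x, 1, 30))]
  yid <- g$edges$id[endsWith(g$edges$seq, substr(y, 171, 200))]
  sub <- toy_subgraph(g, c(xid, yid), cov = 2)
  out <- close_gaps(sub, g, max_gap_edge_len = 100)
  expect_true(gap_id %in% out$edges)
  expect_equal(length(isocloud:::sub_chains(out, g)), 1L)
  # imputed coverage is the mean of the flanks
  expect_equal(unname(out$bc_cov[gap_id]), 2)
})

test_that("a long connecting edge is not used for gap closing", {
  set.seed(37)
  x <- random_dna(1, 200); y <- random_dna(1, 200)
  gapseq <- random_dna(1, 5000)
  u <- random_dna(1, 200); v <- random_dna(1, 200)
  g <- toy_graph(paste0(x, gapseq, y), paste0(u, gapseq, v))
  xid <- g$edges$id[startsWith(g$edges$seq, substr(x, 1, 30))]
  yid <- g$edges$id[endsWith(g$edges$seq, substr(y, 171, 200))]
  sub <- toy_subgraph(g, c(xid, yid), cov = 2)
  out <- close_gaps(sub, g, max_gap_edge_len = 100)
  expect_equal(out$edges, sub$edges)
})

test_that("passes only shrink or grow the edge set as specified", {
  set.seed(38)
  x <- random_dna(1, 150); y <- random_dna(1, 150); w <- random_dna(1, 30)
  g <- toy_graph(paste0(x, y), paste0(x, w))
  sub <- toy_subgraph(g, g$edges$id, cov = 2)
  clipped <- clip_tips(sub, g)
  expect_true(all(clipped$edges %in% sub$edges))
  bulged <- remove_bulges(clipped, g)
  expect_true(all(bulged$edges %in% clipped$edges))
  gapped <- close_gaps(bulged, g)
  expect_true(all(bulged$edges %in% gapped$edges))
})

test_that("composition is the identity on a clean single-isoform cloud", {
  set.seed(39)
  s <- random_dna(1, 90)
  t1 <- paste0(random_dna(1, 150), s, random_dna(1, 150))
  t2 <- paste0(random_dna(1, 150), s, random_dna(1, 150))
  g <- toy_graph(t1, t2)
  g0 <- g
  starts <- seq(1, nchar(t1) - 80, by = 30)
  cl <- read_cloud("B", substring(t1, starts, starts + 79))
  sub <- derive_subgraph(align_cloud(cl, g), g, "B")
  out <- simplify_subgraph(sub, g)
  expect_equal(out$edges, sub$edges)
  expect_identical(g, g0)  # the global graph is never mutated
})

test_that("a cloud with one short coverage gap is healed to the transcript", {
  set.seed(40)
  sshared <- random_dna(1, 40)
  t1 <- paste0(random_dna(1, 250), sshared, random_dna(1, 250))
  t2 <- paste0(random_dna(1, 250), sshared, random_dna(1, 250))
  g <- toy_graph(t1, t2)
  # cloud covers t1 except the shared 40 bp middle: reads on both flanks
  cl <- read_cloud("B", c(substring(t1, seq(1, 171, 30), seq(80, 250, 30)),
                          substring(t1, seq(291, 461, 30), seq(370, 540, 30))))
  sub <- derive_subgraph(align_cloud(cl, g), g, "B")
  expect_gt(length(isocloud:::sub_chains(sub, g)), 1L)
  out <- simplify_subgraph(sub, g)
  chains <- isocloud:::sub_chains(out, g)
  expect_equal(length(chains), 1L)
  p <- new_transcript_path("B", chains[[1]], 0,
                           g$elen[[chains[[1]][length(chains[[1]])]]], g)
  expect_equal(path_sequence(p, g), t1)
})
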