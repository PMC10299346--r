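test_that("pairwise alignment reports identity and coverage as defined", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  h <- pairwise_align(s, s, mode = "local", id_a = "a", id_b = "b")
  expect_equal(h$identity, 100)
  expect_equal(h$query_coverage, 100)
  expect_equal(h$subject_coverage, 100)

  half <- substr(s, 1, 50)
  h2 <- pairwise_align(s, half, mode = "local")
  expect_equal(h2$subject_coverage, 100)
  expect_equal(h2$query_coverage, 50)

  expect_error(pairwise_align("", s), "empty")
})

test_that("local alignment scores match the full Gotoh dynamic-programming oracle", {
  set.seed(77)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    got <- pairwise_align(a, b, mode = "local")$bitscore
    expect_equal(got, gotoh_local_score(a, b), info = paste("case", i))
  }
})

test_that("hit filtering enforces thresholds and keeps the best hit per pair", {
  mk <- function(q, s, id, ev, score) {
    data.frame(query_id = q, subject_id = s, identity = id,
               alignment_length = 100L, mismatches = 0L, gap_opens = 0L,
               qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
               evalue = ev, bitscore = score, self_hit = q == s,
               query_coverage = NA_real_, subject_coverage = NA_real_,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    mk("a", "b", 69.9, 1e-30, 100),   # below identity threshold
    mk("a", "c", 85, 1e-3, 100),      # e-value too large
    mk("a", "d", 70, 1e-30, 100),     # boundary identity: kept
    mk("a", "e", 90, NA, 100),        # no e-value: criterion not applied
    mk("b", "c", 95, 1e-30, 50),      # duplicate pair, lower score
    mk("b", "c", 96, 1e-30, 80),
    mk("d", "d", 100, 0, 200)         # self-hit
  )
  f <- filter_hits(hits)
  expect_equal(nrow(f), 3L)  # a-d (boundary), a-e (no e-value), best b-c
  expect_false(any(f$self_hit))
  expect_true(all(f$identity >= 70))
  bc <- f[f$query_id == "b" & f$subject_id == "c", ]
  expect_equal(bc$bitscore, 80)
})

test_that("component clustering equals brute-force transitive closure on random graphs", {
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(5:15, 1)
    nodes <- paste0("g", seq_len(n))
    n_edges <- sample(0:12, 1)
    ea <- sample(nodes, n_edges, replace = TRUE)
    eb <- sample(nodes, n_edges, replace = TRUE)
    keep <- ea != eb
    ea <- ea[keep]; eb <- eb[keep]
    hits <- if (length(ea)) data.frame(
      query_id = ea, subject_id = eb, identity = 90, alignment_length = 10L,
      mismatches = 0L, gap_opens = 0L, qstart = 1L, qend = 10L, sstart = 1L,
      send = 10L, evalue = NA_real_, bitscore = 20,
      stringsAsFactors = FALSE) else polyivd:::empty_hits()
    fams <- cluster_families(hits, nodes)
    oracle <- transitive_closure_oracle(nodes, ea, eb)
    # same partition: two genes share a family iff the oracle agrees
    pred <- stats::setNames(fams$family_id, fams$gene_id)[nodes]
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_equal(unname(pred[i] == pred[j]),
                   unname(oracle[i] == oracle[j]))
    }
  }
})

test_that("family partition conserves genes and ignores input order", {
  an <- test_analysis()
  sim <- test_sim()
  expect_equal(sort(an$families$gene_id), sort(sim$genes$gene_id))
  expect_equal(anyDuplicated(an$families$gene_id), 0L)

  shuffled <- an$filtered_hits[sample.int(nrow(an$filtered_hits)), ]
  fams2 <- cluster_families(shuffled, sim$genes$gene_id)
  expect_equal(fams2[order(fams2$gene_id), ],
               an$families[order(an$families$gene_id), ],
               ignore_attr = TRUE)
})

test_that("mcl-like clustering is a partition that refines the components", {
  an <- test_analysis()
  sim <- test_sim()
  fams_mcl <- cluster_families(an$filtered_hits, sim$genes$gene_id,
                               method = "mcl")
  # every gene appears exactly once
  expect_equal(sort(fams_mcl$gene_id), sort(sim$genes$gene_id))
  expect_equal(anyDuplicated(fams_mcl$gene_id), 0L)
  # no mcl cluster joins genes from different connected components
  pred_c <- stats::setNames(an$families$family_id, an$families$gene_id)
  per_cluster <- split(fams_mcl$gene_id, fams_mcl$family_id)
  expect_true(all(vapply(per_cluster, function(g)
    length(unique(pred_c[g])) == 1L, logical(1))))
})

test_that("isolated genes become singleton families", {
  fams <- cluster_families(polyivd:::empty_hits(), c("x", "y", "z"))
  expect_equal(nrow(fams), 3L)
  expect_equal(length(unique(fams$family_id)), 3L)
})
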