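test_that("the expansion flag uses the five-copy threshold inclusively and monotonically", {
  ct <- data.frame(family_id = c("F1", "F2", "F3"), genome = "g",
                   n_copies = c(5L, 4L, 9L))
  out <- detect_expansion(ct)
  expect_equal(out$expansion, c(TRUE, FALSE, TRUE))
  # raising the threshold never adds families
  flagged <- function(th) sum(detect_expansion(ct, th)$expansion)
  counts <- vapply(1:10, flagged, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("published expansion-family counts give the published excess percentages", {
  ref <- wheat_reference_tables()
  n <- ref$expansion_counts
  expect_equal(round(excess_percentage(n[["wheat"]], n[["rice"]]), 1), 31.6)
  expect_equal(round(excess_percentage(n[["wheat"]], n[["maize"]]), 1), 6.4)
  expect_equal(round(excess_percentage(n[["wheat"]], n[["millet"]]), 1), 8.3)
  expect_equal(excess_percentage(10, 10), 0)
  expect_true(is.na(excess_percentage(10, 0)))
  # antisymmetry identity: e(a,b) = -e(b,a) * a / b
  a <- 650; b <- 494
  expect_equal(excess_percentage(a, b),
               -excess_percentage(b, a) * a / b, tolerance = 1e-12)
})

test_that("expansion comparison finds dominant families by fold over the others' mean", {
  ct <- expand.grid(family_id = c("F1", "F2"),
                    genome = c("wheat", "rice", "maize"),
                    stringsAsFactors = FALSE)
  ct$n_copies <- c(36L, 6L, 10L, 6L, 10L, 6L)  # F1: 36 vs mean 10 -> fold 3.6
  cmp <- expansion_comparison(ct, focal = "wheat", dominant_fold = 3)
  expect_equal(cmp$dominant$family_id, "F1")
  expect_equal(cmp$dominant$fold, 3.6)
  cmp2 <- expansion_comparison(ct, focal = "wheat", dominant_fold = 4)
  expect_equal(nrow(cmp2$dominant), 0L)
})

test_that("cross-genome clustering recovers planted sharing and expansion patterns", {
  set.seed(88)
  mk_fam <- function(n, base) {
    vapply(seq_len(n), function(i) mutate_copy(base, 0.03), character(1))
  }
  base1 <- polyivd:::random_cds(300)   # shared by both genomes
  base2 <- polyivd:::random_cds(300)   # genome 1 only, expanded (6 copies)
  base3 <- polyivd:::random_cds(300)   # genome 2 only
  g1 <- c(stats::setNames(mk_fam(2, base1), paste0("a_sh", 1:2)),
          stats::setNames(mk_fam(6, base2), paste0("a_ex", 1:6)))
  g2 <- c(stats::setNames(mk_fam(3, base1), paste0("b_sh", 1:3)),
          stats::setNames(mk_fam(2, base3), paste0("b_sp", 1:2)))
  res <- cross_genome_families(list(G1 = g1, G2 = g2))

  # shared family present in both genomes with planted copy numbers
  shared_fam <- res$families$family_id[res$families$gene_id == "a_sh1"]
  sh <- res$copy_table[res$copy_table$family_id == shared_fam, ]
  expect_equal(sh$n_copies[sh$genome == "G1"], 2L)
  expect_equal(sh$n_copies[sh$genome == "G2"], 3L)
  expect_true(shared_fam %in% res$common)

  # planted specific families are specific; expansion flag fires in G1 only
  ex_fam <- res$families$family_id[res$families$gene_id == "a_ex1"]
  sp_fam <- res$families$family_id[res$families$gene_id == "b_sp1"]
  expect_true(ex_fam %in% res$specific$G1)
  expect_true(sp_fam %in% res$specific$G2)
  flags <- detect_expansion(res$copy_table)
  expect_true(flags$expansion[flags$family_id == ex_fam &
                                flags$genome == "G1"])
  expect_false(any(flags$expansion[flags$genome == "G2"]))

  # common/specific partition equals a brute-force membership check
  present <- res$copy_table[res$copy_table$n_copies > 0, ]
  for (f in unique(res$copy_table$family_id)) {
    gs <- present$genome[present$family_id == f]
    expect_equal(f %in% res$common, setequal(gs, c("G1", "G2")))
    expect_equal(f %in% res$specific$G1, identical(gs, "G1"))
    expect_equal(f %in% res$specific$G2, identical(gs, "G2"))
  }
})

test_that("WGD paralog pairs are restricted to synteny-block membership", {
  blocks <- structure(list(list(
    chrom_a = "c1", chrom_b = "c2", orientation = "parallel", score = 3,
    pairs = data.frame(gene_a = c("a1", "a2", "a3"),
                       gene_b = c("b1", "b2", "b3"),
                       rank_a = 1:3, rank_b = 1:3))),
    class = "synteny_blocks")
  pairs <- data.frame(gene_a = c("a1", "a2", "x9"),
                      gene_b = c("b1", "b2", "y9"))
  out <- wgd_paralog_pairs(pairs, blocks)
  expect_equal(out$gene_a, c("a1", "a2"))
  # a pair outside any block is excluded
  expect_false(any(out$gene_a == "x9"))
})
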