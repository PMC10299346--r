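# Hand-enumerated NG86 oracles. For each toy pair, synonymous site fractions
# and pathway-averaged difference counts were worked out by hand from the
# universal code (changes to stop codons excluded from site fractions;
# pathways through stop codons excluded when avoidable):
#
# codon sites used below:
#   TTT (Phe): pos3 {TTC syn, TTA, TTG} -> 1/3; pos1, pos2 -> 0.  s = 1/3
#   TTC (Phe): symmetric to TTT.                                  s = 1/3
#   TCA (Ser): pos1 0; pos2 valid {TTA} 0 (TAA, TGA are stops);
#              pos3 {TCT,TCC,TCG all Ser} -> 1.                   s = 1
#   GGG (Gly): pos3 all Gly -> 1; pos1, pos2 -> 0.                s = 1
#   AAA (Lys): pos3 {AAG syn, AAT, AAC} -> 1/3; pos1 valid {CAA,GAA} 0
#              (TAA stop); pos2 0.                                s = 1/3
#   AGA (Arg): pos1 valid {CGA syn, GGA} -> 1/2 (TGA stop);
#              pos3 {AGG syn, AGT, AGC} -> 1/3; pos2 0.           s = 5/6
#   GTA (Val): pos3 all Val -> 1; pos1, pos2 -> 0.                s = 1
#   TGG (Trp): all positions 0 (TAG/TGA excluded as stops).       s = 0
#   ATG (Met): all positions 0.                                   s = 0
#   CCC (Pro): pos3 all Pro -> 1; pos1, pos2 -> 0.                s = 1

jc <- function(p) -0.75 * log(1 - 4 * p / 3)

ng86_oracles <- list(
  # one synonymous difference (TTT->TTC), S = mean(4/3+1, 4/3+1) = 7/3
  list(a = "TTTTCAGGG", b = "TTCTCAGGG",
       S = 7 / 3, N = 9 - 7 / 3, sd = 1, nd = 0),
  # one nonsynonymous difference (AAA->AGA), S = mean(1/3+1, 5/6+1) = 19/12
  list(a = "AAAGGG", b = "AGAGGG",
       S = 19 / 12, N = 6 - 19 / 12, sd = 0, nd = 1),
  # two-position codon (TTT vs GTA): path via GTT gives 1 syn + 1 nonsyn,
  # path via TTA gives 2 nonsyn; average sd = 0.5, nd = 1.5
  list(a = "TTTGGG", b = "GTAGGG",
       S = mean(c(4 / 3, 2)), N = 6 - mean(c(4 / 3, 2)), sd = 0.5, nd = 1.5),
  # TGG vs TCA: the pos3-first path passes through TGA (stop) and is
  # excluded, leaving TGG->TCG->TCA with 1 nonsyn + 1 syn
  list(a = "TGGGGG", b = "TCAGGG",
       S = mean(c(0, 1)) + 1, N = 6 - (mean(c(0, 1)) + 1), sd = 1, nd = 1),
  # identical sequences
  list(a = "ATGAAACCC", b = "ATGAAACCC",
       S = 4 / 3, N = 9 - 4 / 3, sd = 0, nd = 0)
)

test_that("NG86 counts and rates match the hand-enumerated oracles", {
  for (k in seq_along(ng86_oracles)) {
    o <- ng86_oracles[[k]]
    codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    res <- kaks(list(codons_a = codons(o$a), codons_b = codons(o$b)))
    expect_equal(res$S, o$S, tolerance = 1e-10, info = paste("case", k))
    expect_equal(res$N, o$N, tolerance = 1e-10, info = paste("case", k))
    expect_equal(res$sd, o$sd, tolerance = 1e-10, info = paste("case", k))
    expect_equal(res$nd, o$nd, tolerance = 1e-10, info = paste("case", k))
    ks_want <- jc(o$sd / o$S)
    ka_want <- jc(o$nd / o$N)
    if (is.finite(ks_want)) {
      expect_equal(res$Ks, ks_want, tolerance = 1e-10, info = paste("case", k))
    }
    expect_equal(res$Ka, ka_want, tolerance = 1e-10, info = paste("case", k))
    # S + N conservation: three sites per aligned codon
    expect_equal(res$S + res$N, 3 * nchar(o$a) / 3, tolerance = 1e-10)
  }
})

test_that("saturated synonymous proportions are reported as infinite Ks", {
  # single codon TTT vs TTC: ps = 1/(1/3) = 3 >= 3/4
  res <- kaks(list(codons_a = "TTT", codons_b = "TTC"))
  expect_true(is.infinite(res$Ks))
  expect_true(is.na(res$ratio))
})

test_that("kaks is symmetric and a lone nonsynonymous change gives Ks = 0", {
  set.seed(60)
  cds <- polyivd:::random_cds(303)
  mut <- mutate_copy(cds, 0.05, seed = 2, codon_aware = TRUE)
  r1 <- kaks_pair(cds, mut, "x", "y")
  r2 <- kaks_pair(mut, cds, "y", "x")
  for (col in c("S", "N", "sd", "nd", "Ka", "Ks")) {
    expect_equal(r2[[col]], r1[[col]], tolerance = 1e-12, info = col)
  }

  # 100 identical codons except one nonsynonymous change
  base <- strrep("GGT", 100)            # Gly x100
  alt <- paste0("AGT", strrep("GGT", 99))  # Gly -> Ser at codon 1
  res <- kaks(list(codons_a = substring(base, seq(1, 298, 3), seq(3, 300, 3)),
                   codons_b = substring(alt, seq(1, 298, 3), seq(3, 300, 3))))
  expect_equal(res$Ks, 0)
  expect_gt(res$Ka, 0)
  expect_true(is.na(res$ratio))
})

test_that("adding a synonymous difference never decreases Ks", {
  base <- rep("GGT", 20)
  prev <- kaks(list(codons_a = base, codons_b = base))$Ks
  for (i in 1:5) {
    alt <- base
    alt[seq_len(i)] <- "GGC"  # synonymous Gly codons
    now <- kaks(list(codons_a = base, codons_b = alt))$Ks
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("codon alignment threads proteins, drops indel codons, rejects internal stops", {
  cds <- "ATGAAACCCGGGTTT"
  al <- codon_align(cds, cds)
  expect_equal(al$codons_a, al$codons_b)
  expect_equal(length(al$codons_a), 5L)

  # one internal codon inserted: that column is dropped, the rest align
  ins <- "ATGAAAGACCCCGGGTTT"
  al2 <- codon_align(cds, ins)
  expect_equal(length(al2$codons_a), 5L)
  expect_equal(al2$codons_a, al2$codons_b)

  # terminal stop is trimmed, internal stop is an error naming the gene
  expect_silent(codon_align(paste0(cds, "TGA"), cds))
  expect_error(codon_align("ATGTAACCC", cds, id_a = "geneX"), "geneX")
  expect_error(codon_align("ATGAA", cds, id_a = "geneY"), "geneY")
})

test_that("reciprocal best hits require mutual best partners and strict thresholds", {
  mk <- function(q, s, id, score, cov = 100) {
    data.frame(query_id = q, subject_id = s, identity = id,
               alignment_length = 100L, mismatches = 0L, gap_opens = 0L,
               qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
               evalue = NA_real_, bitscore = score, self_hit = FALSE,
               query_coverage = cov, subject_coverage = cov,
               stringsAsFactors = FALSE)
  }
  hits <- rbind(
    mk("A", "B", 90, 200), mk("B", "A", 90, 200),    # mutual pair
    mk("C", "B", 95, 150), mk("B", "C", 95, 100),    # C best-hits B, B prefers A
    mk("D", "E", 59, 300), mk("E", "D", 59, 300),    # identity 59: excluded
    mk("F", "G", 60, 300), mk("G", "F", 60, 300)     # identity 60: strict >
  )
  pairs <- rbh_pairs(hits)
  expect_equal(pairs, data.frame(gene_a = "A", gene_b = "B",
                                 stringsAsFactors = FALSE))
})

test_that("Ks filtering removes saturated pairs and summarises per class", {
  res <- data.frame(
    gene_a = letters[1:5], gene_b = LETTERS[1:5],
    Ka = c(0.1, 0.2, 0.05, 0.3, 0),
    Ks = c(0.5, 3.2, 0.09, Inf, 0),
    p_value = c(0.01, 0.01, 0.2, 0.01, 1),
    class = c("OP", "OP", "IP", "OP", "IP"))
  out <- ks_filter_and_summarize(res)
  expect_equal(nrow(out$filtered), 3L)          # Ks >= 3 and Inf removed
  expect_true(all(out$filtered$Ks < 3))
  expect_equal(out$summary$n[out$summary$class == "IP"], 2L)
  expect_equal(out$summary$median_ks[out$summary$class == "IP"], 0.045)

  strict <- ks_filter_and_summarize(res, p_max = 0.05)
  expect_equal(nrow(strict$filtered), 1L)

  # identical-sequence pairs (Ks = 0) are retained
  expect_true(0 %in% out$filtered$Ks)
})
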