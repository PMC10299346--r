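test_that("center-star alignment handles identical, gapped and variant inputs", {
  # two identical sequences: full-length effective, no variants
  ra <- align_family_region(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(ra$L, 10L)
  expect_equal(ra$X_literal, 0L)
  expect_equal(ra$X_pairdiff, 0)

  # deletion in one member creates a gap column excluded from L;
  # two substitutions create two variant columns
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTACGTC", s3 = "ATGTACGTAG")
  # s2 lacks one base; s3 differs at sites 2 and 10
  ra2 <- align_family_region(seqs)
  expect_equal(ra2$D, 3L)
  expect_equal(ra2$L, 9L)
  expect_equal(ra2$X_literal, 2L)

  # {ACGT, ACGA, ACGA}: one variant column, pairs (1,2) and (1,3) differ
  ra3 <- align_family_region(c(x = "ACGT", y = "ACGA", z = "ACGA"))
  expect_equal(ra3$X_literal, 1L)
  expect_equal(ra3$X_pairdiff, 2)

  expect_error(align_family_region(c(a = "ACGT")), ">= 2")
})

test_that("pi follows 2X/(LD(D-1)) with both difference-count modes", {
  # depth 2: both modes reduce to X/L
  al <- list(D = 2L, L = 100L, X_literal = 5L, X_pairdiff = 5)
  expect_equal(pi_diversity(al), 0.05)
  expect_equal(pi_diversity(al, "literal"), 0.05)

  al0 <- list(D = 2L, L = 100L, X_literal = 0L, X_pairdiff = 0)
  expect_equal(pi_diversity(al0), 0)

  al3 <- list(D = 3L, L = 10L, X_literal = 3L, X_pairdiff = 6)
  expect_equal(pi_diversity(al3), 0.2)

  expect_true(is.na(pi_diversity(list(D = 3L, L = 0L, X_literal = 0L,
                                      X_pairdiff = 0))))
})

test_that("pairdiff pi equals the all-pairs brute-force oracle on random alignments", {
  set.seed(314)
  for (i in 1:100) {
    depth <- sample(2:6, 1)
    len <- sample(5:50, 1)
    msa <- random_msa(depth, len)
    ra <- align_family_region(msa)
    if (ra$L == 0) {
      expect_true(is.na(pi_diversity(ra)))
    } else {
      expect_equal(pi_diversity(ra), pi_bruteforce(msa), tolerance = 1e-12)
    }
  }
})

test_that("pi bounds hold and input order does not matter", {
  set.seed(55)
  for (i in 1:20) {
    msa <- random_msa(sample(2:5, 1), 30, gap_prob = 0.05)
    ra <- align_family_region(msa)
    if (ra$L == 0) next
    d <- ra$D
    expect_lte(pi_diversity(ra), 1)
    expect_gte(pi_diversity(ra), 0)
    expect_lte(pi_diversity(ra, "literal"), 2 / (d * (d - 1)) + 1e-12)
    perm <- sample.int(nrow(msa))
    expect_equal(pi_diversity(align_family_region(msa[perm, , drop = FALSE])),
                 pi_diversity(ra))
  }
  # permuting unaligned input sequences leaves pi unchanged too
  seqs <- c(a = "ACGTTGCAACGT", b = "ACGTAGCAACGA", c = "AGGTTGCATCGT")
  p1 <- pi_diversity(align_family_region(seqs))
  p2 <- pi_diversity(align_family_region(seqs[c(3, 1, 2)]))
  expect_equal(p2, p1)
})

test_that("published per-type region averages and the grand mean are reproduced", {
  ref <- wheat_reference_tables()
  avg <- type_region_averages(ref$region_pi)
  get <- function(t, g) avg$averages$average_pi[avg$averages$type == t &
                                                  avg$averages$genome == g]
  expect_lt(abs(get("OP", "AK58") - 0.3716), 5.1e-5)
  expect_lt(abs(get("SOR", "AK58") - 0.1243), 5.1e-5)
  expect_lt(abs(get("IP", "AK58") - 0.1414), 5.1e-5)
  expect_lt(abs(avg$grand_mean - 0.2219), 5.1e-5)
})

test_that("published species region averages are reproduced", {
  ref <- wheat_reference_tables()
  avg <- species_region_averages(ref$species_region_pi)
  get <- function(s, r) avg$average_pi[avg$species == s & avg$region == r]
  expect_lt(abs(get("Fielder", "cds") - 0.0653), 5.1e-5)
  expect_lt(abs(get("T_dicoccoides", "upstream2kb") - 0.4956), 5.1e-5)
})

test_that("diversity summary aggregates per type and runs rank-sum tests", {
  pt <- data.frame(
    family_id = rep(paste0("F", 1:6), 2),
    region = rep(c("cds", "utr3"), each = 6),
    pi = c(0.30, 0.32, 0.28, 0.01, 0.02, 0.015,
           0.40, 0.38, 0.42, 0.02, 0.01, 0.03),
    type = rep(rep(c("OP", "IP"), each = 3), 2))
  s <- summarize_diversity(pt)
  expect_equal(s$type_averages$average_pi[s$type_averages$type == "OP"],
               mean(c(mean(c(0.30, 0.32, 0.28)), mean(c(0.40, 0.38, 0.42)))))
  expect_true(all(s$tests$p_value <= 1))
  # identical samples give p = 1
  same <- data.frame(family_id = paste0("F", 1:4), region = "cds",
                     pi = c(0.1, 0.2, 0.1, 0.2),
                     type = c("OP", "OP", "IP", "IP"))
  s2 <- summarize_diversity(same)
  expect_equal(s2$tests$p_value, 1)
})

test_that("per-term diversity keeps only families with >= 2 annotated copies", {
  sim <- test_sim()
  an <- test_analysis()
  fam_multi <- an$classification$family_id[an$classification$n_genes >= 3][1]
  members <- an$families$gene_id[an$families$family_id == fam_multi]
  term_table <- data.frame(
    gene_id = c(members[1:2], members[3]),
    term = c("termA", "termA", "termB"))
  res <- go_term_family_diversity(sim$genes, an$families, term_table)
  expect_equal(unique(res$term), "termA")   # termB has a single copy
  expect_equal(res$D, 2L)
  res_none <- go_term_family_diversity(sim$genes, an$families, term_table,
                                       terms = "absent")
  expect_equal(nrow(res_none), 0L)
})

test_that("simulated outparalog families are more diverse than inparalog families", {
  sim <- test_sim()
  an <- test_analysis()
  cls <- an$classification
  multi <- cls$family_id[cls$n_genes >= 2]
  fams <- an$families[an$families$family_id %in% multi, ]
  pt <- family_region_pi(sim$genes, fams, regions = "cds")
  pt$type <- cls$type[match(pt$family_id, cls$family_id)]
  pt$type[pt$family_id %in% cls$family_id[cls$is_OP]] <- "OP"
  expect_gt(mean(pt$pi[pt$type == "OP"]), mean(pt$pi[pt$type == "IP"]))
})
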