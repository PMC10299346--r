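test_that("tau hits its limits and matches hand evaluation", {
  expect_equal(tau(c(1, 0, 0, 0, 0)), 1)
  expect_equal(tau(c(3, 3, 3, 3)), 0)
  # (8,4,2,2): Xi = (1, .5, .25, .25); tau = (0 + .5 + .75 + .75)/3 = 2/3
  expect_equal(tau(c(8, 4, 2, 2)), 2 / 3)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), ">= 2")
})

test_that("tau is scale-invariant and monotone under concentration", {
  set.seed(42)
  for (i in 1:20) {
    x <- runif(5, 0, 100)
    expect_equal(tau(3.7 * x), tau(x))
    # move mass from a minor tissue to the top tissue
    top <- which.max(x)
    minor <- which.min(x)
    shift <- x
    delta <- x[minor] * 0.5
    shift[minor] <- shift[minor] - delta
    shift[top] <- shift[top] + delta
    expect_gte(tau(shift), tau(x) - 1e-12)
  }
})

test_that("family divergence applies the strict CV and fold-change thresholds", {
  fams <- data.frame(family_id = rep(c("F1", "F2", "F3"), each = 2),
                     gene_id = paste0("g", 1:6))
  mat <- rbind(
    g1 = c(10, 10), g2 = c(10, 10),   # CV = 0: not diverged
    g3 = c(10, 10), g4 = c(1, 1),     # CV ~ 1.16, log2FC ~ 3.3: diverged
    g5 = c(10, 10), g6 = c(4.4, 4.4)  # CV ~ 0.55: below threshold
  )
  colnames(mat) <- c("s1", "s2")
  em <- expression_matrix(mat, c(s1 = "leaf", s2 = "leaf"))
  dv <- family_divergence(fams, em)
  f1 <- dv[dv$family_id == "F1", ]
  expect_equal(f1$cv, 0)
  expect_false(f1$diverged)
  f2 <- dv[dv$family_id == "F2", ]
  expect_equal(f2$cv, sd(c(10, 1)) / mean(c(10, 1)))
  expect_equal(f2$log2fc, log2(10.01 / 1.01))
  expect_true(f2$diverged)
  expect_false(dv$diverged[dv$family_id == "F3"])

  # CV exactly at the threshold is NOT diverged (strict inequality)
  x <- c(1, 1)
  # choose b so that sd/mean == 0.6 exactly: sd = (a-b)/sqrt(2), mean=(a+b)/2
  a <- 10; b <- a * (sqrt(2) - 0.6) / (sqrt(2) + 0.6)
  mat2 <- rbind(h1 = c(a, a), h2 = c(b, b)); colnames(mat2) <- c("s1", "s2")
  em2 <- expression_matrix(mat2, c(s1 = "leaf", s2 = "leaf"))
  fams2 <- data.frame(family_id = "F", gene_id = c("h1", "h2"))
  dv2 <- family_divergence(fams2, em2)
  expect_equal(dv2$cv, 0.6, tolerance = 1e-12)
  expect_false(dv2$diverged)
})

test_that("module divergence requires full assignment and ignores label names", {
  fams <- data.frame(family_id = rep(c("F1", "F2", "F3"), each = 2),
                     gene_id = paste0("g", 1:6))
  mods <- c(g1 = "M7", g2 = "M7", g3 = "M7", g4 = "M12", g5 = "M1")
  # g6 unassigned -> F3 excluded from the denominator
  types <- data.frame(family_id = c("F1", "F2", "F3"),
                      type = c("OP", "OP", "IP"))
  md <- module_divergence(fams, mods, types)
  expect_equal(nrow(md$calls), 2L)
  expect_false(md$calls$diverged[md$calls$family_id == "F1"])
  expect_true(md$calls$diverged[md$calls$family_id == "F2"])
  expect_equal(md$fractions$fraction_diverged[md$fractions$type == "OP"], 0.5)

  # relabeling modules changes nothing
  relab <- c(M7 = "A", M12 = "B", M1 = "C")
  mods2 <- stats::setNames(relab[mods], names(mods))
  md2 <- module_divergence(fams, mods2, types)
  expect_equal(md2$calls$diverged, md$calls$diverged)
})

test_that("term enrichment matches the hypergeometric tail and Bonferroni scaling", {
  universe <- paste0("g", 1:20)
  gene_set <- paste0("g", 1:10)
  # term annotates 8 in-set genes and 2 out-of-set genes: (8,2;2,8) table
  term_table <- data.frame(
    gene_id = c(paste0("g", 1:8), "g11", "g12",
                universe),
    term = c(rep("t1", 10), rep("everything", 20)))
  res <- term_enrichment(gene_set, universe, term_table)
  p_t1 <- res$p_value[res$term == "t1"]
  expect_equal(p_t1, hypergeom_tail_oracle(8, 10, 10, 20), tolerance = 1e-12)
  # a term covering the whole universe cannot be enriched
  expect_equal(res$p_value[res$term == "everything"], 1)
  expect_false(res$enriched[res$term == "everything"])
  # Bonferroni multiplies by the number of tested terms, capped at 1
  expect_equal(res$p_adjusted, pmin(1, res$p_value * nrow(res)))
  expect_error(term_enrichment(gene_set, character(0), term_table), "universe")
})

test_that("fallback co-expression modules group genes by tissue pattern", {
  sim <- test_sim()
  em <- simulate_expression(sim$config, sim$truth)
  mods <- simple_coexpression_modules(em)
  spec <- sim$truth[sim$truth$specific, ]
  # genes specific to the same tissue share a module ...
  for (t in unique(spec$tissue)) {
    expect_equal(length(unique(mods[spec$gene_id[spec$tissue == t]])), 1L,
                 label = paste("tissue", t))
  }
  # ... and genes specific to different tissues do not
  one_per_tissue <- spec[!duplicated(spec$tissue), ]
  expect_equal(anyDuplicated(mods[one_per_tissue$gene_id]), 0L)
})
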