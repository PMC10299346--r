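#' Tissue-specificity index τ
#'
#' `τ = Σ(1 − Xi)/(n − 1)` where `Xi` is the gene's per-tissue mean divided
#' by its maximum tissue mean (dispersion normalisation) and `n` the number
#' of tissues. τ is 0 for uniformly expressed genes, 1 for genes expressed in
#' a single tissue, and is scale-invariant. A gene with no expression in any
#' tissue has no defined τ and returns `NA`.
#'
#' @param x numeric vector of per-tissue mean expression (length ≥ 2,
#'   non-negative).
#' @param normalization `"max"` (default: divide by the maximum) or
#'   `"max-min"` (rescale to the `[min, max]` range before averaging).
#' @return τ in `[0, 1]`, or `NA` for an all-zero gene.
#' @export
tau <- function(x, normalization = c("max", "max-min")) {
  normalization <- match.arg(normalization)
  n <- length(x)
  if (n < 2) stop("tau needs >= 2 tissues")
  if (any(is.na(x))) return(NA_real_)
  m <- max(x)
  if (m <= 0) return(NA_real_)
  xi <- if (normalization == "max") x / m else {
    if (m == min(x)) rep(1, n) else (x - min(x)) / (m - min(x))
  }
  sum(1 - xi) / (n - 1)
}

#' τ for every gene of an expression matrix
#'
#' @param em an `expression_matrix`.
#' @param normalization see [tau()].
#' @return data.frame `gene_id`, `tau`, `top_tissue` (the tissue with the
#'   highest mean).
#' @export
tau_table <- function(em, normalization = "max") {
  tm <- tissue_means(em)
  data.frame(
    gene_id = rownames(tm),
    tau = apply(tm, 1, tau, normalization = normalization),
    top_tissue = colnames(tm)[max.col(tm, ties.method = "first")],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression-divergence call for one family's copies
#'
#' Computes, across a family's copies, the coefficient of variation
#' (CV = sd/mean of the copies' expression in the selected samples) and the
#' extreme log2 fold change between the highest and lowest copy (with a
#' pseudocount so zero-expression copies do not blow up the ratio). The
#' family is called diverged when CV > `cv_min` (strict) and
#' |log2FC| ≥ `lfc_min`. When at least two replicate samples are selected, a
#' two-sided Wilcoxon rank-sum between the extreme copies' replicate values
#' supplies a p-value; otherwise the call rests on CV and fold change alone.
#'
#' @param families a `homolog_families` table.
#' @param em an `expression_matrix`.
#' @param samples sample columns to use (default: all).
#' @param cv_min,lfc_min divergence thresholds.
#' @param pseudocount added to numerator and denominator of the fold change.
#' @return data.frame `family_id`, `n_copies`, `cv`, `log2fc`, `p_value`,
#'   `diverged` (families with <2 copies in the matrix are skipped).
#' @export
family_divergence <- function(families, em, samples = NULL,
                              cv_min = 0.6, lfc_min = 1, pseudocount = 0.01) {
  if (is.null(samples)) samples <- colnames(em)
  out <- list()
  for (f in unique(families$family_id)) {
    members <- intersect(families$gene_id[families$family_id == f],
                         rownames(em))
    if (length(members) < 2) next
    vals <- em[members, samples, drop = FALSE]
    copy_means <- rowMeans(vals)
    cv <- stats::sd(copy_means) / mean(copy_means)
    hi <- members[which.max(copy_means)]
    lo <- members[which.min(copy_means)]
    lfc <- log2((max(copy_means) + pseudocount) /
                  (min(copy_means) + pseudocount))
    p <- if (length(samples) >= 2) {
      suppressWarnings(stats::wilcox.test(vals[hi, ], vals[lo, ])$p.value)
    } else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      family_id = f, n_copies = length(members), cv = cv, log2fc = lfc,
      p_value = p, diverged = cv > cv_min && abs(lfc) >= lfc_min,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(family_id = character(0), n_copies = integer(0),
                      cv = numeric(0), log2fc = numeric(0),
                      p_value = numeric(0), diverged = logical(0)))
  }
  do.call(rbind, out)
}

#' Co-expression module splitting of families
#'
#' A family is module-diverged when its copies occupy more than one
#' co-expression module. Only families in which every copy has a module
#' assignment enter the denominator; families with any unassigned copy are
#' excluded. Per-type diverged fractions are reported when a type table is
#' supplied.
#'
#' @param families a `homolog_families` table.
#' @param gene_to_module named character vector (gene → module) or data.frame
#'   `gene_id`, `module`.
#' @param types optional data.frame `family_id`, `type`.
#' @return list with `calls` (family_id, n_modules, diverged) and
#'   `fractions` (per type: n families considered, fraction diverged;
#'   `NULL` without `types`).
#' @export
module_divergence <- function(families, gene_to_module, types = NULL) {
  if (is.data.frame(gene_to_module)) {
    gene_to_module <- stats::setNames(as.character(gene_to_module$module),
                                      gene_to_module$gene_id)
  }
  calls <- list()
  for (f in unique(families$family_id)) {
    members <- families$gene_id[families$family_id == f]
    mods <- gene_to_module[members]
    if (any(is.na(mods))) next  # a copy without a clear module: excluded
    calls[[length(calls) + 1L]] <- data.frame(
      family_id = f, n_modules = length(unique(mods)),
      diverged = length(unique(mods)) > 1L, stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(family_id = character(0), n_modules = integer(0),
               diverged = logical(0))
  fractions <- NULL
  if (!is.null(types) && nrow(calls)) {
    calls$type <- types$type[match(calls$family_id, types$family_id)]
    fractions <- do.call(rbind, lapply(unique(calls$type), function(t) {
      sel <- calls$type == t
      data.frame(type = t, n = sum(sel),
                 fraction_diverged = mean(calls$diverged[sel]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(calls = calls, fractions = fractions)
}

#' Fisher term enrichment with Bonferroni correction
#'
#' For every term annotating at least one universe gene, a one-sided Fisher
#' exact test on the 2×2 membership table (in set / annotated) measures
#' over-representation of the term in the gene set; p-values are
#' Bonferroni-corrected over the tested terms. The engine is generic — any
#' gene → term table (GO, KEGG, PO, ...) works.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all genes considered.
#' @param term_table data.frame `gene_id`, `term`.
#' @param p_max adjusted-p ceiling for the `enriched` flag.
#' @return data.frame `term`, `set_annotated`, `set_size`,
#'   `universe_annotated`, `universe_size`, `p_value`, `p_adjusted`,
#'   `enriched`, ordered by p-value.
#' @export
term_enrichment <- function(gene_set, universe, term_table, p_max = 0.05) {
  if (!length(universe)) stop("empty universe")
  gene_set <- intersect(unique(gene_set), universe)
  universe <- unique(universe)
  tt <- term_table[term_table$gene_id %in% universe, , drop = FALSE]
  terms <- unique(tt$term)
  n_set <- length(gene_set)
  n_uni <- length(universe)
  rows <- lapply(terms, function(term) {
    annotated <- unique(tt$gene_id[tt$term == term])
    a <- length(intersect(gene_set, annotated))
    tab <- matrix(c(a, n_set - a,
                    length(annotated) - a,
                    n_uni - n_set - (length(annotated) - a)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = term, set_annotated = a, set_size = n_set,
               universe_annotated = length(annotated), universe_size = n_uni,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), set_annotated = integer(0),
                      set_size = integer(0), universe_annotated = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      p_adjusted = numeric(0), enriched = logical(0)))
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$enriched <- out$p_adjusted < p_max
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Fallback co-expression module assignment by correlation clustering
#'
#' Average-linkage hierarchical clustering on 1 − Pearson correlation of
#' expression profiles, cut at a fixed height. This is a simple stand-in for
#' a dedicated co-expression network analysis, intended for synthetic tests;
#' real module tables should be supplied to [module_divergence()] directly.
#'
#' @param em an `expression_matrix`.
#' @param cut_height dissimilarity cut (1 − r).
#' @return named character vector gene → module (`"M1"`, `"M2"`, ...); genes
#'   with zero variance are unassigned (`NA`).
#' @export
simple_coexpression_modules <- function(em, cut_height = 0.4) {
  v <- apply(em, 1, stats::sd)
  usable <- rownames(em)[v > 0]
  out <- stats::setNames(rep(NA_character_, nrow(em)), rownames(em))
  if (length(usable) >= 2) {
    cc <- stats::cor(t(em[usable, , drop = FALSE]))
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    cl <- stats::cutree(hc, h = cut_height)
    out[usable] <- paste0("M", cl)
  }
  out
}
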