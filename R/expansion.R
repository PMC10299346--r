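#' Flag expansion families by copy-number threshold
#'
#' An expansion family has `threshold` (default 5) or more gene copies in a
#' single genome. Works on a long copy table so it applies equally to
#' one-genome family tables and cross-genome copy tables.
#'
#' @param copy_table data.frame `family_id`, `genome`, `n_copies`.
#' @param threshold minimum copies for the expansion flag (inclusive).
#' @return the table with an added logical `expansion` column.
#' @export
detect_expansion <- function(copy_table, threshold = 5L) {
  stopifnot(all(c("family_id", "genome", "n_copies") %in% names(copy_table)))
  copy_table$expansion <- copy_table$n_copies >= threshold
  copy_table
}

#' Cluster gene families across genomes and tabulate per-genome copies
#'
#' Pools the genomes' sequences, runs the all-vs-all search, keeps hits with
#' identity and query coverage above the cross-genome thresholds (strict >),
#' takes connected components, and tabulates each family's copy number per
#' genome. Families present in every genome are `common`; families confined
#' to one genome are `specific` to it.
#'
#' @param genome_seqs named list: genome → named sequence set (character
#'   vector or `XStringSet`).
#' @param type `"nucleotide"` or `"protein"`.
#' @param min_identity,min_coverage cross-genome thresholds (percent, strict).
#' @return list with `copy_table` (`family_id`, `genome`, `n_copies`),
#'   `families` (`homolog_families` over all genes), `common` and `specific`
#'   (family id vectors / named list).
#' @export
cross_genome_families <- function(genome_seqs, type = "nucleotide",
                                  min_identity = 70, min_coverage = 70) {
  genomes <- names(genome_seqs)
  all_seqs <- character(0)
  origin <- character(0)
  for (g in genomes) {
    s <- stats::setNames(as.character(genome_seqs[[g]]),
                         names(genome_seqs[[g]]))
    if (any(names(s) %in% names(all_seqs))) {
      stop("gene ids must be unique across genomes")
    }
    all_seqs <- c(all_seqs, s)
    origin <- c(origin, stats::setNames(rep(g, length(s)), names(s)))
  }
  hits <- all_vs_all(all_seqs, type = type)
  keep <- filter_hits(hits, min_identity = min_identity)
  qc <- ifelse(is.na(keep$query_coverage), Inf, keep$query_coverage)
  keep <- keep[keep$identity > min_identity & qc > min_coverage, ,
               drop = FALSE]
  fams <- cluster_families(keep, names(all_seqs))

  fam_ids <- unique(fams$family_id)
  copy_table <- do.call(rbind, lapply(fam_ids, function(f) {
    members <- fams$gene_id[fams$family_id == f]
    data.frame(family_id = f, genome = genomes,
               n_copies = vapply(genomes, function(g)
                 sum(origin[members] == g), integer(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(copy_table) <- NULL
  present <- copy_table[copy_table$n_copies > 0, , drop = FALSE]
  n_genomes_of <- table(present$family_id)
  common <- names(n_genomes_of)[n_genomes_of == length(genomes)]
  specific <- lapply(genomes, function(g) {
    one <- names(n_genomes_of)[n_genomes_of == 1]
    intersect(one, present$family_id[present$genome == g])
  })
  names(specific) <- genomes
  list(copy_table = copy_table, families = fams,
       common = sort(common), specific = specific)
}

#' Percent excess of one genome's expansion-family count over another's
#'
#' `excess = (a − b)/b × 100`; undefined (NA) when the baseline is zero.
#'
#' @param a,b expansion-family counts (focal, baseline).
#' @return percent excess.
#' @export
excess_percentage <- function(a, b) {
  if (b == 0) return(NA_real_)
  (a - b) / b * 100
}

#' Compare expansion families across genomes
#'
#' From a cross-genome copy table: per-genome expansion-family counts,
#' pairwise percent excess of the focal genome over each other genome, and
#' dominant-expansion families — families whose copy number in the focal
#' genome is at least `dominant_fold` times the arithmetic mean of the other
#' genomes' copy numbers.
#'
#' @param copy_table data.frame `family_id`, `genome`, `n_copies`.
#' @param focal focal genome (default: first in the table).
#' @param threshold expansion copy-number threshold.
#' @param dominant_fold fold multiple for dominance (e.g. 2 or 3).
#' @return list with `expansion_counts` (named), `excess_pct` (named, focal
#'   vs each other genome), and `dominant` (data.frame `family_id`,
#'   `focal_copies`, `other_mean`, `fold`).
#' @export
expansion_comparison <- function(copy_table, focal = NULL, threshold = 5L,
                                 dominant_fold = 3) {
  ct <- detect_expansion(copy_table, threshold)
  genomes <- unique(ct$genome)
  if (is.null(focal)) focal <- genomes[1]
  counts <- vapply(genomes, function(g)
    sum(ct$expansion[ct$genome == g]), integer(1))
  others <- setdiff(genomes, focal)
  excess <- vapply(others, function(g)
    excess_percentage(counts[[focal]], counts[[g]]), numeric(1))

  wide <- do.call(rbind, lapply(unique(ct$family_id), function(f) {
    r <- ct[ct$family_id == f, ]
    data.frame(family_id = f,
               focal_copies = r$n_copies[r$genome == focal],
               other_mean = mean(r$n_copies[r$genome != focal]),
               stringsAsFactors = FALSE)
  }))
  wide$fold <- ifelse(wide$other_mean > 0, wide$focal_copies / wide$other_mean,
                      ifelse(wide$focal_copies > 0, Inf, NA_real_))
  dominant <- wide[!is.na(wide$fold) & wide$fold >= dominant_fold &
                     wide$focal_copies >= threshold, , drop = FALSE]
  rownames(dominant) <- NULL
  list(expansion_counts = counts, excess_pct = excess, dominant = dominant)
}

#' WGD-retained paralog pairs: paralogs restricted to synteny blocks
#'
#' Keeps only the paralog pairs that fall inside a synteny block (within or
#' between genomes); pairs outside any block are discarded.
#'
#' @param pairs data.frame `gene_a`, `gene_b` of candidate paralog pairs.
#' @param blocks a `synteny_blocks` object (or a precomputed collinear pair
#'   set data.frame).
#' @return data.frame `gene_a`, `gene_b` (canonical order).
#' @export
wgd_paralog_pairs <- function(pairs, blocks) {
  coll <- if (inherits(blocks, "synteny_blocks")) {
    collinear_pair_set(blocks)
  } else blocks
  key <- paste(pmin(pairs$gene_a, pairs$gene_b),
               pmax(pairs$gene_a, pairs$gene_b))
  ckey <- paste(coll$gene_a, coll$gene_b)
  out <- unique(data.frame(gene_a = pmin(pairs$gene_a, pairs$gene_b),
                           gene_b = pmax(pairs$gene_a, pairs$gene_b),
                           stringsAsFactors = FALSE)[key %in% ckey, ,
                                                     drop = FALSE])
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
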