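#' Center-star multiple alignment of a family's region sequences
#'
#' Deterministic center-star MSA: the center is the longest sequence (ties
#' broken by smallest id), every other member is globally aligned to it, and
#' the pairwise alignments are merged by taking, at each center position, the
#' maximum insertion length over all pairs. Chosen over progressive
#' alignment for determinism and testability; pairwise scoring matches the
#' homology module's nucleotide defaults.
#'
#' @param seqs named character vector (or `DNAStringSet`) of ≥2 sequences.
#' @return character matrix of aligned rows (rownames = sequence ids,
#'   gap = `"-"`), in input order.
#' @export
center_star_align <- function(seqs) {
  seqs <- stats::setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2) stop("need >= 2 sequences to align")
  if (any(!nzchar(seqs))) stop("empty sequence in alignment input")
  ord <- order(-nchar(seqs), names(seqs))
  center_id <- names(seqs)[ord[1]]
  center <- seqs[[center_id]]
  others <- setdiff(names(seqs), center_id)
  lc <- nchar(center)

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE)
  aligned <- lapply(others, function(id) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(center), Biostrings::DNAString(seqs[[id]]),
      type = "global", substitutionMatrix = sub_mat,
      gapOpening = 5, gapExtension = 1)
    list(c = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
         o = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]])
  })
  names(aligned) <- others

  ## insertion profile: gaps in the center row before center position p
  ins_profile <- function(cc) {
    ins <- integer(lc + 1L)
    p <- 1L
    for (ch in cc) {
      if (ch == "-") ins[p] <- ins[p] + 1L else p <- p + 1L
    }
    ins
  }
  profiles <- lapply(aligned, function(a) ins_profile(a$c))
  global_ins <- Reduce(pmax, profiles, integer(lc + 1L))

  expand_center <- function() {
    chars <- strsplit(center, "")[[1]]
    out <- character(0)
    for (p in seq_len(lc)) {
      out <- c(out, rep("-", global_ins[p]), chars[p])
    }
    c(out, rep("-", global_ins[lc + 1L]))
  }

  expand_other <- function(a) {
    out <- character(0)
    p <- 1L
    pending <- character(0)  # other chars aligned to center gaps before pos p
    for (k in seq_along(a$c)) {
      if (a$c[k] == "-") {
        pending <- c(pending, a$o[k])
      } else {
        out <- c(out, pending, rep("-", global_ins[p] - length(pending)),
                 a$o[k])
        pending <- character(0)
        p <- p + 1L
      }
    }
    c(out, pending, rep("-", global_ins[lc + 1L] - length(pending)))
  }

  width <- lc + sum(global_ins)
  msa <- matrix("-", nrow = length(seqs), ncol = width,
                dimnames = list(names(seqs), NULL))
  msa[center_id, ] <- expand_center()
  for (id in others) msa[id, ] <- expand_other(aligned[[id]])
  msa
}

#' Alignment depth, effective length and difference counts for one region
#'
#' Builds (or accepts) a multiple alignment of one region across a family's
#' copies and counts: `D`, the alignment depth (number of sequences); `L`,
#' the effective alignment length (columns with no gap and no ambiguous
#' base); `X_literal`, the number of variant columns; and `X_pairdiff`, the
#' total pairwise differences summed over effective columns. Columns
#' containing gaps or ambiguity codes are excluded from both `L` and the
#' difference counts.
#'
#' @param seqs named sequences (aligned on the fly with
#'   [center_star_align()]), or an already-aligned character matrix.
#' @param family_id,region optional labels carried through.
#' @return object of class `region_alignment`: list with `family_id`,
#'   `region`, `D`, `L`, `X_literal`, `X_pairdiff`, `msa`.
#' @export
align_family_region <- function(seqs, family_id = NA_character_,
                                region = NA_character_) {
  msa <- if (is.matrix(seqs)) seqs else center_star_align(seqs)
  d <- nrow(msa)
  eff <- apply(msa, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  effm <- msa[, eff, drop = FALSE]
  l <- ncol(effm)
  x_lit <- 0L
  x_pd <- 0
  if (l > 0) {
    per_col <- apply(effm, 2, function(col) {
      counts <- table(col)
      c(lit = as.integer(length(counts) > 1L),
        pd = d * (d - 1) / 2 - sum(choose(counts, 2)))
    })
    x_lit <- sum(per_col["lit", ])
    x_pd <- sum(per_col["pd", ])
  }
  structure(list(family_id = family_id, region = region, D = d, L = l,
                 X_literal = x_lit, X_pairdiff = x_pd, msa = msa),
            class = "region_alignment")
}

#' Nucleotide diversity of a region alignment
#'
#' Computes `pi = 2 X / (L D (D − 1))` where `D` is the alignment depth, `L`
#' the effective alignment length and `X` a difference count. In the default
#' `"pairdiff"` mode `X` is the total count of pairwise differences over
#' effective columns, which makes the statistic the mean pairwise per-site
#' difference (Nei's nucleotide diversity: the denominator `D(D−1)/2` is the
#' number of sequence pairs). The `"literal"` mode instead takes `X` as the
#' number of variant columns; because `X ≤ L` that reading caps the statistic
#' at `2/(D(D−1))` (1/3 at depth 3), which is incompatible with per-region
#' diversities of 0.4 and above observed in diverged outparalog families, so
#' `"pairdiff"` is the default and `"literal"` is kept as an option. The two
#' modes coincide at depth 2.
#'
#' @param alignment a `region_alignment` from [align_family_region()].
#' @param mode `"pairdiff"` (default) or `"literal"`.
#' @return numeric π value, or `NA` when `L = 0` (undefined).
#' @export
pi_diversity <- function(alignment, mode = c("pairdiff", "literal")) {
  mode <- match.arg(mode)
  d <- alignment$D; l <- alignment$L
  if (d < 2) stop("alignment depth must be >= 2")
  if (l == 0) return(NA_real_)
  x <- if (mode == "pairdiff") alignment$X_pairdiff else alignment$X_literal
  2 * x / (l * d * (d - 1))
}

#' Per-family, per-region nucleotide diversity across a genome
#'
#' For every family with at least two members carrying the region, aligns the
#' member sequences (center-star) and computes π. Families with fewer than
#' two sequences for a region are skipped for that region.
#'
#' @param genes a `gene_set`.
#' @param families a `homolog_families` table.
#' @param regions regions to process (see [gene_sequences()]).
#' @param mode π mode, see [pi_diversity()].
#' @return data.frame `family_id`, `region`, `D`, `L`, `X_literal`,
#'   `X_pairdiff`, `pi`.
#' @export
family_region_pi <- function(genes, families,
                             regions = c("upstream2kb", "utr5", "cds", "utr3"),
                             mode = "pairdiff") {
  out <- list()
  for (region in regions) {
    seqs <- gene_sequences(genes, region)
    for (f in unique(families$family_id)) {
      members <- families$gene_id[families$family_id == f]
      s <- seqs[names(seqs) %in% members]
      if (length(s) < 2) next
      ra <- align_family_region(s, family_id = f, region = region)
      out[[length(out) + 1L]] <- data.frame(
        family_id = f, region = region, D = ra$D, L = ra$L,
        X_literal = ra$X_literal, X_pairdiff = ra$X_pairdiff,
        pi = pi_diversity(ra, mode), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(family_id = character(0), region = character(0),
                      D = integer(0), L = integer(0), X_literal = integer(0),
                      X_pairdiff = numeric(0), pi = numeric(0)))
  }
  do.call(rbind, out)
}

#' Summarise diversity by homolog type and region
#'
#' Per type × region: family count, mean and median π. The per-type
#' region average is the mean of that type's per-region means (i.e. the row
#' mean over regions, matching how per-type averages are reported). Pairwise
#' two-sided Wilcoxon rank-sum tests compare types within each region.
#'
#' @param pi_table output of [family_region_pi()] with a `type` column added
#'   (one row per family × region).
#' @return list with `by_type_region` (type, region, n, mean, median),
#'   `type_averages` (type, average over regions), and `tests` (type_a,
#'   type_b, region, p_value).
#' @export
summarize_diversity <- function(pi_table) {
  stopifnot("type" %in% names(pi_table))
  tab <- pi_table[!is.na(pi_table$pi), , drop = FALSE]
  combos <- unique(tab[, c("type", "region")])
  by_tr <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- tab$type == combos$type[i] & tab$region == combos$region[i]
    data.frame(type = combos$type[i], region = combos$region[i],
               n = sum(sel), mean_pi = mean(tab$pi[sel]),
               median_pi = stats::median(tab$pi[sel]),
               stringsAsFactors = FALSE)
  }))
  type_avg <- do.call(rbind, lapply(unique(by_tr$type), function(t) {
    data.frame(type = t,
               average_pi = mean(by_tr$mean_pi[by_tr$type == t]),
               stringsAsFactors = FALSE)
  }))
  types <- unique(tab$type)
  tests <- list()
  if (length(types) > 1) {
    for (region in unique(tab$region)) {
      cmb <- utils::combn(sort(types), 2)
      for (k in seq_len(ncol(cmb))) {
        x <- tab$pi[tab$type == cmb[1, k] & tab$region == region]
        y <- tab$pi[tab$type == cmb[2, k] & tab$region == region]
        if (length(x) && length(y)) {
          p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
          tests[[length(tests) + 1L]] <- data.frame(
            type_a = cmb[1, k], type_b = cmb[2, k], region = region,
            p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(by_type_region = by_tr,
       type_averages = type_avg,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Per-type region averages and grand mean of a diversity table
#'
#' Reporting arithmetic for a long-format diversity table (one π per type ×
#' genome × region): the per-type/genome average is the mean over its
#' regions, and the grand mean is the mean of all per-type/genome averages.
#' Feeding a published table's printed region values reproduces its printed
#' "Average" column and genome-wide figure.
#'
#' @param tab data.frame with columns `type`, `genome`, `region`, `pi`.
#' @return list with `averages` (type, genome, average_pi) and `grand_mean`.
#' @export
type_region_averages <- function(tab) {
  combos <- unique(tab[, c("type", "genome")])
  avg <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- tab$type == combos$type[i] & tab$genome == combos$genome[i]
    data.frame(type = combos$type[i], genome = combos$genome[i],
               average_pi = mean(tab$pi[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(averages = avg, grand_mean = mean(avg$average_pi))
}

#' Per-species, per-region averages over homolog types
#'
#' Companion to [type_region_averages()] for tables laid out species × region
#' with one column of π per type: the average for a species/region row is the
#' mean over the types present (missing types are dropped, as for diploids
#' that have only inparalogs).
#'
#' @param tab data.frame with columns `species`, `region`, `type`, `pi`
#'   (π may be `NA` for absent types).
#' @return data.frame `species`, `region`, `average_pi`.
#' @export
species_region_averages <- function(tab) {
  combos <- unique(tab[, c("species", "region")])
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- tab$species == combos$species[i] & tab$region == combos$region[i]
    data.frame(species = combos$species[i], region = combos$region[i],
               average_pi = mean(tab$pi[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Per-term family diversity for an annotation term set
#'
#' For each term, collects the families with at least two annotated copies,
#' aligns those copies over the requested region and computes π — the
#' distribution view used to compare homolog diversity across functional
#' categories. Terms absent from the table yield an empty distribution.
#'
#' @param genes a `gene_set`.
#' @param families a `homolog_families` table.
#' @param term_table data.frame `gene_id`, `term`.
#' @param terms terms to process (default: all in `term_table`).
#' @param region region to align (see [gene_sequences()]).
#' @param types optional data.frame `family_id`, `type` to carry through.
#' @return data.frame `term`, `family_id`, `type`, `D`, `pi`.
#' @export
go_term_family_diversity <- function(genes, families, term_table,
                                     terms = NULL, region = "gene_body",
                                     types = NULL) {
  if (is.null(terms)) terms <- unique(term_table$term)
  seqs <- gene_sequences(genes, region)
  out <- list()
  for (term in terms) {
    annotated <- term_table$gene_id[term_table$term == term]
    if (!length(annotated)) next
    fams <- unique(families$family_id[families$gene_id %in% annotated])
    for (f in fams) {
      members <- intersect(families$gene_id[families$family_id == f],
                           annotated)
      s <- seqs[names(seqs) %in% members]
      if (length(s) < 2) next  # require >= 2 annotated copies
      ra <- align_family_region(s, family_id = f, region = region)
      out[[length(out) + 1L]] <- data.frame(
        term = term, family_id = f,
        type = if (!is.null(types))
          types$type[match(f, types$family_id)] else NA_character_,
        D = ra$D, pi = pi_diversity(ra), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(term = character(0), family_id = character(0),
                      type = character(0), D = integer(0), pi = numeric(0)))
  }
  do.call(rbind, out)
}
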