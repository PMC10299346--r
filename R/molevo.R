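## ---- NG86 Ka/Ks machinery (universal genetic code) ----

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

## synonymous fraction at each position of a codon: among the three possible
## single-nucleotide changes, the fraction that is synonymous; changes to
## stop codons are excluded from the fraction's denominator (the position
## still contributes one full site, so S + N = 3 per codon).
ng86_syn_fractions <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa0 <- codon_aa(codon)
  vapply(1:3, function(p) {
    alt <- setdiff(DNA_BASES, chars[p])
    new_codons <- vapply(alt, function(b) {
      cc <- chars; cc[p] <- b; paste(cc, collapse = "")
    }, character(1))
    valid <- !vapply(new_codons, is_stop_codon, logical(1))
    if (!any(valid)) return(0)
    mean(vapply(new_codons[valid], codon_aa, character(1)) == aa0)
  }, numeric(1))
}

ng86_sites <- function(codons) {
  s <- sum(vapply(codons, function(cd) sum(ng86_syn_fractions(cd)),
                  numeric(1)))
  c(S = s, N = 3 * length(codons) - s)
}

## synonymous / nonsynonymous difference counts between one codon pair,
## averaged (unweighted) over all minimal mutational pathways; pathways that
## pass through a stop codon are excluded unless none avoids one.
ng86_diffs <- function(codon_a, codon_b) {
  ca <- strsplit(codon_a, "")[[1]]
  cb <- strsplit(codon_b, "")[[1]]
  pos <- which(ca != cb)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- seq_len(k)
    out <- list()
    permute <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1L]] <<- pos[prefix]; return() }
      for (r in seq_along(rest)) permute(c(prefix, rest[r]), rest[-r])
    }
    permute(integer(0), idx)
    out
  }
  path_counts <- function(order) {
    cur <- ca
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- cb[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (is_stop_codon(c2) && !identical(nxt, cb)) return(NULL)
      if (is_stop_codon(c1) || is_stop_codon(c2)) {
        nd <- nd + 1  # steps touching a stop count as nonsynonymous
      } else if (codon_aa(c1) == codon_aa(c2)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, path_counts)
  valid <- res[!vapply(res, is.null, logical(1))]
  if (!length(valid)) {
    ## all pathways pass through a stop: fall back to all pathways
    valid <- lapply(perms, function(order) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur; nxt[p] <- cb[p]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        syn <- !is_stop_codon(c1) && !is_stop_codon(c2) &&
          codon_aa(c1) == codon_aa(c2)
        if (syn) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  m <- do.call(rbind, valid)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)  # saturated
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for one codon alignment
#'
#' Nei–Gojobori (1986) counting with Jukes–Cantor correction: per-codon
#' synonymous site fractions from the universal code (averaged over both
#' sequences), multi-hit codons averaged over their minimal mutational
#' pathways (pathways through stop codons excluded when avoidable), then
#' `Ka = −3/4·ln(1 − 4/3·pn)` and likewise `Ks`. A proportion ≥ 3/4 is
#' reported as saturated (`Inf`) and the ratio as `NA`. Significance of
#' `Ka ≠ Ks` is a two-sided Fisher exact test on the (sd, nd, S−sd, N−nd)
#' table; the fractional NG86 counts are rounded to integers for the test.
#'
#' Note this is plain NG86 — a counting method; model-averaging estimators
#' produce different per-pair values, so only class-level contrasts should be
#' compared across methods.
#'
#' @param alignment a codon alignment from [codon_align()], or a list with
#'   character vectors `codons_a`, `codons_b` of equal length.
#' @return one-row data.frame: `gene_a`, `gene_b`, `S`, `N`, `sd`, `nd`,
#'   `ps`, `pn`, `Ka`, `Ks`, `ratio`, `p_value`.
#' @export
kaks <- function(alignment) {
  ca <- alignment$codons_a; cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb), length(ca) >= 1)
  sites_a <- ng86_sites(ca)
  sites_b <- ng86_sites(cb)
  s_sites <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  n_sites <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  d <- vapply(seq_along(ca), function(i) ng86_diffs(ca[i], cb[i]),
              numeric(2))
  sd_ <- sum(d["sd", ])
  nd_ <- sum(d["nd", ])
  ps <- if (s_sites > 0) sd_ / s_sites else NA_real_
  pn <- if (n_sites > 0) nd_ / n_sites else NA_real_
  ks <- jukes_cantor(ps)
  ka <- jukes_cantor(pn)
  ratio <- if (!is.na(ks) && is.finite(ks) && ks > 0 && is.finite(ka)) {
    ka / ks
  } else NA_real_
  tab <- matrix(round(c(sd_, s_sites - sd_, nd_, n_sites - nd_)), nrow = 2)
  p <- if (all(tab >= 0)) stats::fisher.test(tab)$p.value else NA_real_
  data.frame(
    gene_a = alignment$id_a %||% NA_character_,
    gene_b = alignment$id_b %||% NA_character_,
    S = s_sites, N = n_sites, sd = sd_, nd = nd_, ps = ps, pn = pn,
    Ka = ka, Ks = ks, ratio = ratio, p_value = p,
    stringsAsFactors = FALSE)
}

#' Protein-guided codon alignment of two CDS
#'
#' Translates both CDS (terminal stop codons are trimmed first; an internal
#' stop is an error naming the offending gene), aligns the proteins globally,
#' and threads codons through the protein alignment. Codon columns where
#' either side is gapped, or where a codon contains a non-ACGT base, are
#' dropped pairwise.
#'
#' @param cds_a,cds_b in-frame CDS (character scalars, length divisible by 3).
#' @param id_a,id_b gene ids carried into the result.
#' @return list with `codons_a`, `codons_b`, `id_a`, `id_b`.
#' @export
codon_align <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  split_codons <- function(cds, id) {
    cds <- toupper(as.character(cds))
    if (nchar(cds) %% 3L != 0L) {
      stop("CDS length of '", id, "' not divisible by 3")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    while (length(codons) && is_stop_codon(codons[length(codons)])) {
      codons <- codons[-length(codons)]
    }
    if (any(vapply(codons, is_stop_codon, logical(1)))) {
      stop("internal stop codon in CDS of '", id, "'")
    }
    codons
  }
  ca <- split_codons(cds_a, id_a)
  cb <- split_codons(cds_b, id_b)
  if (!length(ca) || !length(cb)) stop("empty CDS after stop trimming")

  aa_a <- paste(vapply(ca, function(cd) {
    if (grepl("[^ACGT]", cd)) "X" else codon_aa(cd)
  }, character(1)), collapse = "")
  aa_b <- paste(vapply(cb, function(cd) {
    if (grepl("[^ACGT]", cd)) "X" else codon_aa(cd)
  }, character(1)), collapse = "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(aa_a), Biostrings::AAString(aa_b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]

  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      cda <- ca[ia]; cdb <- cb[ib]
      if (!grepl("[^ACGT]", cda) && !grepl("[^ACGT]", cdb)) {
        keep_a <- c(keep_a, cda); keep_b <- c(keep_b, cdb)
      }
    }
  }
  list(codons_a = keep_a, codons_b = keep_b, id_a = id_a, id_b = id_b)
}

#' Ka/Ks for a pair of CDS sequences
#'
#' Convenience wrapper: [codon_align()] then [kaks()].
#'
#' @inheritParams codon_align
#' @return one-row data.frame, see [kaks()].
#' @export
kaks_pair <- function(cds_a, cds_b, id_a = "a", id_b = "b") {
  kaks(codon_align(cds_a, cds_b, id_a, id_b))
}

#' Reciprocal (bidirectional) best-hit pairs
#'
#' Pairs genes that are each other's best-scoring partner under the stated
#' thresholds (all strict: identity > `min_identity`, coverage >
#' `min_coverage` where coverage is available, e-value < `max_evalue` where
#' present). Ties in best-hit selection are broken by identity and then
#' subject id, for determinism.
#'
#' @param hits a `hit_table`.
#' @param min_identity percent identity floor (strict).
#' @param min_coverage percent query-coverage floor (strict).
#' @param max_evalue e-value ceiling (strict, applied when present).
#' @return data.frame `gene_a`, `gene_b` (canonical order).
#' @export
rbh_pairs <- function(hits, min_identity = 60, min_coverage = 60,
                      max_evalue = 1e-5) {
  h <- as.data.frame(hits)
  h <- h[h$query_id != h$subject_id & h$identity > min_identity, , drop = FALSE]
  has_e <- !is.na(h$evalue)
  h <- h[!has_e | h$evalue < max_evalue, , drop = FALSE]
  if (!is.null(h$query_coverage)) {
    qc <- ifelse(is.na(h$query_coverage), Inf, h$query_coverage)
    h <- h[qc > min_coverage, , drop = FALSE]
  }
  if (!nrow(h)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  h <- h[order(h$query_id, -h$bitscore, -h$identity, h$subject_id), ,
         drop = FALSE]
  best <- h[!duplicated(h$query_id), c("query_id", "subject_id")]
  partner <- stats::setNames(best$subject_id, best$query_id)
  mutual <- names(partner)[!is.na(partner[partner]) &
                             partner[partner] == names(partner)]
  if (!length(mutual)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- unique(data.frame(gene_a = pmin(mutual, partner[mutual]),
                           gene_b = pmax(mutual, partner[mutual]),
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter Ka/Ks results and summarise per pair class
#'
#' Removes pairs with `Ks >= ks_max` (saturated pairs included) as a
#' conservative guard against alignment artefacts, optionally keeps only
#' pairs whose Ka ≠ Ks test is significant, and reports per-class medians
#' and means. `Ks = 0` pairs are retained.
#'
#' @param results data.frame of [kaks()] rows with a `class` column (e.g.
#'   `"IP"` / `"OP"` / `"cross"`).
#' @param ks_max exclusive Ks ceiling (pairs with `Ks >= ks_max` removed).
#' @param p_max optional significance ceiling on the Ka ≠ Ks p-value.
#' @return list with `filtered` (surviving rows) and `summary` (per class:
#'   `n`, `median_ks`, `mean_ks`, `median_ka`, `mean_ka`).
#' @export
ks_filter_and_summarize <- function(results, ks_max = 3, p_max = NULL) {
  stopifnot("class" %in% names(results))
  keep <- !is.na(results$Ks) & results$Ks < ks_max
  if (!is.null(p_max)) keep <- keep & !is.na(results$p_value) &
      results$p_value < p_max
  filtered <- results[keep, , drop = FALSE]
  classes <- unique(filtered$class)
  summary <- do.call(rbind, lapply(classes, function(cl) {
    r <- filtered[filtered$class == cl, , drop = FALSE]
    data.frame(class = cl, n = nrow(r),
               median_ks = stats::median(r$Ks), mean_ks = mean(r$Ks),
               median_ka = stats::median(r$Ka), mean_ka = mean(r$Ka),
               stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(class = character(0), n = integer(0),
                          median_ks = numeric(0), mean_ks = numeric(0),
                          median_ka = numeric(0), mean_ka = numeric(0))
  }
  list(filtered = filtered, summary = summary)
}
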