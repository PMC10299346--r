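#' Unordered homolog pairs from a filtered hit table
#'
#' @param hits a filtered `hit_table`.
#' @return data.frame `gene_a`, `gene_b` (canonical order, deduplicated).
#' @export
homolog_pairs <- function(hits) {
  h <- as.data.frame(hits)
  h <- h[h$query_id != h$subject_id, , drop = FALSE]
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  out <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## longest gap-constrained chain DP over pairs with ranks (ra, rb); both ranks
## must strictly increase, rank gaps are capped at max_gap and penalised at
## gap_penalty per skipped gene. Returns the best chain (indices into `ra`),
## ties resolved toward the leftmost (smallest ra) chain end.
chain_dp <- function(ra, rb, max_gap, gap_penalty) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  score <- rep(1, n)
  back <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      ga <- ra[j] - ra[i] - 1L
      gb <- rb[j] - rb[i] - 1L
      if (ra[i] >= ra[j] || rb[i] >= rb[j]) next
      if (ga > max_gap || gb > max_gap) next
      cand <- score[i] + 1 - gap_penalty * (ga + gb)
      if (cand > score[j] + 1e-12) { score[j] <- cand; back[j] <- i }
    }
  }
  end <- which.max(score)  # ties: first (leftmost) maximum
  chain <- integer(0)
  k <- end
  while (!is.na(k)) { chain <- c(k, chain); k <- back[k] }
  list(idx = ord[chain], score = score[end])
}

## collapse tandem arrays (homologous genes at adjacent ranks on one
## chromosome) to their lowest-rank member before chaining
tandem_collapse <- function(genes, pairs) {
  ra <- genes$rank[match(pairs$gene_a, genes$gene_id)]
  rb <- genes$rank[match(pairs$gene_b, genes$gene_id)]
  ca <- genes$chromosome[match(pairs$gene_a, genes$gene_id)]
  cb <- genes$chromosome[match(pairs$gene_b, genes$gene_id)]
  tand <- which(ca == cb & abs(ra - rb) == 1L)
  rep_of <- stats::setNames(genes$gene_id, genes$gene_id)
  if (length(tand)) {
    g <- igraph::graph_from_data_frame(
      pairs[tand, c("gene_a", "gene_b")], directed = FALSE,
      vertices = genes$gene_id)
    memb <- igraph::components(g)$membership
    for (cl in split(names(memb), memb)) {
      if (length(cl) < 2) next
      r <- genes$rank[match(cl, genes$gene_id)]
      rep_of[cl] <- cl[which.min(r)]
    }
  }
  rep_of
}

#' Detect synteny blocks between (and within) chromosomes
#'
#' Chains homologous gene pairs whose rank order is conserved on both
#' chromosomes, by weighted longest-chain dynamic programming: each pair
#' scores +1, rank gaps are penalised at `gap_penalty` per skipped gene and
#' capped at `max_gap`. Both orientations are searched (the antiparallel
#' chain negates the second chromosome's ranks). Chains are extracted
#' greedily by score (ties toward the leftmost start), removing used pairs,
#' until no chain of at least `min_block_size` pairs remains. Tandem arrays
#' (homologous genes at adjacent ranks on one chromosome) are collapsed to a
#' single representative before chaining so they cannot inflate
#' within-chromosome blocks.
#'
#' @param genes a `gene_set` (or data.frame with `gene_id`, `chromosome`,
#'   `rank`).
#' @param pairs data.frame of homologous pairs (`gene_a`, `gene_b`), e.g.
#'   from [homolog_pairs()].
#' @param min_block_size minimum pairs per reported block (default 3).
#' @param max_gap maximum rank gap (genes skipped) between consecutive pairs.
#' @param gap_penalty chain score penalty per skipped gene.
#' @param collapse_tandem collapse tandem arrays before chaining.
#' @return object of class `synteny_blocks`: list of blocks, each with
#'   `chrom_a`, `chrom_b`, `orientation` (`"parallel"`/`"antiparallel"`),
#'   `score`, and a `pairs` data.frame (`gene_a`, `gene_b`, `rank_a`,
#'   `rank_b`).
#' @export
detect_blocks <- function(genes, pairs, min_block_size = 3L, max_gap = 25L,
                          gap_penalty = 0.1, collapse_tandem = TRUE) {
  if (!nrow(pairs)) return(structure(list(), class = "synteny_blocks"))
  pairs <- unique(data.frame(gene_a = pmin(pairs$gene_a, pairs$gene_b),
                             gene_b = pmax(pairs$gene_a, pairs$gene_b),
                             stringsAsFactors = FALSE))
  pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]

  if (collapse_tandem) {
    rep_of <- tandem_collapse(genes, pairs)
    pairs$gene_a <- unname(rep_of[pairs$gene_a])
    pairs$gene_b <- unname(rep_of[pairs$gene_b])
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    pairs <- unique(data.frame(gene_a = pmin(pairs$gene_a, pairs$gene_b),
                               gene_b = pmax(pairs$gene_a, pairs$gene_b),
                               stringsAsFactors = FALSE))
  }

  idx_a <- match(pairs$gene_a, genes$gene_id)
  idx_b <- match(pairs$gene_b, genes$gene_id)
  keep <- !is.na(idx_a) & !is.na(idx_b)
  pairs <- pairs[keep, , drop = FALSE]
  idx_a <- idx_a[keep]; idx_b <- idx_b[keep]

  ## orient each pair so chrom_a <= chrom_b (same-chrom: rank_a < rank_b)
  ca <- genes$chromosome[idx_a]; cb <- genes$chromosome[idx_b]
  ra <- genes$rank[idx_a]; rb <- genes$rank[idx_b]
  flip <- ca > cb | (ca == cb & ra > rb)
  tmp <- pairs$gene_a[flip]; pairs$gene_a[flip] <- pairs$gene_b[flip]
  pairs$gene_b[flip] <- tmp
  tmp <- ca[flip]; ca[flip] <- cb[flip]; cb[flip] <- tmp
  tmp <- ra[flip]; ra[flip] <- rb[flip]; rb[flip] <- tmp

  blocks <- list()
  for (cp in unique(paste(ca, cb, sep = "\r"))) {
    sel <- which(paste(ca, cb, sep = "\r") == cp)
    sub <- data.frame(gene_a = pairs$gene_a[sel], gene_b = pairs$gene_b[sel],
                      ra = ra[sel], rb = rb[sel], stringsAsFactors = FALSE)
    chroms <- strsplit(cp, "\r", fixed = TRUE)[[1]]
    repeat {
      if (nrow(sub) < min_block_size) break
      par_chain <- chain_dp(sub$ra, sub$rb, max_gap, gap_penalty)
      anti_chain <- chain_dp(sub$ra, -sub$rb, max_gap, gap_penalty)
      if (par_chain$score >= anti_chain$score) {
        best <- par_chain; orient <- "parallel"
      } else {
        best <- anti_chain; orient <- "antiparallel"
      }
      if (length(best$idx) < min_block_size) break
      bp <- sub[best$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = chroms[1], chrom_b = chroms[2],
        orientation = orient, score = best$score,
        pairs = data.frame(gene_a = bp$gene_a, gene_b = bp$gene_b,
                           rank_a = bp$ra, rank_b = bp$rb,
                           stringsAsFactors = FALSE))
      sub <- sub[-best$idx, , drop = FALSE]
    }
  }
  structure(blocks, class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks: %d block(s)\n", length(x)))
  for (b in utils::head(x, 10)) {
    cat(sprintf("  %s ~ %s  %s  %d pairs  score %.2f\n",
                b$chrom_a, b$chrom_b, b$orientation, nrow(b$pairs), b$score))
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Union of gene pairs over all synteny blocks
#'
#' The collinear pair set gates outparalog status and WGD-paralog calls:
#' only pairs inside a block count as collinear.
#'
#' @param blocks a `synteny_blocks` object.
#' @return data.frame `gene_a`, `gene_b` (canonical order, unique); the
#'   relation is symmetric.
#' @export
collinear_pair_set <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  all_pairs <- do.call(rbind, lapply(blocks, function(b)
    b$pairs[, c("gene_a", "gene_b")]))
  out <- unique(data.frame(gene_a = pmin(all_pairs$gene_a, all_pairs$gene_b),
                           gene_b = pmax(all_pairs$gene_a, all_pairs$gene_b),
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export synteny blocks as a collinearity-style pair table
#'
#' @param blocks a `synteny_blocks` object.
#' @param file output TSV path.
#' @return invisibly, `file`.
#' @export
write_blocks <- function(blocks, file) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = sprintf("B%04d", i), chrom_a = b$chrom_a,
               chrom_b = b$chrom_b, orientation = b$orientation,
               b$pairs, stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block_id = character(0), chrom_a = character(0),
               chrom_b = character(0), orientation = character(0),
               gene_a = character(0), gene_b = character(0),
               rank_a = integer(0), rank_b = integer(0))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
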