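#' Pairwise alignment of two sequences as a hit record
#'
#' Wraps Needleman–Wunsch / Smith–Waterman dynamic programming into the
#' 12-column hit-record layout used throughout the package. Identity is
#' matches over aligned columns (×100); coverage is the aligned span over each
#' sequence's length (×100). Nucleotide scoring defaults to +1/−1 with gap
#' open 5 / extend 1; protein scoring to BLOSUM62 with gap open 11 / extend 1.
#' No e-value is computed for built-in alignments (`evalue` is `NA`);
#' identity and coverage filtering substitute for it.
#'
#' @param seq_a,seq_b sequences (character scalars or `XString`).
#' @param mode `"local"` or `"global"`.
#' @param type `"nucleotide"` or `"protein"`.
#' @param id_a,id_b ids recorded in the hit.
#' @return one-row `hit_table` data.frame.
#' @export
pairwise_align <- function(seq_a, seq_b, mode = c("local", "global"),
                           type = c("nucleotide", "protein"),
                           id_a = "query", id_b = "subject") {
  mode <- match.arg(mode)
  type <- match.arg(type)
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")

  if (type == "nucleotide") {
    a <- Biostrings::DNAString(seq_a); b <- Biostrings::DNAString(seq_b)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    go <- 5; ge <- 1
  } else {
    a <- Biostrings::AAString(seq_a); b <- Biostrings::AAString(seq_b)
    mat <- "BLOSUM62"
    go <- 11; ge <- 1
  }
  al <- Biostrings::pairwiseAlignment(
    a, b, type = mode, substitutionMatrix = mat,
    gapOpening = go, gapExtension = ge)

  pat <- as.character(Biostrings::alignedPattern(al))
  n_cols <- nchar(pat)
  matches <- Biostrings::nmatch(al)
  identity <- 100 * matches / n_cols
  qr <- al@pattern@range
  sr <- al@subject@range
  qspan <- IRanges::width(qr); sspan <- IRanges::width(sr)

  hits <- data.frame(
    query_id = id_a, subject_id = id_b,
    identity = identity, alignment_length = n_cols,
    mismatches = Biostrings::nmismatch(al),
    gap_opens = length(Biostrings::indel(al)@insertion[[1]]) +
      length(Biostrings::indel(al)@deletion[[1]]),
    qstart = IRanges::start(qr), qend = IRanges::end(qr),
    sstart = IRanges::start(sr), send = IRanges::end(sr),
    evalue = NA_real_, bitscore = Biostrings::score(al),
    self_hit = id_a == id_b,
    query_coverage = 100 * qspan / nchar(seq_a),
    subject_coverage = 100 * sspan / nchar(seq_b),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("hit_table", "data.frame")
  hits
}

## k-mer candidate-pair prefilter: pairs of sequences sharing at least
## `min_shared` distinct k-mers. Random unrelated sequences at these lengths
## essentially never pass, which keeps the all-vs-all alignment count near
## the number of truly homologous pairs.
kmer_candidate_pairs <- function(seqs, k, min_shared = 5L) {
  n <- length(seqs)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0)))
  kmer_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    s <- seqs[[i]]
    len <- nchar(s)
    if (len < k) next
    kms <- unique(substring(s, 1:(len - k + 1L), k:len))
    for (km in kms) {
      kmer_env[[km]] <- c(kmer_env[[km]], i)
    }
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (km in ls(kmer_env)) {
    members <- kmer_env[[km]]
    m <- length(members)
    if (m < 2L || m > 100L) next
    for (a in 1:(m - 1L)) for (b in (a + 1L):m) {
      key <- paste0(members[a], ":", members[b])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  keys <- ls(counts)
  keep <- keys[vapply(keys, function(kk) counts[[kk]] >= min_shared,
                      logical(1))]
  if (!length(keep)) return(data.frame(i = integer(0), j = integer(0)))
  ij <- do.call(rbind, strsplit(keep, ":", fixed = TRUE))
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

#' All-vs-all similarity search over a sequence set
#'
#' Built-in search: a k-mer seeding step (nucleotide 11-mers / protein 4-mers)
#' nominates candidate pairs, which are then aligned with [pairwise_align()].
#' Each unordered candidate pair yields two hit rows (both orientations), so
#' downstream best-hit logic sees the same table shape as an imported search.
#'
#' @param seqs named `DNAStringSet`/`AAStringSet` or named character vector.
#' @param type `"nucleotide"` or `"protein"`.
#' @param mode alignment mode for candidate pairs.
#' @param k k-mer size (default 11 for nucleotide, 4 for protein).
#' @param min_shared_kmers minimum distinct shared k-mers to nominate a pair.
#' @return a `hit_table` with one row per ordered candidate pair.
#' @export
all_vs_all <- function(seqs, type = c("nucleotide", "protein"),
                       mode = "local", k = NULL, min_shared_kmers = 5L) {
  type <- match.arg(type)
  if (is.null(k)) k <- if (type == "nucleotide") 11L else 4L
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named")
  chr <- as.character(seqs)
  cand <- kmer_candidate_pairs(chr, k, min_shared_kmers)
  if (!nrow(cand)) return(empty_hits())
  rows <- vector("list", 2L * nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    h <- pairwise_align(chr[i], chr[j], mode = mode, type = type,
                        id_a = ids[i], id_b = ids[j])
    h2 <- h
    h2$query_id <- h$subject_id; h2$subject_id <- h$query_id
    h2$qstart <- h$sstart; h2$qend <- h$send
    h2$sstart <- h$qstart; h2$send <- h$qend
    h2$query_coverage <- h$subject_coverage
    h2$subject_coverage <- h$query_coverage
    rows[[2L * r - 1L]] <- h
    rows[[2L * r]] <- h2
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Filter homology hits to high-confidence edges
#'
#' Applies the identity threshold (retain identity ≥ `min_identity`), the
#' e-value cutoff (`evalue < max_evalue`, applied only to hits that carry an
#' e-value — built-in alignments do not), and an optional coverage floor
#' (both query and subject coverage ≥ `min_coverage`). Self-hits are removed
#' and only the best-scoring hit per ordered (query, subject) pair is kept
#' (ties broken by identity, then subject id, for determinism).
#'
#' @param hits a `hit_table`.
#' @param min_identity percent identity floor (kept when `>=`).
#' @param max_evalue e-value ceiling (kept when `<`), applied when present.
#' @param min_coverage optional percent coverage floor.
#' @return filtered `hit_table`.
#' @export
filter_hits <- function(hits, min_identity = 70, max_evalue = 1e-5,
                        min_coverage = NULL) {
  h <- as.data.frame(hits)
  h <- h[!(h$query_id == h$subject_id), , drop = FALSE]
  h <- h[h$identity >= min_identity, , drop = FALSE]
  has_e <- !is.na(h$evalue)
  h <- h[!has_e | h$evalue < max_evalue, , drop = FALSE]
  if (!is.null(min_coverage)) {
    qc <- ifelse(is.na(h$query_coverage), Inf, h$query_coverage)
    sc <- ifelse(is.na(h$subject_coverage), Inf, h$subject_coverage)
    h <- h[qc >= min_coverage & sc >= min_coverage, , drop = FALSE]
  }
  if (nrow(h)) {
    h <- h[order(h$query_id, h$subject_id, -h$bitscore, -h$identity), ,
           drop = FALSE]
    h <- h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
  }
  rownames(h) <- NULL
  class(h) <- c("hit_table", "data.frame")
  h
}

## Markov-cluster-like iteration on the (symmetrised) edge weight matrix:
## column-normalise, square (expansion), raise entries to `inflation`,
## iterate to a fixed point, then read clusters off the attractor structure.
mcl_clusters <- function(adj, inflation = 2, tol = 1e-6, max_iter = 100) {
  m <- adj + t(adj)
  diag(m) <- 1  # self-loops stabilise the iteration
  m <- sweep(m, 2, colSums(m), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- m2^inflation
    m2 <- sweep(m2, 2, colSums(m2), "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
  }
  g <- igraph::graph_from_adjacency_matrix(m > 1e-8, mode = "max")
  igraph::components(g)$membership
}

#' Cluster genes into homolog families
#'
#' Builds the homology graph from filtered hits over the full gene universe
#' (genes with no surviving edge become singleton families) and partitions it.
#' The default method takes connected components, which is deterministic and
#' recovers intended memberships when divergences sit inside the filter
#' thresholds; an `"mcl"` option (power–inflation iteration, inflation 2)
#' mirrors the Markov clustering approach commonly used for family
#' construction. Family ids are assigned in order of each family's smallest
#' member gene id.
#'
#' @param hits filtered `hit_table` (see [filter_hits()]).
#' @param gene_ids character vector of all genes to partition.
#' @param method `"components"` or `"mcl"`.
#' @param inflation MCL inflation exponent.
#' @return data.frame of class `homolog_families` with columns `family_id`,
#'   `gene_id`.
#' @export
cluster_families <- function(hits, gene_ids, method = c("components", "mcl"),
                             inflation = 2) {
  method <- match.arg(method)
  gene_ids <- sort(unique(gene_ids))
  h <- as.data.frame(hits)
  h <- h[h$query_id %in% gene_ids & h$subject_id %in% gene_ids, , drop = FALSE]

  if (method == "components" || nrow(h) == 0L) {
    g <- igraph::make_empty_graph(n = length(gene_ids), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
    if (nrow(h)) {
      g <- igraph::add_edges(g, rbind(match(h$query_id, gene_ids),
                                      match(h$subject_id, gene_ids)))
    }
    membership <- igraph::components(g)$membership
  } else {
    n <- length(gene_ids)
    adj <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
    adj[cbind(match(h$query_id, gene_ids), match(h$subject_id, gene_ids))] <-
      pmax(h$bitscore, 1e-6)
    membership <- mcl_clusters(adj, inflation = inflation)
  }

  fam <- split(gene_ids, membership)
  fam <- fam[order(vapply(fam, min, character(1)))]
  out <- data.frame(
    family_id = rep(sprintf("F%05d", seq_along(fam)),
                    vapply(fam, length, integer(1))),
    gene_id = unlist(fam, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("homolog_families", "data.frame")
  out
}

#' Per-subgenome copy counts (occupancy) of each family
#'
#' @param families a `homolog_families` table.
#' @param genes a `gene_set` (or data.frame with `gene_id`, `subgenome`).
#' @param subgenomes subgenome labels to tabulate.
#' @return data.frame `family_id`, one count column per subgenome, `n_genes`,
#'   `n_unknown` (members whose subgenome could not be resolved).
#' @export
family_occupancy <- function(families, genes, subgenomes = c("A", "B", "D")) {
  sg <- genes$subgenome[match(families$gene_id, genes$gene_id)]
  fam_ids <- unique(families$family_id)
  occ <- t(vapply(fam_ids, function(f) {
    s <- sg[families$family_id == f]
    c(vapply(subgenomes, function(x) sum(s == x, na.rm = TRUE), integer(1)),
      n_genes = length(s),
      n_unknown = sum(is.na(s) | !(s %in% subgenomes)))
  }, integer(length(subgenomes) + 2L)))
  out <- data.frame(family_id = fam_ids, occ, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  names(out) <- c("family_id", subgenomes, "n_genes", "n_unknown")
  out
}
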