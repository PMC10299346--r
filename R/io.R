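#' Read a genome annotation into a gene set
#'
#' Parses a GFF3 annotation and its genome FASTA into the package's internal
#' gene table. Coordinates are converted to 0-based half-open at this boundary;
#' the subgenome of every gene is inferred from its chromosome name; genes get
#' a `rank` (ordinal position along their chromosome by start coordinate, ties
#' broken by gene id) used later by the synteny chainer.
#'
#' Genes whose chromosome has no FASTA contig are a hard error naming the
#' contig. Genes with no CDS feature are retained; CDS-dependent analyses skip
#' them. A spliced CDS length not divisible by 3 triggers a warning, not an
#' error.
#'
#' @param gff3_file path to a GFF3 file (1-based closed coordinates).
#' @param fasta_file path to the matching genome FASTA.
#' @param subgenome_pattern regex passed to [subgenome_from_chromosome()].
#' @return an object of class `gene_set`: a data.frame with columns `gene_id`,
#'   `chromosome`, `subgenome`, `strand`, `start`, `end`, `rank`, carrying the
#'   genome (`DNAStringSet`) and a feature table as attributes.
#' @seealso [gene_sequences()] to pull region sequences out of a gene set.
#' @export
read_annotation <- function(gff3_file, fasta_file,
                            subgenome_pattern = "[0-9]([ABD])$") {
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))

  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- vapply(
    if (is.null(md$Parent)) rep(list(character(0)), length(gr)) else md$Parent,
    function(p) if (length(p)) p[1] else NA_character_, character(1)
  )
  id2parent <- stats::setNames(parents, ids)

  ## resolve any feature's Parent chain up to its gene
  top_gene <- function(id) {
    seen <- character(0)
    while (!is.na(id) && id %in% names(id2parent) && !is.na(id2parent[[id]]) &&
           !(id %in% seen)) {
      seen <- c(seen, id)
      id <- id2parent[[id]]
    }
    id
  }

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no 'gene' features found in ", gff3_file)
  g <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(g)$ID)
  chrom <- as.character(GenomicRanges::seqnames(g))

  missing_contig <- setdiff(unique(chrom), names(genome))
  if (length(missing_contig)) {
    stop("annotated chromosome(s) missing from FASTA: ",
         paste(missing_contig, collapse = ", "))
  }

  genes <- data.frame(
    gene_id = gid,
    chromosome = chrom,
    subgenome = subgenome_from_chromosome(chrom, subgenome_pattern),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g) - 1L,
    end = GenomicRanges::end(g),
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  feat_types <- c(CDS = "cds", five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  keep <- type %in% names(feat_types)
  features <- data.frame(
    gene_id = character(0), type = character(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE
  )
  if (any(keep)) {
    f <- gr[keep]
    owner <- vapply(which(keep), function(i) {
      p <- parents[i]
      if (is.na(p)) NA_character_ else top_gene(p)
    }, character(1))
    features <- data.frame(
      gene_id = owner,
      type = unname(feat_types[type[keep]]),
      start = GenomicRanges::start(f) - 1L,
      end = GenomicRanges::end(f),
      stringsAsFactors = FALSE
    )
    features <- features[!is.na(features$gene_id) &
                           features$gene_id %in% genes$gene_id, ]
    features <- features[order(features$gene_id, features$type, features$start), ]
  }

  cds_len <- tapply(features$end[features$type == "cds"] -
                      features$start[features$type == "cds"],
                    features$gene_id[features$type == "cds"], sum)
  bad <- names(cds_len)[cds_len %% 3L != 0L]
  if (length(bad)) {
    warning("spliced CDS length not divisible by 3 for: ",
            paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  }

  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                           FUN = seq_along)
  rownames(genes) <- NULL

  structure(genes,
            features = features,
            genome = genome,
            class = c("gene_set", "data.frame"))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes on %d chromosome(s), subgenomes: %s\n",
              nrow(x), length(unique(x$chromosome)),
              paste(sort(unique(x$subgenome)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Extract region sequences for every gene in a gene set
#'
#' Supported regions follow the four-region scheme used throughout the
#' diversity analysis plus the whole transcribed span: `upstream2kb` (promoter
#' side, truncated at contig edges), `utr5`, `cds` (spliced), `utr3`, and
#' `gene_body` (the genomic span). Minus-strand sequences are
#' reverse-complemented so everything is returned 5'→3' in transcript
#' orientation; for minus-strand genes the upstream region lies 3' of the
#' genomic end coordinate.
#'
#' @param genes a `gene_set` from [read_annotation()] or [simulate_genome()].
#' @param region one of `"upstream2kb"`, `"utr5"`, `"cds"`, `"utr3"`,
#'   `"gene_body"`.
#' @param upstream_length promoter length in bp for `upstream2kb`.
#' @return named `DNAStringSet` (genes lacking the region are omitted).
#' @export
gene_sequences <- function(genes,
                           region = c("gene_body", "cds", "utr5", "utr3",
                                      "upstream2kb"),
                           upstream_length = 2000L) {
  region <- match.arg(region)
  genome <- attr(genes, "genome")
  if (is.null(genome)) stop("gene_set carries no genome sequences")
  features <- attr(genes, "features")

  fetch <- function(chrom, ivs, minus) {
    ivs <- ivs[order(ivs$start), , drop = FALSE]
    parts <- vapply(seq_len(nrow(ivs)), function(i) {
      as.character(Biostrings::subseq(genome[[chrom]],
                                      start = ivs$start[i] + 1L,
                                      end = ivs$end[i]))
    }, character(1))
    s <- paste(parts, collapse = "")
    if (minus) {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }

  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    chrom <- genes$chromosome[i]
    minus <- genes$strand[i] == "-"
    clen <- Biostrings::width(genome)[match(chrom, names(genome))]
    seq_i <- NULL
    if (region == "gene_body") {
      seq_i <- fetch(chrom, data.frame(start = genes$start[i],
                                       end = genes$end[i]), minus)
    } else if (region == "upstream2kb") {
      if (minus) {
        s0 <- genes$end[i]; e0 <- min(clen, genes$end[i] + upstream_length)
      } else {
        s0 <- max(0L, genes$start[i] - upstream_length); e0 <- genes$start[i]
      }
      if (e0 > s0) seq_i <- fetch(chrom, data.frame(start = s0, end = e0), minus)
    } else {
      ivs <- features[features$gene_id == gid & features$type == region,
                      c("start", "end"), drop = FALSE]
      if (nrow(ivs)) seq_i <- fetch(chrom, ivs, minus)
    }
    if (!is.null(seq_i) && nzchar(seq_i)) out[gid] <- seq_i
  }
  Biostrings::DNAStringSet(out)
}

#' Write a gene set back to GFF3 (and optionally FASTA)
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' converted back to GFF3's 1-based closed convention, and CDS/UTR features
#' are emitted as children of a single mRNA per gene.
#'
#' @param genes a `gene_set`.
#' @param gff3_file output GFF3 path.
#' @param fasta_file optional output FASTA path for the attached genome.
#' @return invisibly, `gff3_file`.
#' @export
write_annotation <- function(genes, gff3_file, fasta_file = NULL) {
  features <- attr(genes, "features")
  gff_type <- c(cds = "CDS", utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")

  rows <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    tid <- paste0(gid, ".1")
    g1 <- coords_to_gff(genes$start[i], genes$end[i])
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = genes$chromosome[i], type = "gene",
      start = g1$start, end = g1$end, strand = genes$strand[i],
      ID = gid, Parent = NA_character_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = genes$chromosome[i], type = "mRNA",
      start = g1$start, end = g1$end, strand = genes$strand[i],
      ID = tid, Parent = gid, stringsAsFactors = FALSE)
    fi <- features[features$gene_id == gid, , drop = FALSE]
    if (nrow(fi)) {
      f1 <- coords_to_gff(fi$start, fi$end)
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = genes$chromosome[i], type = unname(gff_type[fi$type]),
        start = f1$start, end = f1$end, strand = genes$strand[i],
        ID = NA_character_, Parent = tid, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  gr <- GenomicRanges::GRanges(
    seqnames = tab$seqid,
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand
  )
  S4Vectors::mcols(gr)$type <- tab$type
  S4Vectors::mcols(gr)$ID <- tab$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  S4Vectors::mcols(gr)$phase <- ifelse(tab$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff3_file, format = "gff3")

  if (!is.null(fasta_file)) {
    Biostrings::writeXStringSet(attr(genes, "genome"), fasta_file)
  }
  invisible(gff3_file)
}

#' Read a 12-column tabular homology hit table
#'
#' The layout is the ubiquitous tab-separated search output (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bit score). Malformed lines are skipped with a
#' warning reporting how many were dropped. When sequence lengths are
#' supplied, query/subject coverage is computed as aligned span over sequence
#' length; self-hits (query == subject) are flagged.
#'
#' @param file path to the tabular hits file.
#' @param seq_lengths optional named integer vector of sequence lengths used
#'   to compute coverages.
#' @return data.frame of class `hit_table` with one row per hit.
#' @export
read_hits <- function(file, seq_lengths = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) == 12L && !anyNA(suppressWarnings(as.numeric(p[3:12])))
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " malformed line(s) skipped in ", file)
  }
  parts <- parts[ok]
  if (!length(parts)) {
    return(empty_hits())
  }
  m <- do.call(rbind, parts)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]),
    gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  hits$self_hit <- hits$query_id == hits$subject_id
  hits$query_coverage <- NA_real_
  hits$subject_coverage <- NA_real_
  if (!is.null(seq_lengths)) {
    ql <- seq_lengths[hits$query_id]
    sl <- seq_lengths[hits$subject_id]
    hits$query_coverage <- 100 * (abs(hits$qend - hits$qstart) + 1) / ql
    hits$subject_coverage <- 100 * (abs(hits$send - hits$sstart) + 1) / sl
  }
  class(hits) <- c("hit_table", "data.frame")
  hits
}

empty_hits <- function() {
  structure(
    data.frame(query_id = character(0), subject_id = character(0),
               identity = numeric(0), alignment_length = integer(0),
               mismatches = integer(0), gap_opens = integer(0),
               qstart = integer(0), qend = integer(0),
               sstart = integer(0), send = integer(0),
               evalue = numeric(0), bitscore = numeric(0),
               self_hit = logical(0), query_coverage = numeric(0),
               subject_coverage = numeric(0), stringsAsFactors = FALSE),
    class = c("hit_table", "data.frame"))
}

#' Write hits in the 12-column tabular layout
#'
#' @param hits a `hit_table`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_hits <- function(hits, file) {
  cols <- c("query_id", "subject_id", "identity", "alignment_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  utils::write.table(as.data.frame(hits)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a genes-by-samples FPKM expression matrix
#'
#' The first column holds gene ids; every remaining column is one sample of
#' non-negative FPKM values. The sample→tissue map groups replicate columns
#' into tissues for the per-tissue mean view used by the tissue-specificity
#' index.
#'
#' @param file path to the TSV expression table (header row of sample names).
#' @param sample_map named character vector `c(sample = tissue, ...)` or a
#'   two-column data.frame (`sample`, `tissue`).
#' @return an `expression_matrix`: numeric matrix with a `tissues` attribute.
#' @export
read_expression <- function(file, sample_map) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- tab[[1]]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene_id rows: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression values in ", file)
  rownames(mat) <- gene_ids
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative FPKM at gene '%s', sample '%s'",
                 rownames(mat)[neg[1, 1]], colnames(mat)[neg[1, 2]]))
  }
  expression_matrix(mat, sample_map)
}

#' Construct an expression matrix object
#'
#' @param mat numeric genes × samples matrix (non-negative).
#' @param sample_map named character vector `c(sample = tissue, ...)` or a
#'   two-column data.frame (`sample`, `tissue`).
#' @return an `expression_matrix`.
#' @export
expression_matrix <- function(mat, sample_map) {
  if (is.data.frame(sample_map)) {
    sample_map <- stats::setNames(as.character(sample_map$tissue),
                                  sample_map$sample)
  }
  missing <- setdiff(names(sample_map), colnames(mat))
  if (length(missing)) {
    stop("sample(s) in map but not in matrix header: ",
         paste(missing, collapse = ", "))
  }
  unmapped <- setdiff(colnames(mat), names(sample_map))
  if (length(unmapped)) {
    stop("unmapped sample column(s): ", paste(unmapped, collapse = ", "))
  }
  structure(mat, tissues = sample_map[colnames(mat)],
            class = c("expression_matrix", class(mat)))
}

#' Per-tissue mean expression view
#'
#' @param em an `expression_matrix`.
#' @return numeric genes × tissues matrix of per-tissue means.
#' @export
tissue_means <- function(em) {
  tissues <- attr(em, "tissues")
  ut <- unique(unname(tissues))
  out <- vapply(ut, function(t) {
    rowMeans(em[, tissues == t, drop = FALSE])
  }, numeric(nrow(em)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(em),
                                       dimnames = list(rownames(em), ut))
  colnames(out) <- ut
  out
}
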