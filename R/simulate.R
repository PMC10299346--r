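#' Configuration for the synthetic three-subgenome genome
#'
#' The generator emulates the statistical structure a hexaploid (A/B/D)
#' intra-varietal diversity analysis assumes: families of every homolog type
#' with controlled copy numbers, high sequence divergence between subgenome
#' copies versus low divergence between tandem copies (mirroring the strong
#' Ks contrast between outparalog and inparalog pairs), collinear gene order
#' between subgenomes with an optional shuffled fraction, the four-region
#' gene structure (2 kb upstream, 5'UTR, CDS, 3'UTR), and tissue-structured
#' expression with designated tissue-specific genes.
#'
#' `between_subgenome_divergence` is the per-site substitution proportion
#' applied to each subgenome copy relative to the family ancestor, so the
#' expected pairwise divergence between two subgenome copies is roughly twice
#' this value (minus coincident hits). The default 0.10 keeps cross-subgenome
#' pairs at ~81% nucleotide identity — clearly diverged yet well inside the
#' 70% identity detection threshold, so truth labels are recoverable.
#' `tandem_divergence` (default 0.01) keeps tandem copies nearly identical,
#' reproducing the qualitative outparalog ≫ inparalog divergence contrast.
#'
#' @param n_families number of gene families to simulate.
#' @param subgenomes subgenome labels (chromosome names become `1A`, `1B`, ...).
#' @param p_sor,p_triplet,p_dyad,p_ip,p_singleton homolog-type proportions;
#'   must sum to 1.
#' @param between_subgenome_divergence,tandem_divergence per-site substitution
#'   proportions in `[0, 0.75)`.
#' @param shuffle_fraction fraction of (non-tandem) genes relocated within
#'   their chromosome to break collinearity.
#' @param region_lengths named lengths (bp) of `upstream`, `utr5`, `cds`,
#'   `utr3`; `cds` must be a multiple of 3.
#' @param tandem_copies copies per tandem array (inparalogs and the duplicated
#'   subgenome of triplets).
#' @param n_tissues,n_reps,n_specific_genes expression design: tissues,
#'   replicates per tissue, and number of designated tissue-specific genes.
#' @param expression_noise_sd sdlog of the multiplicative lognormal noise.
#' @param p_minus_strand probability a gene is placed on the minus strand.
#' @param seed integer seed; fully determines all output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_families = 100L,
                       subgenomes = c("A", "B", "D"),
                       p_sor = 0.40, p_triplet = 0.25, p_dyad = 0.10,
                       p_ip = 0.15, p_singleton = 0.10,
                       between_subgenome_divergence = 0.10,
                       tandem_divergence = 0.01,
                       shuffle_fraction = 0.05,
                       region_lengths = c(upstream = 2000L, utr5 = 150L,
                                          cds = 900L, utr3 = 200L),
                       tandem_copies = 2L,
                       n_tissues = 5L, n_reps = 2L, n_specific_genes = 30L,
                       expression_noise_sd = 0.2,
                       p_minus_strand = 0.25,
                       seed = 42L) {
  p <- c(p_sor, p_triplet, p_dyad, p_ip, p_singleton)
  if (abs(sum(p) - 1) > 1e-8) stop("type proportions must sum to 1")
  for (d in c(between_subgenome_divergence, tandem_divergence)) {
    if (d < 0 || d >= 0.75) stop("divergence must lie in [0, 0.75)")
  }
  if (region_lengths[["cds"]] %% 3L != 0L) stop("cds length must be a multiple of 3")
  if (n_tissues < 2L) stop("n_tissues must be >= 2")
  structure(list(
    n_families = as.integer(n_families), subgenomes = subgenomes,
    p_sor = p_sor, p_triplet = p_triplet, p_dyad = p_dyad, p_ip = p_ip,
    p_singleton = p_singleton,
    between_subgenome_divergence = between_subgenome_divergence,
    tandem_divergence = tandem_divergence,
    shuffle_fraction = shuffle_fraction,
    region_lengths = region_lengths,
    tandem_copies = as.integer(tandem_copies),
    n_tissues = as.integer(n_tissues), n_reps = as.integer(n_reps),
    n_specific_genes = as.integer(n_specific_genes),
    expression_noise_sd = expression_noise_sd,
    p_minus_strand = p_minus_strand,
    seed = as.integer(seed)
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## random CDS: ATG + non-stop codons + TGA
random_cds <- function(n) {
  n_mid <- n %/% 3L - 2L
  codons <- character(n_mid)
  i <- 1L
  while (i <= n_mid) {
    cd <- paste(sample(DNA_BASES, 3, replace = TRUE), collapse = "")
    if (!cd %in% STOP_CODONS) { codons[i] <- cd; i <- i + 1L }
  }
  paste0("ATG", paste(codons, collapse = ""), "TGA")
}

mutate_dna_chars <- function(chars, divergence) {
  hit <- which(stats::runif(length(chars)) < divergence)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  chars
}

aa_of <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

mutate_cds_chars <- function(chars, divergence, synonymous_only = FALSE) {
  n_codon <- length(chars) %/% 3L
  for (ci in seq_len(n_codon)) {
    idx <- (ci - 1L) * 3L + 1:3
    codon <- paste(chars[idx], collapse = "")
    if (codon %in% STOP_CODONS) next  # keep stops (terminal) intact
    for (p in 1:3) {
      if (stats::runif(1) >= divergence) next
      codon_now <- paste(chars[idx], collapse = "")
      cand <- setdiff(DNA_BASES, chars[idx[p]])
      new_codons <- vapply(cand, function(b) {
        cc <- chars[idx]; cc[p] <- b; paste(cc, collapse = "")
      }, character(1))
      ok <- !new_codons %in% STOP_CODONS
      if (synonymous_only) {
        ok <- ok & vapply(new_codons, aa_of, character(1)) == aa_of(codon_now)
      }
      cand <- cand[ok]
      if (length(cand)) chars[idx[p]] <- sample(cand, 1)
    }
  }
  chars
}

#' Mutate a sequence copy to a target per-site divergence
#'
#' Substitution-only mutagenesis: every site is substituted with probability
#' `divergence`, drawing uniformly among the three other bases, so the
#' expected fraction of substituted sites equals `divergence`. In codon-aware
#' mode substitutions never create a stop codon (existing stop codons are left
#' untouched), and with `synonymous_only = TRUE` only synonymous changes are
#' accepted — useful for constructing pairs with Ka = 0.
#'
#' @param sequence a character scalar (DNA).
#' @param divergence per-site substitution proportion in `[0, 0.75)`.
#' @param seed optional integer seed making the call self-contained.
#' @param codon_aware treat the sequence as an in-frame CDS.
#' @param synonymous_only with `codon_aware`, restrict to synonymous changes.
#' @return the mutated sequence (character scalar).
#' @export
mutate_copy <- function(sequence, divergence, seed = NULL,
                        codon_aware = FALSE, synonymous_only = FALSE) {
  if (divergence < 0 || divergence >= 0.75) stop("divergence must lie in [0, 0.75)")
  run <- function() {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    chars <- if (codon_aware) {
      mutate_cds_chars(chars, divergence, synonymous_only)
    } else {
      mutate_dna_chars(chars, divergence)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

type_counts <- function(config) {
  p <- c(SOR = config$p_sor, triplet = config$p_triplet, dyad = config$p_dyad,
         IP = config$p_ip, singleton = config$p_singleton)
  n <- config$n_families
  k <- floor(p * n)
  rem <- n - sum(k)
  if (rem > 0) {
    frac <- p * n - k
    ord <- order(-frac, names(p))  # deterministic remainder assignment
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  k
}

#' Simulate a three-subgenome genome with known homolog-family truth
#'
#' Families are laid down in a common ancestral order on one chromosome per
#' subgenome, so unshuffled genes are collinear between subgenomes; a seeded
#' random fraction of non-tandem genes is then relocated to break
#' collinearity. Single-copy ortholog families emit exactly one gene per
#' subgenome; triplets one per subgenome with one subgenome carrying a tandem
#' array; dyads occupy exactly two subgenomes; inparalogs one subgenome with a
#' tandem array; singletons are unrelated random sequences. Each gene consists
#' of a family-derived 2 kb upstream region placed beside a gene body
#' (5'UTR + CDS + 3'UTR), separated from its neighbour by random filler so
#' upstream regions never overlap. CDS mutations are codon-aware and never
#' introduce stop codons.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, `genome.fa`, `genes.gff3`
#'   and `truth.tsv` are written there.
#' @return list with `genes` (a `gene_set` carrying the genome), and `truth`
#'   (data.frame: `gene_id`, `family_id`, `type`, `subgenome`, `tandem_index`,
#'   `specific`, `tissue`).
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_impl(config, out_dir))
}

simulate_genome_impl <- function(config, out_dir) {
  rl <- config$region_lengths
  sgs <- config$subgenomes
  counts <- type_counts(config)
  types <- sample(rep(names(counts), counts))  # interleave types along order

  ## per-subgenome ordered slot lists; each slot = one gene record
  slots <- stats::setNames(lapply(sgs, function(x) list()), sgs)
  truth <- list()

  make_regions <- function() list(
    upstream = random_dna(rl[["upstream"]]),
    utr5 = random_dna(rl[["utr5"]]),
    cds = random_cds(rl[["cds"]]),
    utr3 = random_dna(rl[["utr3"]])
  )
  mutate_regions <- function(regions, d) list(
    upstream = paste(mutate_dna_chars(strsplit(regions$upstream, "")[[1]], d),
                     collapse = ""),
    utr5 = paste(mutate_dna_chars(strsplit(regions$utr5, "")[[1]], d),
                 collapse = ""),
    cds = paste(mutate_cds_chars(strsplit(regions$cds, "")[[1]], d),
                collapse = ""),
    utr3 = paste(mutate_dna_chars(strsplit(regions$utr3, "")[[1]], d),
                 collapse = "")
  )

  for (fi in seq_along(types)) {
    fam_id <- sprintf("FAM%04d", fi)
    ftype <- types[fi]
    anc <- make_regions()
    d_b <- config$between_subgenome_divergence
    d_t <- config$tandem_divergence

    emit <- function(sg, copy_regions, tandem_index, tandem_group) {
      gid <- sprintf("%s_%s%d", fam_id, sg, tandem_index)
      slots[[sg]][[length(slots[[sg]]) + 1L]] <<- list(
        gene_id = gid, family = fi, regions = copy_regions,
        strand = if (stats::runif(1) < config$p_minus_strand) "-" else "+",
        tandem_group = tandem_group
      )
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = gid, family_id = fam_id, type = ftype, subgenome = sg,
        tandem_index = tandem_index, stringsAsFactors = FALSE
      )
    }

    if (ftype == "SOR") {
      for (sg in sgs) emit(sg, mutate_regions(anc, d_b), 1L, NA_character_)
    } else if (ftype == "triplet") {
      dup_sg <- sgs[(fi %% length(sgs)) + 1L]
      for (sg in sgs) {
        base <- mutate_regions(anc, d_b)
        emit(sg, base, 1L,
             if (sg == dup_sg) paste0(fam_id, sg) else NA_character_)
        if (sg == dup_sg) {
          for (k in seq_len(config$tandem_copies - 1L)) {
            emit(sg, mutate_regions(base, d_t), k + 1L, paste0(fam_id, sg))
          }
        }
      }
    } else if (ftype == "dyad") {
      pair <- sgs[((fi + 0:1) %% length(sgs)) + 1L]
      for (sg in pair) emit(sg, mutate_regions(anc, d_b), 1L, NA_character_)
    } else if (ftype == "IP") {
      sg <- sgs[(fi %% length(sgs)) + 1L]
      base <- mutate_regions(anc, d_b)
      emit(sg, base, 1L, paste0(fam_id, sg))
      for (k in seq_len(config$tandem_copies - 1L)) {
        emit(sg, mutate_regions(base, d_t), k + 1L, paste0(fam_id, sg))
      }
    } else {  # singleton: unrelated random sequence
      sg <- sgs[(fi %% length(sgs)) + 1L]
      emit(sg, make_regions(), 1L, NA_character_)
    }
  }

  ## shuffle a fraction of non-tandem genes within each chromosome
  for (sg in sgs) {
    sl <- slots[[sg]]
    n <- length(sl)
    movable <- which(vapply(sl, function(x) is.na(x$tandem_group), logical(1)))
    n_move <- floor(config$shuffle_fraction * n)
    if (n_move > 0 && length(movable) >= n_move) {
      move <- movable[sample.int(length(movable), n_move)]
      rest <- sl[-move]
      for (m in move[sample.int(length(move))]) {
        pos <- sample.int(length(rest) + 1L, 1L)
        rest <- append(rest, sl[m], after = pos - 1L)
      }
      slots[[sg]] <- rest
    }
  }

  ## lay out chromosome sequences and gene/feature tables
  filler_len <- 1000L
  gene_rows <- list(); feat_rows <- list(); chrom_seqs <- character(0)
  for (sg in sgs) {
    chrom <- paste0("1", sg)
    parts <- character(0)
    pos <- 0L
    for (g in slots[[sg]]) {
      body <- paste0(g$regions$utr5, g$regions$cds, g$regions$utr3)
      up <- g$regions$upstream
      filler <- random_dna(filler_len)
      if (g$strand == "+") {
        block <- paste0(filler, up, body)
        gstart <- pos + filler_len + nchar(up)
        gend <- gstart + nchar(body)
        u5 <- c(gstart, gstart + rl[["utr5"]])
        cd <- c(u5[2], u5[2] + rl[["cds"]])
        u3 <- c(cd[2], cd[2] + rl[["utr3"]])
      } else {
        rc <- function(s) as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(s)))
        block <- paste0(filler, rc(body), rc(up))
        gstart <- pos + filler_len
        gend <- gstart + nchar(body)
        u3 <- c(gstart, gstart + rl[["utr3"]])
        cd <- c(u3[2], u3[2] + rl[["cds"]])
        u5 <- c(cd[2], cd[2] + rl[["utr5"]])
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, chromosome = chrom, subgenome = sg,
        strand = g$strand, start = gstart, end = gend,
        stringsAsFactors = FALSE)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id,
        type = c("utr5", "cds", "utr3"),
        start = c(u5[1], cd[1], u3[1]),
        end = c(u5[2], cd[2], u3[2]),
        stringsAsFactors = FALSE)
      parts <- c(parts, block)
      pos <- pos + nchar(block)
    }
    chrom_seqs[chrom] <- paste(parts, collapse = "")
  }

  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chromosome,
                           FUN = seq_along)
  rownames(genes) <- NULL
  features <- do.call(rbind, feat_rows)
  genome <- Biostrings::DNAStringSet(chrom_seqs)

  genes <- structure(genes, features = features, genome = genome,
                     class = c("gene_set", "data.frame"))

  truth <- do.call(rbind, truth)
  truth$specific <- FALSE
  truth$tissue <- NA_character_
  n_spec <- min(config$n_specific_genes, nrow(truth))
  spec_idx <- sample(nrow(truth), n_spec)
  truth$specific[spec_idx] <- TRUE
  truth$tissue[spec_idx] <- paste0("T", sample(config$n_tissues, n_spec,
                                               replace = TRUE))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation(genes, file.path(out_dir, "genes.gff3"),
                     file.path(out_dir, "genome.fa"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(genes = genes, truth = truth)
}

#' Simulate tissue-structured expression for a synthetic genome
#'
#' Designated tissue-specific genes express at a high level in exactly one
#' tissue and zero elsewhere; all other genes express near-uniformly across
#' tissues. Noise is multiplicative lognormal (seeded), so specific genes stay
#' specific and the tissue-specificity index τ hits its design limits (1 for
#' specific genes, near 0 for broad ones) up to noise.
#'
#' @param config a [sim_config()].
#' @param truth the truth table from [simulate_genome()].
#' @return an `expression_matrix` (genes × samples, FPKM-like scale) with a
#'   sample→tissue map.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    tissues <- paste0("T", seq_len(config$n_tissues))
    samples <- as.vector(outer(tissues, seq_len(config$n_reps),
                               function(t, r) paste0(t, "_r", r)))
    sample_tissue <- stats::setNames(sub("_r[0-9]+$", "", samples), samples)
    mat <- matrix(0, nrow = nrow(truth), ncol = length(samples),
                  dimnames = list(truth$gene_id, samples))
    for (i in seq_len(nrow(truth))) {
      base <- if (truth$specific[i]) {
        ifelse(sample_tissue == truth$tissue[i], 100, 0)
      } else {
        rep(50, length(samples))
      }
      noise <- stats::rlnorm(length(samples), meanlog = 0,
                             sdlog = config$expression_noise_sd)
      mat[i, ] <- base * noise
    }
    expression_matrix(mat, sample_tissue)
  })
}
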