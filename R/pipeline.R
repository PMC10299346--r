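#' Core genome analysis: homology, families, synteny, classification
#'
#' Runs the within-genome stages in dependency order: all-vs-all search over
#' CDS (or supplied) sequences, hit filtering, family clustering, homolog-type
#' classification, synteny-block detection over the filtered homolog pairs,
#' and outparalog identification among triplets.
#'
#' @param genes a `gene_set`.
#' @param seqs optional named sequences to search (default: spliced CDS).
#' @param search_type `"nucleotide"` or `"protein"`.
#' @param min_identity identity threshold for homology edges.
#' @param min_coverage coverage threshold for homology edges; the built-in
#'   search computes no e-value, so a coverage floor takes the e-value
#'   cutoff's role of discarding short spurious local matches.
#' @param min_block_size,max_gap synteny chaining parameters.
#' @param op_rule outparalog connectivity rule, see [identify_op_families()].
#' @param cluster_method family clustering method.
#' @return list with `hits`, `filtered_hits`, `families`, `classification`
#'   (with `is_OP`), `op_genes`, `blocks`, `collinear_pairs`, `census`.
#' @export
analyze_genome <- function(genes, seqs = NULL, search_type = "nucleotide",
                           min_identity = 70, min_coverage = 50,
                           min_block_size = 3L,
                           max_gap = 25L, op_rule = "span3",
                           cluster_method = "components") {
  if (is.null(seqs)) seqs <- gene_sequences(genes, "cds")
  hits <- all_vs_all(seqs, type = search_type)
  filtered <- filter_hits(hits, min_identity = min_identity,
                          min_coverage = min_coverage)
  families <- cluster_families(filtered, genes$gene_id,
                               method = cluster_method)
  classification <- classify_families(families, genes)
  pairs <- homolog_pairs(filtered)
  blocks <- detect_blocks(genes, pairs, min_block_size = min_block_size,
                          max_gap = max_gap)
  coll <- collinear_pair_set(blocks)
  op <- identify_op_families(classification, families, genes, coll,
                             rule = op_rule)
  cen <- census(op$families, total_genes = nrow(genes),
                op_genes = op$op_genes)
  list(hits = hits, filtered_hits = filtered, families = families,
       classification = op$families, op_genes = op$op_genes,
       blocks = blocks, collinear_pairs = coll, census = cen)
}

#' Homolog pairs by class (IP tandem pairs, OP cross-subgenome pairs)
#'
#' Builds the pair sets whose Ka/Ks distributions date the two duplication
#' modes: within-subgenome pairs of inparalog families (`"IP"`) and
#' cross-subgenome pairs of outparalog-flagged triplet families (`"OP"`,
#' restricted to collinear members when an OP gene list is given).
#'
#' @param analysis output of [analyze_genome()].
#' @param genes the `gene_set`.
#' @return data.frame `gene_a`, `gene_b`, `class`.
#' @export
class_pairs <- function(analysis, genes) {
  fams <- analysis$families
  cls <- analysis$classification
  sg <- stats::setNames(genes$subgenome, genes$gene_id)
  out <- list()
  for (f in cls$family_id[cls$type == "IP"]) {
    members <- sort(fams$gene_id[fams$family_id == f])
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    out[[length(out) + 1L]] <- data.frame(
      gene_a = cmb[1, ], gene_b = cmb[2, ], class = "IP",
      stringsAsFactors = FALSE)
  }
  op_fams <- if (is.null(cls$is_OP)) character(0) else
    cls$family_id[cls$is_OP]
  for (f in op_fams) {
    members <- sort(fams$gene_id[fams$family_id == f])
    if (!is.null(analysis$op_genes)) {
      members <- intersect(members, analysis$op_genes)
    }
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    cross <- sg[cmb[1, ]] != sg[cmb[2, ]]
    if (!any(cross)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_a = cmb[1, cross], gene_b = cmb[2, cross], class = "OP",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      class = character(0)))
  }
  do.call(rbind, out)
}

#' Ka/Ks for a classed pair table
#'
#' @param pairs data.frame `gene_a`, `gene_b`, `class`.
#' @param cds named CDS sequences covering the paired genes.
#' @return data.frame of [kaks()] rows with the `class` column attached.
#' @export
kaks_for_pairs <- function(pairs, cds) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!(a %in% names(cds)) || !(b %in% names(cds))) return(NULL)
    r <- kaks_pair(as.character(cds[[a]]), as.character(cds[[b]]),
                   id_a = a, id_b = b)
    r$class <- pairs$class[i]
    r
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- kaks(list(codons_a = "AAA", codons_b = "AAA"))[0, ]
    out$class <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}

pipeline_stages <- c("load", "homology", "classify", "diversity", "kaks",
                     "expression", "report")

config_checksum <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full intra-varietal diversity pipeline
#'
#' Executes the stages in dependency order — load (or simulate) → homology →
#' synteny/classification → diversity → Ka/Ks → expression → report — and
#' persists TSV reports plus a JSON run manifest recording every threshold
#' and decision taken (op rule, π mode, identity cutoffs, seed). When the
#' output directory already contains a manifest with the same configuration
#' checksum, the run is skipped and previous outputs are kept (idempotent
#' reruns). Stages whose inputs are absent (e.g. no expression matrix) are
#' skipped with a notice in the manifest.
#'
#' @param config list. Either `sim` (a [sim_config()]) or `gff3` + `fasta`
#'   paths; optional `expression` (an `expression_matrix` or TSV path with
#'   `sample_map`), `trait_genes` (data.frame `gene_id`, `trait`), and
#'   overrides `min_identity`, `min_block_size`, `max_gap`, `op_rule`,
#'   `pi_mode`, `regions`, `ks_max`.
#' @param out_dir output directory for reports and the manifest.
#' @return invisibly, a list with all stage results plus `skipped` (logical).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  checksum <- config_checksum(config)
  manifest_file <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_file)) {
    prev <- jsonlite::read_json(manifest_file)
    if (identical(prev$config_checksum, checksum) &&
        file.exists(file.path(out_dir, "census.tsv"))) {
      message("configuration unchanged; outputs kept, stages skipped")
      return(invisible(list(skipped = TRUE, manifest = prev)))
    }
  }

  p <- function(name, default) config[[name]] %||% default
  min_identity <- p("min_identity", 70)
  min_block_size <- p("min_block_size", 3L)
  max_gap <- p("max_gap", 25L)
  op_rule <- p("op_rule", "span3")
  pi_mode <- p("pi_mode", "pairdiff")
  regions <- p("regions", c("upstream2kb", "utr5", "cds", "utr3"))
  ks_max <- p("ks_max", 3)
  notices <- character(0)

  ## -- load / simulate --
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_genome(config$sim)
    genes <- sim$genes
    truth <- sim$truth
  } else if (!is.null(config$gff3) && !is.null(config$fasta)) {
    genes <- read_annotation(config$gff3, config$fasta,
                             p("subgenome_pattern", "[0-9]([ABD])$"))
  } else {
    stop("stage 'load' failed: config needs either 'sim' or 'gff3'+'fasta'")
  }

  ## -- homology + synteny + classification --
  analysis <- analyze_genome(genes, min_identity = min_identity,
                             min_block_size = min_block_size,
                             max_gap = max_gap, op_rule = op_rule)

  ## -- diversity --
  type_of <- stats::setNames(analysis$classification$type,
                             analysis$classification$family_id)
  multi <- analysis$classification$family_id[
    analysis$classification$n_genes >= 2]
  fam_sub <- analysis$families[analysis$families$family_id %in% multi, ]
  pi_tab <- family_region_pi(genes, fam_sub, regions = regions,
                             mode = pi_mode)
  pi_tab$type <- unname(type_of[pi_tab$family_id])
  pi_tab$type[pi_tab$family_id %in%
                analysis$classification$family_id[
                  analysis$classification$is_OP]] <- "OP"
  diversity <- summarize_diversity(pi_tab)

  ## -- Ka/Ks --
  cds <- gene_sequences(genes, "cds")
  cpairs <- class_pairs(analysis, genes)
  kaks_res <- if (nrow(cpairs)) {
    ks_filter_and_summarize(kaks_for_pairs(cpairs, cds), ks_max = ks_max)
  } else {
    notices <- c(notices, "kaks: no IP/OP pairs, stage skipped")
    NULL
  }

  ## -- expression --
  expr_res <- NULL
  em <- NULL
  if (!is.null(config$expression)) {
    em <- if (inherits(config$expression, "expression_matrix")) {
      config$expression
    } else {
      read_expression(config$expression, config$sample_map)
    }
  } else if (!is.null(config$sim) && isTRUE(p("simulate_expression", TRUE))) {
    em <- simulate_expression(config$sim, truth)
  }
  if (!is.null(em)) {
    expr_res <- list(tau = tau_table(em),
                     divergence = family_divergence(analysis$families, em))
  } else {
    notices <- c(notices, "expression: no matrix supplied, stage skipped")
  }

  ## -- trait crosstab --
  trait_res <- NULL
  if (!is.null(config$trait_genes)) {
    gene_types <- merge(analysis$families, analysis$classification,
                        by = "family_id")[, c("gene_id", "type")]
    trait_res <- crosstab_trait_genes(config$trait_genes, gene_types)
  }

  results <- list(genes = genes, truth = truth, analysis = analysis,
                  pi_table = pi_tab, diversity = diversity,
                  kaks = kaks_res, expression = expr_res, trait = trait_res,
                  skipped = FALSE)
  manifest <- list(
    tool = "polyivd",
    version = as.character(utils::packageVersion("polyivd")),
    config_checksum = checksum,
    parameters = list(min_identity = min_identity,
                      min_block_size = min_block_size, max_gap = max_gap,
                      op_rule = op_rule, pi_mode = pi_mode,
                      regions = regions, ks_max = ks_max,
                      seed = if (!is.null(config$sim)) config$sim$seed else NULL),
    notices = notices)
  write_reports(results, out_dir, manifest = manifest)
  invisible(results)
}

#' Write pipeline reports
#'
#' Emits TSV tables mirroring the census / diversity / trait / Ka-Ks layouts
#' (percentages printed to one decimal, π to four decimals) plus the JSON
#' manifest. An empty trait list still produces a header-only trait file.
#'
#' @param results list from [run_pipeline()] (needs at least `analysis`).
#' @param out_dir output directory.
#' @param manifest optional manifest list to serialise alongside.
#' @return invisibly, `out_dir`.
#' @export
write_reports <- function(results, out_dir, manifest = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cen <- results$analysis$census
  cen_out <- data.frame(type = cen$type, families = cen$families,
                        genes = cen$genes,
                        percent = sprintf("%.1f", cen$percent))
  utils::write.table(cen_out, file.path(out_dir, "census.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (!is.null(results$pi_table)) {
    pt <- results$pi_table
    pt$pi <- sprintf("%.4f", pt$pi)
    utils::write.table(pt[, setdiff(names(pt), "msa")],
                       file.path(out_dir, "diversity_per_family.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ds <- results$diversity$by_type_region
    ds$mean_pi <- sprintf("%.4f", ds$mean_pi)
    ds$median_pi <- sprintf("%.4f", ds$median_pi)
    utils::write.table(ds, file.path(out_dir, "diversity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(results$kaks)) {
    utils::write.table(results$kaks$filtered,
                       file.path(out_dir, "kaks_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(results$kaks$summary,
                       file.path(out_dir, "kaks_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(results$expression)) {
    utils::write.table(results$expression$tau,
                       file.path(out_dir, "tau.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(results$expression$divergence,
                       file.path(out_dir, "expression_divergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  trait_file <- file.path(out_dir, "trait_crosstab.tsv")
  if (!is.null(results$trait) && length(results$trait$counts)) {
    tc <- as.data.frame.matrix(results$trait$counts)
    tc <- cbind(trait = rownames(tc), tc)
    utils::write.table(tc, trait_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    writeLines("trait\tOP\tSOR\tIP\tsingleton", trait_file)
  }

  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out_dir)
}
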