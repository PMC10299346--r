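#' Classify a family's homolog type from its subgenome occupancy
#'
#' The type taxonomy partitions families by which subgenomes they occupy:
#' inparalogs (`IP`) are duplicated genes confined to a single subgenome;
#' `dyad` families occupy exactly two subgenomes; `triplet` families occupy
#' all three with more than three total copies; single-copy orthologs (`SOR`)
#' have exactly one copy in each subgenome; a `singleton` has one copy in
#' total. Members with unresolved subgenomes are excluded from occupancy; a
#' family emptied by that exclusion is labelled `unclassified`.
#'
#' @param occupancy named integer vector of copy counts per subgenome (counts
#'   for unknown subgenomes must already be excluded).
#' @return one of `"IP"`, `"dyad"`, `"triplet"`, `"SOR"`, `"singleton"`,
#'   `"unclassified"`.
#' @export
classify_family <- function(occupancy) {
  occupancy <- occupancy[occupancy > 0]
  n_sub <- length(occupancy)
  total <- sum(occupancy)
  if (n_sub == 0L) return("unclassified")
  if (total == 1L) return("singleton")
  if (n_sub == 1L) return("IP")
  if (n_sub == 2L) return("dyad")
  if (total == 3L) return("SOR")
  "triplet"
}

#' Classify every family in a clustering
#'
#' @param families a `homolog_families` table.
#' @param genes a `gene_set` (or data.frame with `gene_id`, `subgenome`).
#' @param subgenomes subgenome labels.
#' @return data.frame `family_id`, `type`, `n_genes`, plus one occupancy
#'   column per subgenome.
#' @export
classify_families <- function(families, genes, subgenomes = c("A", "B", "D")) {
  occ <- family_occupancy(families, genes, subgenomes)
  if (any(occ$n_unknown > 0)) {
    warning(sum(occ$n_unknown),
            " gene(s) on unknown subgenomes excluded from occupancy")
  }
  occ$type <- apply(occ[, subgenomes, drop = FALSE], 1, function(x)
    classify_family(stats::setNames(as.integer(x), subgenomes)))
  occ[, c("family_id", "type", "n_genes", subgenomes)]
}

#' Flag outparalog families among triplets via cross-subgenome collinearity
#'
#' A triplet family is an outparalog (OP) family when its cross-subgenome
#' collinear links connect members of all three subgenomes into a single
#' component (`rule = "span3"`, the default); `rule = "any-pair"` relaxes
#' this to at least one cross-subgenome collinear link. The OP gene list
#' contains the members participating in those links.
#'
#' @param classification output of [classify_families()].
#' @param families the `homolog_families` table.
#' @param genes a `gene_set`.
#' @param collinear_pairs data.frame from [collinear_pair_set()].
#' @param rule `"span3"` or `"any-pair"`.
#' @return list with `families` (the classification table plus an `is_OP`
#'   column) and `op_genes` (character vector).
#' @export
identify_op_families <- function(classification, families, genes,
                                 collinear_pairs,
                                 rule = c("span3", "any-pair")) {
  rule <- match.arg(rule)
  sg <- stats::setNames(genes$subgenome, genes$gene_id)
  pair_key <- paste(collinear_pairs$gene_a, collinear_pairs$gene_b)
  classification$is_OP <- FALSE
  op_genes <- character(0)

  for (f in classification$family_id[classification$type == "triplet"]) {
    members <- families$gene_id[families$family_id == f]
    if (length(members) < 2) next
    combs <- utils::combn(sort(members), 2)
    keys <- paste(combs[1, ], combs[2, ])
    coll <- combs[, keys %in% pair_key, drop = FALSE]
    if (!ncol(coll)) next
    cross <- sg[coll[1, ]] != sg[coll[2, ]]
    coll <- coll[, cross, drop = FALSE]
    if (!ncol(coll)) next
    is_op <- if (rule == "any-pair") TRUE else {
      g <- igraph::graph_from_edgelist(t(coll), directed = FALSE)
      memb <- igraph::components(g)$membership
      any(vapply(split(names(memb), memb), function(m)
        length(unique(sg[m])) == 3L, logical(1)))
    }
    if (is_op) {
      classification$is_OP[classification$family_id == f] <- TRUE
      op_genes <- c(op_genes, unique(as.vector(coll)))
    }
  }
  list(families = classification, op_genes = sort(unique(op_genes)))
}

#' Homolog census from family/gene counts per type
#'
#' Pure census arithmetic on a counts table: percentages are gene counts over
#' the genome total (×100), with aggregate rows for paralogs (IP + dyad +
#' triplet) and the homolog total (paralogs + SOR). This is the operation
#' behind the census report, and it reproduces a published census table's
#' percentages from its printed counts.
#'
#' @param counts data.frame with columns `type` (`IP`, `dyad`, `triplet`,
#'   `SOR`, and optionally `OP`, `singleton`), `families`, `genes`.
#' @param total_genes genome-wide gene count (the percentage denominator).
#' @return data.frame of class `homolog_census` with columns `type`,
#'   `families`, `genes`, `percent`, including `paralogs` and `total_homolog`
#'   aggregate rows.
#' @export
census_from_counts <- function(counts, total_genes) {
  stopifnot(all(c("type", "families", "genes") %in% names(counts)))
  paralog_types <- c("IP", "dyad", "triplet")
  par_row <- data.frame(
    type = "paralogs",
    families = sum(counts$families[counts$type %in% paralog_types]),
    genes = sum(counts$genes[counts$type %in% paralog_types]),
    stringsAsFactors = FALSE)
  sor_genes <- sum(counts$genes[counts$type == "SOR"])
  sor_fams <- sum(counts$families[counts$type == "SOR"])
  tot_row <- data.frame(type = "total_homolog",
                        families = par_row$families + sor_fams,
                        genes = par_row$genes + sor_genes,
                        stringsAsFactors = FALSE)
  out <- rbind(counts[, c("type", "families", "genes")], par_row, tot_row)
  out$percent <- 100 * out$genes / total_genes
  out$total_genes <- total_genes
  class(out) <- c("homolog_census", "data.frame")
  out
}

#' Census of a classified genome
#'
#' Tabulates families and genes per homolog type from a classification and
#' delegates the percentage arithmetic to [census_from_counts()]. When an OP
#' flag is present (see [identify_op_families()]) an `OP` row reports the
#' OP families and their collinear gene count.
#'
#' @param classification output of [classify_families()], optionally with an
#'   `is_OP` column.
#' @param total_genes genome-wide gene count; defaults to the number of
#'   classified genes.
#' @param op_genes optional OP gene list (for the `OP` row's gene count).
#' @return a `homolog_census` data.frame.
#' @export
census <- function(classification, total_genes = NULL, op_genes = NULL) {
  if (is.null(total_genes)) total_genes <- sum(classification$n_genes)
  types <- c("IP", "dyad", "triplet", "SOR", "singleton")
  counts <- do.call(rbind, lapply(types, function(t) {
    sel <- classification$type == t
    data.frame(type = t, families = sum(sel),
               genes = sum(classification$n_genes[sel]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(classification$is_OP)) {
    counts <- rbind(counts, data.frame(
      type = "OP", families = sum(classification$is_OP),
      genes = if (!is.null(op_genes)) length(op_genes) else
        sum(classification$n_genes[classification$is_OP]),
      stringsAsFactors = FALSE))
  }
  census_from_counts(counts, total_genes)
}

#' Cross-tabulate trait genes against homolog types
#'
#' Maps a list of trait-annotated genes (e.g. cloned agronomic genes) to
#' their homolog types and tabulates counts per trait and type. Genes absent
#' from the type assignment are reported separately, not dropped silently.
#'
#' @param trait_genes data.frame with columns `gene_id`, `trait`.
#' @param gene_types data.frame with columns `gene_id`, `type`.
#' @return list with `counts` (trait × type matrix), `unmapped` (character
#'   vector), and `ratios` (see [trait_ratios()]).
#' @export
crosstab_trait_genes <- function(trait_genes, gene_types) {
  if (!nrow(trait_genes)) {
    return(list(counts = matrix(integer(0), 0, 0), unmapped = character(0),
                ratios = NULL))
  }
  type <- gene_types$type[match(trait_genes$gene_id, gene_types$gene_id)]
  unmapped <- trait_genes$gene_id[is.na(type)]
  ok <- !is.na(type)
  counts <- table(trait = trait_genes$trait[ok], type = type[ok])
  counts <- unclass(counts)
  list(counts = counts, unmapped = unmapped, ratios = trait_ratios(counts))
}

#' Type shares of a trait × type count table
#'
#' `ratio1` is each type's total over the full gene list (the share of the
#' listed genes belonging to that type); `op_sor_share_pct` is the combined
#' OP + SOR percentage. Works directly on printed count tables.
#'
#' @param counts trait × type count matrix (types as columns).
#' @return list with `type_totals`, `list_total`, `ratio1` (named numeric),
#'   and `op_sor_share_pct`.
#' @export
trait_ratios <- function(counts) {
  type_totals <- colSums(counts)
  list_total <- sum(counts)
  ratio1 <- type_totals / list_total
  opsor <- sum(type_totals[colnames(counts) %in% c("OP", "OPs", "SOR", "SORs")])
  list(type_totals = type_totals, list_total = list_total, ratio1 = ratio1,
       op_sor_share_pct = 100 * opsor / list_total)
}
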