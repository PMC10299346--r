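#' Published wheat intra-varietal homolog statistics bundled with the package
#'
#' Plain-text copies of the published genome-scale statistics for the wheat
#' varieties AK58 and Chinese Spring (and related Triticeae genomes): the
#' homolog census counts per type, the per-type per-region nucleotide
#' diversities, the per-species region diversities, the cloned agronomic-gene
#' crosstab counts, and the expansion-family counts for wheat, rice, maize
#' and millet. These are *inputs* to the package's reporting arithmetic —
#' the census, diversity-average and crosstab operations recompute every
#' derived percentage and average from them — and serve as a desk-scale
#' stand-in for the full genome analyses they summarise.
#'
#' @return named list of data.frames: `census_counts`, `genome_totals`,
#'   `region_pi`, `species_region_pi`, `trait_counts` (trait × type matrix),
#'   `expansion_counts` (named integer vector).
#' @export
wheat_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "polyivd",
                                  mustWork = TRUE)
  rd <- function(f) utils::read.table(path(f), header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE)
  trait <- rd("trait_crosstab_counts.tsv")
  trait_counts <- as.matrix(trait[, -1])
  rownames(trait_counts) <- trait$trait
  exp_tab <- rd("expansion_family_counts.tsv")
  list(
    census_counts = rd("wheat_census_counts.tsv"),
    genome_totals = rd("wheat_genome_totals.tsv"),
    region_pi = rd("wheat_region_pi.tsv"),
    species_region_pi = rd("species_region_pi.tsv"),
    trait_counts = trait_counts,
    expansion_counts = stats::setNames(exp_tab$expansion_families,
                                       exp_tab$genome)
  )
}
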