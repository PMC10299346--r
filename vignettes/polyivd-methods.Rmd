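---
title: "Methods: intra-varietal homolog diversity analysis with polyivd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-varietal homolog diversity analysis with polyivd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Allopolyploid crops such as hexaploid bread wheat carry three ancestral
diploid genome complements (subgenomes A, B and D) inside every variety.
A large share of such a genome's genes therefore have *homologs within the
same variety* — cross-subgenome orthologs/outparalogs from the ancient
speciation-and-merger events and tandem inparalogs from later, local
duplications. The diversity among these copies (in sequence, expression and
function) is a within-genome reservoir of variation that conventional,
between-accession allele diversity analysis never looks at. `polyivd`
implements that intra-varietal analysis as a reusable, testable pipeline.

## Homolog taxonomy

Genes are clustered into families from an all-vs-all similarity search
(identity ≥ 70%, best hit per ordered pair, connected components by
default with a Markov-cluster-like option), then each family is typed by
its *subgenome occupancy*:

| type      | occupancy rule                                            |
|-----------|-----------------------------------------------------------|
| singleton | one copy in total                                          |
| IP        | ≥ 2 copies, all in one subgenome (inparalogs, tandem)      |
| dyad      | exactly two subgenomes occupied                            |
| SOR       | exactly one copy in each of the three subgenomes           |
| triplet   | all three subgenomes occupied, more than three copies      |
| OP        | triplet whose cross-subgenome collinear links span A, B, D |

Two boundaries deserve comment. First, the SOR/triplet boundary is strict:
any family covering three subgenomes with more than three members is a
triplet — in the published wheat census the SOR gene/family ratio is exactly
3.0, which forces this reading. Second, a family occupying two subgenomes
with extra tandem copies (say A:2, B:1) is a dyad, not an inparalog:
"duplicated in two subgenomes" is read as occupancy. Genes whose chromosome
name does not resolve to a subgenome are excluded from occupancy but still
counted in the genome total, so census percentages keep the whole-genome
denominator.

The outparalog (OP) rule is configurable. The definition — paralogs with
collinearity between subgenomes in triplets — does not say whether one
collinear pair suffices. The default (`span3`) requires the family's
cross-subgenome collinear links to connect members of all three subgenomes
into one component; `any-pair` accepts a single link. `span3` was chosen as
the stricter, more specific reading; the choice is recorded in the run
manifest. The OP gene list contains only members that participate in
collinear links, so extra tandem copies inside an OP family are not counted
as OP genes.

## Collinearity

Synteny blocks are found by weighted longest-chain dynamic programming over
homologous gene pairs ordered by their gene *rank* (ordinal position along
the chromosome, ties broken by gene id). Each pair scores +1; rank gaps are
penalised at 0.1 per skipped gene and capped at 25 genes; chains shorter
than 3 pairs are discarded; both orientations are searched by negating the
second chromosome's ranks; chains are extracted greedily by score with ties
resolved toward the leftmost start. Only the minimum block size (3) comes
from the original analysis protocol; the gap cap and penalty mirror common
defaults of collinearity tools and are package decisions, recorded in the
manifest. Tandem arrays (homologous genes at adjacent ranks on one
chromosome) are collapsed to their lowest-rank member before chaining so
that arrays cannot masquerade as within-chromosome blocks; reported block
pairs are between those representatives, which is consistent with counting
only collinear members as OP genes.

## The π statistic

Within each family, every gene region — 2 kb upstream, 5′UTR, CDS, 3′UTR
(and optionally the whole gene body) — is multiply aligned with a
deterministic center-star method (center = longest member, ties by id;
pairwise global alignments merged on the center's coordinates). Columns
containing a gap or an ambiguity code are excluded everywhere, defining the
effective length *L*. Diversity is

π = 2·X / (L·D·(D−1)),

with *D* the alignment depth. Two readings of *X* are provided. The
default (`pairdiff`) counts the total pairwise differences over effective
columns, which makes π the mean pairwise per-site difference — Nei's
nucleotide diversity, since D·(D−1)/2 is the number of sequence pairs. The
`literal` mode counts variant columns instead; because then X ≤ L, that
reading caps π at 2/(D·(D−1)) — 1/3 at depth 3 — which is incompatible
with per-region diversities above 0.4 reported for diverged outparalog
families, so it cannot be what the published figures used. Both modes
coincide at depth 2. Per-type averages are computed family-first: π per
family per region, means per type × region, and a per-type "average" as the
mean of the four region means — this row-mean convention exactly reproduces
the published per-type average columns from their printed region values.

## Ka/Ks

Duplication ages are compared through synonymous substitution rates.
Pairs are formed by reciprocal best hit (e-value < 1e-5 where available,
identity > 60%, coverage > 60%, all strict), codon-aligned through a global
protein alignment, and scored with NG86: per-codon synonymous site
fractions from the universal code averaged over both sequences (mutations
to stop codons are excluded from the fractions' denominators, so S + N
remains three sites per codon); multi-hit codons averaged over their
minimal mutational pathways, excluding pathways through stop codons when
avoidable; Jukes–Cantor correction with saturation (p ≥ 3/4) reported as
infinite. Pairs with Ks ≥ 3 are removed before summarising, and a
significance filter (Fisher exact test of sd/nd vs S/N, counts rounded to
integers) is available.

This is deliberately plain NG86, a counting method. The published wheat
analysis used a model-averaging estimator, whose per-pair values differ;
`polyivd` therefore treats only *class-level contrasts* (tandem inparalog
pairs young, cross-subgenome outparalog pairs old) as comparable across
methods, never the absolute published Ks values.

## Expression divergence

Tissue specificity uses the τ index: per-tissue means are divided by the
maximum tissue mean (dispersion normalisation; a max–min variant is
available by flag) and τ = Σ(1−Xi)/(n−1), 0 for uniform, 1 for
single-tissue expression; all-zero genes have no τ. A family's expression
divergence across copies is called when the coefficient of variation
exceeds 0.6 (strict) and the extreme |log2 fold change| is at least 1. A
pseudocount of 0.01 FPKM stabilises the fold change against zero-expression
copies; the source analysis states no pseudocount, so this is a package
decision. The associated p-value is a two-sided Wilcoxon rank-sum between
the extreme copies' replicate values when at least two replicates exist —
the original criterion's test is unspecified, so this choice is logged in
output metadata and the call otherwise rests on CV and fold change.
Co-expression module splitting takes a gene→module table as input (module
inference itself is out of scope; a simple correlation-clustering fallback
exists for synthetic tests), considers only families whose copies are all
assigned, and calls a family diverged when its copies occupy more than one
module. Term enrichment is a generic one-sided Fisher exact engine with
Bonferroni correction over tested terms.

## Expansion families

A family with five or more copies in a single genome is an expansion
family; copies are counted genome-wide regardless of subgenome (matching
how the published whole-genome expansion counts are framed), with
per-subgenome counts also available. Cross-genome families are clustered
with the same machinery at identity and query coverage > 70%, partitioned
into common (all genomes) and specific (one genome) sets. Comparisons
report percent excess, (a−b)/b·100, and dominant-expansion families whose
focal copy number is at least a chosen multiple (2× or 3×) of the *mean*
of the other genomes' copy numbers.

## The synthetic hexaploid generator

Every stage is testable without data downloads because the package can
generate a toy three-subgenome genome whose truth is known. The generator
emulates exactly the structure the analysis assumes: families of each type
with controlled occupancy; high divergence between subgenome copies versus
low divergence between tandem copies, mirroring the strong outparalog
versus inparalog Ks contrast (roughly 1.1 vs 0.09 in wheat); ancestral
gene order shared across subgenomes, with a seeded fraction of genes
relocated to give the chainer true negatives; the four-region gene
structure; and tissue-structured expression with designated
single-tissue-specific genes under multiplicative lognormal noise.

Defaults and why:

* **Type proportions** 0.40 SOR / 0.25 triplet / 0.10 dyad / 0.15 IP /
  0.10 singleton — the same ordering as the wheat census (SOR families most
  numerous, then triplets), compressed to toy scale.
* **Divergences** 0.10 per site between subgenome copies and the ancestor
  (≈ 0.19 pairwise, ≈ 81% identity) and 0.01 for tandem copies. The
  between-subgenome value is scaled so cross-subgenome pairs remain clearly
  inside the 70% identity detection threshold — the wheat contrast is
  emulated in *ordering*, not magnitude, because copies pushed toward the
  detection boundary would make truth-label recovery a coin flip by design.
* **Region lengths** upstream 2000, 5′UTR 150, CDS 900, 3′UTR 200 bp;
  ancestral sequences uniform over A/C/G/T. Intergenic filler keeps
  upstream regions from overlapping neighbours.
* **CDS mutations are codon-aware** and never create stop codons (a
  synonymous-only mode exists to construct Ka = 0 pairs); the terminal stop
  is kept fixed.
* **Expression**: specific genes at level 100 in exactly one tissue and 0
  elsewhere; broad genes at 50 everywhere; lognormal noise with sdlog 0.2;
  5 tissues × 2 replicates.

The simulation does *not* emulate indels, transposon insertion,
pseudogenization, fractionation, or realistic codon usage — so passing
tests demonstrate the pipeline's logic and statistics, not robustness to
the full messiness of real assemblies. The identity threshold, not a
homology post-check, isolates singletons; at these lengths accidental
homology between random sequences is vanishingly rare, and the search's
coverage floor (below) removes the short spurious matches that do occur.

## Numerical choices

* Internal coordinates are 0-based half-open; GFF3 conversion happens only
  at the I/O boundary. Gene rank is computed once at load, ties broken by
  gene id.
* The built-in all-vs-all search seeds candidate pairs with shared k-mers
  (nucleotide 11-mers, protein 4-mers, ≥ 5 shared) and aligns candidates
  with affine-gap dynamic programming (+1/−1, gap open 5 / extend 1 for
  nucleotide; BLOSUM62, 11/1 for protein). No e-value is computed: for
  built-in hits a coverage floor (50% by default in the pipeline) takes the
  e-value cutoff's role of discarding short spurious local matches, while
  the e-value criterion still applies to imported hit tables.
* On simulated genomes the pipeline searches nucleotide CDS rather than
  proteins: random codon substitutions at the simulator's divergence keep
  nucleotide identity near 81% but push protein identity below the 70%
  threshold, so the nucleotide mode is the one whose detection range the
  simulation is calibrated to. Protein mode remains the natural choice for
  real proteomes and is a flag away.
* Deterministic tie-breaks throughout: family ids by smallest member id,
  center-star center by length then id, best hits by score then identity
  then subject id, chain extraction by score then leftmost start.
* Reported percentages are printed to one decimal and π to four decimals,
  matching the published tables' precision; unrounded values are kept
  internally.

## Problem sizes and what the tests show

The test suite runs the full pipeline on a 30-family synthetic genome
(~83 genes) for module-level checks and a 100-family genome (~280 genes)
for the end-to-end properties (truth-label recovery ≥ 99%, median Ks of
inparalog pairs below outparalog pairs, π ordering). These sizes keep the
whole suite within minutes while leaving every code path exercised;
genome-scale inputs stream through the same functions. The published
genome-scale statistics (census shares, per-type π averages, cloned-gene
shares, expansion excess) are reproduced exactly from the bundled printed
tables by the same reporting operations the pipeline uses — they validate
the arithmetic, not a re-analysis of the wheat assemblies.

## Known limitations

* Connected-components clustering can chain families together through a
  promiscuous member; the MCL-like option mitigates but does not reproduce
  a dedicated Markov clustering implementation.
* Center-star alignment is exact enough for within-family divergences here
  but is not a progressive aligner; deep families with indel-rich regions
  would deserve an external MSA.
* NG86 saturates above p = 3/4 and the Fisher test on rounded fractional
  counts is approximate.
* The expression stage assumes an FPKM-like matrix; no normalisation or
  quantification is performed.
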