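---
title: "Comparing closely related genome assemblies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing closely related genome assemblies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napcomp)
```

`napcomp` addresses a deceptively simple question: when two genome
assemblies of the same species disagree about gene content, which
differences are biology and which are artefacts of assembly and
annotation? Its setting is a pair of homozygous crop cultivars — an
allopolyploid like *Brassica napus*, with two highly similar (homeologous)
subgenomes that aggravate every one of the failure modes below. This
vignette documents the models behind each stage, the parameters that
matter, what the synthetic benchmarks do and do not show, and the
numerical choices.

## Linkage-based contig placement

A draft reference leaves thousands of contigs unanchored. If a
doubled-haploid (DH) population derived from a biparental cross has been
skim-sequenced, every SNP locus carries a genotype vector over the
individuals, and loci that are physically close co-segregate. The
placement engine exploits this:

1. Anchored loci are grouped into fixed windows of `bin_bp` (default
   1 Mbp) and collapsed to a per-individual **consensus vector** (majority
   code; ties and all-missing become missing). Consensus-level comparison,
   rather than per-SNP comparison, is robust to the very high missingness
   of skim genotyping.
2. For each unplaced contig, the **recombination fraction**
   $r = \#\{\text{discordant}\} / \#\{\text{informative}\}$ is computed
   against every bin, undefined below `min_informative = 10` joint
   non-missing individuals.
3. The contig is **placed** at the midpoint of the bin minimizing $r$ when
   $r_{best} \le$ `r_max` (0.25) *and* the best bin on every other
   pseudomolecule trails by at least `delta_conflict` (0.05). A second
   pseudomolecule within that margin yields a **conflict**; the contig is
   never force-placed, because in an A/C allopolyploid a contig matching
   two chromosomes is exactly what homeologous sequence similarity (or a
   mis-called duplicated SNP) produces.

In a DH population unlinked loci sit near $r = 0.5$, so `r_max = 0.25`
excludes them by a wide margin; `min_informative = 10` keeps small-sample
flukes ($P(\hat r \le 0.25)$ under $r = 0.5$ is already < 0.06 at 10
informative individuals, and consensus vectors typically leave 40+) out of
the candidate set. Contigs whose best $r$ is defined but above `r_max`
have no status of their own in the four-way outcome (placed / no-SNP /
conflict / insufficient); they are reported as `insufficient`, i.e. no
usable linkage. Orientation is never inferred — genotypes carry no
orientation signal — so AGP records emit `?`, and the insertion
granularity is the anchor bin, not the base: finer placement would require
a genetic map, which is out of scope.

## Homology-based contig sorting

The second anchoring route needs only a related reference: each contig
≥ `min_contig_bp` (1 kbp) goes to the pseudomolecule of its best
alignment (e-value ≤ 1e-6), *unless* the runner-up on a different
pseudomolecule is within `ambiguity_window` (1%) of the best bit-score —
boundary inclusive, the stricter reading of "within 1%" — in which case
the contig stays unplaced. Multiple strong hits inside one pseudomolecule
(tandem repeats) never trigger ambiguity. Bit-score is the ranking key, as
the conventional alignment-quality statistic. Emitted scaffolds
concatenate placed contigs by target position with cosmetic 100-N gaps,
recorded in AGP so the operation is reversible.

## Collapsed and repetitive regions from differential mapping

Two mapping modes of the same reads tell copy-number truth about an
assembly:

* **Collapsed** sequence (several genomic copies, one assembly copy)
  attracts the reads of all its copies, and they map *uniquely*:
  unique-placement depth rises to ~g·D. The per-position predicate is
  `unique >= collapse_multiplier * D` with `collapse_multiplier = 1.75` —
  below the doubled-coverage expectation of 2 so that Poisson noise around
  2D does not punch holes in true regions, yet 7.5 standard deviations
  above single-copy depth at D = 75.
* **Repetitive** sequence (present more than once in the assembly) is the
  mirror image: reads cannot map uniquely (`unique <= rep_unique_frac * D`,
  default 0.1·D) but they do exist (`all >= rep_all_frac * D`, default
  0.5·D). The second predicate is what separates an assembly repeat from a
  plain coverage dropout, where both tracks are empty.

D, the single-copy depth, is estimated as the modal positive depth after
discarding the top 1% of values (organelle spikes, extreme collapses);
modal ties resolve downward. Maximal predicate-true runs of at least
`min_block_bp = 50` become regions; no gap joining is applied by default,
matching the literal minimum-block reading, with `max_gap` available for
noisy tracks. The two predicates are mutually exclusive at any position
(unique depth cannot be both ≥ 1.75·D and ≤ 0.1·D), so the two region
tracks never overlap. A gene is *located in* a class when at least
`region_overlap_frac = 0.5` of its exonic bases fall inside that class's
regions; exon bases rather than the whole gene span, so introns overlapping
a region do not drag a gene in.

## Gene presence/absence and expression presence

Absence calling deliberately bypasses annotation: a gene is absent under a
cultivar's genomic reads when fewer than `loss_min_frac = 5%` of its
exonic bases reach depth `loss_min_depth = 1`. This is robust in both
directions — a handful of mismapped reads cannot rescue a deleted gene,
and at 10x coverage the chance that a real 1 kb gene drops below 5%
coverage is negligible ($P(\text{base uncovered}) = e^{-10}$).
Expression presence uses a fragment floor instead: ≥ `expr_min_fragments
= 5` unique fragments in a library, because homeologous gene copies leak
small numbers of mismapped RNA-seq reads. Cross-cultivar patterns then
classify per gene from the reference/query/donor/population flags; the
population is *segregating* when at least one library is expressed and at
least one is not, the expected signature of a real deletion segregating in
a DH population.

## K-mer genome and assembly size

From a k-mer multiplicity histogram, with error valley $v$ (first local
minimum of the sparse count sequence; plateaus count as minima) and
coverage peak $p$ (count-maximizing multiplicity above $v$):

$$\widehat{G} = \frac{\sum_{m > v} m \cdot c_m}{p}, \qquad
  \widehat{A} = \sum_{m > v} c_m.$$

$\widehat{G}$ counts every genomic copy (each contributes its coverage to
the numerator); $\widehat{A}$ counts each distinct solid k-mer once, which
is what an assembler can at best represent. Their difference is the repeat
content expected to collapse, and $\widehat{G} \ge \widehat{A}$ for any
coverage-shaped histogram. One numerical subtlety: at integer coverage $c$
a Poisson histogram has an exact modal tie between $c-1$ and $c$, so the
raw argmax injects a $\pm 1/c$ relative error into $\widehat{G}$. The
divisor is therefore refined to the count-weighted centroid of the bins
reaching half the peak count (within $p/2$ of $p$, so higher-copy-number
peaks stay out) — a sub-integer peak estimate insensitive to the tie. All
single-bin worked cases are unaffected, and recovery error at coverage 30
drops to ~0.5%. Heterozygosity is not modelled: both cultivars are
homozygous lines, so there is no heterozygous half-coverage peak.

## Collinearity classification

Protein-level reciprocal best hits (e ≤ `homolog_evalue` = 1e-10; ties by
e-value then lexicographic id) define gene pairs; within each chromosome
pair, pairs are chained greedily (longest chain first, leftmost on ties)
under two constraints: gene-rank gaps of at most `max_rank_gap = 5` on
*both* genomes, and strictly monotone partner ranks (increasing = same
orientation, decreasing = inverted). Chains below `min_block_genes = 5`
are dropped. This gap-bounded monotone chaining replaces a black-box
collinearity scorer with a procedure that an exhaustive oracle can verify
on small instances. Genes outside blocks classify by their partner's
location: on the expected chromosome (same-named chromosome between two
cultivars of one species, or the configured A/C homeolog); additionally in
the expected *region* when within `expected_region_bp` (1 Mbp — unstated
in any source, chosen as the scale of local rearrangement, configurable
and reported) of the position linearly interpolated from flanking block
anchors; otherwise elsewhere. Expected-region genes are by construction a
subset of expected-chromosome genes.

## The synthetic-data generator

Every stage is validated against generated data with known truth, because
the real inputs are hundreds of gigabases of reads. The generator emulates:

* **Parents**: two homozygous genomes differing by Poisson-rate
  substitutions (default benchmark density: 10 SNP/100 kbp, one per
  stratum so no anchor window is empty), with a duplication registry
  recording which segments the "assembly" represents fewer times than the
  genome (collapsed) or more than once (repeats, appended copies).
* **DH population**: each chromosome is a mosaic of the two parental
  haplotypes; adjacent loci at map distance $d$ Morgans recombine with
  probability $r = \tfrac12\tanh(2d)$ (Kosambi). Interference beyond the
  map-function relationship is not modelled — adjacent intervals recombine
  independently — which is sufficient for placement benchmarking. The
  standard benchmark uses 92 individuals, 10 chromosomes of 20 Mbp at
  2 cM/Mbp, 200 anchor bins, 100 hidden contigs of 0.5 Mbp, and 50%
  missingness, the call-rate regime of skim genotyping.
* **Coverage**: depth is generated as a Poisson *read-start pileup*
  (100 bp reads) rather than independent per-base draws. Means follow the
  copy-number model exactly (collapsed g-copy segments at g·D uniquely
  mapped; repeats at unique 0 / all g·D per g copies), but depth is
  correlated over the read length, as real genomecov output is. This
  matters: under independent per-base noise the probability that 50
  consecutive bases each individually exceed 1.75·D inside a true 2D
  region is below $10^{-3}$ at any realistic depth, so a run-length caller
  would find nothing — the correlation is a property of real data the
  region caller depends on, not a convenience. The region benchmark uses
  75x, the per-cultivar whole-genome sequencing depth of a typical crop
  resequencing project, on a 2 Mbp assembly with 20 collapsed and 20
  repeated segments of 0.5-3 kbp.
* **Gene loss and k-mer histograms**: deletions zero exonic depth over an
  otherwise constant (noiseless) or per-base Poisson track — presence
  calling is per-base, so no run structure is needed there; histograms are
  Poisson mixtures over copy numbers plus an error mass at multiplicity
  1-2.

What these benchmarks do **not** show: robustness to genotyping *error*
(only missingness is modelled), to mapping biases and GC-dependent
coverage waves, to partially collapsed tandem arrays, or to annotation
disagreement between cultivars — on real data the thresholds above are
starting points to be inspected against the depth histogram and the
conflict rate, not guarantees.

## Numerical and interface choices

All internal coordinates are 0-based half-open; GFF3 and 1-based-inclusive
hit tables are converted at parse time only, and `tstart > tend` in blast
tables becomes an ordered interval with a minus strand. Heterozygous codes
in a DH genotype matrix are coerced to missing with a warning (a DH
population is homozygous by construction; residual heterozygosity is a
no-call). Multi-isoform genes use the union of all isoform exons, so
coverage-based calls do not depend on isoform choice. Ties are broken
deterministically everywhere (bins: more SNPs then smaller coordinate;
hits: e-value then target id; scaffolds: contig id), so identical inputs
and seeds give byte-identical outputs. The configuration is a flat
`key = value` TOML file mirroring `nc_config()`; the transposase-domain
blocklist used in gene-set filtering ships as an editable text file. The
problem sizes used by the test-suite benchmarks (above) were chosen as the
smallest at which the statistical claims are comfortably non-marginal.

## Known limitations

Chimeric contigs are not split (a conflict flag is the only symptom);
placement cannot orient contigs; the region caller reports assembly
states, not genotypes, and statistical comparison of region counts between
assemblies is left to standard tests on its summary output; the k-mer
module does not count k-mers from reads — any counter's histogram is
accepted.
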