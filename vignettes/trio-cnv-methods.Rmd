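---
title: "Methods: read-depth CNV discovery and variant triage in trio genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV discovery and variant triage in trio genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triocnv)
```

## The problem

A family quartet — two affected siblings and their unaffected parents —
is genome-sequenced together with a panel of control genomes of similar
depth. The diagnostic question is whether the siblings share a recessive
genotype: a homozygous variant, or a compound heterozygote pairing two
different damaging alleles of one gene, one from each parent. Small
variants come from a standard short-read pipeline; intragenic
copy-number variants (CNVs), which routinely escape exome-scale
analysis, require a dedicated read-depth analysis. `triocnv` implements
that analysis end to end: depth normalization, segmentation, a filter
cascade that reduces genome-wide calls to a reportable handful,
base-pair breakpoint refinement, and the small-variant triage that can
pair an SNV with a deletion allele.

## Coverage model

The genome is partitioned into fixed 1000-bp bins (`bin_genome()`), and
each sample's per-bin read count is normalized as reads per kilobase per
million mapped reads:

$$\mathrm{RPKM}_i = \frac{c_i \times 10^9}{w_i \, N},$$

with $c_i$ the bin count, $w_i$ the bin width in bp and $N$ the sample's
total mapped reads. RPKM makes bins comparable across samples of
different sequencing yield; the conservation identity
$\sum_i \mathrm{RPKM}_i w_i N / 10^9 = \sum_i c_i$ is exact and is
asserted in the tests. The copy-number signal of a test sample is the
per-bin log2 ratio against the *median* RPKM of the control panel
(`build_ratio_track()`); the median is robust to a single aberrant
control. A heterozygous deletion halves the expected depth, so its
signature is $\log_2(1/2) = -1$; a homozygous deletion goes to $-\infty$
in theory and to a configurable floor of $-5$ in practice, so that
segmentation never sees infinities. Bins whose control median falls at
or below $\varepsilon = 0.1$ RPKM are masked out: a ratio against
(near-)zero coverage is noise, not signal. Both constants are arguments,
not magic numbers.

No GC or mappability correction is applied and no smoothing is done:
the pipeline models clean depth signal, and the evidence attributes that
real alignment artifacts would contribute are carried as data (see the
fixture section).

## Circular binary segmentation

The masked log2-ratio track is segmented per contig by circular binary
segmentation. The sequence is treated as a circle; for every arc
$(i, j)$ the pooled-variance two-sample $t$ statistic compares the
values inside the arc with the complement, and the arc maximizing $|t|$
is the candidate split (`max_arc_statistic()`, exhaustive over all
$O(n^2)$ arcs, implemented in C++). Significance is assessed by
permutation (`permutation_pvalue()`):

$$p = \frac{1 + \#\{\text{permutations with } \max|t| \ge |t_{obs}|\}}
           {1 + n_{perm}},$$

which is the standard add-one estimator and can never return 0. If
$p < \alpha$ the segment splits into two children (boundary arc) or
three (interior arc), and recursion continues while children respect
the minimum width. Defaults are $\alpha = 0.01$, $n_{perm} = 10{,}000$
(analysis drivers use 1000, which bounds the attainable $p$ at
$1/1001$ — still an order of magnitude below $\alpha$), and a minimum
segment width of 2 bins.

Numerical conventions, all exercised by tests:

* zero pooled variance with equal means gives $t = 0$ (a constant
  sequence never splits); with unequal means it gives $\pm\infty$ (a
  noise-free step always wins the arc search);
* ties in the arc search break to the smallest $i$, then smallest $j$,
  so results are deterministic;
* each candidate split derives its permutation seed from the global
  seed and the node's boundaries. P-values are therefore intrinsic to a
  node rather than dependent on recursion order, runs are exactly
  reproducible, and tightening $\alpha$ provably never increases the
  number of segments (the recursion tree of a stricter $\alpha$ is a
  subtree of the looser one);
* masked bins are excluded from the index space; a segment's genomic
  span runs from its first to last member bin, absorbing masked gaps —
  the usual read-depth convention.

An optional `undo_sd` pass merges adjacent segments whose mean
difference is below a multiple of the residual standard deviation,
mirroring common segmentation practice; it is off by default.

The implementation is validated against an independent brute-force
oracle (direct enumeration of every arc with naive mean/variance
arithmetic, and an R re-implementation of the recursion) on tracks of
up to 30 bins, and by parameter recovery on a 100-bin track with an
engineered 20-bin shift of $-1$: both boundaries are recovered exactly
in $\ge 45/50$ seeded replicates at $n_{perm} = 1000$.

## From segments to filtered calls

Segments become typed calls by thresholds on the segment mean
(`call_segments()`): deletion at $\le -0.6$ (heterozygous expectation
$-1$, with slack for noise), homozygous deletion at $\le -2.5$,
duplication at $\ge 0.45$ (three-copy expectation
$\log_2 3/2 \approx 0.58$). Calls spanning fewer than 3 bins are
suppressed and only autosomes are considered. The cascade then applies
four stages, in order (`run_cascade()`):

1. **Shared in affected siblings.** Every affected sibling must carry a
   same-type call with $\ge 50\%$ reciprocal overlap; shared calls take
   the union region. "Shared" has no universal definition, so the
   field-standard reciprocal-overlap criterion is used and the fraction
   is configurable.
2. **Segmental duplications.** Calls whose span is covered more than
   50% by the segmental-duplication track are removed; low-copy repeats
   are the dominant source of spurious read-depth calls.
3. **Evidence review.** A true heterozygous deletion cannot contain
   balanced heterozygous SNVs (one haplotype is missing), and a real
   breakpoint leaves discordant pairs and clipped reads. A deletion is
   rejected iff it contains $\ge 3$ balanced het SNVs (allele balance
   0.35–0.65) *and* has neither discordant-pair nor clipped-read
   support. This operationalizes what is, in routine practice, a manual
   browser review; the conjunction is deliberately conservative, and
   both the SNV count and the balance window are configurable.
   Duplications pass through with the stage recorded as not applicable.
4. **Population structural variants.** Calls matching a population SV
   ($\ge 50\%$ reciprocal overlap) with frequency above 0.01 are
   removed; the threshold mirrors the small-variant MAF filter.

Every call records each stage outcome once, in order, in
`filter_status`; the ledger counts entries and survivors per stage, and
survivors are always a subset of the previous stage (a property test).
Panel-gene and exon annotations are reported on every call; panel
restriction is an annotation plus an optional hard filter rather than a
silent drop, so off-panel survivors remain visible.

### The packaged ledger fixture

The package ships a small synthetic call set
(`make_ledger_fixture()`) whose attributes drive the cascade to the
reference stage profile: five heterozygous deletions entering evidence
review, three rejected there, two continuing to split-read analysis,
one removed as a common population SV (frequency 0.2357), and one final
intragenic deletion overlapping panel-gene exons 14–16. The evidence
attributes (internal het-SNV counts, read-pair support) are encoded as
data rather than derived from reads because the stage they model is an
expert review of alignments; the read-level path is exercised
separately by the breakpoint module. The fixture is labelled synthetic
in its filename and is a constructed stand-in, not patient data.

## Split-read breakpoint refinement

Bin-level segmentation localizes a deletion to kilobase resolution;
exact breakpoints come from reads that cross the junction. The read
simulator emits junction-spanning reads the way an aligner reports
them: the longer portion anchors the alignment (ties go to the prefix)
and the shorter portion is soft-clipped, its length equal to the
read's overhang past the junction. `collect_split_reads()` groups
clips of $\ge 5$ bp by (position, side) — a right clip marks the first
deleted base, a left clip the last — and builds a majority-vote
consensus of the clipped sequence anchored at the clip boundary.
`refine_breakpoints()` pairs the best-supported right- and left-clip
clusters, requires each consensus to map across the junction onto the
mate flank (exact matching with one mismatch tolerated per 20 bp; no
external aligner needed at this scale), and normalizes the pair through
any breakpoint-flank microhomology by left alignment: when $m$
identical bases flank both breakpoints, all $m + 1$ equivalent
placements shift to the smallest coordinates and $m$ is reported.
Missing either cluster side, or a consensus that fails to cross-map,
yields an explicit "insufficient split-read evidence" outcome — an
analysis result, not an error.

Deletion size is reported as `last - first` to match the arithmetic
convention commonly printed for HGVS ranges (`g.<first>_<last>del`);
the inclusive span `last - first + 1` is emitted alongside, so the
one-base convention gap is surfaced rather than hidden.

## Trio small-variant triage

`filter_variants()` applies, in order: restriction to exonic/splicing
consequences, removal of synonymous variants, a gnomAD MAF cutoff of
0.01, an in-house cohort frequency cutoff (default 0.05 — cohort
practice varies, so this is configurable and the column optional), and
a REVEL cutoff of 0.5 applied to missense variants *with an available
score* (REVEL is defined for missense only; variants without a score
are retained rather than silently lost). Every removed variant is
returned in a `removed` attribute with the rule that removed it.

`classify_inheritance()` then forms the three recessive candidate
sets: homozygous (1/1 in all affected, 0/1 in both parents), compound
heterozygous (gene-grouped pairs heterozygous in all affected, one
allele transmitted from each parent with phase established by
transmission, and neither parent carrying both), and shared
heterozygous (the remainder). A variant with a missing parental
genotype is routed to the shared-het set with `phase_unknown = TRUE`,
never dropped. Because a deletion can be one allele of a compound
heterozygote, `cnv_pseudo_variant()` injects a CNV call as a
frameshift-equivalent allele with genotypes from its carrier parent, so
the SNV + deletion pairing falls out of the ordinary compound-het
logic. No multiple-testing machinery is involved: this is
deterministic filtering, not hypothesis testing.

## What the simulator does and does not emulate

`simulate_trio_coverage()` draws per-bin counts from a negative
binomial with mean $\mu \cdot \mathrm{CN}/2$ for engineered-event
carriers and $\mu$ otherwise. Defaults, chosen once as a realistic
modern short-read design: $\mu = 200$ reads per 1000-bp bin
(a 30x genome at 150-bp reads), dispersion (size) 100, i.e. a
coefficient of variation of about 8% — mild overdispersion relative to
Poisson, which is reachable as `nb_dispersion = Inf`. Copy-number-0
regions keep 1% of the baseline mean to emulate stray mismapped reads.
The trio is drawn with four controls, matching the emulated study
design. Test problem sizes (contigs of a few hundred kilobases, 50
seeded replicates for recovery rates, $n_{perm}$ of 300–1000) are the
package's own choices to keep the suite fast while leaving the
statistics meaningful.

Deliberately not simulated: GC and mappability bias, alignment
artifacts, sequencing errors in read bases, insert-size anomalies, and
sex chromosomes. Passing tests therefore demonstrate correctness of
the normalization, segmentation, filtering and breakpoint logic on
clean signal plus encoded evidence attributes — they do not certify
performance on real genomes, where bias correction and an aligner
would sit upstream.

The read simulator uses jittered stratified start positions rather than
fully independent uniform starts: coverage of the junction is then
near-deterministic at a given depth, which is what the breakpoint
recovery guarantees are stated against.

## Known limitations

* Segmentation enumerates all arcs exactly; the $O(n^2)$ kernel is fast
  in C++ for contigs of a few thousand bins but does not implement the
  sampling speedups needed for million-bin whole genomes at fine
  resolution.
* The evidence filter is a fixed conjunction rule; a probabilistic
  treatment of het-SNV counts and read-pair support is out of scope.
* Breakpoint refinement handles deletions only — no insertions,
  inversions or translocations — and cross-maps consensi by exact
  matching with bounded mismatches rather than realignment.
* The triage assumes a quartet with both parents genotyped; de novo
  models are not implemented.

## Reproducibility

Every stochastic component takes an explicit integer seed; fixed seeds
make simulator outputs byte-identical and segmentation node seeds make
CBS reproducible independent of recursion order. `scripts/acceptance.R`
re-runs the headline computations from a single command-line seed and
writes the resulting quantities as JSON.
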