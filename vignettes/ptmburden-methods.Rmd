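---
title: "Methods: burden and selection analysis of PTM-disrupting mutations in the tumor matrisome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PTM-disrupting mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmburden)
```

## The problem

The matrisome — collagens, ECM glycoproteins and proteoglycans (the core
matrisome) plus ECM-affiliated proteins, ECM regulators and secreted factors
(matrisome-associated) — depends on post-translational modifications for
almost everything it does: prolyl/lysyl hydroxylation stabilizes collagen
triple helices, glycans mediate receptor recognition, phosphorylation and
the lysine-directed modifications regulate the dual-localized regulators.
A somatic mutation replacing a modified residue removes the modification
site outright. `ptmburden` quantifies how often this happens in tumor
cohorts, whether it happens less often than chance would predict (purifying
selection), and where in the protein it lands when it does.

The package consumes protein-coordinate mutation calls (sample, cohort,
gene/protein, residue interval, effect class, alleles), a PTM site catalog,
a matrisome gene catalog, domain and functional-region intervals, protein
sequences and an interaction edge list. Because the real inputs are large
external downloads, the package carries a generative model of all of them;
everything below is exercised end-to-end on simulated cohorts.

## PTM^mut calling

A non-silent mutation is a PTM^mut iff its residue footprint overlaps at
least one annotated PTM position of the same protein. Footprints are
1-based, inclusive intervals (the UniProt feature convention):

* SNVs: the single reported residue. No proximity window — a mutation one
  residue away from a site is not a PTM^mut.
* In-frame indels: the full `[aa_start, aa_end]` interval.
* Nonsense, frameshift and splice-site records: the single start residue.

The truncation rule is a genuine design choice: a nonsense mutation
physically removes every downstream PTM site, but counting the lost tail
would let truncations dominate every tally and turn the statistic into a
truncation counter. We count only the residue actually substituted;
`mutation_footprint()` centralizes the rule. Splice-site records are
admissible only when the input row carries a protein position (rows without
one are dropped at read time with a warning).

A residue carrying two PTM types (e.g. a lysine that is both sumoylated and
ubiquitylated) contributes two (position, type) hits but one PTM^mut, so
type-stratified tallies see both modifications while overall counts are not
inflated. Silent mutations are never PTM^mut but are retained for the
selection statistics.

## The burden measure

For each (protein, PTM type, cancer) with at least one known site,

$$\mathrm{burden} = 100 \times \frac{\#\{\text{distinct site positions hit}\}}{\#\{\text{sites known}\}}.$$

Distinct-site counting makes the burden invariant to recurrent hits and to
duplicated records. Proteins with no sites of a type are absent rather than
zero — a zero burden means "sites exist, none hit".

The global burden of a gene set is the unweighted mean of local burdens
over all (protein ∈ set, cancer) cells, per PTM type, and the fold of the
matrisome against the rest of the genome is
`global(matrisome)/global(rest) − 1` (reported missing when the rest burden
is zero, as for hydroxylation, which has no sites outside collagens).
Whether to average means or pool counts is genuinely open; the unweighted
mean-of-means is the default because it weighs every protein–cohort cell
equally and is exactly recomputable by hand, and `method = "pooled"`
(summed hits over summed sites) is provided for sensitivity analysis.

The random-set control draws `n_draws = 100` gene sets of the matrisome's
size from the non-matrisome pool (without replacement, seeded) and compares
PTM^mut / non-PTM^mut counts with a two-sided 2×2 chi-square test without
continuity correction — the count regime is large, and the uncorrected
statistic matches the textbook formula the tests verify against; a
`correct` flag restores Yates. Draws with any expected cell below 1 are
flagged and excluded from the min/max summary.

## Selection: dN/dS and r_dNdS

Per gene, dN/dS is the raw ratio of non-silent to silent mutation counts at
a position class — deliberately not an opportunity-normalized codon-model
estimate, because the inputs are protein-coordinate calls with no codon
information. Silent mutations are assigned to the PTM / non-PTM class by
residue index (the same rule as non-silent calls); whether same-codon or
same-residue assignment is more faithful is unknowable from protein
coordinates, and residue-index assignment keeps the two classes exactly
complementary.

With pseudocount $a$ (default 0.5, disable-able):

$$\mathrm{dN/dS} = \frac{N + a}{S + a}, \qquad
r_{dN/dS} = \frac{\mathrm{dN/dS}(\text{PTM positions})}{\mathrm{dN/dS}(\text{non-PTM positions})}.$$

The pseudocount exists because silent counts at PTM positions are sparse at
realistic cohort sizes; $a = 0.5$ is the Haldane–Anscombe convention for
count ratios. With $a = 0$, r_dNdS is exactly scale-invariant (doubling all
four counts changes nothing), a property the tests assert.

**Summarizing r_dNdS over genes.** `mean_rdnds()` defaults to the geometric
mean. r_dNdS is a quotient of count ratios and its sampling distribution is
strongly right-skewed when per-gene silent counts are small (a few silent
mutations at PTM positions per gene at the cohort sizes we simulate); the
arithmetic mean is then inflated by $E[1/(S+a)] > 1/(E[S]+a)$ and sits well
above 1 even under neutrality, whereas the log scale centres a neutral
cohort on 0. The calibration tests verify that the geometric mean over
20 neutral replicates lies in [0.8, 1.2]. The arithmetic mean remains
available and its bias is the reason it is not the default.

Gene sets are compared by a two-sided Mann–Whitney U test on defined
r_dNdS values, at the conventional 0.05 threshold.

## Hotspots, domains, motifs, context

Hotspots group PTM^mut hits by (gene, position, PTM type) and keep groups
observed in ≥ `min_cohorts = 3` distinct cohorts, sorted by cohort count
then gene; a position-only key (`match_type = FALSE`) collapses co-located
types. The typed key is the default because a doubly modified lysine is two
distinct biological lesions at one residue.

Domain ratios pool all instances of a domain across the proteins of a gene
set and count non-silent mutations overlapping any instance, split into
PTM^mut and non-PTM^mut; a mutation overlapping two instances of the same
domain counts once for that domain. Differential domains require both set
ratios defined and a ≥ `fold = 2` difference in either direction (at
`fold = 1` this degenerates to "any difference", which the default set is a
subset of — a tested sanity bound).

Motif scanning matches the fixed adhesion/recognition motifs (GPP, GVD,
RGD, LDV, GFPGER, GLPGER) case-insensitively, including overlapping
occurrences, and keeps occurrences whose *span* intersects the ±3-residue
window around the mutated position. Span intersection (rather than distance
to the motif start) is the configurable default: "within ±3 residues" most
naturally means the motif reaches into the window. Context windows fetch
±10 residues, clipped at protein ends, and property profiles tally the
fixed five-class partition (polar S/T/N/Q/Y/C, hydrophobic A/V/L/I/M/F/W,
acidic D/E, basic K/R/H, special G/P) per aligned offset; percentages sum
to 100 within each offset over the contexts long enough to cover it.

## Network and co-occurrence

The PTM^mut network is the induced subgraph of the interaction edge list on
genes harboring ≥ 1 PTM^mut; isolated genes are dropped, self-edges are kept
as homotypic interactions and counted once in `total_degree` (one biological
partner), and nodes whose PTM^mut overlap functional regions are flagged.
Patient-level co-occurrence lists every (sample, interacting heterodimeric
pair) where the sample carries PTM^mut in both genes; the matching key for
the healthy-sample set-difference filter defaults to (gene, position), with
an allele-aware key available, because requiring allele identity against
normal panels of uncertain allele annotation would under-filter.

## The synthetic cohort generator

The generator encodes the statistical structure the analysis is built to
detect; its defaults are the package's fixed study conditions.

* **Catalog**: 200 genes, 4.8% matrisome (the genome-wide matrisome
  proportion), categories apportioned by largest remainder from the real
  matrisome composition (collagens ~4%, glycoproteins ~19%, proteoglycans
  ~3%, affiliated ~17%, regulators ~23%, secreted ~34%); log-normal protein
  lengths (median 400 aa), coding gene length `3*(L+1)`.
* **Annotations**: uniform random sequences with PTM-site residues forced
  to type-valid letters (hydroxylation on P/K and only on collagens,
  N-glycosylation on N, O-glycosylation on S/T, phosphorylation on S/T/Y,
  the lysine modifications on K, methylation on K/R); site density 0.12
  sites/residue — deliberately annotation-dense so per-gene burden and
  selection statistics are well conditioned at desk-scale cohorts; a 2%
  dual-site rate puts a second lysine-directed type on some lysines;
  domains from a 30-id shared pool; functional regions on 60% of proteins
  (the rest form the "no information" stratum); ~1.5 interaction edges per
  gene with 2% homotypic loops.
* **Cohorts**: 5 cancers × 50 samples, Poisson(40) mutations per sample,
  genes picked proportional to gene length, positions uniform, 30% silent,
  Ti/Tv 2.0, effect mix dominated by missense. Selection is a per-candidate
  rejection: a non-silent candidate whose footprint touches a PTM position
  is redrawn with probability `ptm_selection_s` (each fresh candidate gets
  exactly one rejection trial, so the realized hit rate is
  `(1−s)·p/(1−s·p)` for baseline hit probability p); `selection_scope`
  restricts selection to matrisome sites for parameter-recovery runs.
  Hotspots are injected verbatim after selection so detection tests are
  deterministic at any s.

Everything is deterministic given the root seed: each stage derives its own
child seed, so module-level reruns match pipeline runs and fixture bundles
are byte-identical across regenerations.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: trinucleotide mutational signatures and
transcript-level Ti/Tv structure (alleles are drawn independently of the
residue context), codon structure (mutations are generated directly in
protein coordinates), inter-sample mutation-rate heterogeneity beyond
Poisson, correlated placement of PTM sites in clusters, realistic
(sparser) PTM annotation density, and any relationship between SIFT/
PolyPhen labels and true damage (labels are random). Results on real
cohorts additionally inherit the biases of the site databases themselves.

## Numerical choices and degenerate inputs

* Zero-denominator folds and ratios are reported `NA`, never infinite.
* Chi-square tables with an empty margin give `NA` with a warning.
* Correlations need ≥ 3 points and non-constant vectors; otherwise `NA`.
* Ties in top-gene ranking break alphabetically; hotspot ordering is
  cohort-count descending, then gene, then position — all deterministic.
* Readers drop invariant-violating rows with a warning carrying the count;
  a missing required column is a hard error naming the column.

## Problem sizes

The test suite runs oracle-equivalence checks on 20 random fixtures of
≤ 1,000 mutations each, and parameter recovery on 20 neutral plus 20
selected replicates of 200-gene, 5-cohort, 50-samples-per-cohort cohorts
(~10⁴ mutations each) — sizes chosen so the whole suite completes in about
a minute on one CPU while keeping every statistic in its well-conditioned
regime. The acceptance script reuses the same conditions with 10 replicates
per arm.

## Limitations

The dN/dS proxy has no mutational-opportunity correction, so it should be
read as a within-gene contrast (PTM vs non-PTM positions of the same gene),
which cancels gene-level rate effects but not residue-composition effects.
The burden's mean-of-means weighting treats a 10-site protein and a
500-site protein equally. Truncating mutations are deliberately undercounted
as PTM disruptors. And the co-occurrence chi-square treats patients as
exchangeable units, ignoring tumor mutational burden differences — on real
cohorts a per-sample burden covariate would be advisable before
interpreting its p-value.
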