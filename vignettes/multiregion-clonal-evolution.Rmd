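---
title: "Models and methods: multi-region clonal evolution analysis"
author: "mseqevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multi-region clonal evolution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mseqevo)
```

# Scope

`mseqevo` analyses multi-region exome sequencing (MSeq) of hypermutated,
mismatch-repair-deficient (dMMR) tumours: several spatially separated
samples of one tumour, each yielding somatic variant allele counts and an
allele-specific copy-number profile with a purity estimate. From these the
package derives mutation categories (ubiquitous / shared / private),
cancer-cell fractions (CCF), a clone tree, copy-number-gain timing,
mutational-signature exposures, compartment-wise dN/dS, and single-region
versus multi-region clonality comparisons. A ground-truthed simulator of
branched tumours provides the validation substrate for every step.

Read alignment, raw variant calling and copy-number segmentation are out of
scope: variant tables and segment profiles are the package's inputs.

# Variant filtering model

Filtering follows a fixed, documented order so that every rejected site has
one deterministic reason:

1. sex-chromosome exclusion (X/Y calls are not analysed);
2. tumour depth: every region must reach 70x at the site;
3. germline depth: the matched normal must reach 20x;
4. germline evidence: a site is rejected only when the normal VAF exceeds
   2% *and* the normal alt count exceeds 2 — both conditions, a conjunction
   pinned by boundary tests.

A panel of unrelated normals then removes recurrent technical artifacts: a
site carried at VAF >= 2% by at least 20% of the panel is dropped (with a
14-normal panel, 3 carriers reject, 2 retain).

Mutation calling is two-tiered: a mutation is accepted when at least one
region reaches VAF >= 5% (tier 1, a minimum, hence `>=`), and is then
scored present in each region whose VAF strictly exceeds 2.5% (tier 2,
"exceeds", hence `>`). The mixed conventions follow the respective wordings
of the thresholds; both boundaries are pinned by tests. Presence patterns
partition retained mutations into ubiquitous (all regions), private (one
region) and shared (otherwise); heterogeneous = shared + private.

# Copy-number metrics

*Ploidy* is the segment-length-weighted mean of the unrounded total copy
number. The *weighted genome instability index* (wGII) is, per autosome,
the fraction of covered bases whose rounded integer copy number differs
from the rounded ploidy, averaged (unweighted) over the autosomes present;
wGII > 0.2 (strict) flags chromosomal instability. Aberrant cover is
measured by length rather than by segment count, making the score invariant
to breakpoint splitting; autosomes absent from a profile are excluded from
the mean rather than counted as zero. Half-integer copy numbers round half
up. LOH is called where the minor allele count is zero with at least one
major copy; an event is "ubiquitous" when present in every region.

# CCF model

For a mutation with allele frequency VAF in a sample of purity $p$ at a
locus of total copy number $CN$, the mutation copy number is

$$ \mathrm{MUT}_{CN} = \mathrm{VAF} \cdot \frac{1}{p}\,\bigl(p\,CN + 2(1-p)\bigr). $$

Multiplicity is the nearest integer clamped to $[1, CN_{major}]$, and
$\mathrm{CCF} = \mathrm{MUT}_{CN}/m$, reported capped at 1 with the raw
value retained. The nearest-integer rule is exact in noiseless limits and
is the simplest testable choice. Clonality uses CCF >= 0.7: of the two
phrasings in circulation (">0.7" vs "0.7 or above") we adopt the inclusive
one and pin it with a boundary test at exactly 0.70.

*Gain timing.* In a gained segment (major copy number >= 2), the statistic
is the fraction of ubiquitous mutations carrying the full major copy
number. An early gain (preceding mutation accrual) leaves mutations on
single copies, so the fraction is near zero; `early` is called at <= 0.05
("near-complete absence", configurable), `late` otherwise, and segments
with fewer than 10 informative mutations are unassessable.

# Clone-tree reconstruction

Mutations are clustered by presence pattern (CCF > 1e-4 = present), then by
average-linkage hierarchical clustering of CCF vectors within a pattern
(cut height 0.6 — deliberately conservative, since patterns already
separate clones in well-behaved data). Clusters below 8 members dissolve
into the unassigned set unless they contain a flagged driver mutation,
mirroring the manual rescue of small driver-bearing subclones.

The tree over clusters is rooted at the germline (CCF 1 everywhere) and
built under two constraints: *containment* (a child's presence regions lie
within its parent's) and the *lineage sum rule* within slack
$\varepsilon = 0.1$ CCF per region. The error score of a tree is the total
sum-rule excess $\sum_{r,v}\max(0, \sum_{c \in \mathrm{children}(v)}
\mathrm{CCF}_c(r) - \mathrm{CCF}_v(r))$. The search is exhaustive up to 12
clusters and greedy with local search beyond. Trees are ranked by error;
ties are broken by preferring the most specific valid parent for each node
(smallest parent CCF mass), then lexicographically. The specificity
tie-break matters: a chain trunk→A→B and the flat alternative trunk→{A,B}
often tie at error 0, and only the specific-parent preference recovers
chains. The exhaustive search is mirrored by an independent enumeration
oracle in the test suite.

*Conflicts.* A mutation absent from a region where its clade is present
conflicts with the tree. Since clusters are presence-pure, a mutation
deleted by a regional copy loss ends up in a smaller cluster; conflict
detection therefore first matches each mutation to its *home clade* — the
most specific cluster whose regions strictly contain the mutation's and
whose centroid is within 0.25 CCF of the mutation in every shared region —
and then classifies each missing region as `explained_by_loss` when the
locus copy number there is lower than in every region carrying the
mutation, `unexplained` when flat.

*Parallel evolution.* A gene with driver mutations on two or more branches
that are not ancestrally related emits a `parallel` event (with a
same-residue flag for identical or hotspot-proximal protein changes);
trunk-plus-branch combinations emit a `trunk_branch` (progressive
inactivation) event; trunk-only genes emit nothing.

# Mutational signatures

SNVs are tabulated over the 96 pyrimidine-frame trinucleotide categories
(purine-reference substitutions reverse-complemented; contig-edge loci
excluded and logged). Spectra are refit against a signature catalog by
non-negative least squares on normalised frequencies — with a weight cutoff
of 0 this coincides with iterative refitting approaches while being
deterministic and directly testable. Reporting masks signatures
contributing less than 5% in every analysed mutation group. No
trinucleotide-abundance normalisation is applied by default (spectra and
catalog live in the same sequence space in all shipped analyses). The
shipped catalog generator produces a synthetic 30-signature,
COSMIC-v2-shaped matrix (sparse random peak profiles); it is a labelled
synthetic stand-in, not the published catalog, and tests also run against
subsets and exact mixtures of it.

# Selection (dN/dS)

An opportunity model enumerates every possible single-base substitution in
a set of in-frame coding sequences, labelling each synonymous or
non-synonymous and assigning its 96-context class (sequence flanks wrap
circularly so every site contributes a full trinucleotide; counts conserve
3 per site; stop-containing frames are excluded with a warning).

The estimator is a conditional maximum-likelihood ratio under a per-context
Poisson model: synonymous counts with rate $\lambda_c L_{S,c}$ and
non-synonymous with rate $\omega \lambda_c L_{N,c}$. Conditioning on the
per-context totals removes the $\lambda_c$ exactly, leaving a binomial
profile likelihood in $\omega$; the 95% CI is the likelihood-ratio
interval. We chose this over the simpler plug-in
$n_N / \sum_c (n_{S,c}/L_{S,c}) L_{N,c}$ because the plug-in's denominator
is itself a noisy weighted count: at 500 mutations it inflates the ratio by
~6% and drops CI coverage to ~86%, whereas the conditional MLE measures
mean 1.00 and 96% coverage on neutral simulations — and stays centred on 1
under a strongly context-biased neutral process (10x C>T at NpCpG) where
the naive count ratio is visibly biased. Compartments are the presence
categories (ubiquitous / shared / private); a compartment without
synonymous mutations is flagged undefined rather than estimated.

# The simulator

The generator produces the statistical structure the analysis assumes and
is itself first-class, tested code.

**Clone tree and space.** A rooted tree (default: random, biased to
branched shapes of depth <= 3) assigns each clone a set of regions: the
root occupies all regions and each node's children receive disjoint,
nonempty, strict subsets of the parent's regions. This encodes the
spatially ordered growth seen in MSeq data (closely related clones in
close proximity) and has two analytically convenient consequences: the
clones present in any region form a root-to-tip path, and non-ancestral
clones have incomparable region sets. Per region, CCFs along the path are
drawn decreasing from 1 with a floor of 0.3 (`min_clone_ccf`, the
detectability floor) and minimum gaps, which guarantees the lineage sum
rule by construction and a between-clone CCF separation of at least ~0.3 in
some region. A Dirichlet mixture over arbitrary clone subsets was
considered and rejected: it cannot guarantee the sum rule or separable
presence patterns, both of which the downstream contracts require.

**Mutations.** Default burden reflects the dMMR regime: 700 truncal
mutations and ~1100 across branches, 27% indels (the observed 20-34%
range), per-region purity uniform in 0.2-0.9, Poisson depth 200x in tumour
regions and 100x in the normal. SNV contexts are drawn from signature
mixtures that differ between trunk (more spontaneous-deamination-type
signature) and branches (MSI-type signatures dominate), and positions are
drawn uniformly among genome sites matching the sampled trinucleotide —
which makes the process selectively neutral given context, so pipeline
dN/dS on simulated tumours centres on 1. The toy genome is fully coding
(stop-free in-frame gene tiles), so consequences are derived from actual
codon changes. Observed counts are `Binomial(depth, VAF_expected)` with
`VAF_expected = p·m·CCF / (p·CN_total + 2(1-p))`; a per-base error rate
(default 0.1%) adds alt reads at wild-type sites so filter specificity is
testable, and `depth_override = Inf` renders noiseless data (depth 1e6).

**Copy number.** CNA and loss events are regionally clonal: they apply in
regions where the carrying clone's CCF exceeds 0.5 (a deliberate
simplification — fractional-CN mixtures are not modelled). A gain timed
`before_mutations` leaves all subsequent mutations at multiplicity 1; one
timed `after_mutations` duplicates pre-existing mutations on the gained
parental allele with probability 1/2. A loss event deletes ancestral
mutations on the lost allele (allele assignments are drawn once per
mutation) in affected regions, records them in the ground truth, and drops
the segment to (1, 0).

**Artifacts.** A configurable fraction of sites are recurrent artifacts:
they carry moderate VAFs in tumour regions and appear at VAF >= 2% in a
binomial fraction (default 0.3) of panel normals. Background panel noise
caps error support at one read — recurrent multi-read support is precisely
what the artifact mechanism models — so non-artifact sites never cross the
carrier threshold. Note that with prevalence 0.3, a minority of artifacts
legitimately evade the 20% panel filter (the binomial lower tail), which is
faithful to how such filters behave.

**What the simulator does not emulate.** Read-level errors (mapping,
strand bias), germline variation, subclonal copy-number mixtures within a
region, inter-region purity correlation structure, and realistic genome
coordinates. Passing tests therefore demonstrate correctness of the
analysis logic under the stated generative model, not performance on real
sequencing data.

# Numerical choices and degenerate inputs

* Half-integer rounding is half-up everywhere (copy numbers,
  multiplicities), avoiding banker's-rounding surprises at 0.5 and 2.5.
* Tree ranking keys are rounded to 9 decimals before ordering so float
  noise cannot break genuine ties; sum-rule slack comparisons carry a 1e-9
  tolerance.
* Zero-depth regions count as VAF 0; empty presence matrices summarise to
  zeros; an all-zero spectrum and an empty CCF matrix are errors.
* All randomness flows through seeds derived from a single master seed
  (kept below 2^31), and pipeline reruns are byte-identical, which the
  manifest (per-file MD5, config hash) makes checkable.

# Problem sizes used in the shipped analyses

The test suite and the reproduction script use a ~2,000-mutation tumour for
CCF recovery, 50 (suite) / 25 (script) simulated tumours of 4-8 clones over
7 regions for topology recovery, 200 / 100 neutral replicates of 500
mutations for dN/dS calibration, and 100 / 50 sampled 1,000-mutation
mixtures for signature refitting. These sizes give stable estimates of the
respective error rates while keeping a full run to a few minutes on one
core.

# Known limitations

* Per-mutation CCF error at 200x depth is dominated by binomial counting
  noise: with purity in 0.3-0.9 the mean absolute error is ~0.05-0.06 and
  cannot be reduced by the estimator alone (cluster-level averaging, which
  the tree module performs, is the standard remedy).
* Tree search beyond 12 clusters is greedy with local search; optimality is
  only guaranteed in the exhaustive regime (the regime of the shipped
  analyses).
* The clustering cut height (0.6) is tuned for data in which presence
  patterns separate clones; tumours with many same-pattern subclones need a
  smaller cut and will fragment more.
* dN/dS is a global per-compartment ratio over a 96-class strand-collapsed
  model; per-gene selection testing (192 classes, gene-level dispersion) is
  a non-goal.
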