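---
title: "Methods: allele calling, differentiation, and expression-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele calling, differentiation, and expression-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Studies of chemically mediated adaptation in small gene families — the
motivating case is floral stearoyl-ACP desaturase (SAD) paralogs whose
allele-specific expression shapes alkene double-bond positions in the
floral odor of sexually deceptive orchids — face a common chain of
inference steps:

1. cloned amplicon sequences per locus must be collapsed into alleles
   despite PCR and sequencing errors;
2. near-identical alleles must be grouped into *allele groups*, the unit
   at which semi-quantitative expression assays can genotype individuals;
3. loss-of-function (LoF) lesions must be annotated and their clustering
   in particular groups tested;
4. among-species differentiation (F~ST~) must be estimated from
   genotypes that are only known up to the individual's *expressed* set
   of allele groups; and
5. compound amounts must be regressed on allele-group expression under
   the study's prescribed variable transforms.

`popallele` implements this chain as composable, seeded, table-in /
table-out functions plus a pipeline driver, and ships a synthetic-data
generator so every statistical property of the chain can be tested
end-to-end without the (undeposited) field data.

# Allele calling

**Merge rule.** Reads whose pairwise difference is at most `d_merge`
are treated as the same allele observed with errors.  The default
`d_merge = 1` is the literal reading of a "fewer than two nucleotide
differences" rule; the complementary singleton rule ("more than two")
leaves the exactly-two case undefined, and we resolve it conservatively
against over-merging.  `d_merge` is a configuration knob.

**Chaining.** The source protocol does not state how chains (A–B = 1,
B–C = 1, A–C = 2) behave.  We use single linkage — connected components
of the ≤ `d_merge` graph — because it is the only choice that is
provably invariant to input order.

**Gap handling.** Under the default `indel_as_diff` policy a gap-vs-base
column counts one difference and a run of *k* contiguous gap columns on
the same side counts as a single indel event; `N` is never scored.

**Consensus.** Per-column majority over cluster members; ties take the
character of the member read with the lexicographically smallest id,
which makes consensus construction deterministic.

**Distances and trees.** Allele groups come from a p-distance matrix
with pairwise deletion of gaps, clustered by UPGMA (member-count
weighted averages, heights half the merge distance, ties broken by the
smallest label pair).  Bootstrap support resamples alignment columns
with replacement (1000 pseudo-replicates by default) and counts, per
internal clade of the reference tree, the replicates containing the same
leaf set; a replicate producing a pair with no co-scored sites is
redrawn at most 10 times.

**Group cut.** A group is a maximal clade with support ≥ `min_support`
(default 0.70) and node height ≤ `max_within_distance` (default 0.03
substitutions/site).  The source protocol states no numeric cutoffs;
both defaults are explicit choices of this package and are echoed in the
run log.  The root clade qualifies on height alone: its bipartition is
trivial, so demanding bootstrap support for it would be meaningless, and
a locus whose whole tree is shallow legitimately forms one group.
Leaves in no qualifying clade become singleton groups.  Labels are
"A", "B", … by decreasing group size.

# LoF annotation and enrichment

An allele aligned to the locus reference is annotated with
`frameshift_indel` (any gap run whose length is not a multiple of 3),
`premature_stop` (an in-frame stop of the degapped allele strictly
upstream of the reference stop — reading the degapped sequence
automatically tracks frame through earlier indels), and `start_loss`.
The reference is the longest intact-ORF allele, overridable in
configuration; a reference with an internal stop is a configuration
error, not a data point.

Enrichment per group uses a one-sided Fisher exact test of
{group vs all other groups} × {nonfunctional vs functional}, i.e. an
upper hypergeometric tail.  The pooled-background 2×2 construction is
this package's explicit choice of null for "more lesions than expected
by chance"; the source analysis names the test but not the margin
construction.

Classification into the three categories (functional expressed /
nonfunctional expressed / non-expressed) is per (group, species):
non-expressed when no individual of the species exceeds the detection
floor (default normalized intensity 0.05 — gels give presence/absence,
the floor is ours); otherwise majority functionality of member alleles,
ties conservatively nonfunctional.  An external-evidence flag can force
a group nonfunctional, covering cases sequence heuristics cannot see
(biochemically inactive enzymes; repetitive insertions at the CDS
start).

# dN/dS screen

The codon-model branch tests of the source analysis are out of scope;
the package provides the Nei–Gojobori (1986) pairwise screen instead.
Site counts are per-codon synonymous fractions averaged over both
sequences; multi-hit codons average over all orderings of the mutational
pathway; proportions are Jukes–Cantor corrected
(d = −¾ ln(1 − 4p/3), undefined and flagged at p ≥ ¾).  Conventions:
gap-containing codon columns are removed; codon columns where either
sequence is a stop are excluded; changes into stops count as
nonsynonymous in site counting; pathways through stops are excluded from
the average unless every pathway is blocked.  The ratio is `NA` when
dS = 0.

# F~ST~ with in-silico diploid resampling

Individuals are genotyped only up to their expressed allele-group set,
so each of 100 replicates (default) redraws a diploid genotype per
individual: one expressed group → homozygote, two → one copy of each,
more than two (possible under gel misassignment) → two drawn uniformly
without replacement.  Each replicate is summarized by the multiallelic
Weir–Cockerham (1984) θ — per-allele variance components a/b/c summed
over alleles — and the estimate is reported as the replicate mean with
SE = sd/√n over replicates (the "mean ± SE over replicates" reading;
the alternative, over loci, is not used).  Choices worth stating:

* the exact F~ST~ flavor of the original Arlequin run is unstated; we
  implement frequency-based W&C θ on group labels and keep
  distance-weighted variants out of scope, because a single well-defined
  estimator can be oracle-checked;
* θ is *not* truncated at zero in replicates (negative estimates carry
  calibration information); summary tables add a clamped column;
* a monomorphic locus yields NaN with a flag; a locus expressed in fewer
  than two groups of the chosen grouping is "inestimable", not an error
  (the real-data situation of a homolog observed in one species only);
* one master seed; replicate r draws from a derived stream
  `derive_seed(seed, r)`, recorded in the run report.

The species-distribution test is a Pearson χ² on the species × category
table, dropping zero margins with a warning, warning on expected counts
below 5, and optionally adding a seeded Monte-Carlo p-value from 10^4
fixed-margin tables.

# Association models

The transform mapping is part of the method, not a preference: relative
compound proportions use arcsin √x, absolute amounts (µg) use
ln(x + 0.01) with the shift exactly 0.01, expression uses √x.  The
pipeline validates the mapping before any computation and rejects, e.g.,
arcsin √x requested for amounts.

"GLM" is interpreted as a Gaussian-identity linear model fitted by least
squares on transformed variables — the transforms exist to make
residuals approximately normal, so a non-Gaussian family would be
second-guessing the design.  The "LME" is a random-intercept model
(population as random factor) fitted by REML; its fixed-effect p-values
use a Wald normal approximation, stated in the output metadata, because
the source does not specify a degrees-of-freedom method.  Adjusted R²
is reported for the fixed model only (1 − (1−R²)(n−1)/(n−k−1));
complete cases only; collinear designs are an error listing the
offending terms; raw p-values are reported, as in the source analysis.

Backward stepwise AIC drops, at each step, the single term whose removal
most decreases AIC, stopping when no removal decreases it — so the final
AIC can never exceed the full model's.  Mixed models are compared on
ML AIC (REML likelihoods are not comparable across fixed-effect
structures) and the final model is refitted by REML.  Both model kinds
are reported side by side without adjudication.

# The synthetic world

The generator emulates the study design: diploid individuals in
2–3 species × several populations; per-locus allele pools derived from a
random ancestral CDS by Poisson(`mutations_per_allele`) point mutations
(start and terminal stop kept; internal-stop-creating draws are
rejected and redrawn *without* redrawing the count, so the stated
mutation count stays the expectation); LoF alleles receive an internal
stop or a 1–2 bp deletion.  Insertions are not simulated, which keeps
all sequences in the ancestor's coordinate frame and removes any
dependence on an external aligner (alignment is out of scope).

**Island model.** Species allele frequencies are drawn from a Dirichlet
centred on global base frequencies with concentration
c = 12·m/(1 − m), a Balding–Nichols-style device giving expected
species-level F~ST~ = 1/(1 + c); m = 0.2 — the package default — gives
the convenient calibration point 0.25, in the range of the neutral loci
of the motivating study (≈ 0.22–0.25).  Populations within a species
are a mild Dirichlet perturbation (concentration 300) of the species
frequencies.  m = 1 is exact panmixia; m = 0 fixes each lineage.

**Divergent selection.** The functional-allele mass alternates between
0.95 and 0.05 across species lineages, and within each set the
composition is drawn sweep-like (concentration 1, independent of the
migration concentration): divergent selection drives each lineage
toward its locally favoured variant, so the selected locus shows
near-fixation of different alleles, not just a shifted mass — matching
the empirical picture of a selected desaturase locus nearly fixed for
different allele groups in different species.

**Ledger F~ST~.** The truth ledger stores, per locus, the realized
parametric F~ST~ as the large-sample limit of the W&C estimand,
Σ~a~ s²~a~ / Σ~a~ (p̄~a~(1 − p̄~a~) + s²~a~/r) with the (r − 1)-divisor
among-group variance.  (A divide-by-r "descriptive" variance would
differ from the estimator by a factor ~2 at r = 2 and make calibration
meaningless.)

**Expression and phenotype.** Expression of a carried allele is
copies × lognormal(0, 0.25) — the shape of housekeeping-normalized band
densities — gated by a per-species × per-locus on/off regulatory state
(the hybrid-suppression contrast can be emulated qualitatively through
this switch; quantitative hybrid genetics is out of scope).  The
compound driven by a locus is
`expression_effect` (default 2 µg/unit) × summed functional expression
+ N(0, `noise_sd` = 0.5 µg), truncated at zero (amounts are masses).
Defaults put typical amounts near 4 µg with noise 0.5 µg, a
signal-to-noise ratio in the range of strongly associated compounds in
such data; clones per allele default to 3, the "at least three times
the number of possible alleles" cloning depth.

**What a green test does not establish.** The generator has no
coalescent genealogy, no recombination, no aligner (reads are emitted
pre-aligned), no insertion polymorphism, and lognormal expression noise
only; real gel densitometry has censoring and saturation the generator
does not emulate.  Green acceptance tests establish that the chain's
estimators are correct and calibrated *in this stated world*, not that
the world captures every property of field data.

# The synthetic world behind the acceptance tests

* **Allele-calling recovery** uses an 800 bp CDS (267 codons), clone
  error 5×10⁻⁴/base, 3 clones per allele copy, and alleles ≥ 5
  differences apart, with `mutations_per_allele = 30` so that realized
  separation (~60 nt) places distinct alleles in distinct groups at the
  default group cut while error reads (≤ a few nt from their source)
  are absorbed into the source's group.  Recovery is judged at the
  genotyping-unit level: every individual's set of called allele groups
  must equal its true allele set mapped through the truth-to-group
  table.  Bootstrap uses 200 pseudo-replicates here (a cost choice; the
  support values being thresholded are essentially 0 or 1 in this
  world).
* **F~ST~ calibration** uses 3 species × 2 populations × 30 diploids at
  m = 0.2 and compares the resampled mean against the same seed's
  ledger value (|Δ| < 0.08).  The **contrast** world adds one divergent
  locus (pool of 4 alleles, LoF rate 0.5 so both functional and
  nonfunctional sets are populated) to three neutral loci and requires
  the selected locus to rank first.
* **Association** uses n = 60 (3 × 2 × 10) with four loci, each driving
  its own compound; predictors are √(summed functional expression),
  responses ln(amount + 0.01).

All parameters above were fixed from the stated design before the
acceptance runs; none is tuned on test outcomes.

# Numerical choices and degenerate inputs

* All randomness flows from one master seed through
  `derive_seed(master, offset)` (a fixed affine map mod 2³¹ − 1), so a
  config rerun is byte-identical.
* UPGMA tie-breaks: smallest label pair, with equality tolerance 10⁻¹⁵;
  bootstrap matching uses exact leaf-set identity of rooted clades.
* `wc_fst` guards: < 2 populations is an error; monomorphic input and
  a mean sample size of 1 return NaN with flags; a zero denominator is
  flagged `zero_variance`.
* Stepwise AIC uses a strict-improvement threshold of 10⁻¹⁰ to avoid
  dropping terms on floating-point ties.
* `ng86_dnds` requires alignment length divisible by 3 and flags
  undefined Jukes–Cantor corrections instead of returning infinities.

# Known limitations

* Alignment is accepted, not computed; inputs must share a coordinate
  frame per locus.
* The dN/dS screen is pairwise NG86 only — no branch or branch-site
  models, by design.
* The mixed model reports no adjusted R² and uses normal-approximation
  p-values; with few populations the random-intercept variance is
  weakly identified.
* Fisher-exact enrichment is conservative at small counts (the null
  rejection rate in the acceptance run is ≈ 2%, well under nominal),
  so marginal enrichments may be missed.
* F~ST~ supports one grouping level per call; no hierarchical AMOVA.
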