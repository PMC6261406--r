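---
title: "Methods: case-control CNV analysis with cnvcase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control CNV analysis with cnvcase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcase)
```

# Scope and data model

`cnvcase` implements the analysis stages of a genome-wide copy number
variation (CNV) case-control study in an admixed cohort: per-sample and
per-chromosome burden comparison, CNV-region (CNVR) construction, a
four-step rare-CNV identification pipeline, single- and joint two-locus
copy-number genotype association, and target-specific copy number
quantification by qPCR (delta-delta-Ct) and droplet digital PCR.

All coordinates are 1-based inclusive on GRCh37 (autosomes and X; size
of an interval is `end - start + 1`). This is the convention of array
analysis reports, and it is the convention under which the published
21-row rare-CNV table shipped at
`inst/extdata/table1_rare_cnvs.tsv` reproduces every printed kb size
from its printed coordinates with half-up rounding of
`(end - start + 1)/1000`. BED input/output converts explicitly to and
from 0-based half-open. Whether an array export's end coordinate is
inclusive of the last probe is a convention choice, not something the
data can decide; we fix 1-based inclusive because the published sizes
are exactly consistent with it.

A CNV call is a row of a segment table: sample, interval, integer copy
number state (never 2), a derived loss/gain type, an optional supporting
probe count, and a caller label (primary or secondary). Calls without
probe counts (simulated or PCR-derived) bypass probe filters with a
warning rather than an error, because probe support is array-specific
metadata, not a property of the variant.

# Burden comparison

Per-sample burden summaries count calls and sum sizes by type and by
chromosome, including zero-call samples. Case-control comparison fits a
maximum-likelihood logistic regression of case status on one burden
measure, adjusted for sex and **one** ancestry component: the three
admixture proportions (African, European, Amerindian) sum to 1 and are
exactly collinear, so one component enters per model and the component
is switchable (African by default). The odds ratio is per unit of the
measure — per call or per bp — which is how per-call effect sizes such
as a 0.7-per-duplication odds ratio arise. Size burdens use total bp per
sample by default (mean bp is available through the summary columns);
total bp is the quantity that grows with both call count and call size
and is the usual burden measure.

Per-chromosome comparisons are two-sample t-tests of per-sample call
counts and summed sizes. Welch's unequal-variance form is the default
(group sizes are typically very unbalanced, e.g. 23 vs 110); the
pooled-variance Student form is available by flag. Raw p-values are
reported by default, with Benjamini-Hochberg correction optional,
because per-chromosome screens in this design are descriptive.

# CNV regions

A CNVR is the union of transitively overlapping same-type calls across
subjects on one chromosome. Membership requires at least one shared
base: book-ended calls (end + 1 = start) do not merge. Gains and losses
are never merged, and copy-number magnitude (0 vs 1, 3 vs 4) is ignored
for region typing. A subject contributing several member calls counts
once as a carrier. Construction uses interval reduction
(`IRanges::reduce`, `min.gapwidth = 0`); the test suite proves
equivalence to the connected components of the brute-force pairwise
overlap graph on thousands of random instances.

Each region is tested two ways: an adjusted logistic regression of case
status on the carrier indicator (sex + one ancestry component), and an
unadjusted Fisher's exact test on the carrier 2x2 table, reported with
the cross-product odds ratio (Haldane-Anscombe 0.5 correction on empty
cells). Both are emitted because small carrier counts can make either
more informative; with covariates the two odds ratios differ and no
attempt is made to force agreement.

# The four-step rare-CNV pipeline

Rare variants (population frequency < 1%) are identified by a fixed
cascade:

1. remove case calls matched by a same-type control-cohort call;
2. remove calls matched by a population-frequency panel entry at or
   above 1% — calls matching only sub-1% entries are retained and
   labeled `"< 1%"`, calls matching nothing are labeled `"-"`;
3. remove calls matched by a known-variant (DGV-like) panel entry;
4. retain only calls replicated by the secondary caller in the **same
   subject**.

Matching everywhere is same-type with a 50% reciprocal overlap by
default. The source protocols do not state an overlap rule; 50%
reciprocal is standard CNV-matching practice, it is a single
configuration knob applied identically at every step, and the rule used
is recorded in the report for audit. Step order is fixed as above
because the cascade counts only make sense sequentially. Retained sets
are nested by construction and removal reasons partition the removed
calls; both properties are asserted in tests, and every overlap filter
is proven equivalent to a brute-force all-pairs matcher.

The functional gene-list screen re-applies the probe filter at relaxed
thresholds (15/15 instead of the stringent genome-wide 25/50) and
reports calls overlapping curated gene lists (1: genes with CNVs
reported in the disease; 2: linkage/GWAS genes; 3: autoimmunity genes).

# Locus genotypes and joint association

Integer copy number classifies as deletion (< 2), diploid (2) or
duplication (> 2). For two loci A and B the joint genotype is one of
eight categories (diploid at both; del or dup at A only, at B only, or
at both; `mixed` = del at one and dup at the other). One logistic model
with category indicator variables plus sex and one ancestry component
estimates each category's odds ratio against the diploid-at-both
reference (Wald 95% intervals). `mixed` subjects are excluded from the
model by default and reported in the counts only — the headline
contrasts are the six del/dup categories — since pooling a
del-and-dup genotype into either class would blur both.

Sparse categories can separate the likelihood. Separation is detected
(boundary fitted probabilities or exploded standard errors) and the
model is refit with Firth's bias-reduced penalized likelihood
(Jeffreys-prior score correction), which gives finite estimates and
usable intervals at small carrier counts; results carry a method label
so penalized fits are never silent.

# Assay quantification

**qPCR (delta-delta-Ct).** Triplicate QC: if the replicate range is
within 0.5 cycles use the mean of three; otherwise drop the replicate
farthest from the median and use the mean of two; fewer than two finite
replicates fails the sample. `dCt = mean(Ct_target) -
mean(Ct_reference)`, `ddCt = dCt - dCt_calibrator` from a known-diploid
calibrator, and `CN = 2 * 2^(-ddCt)` at assumed perfect efficiency
(efficiency-corrected quantification is out of scope). Replicate
standard errors propagate to a 95% CI on the estimate. A non-amplified
target with an amplified reference is copy number 0.

**ddPCR.** With positive fraction `p` of `N` accepted droplets, the
Poisson-corrected concentration is `lambda = -ln(1 - p)` copies per
droplet over the droplet volume (0.85 nL default, vendor-standard). The
single-well 95% CI transforms the normal-approximation binomial
interval on `p` through the same map; zero positives yield 0 with a
rule-of-three upper bound; saturated wells error. Copy number is
`2 * conc_target / conc_reference`, with a delta-method CI on the log
ratio treating wells as independent (`var(lambda) = p / ((1-p) N)`).
Droplet volume cancels from the ratio when shared. A run is gated by an
internal-control sample that must be called diploid at both genes.

**Integer calling.** Both assays call integers by half-up rounding with
a no-call band: estimates within 0.15 of a half-integer are ambiguous
and yield no call. The source protocols state neither QC rules nor
rounding thresholds; these values are flagged in output metadata.

# The synthetic cohort generator

The generator exists so that every stage can be tested against known
truth. Its defaults are the study conditions: 23 cases and 110 controls
for the array stage; negative-binomial per-sample call counts with
means 19 (cases) and 24 (controls) and dispersion 5 (matching reported
SDs near 10-11 and ranges 5-55 / 7-74, which a Poisson cannot produce);
losses are 76% of case calls and 62% of control calls; lognormal sizes
with log-means `log(20 kb)` (losses) and `log(70 kb)` (gains) and
log-SD 0.9, making mean deletion size ~3.5x smaller than duplications,
inside the reported 3.2-4.0 band; chromosome assignment proportional to
GRCh37 length with the X weight multiplied by 6, which puts ~24% of
calls on X — the highest of any chromosome, matching the control
group's X share (a single multiplier cannot simultaneously reproduce
the higher case-group share); admixture proportions
Dirichlet(2, 7, 1), i.e. mean 20% African / 70% European / 10%
Amerindian, a realistic tri-hybrid Brazilian profile.

Calls are drawn either from a shared pool of 300 polymorphic loci with
log-uniform population frequencies (0.2%-40%) or as subject-private
segments. All generated intervals — pool loci, private calls, risk
loci, secondary-caller noise — are placed pairwise non-overlapping by
rejection sampling (widths capped at 1 Mb to keep genome occupancy
low). This makes interval-overlap matching coincide with locus
identity, so ground-truth rarity is well defined and the rare pipeline
can be held to exact sensitivity and specificity 1 when its overlap
rule matches the generator's disjoint geometry. The frequency and
known-variant panels jointly cover the entire pool, and a case call's
truth label is: frequency < 1%, carried by no control, absent from the
known-variant panel, and replicated by the secondary caller — computed
from generative state, never by re-running the matcher.

Two risk loci are planted by default, whole-gene analogues of the
chromosome 1 Fc-gamma-receptor locus (deletion odds ratio 3.6,
duplication 0.2) and the chromosome 8 ADAM-family locus (deletion 1.0,
duplication 0.2). Control carrier frequencies are set to 0.10/0.10 per
class; these are stated assumptions — realistic for multi-allelic CNV
loci — because control frequencies are not printed in the source
material. Per-locus case probabilities come from marginal odds
inversion (`odds_case = odds_control * OR`). For joint two-locus
planting, `plant_joint_genotypes()` draws categories from a multinomial
whose case weights are control probabilities times the target category
odds ratios, renormalized — exactly the generating process under which
the dummy-coded logistic model's odds ratios equal the targets.

The qPCR generator writes Ct triplicates with
`Ct_target = Ct_ref - log2(CN/2)` plus Gaussian replicate noise,
defaulting to 0.03 cycles. That default encodes a deliberate
constraint: discriminating CN 4 from CN 3 by relative quantification
requires the ddCt error (including the calibrator's own shared
triplicate error) to be far below `log2(4/3.5) = 0.19` cycles, so
reliable integer recovery across CN 0-4 — which the test suite demands
at 99% — is only attainable in an excellent-triplicate regime. Plates
with routine 0.1-0.3-cycle scatter will no-call or miscall high copy
numbers, and that is a property of the assay, not of the caller. The
ddPCR generator draws droplet positives binomially from Poisson
occupancy probabilities; no such constraint arises at 15,000 droplets.

What the generator does **not** emulate: probe-level intensities and
segmentation artifacts, breakpoint jitter between callers (replicated
calls share exact coordinates), linkage between loci, overlapping
polymorphic loci (real CNV hotspots nest and stack), batch effects, and
ancestry-correlated CNV frequencies. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to segmentation noise — rule sensitivity on real
data should be explored through the `overlap_rule` and threshold knobs.

# Numerical choices and problem sizes

Half-up rounding (`floor(x + 0.5)`) is used for kb sizes and integer
CN calls, avoiding banker's-rounding surprises at .5 boundaries. CNVR
output order is canonicalized (type, chromosome, start) so results are
independent of input order. Logistic fits use `stats::glm`; Wald
intervals use 1.96 SE. The test suite exercises: parameter recovery for
the planted odds ratios (3.6 single-deletion, 5.9 joint-deletion, 0.2
duplication) at n = 2,000 over 100-200 replicates with >= 90% CI
coverage and >= 90% synergy-ordering rate; type-I error within two
binomial SE of 5% under permuted labels (400 replicates); brute-force
oracle equivalence for all overlap machinery (up to 500x500 instances
and 1,000 random CNVR instances); and >= 99% integer-CN recovery for
both assay routes over CN 0-4 (200 samples). These sizes were chosen to
give stable Monte-Carlo estimates at interactive runtimes.

# Limitations

Adjusted odds ratios from the original study are not point-reproducible
without individual-level genotypes and ancestry estimates, which are
not published; the package therefore validates its association
machinery by parameter recovery on synthetic cohorts planted at the
published effect sizes. Ancestry inference itself (AIM panels) is out
of scope — admixture proportions are consumed as input. The rare
pipeline's exactness guarantee holds under the generator's disjoint
geometry; on real data the reciprocal-overlap rule is a tunable with
real sensitivity, and the per-step audit trail exists precisely so such
choices remain visible.
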