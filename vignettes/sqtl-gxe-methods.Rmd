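---
title: "Mapping environment-responsive splicing QTLs in a multiparental panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping environment-responsive splicing QTLs in a multiparental panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A recombinant inbred line (RIL) panel descended from eight founder strains
is assayed by RNA-seq under two conditions — control food and food spiked
with lead acetate — with every line measured once per condition (a paired
design: 2 × n lines). Genotypes are not SNPs but *founder haplotype
probabilities*: at every genomic locus j and line i, a vector
G<sub>ij</sub> over the eight founders A1..A8 that sums to one. The
question is which loci change *splicing* in response to lead, and in a
founder-specific way: a genotype-by-environment (G×E) interaction on
splicing ratios rather than on overall expression.

`sqtlgxe` implements that analysis end to end, together with a synthetic
data generator that emulates the study design so every stage can be
exercised and validated without the original sequencing data.

## The two splicing phenotypes

Two complementary quantitative traits are built from exon- and
transcript-level read counts:

1. **Exon fraction** (`exon_fraction()`): for exon e of gene g in sample
   n, the exon's reads divided by the summed reads of *all* transcripts of
   g in that sample. The gene-level denominator is well defined even for
   exons shared between isoforms. Cells with a zero denominator are
   missing under the default `zero_policy = "drop"`, and phenotypes
   missing in more than 20% of samples are removed; a pseudocount mode
   exists for dense designs. Changes in this trait flag differential exon
   usage regardless of which isoform drives it.

2. **Isoform dosage** (`isoform_groups()`): for every gene with at least
   two expressed isoforms, the block of (normalized) transcript values
   across samples, analysed jointly. This catches events where isoform
   totals shift together and the per-exon fraction barely moves.

Each phenotype is anchored at the midpoint of its host gene's span; the
anchor is what cis/trans classification and the sQTL-map axes use. The
convention is ours — any fixed per-gene point works, and the midpoint is
robust to transcript-end annotation noise.

## Normalization

Raw fractions and transcript counts are not Gaussian and carry sample-level
technical structure, so two steps precede model fitting:

* **Quantile normalization** (`quantile_normalize()`) forces every sample
  column onto the cross-sample mean order-statistic vector. Ranks are
  computed on non-missing values only; tied values receive the mean of
  their tied target values; missing cells stay missing. Columns with
  different missingness are matched to the reference by interpolation on
  rank quantiles. Note the reference itself is data-dependent: a monotone
  transform of one column changes the reference, so only within-column
  *ranks* are invariant to such transforms.

* **Principal-component removal** (`remove_pcs()`) centers each phenotype
  and regresses out the top sample-space components: 3 for exon fractions,
  4 for transcript values (both overridable). The differing counts are
  deliberate — fractions are within-gene ratios, so gene-scaling technical
  variation cancels and their latent structure has lower rank than the
  expression matrix. Because the contrast tested downstream is aligned
  with the treatment, the treatment vector can be *protected*: each
  component is residualized on it before removal (`protect = E`), so
  treatment-aligned signal is never absorbed. The removed basis is
  returned in the report; residuals are orthogonal to it (re-projection is
  a no-op within 1e-8), and a rank-1 matrix is annihilated exactly by
  removing one component. Missing cells are mean-imputed for the
  decomposition and restored afterwards.

## The nested G×E models

Every (phenotype, locus) pair is tested with a partial F-test between
nested ordinary-least-squares models. For the univariate exon-fraction
trait Y with treatment indicator E (0 = control, 1 = lead):

* H0: Y = μ + βᴱE + ε
* HA: Y = μ + βᴱE + Σᵢ (βᵢᴳ Gᵢ + βᵢᴳˣᴱ Gᵢ E) + ε

with i running over founders. The eight probability columns sum to one and
are collinear with the intercept, so one founder (default A8) is dropped
from the genotype and interaction blocks; the F statistic is invariant to
the choice (tested to 1e-8), as it is to all-zero dummy founder columns,
which are removed rather than allowed to make the fit rank-deficient.

For the isoform-dosage trait the response is stacked across isoforms k,
with per-isoform intercepts μₖ and per-isoform treatment terms in *both*
models; the null also carries a genotype main effect shared across
isoforms, and the alternative adds genotype×isoform and
genotype×treatment×isoform blocks, tested jointly (`tested_block =
"as_printed"`). A variant (`"gxe_only"`) moves the genotype×isoform block
into the null so that only the three-way interaction is tested; it is the
statistically cleaner question, but the shared-main-effect form is the
default because it matches the model as conventionally written.

Numerical contracts: missing responses are dropped pairwise per fit; a
design that is rank-deficient beyond the planned reference drop, or has
fewer observations than parameters, or fewer than two samples per
treatment arm, is *flagged* and gets a missing p-value (never 1); a
constant response gives F = 0, p = 1. Fits go through pivoted QR; both
models' F and p agree with an independent normal-equations solver to 1e-8
on randomized instances, and 2,000 null fits per model pass a
Kolmogorov–Smirnov uniformity check at α = 0.01.

One caveat we measured: the stacked isoform model treats all (sample,
isoform) residuals as independent, but isoform values of one sample are
correlated (compositionally and through shared sample factors). The
resulting null p-values are close to uniform but mildly left-shifted
(median ≈ 0.46 in our simulations) — acceptable at the stringent p ≤ 1e-4
calling threshold, and worth remembering when interpreting mid-range
p-values.

## Significance, method combination, cis/trans

P-values become Storey q-values (`qvalues()`): π0 is estimated by the
smoother over λ = 0.05..0.95 (cubic spline, evaluated at λ = 0.95) and the
q-value is π0·m·p/rank with a cumulative-minimum monotonicity step. With
π0 = 1 this reduces exactly to Benjamini–Hochberg. An association is
called significant by the joint rule **p ≤ 1e-4 and q ≤ 0.39**
(`call_significant()`). The q-threshold alone is deliberately liberal — at
a nominal 39% FDR the expected false fraction among the q-only calls *is*
about 0.4, and π0-estimation error or test correlation push the realized
value higher — so it is the joint rule, dominated in practice by the
p-cutoff, that controls discoveries; our pooled planted-truth experiments
realize an FDP of a few percent under it.

Calls from the two phenotype methods are combined on the (gene, locus)
key (`combine_methods()`), labeled `exon_only` / `isoform_only` /
`shared`, with the union identity nUnion = nA + nB − nShared enforced by
construction. Each call is cis when its locus lies on the host gene's
chromosome within 1 Mb of the anchor (closed bound), else trans; 1 Mb is
the conventional QTL-scale window, configurable.

## Trans-hotspot detection

A trans-sQTL hotspot is one locus whose genotype associates with splicing
of many genes genome-wide — a vertical band on the sQTL map. Loci are
binned (`find_hotspots()`), each bin scored by its number of distinct
trans-target genes. Two design points matter:

* **Clumping.** Founder mosaics are correlated along a chromosome, so one
  gene's association spans several linked loci. Calls are collapsed to one
  exchangeable unit per (gene, bin) before scoring; otherwise the
  LD-duplicated calls flood the null and mask the hotspot itself.
* **The null.** Each null draw reassigns every unit a locus uniform over
  the *tested grid* (then bins it). Permuting the observed locus column
  would preserve the hotspot's own pile-up in every permutation — the
  locus multiset is invariant under permutation — and would have no power
  against exactly the alternative being tested. The uniform-reassignment
  null preserves the unit count and gene multiplicities while breaking
  locus clustering.

Bins pass at an empirical p below 0.05/(number of scored bins). Condition
specificity can be assessed by running the detector on treatment-
interaction calls versus control-only refits.

## AS event classification

For annotating sQTL genes, transcript pairs are classified into the four
canonical alternative-splicing event types (`classify_event()`): an intron
of one isoform inside an exon of the other is **intron retention**; an
internal exon absent between two shared splice sites is **exon skipping**;
intron pairs sharing one boundary but not the other are **alternative
donor** (5′ splice site differs) or **alternative acceptor** (3′ differs),
strand-aware. Terminal-exon differences are labeled `other` — they are
transcription start/end effects, not splicing proper. The classification
is symmetric in argument order, translation-invariant, swaps
donor/acceptor under a pure strand relabel, and is a fixed point under
mirror-and-strand-flip (the same molecule read from the other end).
`summarize_events()` tallies types over all isoform pairs of each distinct
sQTL gene, reporting both pair-level and gene-level counts.

## Differential expression

The auxiliary expression-level contrast fits, per transcript, log2 CPM on
treatment with the RIL as a categorical covariate — the paired contrast in
this balanced design — using one shared QR decomposition for all
transcripts; results match per-transcript `lm()` to machine precision. MA
quantities are M = log2(lead mean / control mean) and A = their average,
with a pseudocount. We use CPM rather than length-normalized abundances;
M is length-invariant under the ratio so the divergence is immaterial for
the fold-change scale.

## The synthetic data generator

The generator defines the study conditions:

* **Genotypes** (`simulate_founder_mosaics()`): founder labels follow a
  Markov chain along each chromosome (switch probability 0.05 per 10 kb
  step, uniform over the other founders), emulating the block mosaics
  that many generations of intercrossing and inbreeding produce —
  phenomenologically, not by simulating the breeding design or the HMM
  genotyper. A Dirichlet jitter (`blur = 0.05`, concentration 200) turns
  labels into soft probabilities like real HMM output.
* **Annotation** (`make_annotation()`): genes laid along chromosomes, each
  with a pool of non-overlapping exons; isoforms take ordered subsets
  sharing first and last exons, so multi-isoform genes naturally exhibit
  skipping and donor/acceptor differences, and with probability 0.15 an
  isoform retains an intron (fusing an adjacent exon pair), so all four
  event types occur.
* **Counts** (`simulate_counts()`): gene baselines are lognormal (sdlog
  0.6 around a mean depth of 400 reads); isoform proportions are
  logistic-normal (per-sample log-weight sd 0.25); transcript counts are
  negative binomial with dispersion 0.1 (a typical bulk RNA-seq value);
  library-size factors are lognormal (sdlog 0.15). Exon counts are
  *binomial subsamples* of the gene's realized transcript reads at the
  exon's inclusion fraction — exon reads are a subset of gene reads, so
  the exon/gene ratio is free of double-counted overdispersion and never
  exceeds one. Four latent sample factors (loading sd 0.3) perturb
  transcript log-means; exon-inclusion logits load only the first three,
  because ratios cancel gene-scaling technical variation — mirroring the
  pipeline's 4-versus-3 component removal.
* **Planted truth** (`sim_truth()`): a cis G×E effect of size δ on founder
  f at locus j shifts the target's latent scale by δ·G·E — the logit of
  expected exon inclusion for exon targets, the log expected count of the
  target transcript for isoform targets. Raw fractions live in [0, 1], so
  "phenotype units" must mean this latent scale; the group-mean recovery
  oracle measures empirical-logit / log-count contrasts accordingly. The
  generator resolves the concrete target at simulation time to an
  *alternatively used* feature (mid-inclusion exon, most-expressed
  isoform): a near-saturated exon cannot respond to a splicing QTL. A
  trans hotspot applies isoform-usage shifts of this form to many genes
  from one locus.

What the generator does **not** emulate: sequence content and read-level
artifacts (mappability, GC, positional bias), annotation errors,
non-founder genetic variation, linkage between chromosomes, dominance (the
panel is homozygous), and expression-level QTLs. Passing tests therefore
demonstrate the statistical machinery under a faithful abstraction of the
design, not robustness to every failure mode of real sequencing data.

## Interactions we measured, and their consequences

Three desk-scale phenomena shaped the defaults and the validation design;
all stem from the panel being hundreds of phenotypes instead of ~10⁵:

* **PC removal can eat the signal.** Without latent confounders the top
  sample-space PCs lock onto the planted QTL direction itself (a planted
  effect at p ≈ 1e-45 raw became p ≈ 0.24 after removal). With the
  batch-like factor layer present — the structure PC removal exists to
  absorb — removal *recovers* masked signal (p 4e-3 raw → 4e-17
  normalized). Relatedly, a trans hotspot co-shifting a large share of
  transcripts is itself a leading PC; recovery requires it to be a small
  share of the transcriptome, as it is in real data (we use 50 targets
  among 250 background genes).
* **Leakage.** When planted effects are coherent (many targets driven from
  one chromosome), the partially absorbed dose direction leaks with
  opposite sign into null phenotypes, inflating their tails; spreading
  effects across chromosomes removes the coherence. At transcriptome
  scale both effects are negligible.
* **Power at the detection edge.** With these noise conditions, a δ = 1.0
  latent-logit cis G×E effect at 100 RILs is detected at p < 1e-4 in
  roughly 70% of replicates (the noncentrality sits almost exactly at the
  threshold; per-seed founder mass and the target's baseline inclusion
  decide the outcome). At the generator's canonical δ = 1.5 the rate is
  ~85–90%. Both rates are recomputed by the acceptance script.

## Problem sizes

The validation suite runs at deliberately compact sizes: oracle checks on
12–30-sample designs; null calibration with 2,000 fits per model; recovery
over 20 seeds at 100 RILs × 10 genes; false-discovery and hotspot
experiments at 60 RILs with 40–250 genes and 10–27 loci over up to five
chromosome arms; the worked analysis under `analysis/` uses 60 RILs, 120
genes, 27 loci. These sizes keep every property measurable in minutes
while preserving the regime the method operates in.
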