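---
title: "Detecting condensate-sensitive TAD boundaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condensate-sensitive TAD boundaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Topologically associating domains (TADs) partition mammalian chromosomes
into self-interacting blocks separated by boundary elements. Most
boundaries are anchored by CTCF/cohesin loop extrusion, but a subset
appears to be maintained instead by transcription-associated biomolecular
condensates: brief exposure to 1,6-hexanediol (1,6-HD), which dissolves
many membraneless assemblies, transiently weakens the insulation of roughly
a fifth of boundaries (HDS boundaries), which then recover after washout.
These boundaries are highly transcribed, occur in genomic clusters, engage
in elevated interchromosomal contacts, and are enriched for housekeeping
genes.

`insuldiff` implements the complete computational chain needed to detect
and characterise such boundaries from perturbation Hi-C and PRO-seq
experiments, together with a synthetic-data generator with known ground
truth so that every stage can be validated quantitatively. The package is
organised as an analysis workflow: numbered drivers under `analysis/` run
the stages over simulated data; all computation lives in package functions.

# The insulation model

For a balanced cis contact matrix at bin size $b$ (40 kb by default) and a
window of $w$ bins, the raw insulation of bin $i$ is the mean contact count
over the $w \times w$ square of bin pairs $(u, v)$ that straddle it
($i - w \le u < i < v \le i + w$). The reported score is

$$s_i = \log_2 \frac{\mathrm{raw}_i}{\overline{\mathrm{raw}}_{\text{chrom}}},$$

and TAD boundaries are local minima of $s$ with topographic prominence at
least 0.1 log2 units. Design choices that the underlying experimental
literature leaves open, fixed here once:

* **Window 480 kb** (12 bins at 40 kb). Spans typical TADs; configurable.
* **Balancing first.** Matrices are balanced by symmetric iterative
  proportional fitting until all unmasked row sums agree to a relative
  $10^{-5}$; bins with fewer than 5 nonzero entries are masked. A
  raw-count mode is retained.
* **Chromosome-wide mean** in the denominator, removing per-chromosome
  coverage differences. A side effect worth knowing: a strong perturbation
  that raises contact flow across some boundaries shifts the chromosome
  mean slightly, imprinting small (±0.01–0.03 log2) systematic deltas on
  *unaffected* boundaries. At the simulated depth this is well below the
  replicate noise floor but it is visible on noise-free expected matrices.
* **Zero guard.** A raw insulation of exactly 0 (a contact-free junction)
  is floored at half the smallest positive raw value on that chromosome, so
  such boundaries remain callable with a finite score.
* **Plateau minima** resolve to their leftmost bin; masked bins split a
  chromosome into independently scanned segments. For a sharp planted
  boundary the two flanking bins form a two-bin plateau, so calls land one
  bin left of the planted edge — recovery is therefore always assessed
  within ±1 bin.

# Differential testing

Boundaries are called once on the pooled control and then scored in every
sample at the same bin (a masked bin gives a missing value, never a zero).
Per boundary, a Gaussian identity-link GLM `score ~ condition` is fit; with
two replicates per condition this is exactly the pooled two-sample t-test,
and the package's vectorised implementation is tested to agree with the
GLM path to ten significant digits. Benjamini–Hochberg correction runs
across all boundaries with a defined p-value; a boundary is **HDS** when
$q < 0.05$ *and* the treated-minus-control delta is positive (weakened
insulation moves the log-ratio toward zero). Zero-variance boundaries are
flagged (`p = NaN`) and excluded from the FDR computation rather than
swallowed.

Two variance modes exist. The default is the plain per-boundary GLM. An
optional `var_mode = "pooled"` replaces each boundary's variance with the
cross-boundary mean (degrees of freedom summed). We evaluated both in the
power study and kept the default: boundary score variances are strongly
heterogeneous (replicate standard deviations from 0.01 to 0.14 in the demo
conditions), and a shared variance understates the standard error at noisy
boundaries, which measurably inflated the false discovery rate. The pooled
mode remains available, clearly labelled, for users with very limited
replication who accept that trade-off.

The same machinery drives the compartment switch test and the recovery
time course (each post-treatment time point contrasted against control; the
generator's recovery schedule makes HDS counts decay to zero by the 3-h
analogue).

# Compartments

At 500-kb bins, expected counts per diagonal are the diagonal means; the
observed/expected matrix is correlated across valid bins (Pearson) and the
leading eigenvector of the correlation matrix is the compartment profile,
computed per chromosome (genome-wide PCA would be vulnerable to
translocation-like artifacts and is not what the field's tools do). The
eigenvector sign is fixed by positive correlation with a caller-supplied
orientation track — gene density on real data, the planted labels in
simulation. Chromosomes with fewer than 10 valid bins are skipped with a
warning. The switched-bin test mirrors the boundary GLM per bin; it is a
reconstruction, since the experimental literature reports switched-bin
counts without describing the test.

# Spatial clustering and trans contacts

HDS boundaries within 1 Mb of a centromere are removed first (strict
inequality: a boundary exactly 1 Mb away is kept). Clustering is a single
linear sweep per chromosome merging consecutive boundaries with gaps at or
below 2 Mb; runs of at least two are clusters. The gap threshold is not
dictated by the data and is configurable; the cluster summary (count, mean,
min, max members, clustered fraction) is always reported so users can
compare against published descriptives.

Interchromosomal aggregation assigns each 4-Mb bin its HDS-boundary count,
groups bins (0, 1, 2, 3+), normalises each sample to counts-per-million of
total trans contacts, and averages CPM over interchromosomal bin pairs
whose two bins share a group (a one-sided mode is available). A companion
table of total boundary counts per group guards against the confounder
that HDS-dense bins might simply be boundary-dense. Housekeeping genes are
defined as the intersection of per-tissue top-fraction expression lists
(top 1% on real data; 5% at demo scale, where 1% of 200 genes would leave
the intersection empty), and their enrichment on cluster spans is a simple
density ratio (genes per Mb inside vs outside, midpoint containment).

# PRO-seq pausing

The pausing index of a gene is the read density of the promoter-proximal
window over the gene-body density, with strand-aware windows
$[\mathrm{TSS}-50, \mathrm{TSS}+300)$ and $[\mathrm{TSS}+300,
\mathrm{TES})$ in the direction of transcription; the cited convention
does not pin the window sizes, so they are configurable, and the index is
reported only when the body has at least 10 reads. Differential pausing
sums pause/body counts over replicates and applies Fisher's exact test per
gene with BH correction; classes follow the direction of the index change
at $q < 0.05$. Annotation-driven quantification replaces de novo transcript
discovery — a deliberate simplification.

# The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions used throughout the tests and the acceptance script.

Cis contacts for bins $i, j$ have expectation

$$E_{ij} = D\,(1+|i-j|)^{-\alpha}\; \tau^{[\text{same TAD}]}
\prod_{\text{boundaries } b \text{ between } i,j} \pi_b^{\text{eff}},$$

with Poisson sampling, $\alpha = 1$ (the canonical contact decay),
intra-TAD boost $\tau = 2$, and $D$ scaled so each chromosome receives an
expected $10^6$ contacts per replicate. Boundary permeabilities are drawn
once per configuration from $U(0.15, 0.5)$. Treatment raises the effective
permeability of HDS boundaries only, $\pi^{\text{eff}} = \pi + w(1-\pi)$,
over a schedule $w = (0, 0.6, 0.25, 0)$ for control, treatment, 30-min and
3-h recovery analogues — chosen so that insulation shifts are modest (of
order one log2 unit at the boundary bin) rather than total ablations. The
demo genome is two (or more) 20-Mb chromosomes with 10 boundaries each,
20% HDS placed as adjacent pairs so that they form genomic clusters, and
mid-chromosome centromeres.

Trans contacts are uniform at a baseline rate with a multiplicative
enrichment $\varepsilon$ when both 4-Mb bins belong to a designated hub
set; treatment relaxes $\varepsilon$ toward 1 by the same schedule. The
dedicated trans demo genome plants an HDS-count gradient (0–3 per bin)
whose hub-membership fraction rises with the count, so group means
increase strictly and the top/bottom CPM ratio converges to $\varepsilon$.

PRO-seq reads per gene are Poisson around expression × depth; a fraction
`f_pause` lands uniformly in the strand-aware pause window and the rest
uniformly in the body, giving the closed-form expected pausing index
$f L_{\text{body}} / ((1-f) L_{\text{pause}})$ used as the oracle in
tests. Genes near HDS boundaries transcribe at twice baseline and raise
`f_pause` from 0.4 to 0.7 under full weakening. Expression tables are
log-normal over 54 tissues with housekeeping genes drawn high in all
tissues and placed inside cluster spans with probability 0.35 (giving a
roughly five-fold density enrichment in expectation; single demo runs
fluctuate widely because only ~10 genes and ~4 Mb of cluster span are
involved). Compartment structure is simulated at 500 kb as an alternating
±1 block pattern multiplying contacts by $1 \pm s$ ($s = 0.4$) for same-
vs different-label bins; it is kept out of the 40-kb boundary simulations
so the two analyses stay orthogonal.

Randomness: every stream is derived deterministically from the master seed
plus (stage, condition, replicate) labels, so outputs are bit-reproducible
and adding a replicate never perturbs existing ones.

**What the generator does not emulate:** loop/stripe features, fragment- or
read-level noise, mappability and GC bias, copy-number variation,
negative-binomial overdispersion (a Poisson model is the simplest that
exercises the GLM; an overdispersion hook exists in the design but real
Hi-C replicates are noisier), or realistic genome sizes. Passing tests
demonstrate that the implementation recovers planted signal under its own
generative assumptions at desk scale — not that the pipeline's thresholds
are tuned for any particular real dataset.

# Numerical and degenerate-input choices

* Balancing failure after 1,000 iterations raises an error carrying the
  iteration count; all-zero rows are masked, not iterated on.
* Chromosomes shorter than $2w+1$ bins yield an all-masked insulation
  track with a warning, not an error; short terminal bins are always
  masked.
* Insulation scoring is exact against an exhaustive enumeration oracle on
  random matrices (property-tested), and clustering is exact against a
  brute-force transitive-closure oracle.
* Ties: plateau minima take the leftmost bin; union-mode boundary merging
  across samples keeps the lower-score bin of calls within one bin.
* An empty TAD partition is a single-TAD genome, not an error; an empty
  boundary table classifies to an empty result; an empty housekeeping
  intersection flags the enrichment as undefined rather than returning a
  number.

# Problem sizes

The bundled study design was sized so that the whole chain — simulation,
balancing, scoring, calling, testing — runs end to end in seconds and the
full validation suite in a few minutes on a single core: 2×20-Mb demo
genome (1,000 bins at 40 kb) for boundary analyses, 4 chromosomes for the
power study (40 boundaries, 8 HDS, three independent simulated
experiments), 200 null runs × 5,000 boundaries for calibration, 200 genes
for PRO-seq. Statistical conclusions (calibration bands, sensitivity,
FDR) are reported with the problem size that produced them.

# Known limitations

* Two replicates per condition leave the per-boundary variance estimate on
  2 degrees of freedom; realized FDR in any single experiment is coarse
  (one false call among ~10 discoveries is a 10% jump), which is why power
  and FDR are quoted as aggregates over independent simulated experiments.
* The differential-compartment and differential-pausing tests are
  reconstructions of analyses whose exact form is not published; they are
  internally consistent with the boundary GLM but not guaranteed to match
  any external implementation.
* The pipeline consumes bin-level contact matrices; alignment, pair
  filtering and matrix construction from raw reads are out of scope.
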