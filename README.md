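# insuldiff

Differential insulation analysis of TAD boundaries from perturbation Hi-C,
with companion nascent-transcription (PRO-seq) analytics and a synthetic
data generator with known ground truth.

## The problem

A subset of topologically associating domain (TAD) boundaries is maintained
not by CTCF/cohesin loop extrusion but by transcription-associated
condensates: dissolving those assemblies (e.g. with a brief 1,6-hexanediol
treatment) transiently weakens the insulation of ~20% of boundaries, which
recover after washout. Detecting these condensate-sensitive ("HDS")
boundaries requires a chain of analyses:

1. **Insulation score** per 40-kb bin: for window $w$,
   $s_i = \log_2\!\big(\mathrm{mean}\{C_{uv}: i-w \le u < i < v \le i+w\} \,/\, \bar{s}_{\mathrm{chrom}}\big)$
   on a balanced contact matrix; TAD boundaries are prominent local minima.
2. **Differential insulation**: per boundary, a Gaussian GLM
   `score ~ condition` across replicates (equal to the pooled t-test at
   2v2), Benjamini–Hochberg FDR, and classification as HDS when
   $q < 0.05$ with a positive (weakening) effect.
3. **A/B compartments** at 500 kb: leading eigenvector of the
   distance-normalised correlation matrix, per chromosome, plus a per-bin
   switch test.
4. **Spatial analyses**: centromere filtering, clustering of HDS boundaries
   along the genome (2-Mb gap sweep), interchromosomal contact aggregation
   of 4-Mb bins grouped by HDS-boundary count (CPM-normalised), and
   housekeeping-gene enrichment on cluster spans.
5. **PRO-seq pausing**: pausing index
   $\mathrm{PI} = (\mathrm{pause\ reads}/L_p)/(\mathrm{body\ reads}/L_b)$
   with strand-aware windows, and differential pausing by Fisher's exact
   test on summed pause/body counts.

All of this is implemented here over plain text formats (bin-pair triplet
TSV, BED, bedGraph, TSV), with a generator that simulates the full
multi-condition, multi-replicate study design — distance-decaying TADs with
boundaries of known permeability, a treatment that weakens a known HDS
subset and then recovers, trans-contact hubs, and PRO-seq with tunable
pausing — so every stage is validated against planted truth.

## Worked example

The numbered scripts under `analysis/` run the whole study on the bundled
synthetic design (seed via the `SEED` environment variable, default 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_insulation_boundaries.R
Rscript analysis/03_differential_boundaries.R
Rscript analysis/04_compartments.R
Rscript analysis/05_clusters_trans.R
Rscript analysis/06_proseq.R
```

which prints, at seed 1:

```
simulated 4 conditions x 2 replicates (seed 1): 35 files under results/data
planted: 20 boundaries (4 HDS), depth 1000000 contacts/chromosome/replicate
called 22 boundaries on the pooled control; 20/20 planted boundaries recovered within 1 bin
treat_5min vs control: 4 HDS, 18 unaffected (18.2% HDS)
HDS calls per time point: treat_5min=4, recover_30min=4, recover_3h=0
PC1 sign matches the planted checkerboard on 100.0% of 80 valid bins
switched bins at FDR < 0.05: 0 of 80 tested
HDS clusters: 2 (mean 2.0 members, min 2, max 2); 100% of HDS boundaries clustered
trans CPM top/bottom group ratio: 1.98 (control), 1.41 (treatment)
housekeeping enrichment on clusters: 13.96-fold (6/10 genes inside; clusters = 9.7% of genome)
central PRO-seq density: HDS 0.0661 vs unaffected 0.0322 reads/bp
differential pausing: 12 more paused, 2 less paused, 186 unchanged
20.0% of boundary-region transcripts lie on HDS boundaries
```

Reading this: all 20 planted boundaries are recovered within one 40-kb bin;
exactly the 4 planted HDS boundaries are called significant against the
control and none remain by the 3-h recovery analogue; compartments are
untouched by the perturbation; the planted interchromosomal hub enrichment
(2×) is recovered in the control and relaxes under treatment (the schedule
predicts 1.4); HDS-boundary genes show twice the nascent transcription of
unaffected ones and are the genes called significantly more paused. The
trans ratio and boundary counts are deterministic given the seed; the
housekeeping enrichment fluctuates between runs because only ~10
housekeeping genes and ~4 Mb of cluster span are involved at demo scale
(its expectation under the generator is about five-fold).

Equivalently from R, `run_pipeline(seed = 1, outdir = "out")` executes the
same chain in one call and writes a manifest with MD5 checksums of every
output; rerunning with the same seed reproduces the checksums bit for bit.

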