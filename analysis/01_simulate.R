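#!/usr/bin/env Rscript
# Stage 1: generate the synthetic perturbation study.
#
# Two 20-Mb chromosomes at 40-kb bins, 20 planted TAD boundaries (20% HDS,
# placed as adjacent pairs), a treatment/recovery schedule (control,
# treatment, 30-min and 3-h recovery), two replicates per condition, plus a
# four-chromosome trans genome with a planted hub gradient, a 500-kb
# compartment checkerboard, PRO-seq coverage and a 54-tissue expression
# table. Everything is written in open text formats under results/data/.

library(insuldiff)
seed <- as.integer(Sys.getenv("SEED", "1"))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- demo_config(seed = seed)
write_layout(cfg$layout, file.path(out, "genome.chrom.sizes"),
             centromeres_path = file.path(out, "centromeres.bed"))
write_ground_truth(cfg, out)
write_bed(cfg$genes, file.path(out, "genes.bed"))

for (cond in cfg$conditions$condition) {
  for (r in seq_len(cfg$n_replicates)) {
    nm <- sprintf("%s_rep%d", cond, r)
    write_contacts(simulate_cis(cfg, cond, r),
                   file.path(out, sprintf("cis_%s.tsv", nm)))
    cov <- simulate_proseq(cfg, cond, r)
    write_bedgraph(cov$plus, file.path(out, sprintf("proseq_%s_plus.bedgraph", nm)))
    write_bedgraph(cov$minus, file.path(out, sprintf("proseq_%s_minus.bedgraph", nm)))
  }
}

tcfg <- trans_demo_config(seed = seed)
for (cond in tcfg$conditions$condition)
  write_contacts(pool_maps(lapply(1:2, function(r) simulate_trans(tcfg, cond, r))),
                 file.path(out, sprintf("trans_%s.tsv", cond)))
data.table::fwrite(tcfg$boundaries, file.path(out, "trans_truth_boundaries.tsv"), sep = "\t")

data.table::fwrite(simulate_expression(cfg), file.path(out, "expression.tsv"), sep = "\t")

message(sprintf("simulated %d conditions x %d replicates (seed %d): %d files under %s",
                nrow(cfg$conditions), cfg$n_replicates, seed,
                length(list.files(out)), out))
message(sprintf("planted: %d boundaries (%d HDS), depth %.0f contacts/chromosome/replicate",
                nrow(cfg$boundaries), sum(cfg$boundaries$hds), cfg$cis_depth))
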