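#!/usr/bin/env Rscript
# Stage 6: nascent-transcription analytics — boundary-centred PRO-seq
# profiles by boundary class, per-gene pausing indices, differential pausing
# (Fisher on pause/body counts), enrichment of deregulated genes on HDS vs
# unaffected boundary regions, and the HDS share of boundary transcripts.

library(insuldiff)
seed <- as.integer(Sys.getenv("SEED", "1"))
out <- "results"
data_dir <- "results/data"
cfg <- demo_config(seed = seed)

conds <- cfg$conditions$condition[1:2]
read_cov <- function(nm) list(
  plus = read_bedgraph(file.path(data_dir, sprintf("proseq_%s_plus.bedgraph", nm))),
  minus = read_bedgraph(file.path(data_dir, sprintf("proseq_%s_minus.bedgraph", nm))))

classified <- data.table::fread(file.path(out, "boundary_table.tsv"))

# boundary-centred profile, control replicate 1, split by class
cov1 <- read_cov(sprintf("%s_rep1", conds[1]))
prof <- boundary_transcription(cov1, classified, flank = 4e5, n_bins = 20)
cls <- profile_by_class(prof, classified$class)
data.table::fwrite(data.table::as.data.table(cls, keep.rownames = "class"),
                   file.path(out, "boundary_profiles.tsv"), sep = "\t")
center <- ncol(cls) / 2 + 0:1
message(sprintf("central PRO-seq density: HDS %.4f vs unaffected %.4f reads/bp",
                mean(cls["HDS", center]), mean(cls["unaffected", center])))

# pausing per condition/replicate, then the differential Fisher test
genes <- read_genes(file.path(data_dir, "genes.bed"), cfg$layout)
tabs <- lapply(conds, function(cond) lapply(1:2, function(r)
  pausing_index(read_cov(sprintf("%s_rep%d", cond, r)), genes)))
names(tabs) <- conds
pausing <- differential_pausing(tabs[[1]], tabs[[2]], fdr = 0.05)
data.table::fwrite(pausing, file.path(out, "pausing.tsv"), sep = "\t")
message(sprintf("differential pausing: %d more paused, %d less paused, %d unchanged",
                sum(pausing$class == "more_paused"), sum(pausing$class == "less_paused"),
                sum(pausing$class == "unchanged")))

# deregulated-gene enrichment on HDS vs unaffected regions (span-normalised)
region <- function(b) b[, .(chrom, start = pmax(0, midpoint - 2e5), end = midpoint + 2e5)]
hds_r <- region(classified[class == "HDS"])
una_r <- region(classified[class == "unaffected"])
up_genes <- genes[name %in% pausing[class == "more_paused"]$gene]
if (nrow(up_genes)) {
  enr <- deregulated_boundary_enrichment(up_genes, hds_r, una_r)
  message(sprintf("more-paused genes: %.2f-fold enriched on HDS vs unaffected regions (%d vs %d genes)",
                  enr$enrichment, enr$n_hds, enr$n_unaffected))
}
frac <- fraction_boundary_transcripts(genes, hds_r, rbind(hds_r, una_r))
message(sprintf("%.1f%% of boundary-region transcripts lie on HDS boundaries", 100 * frac))
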