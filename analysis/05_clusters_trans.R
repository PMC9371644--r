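#!/usr/bin/env Rscript
# Stage 5: genomic clustering of HDS boundaries (2-Mb gap sweep, after the
# 1-Mb centromere filter), interchromosomal contact aggregation by
# HDS-boundary density (CPM over 4-Mb bins), the total-boundary confounder
# check, and housekeeping-gene enrichment on cluster spans.

library(insuldiff)
seed <- as.integer(Sys.getenv("SEED", "1"))
out <- "results"
data_dir <- "results/data"
cfg <- demo_config(seed = seed)

classified <- data.table::fread(file.path(out, "boundary_table.tsv"))
hds <- filter_centromeric(classified[class == "HDS"], cfg$layout)
clustering <- cluster_boundaries(hds, gap = 2e6)
s <- clustering$summary
message(sprintf("HDS clusters: %d (mean %.1f members, min %s, max %s); %.0f%% of HDS boundaries clustered",
                s$n_clusters, s$mean_members, s$min_members, s$max_members,
                100 * s$frac_clustered))
if (nrow(clustering$clusters))
  write_bed(clustering$clusters[, .(chrom, start, end,
                                    name = sprintf("%s_n%d", cluster_id, n_members))],
            file.path(out, "hds_clusters.bed"))

# trans aggregation on the dedicated hub genome, per condition
tcfg <- trans_demo_config(seed = seed)
t_hds <- data.table::fread(file.path(data_dir, "trans_truth_boundaries.tsv"))[hds == TRUE]
agg <- data.table::rbindlist(lapply(tcfg$conditions$condition, function(cond) {
  tm <- read_contacts(file.path(data_dir, sprintf("trans_%s.tsv", cond)), tcfg$trans_bins)
  trans_aggregate(tm, t_hds, condition = cond)
}))
data.table::fwrite(agg, file.path(out, "trans_aggregate.tsv"), sep = "\t")
ctrl <- agg[condition == tcfg$conditions$condition[1]]
trt <- agg[condition == tcfg$conditions$condition[2]]
message(sprintf("trans CPM top/bottom group ratio: %.2f (control), %.2f (treatment)",
                ctrl$mean_cpm[nrow(ctrl)] / ctrl$mean_cpm[1],
                trt$mean_cpm[nrow(trt)] / trt$mean_cpm[1]))

confound <- control_total_boundaries(tcfg$trans_bins, tcfg$boundaries, t_hds)
data.table::fwrite(confound, file.path(out, "trans_total_boundary_control.tsv"), sep = "\t")

# housekeeping enrichment on cluster spans
expr <- data.table::fread(file.path(data_dir, "expression.tsv"))
genes <- read_genes(file.path(data_dir, "genes.bed"), cfg$layout)
if (nrow(clustering$clusters)) {
  hk <- housekeeping_enrichment(expr, genes, clustering$clusters, cfg$layout,
                                top_fraction = 0.05)
  message(sprintf("housekeeping enrichment on clusters: %.2f-fold (%d/%d genes inside; clusters = %.1f%% of genome)",
                  hk$enrichment, hk$n_inside, hk$n_housekeeping,
                  100 * hk$cluster_fraction))
  data.table::fwrite(
    data.table::data.table(metric = c("enrichment", "n_housekeeping", "n_inside", "cluster_fraction"),
                           value = c(hk$enrichment, hk$n_housekeeping, hk$n_inside, hk$cluster_fraction)),
    file.path(out, "housekeeping_enrichment.tsv"), sep = "\t")
}
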