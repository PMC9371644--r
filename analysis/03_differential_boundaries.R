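#!/usr/bin/env Rscript
# Stage 3: per-boundary Gaussian GLM of insulation scores (treatment vs
# control), BH FDR, HDS classification, and the recovery time course.

library(insuldiff)
out <- "results"
scored <- data.table::fread(file.path(out, "boundary_scores.tsv"))
samples <- data.table::fread(file.path(out, "sample_sheet.tsv"))

conds <- unique(samples$condition)
control <- conds[1]

tested <- differential_boundaries(scored, samples, control, conds[2])
classified <- classify_boundaries(tested, q_threshold = 0.05)
data.table::fwrite(classified, file.path(out, "boundary_table.tsv"), sep = "\t")
for (cl in c("HDS", "unaffected"))
  write_bed(classified[class == cl, .(chrom, start, end, name = boundary_id)],
            file.path(out, sprintf("boundaries_%s.bed", tolower(cl))))
summ <- attr(classified, "summary")
message(sprintf("%s vs %s: %d HDS, %d unaffected (%.1f%% HDS)",
                conds[2], control, summ$n_hds, summ$n_unaffected,
                100 * summ$n_hds / nrow(classified)))

# recovery: the same contrast at each later time point
recovery <- lapply(conds[-1], function(tc)
  classify_boundaries(differential_boundaries(scored, samples, control, tc), 0.05))
names(recovery) <- conds[-1]
ov <- overlap_timepoints(recovery)
message("HDS calls per time point: ",
        paste(sprintf("%s=%d", names(ov$sizes), ov$sizes), collapse = ", "))
data.table::fwrite(
  data.table::data.table(timepoint = names(ov$sizes), n_hds = as.integer(ov$sizes)),
  file.path(out, "hds_recovery.tsv"), sep = "\t")
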