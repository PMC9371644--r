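#!/usr/bin/env Rscript
# Stage 2: balance contact maps, compute insulation tracks (480-kb window),
# call TAD boundaries on the pooled control at insulation minima.
# Reads the stage-1 contact maps back from disk.

library(insuldiff)
seed <- as.integer(Sys.getenv("SEED", "1"))
data_dir <- "results/data"
out <- "results"
cfg <- demo_config(seed = seed)

samples <- data.table::CJ(condition = cfg$conditions$condition,
                          replicate = seq_len(cfg$n_replicates), sorted = FALSE)
samples[, sample := sprintf("%s_rep%d", condition, replicate)]

maps <- lapply(samples$sample, function(nm)
  read_contacts(file.path(data_dir, sprintf("cis_%s.tsv", nm)), cfg$bins))
names(maps) <- samples$sample

tracks <- lapply(maps, insulation_score, window = 480e3)
for (nm in names(tracks))
  write_insulation(tracks[[nm]], file.path(out, sprintf("insulation_%s.bedgraph", nm)))

ctrl <- samples[condition == cfg$conditions$condition[1]]$sample
boundaries <- call_boundaries(insulation_score(pool_maps(maps[ctrl]), 480e3),
                              prominence_min = 0.1)
write_bed(boundaries[, .(chrom, start, end, name = boundary_id,
                         score = round(score, 4))],
          file.path(out, "boundaries.bed"))

scored <- score_boundaries_across_samples(boundaries, tracks)
data.table::fwrite(scored, file.path(out, "boundary_scores.tsv"), sep = "\t")
data.table::fwrite(samples, file.path(out, "sample_sheet.tsv"), sep = "\t")

truth <- data.table::fread(file.path(data_dir, "truth_boundaries.tsv"))
hit <- vapply(seq_len(nrow(truth)), function(i)
  any(boundaries$chrom == truth$chrom[i] &
        abs((boundaries$start) - truth$pos[i]) <= 2 * cfg$bin_size), TRUE)
message(sprintf("called %d boundaries on the pooled control; %d/%d planted boundaries recovered within 1 bin",
                nrow(boundaries), sum(hit), nrow(truth)))
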