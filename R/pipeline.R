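#' Pool replicate contact maps by summing counts
#' @param maps List of [contact_map()]s on the same bin table.
#' @return A [contact_map()].
#' @export
pool_maps <- function(maps) {
  contact_map(maps[[1]]$bins,
              data.table::rbindlist(lapply(maps, function(m) m$pixels)))
}

#' Write an insulation track as bedGraph (valid bins only)
#' @param track An [insulation_score()] track.
#' @param path Output path.
#' @export
write_insulation <- function(track, path) {
  write_bedgraph(track[valid == TRUE, .(chrom, start, end, value = score)], path)
}

#' Run the full demo analysis end to end
#'
#' Executes the pipeline on the bundled synthetic study design: simulate
#' cis/trans/PRO-seq/expression data, balance and score insulation, call
#' boundaries on the pooled control, test each boundary for differential
#' insulation (control vs treated) with BH FDR, classify HDS vs unaffected,
#' analyse compartments at 500 kb, cluster HDS boundaries, aggregate trans
#' contacts by HDS density, compute pausing indices and differential
#' pausing, and measure housekeeping enrichment on clusters. All outputs are
#' written under `outdir` in open text formats and recorded, with MD5
#' checksums and every parameter, in `manifest.tsv`.
#'
#' @param seed Master seed for all stochastic stages.
#' @param outdir Output directory.
#' @param config Cis study design (default [demo_config()] under `seed`).
#' @param window Insulation window in bp (default 480 kb).
#' @param prominence_min Boundary-calling prominence threshold (default 0.1).
#' @param fdr FDR threshold for all differential calls (default 0.05).
#' @param cluster_gap Boundary clustering gap in bp (default 2 Mb).
#' @param control,treated Condition labels used for the differential
#'   contrasts (defaults: the schedule's first and second conditions).
#' @return Invisibly, a list with the principal result tables and the
#'   manifest.
#' @export
run_pipeline <- function(seed = 1, outdir, config = demo_config(seed),
                         window = 480e3, prominence_min = 0.1, fdr = 0.05,
                         cluster_gap = 2e6,
                         control = config$conditions$condition[1],
                         treated = config$conditions$condition[2]) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) { files[[length(files) + 1L]] <<- path; path }

  conds <- config$conditions$condition
  reps <- seq_len(config$n_replicates)
  samples <- data.table::CJ(condition = conds, replicate = reps, sorted = FALSE)
  samples[, sample := sprintf("%s_rep%d", condition, replicate)]

  ## simulate ----------------------------------------------------------------
  cis <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i]
    cis[[s$sample]] <- simulate_cis(config, s$condition, s$replicate)
    write_contacts(cis[[s$sample]], emit(file.path(outdir, sprintf("cis_%s.tsv", s$sample))))
  }
  write_ground_truth(config, outdir)
  emit(file.path(outdir, "truth_boundaries.tsv")); emit(file.path(outdir, "truth_genes.tsv"))

  ## insulation --------------------------------------------------------------
  tracks <- lapply(cis, insulation_score, window = window)
  for (nm in names(tracks))
    write_insulation(tracks[[nm]], emit(file.path(outdir, sprintf("insulation_%s.bedgraph", nm))))

  ## boundaries on the pooled control ----------------------------------------
  ctrl_samples <- samples[condition == control]$sample
  pooled <- pool_maps(cis[ctrl_samples])
  ref_track <- insulation_score(pooled, window = window)
  boundaries <- call_boundaries(ref_track, prominence_min = prominence_min)
  write_bed(boundaries[, .(chrom, start, end, name = boundary_id, score = round(score, 4))],
            emit(file.path(outdir, "boundaries.bed")))

  ## differential insulation -------------------------------------------------
  scored <- score_boundaries_across_samples(boundaries, tracks)
  tested <- differential_boundaries(scored, samples, control, treated)
  classified <- classify_boundaries(tested, q_threshold = fdr)
  data.table::fwrite(classified, emit(file.path(outdir, "boundary_table.tsv")), sep = "\t")
  for (cl in c("HDS", "unaffected"))
    write_bed(classified[class == cl, .(chrom, start, end, name = boundary_id)],
              emit(file.path(outdir, sprintf("boundaries_%s.bed", tolower(cl)))))

  ## recovery over the schedule ----------------------------------------------
  recovery <- lapply(setdiff(conds, control), function(tc)
    classify_boundaries(differential_boundaries(scored, samples, control, tc), q_threshold = fdr))
  names(recovery) <- setdiff(conds, control)
  overlaps <- overlap_timepoints(recovery)

  ## compartments (500 kb) ---------------------------------------------------
  comp_cfg <- compartment_config(seed, n_chroms = length(config$layout$chroms))
  comp_tracks <- list()
  for (i in seq_len(nrow(samples))) {
    s <- samples[i]
    cmap <- simulate_cis(comp_cfg, s$condition, s$replicate)
    comp_tracks[[s$sample]] <- compartment_pc1(cmap, comp_cfg$compartments$labels)
  }
  write_bedgraph(comp_tracks[[samples$sample[1]]][!is.na(pc1), .(chrom, start, end, value = round(pc1, 6))],
                 emit(file.path(outdir, "compartments_pc1.bedgraph")))
  comp_diff <- differential_compartments(comp_tracks, samples, control, treated, fdr = fdr)
  data.table::fwrite(comp_diff, emit(file.path(outdir, "compartments_differential.tsv")), sep = "\t")

  ## clustering + housekeeping -----------------------------------------------
  hds <- filter_centromeric(classified[class == "HDS"], config$layout)
  clustering <- cluster_boundaries(hds, gap = cluster_gap)
  if (nrow(clustering$clusters))
    write_bed(clustering$clusters[, .(chrom, start, end, name = sprintf("%s_n%d", cluster_id, n_members))],
              emit(file.path(outdir, "hds_clusters.bed")))
  expr <- simulate_expression(config)
  data.table::fwrite(expr, emit(file.path(outdir, "expression.tsv")), sep = "\t")
  hk <- if (nrow(clustering$clusters))
    housekeeping_enrichment(expr, config$genes, clustering$clusters, config$layout,
                            top_fraction = 0.05)
  else list(enrichment = NA_real_)

  ## trans aggregation -------------------------------------------------------
  trans_cfg <- trans_demo_config(seed)
  trans_res <- lapply(conds, function(cond) {
    tm <- pool_maps(lapply(reps, function(r) simulate_trans(trans_cfg, cond, r)))
    trans_aggregate(tm, trans_cfg$boundaries[hds == TRUE], condition = cond)
  })
  trans_tab <- data.table::rbindlist(trans_res)
  data.table::fwrite(trans_tab, emit(file.path(outdir, "trans_aggregate.tsv")), sep = "\t")

  ## PRO-seq -----------------------------------------------------------------
  pause_tables <- list()
  for (cond in c(control, treated)) {
    for (r in reps) {
      cov <- simulate_proseq(config, cond, r)
      nm <- sprintf("%s_rep%d", cond, r)
      write_bedgraph(cov$plus, emit(file.path(outdir, sprintf("proseq_%s_plus.bedgraph", nm))))
      write_bedgraph(cov$minus, emit(file.path(outdir, sprintf("proseq_%s_minus.bedgraph", nm))))
      pause_tables[[nm]] <- pausing_index(cov, config$genes)
    }
  }
  ctrl_nm <- sprintf("%s_rep%d", control, reps)
  trt_nm <- sprintf("%s_rep%d", treated, reps)
  pausing <- differential_pausing(pause_tables[ctrl_nm], pause_tables[trt_nm], fdr = fdr)
  data.table::fwrite(pausing, emit(file.path(outdir, "pausing.tsv")), sep = "\t")

  ## manifest ----------------------------------------------------------------
  files <- unique(unlist(files))
  manifest <- data.table::data.table(file = basename(files),
                                     md5 = unname(tools::md5sum(files)))
  params <- data.table::data.table(
    file = paste0("param:", c("seed", "window", "prominence_min", "fdr", "cluster_gap",
                              "control", "treated", "bin_size", "cis_depth")),
    md5 = as.character(c(seed, window, prominence_min, fdr, cluster_gap,
                         control, treated, config$bin_size, config$cis_depth)))
  manifest <- data.table::rbindlist(list(params, manifest))
  data.table::fwrite(manifest, file.path(outdir, "manifest.tsv"), sep = "\t")

  invisible(list(boundaries = boundaries, classified = classified,
                 recovery = recovery, overlaps = overlaps,
                 compartments = comp_diff, clustering = clustering,
                 housekeeping = hk, trans = trans_tab, pausing = pausing,
                 manifest = manifest))
}
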