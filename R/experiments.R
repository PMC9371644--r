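#' Detection power and FDR of the differential boundary analysis
#'
#' Runs complete simulated experiments (two control + two treated replicate
#' Hi-C maps per experiment, with independent replicate streams across
#' experiments), applies the full chain — balancing, insulation scoring,
#' boundary calling on the pooled control, cross-sample scoring, the
#' differential test, BH classification — and scores the HDS calls against
#' the generator's ground truth. A call matches a planted boundary when its
#' bin lies within one bin of the planted edge. Sensitivity and empirical
#' FDR are aggregated over experiments.
#'
#' @param config A [sim_config()] with HDS boundaries planted.
#' @param n_experiments Independent experiments to aggregate (default 3).
#' @param window,prominence_min,fdr Analysis parameters.
#' @param control,treated Condition labels (defaults: first two of the
#'   schedule).
#' @param var_mode Variance mode for [row_t_test()] (default: the plain
#'   per-boundary GLM). The fully pooled mode trades the per-boundary
#'   variance for a shared one and is vulnerable to variance heterogeneity
#'   across boundaries.
#' @return List: `sensitivity`, `fdr`, `n_calls`, `n_true`, `per_experiment`
#'   `data.table`.
#' @export
boundary_power_experiment <- function(config, n_experiments = 3,
                                      window = 480e3, prominence_min = 0.1, fdr = 0.05,
                                      control = config$conditions$condition[1],
                                      treated = config$conditions$condition[2],
                                      var_mode = "per_boundary") {
  truth <- config$boundaries
  offs <- chrom_offsets(config$bins)
  truth_bin <- offs[data.table::data.table(chrom = truth$chrom)]$offset +
    as.integer(truth$pos / config$bin_size)
  per <- data.table::rbindlist(lapply(seq_len(n_experiments), function(e) {
    reps <- c(2 * e - 1, 2 * e)
    samples <- data.table::data.table(
      sample = c(paste0("c", reps), paste0("t", reps)),
      condition = rep(c(control, treated), each = 2),
      replicate = rep(reps, 2))
    maps <- lapply(seq_len(nrow(samples)), function(i)
      simulate_cis(config, samples$condition[i], samples$replicate[i]))
    names(maps) <- samples$sample
    tracks <- lapply(maps, insulation_score, window = window)
    called <- call_boundaries(insulation_score(pool_maps(maps[samples$condition == control]),
                                               window), prominence_min)
    scored <- score_boundaries_across_samples(called, tracks)
    cl <- classify_boundaries(
      differential_boundaries(scored, samples, control, treated, var_mode = var_mode), fdr)
    hds_calls <- cl[cl$class == "HDS"]
    match_idx <- vapply(seq_len(nrow(hds_calls)), function(i) {
      j <- which(truth$chrom == hds_calls$chrom[i] &
                   abs(truth_bin - 1L - hds_calls$bin_id[i]) <= 1L)
      if (length(j)) j[1] else NA_integer_
    }, 1L)
    tp_idx <- unique(match_idx[!is.na(match_idx) & truth$hds[match_idx]])
    data.table::data.table(experiment = e, n_calls = nrow(hds_calls),
                           tp = length(tp_idx),
                           fp = nrow(hds_calls) - sum(!is.na(match_idx) & truth$hds[match_idx]))
  }))
  list(sensitivity = sum(per$tp) / (n_experiments * sum(truth$hds)),
       fdr = if (sum(per$n_calls)) sum(per$fp) / sum(per$n_calls) else 0,
       n_calls = sum(per$n_calls), n_true = sum(truth$hds),
       per_experiment = per)
}
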