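#' Gaussian GLM test of one boundary's insulation scores
#'
#' Fits an identity-link Gaussian GLM `score ~ condition` and returns the
#' treated-vs-control coefficient (delta, log2 units), its t statistic and a
#' two-sided p-value. With two replicates per condition this is exactly the
#' pooled two-sample t-test.
#'
#' @param scores Numeric vector of insulation scores.
#' @param condition Factor-like vector parallel to `scores` with exactly two
#'   levels; the first level is the control.
#' @return List with `delta`, `statistic`, `p`, `df`. Zero pooled variance
#'   yields `p = NaN` (the boundary is later excluded from FDR).
#' @export
test_boundary <- function(scores, condition) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("exactly two conditions required")
  if (any(table(condition) < 2)) stop("insufficient replication: need >= 2 replicates per condition")
  fit <- stats::glm(scores ~ condition, family = stats::gaussian())
  co <- summary(fit)$coefficients
  delta <- unname(co[2, 1])
  stat <- unname(co[2, 3])
  p <- unname(co[2, 4])
  if (!is.finite(stat)) { stat <- NaN; p <- NaN }
  list(delta = delta, statistic = stat, p = p, df = fit$df.residual)
}

#' Vectorised pooled two-sample t-tests over a score matrix
#'
#' Row-wise closed-form pooled t-test; algebraically identical to the
#' per-row Gaussian GLM of [test_boundary()].
#'
#' @param mat Numeric matrix, rows = boundaries, columns = samples. `NA`s
#'   are dropped per row.
#' @param condition Two-level factor over the columns (first level =
#'   control).
#' @param var_mode `"per_boundary"` (default): each boundary uses its own
#'   pooled variance, the plain GLM. `"pooled"`: a single residual variance
#'   estimated across all boundaries (mean of per-boundary pooled variances,
#'   degrees of freedom summed) replaces the per-boundary estimate — a
#'   stabilised option for designs with only two replicates per condition,
#'   where per-boundary variances are too noisy to rank p-values reliably.
#' @return `data.table` with `delta`, `statistic`, `p`, `df`, `n_control`,
#'   `n_treated`.
#' @export
row_t_test <- function(mat, condition, var_mode = c("per_boundary", "pooled")) {
  var_mode <- match.arg(var_mode)
  condition <- factor(condition)
  stopifnot(nlevels(condition) == 2, ncol(mat) == length(condition))
  a <- condition == levels(condition)[1]
  ma <- mat[, a, drop = FALSE]; mb <- mat[, !a, drop = FALSE]
  na <- rowSums(!is.na(ma)); nb <- rowSums(!is.na(mb))
  mean_a <- rowMeans(ma, na.rm = TRUE); mean_b <- rowMeans(mb, na.rm = TRUE)
  ss <- function(m, mu) rowSums((m - mu)^2, na.rm = TRUE)
  sp2 <- (ss(ma, mean_a) + ss(mb, mean_b)) / (na + nb - 2)
  delta <- mean_b - mean_a
  df <- na + nb - 2
  if (var_mode == "pooled") {
    use <- df > 0 & is.finite(sp2)
    sp2 <- rep(mean(sp2[use]), length(sp2))
    df <- rep(sum((na + nb - 2)[use]), length(df))
  }
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  stat <- delta / se
  p <- 2 * stats::pt(-abs(stat), df)
  p[se == 0] <- NaN
  stat[se == 0] <- NaN
  bad <- na < 2 | nb < 2
  delta[bad] <- NA_real_; stat[bad] <- NaN; p[bad] <- NaN
  data.table::data.table(delta = delta, statistic = stat, p = p, df = df,
                         n_control = na, n_treated = nb)
}

#' Differential insulation of a boundary set between two conditions
#'
#' @param scored Output of [score_boundaries_across_samples()].
#' @param samples `data.frame` sample sheet with columns `sample` and
#'   `condition`; only rows whose condition equals `control` or `treated`
#'   are used.
#' @param control,treated Condition labels.
#' @inheritParams row_t_test
#' @return `scored` plus `delta`, `statistic`, `p`.
#' @export
differential_boundaries <- function(scored, samples, control, treated,
                                    var_mode = c("per_boundary", "pooled")) {
  samples <- data.table::as.data.table(samples)
  use <- samples[condition %in% c(control, treated)]
  if (!nrow(use)) stop("no samples for the requested conditions")
  cols <- paste0("score_", use$sample)
  missing_cols <- setdiff(cols, names(scored))
  if (length(missing_cols)) stop("scored table lacks columns: ", paste(missing_cols, collapse = ", "))
  mat <- as.matrix(scored[, cols, with = FALSE])
  res <- row_t_test(mat, factor(use$condition, levels = c(control, treated)),
                    var_mode = var_mode)
  out <- data.table::copy(scored)
  out[, c("delta", "statistic", "p") := .(res$delta, res$statistic, res$p)]
  out[]
}

#' Classify boundaries as HDS vs unaffected at an FDR threshold
#'
#' Benjamini-Hochberg correction across all boundaries with a defined
#' p-value; a boundary is HDS when `q < q_threshold` and `delta > 0`
#' (insulation weakening moves the log2 score toward 0, i.e. upward).
#' Boundaries with undefined p (zero variance) are excluded from FDR and
#' classified unaffected.
#'
#' @param table Output of [differential_boundaries()].
#' @param q_threshold FDR threshold (default 0.05).
#' @return `table` plus `q` and `class`; attribute `summary` holds
#'   `n_hds` / `n_unaffected`.
#' @export
classify_boundaries <- function(table, q_threshold = 0.05) {
  out <- data.table::copy(table)
  if (!nrow(out)) {
    out[, `:=`(q = numeric(), class = character())]
    return(out[])
  }
  ok <- is.finite(out$p)
  out[, q := NA_real_]
  out[ok, q := stats::p.adjust(p, method = "BH")]
  out[, class := ifelse(ok & q < q_threshold & delta > 0, "HDS", "unaffected")]
  data.table::setattr(out, "summary",
                      list(n_hds = sum(out$class == "HDS"),
                           n_unaffected = sum(out$class != "HDS")))
  out[]
}

#' HDS-set overlaps across time points
#'
#' @param tables Named list of classified boundary tables (one per time
#'   point).
#' @return List with per-time-point HDS counts, all pairwise intersection
#'   counts, and the full intersection count.
#' @export
overlap_timepoints <- function(tables) {
  sets <- lapply(tables, function(t) t$boundary_id[t$class == "HDS"])
  nm <- names(sets)
  pairs <- if (length(sets) >= 2) {
    cmb <- utils::combn(nm, 2)
    stats::setNames(apply(cmb, 2, function(pp) length(intersect(sets[[pp[1]]], sets[[pp[2]]]))),
                    apply(cmb, 2, paste, collapse = " & "))
  } else NULL
  list(sizes = vapply(sets, length, 1L),
       pairwise = pairs,
       all = length(Reduce(intersect, sets)))
}
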