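#' Aggregate per-cell ratios to well summaries
#'
#' Collapses cell records to one row per (replicate, plate, well). The well
#' ratio is the mean (or median) of the evaluable per-cell N/C ratios;
#' wells with fewer than `min_cells` evaluable cells are excluded with
#' reason `too_few_cells` and carry no ratio.
#'
#' @param cells data.frame of cell records carrying `plate_id`,
#'   `replicate_id`, `well_id`, `nc_ratio` and `evaluable` columns (as
#'   produced by the pipeline's measurement stage).
#' @param layout Plate layout; supplies `gene_id`, `role`, `treatment` and
#'   the full well universe (non-empty wells without any cell records are
#'   emitted as excluded with reason `no_image`).
#' @param min_cells Minimum evaluable cells for a well ratio (default 20).
#' @param aggregator `"mean"` (default) or `"median"`.
#' @return data.frame `well_summary`: one row per non-empty layout well with
#'   `n_cells_evaluable`, `well_ratio`, `excluded`, `reason`.
#' @export
summarize_wells <- function(cells, layout, min_cells = 20,
                            aggregator = c("mean", "median")) {
  aggregator <- match.arg(aggregator)
  agg <- if (aggregator == "mean") mean else stats::median
  validate_plate_layout(layout)
  wells <- as.data.frame(layout[layout$role != "empty", , drop = FALSE])
  key <- function(df) paste(df$replicate_id, df$plate_id, df$well_id)
  wk <- key(wells)
  ck <- if (nrow(cells)) key(cells) else character(0)

  ev <- !is.na(cells$nc_ratio) & cells$evaluable
  idx <- match(ck, wk)
  by_well <- split(cells$nc_ratio[ev & !is.na(idx)],
                   factor(idx[ev & !is.na(idx)],
                          levels = seq_len(nrow(wells))))
  n_eval <- unname(lengths(by_well))
  ratio <- rep(NA_real_, nrow(wells))
  enough <- n_eval >= min_cells & n_eval > 0
  ratio[enough] <- vapply(by_well[enough], agg, 0)
  has_any <- wk %in% ck
  excluded <- n_eval < min_cells
  reason <- rep(NA_character_, nrow(wells))
  reason[excluded] <- ifelse(has_any[excluded], "too_few_cells", "no_image")

  out <- data.frame(wells[, c("plate_id", "replicate_id", "well_id",
                              "gene_id", "role", "treatment")],
                    n_cells_evaluable = n_eval, well_ratio = ratio,
                    excluded = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Z'-factor assay quality statistic
#'
#' `Z' = 1 - 3 (SD_pos + SD_neg) / |mean_pos - mean_neg|` with sample
#' standard deviations (n - 1 denominator). Values approaching 1 indicate a
#' wide assay window relative to control variability; Z' > 0.5 is the
#' conventional bar for a screening-grade assay.
#'
#' @param pos_values,neg_values Well-level ratios of the two control arms
#'   (e.g. vehicle-treated vs stress-treated negative-control wells); at
#'   least 2 values each.
#' @return The Z' value (<= 1).
#' @examples
#' compute_zprime(c(9, 11), c(1.5, 2.5))
#' @export
compute_zprime <- function(pos_values, neg_values) {
  pos_values <- pos_values[!is.na(pos_values)]
  neg_values <- neg_values[!is.na(neg_values)]
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("each control arm needs at least 2 well values", call. = FALSE)
  window <- abs(mean(pos_values) - mean(neg_values))
  if (window == 0)
    stop("zero assay window: control means are equal", call. = FALSE)
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / window
}

#' Call screen hits at mean + k sigma for one replicate
#'
#' Pools all evaluable stress-treated library wells of one replicate across
#' plates, computes their mean `m` and sample standard deviation `sigma`,
#' and calls a well a hit iff `well_ratio > m + k_sigma * sigma` (strict
#' inequality: a well exactly on the line is not a hit). Vehicle-treated
#' and control wells never enter `m`/`sigma` and are never hits. A high
#' ratio means the knockdown blocked the stress-induced cytoplasmic
#' accumulation. With `two_sided = TRUE`, wells below `m - k_sigma * sigma`
#' are additionally flagged in `hit_low` (off by default; the screen's
#' readout direction is high-side).
#'
#' @param wells A `well_summary` data.frame for a single replicate.
#' @param k_sigma Threshold multiplier (default 3).
#' @param min_library_wells Minimum evaluable stress-treated library wells
#'   required (default 10; error below).
#' @param two_sided Also flag low-side outliers (default `FALSE`).
#' @return list with `stats` (one-row data.frame: `replicate_id`, `n_wells`,
#'   `mean_m`, `sd_sigma`, `hit_threshold`) and `wells` (input plus `hit`
#'   and, if requested, `hit_low`). A degenerate screen with `sigma = 0`
#'   yields zero hits with a warning.
#' @export
call_hits <- function(wells, k_sigma = 3, min_library_wells = 10,
                      two_sided = FALSE) {
  if (length(unique(wells$replicate_id)) > 1)
    stop("call_hits operates on a single replicate", call. = FALSE)
  lib <- wells$role == "library" & wells$treatment == "stress" &
    !wells$excluded & !is.na(wells$well_ratio)
  n <- sum(lib)
  if (n < min_library_wells)
    stop(sprintf(
      "only %d evaluable stress-treated library wells (need >= %d)",
      n, min_library_wells), call. = FALSE)
  m <- mean(wells$well_ratio[lib])
  s <- stats::sd(wells$well_ratio[lib])
  thr <- m + k_sigma * s
  if (s == 0) {
    warning("degenerate screen: sigma = 0, no hits called", call. = FALSE)
    wells$hit <- FALSE
  } else {
    wells$hit <- lib & wells$well_ratio > thr
  }
  if (two_sided)
    wells$hit_low <- if (s == 0) FALSE else
      lib & wells$well_ratio < m - k_sigma * s
  list(stats = data.frame(replicate_id = wells$replicate_id[1],
                          n_wells = n, mean_m = m, sd_sigma = s,
                          hit_threshold = thr, stringsAsFactors = FALSE),
       wells = wells)
}

#' Replicate concordance of hit calls
#'
#' Combines per-replicate hit flags per gene; a gene is a final hit iff it
#' was called in at least `min_reps` replicates (default 2 of 3). A gene
#' whose well was excluded in a replicate counts that replicate as a
#' non-hit.
#'
#' @param hit_wells data.frame pooling the `wells` output of [call_hits()]
#'   over replicates; needs `gene_id`, `replicate_id`, `well_ratio`, `hit`,
#'   and `role` columns.
#' @param min_reps Minimum replicates a gene must be called in.
#' @return data.frame with one row per library gene: per-replicate ratio and
#'   hit columns (`ratio_<rep>`, `hit_<rep>`), `n_replicates_hit`,
#'   `final_hit`; sorted by descending `n_replicates_hit`, then mean ratio.
#' @export
replicate_concordance <- function(hit_wells, min_reps = 2) {
  lib <- hit_wells[hit_wells$role == "library" &
                     !is.na(hit_wells$gene_id), , drop = FALSE]
  if (!nrow(lib)) stop("no library wells in input", call. = FALSE)
  reps <- sort(unique(lib$replicate_id))
  genes <- sort(unique(lib$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  hits_mat <- matrix(FALSE, length(genes), length(reps))
  for (j in seq_along(reps)) {
    sub <- lib[lib$replicate_id == reps[j], , drop = FALSE]
    i <- match(genes, sub$gene_id)
    out[[paste0("ratio_", reps[j])]] <- sub$well_ratio[i]
    hits_mat[, j] <- !is.na(i) & !is.na(sub$hit[i]) & sub$hit[i]
    out[[paste0("hit_", reps[j])]] <- hits_mat[, j]
  }
  out$n_replicates_hit <- rowSums(hits_mat)
  out$final_hit <- out$n_replicates_hit >= min_reps
  mean_ratio <- rowMeans(as.matrix(
    out[, paste0("ratio_", reps), drop = FALSE]), na.rm = TRUE)
  out <- out[order(-out$n_replicates_hit, -mean_ratio, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two screen replicates
#'
#' Correlates well ratios of the genes evaluable in both replicates; the
#' paired values are returned for scatter plotting.
#'
#' @param wells_a,wells_b `well_summary` data.frames of two replicates.
#' @return list with `r`, `n_genes`, and `data` (gene_id, ratio_a, ratio_b).
#' @export
replicate_correlation <- function(wells_a, wells_b) {
  pick <- function(w) {
    w <- w[w$role == "library" & !w$excluded & !is.na(w$well_ratio), ]
    stats::setNames(w$well_ratio, w$gene_id)
  }
  a <- pick(wells_a); b <- pick(wells_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3)
    stop("fewer than 3 genes evaluable in both replicates", call. = FALSE)
  x <- a[shared]; y <- b[shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant ratio vector", call. = FALSE)
  list(r = stats::cor(x, y), n_genes = length(shared),
       data = data.frame(gene_id = shared, ratio_a = unname(x),
                         ratio_b = unname(y), stringsAsFactors = FALSE))
}

#' Transfection efficiency from death-siRNA well counts
#'
#' A universally lethal siRNA kills transfected cells, so the cell-count
#' deficit of death-control wells relative to negative-control wells
#' measures transfection efficiency:
#' `1 - mean(death counts) / mean(negative-control counts)`, clamped to
#' \[0, 1\]. Plates below `floor` are flagged as transfection failures.
#'
#' @param death_counts,neg_ctrl_counts Per-well cell counts.
#' @param floor Minimum acceptable efficiency (default 0.5).
#' @return list with `efficiency`, `pass`, and the two mean counts.
#' @examples
#' transfection_qc(c(18, 22), c(190, 210))$efficiency  # 0.9
#' @export
transfection_qc <- function(death_counts, neg_ctrl_counts, floor = 0.5) {
  if (!length(neg_ctrl_counts) || mean(neg_ctrl_counts) == 0)
    stop("negative-control wells have zero cells", call. = FALSE)
  eff <- 1 - mean(death_counts) / mean(neg_ctrl_counts)
  eff <- min(max(eff, 0), 1)
  list(efficiency = eff, pass = eff >= floor,
       mean_death = mean(death_counts),
       mean_neg_ctrl = mean(neg_ctrl_counts))
}
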