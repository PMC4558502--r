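#' Simulate a full on-disk screen
#'
#' Renders every non-empty well of a plate layout (all replicates, all
#' plates) and writes a self-contained screen directory: 16-bit grayscale
#' TIFF image pairs per field, the plate map, the per-cell ground-truth
#' table, and a manifest echoing the seed and configuration.
#'
#' Output tree:
#' \preformatted{
#' <out_dir>/<replicate>/<plate>/<well>_<field>_nuc.tif
#' <out_dir>/<replicate>/<plate>/<well>_<field>_prot.tif
#' <out_dir>/platemap.csv
#' <out_dir>/truth_cells.csv
#' <out_dir>/manifest.yaml
#' }
#'
#' Each well/field gets an RNG substream derived deterministically from the
#' screen seed and the well's position in the canonically sorted layout, so
#' the same seed reproduces the screen bit-for-bit regardless of traversal
#' order.
#'
#' @param cfg A [sim_config()].
#' @param layout A [generate_plate_layout()] result (or equivalent
#'   data.frame).
#' @param planted_hits Optional effect table ([knockdown_effect()] rows);
#'   all referenced genes must be present in the layout.
#' @param fields_per_well Imaged fields per well (default 1).
#' @param out_dir Output directory (created; must be writable).
#' @param seed Integer screen seed.
#' @return Invisibly, a list with the output paths (`dir`, `platemap`,
#'   `truth`, `manifest`) and the total `placement_failures` count.
#' @export
simulate_screen <- function(cfg, layout, planted_hits = NULL,
                            fields_per_well = 1, out_dir, seed = 1L) {
  validate_sim_config(cfg)
  validate_plate_layout(layout)
  stopifnot(fields_per_well >= 1)
  seed <- as.integer(seed)
  if (!is.null(planted_hits)) {
    missing <- setdiff(planted_hits$gene_id, layout$gene_id)
    if (length(missing))
      stop("planted hits reference genes absent from the layout: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok && !dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE)))
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  unlink(probe)

  wells <- layout[layout$role != "empty", , drop = FALSE]
  ord <- order(wells$replicate_id, wells$plate_id, wells$well_id)
  wells <- wells[ord, , drop = FALSE]

  write_platemap(layout, file.path(out_dir, "platemap.csv"))

  truth_all <- vector("list", nrow(wells) * fields_per_well)
  failures <- 0L
  k <- 0L
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    wdir <- file.path(out_dir, w$replicate_id, w$plate_id)
    dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_len(fields_per_well)) {
      k <- k + 1L
      wseed <- well_seed(seed, (i - 1L) * fields_per_well + f)
      fld <- withCallingHandlers(
        render_field(cfg, well = w, effects = planted_hits, seed = wseed),
        warning = function(cond) invokeRestart("muffleWarning"))
      failures <- failures + fld$placement_failures
      write_tiff16(fld$nuc, file.path(wdir, sprintf("%s_%d_nuc.tif",
                                                    w$well_id, f)))
      write_tiff16(fld$prot, file.path(wdir, sprintf("%s_%d_prot.tif",
                                                     w$well_id, f)))
      if (nrow(fld$truth)) {
        truth_all[[k]] <- cbind(
          data.frame(replicate_id = w$replicate_id, plate_id = w$plate_id,
                     well_id = w$well_id, field = f,
                     stringsAsFactors = FALSE),
          fld$truth)
      }
    }
  }
  truth <- do.call(rbind, truth_all[!vapply(truth_all, is.null, logical(1))])
  truth_path <- file.path(out_dir, "truth_cells.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE)

  manifest <- list(
    seed = seed,
    fields_per_well = as.integer(fields_per_well),
    n_wells_rendered = nrow(wells),
    placement_failures = failures,
    planted_hits = if (is.null(planted_hits)) list() else
      as.list(stats::setNames(planted_hits$effect, planted_hits$gene_id)),
    config = unclass(cfg)
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)

  invisible(list(dir = out_dir,
                 platemap = file.path(out_dir, "platemap.csv"),
                 truth = truth_path, manifest = manifest_path,
                 placement_failures = failures))
}

# Deterministic per-well substream seed below 2^31.
well_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %%
               2147483647)
}

#' Statistic-level screen simulation (well ratios drawn directly)
#'
#' Skips image rendering and draws each well's aggregate N/C ratio from a
#' Gaussian centered on the analytic expectation for that well's condition:
#' stress-treated wells at the stressed-null ratio, vehicle wells at the
#' fully nuclear-retained ratio, and planted hits at the attenuated ratio
#' implied by their knockdown effect (see [ratio_for_effect()]). This is the
#' fast path for calibrating the hit-calling statistics at full screen scale.
#'
#' @param layout Plate layout data.frame.
#' @param cfg A [sim_config()] supplying geometry and protein scale.
#' @param well_sd Between-well standard deviation of the ratio (default
#'   0.25, a typical screen-replicate spread on this assay's scale).
#' @param planted_hits Optional effect table; may carry an optional
#'   `ratio` column to pin a hit's expected ratio directly instead of
#'   deriving it from `effect`.
#' @param n_cells_per_well Evaluable cell count recorded for each well
#'   (death-control wells are thinned by `cfg$death_survival_factor`).
#' @param seed Integer seed.
#' @return A `well_summary`-shaped data.frame (one row per non-empty well)
#'   with `well_ratio`, `n_cells_evaluable`, `excluded`, `reason`.
#' @export
simulate_ratio_screen <- function(layout, cfg = sim_config(),
                                  well_sd = 0.25, planted_hits = NULL,
                                  n_cells_per_well = 40, seed = 1L) {
  validate_plate_layout(layout)
  wells <- layout[layout$role != "empty", , drop = FALSE]
  ord <- order(wells$replicate_id, wells$plate_id, wells$well_id)
  wells <- wells[ord, , drop = FALSE]

  mu <- ratio_for_effect(cfg, 0, "stress")
  mu_vehicle <- ratio_for_effect(cfg, 0, "vehicle")
  means <- ifelse(wells$treatment == "vehicle", mu_vehicle, mu)
  if (!is.null(planted_hits)) {
    hit <- match(wells$gene_id, planted_hits$gene_id)
    planted_mean <- if (!is.null(planted_hits$ratio)) {
      planted_hits$ratio
    } else {
      ratio_for_effect(cfg, planted_hits$effect, "stress")
    }
    sel <- !is.na(hit) & wells$treatment == "stress"
    means[sel] <- planted_mean[hit[sel]]
  }
  ratios <- withr::with_seed(as.integer(seed),
                             stats::rnorm(nrow(wells), means, well_sd))
  n_cells <- ifelse(wells$role == "death_ctrl",
                    round(n_cells_per_well * cfg$death_survival_factor),
                    n_cells_per_well)
  out <- data.frame(wells[, c("plate_id", "replicate_id", "well_id",
                              "gene_id", "role", "treatment")],
                    n_cells_evaluable = as.integer(n_cells),
                    well_ratio = ratios,
                    excluded = FALSE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
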