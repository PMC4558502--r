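#' Default run configuration
#'
#' Every pipeline parameter has a default; [run_screen()] merges a user
#' configuration (a named list or a YAML file) over these values and echoes
#' the effective configuration next to the outputs.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    input = NULL,                # existing screen directory, or NULL
    out = NULL,                  # output directory (required)
    simulate = list(             # used when input is NULL
      n_library_genes = 60,
      n_plates = 1,
      n_replicates = 3,
      plate_rows = 8,
      plate_cols = 12,
      controls = list(neg_ctrl = 8, gfp_ctrl = 2, death_ctrl = 2),
      fields_per_well = 1,
      planted_hits = list(),     # list of list(gene_id=, effect=)
      config = list()            # sim_config() overrides
    ),
    segmentation = list(min_area = 30, max_area = 5000,
                        exclude_border = TRUE, connectivity = 8),
    ring = list(gap = 3, width = 5),
    quantify = list(subtract_background = FALSE,
                    saturation_level = BIT16_MAX),
    stats = list(min_cells = 20, k_sigma = 3, min_reps = 2,
                 aggregator = "mean", min_library_wells = 10,
                 transfection_floor = 0.5)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  known <- names(default_run_config())
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "), call. = FALSE)
  cfg <- merge_config(default_run_config(), config)
  if (is.null(cfg$out)) stop("config must set 'out'", call. = FALSE)
  cfg
}

#' Analyze an on-disk screen
#'
#' Runs the image-analysis stages over an existing screen directory (as
#' written by [simulate_screen()], or any directory following the same
#' layout): per field, segment nuclei, build cytoplasmic rings, measure
#' per-cell N/C ratios; then aggregate wells, compute per-plate Z'-factors
#' and transfection efficiency, call hits per replicate at mean + k sigma,
#' and combine replicates into final hit calls.
#'
#' Unreadable or missing fields are recorded in the QC report and skipped;
#' the run aborts only if no well is evaluable.
#'
#' @param screen_dir Screen directory containing `platemap.csv` and the
#'   per-replicate image tree.
#' @param out_dir Output directory for result tables.
#' @param config Partial run configuration (list; see
#'   [default_run_config()]); `input`/`out` are taken from the arguments.
#' @return Invisibly, a `screen_result` list: paths of `cells`, `wells`,
#'   `screen_stats`, `hits`, `correlations`, `qc_report`, `manifest`, plus
#'   the in-memory tables.
#' @export
analyze_screen <- function(screen_dir, out_dir, config = list()) {
  cfg <- merge_config(default_run_config(), config)
  cfg$input <- screen_dir; cfg$out <- out_dir
  layout <- read_platemap(file.path(screen_dir, "platemap.csv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  wells <- layout[layout$role != "empty", , drop = FALSE]
  ord <- order(wells$replicate_id, wells$plate_id, wells$well_id)
  wells <- wells[ord, , drop = FALSE]
  rp <- ring_params(cfg$ring$gap, cfg$ring$width)

  cells_all <- list()
  qc_events <- list()
  counts <- data.frame()
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    wdir <- file.path(screen_dir, w$replicate_id, w$plate_id)
    f <- 1L
    repeat {
      nuc_path <- file.path(wdir, sprintf("%s_%d_nuc.tif", w$well_id, f))
      prot_path <- file.path(wdir, sprintf("%s_%d_prot.tif", w$well_id, f))
      if (!file.exists(nuc_path)) {
        if (f == 1L)
          qc_events[[length(qc_events) + 1L]] <- data.frame(
            stage = "read", replicate_id = w$replicate_id,
            plate_id = w$plate_id, well_id = w$well_id,
            event = "no_image", stringsAsFactors = FALSE)
        break
      }
      rec <- tryCatch({
        nuc <- read_tiff16(nuc_path)
        prot <- read_tiff16(prot_path)
        mask <- withCallingHandlers(
          segment_nuclei(nuc,
                         min_area = cfg$segmentation$min_area,
                         max_area = cfg$segmentation$max_area,
                         exclude_border = cfg$segmentation$exclude_border,
                         connectivity = cfg$segmentation$connectivity),
          warning = function(cond) invokeRestart("muffleWarning"))
        regions <- build_cell_regions(mask, rp)
        measure_cells(prot, regions,
                      saturation_level = cfg$quantify$saturation_level,
                      subtract_background = cfg$quantify$subtract_background)
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        qc_events[[length(qc_events) + 1L]] <- data.frame(
          stage = "field", replicate_id = w$replicate_id,
          plate_id = w$plate_id, well_id = w$well_id,
          event = paste0("field_failed: ", conditionMessage(rec)),
          stringsAsFactors = FALSE)
      } else if (nrow(rec)) {
        cells_all[[length(cells_all) + 1L]] <- cbind(
          data.frame(replicate_id = w$replicate_id, plate_id = w$plate_id,
                     well_id = w$well_id, gene_id = w$gene_id,
                     role = w$role, treatment = w$treatment, field = f,
                     stringsAsFactors = FALSE),
          rec)
      }
      f <- f + 1L
    }
  }
  cells <- if (length(cells_all)) do.call(rbind, cells_all) else
    data.frame(replicate_id = character(0), plate_id = character(0),
               well_id = character(0), nc_ratio = numeric(0),
               evaluable = logical(0))

  wsum <- summarize_wells(cells, layout,
                          min_cells = cfg$stats$min_cells,
                          aggregator = cfg$stats$aggregator)
  if (all(wsum$excluded))
    stop("no well was evaluable", call. = FALSE)

  # plate-level QC: Z' from negative-control wells, transfection from
  # death-siRNA cell counts
  stats_rows <- list(); qc_rows <- list(); hits_pool <- list()
  for (r in sort(unique(wsum$replicate_id))) {
    wr <- wsum[wsum$replicate_id == r, , drop = FALSE]
    for (p in sort(unique(wr$plate_id))) {
      wp <- wr[wr$plate_id == p, , drop = FALSE]
      neg_s <- wp$well_ratio[wp$role == "neg_ctrl" &
                               wp$treatment == "stress"]
      neg_v <- wp$well_ratio[wp$role == "neg_ctrl" &
                               wp$treatment == "vehicle"]
      zp <- tryCatch(compute_zprime(neg_v, neg_s), error = function(e) NA_real_)
      eff <- tryCatch(transfection_qc(
        wp$n_cells_evaluable[wp$role == "death_ctrl"],
        wp$n_cells_evaluable[wp$role == "neg_ctrl"],
        floor = cfg$stats$transfection_floor), error = function(e) NULL)
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        replicate_id = r, plate_id = p, zprime = zp,
        transfection_efficiency = if (is.null(eff)) NA_real_ else
          eff$efficiency,
        transfection_pass = if (is.null(eff)) NA else eff$pass,
        stringsAsFactors = FALSE)
    }
    called <- call_hits(wr, k_sigma = cfg$stats$k_sigma,
                        min_library_wells = cfg$stats$min_library_wells)
    stats_rows[[length(stats_rows) + 1L]] <- called$stats
    hits_pool[[length(hits_pool) + 1L]] <- called$wells
  }
  screen_stats <- do.call(rbind, stats_rows)
  plate_qc <- do.call(rbind, qc_rows)
  all_called <- do.call(rbind, hits_pool)
  hits <- replicate_concordance(all_called, min_reps = cfg$stats$min_reps)

  reps <- sort(unique(wsum$replicate_id))
  corr_rows <- list()
  if (length(reps) >= 2) {
    for (i in seq_len(length(reps) - 1)) for (j in (i + 1):length(reps)) {
      rc <- tryCatch(replicate_correlation(
        wsum[wsum$replicate_id == reps[i], ],
        wsum[wsum$replicate_id == reps[j], ]), error = function(e) NULL)
      if (!is.null(rc))
        corr_rows[[length(corr_rows) + 1L]] <- data.frame(
          rep_a = reps[i], rep_b = reps[j], r = rc$r,
          n_genes = rc$n_genes, stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(corr_rows)) do.call(rbind, corr_rows) else
    data.frame(rep_a = character(0), rep_b = character(0), r = numeric(0),
               n_genes = integer(0))
  qc_report <- list(plate_qc = plate_qc,
                    events = if (length(qc_events))
                      do.call(rbind, qc_events) else
                        data.frame(stage = character(0),
                                   replicate_id = character(0),
                                   plate_id = character(0),
                                   well_id = character(0),
                                   event = character(0)))

  paths <- list(
    cells = file.path(out_dir, "cells.csv"),
    wells = file.path(out_dir, "wells.csv"),
    screen_stats = file.path(out_dir, "screen_stats.csv"),
    hits = file.path(out_dir, "hits.csv"),
    correlations = file.path(out_dir, "correlations.csv"),
    qc_report = file.path(out_dir, "qc_report.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  cells_out <- cells
  cells_out$gene_id[is.na(cells_out$gene_id)] <- ""
  write_result_csv(cells_out, paths$cells,
                   signif_cols = c("nuc_mean", "ring_mean", "nc_ratio"))
  wells_out <- wsum
  wells_out$reason[is.na(wells_out$reason)] <- ""
  write_result_csv(wells_out, paths$wells, signif_cols = "well_ratio")
  write_result_csv(screen_stats, paths$screen_stats,
                   signif_cols = c("mean_m", "sd_sigma", "hit_threshold"))
  hits_out <- hits
  write_result_csv(hits_out, paths$hits,
                   signif_cols = grep("^ratio_", names(hits), value = TRUE))
  write_result_csv(correlations, paths$correlations, signif_cols = "r")
  write_result_csv(qc_report$plate_qc, paths$qc_report,
                   signif_cols = c("zprime", "transfection_efficiency"))
  if (nrow(qc_report$events))
    write_result_csv(qc_report$events,
                     file.path(out_dir, "qc_events.csv"))

  cfg_echo <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_echo)
  manifest <- list(tool = "ncscreen",
                   version = as.character(utils::packageVersion("ncscreen")),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_echo)))
  yaml::write_yaml(manifest, paths$manifest)

  res <- c(paths, list(tables = list(cells = cells, wells = wsum,
                                     screen_stats = screen_stats,
                                     hits = hits,
                                     correlations = correlations,
                                     qc = qc_report)))
  class(res) <- "screen_result"
  invisible(res)
}

#' Run the full pipeline: simulate (optionally) then analyze
#'
#' Single entry point over the whole screen workflow. With an `input`
#' directory in the configuration, analyzes that screen; otherwise
#' simulates a screen from the `simulate` block under `<out>/screen` and
#' analyzes it. The effective merged configuration is echoed to the output
#' directory and stamped (as an MD5 hash) into the run manifest; rerunning
#' with an identical configuration and seed reproduces byte-identical
#' tables.
#'
#' @param config Named list or path to a YAML file; see
#'   [default_run_config()] for the schema. Must set `out`.
#' @return Invisibly, the [analyze_screen()] result.
#' @export
run_screen <- function(config) {
  cfg <- load_run_config(config)
  if (is.null(cfg$input)) {
    sim <- cfg$simulate
    scfg <- do.call(sim_config, sim$config)
    layout <- generate_plate_layout(
      n_library_genes = sim$n_library_genes,
      n_plates = sim$n_plates,
      n_replicates = sim$n_replicates,
      controls_per_plate = unlist(sim$controls),
      plate_rows = sim$plate_rows, plate_cols = sim$plate_cols,
      seed = cfg$seed)
    planted <- if (length(sim$planted_hits)) {
      do.call(rbind, lapply(sim$planted_hits, function(h)
        knockdown_effect(h$gene_id, h$effect)))
    } else NULL
    screen_dir <- file.path(cfg$out, "screen")
    simulate_screen(scfg, layout, planted_hits = planted,
                    fields_per_well = sim$fields_per_well,
                    out_dir = screen_dir, seed = cfg$seed)
    cfg$input <- screen_dir
  }
  analyze_screen(cfg$input, cfg$out, config = cfg)
}

#' @export
print.screen_result <- function(x, ...) {
  st <- x$tables$screen_stats
  cat("screen_result\n")
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %s: %d library wells, m = %.3f, sigma = %.3f, hits > %.3f\n",
                st$replicate_id[i], st$n_wells[i], st$mean_m[i],
                st$sd_sigma[i], st$hit_threshold[i]))
  cat(sprintf("  final hits: %d of %d genes\n",
              sum(x$tables$hits$final_hit), nrow(x$tables$hits)))
  invisible(x)
}
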