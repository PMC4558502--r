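#' Rasterize disks and ellipses to pixel index sets
#'
#' Pixel-center convention: pixel (i, j) of an R matrix (1-based row,
#' column) has its center at coordinates (i, j) and belongs to a shape iff
#' its center does. Returns linear (column-major) indices into an `H x W`
#' matrix, clipped to the image.
#'
#' @param cr,cc Center (row, column), may be fractional.
#' @param r Disk radius in pixels.
#' @param a,b Ellipse semi-axes along rows and columns.
#' @param H,W Image dimensions.
#' @return Integer vector of linear pixel indices.
#' @export
rasterize_disk <- function(cr, cc, r, H, W) {
  r0 <- max(1L, floor(cr - r)); r1 <- min(H, ceiling(cr + r))
  c0 <- max(1L, floor(cc - r)); c1 <- min(W, ceiling(cc + r))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  inside <- outer((rows - cr)^2, (cols - cc)^2, "+") <= r^2
  hit <- which(inside, arr.ind = TRUE)
  (cols[hit[, 2]] - 1L) * H + rows[hit[, 1]]
}

#' @rdname rasterize_disk
#' @export
rasterize_ellipse <- function(cr, cc, a, b, H, W) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(H, ceiling(cr + a))
  c0 <- max(1L, floor(cc - b)); c1 <- min(W, ceiling(cc + b))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  inside <- outer(((rows - cr) / a)^2, ((cols - cc) / b)^2, "+") <= 1
  hit <- which(inside, arr.ind = TRUE)
  (cols[hit[, 2]] - 1L) * H + rows[hit[, 1]]
}

rnorm_pos <- function(n, mean, sd, floor = .Machine$double.eps) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= floor)) {
    bad <- x <= floor
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Logit-normal draw with mean `mu` on the fraction scale and an approximate
# fraction-scale sd (delta method: sd_logit = sd / (mu (1 - mu))).
rfraction <- function(n, mu, sd) {
  if (sd == 0 || mu <= 0 || mu >= 1) return(rep(mu, n))
  stats::plogis(stats::qlogis(mu) + stats::rnorm(n, 0, sd / (mu * (1 - mu))))
}

#' Render a field from an explicit cell table
#'
#' Low-level renderer: given per-cell geometry and protein content, draw the
#' two channels deterministically (noise excepted) and return the completed
#' ground-truth table. [render_field()] samples the cell table and delegates
#' here; calling this directly gives exact control over cell placement for
#' arithmetic checks.
#'
#' Each cell's nucleus is a filled disk; its cytoplasm is the concentric
#' ellipse with semi-axes `nucleus_radius + cyto_extra_a` (rows) and
#' `+ cyto_extra_b` (columns), minus the nuclear disk. Protein-channel
#' intensity is assigned per region as the region total divided by the
#' region pixel count, so region sums are conserved exactly in noise-free
#' renders; overlapping cytoplasms add.
#'
#' @param cfg A [sim_config()]; noise and quantization settings apply.
#' @param cells data.frame with columns `center_r`, `center_c`,
#'   `nucleus_radius`, `cyto_extra_a`, `cyto_extra_b`, `total_protein`,
#'   `f_cyt`. May have zero rows.
#' @return list with elements `nuc` and `prot` (numeric `height x width`
#'   matrices) and `truth`, the input table augmented with `cell_id`,
#'   rasterized areas `a_nuc`, `a_cyt`, the analytic `expected_ratio`, and a
#'   `clipped` flag marking cells with any pixel at the 16-bit maximum.
#' @export
render_cells <- function(cfg, cells) {
  validate_sim_config(cfg)
  H <- cfg$image_height; W <- cfg$image_width
  bg <- cfg$background_level
  nuc <- matrix(bg, H, W)
  prot <- matrix(bg, H, W)
  n <- nrow(cells)
  nuc_idx <- vector("list", n)
  cyt_idx <- vector("list", n)
  a_nuc <- a_cyt <- numeric(n)
  exp_ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ci <- cells[i, ]
    nidx <- rasterize_disk(ci$center_r, ci$center_c, ci$nucleus_radius, H, W)
    eidx <- rasterize_ellipse(ci$center_r, ci$center_c,
                              ci$nucleus_radius + ci$cyto_extra_a,
                              ci$nucleus_radius + ci$cyto_extra_b, H, W)
    cidx <- setdiff(eidx, nidx)
    nuc_idx[[i]] <- nidx; cyt_idx[[i]] <- cidx
    a_nuc[i] <- length(nidx); a_cyt[i] <- length(cidx)
    if (a_nuc[i] > 0) {
      nuc[nidx] <- nuc[nidx] + cfg$nucleus_intensity
      prot[nidx] <- prot[nidx] + (1 - ci$f_cyt) * ci$total_protein / a_nuc[i]
    }
    if (a_cyt[i] > 0)
      prot[cidx] <- prot[cidx] + ci$f_cyt * ci$total_protein / a_cyt[i]
    if (a_nuc[i] > 0 && a_cyt[i] > 0)
      exp_ratio[i] <- expected_nc_ratio(ci$f_cyt, ci$total_protein,
                                        a_nuc[i], a_cyt[i], bg)
  }
  if (cfg$shot_noise) {
    nuc[] <- stats::rpois(length(nuc), pmax(nuc, 0))
    prot[] <- stats::rpois(length(prot), pmax(prot, 0))
  }
  if (cfg$noise_sd > 0) {
    nuc <- nuc + stats::rnorm(length(nuc), 0, cfg$noise_sd)
    prot <- prot + stats::rnorm(length(prot), 0, cfg$noise_sd)
  }
  clip_nuc <- nuc > BIT16_MAX
  clip_prot <- prot > BIT16_MAX
  if (cfg$quantize) {
    nuc <- pmin(pmax(round(nuc), 0), BIT16_MAX)
    prot <- pmin(pmax(round(prot), 0), BIT16_MAX)
  }
  clipped <- vapply(seq_len(n), function(i) {
    any(clip_prot[c(nuc_idx[[i]], cyt_idx[[i]])]) ||
      any(clip_nuc[nuc_idx[[i]]])
  }, logical(1))
  truth <- cbind(data.frame(cell_id = seq_len(n)), cells,
                 data.frame(a_nuc = a_nuc, a_cyt = a_cyt,
                            expected_ratio = exp_ratio, clipped = clipped))
  rownames(truth) <- NULL
  list(nuc = nuc, prot = prot, truth = truth)
}

BIT16_MAX <- 65535

#' Render one synthetic two-channel well field
#'
#' Samples cell geometry and protein content for one imaged field of a well
#' and renders the nuclear-stain and reporter-protein channels together with
#' the per-cell ground truth. The number of cells is Poisson; death-siRNA
#' control wells are thinned by `cfg$death_survival_factor`. Nuclei are
#' placed by rejection sampling so that no two nuclear disks overlap (a
#' 2.5 px clearance keeps segmented components separate); whole cells stay
#' inside the field. The mean cytoplasmic fraction follows the well's
#' treatment and, for stress-treated wells of genes listed in `effects`, the
#' knockdown attenuation.
#'
#' @param cfg A [sim_config()].
#' @param well A list or one-row data.frame with `role`, `treatment` and
#'   optionally `gene_id`; defaults to a stress-treated library well.
#' @param effects Optional effect table from [knockdown_effect()].
#' @param seed Optional integer seed (falls back to `cfg$rng_seed`; if both
#'   are `NULL` the current RNG stream is used).
#' @param n_cells Optional exact cell count, overriding the Poisson draw.
#' @return As [render_cells()], plus `placement_failures`, the number of
#'   cells dropped after `cfg$max_place_attempts` rejections (a warning is
#'   raised when nonzero).
#' @examples
#' fld <- render_field(sim_config(cells_per_field = 5), seed = 7)
#' nrow(fld$truth)
#' @export
render_field <- function(cfg, well = NULL, effects = NULL, seed = NULL,
                         n_cells = NULL) {
  validate_sim_config(cfg)
  if (is.null(well)) well <- list(role = "library", treatment = "stress",
                                  gene_id = NA_character_)
  if (is.null(seed)) seed <- cfg$rng_seed
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            render_field_impl(cfg, well, effects, n_cells)))
  }
  render_field_impl(cfg, well, effects, n_cells)
}

render_field_impl <- function(cfg, well, effects, n_cells) {
  lambda <- cfg$cells_per_field
  if (identical(well$role, "death_ctrl"))
    lambda <- lambda * cfg$death_survival_factor
  n <- if (is.null(n_cells)) stats::rpois(1, lambda) else as.integer(n_cells)

  effect <- 0
  if (!is.null(effects) && !is.null(well$gene_id) && !is.na(well$gene_id)) {
    hit <- match(well$gene_id, effects$gene_id)
    if (!is.na(hit)) effect <- effects$effect[hit]
  }
  mu <- realized_f_cyt(cfg, well$treatment, effect)

  H <- cfg$image_height; W <- cfg$image_width
  acc_r <- acc_c <- acc_rad <- numeric(0)
  rows <- vector("list", n)
  failures <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(cfg$max_place_attempts)) {
      rad <- max(2, stats::rnorm(1, cfg$nucleus_radius_mean,
                                 cfg$nucleus_radius_sd))
      ea <- stats::runif(1, cfg$cyto_radius_extra_min,
                         cfg$cyto_radius_extra_max)
      eb <- stats::runif(1, cfg$cyto_radius_extra_min,
                         cfg$cyto_radius_extra_max)
      ma <- rad + ea; mb <- rad + eb
      if (H - ma <= 1 + ma || W - mb <= 1 + mb) { failures <- failures + 1L; break }
      cr <- stats::runif(1, 1 + ma, H - ma)
      cc <- stats::runif(1, 1 + mb, W - mb)
      ok <- !length(acc_r) ||
        all((acc_r - cr)^2 + (acc_c - cc)^2 > (acc_rad + rad + 2.5)^2)
      if (ok) {
        acc_r <- c(acc_r, cr); acc_c <- c(acc_c, cc)
        acc_rad <- c(acc_rad, rad)
        rows[[i]] <- data.frame(center_r = cr, center_c = cc,
                                nucleus_radius = rad,
                                cyto_extra_a = ea, cyto_extra_b = eb,
                                total_protein = rnorm_pos(
                                  1, cfg$total_protein_mean,
                                  cfg$total_protein_sd),
                                f_cyt = rfraction(1, mu, cfg$f_cyt_sd))
        placed <- TRUE
        break
      }
    }
    if (!placed && is.null(rows[[i]])) failures <- failures + 1L
  }
  cells <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cells))
    cells <- data.frame(center_r = numeric(0), center_c = numeric(0),
                        nucleus_radius = numeric(0),
                        cyto_extra_a = numeric(0), cyto_extra_b = numeric(0),
                        total_protein = numeric(0), f_cyt = numeric(0))
  if (failures > 0)
    warning(sprintf("field emitted with %d fewer cell(s): placement failed",
                    failures), call. = FALSE)
  out <- render_cells(cfg, cells)
  out$placement_failures <- failures
  out
}
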