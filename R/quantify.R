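DISQUALIFYING_FLAGS <- c("border_touching", "ring_empty", "ring_zero_mean",
                         "saturated")

#' Measure per-cell nuclear/cytoplasmic intensity ratios
#'
#' For each cell region, computes the arithmetic mean of the protein-channel
#' intensity over the nucleus pixels and over the cytoplasmic ring pixels,
#' and their ratio `nc_ratio = nuc_mean / ring_mean`. High ratios indicate
#' nuclear retention of the reporter; low ratios indicate cytoplasmic
#' accumulation. Intensities are used raw (no background subtraction) unless
#' `subtract_background` is set, in which case the per-image median is
#' subtracted (negative results floored at zero) before averaging.
#'
#' Cells are flagged and their ratio withheld (`NA`) when: the ring is empty
#' (`ring_empty`), the ring mean is zero (`ring_zero_mean`), any nucleus or
#' ring pixel sits at the saturation level (`saturated`, default the 16-bit
#' maximum), or the nucleus touches the image border (`border_touching`,
#' inherited). `ring_truncated` is carried as a non-disqualifying flag.
#'
#' @param img Protein-channel intensity matrix; must match the regions'
#'   source dimensions (hard error otherwise).
#' @param regions A [build_cell_regions()] result.
#' @param saturation_level Intensity treated as sensor saturation.
#' @param subtract_background Logical; per-image median subtraction.
#' @return data.frame of cell records: `cell_id`, `nuc_mean`, `ring_mean`,
#'   `nc_ratio`, `nuc_area`, `ring_area`, `qc_flags` (semicolon-joined),
#'   `evaluable`.
#' @export
measure_cells <- function(img, regions, saturation_level = BIT16_MAX,
                          subtract_background = FALSE) {
  stopifnot(inherits(regions, "cell_regions"))
  if (!all(dim(img) == regions$dim))
    stop(sprintf("image is %dx%d but regions were built on %dx%d",
                 nrow(img), ncol(img), regions$dim[1], regions$dim[2]),
         call. = FALSE)
  meas <- img
  if (subtract_background)
    meas <- pmax(img - stats::median(img), 0)

  n <- length(regions$cells)
  rec <- data.frame(cell_id = integer(n), nuc_mean = NA_real_,
                    ring_mean = NA_real_, nc_ratio = NA_real_,
                    nuc_area = integer(n), ring_area = integer(n),
                    qc_flags = character(n), evaluable = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cell <- regions$cells[[i]]
    flags <- cell$qc_flags
    nuc_mean <- mean(meas[cell$nucleus_idx])
    ring_mean <- if (cell$ring_area > 0) mean(meas[cell$ring_idx]) else
      NA_real_
    if (!is.na(ring_mean) && ring_mean == 0)
      flags <- union(flags, "ring_zero_mean")
    if (any(img[c(cell$nucleus_idx, cell$ring_idx)] >= saturation_level))
      flags <- union(flags, "saturated")
    disqualified <- any(flags %in% DISQUALIFYING_FLAGS)
    rec$cell_id[i] <- cell$cell_id
    rec$nuc_mean[i] <- nuc_mean
    rec$ring_mean[i] <- ring_mean
    rec$nc_ratio[i] <- if (disqualified || is.na(ring_mean)) NA_real_ else
      nuc_mean / ring_mean
    rec$nuc_area[i] <- cell$nuc_area
    rec$ring_area[i] <- cell$ring_area
    rec$qc_flags[i] <- paste(flags, collapse = ";")
    rec$evaluable[i] <- !disqualified && !is.na(ring_mean)
  }
  rec
}

#' Fraction of cells with cytoplasmic accumulation
#'
#' Image-analysis surrogate for manual blinded counting of "cytoplasmic"
#' cells: a cell is scored cytoplasmic-positive when its N/C ratio falls
#' below the threshold `tau`. Only cells with a defined ratio are counted.
#'
#' @param cells A [measure_cells()] data.frame (or any data.frame with an
#'   `nc_ratio` column).
#' @param tau Ratio threshold; see [suggest_tau()] for a data-driven choice.
#' @return list with `fraction`, `n_positive`, `n_evaluable`.
#' @examples
#' cells <- data.frame(nc_ratio = c(0.5, 0.5, 0.5, 0.5, 3, 3, 3, 3, 3, 3))
#' classify_translocation(cells, tau = 1)$fraction  # 0.4
#' @export
classify_translocation <- function(cells, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L)
  r <- cells$nc_ratio[!is.na(cells$nc_ratio)]
  if (!length(r)) {
    excl <- if (!is.null(cells$qc_flags))
      paste(unique(unlist(strsplit(cells$qc_flags[nzchar(cells$qc_flags)],
                                   ";"))), collapse = ", ")
    else ""
    stop("no evaluable cells",
         if (nzchar(excl)) paste0(" (QC exclusions: ", excl, ")"),
         call. = FALSE)
  }
  pos <- sum(r < tau)
  list(fraction = pos / length(r), n_positive = pos, n_evaluable = length(r))
}

#' Data-driven translocation threshold
#'
#' Returns the midpoint between the median N/C ratios of vehicle-treated and
#' stress-treated reference cells (typically negative-control wells of the
#' same plate). This is an explicit surrogate for a manual counting
#' criterion: any monotone criterion separating the two control populations
#' would serve.
#'
#' @param vehicle_cells,stress_cells Cell tables with `nc_ratio`.
#' @return Threshold `tau` on the ratio scale.
#' @export
suggest_tau <- function(vehicle_cells, stress_cells) {
  mv <- stats::median(vehicle_cells$nc_ratio, na.rm = TRUE)
  ms <- stats::median(stress_cells$nc_ratio, na.rm = TRUE)
  if (is.na(mv) || is.na(ms))
    stop("control cell populations have no evaluable ratios", call. = FALSE)
  (mv + ms) / 2
}
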