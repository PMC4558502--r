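#' Read and write 16-bit grayscale TIFF images
#'
#' Thin wrappers around the `tiff` package that fix the on-disk convention
#' used throughout the screen: single-channel 16-bit grayscale, no
#' compression, intensities stored as integers in \[0, 65535\]. Reading
#' returns a plain numeric matrix on the integer intensity scale (the
#' `tiff` package's \[0, 1\] normalization is undone exactly).
#'
#' @param path File path.
#' @return `read_tiff16`: numeric matrix of intensities in \[0, 65535\].
#' @export
read_tiff16 <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] != 1L)
      stop("expected a single-channel grayscale image: ", path,
           call. = FALSE)
    x <- x[, , 1L]
  }
  round(x * BIT16_MAX)
}

#' @rdname read_tiff16
#' @param img Numeric matrix; values are clipped to \[0, 65535\] and rounded.
#' @return `write_tiff16`: the path, invisibly.
#' @export
write_tiff16 <- function(img, path) {
  img <- pmin(pmax(round(img), 0), BIT16_MAX)
  tiff::writeTIFF(img / BIT16_MAX, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read and validate a plate-map CSV
#'
#' The plate map is a comma-separated file with mandatory header
#' `plate_id,replicate_id,well_id,gene_id,role,treatment`. Roles and
#' treatments are validated against closed, case-sensitive vocabularies
#' (`library`, `neg_ctrl`, `gfp_ctrl`, `death_ctrl`, `empty`; `stress`,
#' `vehicle`, `none`), and duplicate (plate, replicate, well) triples are
#' rejected; offending file lines are cited in errors.
#'
#' @param path Path to the CSV file.
#' @return A `plate_layout` data.frame.
#' @export
read_platemap <- function(path) {
  if (!file.exists(path)) stop("no such plate map: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0)
    stop("plate map is empty: ", path, call. = FALSE)
  df$gene_id[!nzchar(df$gene_id)] <- NA_character_
  validate_plate_layout(df, where = basename(path))
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' @rdname read_platemap
#' @param layout A `plate_layout` data.frame to write.
#' @export
write_platemap <- function(layout, path) {
  validate_plate_layout(layout)
  out <- as.data.frame(layout)[, c("plate_id", "replicate_id", "well_id",
                                   "gene_id", "role", "treatment")]
  out$gene_id[is.na(out$gene_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Stable CSV writer for result tables: ratio-like numeric columns are
# rounded to 6 significant digits so reruns are byte-identical.
write_result_csv <- function(df, path, signif_cols = character(0)) {
  for (cl in intersect(signif_cols, names(df)))
    df[[cl]] <- signif(df[[cl]], 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a segmentation debug overlay
#'
#' Renders nucleus masks (red), ring masks (green) and the rescaled
#' intensity image (blue) into an RGB PNG for visual inspection of the
#' segmentation and ring geometry.
#'
#' @param img Intensity matrix used for the blue channel (rescaled to its
#'   own maximum).
#' @param regions A [build_cell_regions()] result.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_overlay_png <- function(img, regions, path) {
  H <- regions$dim[1]; W <- regions$dim[2]
  stopifnot(all(dim(img) == c(H, W)))
  rgb <- array(0, c(H, W, 3))
  mx <- max(img)
  if (mx > 0) rgb[, , 3] <- img / mx
  red <- matrix(0, H, W); green <- matrix(0, H, W)
  for (cell in regions$cells) {
    red[cell$nucleus_idx] <- 1
    green[cell$ring_idx] <- 1
  }
  rgb[, , 1] <- red; rgb[, , 2] <- green
  EBImage::writeImage(EBImage::Image(aperm(rgb, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}
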