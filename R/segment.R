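#' Segment nuclei from a nuclear-stain channel
#'
#' Foreground is defined by a global Otsu threshold on the intensity
#' histogram; connected components are labeled (8-connectivity by default),
#' filtered by area, and flagged or removed when they touch the image
#' border. No watershed splitting is attempted: the screen geometry keeps
#' nuclei separated, and merged clumps are caught by the `max_area` filter.
#'
#' @param img Single-channel nonnegative intensity matrix (rows x columns).
#' @param min_area,max_area Area filter in pixels; components outside
#'   `[min_area, max_area]` are removed.
#' @param exclude_border If `TRUE` (default) border-touching nuclei are
#'   removed from the analysis set; otherwise they are kept but flagged.
#' @param connectivity 4 or 8 (default) neighbor connectivity.
#' @param threshold Optional explicit foreground threshold (intensity units,
#'   strict `>`); when `NULL`, Otsu's method on a 16-bit histogram is used.
#' @return A `labeled_mask`: list with `labels` (integer matrix, 0 =
#'   background, k > 0 = nucleus k with contiguous labels), `n`, `areas`,
#'   `bbox` (n x 4 matrix `rmin, rmax, cmin, cmax`), `border_touching`
#'   (logical per label), `removed` (data.frame of dropped components with
#'   reasons) and `threshold`. A constant image yields zero labels with a
#'   warning, not an error.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:30, 20:30] <- 5000
#' m <- segment_nuclei(img, min_area = 10)
#' m$n
#' @export
segment_nuclei <- function(img, min_area = 30, max_area = 5000,
                           exclude_border = TRUE, connectivity = 8,
                           threshold = NULL) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(img < 0)) stop("image intensities must be nonnegative",
                         call. = FALSE)
  stopifnot(connectivity %in% c(4, 8), min_area >= 0, max_area >= min_area)

  if (length(unique(as.vector(img))) == 1L) {
    warning("no foreground: constant image", call. = FALSE)
    return(empty_labeled_mask(dim(img), threshold = NA_real_))
  }
  if (is.null(threshold)) {
    mx <- max(max(img), 1)
    threshold <- EBImage::otsu(EBImage::Image(img / mx),
                               range = c(0, 1), levels = 65536) * mx
  }
  mask <- img > threshold
  if (!any(mask)) {
    warning("no foreground above threshold", call. = FALSE)
    return(empty_labeled_mask(dim(img), threshold = threshold))
  }

  lab <- EBImage::imageData(EBImage::bwlabel(mask))  # 4-connected
  storage.mode(lab) <- "integer"
  if (connectivity == 8) lab <- merge_diagonal_labels(lab)

  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0L)
  lb <- lab[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  labs <- sort(unique(lb))
  areas <- as.vector(table(factor(lb, levels = labs)))
  rmin <- tapply(rows, lb, min)[as.character(labs)]
  rmax <- tapply(rows, lb, max)[as.character(labs)]
  cmin <- tapply(cols, lb, min)[as.character(labs)]
  cmax <- tapply(cols, lb, max)[as.character(labs)]
  border <- rmin == 1L | cmin == 1L | rmax == H | cmax == W

  keep <- areas >= min_area & areas <= max_area
  reason <- rep(NA_character_, length(labs))
  reason[areas < min_area] <- "below_min_area"
  reason[areas > max_area] <- "above_max_area"
  if (exclude_border) {
    reason[keep & border] <- "border_touching"
    keep <- keep & !border
  }
  removed <- data.frame(label = labs[!keep], area = areas[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)

  # relabel survivors to contiguous 1..n, preserving original order
  new_id <- integer(max(labs))
  new_id[labs[keep]] <- seq_len(sum(keep))
  out <- matrix(0L, H, W)
  sel <- new_id[lb] > 0L & lb %in% labs[keep]
  out[idx[sel]] <- new_id[lb[sel]]

  structure(list(
    labels = out,
    n = sum(keep),
    areas = unname(areas[keep]),
    bbox = cbind(rmin = unname(rmin[keep]), rmax = unname(rmax[keep]),
                 cmin = unname(cmin[keep]), cmax = unname(cmax[keep])),
    border_touching = unname(border[keep]),
    removed = removed,
    threshold = threshold
  ), class = "labeled_mask")
}

empty_labeled_mask <- function(dm, threshold = NA_real_) {
  structure(list(labels = matrix(0L, dm[1], dm[2]), n = 0L,
                 areas = integer(0),
                 bbox = matrix(integer(0), 0, 4,
                               dimnames = list(NULL, c("rmin", "rmax",
                                                       "cmin", "cmax"))),
                 border_touching = logical(0),
                 removed = data.frame(label = integer(0), area = integer(0),
                                      reason = character(0)),
                 threshold = threshold),
            class = "labeled_mask")
}

#' Build a labeled mask from an explicit label image
#'
#' Wraps an integer label matrix (0 = background, k > 0 = nucleus k) into
#' the `labeled_mask` structure used by [build_cell_regions()], computing
#' areas, bounding boxes and border flags. Labels need not be contiguous;
#' they are compacted preserving numeric order.
#'
#' @param labels Integer matrix of labels.
#' @return A `labeled_mask`.
#' @export
as_labeled_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  H <- nrow(labels); W <- ncol(labels)
  idx <- which(labels > 0L)
  if (!length(idx)) return(empty_labeled_mask(dim(labels)))
  lb <- labels[idx]
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  labs <- sort(unique(lb))
  new_id <- integer(max(labs)); new_id[labs] <- seq_along(labs)
  out <- matrix(0L, H, W); out[idx] <- new_id[lb]
  areas <- as.vector(table(factor(lb, levels = labs)))
  rmin <- tapply(rows, lb, min)[as.character(labs)]
  rmax <- tapply(rows, lb, max)[as.character(labs)]
  cmin <- tapply(cols, lb, min)[as.character(labs)]
  cmax <- tapply(cols, lb, max)[as.character(labs)]
  structure(list(labels = out, n = length(labs), areas = areas,
                 bbox = cbind(rmin = unname(rmin), rmax = unname(rmax),
                              cmin = unname(cmin), cmax = unname(cmax)),
                 border_touching = unname(rmin == 1L | cmin == 1L |
                                            rmax == H | cmax == W),
                 removed = data.frame(label = integer(0), area = integer(0),
                                      reason = character(0)),
                 threshold = NA_real_),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat(sprintf("labeled_mask: %d nuclei on %dx%d px (%d removed)\n",
              x$n, nrow(x$labels), ncol(x$labels), nrow(x$removed)))
  invisible(x)
}

# bwlabel is 4-connected; union labels that touch diagonally to obtain
# 8-connectivity, then compact.
merge_diagonal_labels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  if (H < 2L || W < 2L) return(lab)
  a <- lab[-H, -W]; b <- lab[-1, -1]   # \ diagonal
  c_ <- lab[-H, -1]; d <- lab[-1, -W]  # / diagonal
  sel1 <- a > 0L & b > 0L & a != b
  sel2 <- c_ > 0L & d > 0L & c_ != d
  pairs <- rbind(cbind(a[sel1], b[sel1]), cbind(c_[sel2], d[sel2]))
  if (!nrow(pairs)) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, 1L)
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}
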