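# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's distance-transform / rasterization code paths: all
# geometry here is per-pixel enumeration in squared-integer arithmetic.

# Random label image: disks dropped sequentially; pixels already claimed by
# an earlier nucleus stay with it, so later nuclei can be crescents or be
# swallowed entirely. Exercises irregular shapes and near-contact.
mk_label_image <- function(H, W, n_nuclei, r_range = c(2, 9)) {
  lab <- matrix(0L, H, W)
  for (k in seq_len(n_nuclei)) {
    r <- stats::runif(1, r_range[1], r_range[2])
    cr <- stats::runif(1, 1, H)
    cc <- stats::runif(1, 1, W)
    idx <- which(outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, "+") <= r^2)
    idx <- idx[lab[idx] == 0L]
    lab[idx] <- k
  }
  lab
}

# Per-nucleus squared Euclidean distance maps (pixel centers, integer
# arithmetic, exact). Returns an (H*W) x K matrix, columns in label order.
oracle_dist2_maps <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  labs <- sort(unique(lab[lab > 0L]))
  pr <- as.vector(row(lab)); pc <- as.vector(col(lab))
  d2 <- matrix(Inf, H * W, length(labs))
  for (j in seq_along(labs)) {
    q <- which(lab == labs[j])
    qr <- ((q - 1L) %% H) + 1L
    qc <- ((q - 1L) %/% H) + 1L
    acc <- rep(Inf, H * W)
    for (i in seq_along(q))
      acc <- pmin(acc, (pr - qr[i])^2 + (pc - qc[i])^2)
    d2[, j] <- acc
  }
  d2
}

# Brute-force ring assignment: a background pixel is eligible for nucleus k
# iff gap^2 < d2_k <= (gap+width)^2; among eligible nuclei the closest wins;
# exact ties are dropped. Returns a list of sorted linear index vectors,
# one per label (in label order).
oracle_rings <- function(lab, gap, width, d2 = oracle_dist2_maps(lab)) {
  labs <- sort(unique(lab[lab > 0L]))
  K <- length(labs)
  out <- rep(list(integer(0)), K)
  if (K == 0) return(out)
  g2 <- gap^2; gw2 <- (gap + width)^2
  elig <- d2 > g2 & d2 <= gw2
  d2e <- d2
  d2e[!elig] <- Inf
  rmin <- do.call(pmin, as.data.frame(d2e))
  cand <- which(as.vector(lab) == 0L & rmin < Inf)
  if (!length(cand)) return(out)
  nt <- rowSums(d2e[cand, , drop = FALSE] == rmin[cand])
  winner <- max.col(-d2e[cand, , drop = FALSE], ties.method = "first")
  keep <- nt == 1L
  for (j in seq_len(K))
    out[[j]] <- sort(cand[keep & winner == j])
  out
}

# Ring index sets from a cell_regions object, sorted, in cell order.
impl_rings <- function(regions) {
  lapply(regions$cells, function(cell) sort(cell$ring_idx))
}

# Brute-force disk pixel count by full-image scan.
oracle_disk_area <- function(cr, cc, r, H, W) {
  sum(outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, "+") <= r^2)
}

# A grid of well-separated synthetic cells for ratio-recovery tests: cells
# never overlap, so measured rings sample only their own cytoplasm.
grid_cells <- function(nx = 4, ny = 4, spacing = 90, radius = 10,
                       extra = c(11, 12), total_protein = 2e5,
                       f_cyt = 0.5) {
  centers <- expand.grid(r = spacing * seq_len(ny) - spacing / 2,
                         c = spacing * seq_len(nx) - spacing / 2)
  n <- nrow(centers)
  data.frame(center_r = centers$r, center_c = centers$c,
             nucleus_radius = radius,
             cyto_extra_a = extra[1], cyto_extra_b = extra[2],
             total_protein = total_protein,
             f_cyt = rep_len(f_cyt, n))
}

grid_config <- function(nx = 4, ny = 4, spacing = 90, ...) {
  sim_config(image_width = nx * spacing, image_height = ny * spacing, ...)
}

# Measure a rendered field end-to-end with default segmentation/ring
# parameters; returns cells merged with truth by matching nucleus centers.
measure_rendered <- function(fld, min_area = 10) {
  mask <- suppressWarnings(segment_nuclei(fld$nuc, min_area = min_area))
  regions <- build_cell_regions(mask)
  rec <- measure_cells(fld$prot, regions)
  # match segmented cells to truth rows via nucleus centroid proximity
  H <- nrow(fld$nuc)
  cent <- t(vapply(regions$cells, function(cell) {
    idx <- cell$nucleus_idx
    c(mean(((idx - 1) %% H) + 1), mean(((idx - 1) %/% H) + 1))
  }, c(0, 0)))
  truth_i <- vapply(seq_len(nrow(rec)), function(i) {
    d2 <- (fld$truth$center_r - cent[i, 1])^2 +
      (fld$truth$center_c - cent[i, 2])^2
    which.min(d2)
  }, 0L)
  cbind(rec, fld$truth[truth_i, c("f_cyt", "expected_ratio", "clipped")])
}
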