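#' Analytic nuclear/cytoplasmic mean-intensity ratio
#'
#' The generative model spreads a cell's total reporter protein `T` uniformly
#' over its rasterized nuclear and cytoplasmic regions: every nuclear pixel
#' carries `(1 - f_cyt) * T / A_nuc` signal and every cytoplasmic pixel
#' `f_cyt * T / A_cyt`, on top of an additive background `b`. The expected
#' ratio of region mean intensities is therefore
#'
#' \deqn{R = \frac{(1 - f_{cyt})\,T / A_{nuc} + b}{f_{cyt}\,T / A_{cyt} + b}}
#'
#' which is strictly decreasing in `f_cyt`: nuclear-retained cells score
#' high, cytoplasm-accumulated cells score low.
#'
#' @param f_cyt Cytoplasmic protein fraction in \[0, 1\] (vectorized).
#' @param total_protein Total reporter signal per cell (arbitrary units).
#' @param a_nuc,a_cyt Nuclear and cytoplasmic region areas in pixels.
#' @param background Additive background intensity per pixel.
#' @return Expected N/C mean-intensity ratio (numeric vector).
#' @examples
#' expected_nc_ratio(0.2, 2e5, 317, 1135, 20)  # nuclear-retained, ~9.5
#' expected_nc_ratio(0.62, 2e5, 317, 1135, 20) # translocated, ~2
#' @export
expected_nc_ratio <- function(f_cyt, total_protein, a_nuc, a_cyt, background) {
  stopifnot(a_nuc > 0, a_cyt > 0, background >= 0)
  num <- (1 - f_cyt) * total_protein / a_nuc + background
  den <- f_cyt * total_protein / a_cyt + background
  num / den
}

# Rasterized pixel counts of the mean-geometry cell: a disk nucleus of the
# configured mean radius and a circular cytoplasm extending the midpoint of
# the extra-radius range beyond it. Used by the statistic-level simulator to
# map knockdown effects onto expected well ratios.
mean_cell_areas <- function(cfg) {
  r <- cfg$nucleus_radius_mean
  extra <- (cfg$cyto_radius_extra_min + cfg$cyto_radius_extra_max) / 2
  a_nuc <- disk_pixel_count(r)
  a_tot <- disk_pixel_count(r + extra)
  list(a_nuc = a_nuc, a_cyt = a_tot - a_nuc)
}

# Number of pixel centers inside a disk of radius r centered on a pixel.
disk_pixel_count <- function(r) {
  k <- ceiling(r)
  g <- expand.grid(dr = -k:k, dc = -k:k)
  sum(g$dr^2 + g$dc^2 <= r^2)
}

#' Expected well ratio implied by a knockdown effect
#'
#' Maps a knockdown attenuation onto the expected N/C ratio of a stress-
#' treated well using the configuration's mean cell geometry and mean total
#' protein. `effect = 0` gives the stressed null ratio, `effect = 1` the
#' vehicle-like (fully blocked) ratio.
#'
#' @param cfg A [sim_config()].
#' @param effect Attenuation fraction in \[0, 1\] (vectorized).
#' @param treatment `"stress"` or `"vehicle"`.
#' @return Expected well-level N/C ratio.
#' @export
ratio_for_effect <- function(cfg, effect = 0, treatment = "stress") {
  ar <- mean_cell_areas(cfg)
  f <- vapply(effect, function(e) realized_f_cyt(cfg, treatment, e), 0)
  expected_nc_ratio(f, cfg$total_protein_mean, ar$a_nuc, ar$a_cyt,
                    cfg$background_level)
}
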