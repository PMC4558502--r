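#' Simulation configuration for synthetic screen fields
#'
#' Bundles the generative parameters of the synthetic two-channel microscopy
#' model: field geometry, cell geometry, the partition of each cell's total
#' reporter protein between nucleus and cytoplasm, and the imaging noise
#' model. Defaults emulate a subconfluent adherent-cell field imaged at
#' moderate magnification, scaled so that a fully nuclear-retained cell shows
#' a nuclear/cytoplasmic (N/C) mean-intensity ratio near 9.5 and a
#' stress-translocated cell a ratio near 2, the working range of the assay.
#'
#' @param image_width,image_height Field size in pixels (>= 64).
#' @param cells_per_field Poisson mean of the number of cells per field.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus disk radius (pixels);
#'   per-cell radii are drawn from a normal truncated below at 2 px.
#' @param cyto_radius_extra_min,cyto_radius_extra_max Uniform bounds (pixels)
#'   on how far each cytoplasm ellipse semi-axis extends beyond the nucleus
#'   radius. The default lower bound (9) keeps the default measurement ring
#'   (gap 3 + width 5 = 8 px beyond the nucleus edge) inside the cytoplasm.
#' @param total_protein_mean,total_protein_sd Total reporter fluorescence per
#'   cell, in arbitrary units; drawn from a normal truncated below at zero.
#' @param f_cyt_baseline Mean cytoplasmic protein fraction in the vehicle
#'   (unstressed) condition, in \[0, 1\].
#' @param f_cyt_stress Mean cytoplasmic fraction under stress; must satisfy
#'   `f_cyt_baseline <= f_cyt_stress`.
#' @param f_cyt_sd Per-cell spread of the cytoplasmic fraction, expressed on
#'   the fraction scale; sampling is logit-normal so fractions stay in (0,1).
#' @param background_level Additive background intensity on both channels.
#' @param noise_sd Gaussian read-noise standard deviation (intensity units).
#' @param shot_noise If `TRUE`, pixel values are Poisson-resampled from their
#'   means before read noise is added.
#' @param nucleus_intensity Mean nuclear-stain intensity inside nuclei.
#' @param quantize If `TRUE` (default) rendered images are rounded to
#'   integers and clipped to the 16-bit range, as a camera would record them;
#'   set `FALSE` to obtain continuous noise-free intensities for exact
#'   arithmetic checks.
#' @param death_survival_factor Multiplier on `cells_per_field` applied to
#'   death-siRNA control wells (transfection-efficiency monitor).
#' @param max_place_attempts Rejection-sampling attempts per cell before the
#'   field is emitted with fewer cells.
#' @param rng_seed Optional integer seed stored with the configuration;
#'   generators use it when no explicit seed is passed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(cells_per_field = 5)
#' cfg$f_cyt_stress
#' @export
sim_config <- function(image_width = 360,
                       image_height = 360,
                       cells_per_field = 40,
                       nucleus_radius_mean = 10,
                       nucleus_radius_sd = 1,
                       cyto_radius_extra_min = 9,
                       cyto_radius_extra_max = 14,
                       total_protein_mean = 2e5,
                       total_protein_sd = 4e4,
                       f_cyt_baseline = 0.20,
                       f_cyt_stress = 0.62,
                       f_cyt_sd = 0.05,
                       background_level = 20,
                       noise_sd = 3,
                       shot_noise = TRUE,
                       nucleus_intensity = 8000,
                       quantize = TRUE,
                       death_survival_factor = 0.1,
                       max_place_attempts = 200,
                       rng_seed = NULL) {
  cfg <- list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    cells_per_field = cells_per_field,
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    cyto_radius_extra_min = cyto_radius_extra_min,
    cyto_radius_extra_max = cyto_radius_extra_max,
    total_protein_mean = total_protein_mean,
    total_protein_sd = total_protein_sd,
    f_cyt_baseline = f_cyt_baseline,
    f_cyt_stress = f_cyt_stress,
    f_cyt_sd = f_cyt_sd,
    background_level = background_level,
    noise_sd = noise_sd,
    shot_noise = isTRUE(shot_noise),
    nucleus_intensity = nucleus_intensity,
    quantize = isTRUE(quantize),
    death_survival_factor = death_survival_factor,
    max_place_attempts = as.integer(max_place_attempts),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$image_width < 64L || cfg$image_height < 64L)
    stop("image dimensions must be at least 64 pixels", call. = FALSE)
  if (cfg$cells_per_field < 0)
    stop("cells_per_field must be nonnegative", call. = FALSE)
  pos <- c("nucleus_radius_mean", "cyto_radius_extra_min",
           "cyto_radius_extra_max", "total_protein_mean",
           "nucleus_intensity")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("%s must be strictly positive", p), call. = FALSE)
  }
  nonneg <- c("nucleus_radius_sd", "total_protein_sd", "background_level",
              "noise_sd", "f_cyt_sd")
  for (p in nonneg) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("%s must be nonnegative", p), call. = FALSE)
  }
  if (cfg$cyto_radius_extra_max < cfg$cyto_radius_extra_min)
    stop("cyto_radius_extra_max must be >= cyto_radius_extra_min",
         call. = FALSE)
  if (cfg$f_cyt_baseline < 0 || cfg$f_cyt_stress > 1 ||
      cfg$f_cyt_baseline > cfg$f_cyt_stress)
    stop("need 0 <= f_cyt_baseline <= f_cyt_stress <= 1", call. = FALSE)
  if (cfg$death_survival_factor < 0 || cfg$death_survival_factor > 1)
    stop("death_survival_factor must be in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%dx%d px, %.3g cells/field", x$image_width, x$image_height,
              x$cells_per_field),
      sprintf("f_cyt %.2f (vehicle) -> %.2f (stress)",
              x$f_cyt_baseline, x$f_cyt_stress),
      sprintf("noise: sd %.3g, shot %s", x$noise_sd, x$shot_noise),
      sep = "\n  ")
  invisible(x)
}

#' Knockdown effect on the stress-induced translocation
#'
#' Describes how strongly an siRNA knockdown attenuates the stress shift of
#' the cytoplasmic fraction. `effect = 0` leaves the stress response intact;
#' `effect = 1` blocks it completely, so the cell behaves like vehicle.
#' The realized mean cytoplasmic fraction is
#' `f_cyt_stress - effect * (f_cyt_stress - f_cyt_baseline)`.
#'
#' @param gene_id Gene identifier matching the plate layout.
#' @param effect Attenuation in \[0, 1\].
#' @return A one-row `data.frame` with columns `gene_id`, `effect`; rows of
#'   several calls can be `rbind`ed into an effect table.
#' @examples
#' rbind(knockdown_effect("HK2", 1), knockdown_effect("MAPK11", 0.6))
#' @export
knockdown_effect <- function(gene_id, effect) {
  if (!is.numeric(effect) || length(effect) != 1L || effect < 0 || effect > 1)
    stop("effect must be a single number in [0, 1]", call. = FALSE)
  data.frame(gene_id = as.character(gene_id), effect = as.numeric(effect),
             stringsAsFactors = FALSE)
}

# Realized mean cytoplasmic fraction for a well, given treatment and
# optional knockdown effect.
realized_f_cyt <- function(cfg, treatment, effect = 0) {
  if (identical(treatment, "vehicle")) return(cfg$f_cyt_baseline)
  cfg$f_cyt_stress - effect * (cfg$f_cyt_stress - cfg$f_cyt_baseline)
}
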