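test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(image_width = 32), "64")
  expect_error(sim_config(f_cyt_baseline = 0.7, f_cyt_stress = 0.5),
               "f_cyt")
  expect_error(sim_config(nucleus_radius_mean = -1), "positive")
  expect_error(knockdown_effect("g", 1.2), "\\[0, 1\\]")
})

test_that("layout assigns every library gene once per replicate with controls", {
  lay <- generate_plate_layout(691, n_plates = 2, n_replicates = 3, seed = 3)
  for (r in unique(lay$replicate_id)) {
    lib <- lay[lay$replicate_id == r & lay$role == "library", ]
    expect_equal(nrow(lib), 691)
    expect_false(anyDuplicated(lib$gene_id) > 0)
  }
  # every plate carries the requested controls, including vehicle wells
  for (p in unique(lay$plate_id)) {
    pl <- lay[lay$replicate_id == "R1" & lay$plate_id == p, ]
    expect_gte(sum(pl$role %in% c("neg_ctrl", "gfp_ctrl", "death_ctrl")), 4)
    expect_gte(sum(pl$role == "neg_ctrl" & pl$treatment == "vehicle"), 1)
  }
  # deterministic under a fixed seed; gene placement shared across replicates
  expect_identical(lay,
                   generate_plate_layout(691, 2, 3, seed = 3))
  r1 <- lay[lay$replicate_id == "R1", c("plate_id", "well_id", "gene_id")]
  r2 <- lay[lay$replicate_id == "R2", c("plate_id", "well_id", "gene_id")]
  expect_identical(r1$gene_id, r2$gene_id)
})

test_that("zero-gene layout holds only controls and empties", {
  lay <- generate_plate_layout(0, 1, 1)
  expect_false(any(lay$role == "library"))
  expect_true(all(lay$role %in% c("neg_ctrl", "gfp_ctrl", "death_ctrl",
                                  "empty")))
})

test_that("capacity errors name the deficit; small plates leave empty wells", {
  expect_error(generate_plate_layout(400, 1, 1), "short by 32 wells")
  lay <- generate_plate_layout(
    10, 1, 1, plate_rows = 4, plate_cols = 6,
    controls_per_plate = c(neg_ctrl = 4, gfp_ctrl = 2, death_ctrl = 2))
  expect_equal(sum(lay$role == "library"), 10)
  expect_equal(sum(lay$role == "empty"), 6)
  expect_equal(nrow(lay), 24)
})

test_that("expected ratio decreases strictly in f_cyt and increases in area ratio", {
  f <- seq(0.05, 0.95, by = 0.05)
  r <- expected_nc_ratio(f, 2e5, 317, 1135, 20)
  expect_true(all(diff(r) < 0))
  expect_gt(expected_nc_ratio(0.5, 2e5, 300, 1500, 0),
            expected_nc_ratio(0.5, 2e5, 300, 1000, 0))
})

test_that("noise-free renders conserve each cell's total protein exactly", {
  cfg <- grid_config(2, 2, noise_sd = 0, shot_noise = FALSE,
                     quantize = FALSE)
  cells <- grid_cells(2, 2, f_cyt = c(0.2, 0.4, 0.6, 0.8))
  out <- render_cells(cfg, cells)
  H <- cfg$image_height; W <- cfg$image_width
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    # oracle pixel sets computed independently of the renderer
    nuc <- which(outer((seq_len(H) - ci$center_r)^2,
                       (seq_len(W) - ci$center_c)^2, "+") <=
                   ci$nucleus_radius^2)
    ell <- which(outer(((seq_len(H) - ci$center_r) /
                          (ci$nucleus_radius + ci$cyto_extra_a))^2,
                       ((seq_len(W) - ci$center_c) /
                          (ci$nucleus_radius + ci$cyto_extra_b))^2,
                       "+") <= 1)
    cell_px <- union(nuc, ell)
    total <- sum(out$prot[cell_px]) - length(cell_px) * cfg$background_level
    expect_equal(total, ci$total_protein, tolerance = 1e-12)
    expect_equal(out$truth$a_nuc[i], length(nuc))
    expect_equal(out$truth$a_cyt[i], length(setdiff(ell, nuc)))
  }
})

test_that("rendering is bit-identical under a fixed seed", {
  cfg <- sim_config(image_width = 128, image_height = 128,
                    cells_per_field = 6, nucleus_radius_mean = 6,
                    cyto_radius_extra_min = 9, cyto_radius_extra_max = 11)
  a <- render_field(cfg, seed = 5)
  b <- render_field(cfg, seed = 5)
  expect_identical(a$nuc, b$nuc)
  expect_identical(a$prot, b$prot)
  expect_identical(a$truth, b$truth)
  d <- render_field(cfg, seed = 6)
  expect_false(identical(a$prot, d$prot))
})

test_that("zero-cell fields are background-only with empty truth", {
  cfg <- sim_config(cells_per_field = 0, noise_sd = 0, shot_noise = FALSE)
  fld <- render_field(cfg, seed = 1)
  expect_equal(nrow(fld$truth), 0)
  expect_true(all(fld$nuc == cfg$background_level))
  expect_true(all(fld$prot == cfg$background_level))
})

test_that("overcrowded fields emit fewer cells with a warning count", {
  cfg <- sim_config(image_width = 64, image_height = 64,
                    cells_per_field = 200, nucleus_radius_mean = 8,
                    cyto_radius_extra_min = 9, cyto_radius_extra_max = 10,
                    max_place_attempts = 10)
  expect_warning(fld <- render_field(cfg, seed = 2), "placement failed")
  expect_gt(fld$placement_failures, 0)
  expect_lt(nrow(fld$truth), 200)
})

test_that("death-siRNA wells are thinned by the survival factor", {
  cfg <- sim_config(image_width = 200, image_height = 200,
                    cells_per_field = 40, nucleus_radius_mean = 5,
                    cyto_radius_extra_min = 9, cyto_radius_extra_max = 10)
  n_death <- sum(vapply(1:20, function(s)
    nrow(render_field(cfg, well = list(role = "death_ctrl",
                                       treatment = "stress",
                                       gene_id = NA), seed = s)$truth), 0))
  # Poisson(4) per field over 20 fields: mean 80
  expect_gt(n_death, 40)
  expect_lt(n_death, 130)
})

test_that("simulate_screen writes a reproducible tree with ground truth", {
  cfg <- sim_config(image_width = 128, image_height = 128,
                    cells_per_field = 5, nucleus_radius_mean = 5,
                    nucleus_radius_sd = 0.5,
                    cyto_radius_extra_min = 9, cyto_radius_extra_max = 11)
  lay <- generate_plate_layout(
    4, 1, 1, plate_rows = 4, plate_cols = 6,
    controls_per_plate = c(neg_ctrl = 2, death_ctrl = 1), seed = 2)
  hits <- knockdown_effect(lay$gene_id[lay$role == "library"][1], 1.0)
  d1 <- file.path(tempdir(), "scrA"); d2 <- file.path(tempdir(), "scrB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_screen(cfg, lay, planted_hits = hits, out_dir = d1, seed = 9)
  simulate_screen(cfg, lay, planted_hits = hits, out_dir = d2, seed = 9)
  expect_true(file.exists(file.path(d1, "platemap.csv")))
  expect_true(file.exists(file.path(d1, "manifest.yaml")))
  tifs <- list.files(d1, pattern = "\\.tif$", recursive = TRUE)
  expect_equal(length(tifs), 2 * sum(lay$role != "empty"))
  # byte-identical reruns, including the manifest
  for (f in c("truth_cells.csv", "manifest.yaml", tifs))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # planted full-block hit behaves like vehicle in the ground truth
  tr <- read.csv(file.path(d1, "truth_cells.csv"))
  pm <- read.csv(file.path(d1, "platemap.csv"))
  hit_wells <- pm$well_id[!is.na(pm$gene_id) & pm$gene_id == hits$gene_id]
  veh_wells <- pm$well_id[pm$treatment == "vehicle"]
  str_wells <- pm$well_id[pm$role == "library" & pm$gene_id != hits$gene_id]
  f_hit <- mean(tr$f_cyt[tr$well_id %in% hit_wells])
  f_veh <- mean(tr$f_cyt[tr$well_id %in% veh_wells])
  f_str <- mean(tr$f_cyt[tr$well_id %in% str_wells])
  expect_lt(abs(f_hit - f_veh), 0.1)
  expect_gt(f_str - f_hit, 0.2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted hits must exist in the layout", {
  cfg <- sim_config()
  lay <- generate_plate_layout(2, 1, 1, plate_rows = 4, plate_cols = 6,
                               controls_per_plate = c(neg_ctrl = 2))
  expect_error(simulate_screen(cfg, lay,
                               planted_hits = knockdown_effect("NOPE", 1),
                               out_dir = tempfile(), seed = 1),
               "absent from the layout")
})
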