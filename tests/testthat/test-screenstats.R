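# minimal layout builder for statistics-level tests
stat_layout <- function(n_genes, n_replicates = 1, n_plates = 1,
                        controls = c(neg_ctrl = 4, death_ctrl = 2),
                        seed = 1) {
  rows_needed <- ceiling(sqrt((n_genes / n_plates + sum(controls)) / 1.5))
  generate_plate_layout(n_genes, n_plates, n_replicates,
                        controls_per_plate = controls,
                        plate_rows = max(4, rows_needed),
                        plate_cols = max(6, rows_needed + 8), seed = seed)
}

mock_cells <- function(well, ratios, replicate = "R1", plate = "P1") {
  data.frame(replicate_id = replicate, plate_id = plate, well_id = well,
             nc_ratio = ratios, evaluable = !is.na(ratios),
             stringsAsFactors = FALSE)
}

test_that("well summaries aggregate evaluable cells and apply min_cells", {
  lay <- generate_plate_layout(2, 1, 1, plate_rows = 4, plate_cols = 6,
                               controls_per_plate = c(neg_ctrl = 2))
  lib_wells <- lay$well_id[lay$role == "library"]
  cells <- rbind(mock_cells(lib_wells[1], 2.0),
                 mock_cells(lib_wells[2], c(1, 2, 3)))
  ws <- summarize_wells(cells, lay, min_cells = 1)
  expect_equal(ws$well_ratio[ws$well_id == lib_wells[1]], 2.0)
  expect_equal(ws$well_ratio[ws$well_id == lib_wells[2]], 2.0)
  ws20 <- summarize_wells(cells, lay, min_cells = 20)
  w2 <- ws20[ws20$well_id == lib_wells[2], ]
  expect_true(w2$excluded)
  expect_equal(w2$reason, "too_few_cells")
  expect_true(is.na(w2$well_ratio))
  # wells with no cell records at all are excluded as no_image
  expect_true(all(ws$reason[ws$n_cells_evaluable == 0] == "no_image"))
  # median aggregator
  wmed <- summarize_wells(cells, lay, min_cells = 1, aggregator = "median")
  expect_equal(wmed$well_ratio[wmed$well_id == lib_wells[2]], 2.0)
})

test_that("Z'-factor matches its closed form and error conditions", {
  expect_equal(compute_zprime(c(9, 11), c(1.5, 2.5)),
               1 - 3 * (sd(c(9, 11)) + sd(c(1.5, 2.5))) / 8)
  # noiseless limit
  expect_equal(compute_zprime(c(5, 5, 5), c(1, 1, 1)), 1.0)
  expect_error(compute_zprime(c(2, 2), c(2, 2)), "zero assay window")
  expect_error(compute_zprime(5, c(1, 2)), "at least 2")
})

test_that("Z' is monotone in arm SDs and in the assay window", {
  mk <- function(m, s, n = 5) m + s * scale(seq_len(n))[, 1]
  z0 <- compute_zprime(mk(10, 1), mk(2, 0.5))
  expect_lt(compute_zprime(mk(10, 2), mk(2, 0.5)), z0)
  expect_lt(compute_zprime(mk(10, 1), mk(2, 1)), z0)
  expect_gt(compute_zprime(mk(14, 1), mk(2, 0.5)), z0)
})

test_that("hit calling pools stress-treated library wells and is strict", {
  lay <- stat_layout(50, seed = 4)
  wells <- simulate_ratio_screen(lay, seed = 11)
  res <- call_hits(wells)
  lib <- wells$role == "library" & wells$treatment == "stress"
  expect_equal(res$stats$mean_m, mean(wells$well_ratio[lib]))
  expect_equal(res$stats$sd_sigma, sd(wells$well_ratio[lib]))
  expect_equal(res$stats$hit_threshold,
               res$stats$mean_m + 3 * res$stats$sd_sigma)
  # vehicle controls sit far above the library but are never hits
  expect_false(any(res$wells$hit[res$wells$role != "library"]))

  # near the threshold at k = 3: just below is never a hit, just above is
  w2 <- wells
  i <- which(lib)[1]
  thr <- function(w) {
    v <- w$well_ratio[lib]
    mean(v) + 3 * sd(v)
  }
  x <- res$stats$hit_threshold
  for (rep in 1:50) {  # fixed-point: x -> threshold of screen containing x
    w2$well_ratio[i] <- x
    x_new <- thr(w2)
    if (x_new == x) break
    x <- x_new
  }
  w2$well_ratio[i] <- x
  r2 <- call_hits(w2)
  expect_equal(r2$wells$hit[i], w2$well_ratio[i] > r2$stats$hit_threshold)
  w2$well_ratio[i] <- x * (1 + 1e-6)
  expect_true(call_hits(w2)$wells$hit[i])
  w2$well_ratio[i] <- x * (1 - 1e-6)
  expect_false(call_hits(w2)$wells$hit[i])
})

test_that("a well sitting exactly on the hit line is not called", {
  # symmetric ratios make the pooled mean exact in floating point; with
  # k_sigma = 0 the threshold is that mean, so the boundary well's ratio
  # equals the threshold bit-for-bit and the strict rule must exclude it
  lay <- stat_layout(11, seed = 12)
  wells <- simulate_ratio_screen(lay, seed = 13)
  lib <- which(wells$role == "library")
  wells$well_ratio[lib] <- c(rep(1, 5), rep(3, 5), 2)
  res <- call_hits(wells, k_sigma = 0)
  expect_identical(res$stats$hit_threshold, 2)
  boundary <- lib[11]
  expect_false(res$wells$hit[boundary])
  expect_true(all(res$wells$hit[lib[6:10]]))
})

test_that("a planted ratio-9.71 well tops a 691-gene Gaussian null screen", {
  lay <- stat_layout(691, n_plates = 2, seed = 8)
  wells <- simulate_ratio_screen(lay, seed = 21)
  lib <- which(wells$role == "library")
  nulls <- withr::with_seed(22, rnorm(length(lib), mean = 2.0, sd = 0.25))
  wells$well_ratio[lib] <- nulls
  planted <- lib[1]
  wells$well_ratio[planted] <- 9.71
  res <- call_hits(wells)
  expect_true(res$wells$hit[planted])
  top <- res$wells[which.max(ifelse(res$wells$hit, res$wells$well_ratio,
                                    -Inf)), ]
  expect_equal(top$gene_id, wells$gene_id[planted])
})

test_that("degenerate screens (sigma = 0) warn and call nothing", {
  lay <- stat_layout(20, seed = 5)
  wells <- simulate_ratio_screen(lay, well_sd = 0, seed = 1)
  expect_warning(res <- call_hits(wells), "sigma = 0")
  expect_false(any(res$wells$hit))
})

test_that("hit calling is invariant to well order and plate partitioning", {
  lay <- stat_layout(60, seed = 6)
  wells <- simulate_ratio_screen(lay, seed = 31)
  res <- call_hits(wells)
  perm <- withr::with_seed(1, sample(nrow(wells)))
  res_p <- call_hits(wells[perm, ])
  expect_equal(res_p$stats$mean_m, res$stats$mean_m)
  expect_equal(res_p$stats$hit_threshold, res$stats$hit_threshold)
  key <- paste(wells$plate_id, wells$well_id)
  expect_equal(res_p$wells$hit[match(key, paste(res_p$wells$plate_id,
                                                res_p$wells$well_id))],
               res$wells$hit)
  # relabeling plates must not change screen-wide statistics
  w2 <- wells
  w2$plate_id <- rep(c("P1", "P2"), length.out = nrow(w2))
  # keep (plate, well) unique after relabeling
  w2$well_id <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24),
                        rep(1:24, times = 16))[seq_len(nrow(w2))]
  expect_equal(call_hits(w2)$stats$mean_m, res$stats$mean_m)
})

test_that("insufficient library wells is an error", {
  lay <- stat_layout(5, seed = 2)
  wells <- simulate_ratio_screen(lay, seed = 3)
  expect_error(call_hits(wells), "need >= 10")
})

test_that("replicate concordance applies the 2-of-3 rule", {
  mk_wells <- function(rep, hit_genes) {
    data.frame(replicate_id = rep, gene_id = c("A", "B", "C"),
               role = "library", well_ratio = c(5, 2, 2),
               hit = c("A", "B", "C") %in% hit_genes,
               stringsAsFactors = FALSE)
  }
  pooled <- rbind(mk_wells("R1", c("A", "B")), mk_wells("R2", "A"),
                  mk_wells("R3", character(0)))
  hc <- replicate_concordance(pooled, min_reps = 2)
  expect_true(hc$final_hit[hc$gene_id == "A"])    # 2 of 3
  expect_false(hc$final_hit[hc$gene_id == "B"])   # 1 of 3
  expect_equal(hc$n_replicates_hit[hc$gene_id == "A"], 2)
  # a missing replicate counts as a non-hit
  pooled2 <- rbind(mk_wells("R1", "C"), mk_wells("R2", "C")[-3, ],
                   mk_wells("R3", character(0)))
  hc2 <- replicate_concordance(pooled2, min_reps = 2)
  expect_equal(hc2$n_replicates_hit[hc2$gene_id == "C"], 1)
  expect_false(hc2$final_hit[hc2$gene_id == "C"])
  # single replicate, min_reps = 1: passthrough
  hc3 <- replicate_concordance(mk_wells("R1", "B"), min_reps = 1)
  expect_equal(hc3$final_hit[match(c("A", "B", "C"), hc3$gene_id)],
               c(FALSE, TRUE, FALSE))
})

test_that("replicate correlation matches the direct covariance formula", {
  mk <- function(rep, ratios, genes) {
    data.frame(replicate_id = rep, plate_id = "P1",
               well_id = sprintf("A%02d", seq_along(genes)),
               gene_id = genes, role = "library", treatment = "stress",
               n_cells_evaluable = 30, well_ratio = ratios,
               excluded = FALSE, reason = NA, stringsAsFactors = FALSE)
  }
  g <- sprintf("G%02d", 1:3)
  expect_equal(replicate_correlation(mk("R1", c(1, 2, 3), g),
                                     mk("R2", c(1, 2, 3), g))$r, 1.0)
  expect_equal(replicate_correlation(mk("R1", c(1, 2, 3), g),
                                     mk("R2", c(3, 2, 1), g))$r, -1.0)
  g50 <- sprintf("G%02d", 1:50)
  x <- withr::with_seed(9, rnorm(50, 2, 0.3))
  y <- withr::with_seed(10, x + rnorm(50, 0, 0.2))
  r <- replicate_correlation(mk("R1", x, g50), mk("R2", y, g50))$r
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, manual, tolerance = 1e-12)
  expect_error(replicate_correlation(mk("R1", c(2, 2, 2), g),
                                     mk("R2", c(1, 2, 3), g)),
               "undefined correlation")
  expect_error(replicate_correlation(mk("R1", c(1, 2), g[1:2]),
                                     mk("R2", c(1, 2), g[1:2])),
               "fewer than 3")
})

test_that("transfection QC measures the death-well cell deficit", {
  expect_equal(transfection_qc(20, 200)$efficiency, 0.9)
  expect_equal(transfection_qc(c(100, 100), c(100, 100))$efficiency, 0)
  expect_equal(transfection_qc(0, 150)$efficiency, 1)
  expect_equal(transfection_qc(300, 200)$efficiency, 0)  # clamped
  expect_false(transfection_qc(150, 200)$pass)
  expect_error(transfection_qc(10, 0), "zero cells")
})
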