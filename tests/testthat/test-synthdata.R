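# Synthetic screen generator: design structure, determinism, reference
# library separability, cell populations, rendering, round trips.

test_that("default study design reproduces the screen scale", {
  design <- generate_study_design(screen_config(seed = 1))
  expect_equal(nrow(design$samples), 84)
  expect_equal(length(unique(design$samples$plant)), 3)
  expect_equal(sum(design$samples$plant == "ANA"), 28)

  lay <- design$layout
  # wells unique within plate; >= 1 control per plate
  expect_false(anyDuplicated(lay[, c("plate_id", "well")]) > 0)
  ctrl_per_plate <- tapply(lay$is_control, lay$plate_id, sum)
  expect_true(all(ctrl_per_plate >= 1))
  # quadruplicate wells per (sample, dose, panel)
  trt <- lay[!lay$is_control, ]
  reps <- aggregate(replicate ~ sample_id + dose_ugml + panel, trt, length)
  expect_true(all(reps$replicate == 4))
  expect_true(all(is_valid_well(lay$well)))
})

test_that("minimal design has replicates x doses x panels wells per sample", {
  cfg <- screen_config(n_plants = 1, n_fractions_per_plant = 1, seed = 2)
  design <- generate_study_design(cfg)
  expect_equal(nrow(design$samples), 1)
  trt <- design$layout[!design$layout$is_control, ]
  expect_equal(nrow(trt),
               cfg$replicates * length(cfg$doses) * length(cfg$panels))
})

test_that("design generation is deterministic and config errors are raised", {
  d1 <- generate_study_design(screen_config(seed = 9))
  d2 <- generate_study_design(screen_config(seed = 9))
  expect_identical(d1$layout, d2$layout)
  expect_identical(d1$samples, d2$samples)
  d3 <- generate_study_design(screen_config(seed = 10))
  expect_false(identical(d1$samples$moa_label, d3$samples$moa_label))

  expect_error(screen_config(doses = numeric(0)), "dose ladder")
  expect_error(screen_config(replicates = 0), "replicate")
  expect_error(generate_study_design(
    screen_config(doses = 1:40, replicates = 16)), "384-well")
})

test_that("well-level simulation is seed-deterministic at table level", {
  design <- generate_study_design(screen_config(seed = 5))
  wm1 <- simulate_well_means(design)
  wm2 <- simulate_well_means(design)
  expect_identical(wm1, wm2)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(wm1, f1, sep = "\t")
  data.table::fwrite(wm2, f2, sep = "\t")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("reference library has separable classes and honest edge cases", {
  lib <- generate_reference_library("core", n_compounds = 200,
                                    n_moa_classes = 10, noise_sd = 0.2,
                                    seed = 3)
  expect_equal(nrow(lib$profiles), 200)
  r <- cor(t(lib$profiles))
  same <- outer(lib$labels$moa_label, lib$labels$moa_label, "==")
  diag(same) <- NA
  within_r <- mean(r[which(same)], na.rm = TRUE)
  between_r <- mean(r[which(!same)], na.rm = TRUE)
  expect_gt(within_r, between_r)
  expect_gt(within_r, 0.7)

  # zero noise: class members are identical
  lib0 <- generate_reference_library("core", n_compounds = 20,
                                     n_moa_classes = 5, noise_sd = 0,
                                     seed = 4)
  for (cl in unique(lib0$labels$moa_label)) {
    rows <- lib0$profiles[lib0$labels$moa_label == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }

  expect_error(generate_reference_library(n_compounds = 5, n_moa_classes = 9),
               "exceed")
  expect_error(generate_reference_library(noise_sd = -1), "noise_sd")
})

test_that("survival and effect curves follow the Hill family", {
  expect_equal(hill_survival(0, 8, 2), 1)
  expect_equal(hill_survival(8, 8, 2), 0.5)          # midpoint at EC50
  expect_equal(hill_survival(8, 8, 7.3), 0.5)        # any slope
  expect_equal(hill_survival(25, Inf, 2), 1)         # inert
  doses <- c(0, 1.56, 3.12, 6.25, 12.5, 25, 50)
  for (h in c(0.5, 1, 2, 4)) {
    s <- hill_survival(doses, 6, h)
    expect_true(all(diff(s) <= 0))
  }
})

test_that("simulated populations recover the planted cell-cycle mixture", {
  sigs <- moa_signature_set("core", seed = 3)
  sig <- sigs$topoisomerase_inhibitor
  cells <- simulate_cell_population(sig, dose = 25, seed = 11,
                                    baseline = 55000)
  # classify with the true scale (1000 units per 2N)
  obs <- phase_distribution(classify_cell_cycle(cells$dna_content / 500))
  e <- hill_response(25, sig$effect_ec50, sig$kill_hill)
  target <- control_cycle_shift() +
    (sig$cycle_shift - control_cycle_shift()) * e
  expect_lt(max(abs(obs - target)), 0.01)

  # dose 0 is control-like: count centred on baseline, survival 1
  c0 <- simulate_cell_population(sigs$inert, dose = 0, seed = 2,
                                 baseline = 2000)
  expect_lt(abs(nrow(c0) - 2000), 4 * sqrt(2000))
  obs0 <- phase_distribution(classify_cell_cycle(c0$dna_content / 500))
  expect_lt(max(abs(obs0 - control_cycle_shift())), 0.05)
})

test_that("rendered fields have the constructed photometry", {
  # no cells: pure background
  empty <- render_field_images(data.frame(x = numeric(0), y = numeric(0),
                                          dna_content = numeric(0)),
                               "dna", shape = c(64, 64), noise = "none")
  expect_equal(mean(empty$dna), 200)

  # five separated nuclei: five local maxima above background
  cells <- data.frame(cell_id = 1:5, x = c(40, 120, 200, 60, 180),
                      y = c(40, 60, 90, 180, 200),
                      dna_content = rep(1000, 5))
  im <- render_field_images(cells, "dna", shape = c(256, 256), noise = "none")
  img <- matrix(as.numeric(im$dna), 256, 256)
  seg <- segment_nuclei(correct_background(img))
  expect_equal(seg$n_valid, 5)

  # G2/M integrates to twice G0/G1 (noise-free, whole-image photometry)
  pair <- data.frame(cell_id = 1:2, x = c(70, 190), y = c(70, 190),
                     dna_content = c(1000, 2000))
  im2 <- render_field_images(pair, "dna", shape = c(256, 256), noise = "none")
  img2 <- matrix(as.numeric(im2$dna), 256, 256) - 200
  half <- img2[, 1:128]; other <- img2[, 129:256]
  expect_equal(sum(other) / sum(half), 2, tolerance = 0.02)

  # too-dense request errors
  expect_error(place_cells(500, shape = c(64, 64), min_spacing = 24),
               "too small")
})

test_that("screens round-trip through the directory writer", {
  scr <- simulate_screen(screen_config(n_plants = 1,
                                       n_fractions_per_plant = 3, seed = 6))
  dir <- tempfile("screen")
  write_screen(scr, dir)
  back <- read_screen(dir)
  expect_equal(back$layout, scr$design$layout)
  expect_equal(back$well_means, scr$well_means, tolerance = 1e-12)
  expect_equal(back$meta$seed, 6)            # provenance: seed recorded
  expect_false(dir.exists(file.path(dir, "images")))  # images disabled

  # with one rendered field, the TIFF appears under images/
  cells <- data.frame(cell_id = 1, x = 32, y = 32, dna_content = 1000)
  imgs <- list(`P2-01_A1_f1` = render_field_images(cells, "dna",
                                                   shape = c(64, 64)))
  dir2 <- tempfile("screen")
  write_screen(scr, dir2, images = imgs)
  expect_true(file.exists(file.path(dir2, "images", "P2-01_A1_f1_dna.tif")))
})
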