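# Well aggregation and control-normalized scoring.

test_that("well aggregation matches definitions and ground truth", {
  # identical cells: well mean equals the common value
  cells <- data.frame(cell_id = 1:10, nuclear_area = 150,
                      dna_content = 1000, nuc_p53 = 5, ring_p53 = 2,
                      nuc_casp9 = 3, ring_casp9 = 1, nuc_h2ax = 7,
                      ring_h2ax = 2)
  v <- aggregate_well(cells, "core", staining_panel = "P2")
  expect_equal(unname(v["nuclear_area"]), 150)
  expect_equal(unname(v["p53_nuc_mean"]), 5)
  expect_equal(unname(v["cell_count"]), 10)

  # arithmetic-mean definition on varying cells
  cells$nuclear_area <- seq(100, 190, 10)
  v2 <- aggregate_well(cells, "core", staining_panel = "P2")
  expect_equal(unname(v2["nuclear_area"]), mean(cells$nuclear_area))

  # zero valid cells should have been QC-excluded
  cells$valid <- FALSE
  expect_error(aggregate_well(cells, "core"), "QC")

  # synthetic inert well matches the control expectations within 4 SE
  sig <- moa_signature_set("core", seed = 3)$inert
  pop <- simulate_cell_population(sig, 0, seed = 8, baseline = 4000)
  va <- aggregate_well(pop, "core", staining_panel = "P2")
  ctrl <- control_feature_means("core")
  se_area <- sd(pop$nuclear_area) / sqrt(nrow(pop))
  expect_lt(abs(va["nuclear_area"] - ctrl["nuclear_area"]), 4 * se_area)
  se_p53 <- sd(pop$nuc_p53) / sqrt(nrow(pop))
  expect_lt(abs(va["p53_nuc_mean"] - ctrl["p53_nuc_mean"]), 4 * se_p53)
})

test_that("screen-max scores are bounded, attain +/-1 and keep signs", {
  scr <- simulate_screen(screen_config(seed = 21))
  prof <- compute_feature_scores(scr$well_means)
  expect_true(all(prof$score >= -1 & prof$score <= 1))
  mx <- tapply(abs(prof$score), prof$feature_id, max)
  expect_true(all(mx == 1))   # every feature's extreme sample scores exactly 1

  # planted direction recovered where the effect clears the noise
  design <- scr$design
  at25 <- prof[prof$dose_ugml == 25, ]
  ctrl <- control_feature_means("core")
  noise_se <- design$config$well_cv / sqrt(design$config$replicates)
  hits <- 0; checked <- 0
  for (i in seq_len(nrow(design$samples))) {
    s <- design$samples[i, ]
    if (s$moa_label == "inert") next
    sig <- design$signatures[[s$moa_label]]
    e <- hill_response(25, s$effect_ec50, s$kill_hill)
    eff <- design$config$effect_scale * s$amplitude * sig$effect * e
    eff["cell_count"] <- hill_survival(25, s$kill_ec50, s$kill_hill) - 1
    strong <- abs(eff) > 3 * noise_se
    sc <- at25[at25$sample_id == s$sample_id, ]
    sc <- setNames(sc$score, sc$feature_id)[names(eff)]
    checked <- checked + sum(strong)
    hits <- hits + sum(sign(sc[strong]) == sign(eff[strong]))
  }
  expect_gt(checked, 100)
  expect_equal(hits, checked)
})

test_that("zero deltas score zero and scores are scale-equivariant", {
  wm <- expand.grid(well = sprintf("A%d", 1:8), feature_id = c("f1", "f2"),
                    stringsAsFactors = FALSE)
  wm$plate_id <- "P1-01"; wm$panel <- "P1"
  wm$is_control <- wm$well %in% sprintf("A%d", 1:4)
  wm$sample_id <- ifelse(wm$is_control, "CONTROL", "S1")
  wm$dose_ugml <- ifelse(wm$is_control, 0, 25)
  wm$replicate <- rep(1:4, 4)
  wm$value <- ifelse(wm$feature_id == "f1", 10,          # no effect on f1
                     ifelse(wm$is_control, 10, 14))      # effect on f2
  prof <- compute_feature_scores(wm)
  expect_equal(prof$score[prof$feature_id == "f1"], 0)
  expect_equal(prof$score[prof$feature_id == "f2"], 1)

  # multiplying a feature's raw values by c > 0 leaves screen-max scores alone
  scr <- simulate_screen(screen_config(n_plants = 1,
                                       n_fractions_per_plant = 4, seed = 13))
  wm2 <- scr$well_means
  p1 <- compute_feature_scores(wm2)
  wm2$value[wm2$feature_id == "actin_nuc_mean"] <-
    wm2$value[wm2$feature_id == "actin_nuc_mean"] * 37
  p2 <- compute_feature_scores(wm2)
  expect_equal(p2$score, p1$score, tolerance = 1e-12)
})

test_that("control-vs-control splits score near zero on average", {
  # 100 plates, each with 10 control wells and 10 single-well
  # pseudo-samples drawn from the same control distribution: the 1,000
  # pseudo-sample scores should average out to ~0
  set.seed(99)
  one_plate <- function(p) {
    data.frame(plate_id = sprintf("P1-%03d", p),
               well = well_addresses()[1:20], panel = "P1",
               sample_id = c(rep("CONTROL", 10),
                             sprintf("PSEUDO_%03d_%02d", p, 1:10)),
               dose_ugml = 0, replicate = 1,
               is_control = rep(c(TRUE, FALSE), each = 10),
               feature_id = "f1", value = rlnorm(20, log(100), 0.05))
  }
  wm <- do.call(rbind, lapply(1:100, one_plate))
  prof <- compute_feature_scores(wm)
  expect_equal(nrow(prof), 1000)
  expect_lt(abs(mean(prof$score)), 0.02)

  expect_error(compute_feature_scores(wm[!wm$is_control, ]), "control")
})

test_that("profile matrices assemble, filter and round-trip exactly", {
  scr <- simulate_screen(screen_config(seed = 31))
  prof <- compute_feature_scores(scr$well_means)
  at25 <- prof[prof$dose_ugml == 25, ]
  mat <- build_profile_matrix(at25, "core")
  expect_equal(dim(mat), c(84, 21))
  expect_identical(colnames(mat), core_panel()$feature_id)

  one <- build_profile_matrix(at25[at25$sample_id == "ANA_F01", ], "core")
  expect_equal(dim(one), c(1, 21))

  # missing entries are NA, not zero, and the filter drops gappy samples
  holey <- at25[!(at25$sample_id == "ANA_F02" &
                    at25$feature_id %in% core_panel()$feature_id[1:10]), ]
  mh <- build_profile_matrix(holey, "core")
  expect_equal(sum(is.na(mh["ANA_F02", ])), 10)
  expect_false("ANA_F02" %in% rownames(drop_incomplete_profiles(mh)))

  expect_error(build_profile_matrix(
    data.frame(sample_id = "x", dose_ugml = 1, feature_id = "nope", score = 0),
    "core"), "mixed panels")

  f <- tempfile(fileext = ".tsv")
  write_profile_matrix(mat, f, seed = 31)
  back <- read_profile_matrix(f)
  expect_equal(unname(back), unname(mat), tolerance = 0)
  expect_equal(attr(back, "panel_name"), "core")
})

test_that("robust-z normalization is bounded and centered like screen-max", {
  scr <- simulate_screen(screen_config(n_plants = 1,
                                       n_fractions_per_plant = 6, seed = 17))
  prof <- compute_feature_scores(scr$well_means, method = "robust_z_tanh")
  expect_true(all(prof$score >= -1 & prof$score <= 1))
  d0 <- prof$score[prof$dose_ugml == 0]
  expect_lt(abs(mean(d0)), 0.1)
})
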