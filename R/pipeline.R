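# Orchestrated pipeline runs ------------------------------------------------
#
# simulate -> profile -> cluster/assign -> endpoints as one reproducible,
# seeded run with a serialized config, a manifest of output checksums and a
# summary report. Table mode (the default) works from per-well feature
# values; image rendering/extraction is exercised separately.

#' Build a pipeline run configuration
#'
#' @param seed master seed; every stage derives its own seed from it via
#'   [stage_seed()].
#' @param out_dir output directory.
#' @param screen a [screen_config()] for the fraction screen (its seed is
#'   overridden by `seed`).
#' @param n_reference reference compounds screened alongside the fractions.
#' @param reference_dose dose (ug/ml) at which references and fractions are
#'   profiled for clustering.
#' @param normalization score normalization method.
#' @param linkage clustering linkage.
#' @param cut_height tree cut height for MoA assignment.
#' @param qc_min_objects well QC threshold (valid objects).
#' @param alpha significance level.
#' @param table_mode work from well-level tables (no image stage).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("cytorun"),
                            screen = screen_config(),
                            n_reference = 735, reference_dose = 25,
                            normalization = "screen_max",
                            linkage = "average", cut_height = 0.3,
                            qc_min_objects = 500, alpha = 0.05,
                            table_mode = TRUE) {
  screen$seed <- seed
  structure(list(seed = seed, out_dir = out_dir, screen = screen,
                 n_reference = n_reference, reference_dose = reference_dose,
                 normalization = normalization, linkage = linkage,
                 cut_height = cut_height, qc_min_objects = qc_min_objects,
                 alpha = alpha, table_mode = table_mode),
            class = "pipeline_config")
}

# layout + truth for a reference screen sharing the fraction screen's
# signatures, profiled at a single dose
reference_screen_design <- function(design, n_reference, reference_dose,
                                    seed) {
  cfg <- design$config
  classes <- cfg$classes[cfg$classes$moa_label != "inert", , drop = FALSE]
  ref_cfg <- screen_config(
    n_plants = 1, n_fractions_per_plant = 1, doses = reference_dose,
    replicates = cfg$replicates, panels = cfg$panels,
    controls_per_plate = cfg$controls_per_plate, panel = cfg$panel,
    classes = cfg$classes, baseline_cells = cfg$baseline_cells,
    well_cv = cfg$well_cv, effect_scale = cfg$effect_scale, seed = seed)
  samples <- withr::with_seed(stage_seed(seed, "reflibrary"), data.frame(
    sample_id = sprintf("REF%04d", seq_len(n_reference)),
    plant = "LIB",
    moa_label = classes$moa_label[rep_len(seq_len(nrow(classes)), n_reference)],
    amplitude = stats::runif(n_reference, 0.5, 1),
    stringsAsFactors = FALSE))
  idx <- match(samples$moa_label, cfg$classes$moa_label)
  samples$kill_ec50 <- cfg$classes$kill_ec50[idx]
  samples$kill_hill <- cfg$classes$kill_hill[idx]
  samples$effect_ec50 <- cfg$classes$effect_ec50[idx]

  wells_per_sample <- length(ref_cfg$doses) * ref_cfg$replicates
  samples_per_plate <- (384L - ref_cfg$controls_per_plate) %/% wells_per_sample
  addr <- well_addresses()
  chunks <- split(seq_len(n_reference),
                  ceiling(seq_len(n_reference) / samples_per_plate))
  layout <- list()
  for (pan in ref_cfg$panels) {
    for (ci in seq_along(chunks)) {
      plate_id <- sprintf("R%s-%02d", pan, ci)
      treated <- expand.grid(replicate = seq_len(ref_cfg$replicates),
                             dose_ugml = ref_cfg$doses,
                             sample_id = samples$sample_id[chunks[[ci]]],
                             stringsAsFactors = FALSE)
      ctrl <- data.frame(replicate = seq_len(ref_cfg$controls_per_plate),
                         dose_ugml = 0, sample_id = "CONTROL")
      df <- rbind(treated[, c("sample_id", "dose_ugml", "replicate")],
                  ctrl[, c("sample_id", "dose_ugml", "replicate")])
      df$plate_id <- plate_id
      df$well <- addr[seq_len(nrow(df))]
      df$panel <- pan
      df$is_control <- df$sample_id == "CONTROL"
      layout[[plate_id]] <- df[, c("plate_id", "well", "panel", "sample_id",
                                   "dose_ugml", "replicate", "is_control")]
    }
  }
  structure(list(layout = do.call(rbind, c(layout, make.row.names = FALSE)),
                 samples = samples, signatures = design$signatures,
                 config = ref_cfg, seed = seed),
            class = "screen_design")
}

#' Run the full profiling pipeline
#'
#' Simulates the fraction screen and a reference-compound screen sharing
#' the same phenotype signature set, scores all wells together (references
#' are processed by the same method as the fractions), clusters the
#' profiles at the profiling dose, assigns modes of action, computes the
#' cell-loss and fold-change dose-response endpoints, and writes every
#' table plus a checksum manifest, the serialized config, and a summary
#' report under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_report` list (settings, QC, MoA calls, endpoint
#'   table, file manifest), invisibly writing the output tree.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out, name)
    data.table::fwrite(df, path, sep = "\t")
    written <<- c(written, path)
    path
  }
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("normalization: %s", config$normalization),
    sprintf("linkage: %s", config$linkage),
    sprintf("cut_height: %g", config$cut_height),
    sprintf("qc_min_objects: %d", config$qc_min_objects),
    sprintf("alpha: %g", config$alpha),
    sprintf("cell_cycle_tau: %g", 0.5),
    sprintf("table_mode: %s", config$table_mode))

  stage <- "simulate"
  res <- tryCatch({
    design <- generate_study_design(config$screen)
    wm <- simulate_well_means(design)
    aw <- simulate_assay_wells(design)
    ref_design <- reference_screen_design(design, config$n_reference,
                                          config$reference_dose,
                                          stage_seed(config$seed, "refscreen"))
    ref_wm <- simulate_well_means(ref_design)
    emit(design$layout, "layout.tsv")
    emit(wm, "well_means.tsv")
    emit(aw, "assay_wells.tsv")
    emit(design$samples, "sample_truth.tsv")
    emit(ref_design$samples, "reference_truth.tsv")

    stage <- "profile"
    all_wm <- rbind(wm, ref_wm)
    profiles <- compute_feature_scores(all_wm, method = config$normalization)
    emit(profiles, "profiles.tsv")

    stage <- "moa"
    at_dose <- profiles[profiles$dose_ugml == config$reference_dose, ]
    mat <- build_profile_matrix(at_dose, config$screen$panel)
    mat <- drop_incomplete_profiles(mat)
    d <- pearson_distance_matrix(mat)
    tree <- hierarchical_cluster(d, linkage = config$linkage)
    ref_labels <- stats::setNames(ref_design$samples$moa_label,
                                  ref_design$samples$sample_id)
    calls <- withCallingHandlers(
      assign_moa(tree, mat, ref_labels, h = config$cut_height),
      warning = function(w) invokeRestart("muffleWarning"))
    emit(calls, "calls.tsv")
    nwk <- export_newick(tree)
    nwk_path <- file.path(out, "tree.nwk")
    writeLines(nwk, nwk_path)
    written <- c(written, nwk_path)
    render_heatmap(mat, tree, tsv = file.path(out, "ordered_matrix.tsv"))
    written <- c(written, file.path(out, "ordered_matrix.tsv"))

    stage <- "endpoints"
    counts <- wm[wm$feature_id == "cell_count", ]
    ctrl_mean <- tapply(counts$value[counts$is_control],
                        counts$plate_id[counts$is_control], mean)
    treated <- counts[!counts$is_control, ]
    treated$value <- percent_of_control(treated$value,
                                        ctrl_mean[treated$plate_id])
    poc <- dose_response_table(
      treated[, c("sample_id", "dose_ugml", "replicate", "value")],
      endpoint = "percent_of_control", alpha = config$alpha)
    ep <- list(poc)
    ctrl_assay <- aw[aw$is_control, ]
    for (a in unique(aw$assay)) {
      sub <- aw[aw$assay == a & !aw$is_control, ]
      for (tp in unique(sub$timepoint_h)) {
        cm <- mean(ctrl_assay$value[ctrl_assay$assay == a &
                                      ctrl_assay$timepoint_h == tp])
        rows <- sub[sub$timepoint_h == tp, ]
        rows$value <- rows$value / cm
        ep[[length(ep) + 1]] <- dose_response_table(
          rows[, c("sample_id", "dose_ugml", "timepoint_h", "replicate",
                   "value")],
          endpoint = paste0(a, "_fc"), alpha = config$alpha)
      }
    }
    endpoints <- do.call(rbind, ep)
    emit(endpoints, "endpoints.tsv")
    list(design = design, calls = calls, endpoints = endpoints, tree = tree)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  yaml::write_yaml(list(seed = config$seed,
                        normalization = config$normalization,
                        linkage = config$linkage,
                        cut_height = config$cut_height,
                        qc_min_objects = config$qc_min_objects,
                        alpha = config$alpha,
                        n_reference = config$n_reference,
                        reference_dose = config$reference_dose,
                        table_mode = config$table_mode,
                        screen = config$screen[setdiff(names(config$screen),
                                                       c("classes", "panel"))]),
                   file.path(out, "run_config.yaml"))
  writeLines(log_lines, file.path(out, "run.log"))
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  stages_run <- c("simulate", "profile", "moa", "endpoints")
  if (!config$table_mode) stages_run <- c(stages_run, "imaging")
  data.table::fwrite(manifest, file.path(out, "manifest.tsv"), sep = "\t")
  report <- structure(list(
    settings = log_lines, stages = stages_run, manifest = manifest,
    qc_failures = data.frame(plate_id = character(0), well = character(0)),
    calls = res$calls,
    significant_endpoints = res$endpoints[res$endpoints$significant %in% TRUE, ],
    out_dir = out), class = "pipeline_report")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$out_dir, "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf("  MoA calls: %d fractions, %d assigned\n", nrow(x$calls),
              sum(x$calls$predicted_moa != "unassigned")))
  cat(sprintf("  significant endpoint rows: %d\n",
              nrow(x$significant_endpoints)))
  invisible(x)
}

#' Validate input tables
#'
#' Schema checks with line-numbered findings for the layout, per-cell and
#' profile TSV schemas; reports problems rather than raising (unless a file
#' is unreadable).
#'
#' @param layout,cells,profiles optional paths or data.frames.
#' @return data.frame: input, line, problem (zero rows when clean).
#' @export
validate_inputs <- function(layout = NULL, cells = NULL, profiles = NULL) {
  findings <- list()
  note <- function(input, line, problem)
    findings[[length(findings) + 1]] <<-
    data.frame(input = input, line = line, problem = problem,
               stringsAsFactors = FALSE)
  load_df <- function(x) {
    if (is.character(x)) as.data.frame(data.table::fread(x, sep = "\t")) else x
  }
  if (!is.null(layout)) {
    df <- load_df(layout)
    need <- c("plate_id", "well", "panel", "sample_id", "dose_ugml",
              "replicate", "is_control")
    miss <- setdiff(need, names(df))
    if (length(miss)) note("layout", 1, paste("missing columns:",
                                              paste(miss, collapse = ", ")))
    else {
      bad <- which(!is_valid_well(df$well))
      for (i in bad) note("layout", i + 1,
                          paste0("well '", df$well[i],
                                 "' is off the 16x24 grid"))
      dup <- which(duplicated(df[, c("plate_id", "well")]))
      for (i in dup) note("layout", i + 1,
                          paste0("duplicate (plate, well): ", df$plate_id[i],
                                 " ", df$well[i]))
      baddose <- which(!is.finite(df$dose_ugml) | df$dose_ugml < 0)
      for (i in baddose) note("layout", i + 1, "dose_ugml must be >= 0")
      badrep <- which(!is.finite(df$replicate) | df$replicate < 1)
      for (i in badrep) note("layout", i + 1, "replicate must be >= 1")
    }
  }
  if (!is.null(cells)) {
    df <- load_df(cells)
    need <- c("cell_id", "nuclear_area", "dna_content")
    miss <- setdiff(need, names(df))
    if (length(miss)) note("cells", 1, paste("missing columns:",
                                             paste(miss, collapse = ", ")))
    else {
      bad <- which(df$nuclear_area <= 0 | df$dna_content < 0)
      for (i in bad) note("cells", i + 1,
                          "nuclear_area must be > 0 and dna_content >= 0")
    }
  }
  if (!is.null(profiles)) {
    df <- load_df(profiles)
    if (names(df)[1] != "sample_id")
      note("profiles", 1, "first column must be sample_id")
    else {
      dup <- which(duplicated(df$sample_id))
      for (i in dup) note("profiles", i + 1,
                          paste0("duplicate sample_id: ", df$sample_id[i]))
      vals <- as.matrix(df[, -1, drop = FALSE])
      bad <- which(apply(abs(vals) > 1 & !is.na(vals), 1, any))
      for (i in bad) note("profiles", i + 1, "score outside [-1, 1]")
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(input = character(0), line = integer(0),
                  problem = character(0), stringsAsFactors = FALSE)
}
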