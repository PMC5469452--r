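# Synthetic screen generation ----------------------------------------------
#
# Seeded generators for everything the downstream analysis consumes: plate
# layouts with in-plate untreated controls, per-well feature values, per-well
# follow-up assay readouts, reference-compound libraries, per-cell feature
# tables and rendered fluorescence fields, all with recorded ground truth.
#
# Two granularities are provided. The screen-level generator draws per-WELL
# feature means directly from the phenotype model (control mean scaled by a
# Hill-shaped, signature-directed effect, times lognormal well noise); the
# cell-level generator draws individual cells (DNA content, area, marker
# intensities) for wells where the endpoint or imaging path needs them.

#' Build a screen design configuration
#'
#' @param n_plants number of source organisms (default 3).
#' @param n_fractions_per_plant SPE fractions per plant (default 28).
#' @param doses dose ladder in ug/ml (default 0, 1.56, 3.12, 6.25, 12.5,
#'   25, 50).
#' @param replicates wells per (sample, dose, panel); default 4
#'   (quadruplicate).
#' @param panels staining panel ids.
#' @param controls_per_plate untreated (medium-only) control wells per
#'   plate.
#' @param panel feature panel name or object.
#' @param p_active probability a fraction carries an active signature.
#' @param classes MoA class table (see [moa_class_table()]).
#' @param baseline_cells expected cells per untreated well.
#' @param well_cv lognormal coefficient of variation of well-level feature
#'   values.
#' @param effect_scale maximum relative shift of a feature mean at full
#'   effect (|signature entry| = 1, amplitude 1, saturating dose).
#' @param seed master seed for the whole screen.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_plants = 3, n_fractions_per_plant = 28,
                          doses = c(0, 1.56, 3.12, 6.25, 12.5, 25, 50),
                          replicates = 4, panels = c("P1", "P2", "P3", "P4"),
                          controls_per_plate = 16, panel = "core",
                          p_active = 0.5, classes = moa_class_table(),
                          baseline_cells = 2000, well_cv = 0.05,
                          effect_scale = 0.6, seed = 1) {
  if (length(doses) == 0) stop("dose ladder must not be empty")
  if (replicates < 1) stop("replicate count must be >= 1")
  if (n_plants < 1 || n_fractions_per_plant < 1)
    stop("n_plants and n_fractions_per_plant must be >= 1")
  structure(list(n_plants = n_plants,
                 n_fractions_per_plant = n_fractions_per_plant,
                 doses = doses, replicates = replicates, panels = panels,
                 controls_per_plate = controls_per_plate, panel = panel,
                 p_active = p_active, classes = classes,
                 baseline_cells = baseline_cells, well_cv = well_cv,
                 effect_scale = effect_scale, seed = seed),
            class = "screen_config")
}

#' Generate a screen design: plate layouts plus ground truth
#'
#' Lays out `n_plants * n_fractions_per_plant` fraction samples on 384-well
#' plates (16 rows x 24 columns, column-major fill), one plate series per
#' staining panel, with every (sample, dose) in `replicates` adjacent wells
#' and `controls_per_plate` untreated control wells on every plate. Each
#' sample is assigned a ground-truth phenotype: an MoA class (inert with
#' probability `1 - p_active`) and an effect amplitude drawn uniform on
#' \[0.5, 1\].
#'
#' @param config a [screen_config()].
#' @return a `screen_design` list: `layout` (data.frame: plate_id, well,
#'   panel, sample_id, dose_ugml, replicate, is_control), `samples` (per-
#'   sample ground truth), `signatures` (per-class
#'   [phenotype_signature()]s), `config`, `seed`.
#' @export
generate_study_design <- function(config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  n_samples <- config$n_plants * config$n_fractions_per_plant
  wells_per_sample <- length(config$doses) * config$replicates
  samples_per_plate <- (384L - config$controls_per_plate) %/% wells_per_sample
  if (samples_per_plate < 1)
    stop("dose ladder x replicates does not fit on a 384-well plate ",
         "with ", config$controls_per_plate, " control wells")

  plant_ids <- if (config$n_plants == 3) c("ANA", "CIT", "JUN")
  else sprintf("PL%02d", seq_len(config$n_plants))
  samples <- data.frame(
    sample_id = paste0(rep(plant_ids, each = config$n_fractions_per_plant), "_",
                       sprintf("F%02d", seq_len(config$n_fractions_per_plant))),
    plant = rep(plant_ids, each = config$n_fractions_per_plant),
    stringsAsFactors = FALSE)

  active <- config$classes$moa_label[is.finite(config$classes$kill_ec50) |
                                       config$classes$moa_label != "inert"]
  active <- setdiff(config$classes$moa_label, "inert")
  truth <- withr::with_seed(stage_seed(config$seed, "design"), {
    cls <- ifelse(stats::runif(n_samples) < config$p_active,
                  sample(active, n_samples, replace = TRUE), "inert")
    amp <- ifelse(cls == "inert", 0, stats::runif(n_samples, 0.5, 1))
    list(cls = cls, amp = amp)
  })
  samples$moa_label <- truth$cls
  samples$amplitude <- truth$amp
  idx <- match(samples$moa_label, config$classes$moa_label)
  samples$kill_ec50 <- config$classes$kill_ec50[idx]
  samples$kill_hill <- config$classes$kill_hill[idx]
  samples$effect_ec50 <- config$classes$effect_ec50[idx]

  sigs <- moa_signature_set(config$panel, config$classes,
                            seed = stage_seed(config$seed, "signatures"))

  addr <- well_addresses()
  chunks <- split(seq_len(n_samples),
                  ceiling(seq_len(n_samples) / samples_per_plate))
  layout <- list()
  for (pan in config$panels) {
    for (ci in seq_along(chunks)) {
      plate_id <- sprintf("%s-%02d", pan, ci)
      sidx <- chunks[[ci]]
      treated <- expand.grid(replicate = seq_len(config$replicates),
                             dose_ugml = config$doses,
                             sample_id = samples$sample_id[sidx],
                             stringsAsFactors = FALSE)
      n_t <- nrow(treated)
      ctrl <- data.frame(replicate = seq_len(config$controls_per_plate),
                         dose_ugml = 0, sample_id = "CONTROL",
                         stringsAsFactors = FALSE)
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
  layout <- do.call(rbind, c(layout, make.row.names = FALSE))
  stopifnot(!anyDuplicated(layout[, c("plate_id", "well")]))
  structure(list(layout = layout, samples = samples, signatures = sigs,
                 config = config, seed = config$seed),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("<screen_design> %d samples, %d wells on %d plates, %d panels, seed %d\n",
              nrow(x$samples), nrow(x$layout),
              length(unique(x$layout$plate_id)), length(x$config$panels),
              x$seed))
  invisible(x)
}

# Expected (noise-free) well feature means for one sample at one dose.
# Controls (sample_id "CONTROL") use the inert signature.
truth_well_means <- function(design, sample_id, dose, panel = NULL) {
  panel <- get_panel(panel %||% design$config$panel)
  ctrl <- control_feature_means(panel)
  if (identical(sample_id, "CONTROL")) return(ctrl)
  i <- match(sample_id, design$samples$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  s <- design$samples[i, ]
  sig <- design$signatures[[s$moa_label]]
  e <- hill_response(dose, s$effect_ec50, s$kill_hill)
  v <- ctrl * (1 + design$config$effect_scale * s$amplitude * sig$effect[names(ctrl)] * e)
  surv <- hill_survival(dose, s$kill_ec50, s$kill_hill)
  if ("cell_count" %in% names(v)) v["cell_count"] <- ctrl["cell_count"] * surv
  v
}

#' Simulate per-well feature values for a designed screen
#'
#' Draws one value per (well, feature of the well's panel): the expected
#' well mean under the sample's phenotype signature at its dose, times
#' multiplicative lognormal well noise with coefficient of variation
#' `well_cv`. The cell-count feature follows the cytotoxicity survival
#' curve instead of the signature direction.
#'
#' @param design a `screen_design`.
#' @param seed seed (defaults to a stage seed derived from the design
#'   seed).
#' @return data.frame in long form: plate_id, well, panel, sample_id,
#'   dose_ugml, replicate, is_control, feature_id, value.
#' @export
simulate_well_means <- function(design, seed = stage_seed(design$seed, "wells")) {
  stopifnot(inherits(design, "screen_design"))
  panel <- get_panel(design$config$panel)
  ctrl <- control_feature_means(panel)
  lay <- data.table::as.data.table(design$layout)
  feats <- data.table::data.table(panel = panel$panel,
                                  feature_id = panel$feature_id)
  dt <- merge(lay, feats, by = "panel", allow.cartesian = TRUE, sort = FALSE)

  sam <- design$samples
  cls <- c(stats::setNames(sam$moa_label, sam$sample_id), CONTROL = "inert")
  amp <- c(stats::setNames(sam$amplitude, sam$sample_id), CONTROL = 0)
  kec <- c(stats::setNames(sam$kill_ec50, sam$sample_id), CONTROL = Inf)
  khl <- c(stats::setNames(sam$kill_hill, sam$sample_id), CONTROL = 1)
  eec <- c(stats::setNames(sam$effect_ec50, sam$sample_id), CONTROL = Inf)

  eff_mat <- vapply(design$signatures, function(s) s$effect[panel$feature_id],
                    numeric(nrow(panel)))
  rownames(eff_mat) <- panel$feature_id

  sid <- dt$sample_id
  fi <- match(dt$feature_id, panel$feature_id)
  ci <- match(cls[sid], colnames(eff_mat))
  e <- hill_response(dt$dose_ugml, eec[sid], khl[sid])
  mu <- ctrl[fi] * (1 + design$config$effect_scale * amp[sid] * eff_mat[cbind(fi, ci)] * e)
  is_count <- dt$feature_id == "cell_count"
  if (any(is_count))
    mu[is_count] <- ctrl["cell_count"] *
      hill_survival(dt$dose_ugml[is_count], kec[sid[is_count]], khl[sid[is_count]])
  sdlog <- sqrt(log(1 + design$config$well_cv^2))
  val <- withr::with_seed(seed,
    mu * stats::rlnorm(nrow(dt), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  dt$value <- val
  out <- as.data.frame(dt[, c("plate_id", "well", "panel", "sample_id",
                              "dose_ugml", "replicate", "is_control",
                              "feature_id", "value")])
  out
}

#' Simulate per-well follow-up assay readouts
#'
#' Per-well fluorescence readouts for the five follow-up assays (MitoSOX,
#' membrane permeability, caspase-9, p53, gamma-H2AX) at 24 h and 48 h:
#' baseline times `1 + (induction - 1) * t48 * hill(dose)` with lognormal
#' well noise, where `induction` is the signature's saturating fold change
#' and the 48 h effect is 1.25x the 24 h effect. Untreated control wells
#' (one set per sample group, `CONTROL`) read at baseline.
#'
#' @param design a `screen_design`.
#' @param timepoints hours of treatment.
#' @param n_control control wells per timepoint.
#' @param seed seed.
#' @return data.frame: sample_id, dose_ugml, timepoint_h, replicate, assay,
#'   value, is_control.
#' @export
simulate_assay_wells <- function(design, timepoints = c(24, 48),
                                 n_control = 16,
                                 seed = stage_seed(design$seed, "assays")) {
  stopifnot(inherits(design, "screen_design"))
  assays <- c("mitosox", "permeability", "caspase9", "p53", "h2ax")
  base <- c(mitosox = 200, permeability = 150, caspase9 = 120, p53 = 140,
            h2ax = 110)
  sam <- design$samples
  grid <- expand.grid(replicate = seq_len(design$config$replicates),
                      dose_ugml = design$config$doses,
                      sample_id = sam$sample_id, assay = assays,
                      timepoint_h = timepoints, stringsAsFactors = FALSE)
  ctl <- expand.grid(replicate = seq_len(n_control), dose_ugml = 0,
                     sample_id = "CONTROL", assay = assays,
                     timepoint_h = timepoints, stringsAsFactors = FALSE)
  grid <- rbind(grid, ctl)
  i <- match(grid$sample_id, sam$sample_id)
  ind <- t(vapply(design$signatures, function(s) s$induction, numeric(5)))
  colnames(ind) <- assays
  sat <- ifelse(is.na(i), 1,
                ind[cbind(match(ifelse(is.na(i), "inert", sam$moa_label[i]),
                                rownames(ind)),
                          match(grid$assay, assays))])
  amp <- ifelse(is.na(i), 0, sam$amplitude[i])
  eec <- ifelse(is.na(i), Inf, sam$effect_ec50[i])
  khl <- ifelse(is.na(i), 1, sam$kill_hill[i])
  e <- hill_response(grid$dose_ugml, eec, khl)
  tfac <- ifelse(grid$timepoint_h >= 48, 1.25, 1)
  mu <- base[grid$assay] * (1 + (sat - 1) * amp * tfac * e)
  sdlog <- sqrt(log(1 + 0.05^2))
  grid$value <- withr::with_seed(seed,
    mu * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog))
  grid$is_control <- grid$sample_id == "CONTROL"
  grid[, c("sample_id", "dose_ugml", "timepoint_h", "replicate", "assay",
           "value", "is_control")]
}

#' Simulate a complete synthetic screen
#'
#' Convenience wrapper: design, per-well feature values and per-well assay
#' readouts in one seeded object.
#'
#' @param config a [screen_config()].
#' @return a `synthetic_screen` list: `design`, `well_means`,
#'   `assay_wells`, `seed`.
#' @export
simulate_screen <- function(config = screen_config()) {
  design <- generate_study_design(config)
  structure(list(design = design,
                 well_means = simulate_well_means(design),
                 assay_wells = simulate_assay_wells(design),
                 seed = config$seed),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  print(x$design)
  cat(sprintf("  well feature values: %d rows; assay wells: %d rows\n",
              nrow(x$well_means), nrow(x$assay_wells)))
  invisible(x)
}

#' Generate a reference-compound library with known modes of action
#'
#' Draws `n_moa_classes` mutually separable class effect directions (or
#' reuses supplied signatures) and one profile per compound: its class
#' signature plus independent Gaussian feature noise, clipped to \[-1, 1\].
#' Compounds are assigned to classes as evenly as possible.
#'
#' @param panel feature panel or name.
#' @param n_compounds library size (default 735).
#' @param n_moa_classes number of MoA classes (ignored when `signatures`
#'   given).
#' @param noise_sd per-feature Gaussian noise sd (must be >= 0).
#' @param seed seed.
#' @param signatures optional named list of [phenotype_signature()]s whose
#'   effect vectors are used as class signatures.
#' @param max_cor separability bound on pairwise class-signature
#'   correlation when drawing.
#' @return list: `profiles` (compounds x features matrix), `labels`
#'   (data.frame compound_id, moa_label), `class_effects` (features x
#'   classes matrix).
#' @export
generate_reference_library <- function(panel = "core", n_compounds = 735,
                                       n_moa_classes = 9, noise_sd = 0.2,
                                       seed = 1, signatures = NULL,
                                       max_cor = 0.5) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  panel <- get_panel(panel)
  nf <- nrow(panel)
  if (!is.null(signatures)) {
    class_eff <- vapply(signatures, function(s) s$effect[panel$feature_id],
                        numeric(nf))
    class_eff <- class_eff[, colnames(class_eff) != "inert", drop = FALSE]
  } else {
    if (n_moa_classes > n_compounds)
      stop("n_moa_classes must not exceed n_compounds")
    if (n_moa_classes < 1) stop("n_moa_classes must be >= 1")
    class_eff <- withr::with_seed(stage_seed(seed, "refclasses"), {
      for (try in 1:200) {
        m <- replicate(n_moa_classes, draw_effect_vector(nf))
        if (n_moa_classes < 2 ||
            max(abs(stats::cor(m)[upper.tri(diag(n_moa_classes))])) < max_cor)
          break
      }
      m
    })
    colnames(class_eff) <- sprintf("class_%02d", seq_len(n_moa_classes))
  }
  rownames(class_eff) <- panel$feature_id
  k <- ncol(class_eff)
  if (k > n_compounds) stop("more classes than compounds")
  lab <- colnames(class_eff)[rep_len(seq_len(k), n_compounds)]
  profiles <- withr::with_seed(stage_seed(seed, "refnoise"), {
    t(class_eff[, match(lab, colnames(class_eff)), drop = FALSE]) +
      matrix(stats::rnorm(n_compounds * nf, 0, noise_sd), n_compounds, nf)
  })
  profiles <- clip01(profiles)
  rownames(profiles) <- sprintf("REF%04d", seq_len(n_compounds))
  colnames(profiles) <- panel$feature_id
  list(profiles = profiles,
       labels = data.frame(compound_id = rownames(profiles), moa_label = lab,
                           stringsAsFactors = FALSE),
       class_effects = class_eff)
}

# truncated-normal draw by quantile inversion
rtnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate the cells of one well
#'
#' Draws a per-cell feature table under a phenotype signature at one dose:
#' the cell count is Poisson around `baseline * survival(dose)`; each
#' cell's cycle phase is drawn from the control distribution shifted toward
#' the signature's target in proportion to the Hill effect; DNA content is
#' drawn per phase (G0/G1 and G2/M as truncated normal peaks at 2N and 4N,
#' S uniform across the S bin, sub-2N and super-4N tails for the low/high
#' classes), expressed in intensity units at `dna_anchor` units per 2N;
#' nuclear area and marker intensities are control means scaled by the
#' signature's effect entries with per-cell lognormal variation
#' (mean-preserving).
#'
#' @param signature a [phenotype_signature()].
#' @param dose dose in ug/ml.
#' @param seed seed.
#' @param baseline expected untreated cell count.
#' @param amplitude effect amplitude multiplier in \[0, 1\].
#' @param markers markers to generate intensity columns for (default: the
#'   signature panel's P2 markers minus DNA).
#' @param dna_anchor intensity units per 2N of DNA.
#' @param tau cell-cycle bin half-width in N units (shared with the
#'   classifier).
#' @param cell_cv lognormal per-cell coefficient of variation for areas and
#'   intensities.
#' @param dna_noise_cv multiplicative measurement noise on DNA content
#'   (default 0 = noise-free content).
#' @param effect_scale maximum relative mean shift at full effect.
#' @return data.frame: cell_id, x, y (unit square), phase_true,
#'   nuclear_area, dna_content, then nuc_/ring_ mean-intensity columns per
#'   marker.
#' @export
simulate_cell_population <- function(signature, dose, seed = 1,
                                     baseline = 2000, amplitude = 1,
                                     markers = c("p53", "casp9", "h2ax"),
                                     dna_anchor = 1000, tau = 0.5,
                                     cell_cv = 0.2, dna_noise_cv = 0,
                                     effect_scale = 0.6) {
  stopifnot(inherits(signature, "phenotype_signature"), dose >= 0)
  ctrl_cycle <- control_cycle_shift()
  e <- hill_response(dose, signature$effect_ec50, signature$kill_hill)
  surv <- hill_survival(dose, signature$kill_ec50, signature$kill_hill)
  probs <- ctrl_cycle + (signature$cycle_shift[names(ctrl_cycle)] - ctrl_cycle) * e
  probs <- probs / sum(probs)
  eff <- function(fid) {
    v <- signature$effect[fid]
    if (is.na(v) || is.null(v)) 0 else unname(v)
  }
  shift <- function(fid) 1 + effect_scale * amplitude * eff(fid) * e
  sdlog <- sqrt(log(1 + cell_cv^2))
  lnoise <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  base_nuc <- c(er = 420, lysosome = 520, membrane = 380, p53 = 300,
                casp9 = 260, h2ax = 240, mito = 600, cytc = 340,
                nfkb = 310, actin = 700, tubulin = 760)
  base_ring <- round(base_nuc * 1.6)
  withr::with_seed(seed, {
    n <- stats::rpois(1, baseline * surv)
    phase <- sample(names(probs), n, replace = TRUE, prob = probs)
    dna_n <- numeric(n)
    for (ph in unique(phase)) {
      i <- phase == ph
      m <- sum(i)
      dna_n[i] <- switch(ph,
        low  = stats::runif(m, max(0.2, 2 - tau - 1), 2 - tau),
        g0g1 = rtnorm(m, 2, 0.15, 2 - tau, 2 + tau),
        s    = stats::runif(m, 2 + tau, 4 - tau),
        g2m  = rtnorm(m, 4, 0.20, 4 - tau, 4 + tau),
        high = 4 + tau + stats::rexp(m, rate = 2))
    }
    dna <- dna_n * dna_anchor / 2
    if (dna_noise_cv > 0) {
      sl <- sqrt(log(1 + dna_noise_cv^2))
      dna <- dna * stats::rlnorm(n, -sl^2 / 2, sl)
    }
    df <- data.frame(cell_id = seq_len(n),
                     x = stats::runif(n), y = stats::runif(n),
                     phase_true = phase,
                     nuclear_area = 180 * shift("nuclear_area") * lnoise(n),
                     dna_content = dna, stringsAsFactors = FALSE)
    for (m in markers) {
      df[[paste0("nuc_", m)]] <-
        base_nuc[m] * shift(paste0(m, "_nuc_mean")) * lnoise(n)
      df[[paste0("ring_", m)]] <-
        base_ring[m] * shift(paste0(m, "_ring_mean")) * lnoise(n)
    }
    df
  })
}

#' Place non-overlapping cell centroids in a field
#'
#' Rejection-samples `n` positions at pairwise distance >= `min_spacing`
#' and at least `margin` pixels from the border.
#'
#' @param n number of cells.
#' @param shape image dimensions c(rows, cols).
#' @param min_spacing minimum centroid separation in pixels.
#' @param margin border margin in pixels.
#' @param seed seed.
#' @return matrix with columns x (col), y (row).
#' @export
place_cells <- function(n, shape = c(256, 256), min_spacing = 24,
                        margin = 12, seed = 1) {
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  lim <- shape - 2 * margin
  if (any(lim <= 0) || n * (min_spacing / 2)^2 * pi > prod(lim))
    stop("image too small for ", n, " cells at spacing ", min_spacing)
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, n, 2)
    placed <- 0
    for (attempt in seq_len(200 * n)) {
      cand <- c(stats::runif(1, margin, shape[2] - margin),
                stats::runif(1, margin, shape[1] - margin))
      if (placed == 0 ||
          min(sqrt(rowSums((pts[seq_len(placed), , drop = FALSE] -
                              matrix(cand, placed, 2, byrow = TRUE))^2))) >= min_spacing) {
        placed <- placed + 1
        pts[placed, ] <- cand
        if (placed == n) break
      }
    }
    if (placed < n)
      stop("image too small for ", n, " cells at spacing ", min_spacing)
    colnames(pts) <- c("x", "y")
    pts
  })
}

#' Render synthetic fluorescence field images
#'
#' Renders one 16-bit image per channel from a per-cell table: nuclei as
#' 2-D Gaussian spots whose integrated intensity equals the cell's DNA
#' content times the channel gain (so a 4N nucleus integrates to twice a 2N
#' nucleus); other channels as a nuclear spot plus a broader cytoplasmic
#' halo scaled by the cell's compartment intensities; plus a flat
#' background and optional Poisson shot noise.
#'
#' @param cells data.frame with columns `x`, `y` (pixel coordinates) and
#'   `dna_content`, plus `nuc_<marker>` / `ring_<marker>` columns for any
#'   non-DNA channels requested.
#' @param channels channel names; `"dna"` uses `dna_content`.
#' @param shape image dimensions c(rows, cols).
#' @param background flat background level (counts).
#' @param gain photons per intensity unit for the DNA channel.
#' @param sigma_nuc,sigma_cyto Gaussian radii (pixels) of nucleus and halo.
#' @param noise `"none"` or `"poisson"`.
#' @param seed seed (noise only).
#' @return named list of integer matrices (0..65535), with the centroid
#'   table attached as attribute `centroids`.
#' @export
render_field_images <- function(cells, channels = "dna", shape = c(256, 256),
                                background = 200, gain = 50,
                                sigma_nuc = 3, sigma_cyto = 7,
                                noise = c("none", "poisson"), seed = 1) {
  noise <- match.arg(noise)
  if (nrow(cells) > 0)
    stopifnot(all(cells$x >= 1 & cells$x <= shape[2]),
              all(cells$y >= 1 & cells$y <= shape[1]))
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  spot <- function(x0, y0, sigma, integral) {
    amp <- integral / (2 * pi * sigma^2)
    amp * exp(-((rr - y0)^2 + (cc - x0)^2) / (2 * sigma^2))
  }
  out <- list()
  for (ch in channels) {
    img <- matrix(background, shape[1], shape[2])
    for (i in seq_len(nrow(cells))) {
      if (ch == "dna") {
        img <- img + spot(cells$x[i], cells$y[i], sigma_nuc,
                          gain * cells$dna_content[i])
      } else {
        nuc_v <- cells[[paste0("nuc_", ch)]][i]
        ring_v <- cells[[paste0("ring_", ch)]][i]
        img <- img + spot(cells$x[i], cells$y[i], sigma_nuc,
                          gain * nuc_v * 2 * pi * sigma_nuc^2 / 10) +
          spot(cells$x[i], cells$y[i], sigma_cyto,
               gain * ring_v * 2 * pi * sigma_cyto^2 / 10)
      }
    }
    if (noise == "poisson")
      img <- withr::with_seed(stage_seed(seed, ch),
                              matrix(stats::rpois(length(img), img),
                                     nrow(img), ncol(img)))
    storage.mode(img) <- "double"
    out[[ch]] <- matrix(as.integer(pmin(65535, pmax(0, round(img)))),
                        shape[1], shape[2])
  }
  attr(out, "centroids") <- cells[, intersect(c("cell_id", "x", "y"),
                                              names(cells)), drop = FALSE]
  out
}

# Screen I/O ----------------------------------------------------------------

#' Write a synthetic screen to a directory
#'
#' Writes `layout.tsv`, `well_means.tsv`, `assay_wells.tsv`,
#' `sample_truth.tsv`, `class_effects.tsv` and `ground_truth.yaml` (seed
#' and generating configuration). Tables round-trip bit-exactly through
#' [read_screen()]. Field images, when supplied, are written as 16-bit
#' grayscale TIFFs under `images/` named `{plate}_{well}_{field}_{channel}.tif`.
#'
#' @param screen a `synthetic_screen`.
#' @param dir output directory (created).
#' @param images optional named list `plate_well_field` -> channel image
#'   list from [render_field_images()]; `NULL` writes no image directory.
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir, images = NULL) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    data.table::fwrite(df, file.path(dir, name), sep = "\t")
  tsv(screen$design$layout, "layout.tsv")
  tsv(screen$well_means, "well_means.tsv")
  tsv(screen$assay_wells, "assay_wells.tsv")
  tsv(screen$design$samples, "sample_truth.tsv")
  eff <- vapply(screen$design$signatures, function(s) s$effect,
                numeric(length(screen$design$signatures[[1]]$effect)))
  tsv(data.frame(feature_id = rownames(eff), eff, check.names = FALSE),
      "class_effects.tsv")
  cfg <- screen$design$config
  yaml::write_yaml(list(seed = screen$seed,
                        panel = if (is.character(cfg$panel)) cfg$panel else attr(cfg$panel, "panel_name"),
                        n_plants = cfg$n_plants,
                        n_fractions_per_plant = cfg$n_fractions_per_plant,
                        doses = cfg$doses, replicates = cfg$replicates,
                        panels = cfg$panels,
                        controls_per_plate = cfg$controls_per_plate,
                        p_active = cfg$p_active,
                        baseline_cells = cfg$baseline_cells,
                        well_cv = cfg$well_cv, effect_scale = cfg$effect_scale),
                   file.path(dir, "ground_truth.yaml"))
  if (!is.null(images)) {
    imdir <- file.path(dir, "images")
    dir.create(imdir, showWarnings = FALSE)
    for (fieldname in names(images)) {
      for (ch in names(images[[fieldname]])) {
        EBImage::writeImage(
          EBImage::Image(t(images[[fieldname]][[ch]]) / 65535),
          file.path(imdir, paste0(fieldname, "_", ch, ".tif")),
          type = "tiff", bits.per.sample = 16L)
      }
    }
  }
  invisible(dir)
}

#' Read a written screen back
#'
#' @param dir directory written by [write_screen()].
#' @return list with `layout`, `well_means`, `assay_wells`, `samples`,
#'   `class_effects`, `meta` (the ground-truth YAML).
#' @export
read_screen <- function(dir) {
  rd <- function(name)
    as.data.frame(data.table::fread(file.path(dir, name), sep = "\t"))
  list(layout = rd("layout.tsv"), well_means = rd("well_means.tsv"),
       assay_wells = rd("assay_wells.tsv"), samples = rd("sample_truth.tsv"),
       class_effects = rd("class_effects.tsv"),
       meta = yaml::read_yaml(file.path(dir, "ground_truth.yaml")))
}
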