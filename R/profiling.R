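# Profile construction ------------------------------------------------------
#
# Per-cell records are averaged to per-well feature values, wells are
# averaged over replicates, the in-plate untreated control mean is
# subtracted, and the treated-minus-control differences are normalized to
# scores in [-1, 1].

feature_cell_column <- function(feature, records) {
  # per-cell value vector backing one feature, or NULL for well-level ones
  m <- feature$marker; comp <- feature$compartment
  pick <- function(cands) {
    hit <- cands[cands %in% names(records)]
    if (length(hit)) records[[hit[1]]] else
      stop("cell records lack a column for feature ", feature$feature_id)
  }
  if (feature$feature_id == "cell_count" || feature$statistic == "fraction")
    return(NULL)
  if (grepl("^nuclear_area", feature$feature_id)) return(records$nuclear_area)
  if (feature$feature_id == "dna_intensity" ||
      grepl("^dna_content", feature$feature_id)) return(records$dna_content)
  if (comp == "ratio") {
    nu <- pick(paste0(c("nuc_", "nuc_mean_"), m))
    ri <- pick(paste0(c("ring_", "ring_mean_"), m))
    return(nu / pmax(ri, .Machine$double.eps))
  }
  pre <- if (comp == "nucleus") c("nuc_", "nuc_mean_") else c("ring_", "ring_mean_")
  pick(paste0(pre, m))
}

#' Aggregate one well's cells to per-feature values
#'
#' Computes each panel feature's well value from the valid cells: the
#' feature's statistic (mean, sd, median, mad, q90) over the mapped
#' per-cell measurement; the valid-cell count for the count feature; and
#' DNA-content phase fractions via the cell-cycle classifier for the
#' phase-fraction features (calibrated with `dna_scale`, or self-calibrated
#' from the well when omitted).
#'
#' @param cell_records data.frame of one well's cells (columns as produced
#'   by [simulate_cell_population()] or [extract_cell_features()]); rows
#'   with `valid == FALSE` are dropped first.
#' @param panel feature panel or name.
#' @param staining_panel restrict to features of one staining panel
#'   (`"P1"`..`"P4"`); default all features whose columns are present.
#' @param dna_scale intensity units per 1N for phase classification
#'   (default: calibrated from these cells).
#' @return named numeric vector of well feature values.
#' @export
aggregate_well <- function(cell_records, panel = "core",
                           staining_panel = NULL, dna_scale = NULL) {
  panel <- get_panel(panel)
  if ("valid" %in% names(cell_records))
    cell_records <- cell_records[cell_records$valid, , drop = FALSE]
  if (nrow(cell_records) == 0)
    stop("no valid cells in well; should have been QC-excluded")
  if (!is.null(staining_panel))
    panel <- panel[panel$panel %in% staining_panel, , drop = FALSE]
  need_phase <- any(panel$statistic == "fraction")
  phase_frac <- NULL
  if (need_phase) {
    if (is.null(dna_scale))
      dna_scale <- calibrate_dna_scale(cell_records$dna_content)
    phase_frac <- phase_distribution(
      classify_cell_cycle(cell_records$dna_content / dna_scale))
  }
  out <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    f <- panel[i, ]
    out[i] <- if (f$feature_id == "cell_count") nrow(cell_records)
    else if (f$statistic == "fraction")
      phase_frac[sub("phase_frac_", "", f$feature_id)]
    else {
      v <- feature_cell_column(f, cell_records)
      switch(f$statistic,
             mean = mean(v), sd = stats::sd(v), median = stats::median(v),
             mad = stats::mad(v), q90 = unname(stats::quantile(v, 0.9)))
    }
  }
  stats::setNames(out, panel$feature_id)
}

#' Score treated-versus-control feature differences into \[-1, 1\]
#'
#' Replicate wells of each (sample, dose) are averaged, the mean of the
#' in-plate untreated control wells (same plate and staining panel) is
#' subtracted, and the difference is normalized per feature:
#'
#' * `"screen_max"` (default): divide by the largest |difference| any
#'   sample on the screen attains for that feature, so the extreme sample
#'   scores exactly +/-1 and every score lies in \[-1, 1\] by construction.
#' * `"robust_z_tanh"`: a bounded robust alternative,
#'   `tanh(z / 3)` with `z` the difference over 1.4826 x MAD of the
#'   control wells.
#'
#' A feature whose differences are all zero scores 0 everywhere.
#'
#' @param well_means long-form per-well feature values as from
#'   [simulate_well_means()] (columns plate_id, well, panel, sample_id,
#'   dose_ugml, replicate, is_control, feature_id, value).
#' @param method normalization method.
#' @param per_plate normalize within each plate instead of across the
#'   screen.
#' @param exclude_wells optional data.frame (plate_id, well) of
#'   QC-excluded wells.
#' @return a `cytological_profiles` data.frame: sample_id, dose_ugml,
#'   feature_id, score, n_wells; attribute `method`.
#' @export
compute_feature_scores <- function(well_means,
                                   method = c("screen_max", "robust_z_tanh"),
                                   per_plate = FALSE, exclude_wells = NULL) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(well_means)
  if (!is.null(exclude_wells) && nrow(exclude_wells)) {
    key <- paste(dt$plate_id, dt$well)
    dt <- dt[!key %in% paste(exclude_wells$plate_id, exclude_wells$well)]
  }
  value <- is_control <- feature_id <- plate_id <- dose_ugml <- NULL # NSE notes
  ctrl <- dt[dt$is_control == TRUE,
             list(ctrl_mean = mean(value),
                  ctrl_mad = stats::mad(value)),
             by = c("plate_id", "panel", "feature_id")]
  if (nrow(ctrl) == 0) stop("no control wells found")
  trt <- dt[dt$is_control == FALSE,
            list(trt_mean = mean(value), n_wells = .N),
            by = c("sample_id", "dose_ugml", "plate_id", "panel", "feature_id")]
  m <- merge(trt, ctrl, by = c("plate_id", "panel", "feature_id"))
  if (nrow(m) < nrow(trt))
    stop("some plates/panels have no control wells")
  m$delta <- m$trt_mean - m$ctrl_mean
  if (method == "screen_max") {
    grp <- if (per_plate) c("feature_id", "plate_id") else "feature_id"
    delta <- NULL
    m[, `:=`(scale_max = max(abs(delta))), by = grp]
    m$score <- ifelse(m$scale_max == 0, 0, m$delta / m$scale_max)
  } else {
    spread <- pmax(m$ctrl_mad, .Machine$double.eps)
    m$score <- tanh((m$delta / spread) / 3)
  }
  m$score <- clip01(m$score)
  out <- as.data.frame(m[, c("sample_id", "dose_ugml", "feature_id",
                             "score", "n_wells")])
  out <- out[order(out$sample_id, out$dose_ugml, out$feature_id), ]
  rownames(out) <- NULL
  structure(out, class = c("cytological_profiles", "data.frame"),
            method = method, per_plate = per_plate)
}

#' Assemble profiles into a samples x features matrix
#'
#' Rows are samples (one row per sample and dose; labelled
#' `sample_id@dose` when more than one dose is present), columns follow the
#' panel's feature order. QC-excluded entries stay `NA`, never 0.
#'
#' @param profiles a `cytological_profiles` data.frame (or any long
#'   data.frame with sample_id, dose_ugml, feature_id, score).
#' @param panel feature panel or name; profiles must not contain features
#'   outside the panel.
#' @return numeric matrix with attribute `panel_name`.
#' @export
build_profile_matrix <- function(profiles, panel = "core") {
  panel <- get_panel(panel)
  bad <- setdiff(unique(profiles$feature_id), panel$feature_id)
  if (length(bad))
    stop("profiles contain features outside the panel (mixed panels?): ",
         paste(utils::head(bad, 3), collapse = ", "))
  multi_dose <- length(unique(profiles$dose_ugml)) > 1
  rowid <- if (multi_dose)
    paste0(profiles$sample_id, "@", profiles$dose_ugml) else profiles$sample_id
  rows <- unique(rowid)
  mat <- matrix(NA_real_, length(rows), nrow(panel),
                dimnames = list(rows, panel$feature_id))
  mat[cbind(match(rowid, rows), match(profiles$feature_id, panel$feature_id))] <-
    profiles$score
  attr(mat, "panel_name") <- attr(panel, "panel_name")
  mat
}

#' Drop samples with too many missing features
#'
#' Clustering needs near-complete vectors: samples missing more than
#' `max_missing` of their panel features (QC exclusions) are dropped.
#'
#' @param mat profile matrix.
#' @param max_missing maximum tolerated missing fraction (default 0.25).
#' @return the filtered matrix.
#' @export
drop_incomplete_profiles <- function(mat, max_missing = 0.25) {
  keep <- rowMeans(is.na(mat)) <= max_missing
  mat[keep, , drop = FALSE]
}

#' Write / read a profile matrix as TSV
#'
#' First column `sample_id`, then one column per feature; a JSON sidecar
#' (`<file>.json`) records the panel, normalization method and seed.
#'
#' @param mat profile matrix.
#' @param file output TSV path.
#' @param method,seed recorded in the sidecar.
#' @return `file`, invisibly.
#' @export
write_profile_matrix <- function(mat, file, method = "screen_max", seed = NA) {
  # 17 significant digits: doubles survive the text round trip exactly
  txt <- apply(mat, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1, dimnames = dimnames(mat))
  df <- data.frame(sample_id = rownames(mat), txt, check.names = FALSE)
  data.table::fwrite(df, file, sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(panel = attr(mat, "panel_name") %||% "custom",
         n_features = ncol(mat), method = method, seed = seed),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(file) {
  df <- as.data.frame(data.table::fread(file, sep = "\t"))
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  side <- paste0(file, ".json")
  if (file.exists(side))
    attr(mat, "panel_name") <- jsonlite::read_json(side)$panel
  mat
}
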