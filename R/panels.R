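# Feature panels -----------------------------------------------------------
#
# A feature panel is an ordered data.frame describing which per-cell
# measurements are aggregated into a cytological profile. Each row maps one
# feature to a cellular marker, a compartment (nucleus or cytoplasmic ring),
# the cross-cell statistic used to summarize a well, the phenotypic
# attribute the feature reports on, and the staining panel (P1-P4) in which
# the marker is imaged.

#' Cellular markers and their staining panels
#'
#' The 12 markers behind the core feature set, with the staining panel each
#' is imaged in: P1 carries ER, lysosome and plasma-membrane stains; P2 the
#' DNA stain plus p53, caspase-9 and gamma-H2AX antibodies; P3 the DNA stain
#' plus mitochondria, cytochrome c and NF-kB; P4 the DNA stain plus actin
#' and tubulin. DNA-derived morphology features are reported once, from P2.
#'
#' @return data.frame with columns `marker`, `panel`, `description`.
#' @export
marker_table <- function() {
  data.frame(
    marker = c("dna", "er", "lysosome", "membrane", "p53", "casp9",
               "h2ax", "mito", "cytc", "nfkb", "actin", "tubulin"),
    panel = c("P2", "P1", "P1", "P1", "P2", "P2",
              "P2", "P3", "P3", "P3", "P4", "P4"),
    description = c(
      "DNA stain (nuclear morphology, DNA content, cell count)",
      "endoplasmic reticulum stain",
      "lysosomal stain",
      "plasma-membrane / permeability stain",
      "p53 antibody",
      "cleaved caspase-9 antibody",
      "phospho-H2AX antibody (DNA double-strand breaks)",
      "mitochondrial stain",
      "cytochrome c antibody",
      "NF-kB antibody",
      "actin stain (phalloidin)",
      "beta-tubulin antibody"),
    stringsAsFactors = FALSE
  )
}

new_feature_panel <- function(df, name) {
  stopifnot(!anyDuplicated(df$feature_id))
  df$feature_id <- as.character(df$feature_id)
  structure(df, class = c("feature_panel", "data.frame"), panel_name = name)
}

#' Core cytological feature panel
#'
#' The 21-feature core panel drawn from 12 cellular markers: cell count,
#' nuclear area and integrated DNA intensity from the DNA stain; nuclear and
#' cytoplasmic-ring mean intensities for ER, lysosome, membrane,
#' mitochondria, NF-kB, actin and tubulin; nuclear mean intensity for p53,
#' caspase-9, gamma-H2AX and cytochrome c.
#'
#' @return a `feature_panel` data.frame with columns `feature_id`, `marker`,
#'   `compartment`, `statistic`, `attribute`, `panel`.
#' @export
core_panel <- function() {
  mk <- marker_table()
  both <- c("er", "lysosome", "membrane", "mito", "nfkb", "actin", "tubulin")
  nuc_only <- c("p53", "casp9", "h2ax", "cytc")
  attr_of <- c(dna = "proliferation/nuclear morphology",
               er = "secretory stress", lysosome = "lysosomal mass",
               membrane = "membrane permeability", p53 = "tumor suppressor response",
               casp9 = "intrinsic apoptosis", h2ax = "DNA damage",
               mito = "mitochondrial mass/potential", cytc = "cytochrome c release",
               nfkb = "inflammatory signaling", actin = "cytoskeleton (actin)",
               tubulin = "cytoskeleton (microtubules)")
  rows <- rbind(
    data.frame(feature_id = c("cell_count", "nuclear_area", "dna_intensity"),
               marker = "dna",
               compartment = c("well", "nucleus", "nucleus"),
               statistic = c("count", "mean", "mean"),
               stringsAsFactors = FALSE),
    data.frame(feature_id = paste0(rep(both, each = 2), c("_nuc_mean", "_ring_mean")),
               marker = rep(both, each = 2),
               compartment = rep(c("nucleus", "ring"), length(both)),
               statistic = "mean", stringsAsFactors = FALSE),
    data.frame(feature_id = paste0(nuc_only, "_nuc_mean"),
               marker = nuc_only, compartment = "nucleus",
               statistic = "mean", stringsAsFactors = FALSE)
  )
  rows$attribute <- unname(attr_of[rows$marker])
  rows$panel <- mk$panel[match(rows$marker, mk$marker)]
  new_feature_panel(rows, "core")
}

#' High-resolution cytological feature panel
#'
#' The 135-feature high-resolution panel: 14 DNA-derived morphology and
#' cell-cycle features (count; nuclear-area and DNA-content mean, sd,
#' median, mad; five cell-cycle phase fractions), five distribution
#' statistics (mean, sd, median, mad, q90) per compartment for each of the
#' 11 protein/organelle markers, and a nucleus:ring intensity-ratio feature
#' per marker.
#'
#' @return a `feature_panel` data.frame (see [core_panel()]).
#' @export
full_panel <- function() {
  mk <- marker_table()
  prot <- setdiff(mk$marker, "dna")
  stats_ <- c("mean", "sd", "median", "mad", "q90")
  morph <- data.frame(
    feature_id = c("cell_count",
                   paste0("nuclear_area_", stats_[1:4]),
                   paste0("dna_content_", stats_[1:4]),
                   paste0("phase_frac_", c("low", "g0g1", "s", "g2m", "high"))),
    marker = "dna",
    compartment = c("well", rep("nucleus", 8), rep("well", 5)),
    statistic = c("count", stats_[1:4], stats_[1:4], rep("fraction", 5)),
    stringsAsFactors = FALSE)
  grid <- expand.grid(statistic = stats_, compartment = c("nucleus", "ring"),
                      marker = prot, stringsAsFactors = FALSE)
  comp_tag <- ifelse(grid$compartment == "nucleus", "nuc", "ring")
  marker_feats <- data.frame(
    feature_id = paste0(grid$marker, "_", comp_tag, "_", grid$statistic),
    marker = grid$marker, compartment = grid$compartment,
    statistic = grid$statistic, stringsAsFactors = FALSE)
  ratio <- data.frame(
    feature_id = paste0(prot, "_nuc_ring_ratio"),
    marker = prot, compartment = "ratio", statistic = "mean",
    stringsAsFactors = FALSE)
  rows <- rbind(morph, marker_feats, ratio)
  rows$attribute <- "high-resolution"
  rows$panel <- mk$panel[match(rows$marker, mk$marker)]
  new_feature_panel(rows, "full")
}

#' Resolve a feature panel by name
#'
#' @param panel a `feature_panel`, or `"core"` / `"full"`.
#' @return a `feature_panel`.
#' @export
get_panel <- function(panel) {
  if (inherits(panel, "feature_panel")) return(panel)
  switch(match.arg(panel, c("core", "full")),
         core = core_panel(), full = full_panel())
}

#' Baseline (untreated control) feature expectations
#'
#' Per-feature expected values for an untreated well, used by the simulator
#' as the control anchor of every feature. Marker intensities are arbitrary
#' fluorescence units; DNA content is in intensity units anchored at 1000
#' units per 2N; areas in pixels.
#'
#' @param panel a `feature_panel` or panel name.
#' @return named numeric vector over the panel's features, in panel order.
#' @export
control_feature_means <- function(panel = "core") {
  panel <- get_panel(panel)
  base_nuc <- c(er = 420, lysosome = 520, membrane = 380, p53 = 300,
                casp9 = 260, h2ax = 240, mito = 600, cytc = 340,
                nfkb = 310, actin = 700, tubulin = 760)
  base_ring <- round(base_nuc * 1.6)  # organelle/cytoskeletal signal is mostly cytoplasmic
  ctrl_phase <- control_cycle_shift()
  val <- numeric(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    f <- panel[i, ]
    val[i] <- if (f$feature_id == "cell_count") 2000
    else if (grepl("^nuclear_area", f$feature_id)) {
      switch(f$statistic, mean = 180, median = 176, sd = 45, mad = 40)
    } else if (f$feature_id == "dna_intensity" || grepl("^dna_content", f$feature_id)) {
      # mixture mean of the control cycle at 500 units/N
      switch(f$statistic, mean = 1290, median = 1050, sd = 420, mad = 180)
    } else if (grepl("^phase_frac_", f$feature_id)) {
      ctrl_phase[sub("phase_frac_", "", f$feature_id)]
    } else if (f$compartment == "ratio") {
      unname(base_nuc[f$marker] / base_ring[f$marker])
    } else {
      b <- unname(if (f$compartment == "nucleus") base_nuc[f$marker] else base_ring[f$marker])
      switch(f$statistic, mean = b, median = b * 0.98, sd = b * 0.3,
             mad = b * 0.28, q90 = b * 1.45)
    }
  }
  stats::setNames(val, panel$feature_id)
}
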