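# Phenotype signatures ------------------------------------------------------
#
# A phenotype signature is the simulator's ground-truth description of one
# mode of action (MoA): a per-feature direction of effect in score space, a
# cytotoxicity Hill curve, a target cell-cycle distribution and per-assay
# fold-change inductions at saturation.

#' Baseline cell-cycle distribution of an untreated population
#'
#' Phase fractions over {low, G0/G1, S, G2/M, high} for an unperturbed,
#' exponentially growing adherent culture: a dominant G0/G1 peak, a smaller
#' S compartment, a G2/M shoulder, and small sub-2N (damaged/apoptotic) and
#' super-4N (clumped/polyploid) tails.
#'
#' @return named numeric vector summing to 1.
#' @export
control_cycle_shift <- function() {
  c(low = 0.03, g0g1 = 0.60, s = 0.22, g2m = 0.13, high = 0.02)
}

#' Built-in mode-of-action class parameters
#'
#' Phenotype parameters for the simulator's ten MoA classes: cytotoxicity
#' EC50 (ug/ml) and Hill slope, the target cell-cycle distribution the
#' class drives the population toward at saturating effect, and per-assay
#' fold-change inductions at saturation for the five follow-up assays
#' (MitoSOX, membrane permeability, caspase-9, p53, gamma-H2AX). `inert`
#' has no effect anywhere and is the class of all control wells.
#'
#' @return data.frame, one row per class.
#' @export
moa_class_table <- function() {
  cs <- function(low, g0g1, s, g2m, high) {
    v <- c(low = low, g0g1 = g0g1, s = s, g2m = g2m, high = high)
    v / sum(v)
  }
  cls <- list(
    inert = list(Inf, 1, control_cycle_shift(), c(1, 1, 1, 1, 1)),
    topoisomerase_inhibitor = list(8, 2, cs(.08, .22, .15, .50, .05), c(1.3, 1.2, 2.0, 2.2, 3.0)),
    tubulin_binder = list(10, 2, cs(.06, .18, .14, .57, .05), c(1.2, 1.2, 1.8, 1.6, 1.3)),
    dna_synthesis_inhibitor = list(9, 2, cs(.06, .22, .55, .14, .03), c(1.2, 1.1, 1.6, 1.8, 2.5)),
    mitochondrial_uncoupler = list(14, 1.5, cs(.08, .62, .18, .10, .02), c(3.5, 1.5, 2.5, 1.4, 1.2)),
    membrane_permeabilizer = list(12, 2, cs(.20, .52, .17, .09, .02), c(1.5, 3.5, 1.5, 1.2, 1.1)),
    er_stressor = list(16, 1.5, cs(.10, .64, .16, .08, .02), c(1.6, 1.3, 2.0, 1.5, 1.2)),
    lysosomotropic_agent = list(18, 1.5, cs(.08, .63, .18, .09, .02), c(1.4, 1.6, 1.4, 1.2, 1.1)),
    actin_disruptor = list(15, 2, cs(.07, .58, .18, .12, .05), c(1.2, 1.4, 1.3, 1.2, 1.1)),
    apoptosis_inducer = list(7, 2.5, cs(.35, .38, .13, .11, .03), c(1.8, 1.9, 3.0, 2.5, 1.8))
  )
  assays <- c("mitosox", "permeability", "caspase9", "p53", "h2ax")
  out <- data.frame(moa_label = names(cls), kill_ec50 = vapply(cls, `[[`, 0, 1),
                    kill_hill = vapply(cls, `[[`, 0, 2), stringsAsFactors = FALSE)
  out$effect_ec50 <- ifelse(is.finite(out$kill_ec50), 0.6 * out$kill_ec50, Inf)
  cycle <- t(vapply(cls, `[[`, numeric(5), 3))
  colnames(cycle) <- paste0("cycle_", names(control_cycle_shift()))
  ind <- t(vapply(cls, `[[`, numeric(5), 4))
  colnames(ind) <- paste0("induction_", assays)
  rownames(out) <- NULL
  cbind(out, cycle, ind)
}

#' Construct a phenotype signature
#'
#' @param moa_label class label.
#' @param effect named per-feature effect direction in \[-1, 1\] (score
#'   space), same names/order as the feature panel.
#' @param kill_ec50,kill_hill cytotoxicity Hill parameters (`Inf` EC50 =
#'   non-toxic).
#' @param effect_ec50 EC50 of the feature-shift Hill curve.
#' @param cycle_shift target phase distribution (named, sums to 1).
#' @param induction named saturating fold changes for the five assays
#'   (values >= 1, or < 1 if explicitly suppressive).
#' @return object of class `phenotype_signature`.
#' @export
phenotype_signature <- function(moa_label, effect, kill_ec50, kill_hill,
                                effect_ec50 = if (is.finite(kill_ec50)) 0.6 * kill_ec50 else Inf,
                                cycle_shift = control_cycle_shift(),
                                induction = c(mitosox = 1, permeability = 1,
                                              caspase9 = 1, p53 = 1, h2ax = 1)) {
  stopifnot(nzchar(moa_label), kill_ec50 > 0, kill_hill > 0, effect_ec50 > 0,
            all(cycle_shift >= 0), abs(sum(cycle_shift) - 1) < 1e-9,
            all(effect >= -1 & effect <= 1), !is.null(names(effect)))
  structure(list(moa_label = moa_label, effect = effect,
                 kill_ec50 = kill_ec50, kill_hill = kill_hill,
                 effect_ec50 = effect_ec50, cycle_shift = cycle_shift,
                 induction = induction),
            class = "phenotype_signature")
}

#' @export
print.phenotype_signature <- function(x, ...) {
  cat("<phenotype_signature>", x$moa_label,
      sprintf("| kill EC50 %s ug/ml, hill %.3g | %d features\n",
              format(x$kill_ec50), x$kill_hill, length(x$effect)))
  invisible(x)
}

# draw one score-space effect direction; entries uniform in [-1,1],
# rescaled so the largest magnitude is 1
draw_effect_vector <- function(n_features) {
  v <- stats::runif(n_features, -1, 1)
  v / max(abs(v))
}

#' Generate the signature set for a set of MoA classes
#'
#' Draws one score-space effect direction per class, redrawing until all
#' pairwise Pearson correlations between class effects are below
#' `max_cor` so classes are mutually separable, then attaches the
#' class's cytotoxicity, cell-cycle and induction parameters. The `inert`
#' class always gets an all-zero effect. For cytotoxic classes the
#' `cell_count` and `nuclear_area*` entries (when present in the panel) are
#' forced negative, matching the cell loss the kill curve imposes.
#'
#' @param panel a `feature_panel` or name.
#' @param classes data.frame as [moa_class_table()] (default) or a subset.
#' @param seed integer seed.
#' @param max_cor maximum allowed pairwise |r| between class effects.
#' @return named list of `phenotype_signature`s.
#' @export
moa_signature_set <- function(panel = "core", classes = moa_class_table(),
                              seed = 1, max_cor = 0.5) {
  panel <- get_panel(panel)
  fid <- panel$feature_id
  nf <- length(fid)
  active <- classes[classes$moa_label != "inert", , drop = FALSE]
  eff <- withr::with_seed(seed, {
    for (try in 1:200) {
      m <- replicate(nrow(active), draw_effect_vector(nf))
      if (nrow(active) < 2 || max(abs(stats::cor(m)[upper.tri(diag(nrow(active)))])) < max_cor)
        break
    }
    m
  })
  rownames(eff) <- fid
  sigs <- list()
  for (i in seq_len(nrow(classes))) {
    cl <- classes[i, ]
    e <- if (cl$moa_label == "inert") stats::setNames(numeric(nf), fid)
    else {
      v <- eff[, match(cl$moa_label, active$moa_label)]
      toxic <- is.finite(cl$kill_ec50)
      if (toxic) {
        down <- grepl("^cell_count$|^nuclear_area", fid)
        v[down] <- -abs(v[down])
      }
      stats::setNames(v, fid)
    }
    cyc <- as.numeric(cl[paste0("cycle_", names(control_cycle_shift()))])
    names(cyc) <- names(control_cycle_shift())
    ind <- as.numeric(cl[paste0("induction_", c("mitosox", "permeability", "caspase9", "p53", "h2ax"))])
    names(ind) <- c("mitosox", "permeability", "caspase9", "p53", "h2ax")
    sigs[[cl$moa_label]] <- phenotype_signature(
      cl$moa_label, e, cl$kill_ec50, cl$kill_hill, cl$effect_ec50, cyc, ind)
  }
  sigs
}
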