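# Quantitative endpoints ----------------------------------------------------
#
# Percent-of-control cytotoxicity, DNA-content cell-cycle classification,
# in-plate-normalized fold-change assays, and their Student's t tests.

#' Percent of control
#'
#' `treated / control * 100`: the optical-density (or cell-count) signal of
#' treated wells expressed as a percentage of the untreated in-plate
#' control. Note this is survival-direction; the loss-direction companion
#' is [cell_loss_percent()].
#'
#' @param od_treated treated readout(s), >= 0.
#' @param od_control control readout, > 0.
#' @return percentage(s).
#' @export
percent_of_control <- function(od_treated, od_control) {
  if (any(od_control <= 0)) stop("od_control must be > 0")
  if (any(od_treated < 0)) stop("od_treated must be >= 0")
  od_treated / od_control * 100
}

#' @rdname percent_of_control
#' @export
cell_loss_percent <- function(od_treated, od_control)
  100 - percent_of_control(od_treated, od_control)

#' Calibrate the DNA-content intensity scale
#'
#' Anchors the 2N (G0/G1) peak at the kernel-smoothed mode of the control
#' DNA-content histogram; when the density is multimodal the lower major
#' mode is taken (G0/G1 dominates untreated populations). The returned
#' scale is intensity units per 1N, i.e. `anchor / 2`.
#'
#' @param control_dna_contents raw integrated nuclear intensities of
#'   untreated cells (>= 200 cells required).
#' @param min_cells minimum population size.
#' @return scale in intensity units per 1N.
#' @export
calibrate_dna_scale <- function(control_dna_contents, min_cells = 200) {
  x <- control_dna_contents[is.finite(control_dna_contents)]
  if (length(x) < min_cells)
    stop("need at least ", min_cells, " control cells to calibrate")
  dens <- stats::density(x, n = 2048)
  y <- dens$y
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks_x <- dens$x[is_peak]
  peaks_y <- y[is_peak]
  major <- peaks_y >= 0.5 * max(peaks_y)
  anchor <- min(peaks_x[major])  # lower major mode
  anchor / 2
}

#' Classify DNA content into a cell-cycle phase
#'
#' With bin half-width `tau` (default 0.5 N): content below `2 - tau` is
#' `low` (damaged/apoptotic), within `2 +/- tau` is `g0g1`, strictly
#' between `2 + tau` and `4 - tau` is `s`, within `4 +/- tau` is `g2m`,
#' above `4 + tau` is `high` (clumped/higher ploidy). The five intervals
#' partition `[0, Inf)` for every `tau` in (0, 1).
#'
#' @param dna_n DNA content in N units (calibrated).
#' @param tau bin half-width in N units.
#' @return factor with levels low, g0g1, s, g2m, high.
#' @export
classify_cell_cycle <- function(dna_n, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  if (any(dna_n < 0)) stop("DNA content must be non-negative")
  phase <- cut(dna_n, breaks = c(-Inf, 2 - tau, 2 + tau, 4 - tau, 4 + tau, Inf),
               labels = c("low", "g0g1", "s", "g2m", "high"),
               right = TRUE)
  # cut() with right=TRUE puts 2-tau in "low"; the 2N window is inclusive
  phase[dna_n >= 2 - tau & dna_n <= 2 + tau] <- "g0g1"
  phase[dna_n >= 4 - tau & dna_n <= 4 + tau] <- "g2m"
  phase
}

#' Empirical cell-cycle phase distribution
#'
#' @param phases factor/character vector of phases (as from
#'   [classify_cell_cycle()]).
#' @return named numeric vector of fractions over the five phases, summing
#'   to 1.
#' @export
phase_distribution <- function(phases) {
  if (length(phases) == 0) stop("no cells")
  lv <- c("low", "g0g1", "s", "g2m", "high")
  tab <- table(factor(phases, levels = lv))
  as.numeric(tab / sum(tab)) -> fr
  stats::setNames(fr, lv)
}

#' In-plate-normalized fold change
#'
#' `mean(treated) / mean(control)`: the uniform normalization applied to
#' the MitoSOX, membrane-permeability, caspase-9, p53 and gamma-H2AX
#' readouts.
#'
#' @param treated_intensities,control_intensities per-well readouts.
#' @return fold change (>= 0).
#' @export
fold_change_assay <- function(treated_intensities, control_intensities) {
  cm <- mean(control_intensities)
  if (!is.finite(cm) || cm <= 0) stop("control mean must be > 0")
  mean(treated_intensities) / cm
}

#' Two-tailed Student's t test (pooled variance)
#'
#' Classical equal-variance two-sample t with `n_a + n_b - 2` degrees of
#' freedom and a two-tailed p value. Degenerate inputs follow the
#' convention: zero pooled variance with equal means gives `t = 0, p = 1`;
#' zero pooled variance with unequal means is an error. Welch's form is
#' available behind `var_equal = FALSE`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param alpha significance level for the `significant` flag.
#' @param var_equal pooled (Student's, default) vs Welch.
#' @return list: `t`, `df`, `p`, `significant`.
#' @export
two_tailed_t <- function(group_a, group_b, alpha = 0.05, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1,
                  significant = FALSE))
    stop("zero pooled variance with unequal means: t undefined")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value <= alpha)
}

#' Significance stars
#'
#' Four-tier star annotation: `*` p <= 0.05, `**` p <= 0.01, `***`
#' p <= 0.001, `****` p <= 0.0001; empty otherwise.
#'
#' @param p p value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", ""), right = TRUE) |>
    as.character()
}

#' Dose-response endpoint table
#'
#' Summarizes per-well endpoint values into one row per (sample, dose,
#' timepoint): mean, sample SD and n over replicate wells, Student's t and
#' two-tailed p against the same sample's dose-0 wells, and significance
#' stars. Dose-0 rows carry `NA` statistics (they are the comparator).
#'
#' @param values data.frame with columns `sample_id`, `dose_ugml`,
#'   `replicate`, `value`, and optionally `timepoint_h`.
#' @param endpoint endpoint name recorded in the output.
#' @param alpha significance level.
#' @return data.frame: sample_id, dose_ugml, timepoint_h, endpoint, mean,
#'   sd, n, t, p, stars, significant.
#' @export
dose_response_table <- function(values, endpoint = "endpoint", alpha = 0.05) {
  stopifnot(all(c("sample_id", "dose_ugml", "value") %in% names(values)))
  if (!"timepoint_h" %in% names(values)) values$timepoint_h <- 24
  out <- list()
  for (key in split(values, values[, c("sample_id", "timepoint_h")], drop = TRUE)) {
    sid <- key$sample_id[1]; tp <- key$timepoint_h[1]
    base <- key$value[key$dose_ugml == 0]
    if (length(base) < 2)
      stop("sample ", sid, " (", tp, " h) lacks a dose-0 replicate group")
    for (d in sort(unique(key$dose_ugml))) {
      v <- key$value[key$dose_ugml == d]
      if (d == 0) {
        tt <- list(t = NA_real_, p = NA_real_)
      } else {
        tt <- two_tailed_t(v, base, alpha = alpha)
      }
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, dose_ugml = d, timepoint_h = tp,
        endpoint = endpoint, mean = mean(v), sd = stats::sd(v),
        n = length(v), t = tt$t, p = tt$p,
        stars = if (is.na(tt$p)) "" else significance_stars(tt$p),
        significant = !is.na(tt$p) & tt$p <= alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$timepoint_h, res$dose_ugml), ] -> res
  rownames(res) <- NULL
  res
}
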