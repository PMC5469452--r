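#' Hill response curve
#'
#' Fractional response `(dose/ec50)^slope / (1 + (dose/ec50)^slope)`, the
#' parametric family used throughout the simulator for dose-dependent effects.
#' `hill_survival()` is its complement, the surviving fraction of a
#' cytotoxicity curve. `ec50 = Inf` encodes an inert treatment (response 0,
#' survival 1 at every dose).
#'
#' @param dose non-negative dose (same units as `ec50`, here ug/ml).
#' @param ec50 dose of half-maximal response; must be > 0 (may be `Inf`).
#' @param slope Hill slope; must be > 0.
#' @return numeric vector in \[0, 1\].
#' @export
hill_response <- function(dose, ec50, slope) {
  stopifnot(all(dose >= 0), all(ec50 > 0), all(slope > 0))
  x <- (dose / ec50)^slope
  x[dose == 0] <- 0            # covers ec50 = Inf at dose 0 (0/Inf -> NaN^s)
  x / (1 + x)
}

#' @rdname hill_response
#' @export
hill_survival <- function(dose, ec50, slope) 1 - hill_response(dose, ec50, slope)

#' Derive a stage seed from a master seed
#'
#' Stages of a run draw their own seeds from the master seed and the stage
#' name so each stage is independently reproducible. The rule is a simple
#' polynomial hash of the stage name folded into the seed, reduced modulo
#' 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- seed %% m
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% m
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert & Arabie form). Used to compare a tree cut with planted class
#' labels.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar, 1 for identical partitions, ~0 at chance.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

clip01 <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

# data.table [] semantics inside this package
.datatable.aware <- TRUE

`%||%` <- function(x, y) if (is.null(x)) y else x

# all 384 well addresses, column-major (A1, B1, ..., P1, A2, ...)
well_addresses <- function() {
  rows <- LETTERS[1:16]
  as.vector(vapply(1:24, function(cl) paste0(rows, cl), character(16)))
}

is_valid_well <- function(w) {
  grepl("^[A-P]([1-9]|1[0-9]|2[0-4])$", w)
}
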