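# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# Pearson correlation by the textbook sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# Pooled-variance two-sample t and two-tailed p, from first principles
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Monte-Carlo two-sample permutation p (two-sided, mean difference)
oracle_perm_p <- function(a, b, B = 20000, seed = 1) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  withr::with_seed(seed, {
    hits <- 0
    for (i in seq_len(B)) {
      idx <- sample(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
        hits <- hits + 1
    }
    (hits + 1) / (B + 1)
  })
}

# Naive O(n^3) UPGMA: returns the cophenetic (merge-height) matrix.
# Average linkage over the ORIGINAL dissimilarities between member sets.
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  avg <- function(ci, cj) mean(d[ci, cj, drop = FALSE])
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      a <- avg(clusters[[i]], clusters[[j]])
      if (a < best[1]) best <- c(a, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Cell-cycle binning by explicit case analysis
oracle_phase <- function(dna_n, tau = 0.5) {
  vapply(dna_n, function(x) {
    if (x < 2 - tau) "low"
    else if (x <= 2 + tau) "g0g1"
    else if (x < 4 - tau) "s"
    else if (x <= 4 + tau) "g2m"
    else "high"
  }, character(1))
}

# small helper: profiles drawn around given class effect vectors
planted_profiles <- function(class_effects, labels, noise_sd, seed,
                             prefix = "S") {
  withr::with_seed(seed, {
    m <- t(class_effects[, labels, drop = FALSE]) +
      matrix(rnorm(length(labels) * nrow(class_effects), 0, noise_sd),
             length(labels), nrow(class_effects))
  })
  m <- pmin(pmax(m, -1), 1)
  rownames(m) <- sprintf("%s%03d", prefix, seq_along(labels))
  colnames(m) <- rownames(class_effects)
  m
}
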