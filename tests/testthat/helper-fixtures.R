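# In-code fixture builders and independent oracles shared across tests.

# Tiny quant table: values is a list mapping psite -> named vector of
# sample values (names like "low_5_r1"); unspecified samples are NA.
make_quant <- function(values, times = 5, replicates = 5,
                       loc_prob = 1, genes = NULL, peptides = NULL) {
  samples <- expand.grid(replicate = seq_len(replicates), time = times,
                         condition = c("low", "high"),
                         stringsAsFactors = FALSE)
  samples <- tibble::tibble(
    label = paste0(samples$condition, "_", samples$time, "_r",
                   samples$replicate),
    condition = samples$condition, time = samples$time,
    replicate = samples$replicate)
  psites <- names(values)
  vals <- matrix(NA_real_, length(psites), nrow(samples),
                 dimnames = list(psites, samples$label))
  for (p in psites) vals[p, names(values[[p]])] <- values[[p]]
  acc <- sub("_[STY].*$", "", psites)
  meta <- tibble::tibble(
    psite = psites, protein = acc,
    gene = if (is.null(genes)) paste0("G", seq_along(psites)) else genes,
    loc_prob = rep_len(loc_prob, length(psites)),
    peptide = if (is.null(peptides)) rep(NA_character_, length(psites))
              else peptides)
  psite_quant(meta, vals, samples)
}

# Quant table where every replicate pair at `times` has difference
# diffs[[psite]] + 0 (exact paired differences, for closed-form checks).
make_paired_quant <- function(diffs_by_psite, times = 5) {
  n_rep <- length(diffs_by_psite[[1]])
  values <- lapply(diffs_by_psite, function(d) {
    v <- c()
    for (tm in times) {
      lo <- seq_len(n_rep) + 10           # arbitrary low-glucose values
      v[paste0("low_", tm, "_r", seq_len(n_rep))] <- lo
      v[paste0("high_", tm, "_r", seq_len(n_rep))] <- lo + d
    }
    v
  })
  make_quant(values, times = times, replicates = n_rep)
}

# Adjusted Rand index, written from the contingency-table definition.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Brute-force complete-linkage agglomeration on a dissimilarity matrix:
# returns the merge heights and final leaf partition sequence; used as an
# independent oracle for hclust-based ordering.
brute_complete_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, j, i)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  list(heights = heights, members = clusters[[1]])
}

# Gower dissimilarity for an all-quantitative matrix: mean over variables
# of |x_i - x_j| / range(variable), zero-range variables dropped.
brute_gower <- function(m) {
  rng <- apply(m, 2, function(x) diff(range(x)))
  keep <- rng > 0
  m <- m[, keep, drop = FALSE]
  rng <- rng[keep]
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- mean(abs(m[i, ] - m[j, ]) / rng)
    }
  }
  d
}
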