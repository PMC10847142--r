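# Naive loop-based oracles for the segregation indices, coded independently
# of the package's vectorized implementations.

oracle_mean_deviance <- function(counts, g) {
  M <- nrow(counts)
  N <- sum(counts)
  Ng <- sum(counts[, g])
  acc <- 0
  for (m in seq_len(M)) {
    Nm <- sum(counts[m, ])
    acc <- acc + abs(counts[m, g] / Nm - Ng / N)
  }
  acc / M
}

oracle_dissimilarity <- function(counts, g) {
  N <- sum(counts)
  Ng <- sum(counts[, g])
  p <- Ng / N
  acc <- 0
  for (m in seq_len(nrow(counts))) {
    Nm <- sum(counts[m, ])
    acc <- acc + abs(counts[m, g] / Nm - p) * Nm
  }
  acc / (2 * N * p * (1 - p))
}

oracle_gini <- function(counts, g) {
  N <- sum(counts)
  Ng <- sum(counts[, g])
  p <- Ng / N
  M <- nrow(counts)
  acc <- 0
  for (m in seq_len(M)) {
    for (l in seq_len(M)) {
      Nm <- sum(counts[m, ])
      Nl <- sum(counts[l, ])
      acc <- acc + abs(counts[m, g] / Nm - counts[l, g] / Nl) * Nm * Nl
    }
  }
  acc / (2 * N^2 * p * (1 - p))
}

oracle_correlation_ratio <- function(counts, g) {
  N <- sum(counts)
  Ng <- sum(counts[, g])
  p <- Ng / N
  iso <- 0
  for (m in seq_len(nrow(counts))) {
    iso <- iso + counts[m, g]^2 / sum(counts[m, ])
  }
  (iso / Ng - p) / (1 - p)
}

# random small two-group city with strictly positive tract totals and both
# groups present
random_small_city <- function(id = "r", max_tracts = 10) {
  m <- sample(2:max_tracts, 1)
  repeat {
    c1 <- sample(0:50, m, replace = TRUE)
    c2 <- sample(0:50, m, replace = TRUE)
    tot <- c1 + c2
    if (all(tot > 0) && sum(c1) > 0 && sum(c2) > 0) break
  }
  counts <- cbind(c1, c2)
  dimnames(counts) <- NULL
  city(id, counts)
}

# completely segregated 2k-tract city: k tracts of group 1, k of group 2
complete_segregation_city <- function(k = 3, size = 100) {
  city("sep", rbind(cbind(rep(size, k), 0), cbind(0, rep(size, k))))
}

# evenly distributed city: every tract at the city share
even_city <- function(m = 4, n1 = 60, n2 = 40) {
  city("even", cbind(rep(n1, m), rep(n2, m)))
}
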