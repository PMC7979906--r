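# brute-force / closed-form oracles, independent of the package's own code
# paths: plain double loops and direct formula transcriptions only

# IBS distance by explicit per-pair, per-site enumeration
naive_ibs <- function(calls) {
  n <- nrow(calls)
  d <- matrix(0, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(calls[i, ]) & !is.na(calls[j, ])
      stopifnot(any(ok))
      sim <- mean(1 - abs(calls[i, ok] - calls[j, ok]) / 2)
      d[i, j] <- d[j, i] <- 1 - sim
    }
  }
  d
}

# UPGMA by O(N^3) agglomeration on the original distances; returns the
# cophenetic matrix (merge height joining every pair)
naive_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  avg <- function(a, b) mean(d[clusters[[a]], clusters[[b]]])
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_h <- Inf
    for (a in seq_len(m - 1)) for (b in seq(a + 1, m)) {
      h <- avg(a, b)
      if (h < best_h) { best_h <- h; best <- c(a, b) }
    }
    ia <- clusters[[best[1]]]; ib <- clusters[[best[2]]]
    coph[ia, ib] <- best_h
    coph[ib, ia] <- best_h
    clusters[[best[1]]] <- c(ia, ib)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# conserved heterozygosity by explicit site loop
naive_conserved_het <- function(calls, i, j) {
  den <- 0L; num <- 0L
  for (s in seq_len(ncol(calls))) {
    gi <- calls[i, s]; gj <- calls[j, s]
    if (is.na(gi) || is.na(gj)) next
    if (gi == 1L || gj == 1L) {
      den <- den + 1L
      if (gi == 1L && gj == 1L) num <- num + 1L
    }
  }
  c(conserved = num, denominator = den)
}

# f3 on a bare frequency table: plain sum, no correction, no jackknife
naive_f3 <- function(freq, target, s1, s2) {
  total <- 0
  for (s in seq_len(ncol(freq))) {
    total <- total + (freq[target, s] - freq[s1, s]) * (freq[target, s] - freq[s2, s])
  }
  unname(total / ncol(freq))
}

# ordinary delete-one jackknife standard error of a mean
naive_jackknife_se <- function(values) {
  n <- length(values)
  theta_j <- (sum(values) - values) / (n - 1)
  sqrt((n - 1) / n * sum((theta_j - mean(theta_j))^2))
}

# Monte-Carlo expectation of Weir-Cockerham Fst between two Balding-Nichols
# populations in the infinite-sample-size limit of the variance components
fst_bn_oracle <- function(F1, F2, maf_range = c(0.05, 0.5),
                          n_sites = 50000, seed = 990) {
  set.seed(seed)
  u <- runif(n_sites, maf_range[1], maf_range[2])
  p <- ifelse(runif(n_sites) < 0.5, 1 - u, u)
  draw <- function(F) if (F == 0) p else rbeta(n_sites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  p1 <- draw(F1); p2 <- draw(F2)
  pbar <- (p1 + p2) / 2
  s2 <- (p1 - p2)^2 / 2
  sum(s2) / sum(pbar * (1 - pbar) + s2 / 2)
}

# closed-form expected conserved-het fraction for two unrelated individuals
# in one panmictic population whose site frequencies are uniform on the
# generator's minor-allele range: numeric integration of
# P(both het) / P(at least one het) with h(p) = 2p(1-p)
baseline_conserved_het_oracle <- function(maf_range = c(0.05, 0.5)) {
  h <- function(p) 2 * p * (1 - p)
  width <- maf_range[2] - maf_range[1]
  num <- integrate(function(p) h(p)^2, maf_range[1], maf_range[2])$value / width
  den <- integrate(function(p) 2 * h(p) - h(p)^2, maf_range[1], maf_range[2])$value / width
  num / den
}
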