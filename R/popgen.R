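#' Population map
#'
#' @param sample_id character vector of sample ids.
#' @param population character vector of population labels (same length).
#' @return named character vector (sample id -> population), the package's
#'   population-map representation.
#' @export
population_map <- function(sample_id, population) {
  if (length(sample_id) != length(population)) abort("lengths differ")
  if (anyDuplicated(sample_id)) abort("duplicated sample ids in population map")
  stats::setNames(as.character(population), as.character(sample_id))
}

check_pop_map <- function(gm, pm) {
  missing_ids <- setdiff(gm$samples, names(pm))
  if (length(missing_ids)) {
    abort("population map lacks sample(s): %s", paste(missing_ids, collapse = ", "))
  }
  pm[gm$samples]
}

#' Per-population allele frequencies
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] covering the samples of `gm`.
#' @return list of class `pop_freqs`: `freq` (populations x sites ALT
#'   frequency, `NaN` where a population has no call), `n_ind` (called
#'   individuals per population and site), `populations`.
#' @export
pop_allele_freqs <- function(gm, pm) {
  pm <- check_pop_map(gm, pm)
  pops <- unique(pm)
  if (any(table(pm) == 0)) abort("empty population in map")
  called <- !is.na(gm$calls)
  alt <- gm$calls
  alt[!called] <- 0L
  grp <- factor(pm, levels = pops)
  n_ind <- rowsum(called + 0, grp)
  alt_sum <- rowsum(alt + 0, grp)
  freq <- alt_sum / (2 * n_ind)   # NaN where n_ind == 0
  structure(list(freq = freq, n_ind = n_ind, populations = pops),
            class = "pop_freqs")
}

as_pop_freqs <- function(x, pm = NULL) {
  if (inherits(x, "pop_freqs")) return(x)
  if (inherits(x, "genotype_matrix")) {
    if (is.null(pm)) abort("a population map is required with a genotype matrix")
    return(pop_allele_freqs(x, pm))
  }
  if (is.matrix(x)) {
    # bare frequency table (populations x sites): infinite sample size, so
    # finite-sample corrections vanish
    return(structure(list(freq = x,
                          n_ind = matrix(Inf, nrow(x), ncol(x),
                                         dimnames = dimnames(x)),
                          populations = rownames(x)),
                     class = "pop_freqs"))
  }
  abort("expected a genotype_matrix, pop_freqs, or frequency matrix")
}

#' Per-population heterozygosity and Fis
#'
#' Per polymorphic site within each population: observed heterozygosity `Ho`
#' is the heterozygote fraction among called individuals, expected
#' heterozygosity uses the small-sample unbiased form
#' `He = 2p(1-p) * 2n/(2n-1)`. `Fis = 1 - mean(Ho)/mean(He)` over sites
#' polymorphic in that population (ratio of means). Negative Fis flags
#' heterozygote excess, the signature of clonally propagated groups.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()].
#' @return data.frame per population: `population`, `n` (individuals),
#'   `n_polymorphic`, `ho`, `he` (means over polymorphic sites), `fis`
#'   (`NA` when no polymorphic site).
#' @export
heterozygosity_fis <- function(gm, pm) {
  pm <- check_pop_map(gm, pm)
  pops <- unique(pm)
  out <- lapply(pops, function(pop) {
    calls <- gm$calls[pm == pop, , drop = FALSE]
    if (nrow(calls) < 2) abort("population %s has < 2 individuals", pop)
    n <- colSums(!is.na(calls))
    ok <- n > 0
    p <- colSums(calls, na.rm = TRUE)[ok] / (2 * n[ok])
    ho <- colMeans(calls == 1L, na.rm = TRUE)[ok]
    he <- 2 * p * (1 - p) * (2 * n[ok]) / (2 * n[ok] - 1)
    poly <- p > 0 & p < 1
    fis <- if (any(poly)) 1 - mean(ho[poly]) / mean(he[poly]) else NA_real_
    data.frame(population = pop, n = nrow(calls), n_polymorphic = sum(poly),
               ho = if (any(poly)) mean(ho[poly]) else NA_real_,
               he = if (any(poly)) mean(he[poly]) else NA_real_,
               fis = fis, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Weir-Cockerham (1984) variance components for one population pair,
# vectorised over sites; returns summed a and a+b+c over usable sites
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  usable <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  p1 <- p1[usable]; p2 <- p2[usable]; h1 <- h1[usable]; h2 <- h2[usable]
  n1 <- n1[usable]; n2 <- n2[usable]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = sum(a), abc = sum(a + b + c), n_sites = sum(usable))
}

#' Pairwise Weir-Cockerham Fst
#'
#' Per-site variance components of the Weir-Cockerham (1984) theta
#' estimator, combined genome-wide as the ratio of summed components
#' (sum(a) / sum(a+b+c)). Sites are used per pair when both populations have
#' at least one called individual (complete-case per pair). Slightly
#' negative estimates are reported as-is.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()]; every population needs >= 2 samples.
#' @return list of class `fst_matrix`: `fst` (symmetric matrix, `NA`
#'   diagonal), `n_sites` (usable sites per pair).
#' @export
pairwise_fst <- function(gm, pm) {
  pm <- check_pop_map(gm, pm)
  pops <- unique(pm)
  if (length(pops) < 2) abort("need at least two populations")
  if (any(table(pm)[pops] < 2)) abort("every population needs >= 2 samples")
  per_pop <- lapply(pops, function(pop) {
    calls <- gm$calls[pm == pop, , drop = FALSE]
    n <- colSums(!is.na(calls))
    list(n = n,
         p = ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA_real_),
         h = ifelse(n > 0, colSums(calls == 1L, na.rm = TRUE) / n, NA_real_))
  })
  names(per_pop) <- pops
  k <- length(pops)
  fst <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  nst <- matrix(NA_integer_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      x <- per_pop[[i]]; y <- per_pop[[j]]
      wc <- wc_components(x$p, y$p, x$h, y$h, x$n, y$n)
      est <- if (wc$abc > 0) wc$a / wc$abc else NA_real_
      fst[i, j] <- fst[j, i] <- est
      nst[i, j] <- nst[j, i] <- wc$n_sites
    }
  }
  structure(list(fst = fst, n_sites = nst), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham Fst:\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Weighted block jackknife over consecutive SNP blocks
#'
#' Delete-one-block jackknife with block-size weights (Busing, Meijer &
#' van der Leeden 1999), the standard error scheme of the f-statistics
#' toolchain. The statistic must be a mean of per-site values. The trailing
#' partial block is kept and weighted by its size. With block size 1 this is
#' the ordinary delete-one jackknife.
#'
#' @param values per-site values of the statistic.
#' @param block_size SNPs per block (>= 1).
#' @return list: `estimate` (plain mean), `se` (`NA` with fewer than two
#'   blocks), `z`, `n_blocks`, `n_sites`.
#' @export
block_jackknife <- function(values, block_size = 500L) {
  if (block_size < 1) abort("block_size must be >= 1")
  n <- length(values)
  if (n == 0) abort("no values to jackknife")
  g <- ceiling(n / block_size)
  block <- rep(seq_len(g), each = block_size)[seq_len(n)]
  total <- sum(values)
  theta <- total / n
  m_j <- tabulate(block, nbins = g)
  block_sum <- as.vector(rowsum(values, block))
  theta_j <- (total - block_sum) / (n - m_j)
  if (g < 2) {
    return(list(estimate = theta, se = NA_real_, z = NA_real_,
                n_blocks = g, n_sites = n))
  }
  h_j <- n / m_j
  theta_J <- g * theta - sum((1 - m_j / n) * theta_j)
  tau <- h_j * theta - (h_j - 1) * theta_j
  var_J <- mean((tau - theta_J)^2 / (h_j - 1))
  se <- sqrt(var_J)
  list(estimate = theta, se = se,
       z = if (se > 0) theta / se else NA_real_,
       n_blocks = g, n_sites = n)
}

fstat_result <- function(kind, pops, jk, block_size) {
  structure(list(kind = kind, pops = pops, estimate = jk$estimate,
                 se = jk$se, z = jk$z, block_size = as.integer(block_size),
                 n_blocks = jk$n_blocks, n_sites = jk$n_sites),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d sites, %d blocks of %d)\n",
              x$kind, paste(x$pops, collapse = ", "), x$estimate,
              x$se, x$z, x$n_sites, x$n_blocks, x$block_size))
  invisible(x)
}

#' @export
as.data.frame.fstat_result <- function(x, ...) {
  data.frame(kind = x$kind, pops = paste(x$pops, collapse = ";"),
             estimate = x$estimate, se = x$se, z = x$z,
             block_size = x$block_size, n_blocks = x$n_blocks,
             n_sites = x$n_sites, stringsAsFactors = FALSE)
}

#' Patterson f3 statistic with block-jackknife standard error
#'
#' `f3(target; s1, s2)` averages `(a - b)(a - c)` over usable sites, where
#' `a`, `b`, `c` are the sample ALT frequencies of the target and the two
#' sources. A significantly negative value means the target's frequencies
#' sit between the sources', i.e. the target is admixed. The finite-sample
#' bias from sampling the target frequency is removed by subtracting
#' `a(1-a) / (n_a - 1)` (with `n_a` the called chromosome count); the
#' correction vanishes for a bare frequency table (infinite n). Standard
#' errors come from [block_jackknife()] over consecutive blocks.
#'
#' @param x a [genotype_matrix()], [pop_allele_freqs()] result, or bare
#'   populations x sites frequency matrix.
#' @param target,source1,source2 three distinct population labels.
#' @param pm a [population_map()] (required when `x` is a genotype matrix).
#' @param block_size SNPs per jackknife block (default 500).
#' @param correction apply the target finite-sample correction (default TRUE).
#' @return an `fstat_result`.
#' @export
f3 <- function(x, target, source1, source2, pm = NULL, block_size = 500L,
               correction = TRUE) {
  pf <- as_pop_freqs(x, pm)
  pops <- c(target, source1, source2)
  if (anyDuplicated(pops)) abort("f3 needs three distinct populations")
  missing_pops <- setdiff(pops, rownames(pf$freq))
  if (length(missing_pops)) abort("unknown population(s): %s", paste(missing_pops, collapse = ", "))
  a <- pf$freq[target, ]; b <- pf$freq[source1, ]; c <- pf$freq[source2, ]
  n_chr <- 2 * pf$n_ind[target, ]
  usable <- is.finite(a) & is.finite(b) & is.finite(c) &
    pf$n_ind[source1, ] > 0 & pf$n_ind[source2, ] > 0 & n_chr >= 2
  d <- (a - b) * (a - c)
  if (correction) {
    corr <- ifelse(is.finite(n_chr), a * (1 - a) / (n_chr - 1), 0)
    d <- d - corr
  }
  if (!any(usable)) abort("no usable sites for f3(%s; %s, %s)", target, source1, source2)
  fstat_result("f3", pops, block_jackknife(d[usable], block_size), block_size)
}

#' Patterson f4 statistic with block-jackknife standard error
#'
#' `f4(A, B; C, D)` averages `(a - b)(c - d)` over usable sites; a nonzero
#' value rejects the unrooted tree ((A,B),(C,D)) and indicates gene flow.
#' Swapping C and D negates the statistic exactly; `f4(A, B; C, C)` is
#' identically zero.
#'
#' @inheritParams f3
#' @param p1,p2,p3,p4 population labels for A, B, C, D.
#' @return an `fstat_result`.
#' @export
f4 <- function(x, p1, p2, p3, p4, pm = NULL, block_size = 500L) {
  pf <- as_pop_freqs(x, pm)
  pops <- c(p1, p2, p3, p4)
  missing_pops <- setdiff(pops, rownames(pf$freq))
  if (length(missing_pops)) abort("unknown population(s): %s", paste(missing_pops, collapse = ", "))
  a <- pf$freq[p1, ]; b <- pf$freq[p2, ]
  c <- pf$freq[p3, ]; d <- pf$freq[p4, ]
  usable <- is.finite(a) & is.finite(b) & is.finite(c) & is.finite(d)
  if (!any(usable)) abort("no usable sites for f4")
  vals <- ((a - b) * (c - d))[usable]
  fstat_result("f4", pops, block_jackknife(vals, block_size), block_size)
}
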