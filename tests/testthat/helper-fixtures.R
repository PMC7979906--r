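# small in-code fixtures shared across test files

make_gm <- function(calls, n_loci_pairs = FALSE, samples = NULL) {
  calls <- as.matrix(calls)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(nrow(calls)))
  rownames(calls) <- samples
  ns <- ncol(calls)
  chrom <- if (n_loci_pairs) sprintf("L%03d", rep(seq_len(ceiling(ns / 2)), each = 2))[seq_len(ns)]
           else sprintf("L%03d", seq_len(ns))
  pos <- if (n_loci_pairs) rep(c(10L, 40L), length.out = ns) else rep(10L, ns)
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                    ref = rep_len("A", ns), alt = rep_len("G", ns),
                                    stringsAsFactors = FALSE))
}

random_gm <- function(n_samples, n_sites, missing = 0.1, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
                  nrow = n_samples)
  calls[runif(length(calls)) < missing] <- NA_integer_
  make_gm(calls, n_loci_pairs = TRUE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
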