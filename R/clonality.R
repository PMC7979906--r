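#' Pairwise conserved-heterozygosity record
#'
#' Container for the clonality statistic of one sample pair: among jointly
#' called sites where at least one of the pair is heterozygous, the count
#' and fraction where both are. Grafted or otherwise asexually propagated
#' plants retain the founder's heterozygous sites, so their conservation
#' fraction stays high, while meiosis in sexual relatives breaks it down.
#' Also usable directly with published counts (e.g. 2288 conserved of 3699
#' qualifying sites gives 61.9%).
#'
#' @param n_conserved_het count of sites heterozygous in both samples.
#' @param n_denominator count of qualifying sites (>= 1 heterozygote).
#' @param sample_a,sample_b sample ids (informational).
#' @return object of class `pair_het`: the counts, `fraction`, and
#'   `percent` (fraction times 100, rounded half-up to 1 decimal).
#' @export
pair_het_conservation <- function(n_conserved_het, n_denominator,
                                  sample_a = NA_character_,
                                  sample_b = NA_character_) {
  if (n_conserved_het < 0 || n_denominator < 0 || n_conserved_het > n_denominator) {
    abort("need 0 <= n_conserved_het <= n_denominator")
  }
  fraction <- if (n_denominator > 0) n_conserved_het / n_denominator else NA_real_
  structure(list(sample_a = sample_a, sample_b = sample_b,
                 n_denominator = as.integer(n_denominator),
                 n_conserved_het = as.integer(n_conserved_het),
                 fraction = fraction,
                 percent = if (is.na(fraction)) NA_real_ else
                   round_half_up(100 * fraction, 1)),
            class = "pair_het")
}

#' @export
print.pair_het <- function(x, ...) {
  cat(sprintf("conserved heterozygosity %s / %s: %d of %d sites (%s%%)\n",
              x$sample_a, x$sample_b, x$n_conserved_het, x$n_denominator,
              format(x$percent, nsmall = 1)))
  invisible(x)
}

#' Conserved heterozygosity of a sample pair
#'
#' Restricts the pair to jointly called sites ([pairwise_shared_sites()]),
#' then counts sites where both individuals are heterozygous against the
#' qualifying denominator. Under the default `denominator = "any_het"` the
#' qualifying sites are those where at least one of the pair is
#' heterozygous, which makes "conserved" literal (a heterozygote preserved
#' in the partner) and bounds the fraction at 1. `"pair_variant"` instead
#' uses every co-called site carrying an alternate allele in either sample,
#' for sensitivity analysis.
#'
#' @param gm a [genotype_matrix()].
#' @param a,b distinct sample ids.
#' @param denominator `"any_het"` (default) or `"pair_variant"`.
#' @return a [pair_het_conservation()] record. A zero denominator yields
#'   `NA` fraction (counts still reported).
#' @export
conserved_het <- function(gm, a, b, denominator = c("any_het", "pair_variant")) {
  denominator <- match.arg(denominator)
  shared <- pairwise_shared_sites(gm, a, b)
  ga <- shared$calls[1, ]
  gb <- shared$calls[2, ]
  qualifying <- if (denominator == "any_het") ga == 1L | gb == 1L else ga > 0L | gb > 0L
  pair_het_conservation(sum(ga == 1L & gb == 1L), sum(qualifying), a, b)
}

#' Classify a pair as clonal or not
#'
#' @param phc a `pair_het` record with a defined fraction.
#' @param threshold clonality threshold in (0, 1); the default 0.485 is
#'   anchored at the lowest conservation fraction observed between plants
#'   known to share a graft source, and the boundary is inclusive.
#' @return list of class `clonality_call`: the pair, fraction, threshold,
#'   and `verdict` ("clonal" or "non-clonal").
#' @export
classify_pair <- function(phc, threshold = 0.485) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (is.na(phc$fraction)) abort("undefined fraction (zero qualifying sites); no verdict")
  structure(list(sample_a = phc$sample_a, sample_b = phc$sample_b,
                 fraction = phc$fraction, threshold = threshold,
                 verdict = if (phc$fraction >= threshold) "clonal" else "non-clonal"),
            class = "clonality_call")
}

# conserved-het counts for every pair at once via logical cross-products;
# equals the per-pair conserved_het() path (property-tested)
conserved_het_counts <- function(gm) {
  het <- (!is.na(gm$calls) & gm$calls == 1L) + 0
  called <- (!is.na(gm$calls)) + 0
  both_het <- tcrossprod(het)
  het_vs_called <- tcrossprod(het, called)
  either_het <- het_vs_called + t(het_vs_called) - both_het
  dimnames(both_het) <- dimnames(either_het) <- list(gm$samples, gm$samples)
  list(conserved = both_het, qualifying = either_het)
}

#' Conserved-heterozygosity table for all sample pairs
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional subset of sample ids (default all).
#' @param threshold clonality threshold passed to [classify_pair()].
#' @return long-format data.frame with one row per unordered pair: `a`, `b`,
#'   `n_denominator`, `n_conserved_het`, `fraction`, `percent`, `verdict`
#'   (`NA` verdict when the denominator is zero).
#' @export
het_conservation_table <- function(gm, samples = NULL, threshold = 0.485) {
  if (!is.null(samples)) gm <- subset_gm(gm, samples = samples)
  if (n_samples(gm) < 2) abort("need at least two samples")
  cnt <- conserved_het_counts(gm)
  idx <- which(upper.tri(cnt$conserved), arr.ind = TRUE)
  den <- cnt$qualifying[idx]
  num <- cnt$conserved[idx]
  frac <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(a = gm$samples[idx[, 1]], b = gm$samples[idx[, 2]],
                    n_denominator = as.integer(den),
                    n_conserved_het = as.integer(num),
                    fraction = frac,
                    percent = round_half_up(100 * frac, 1),
                    verdict = ifelse(is.na(frac), NA_character_,
                                     ifelse(frac >= threshold, "clonal", "non-clonal")),
                    stringsAsFactors = FALSE)
  out[order(out$a, out$b), , drop = FALSE]
}

# connected components over a vertex set given an edge list (two-column
# data.frame); returns list of character vectors sorted by first member
connected_components <- function(vertices, edges) {
  parent <- stats::setNames(seq_along(vertices), vertices)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- find(match(edges[[1]][r], vertices))
      j <- find(match(edges[[2]][r], vertices))
      if (i != j) parent[j] <- i
    }
  }
  root <- vapply(seq_along(vertices), find, integer(1))
  comp <- split(vertices, root)
  comp <- lapply(comp, sort)
  comp[order(vapply(comp, `[`, "", 1))]
}

#' Partition samples into clonal groups
#'
#' Builds a graph with an edge for every pair whose conserved-heterozygosity
#' fraction reaches the threshold and returns its connected components:
#' clones of one founder need not all be pairwise above threshold for the
#' lineage to assemble, transitivity closes it. Pairs with an undefined
#' fraction (no qualifying sites) contribute no edge and raise one summary
#' warning.
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional subset of sample ids.
#' @param threshold clonality threshold (default 0.485, inclusive).
#' @return list of class `clonal_partition`: `groups` (list of sorted member
#'   vectors, multi-member components first by first member id), `membership`
#'   (data.frame `sample_id`, `group`, `is_clonal`), and the pair `table`.
#' @export
clonal_clusters <- function(gm, samples = NULL, threshold = 0.485) {
  tab <- het_conservation_table(gm, samples = samples, threshold = threshold)
  ids <- if (is.null(samples)) gm$samples else samples
  undef <- is.na(tab$fraction)
  if (any(undef)) {
    warning(sprintf("%d pair(s) with no qualifying sites skipped", sum(undef)),
            call. = FALSE)
  }
  edges <- tab[!undef & tab$fraction >= threshold, c("a", "b")]
  comp <- connected_components(sort(ids), edges)
  sizes <- lengths(comp)
  comp <- comp[order(sizes < 2, vapply(comp, `[`, "", 1))]
  membership <- data.frame(
    sample_id = unlist(comp, use.names = FALSE),
    group = rep(seq_along(comp), lengths(comp)),
    is_clonal = rep(lengths(comp) > 1, lengths(comp)),
    stringsAsFactors = FALSE)
  structure(list(groups = comp, membership = membership, table = tab,
                 threshold = threshold),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  multi <- x$groups[lengths(x$groups) > 1]
  cat(sprintf("clonal_partition: %d clonal group(s), %d singleton(s), threshold %.3f\n",
              length(multi), sum(lengths(x$groups) == 1), x$threshold))
  for (g in multi) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}
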