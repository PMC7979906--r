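#' Identity-by-state distance matrix
#'
#' For each sample pair, similarity is the mean over jointly called sites of
#' `1 - |g_i - g_j| / 2` (the shared-allele fraction at a biallelic site)
#' and distance is one minus that. Missing data are handled per pair by
#' complete cases; a pair with no jointly called site is an error rather
#' than a silent `NaN`.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return symmetric N x N distance matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2) abort("need at least two samples")
  calls <- gm$calls
  called <- !is.na(calls)
  G0 <- (called & calls == 0L) + 0
  G1 <- (called & calls == 1L) + 0
  G2 <- (called & calls == 2L) + 0
  C <- called + 0
  # sum over co-called sites of |g_i - g_j|
  diff_sum <- tcrossprod(G0, G1) + tcrossprod(G1, G0) +
    tcrossprod(G1, G2) + tcrossprod(G2, G1) +
    2 * (tcrossprod(G0, G2) + tcrossprod(G2, G0))
  n_shared <- tcrossprod(C)
  if (any(n_shared[upper.tri(n_shared)] == 0)) {
    idx <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)[1, ]
    abort("no jointly called sites for pair %s / %s",
          gm$samples[idx[1]], gm$samples[idx[2]])
  }
  d <- diff_sum / (2 * n_shared)
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  d
}

#' UPGMA (average linkage) clustering of an IBS distance matrix
#'
#' Thin wrapper over [stats::hclust()] with `method = "average"`; merges at
#' equal heights follow the input sample order.
#'
#' @param dm symmetric distance matrix (as from [ibs_distance()]).
#' @return an object of class `hclust`.
#' @export
upgma_cluster <- function(dm) {
  if (nrow(dm) < 2) abort("need at least two samples to cluster")
  stats::hclust(stats::as.dist(dm), method = "average")
}

#' Cut a dendrogram into k groups
#'
#' @param hc an `hclust` tree from [upgma_cluster()].
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
cut_dendrogram <- function(hc, k) stats::cutree(hc, k = k)

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` tree.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Genotype principal component analysis
#'
#' Each site is centred by twice its sample allele frequency and, under the
#' default Patterson scaling, divided by `sqrt(p(1-p))`, the binomial
#' standard deviation of a single allele draw. Missing calls are mean
#' imputed (zero after centring). Scores come from the eigendecomposition of
#' the sample-by-sample covariance; the contribution ratio of an axis is its
#' eigenvalue over the sum of positive eigenvalues. Sites monomorphic over
#' the non-missing calls have no defined scaling and are dropped with one
#' summary warning.
#'
#' @param gm a filtered, biallelic [genotype_matrix()] with >= 2 samples.
#' @param n_axes number of axes to retain (default 10, capped at N).
#' @param scaling `"patterson"` (default) or `"none"` (covariance of the
#'   centred matrix only, for sensitivity checks).
#' @return list of class `genotype_pca`: `scores` (N x K, eigenvector times
#'   square-root eigenvalue), `eigenvalues` (K, non-increasing),
#'   `contribution_ratios` (K), `n_sites_used`.
#' @export
genotype_pca <- function(gm, n_axes = 10L, scaling = c("patterson", "none")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  scaling <- match.arg(scaling)
  if (n_samples(gm) < 2) abort("need at least two samples")
  calls <- gm$calls
  p <- site_stats(gm)$freq
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly)) {
    warning(sprintf("dropped %d monomorphic or uncalled site(s) before PCA",
                    sum(!poly)), call. = FALSE)
  }
  if (!any(poly)) abort("no polymorphic sites for PCA")
  calls <- calls[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(calls, 2, 2 * p, `-`)
  if (scaling == "patterson") x <- sweep(x, 2, sqrt(p * (1 - p)), `/`)
  x[is.na(x)] <- 0
  cov <- tcrossprod(x) / ncol(x)
  eig <- eigen(cov, symmetric = TRUE)
  pos <- sum(eig$values > .Machine$double.eps * max(abs(eig$values)))
  k <- min(n_axes, length(eig$values))
  values <- eig$values[seq_len(k)]
  scores <- sweep(eig$vectors[, seq_len(k), drop = FALSE], 2,
                  sqrt(pmax(values, 0)), `*`)
  dimnames(scores) <- list(gm$samples, paste0("PC", seq_len(k)))
  structure(list(scores = scores, eigenvalues = values,
                 contribution_ratios = values / sum(eig$values[seq_len(pos)]),
                 n_sites_used = ncol(x)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, %d sites, %d axes\n",
              nrow(x$scores), x$n_sites_used, ncol(x$scores)))
  cat("contribution ratios:",
      paste0(round_half_up(100 * x$contribution_ratios, 1), "%"), "\n")
  invisible(x)
}
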