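#' Biallelic genotype matrix
#'
#' The central container of the package: an individuals-by-sites matrix of
#' biallelic SNP genotypes coded as the count of alternate alleles (0, 1, 2),
#' with `NA` for missing calls, plus per-site metadata.
#'
#' @param calls integer matrix, samples in rows, sites in columns; entries in
#'   \{0, 1, 2, NA\}.
#' @param sites data.frame with one row per site and columns `chrom`, `pos`
#'   (1-based), `ref`, `alt` (single nucleotides), and optionally `locus_id`
#'   (RAD-locus grouping key; defaults to `chrom`, the convention of de novo
#'   RAD genotypers where each locus is its own "chromosome").
#' @param samples character vector of unique sample ids; defaults to
#'   `rownames(calls)`.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls` (integer matrix), `samples` (character), `sites` (data.frame).
#' @export
genotype_matrix <- function(calls, sites, samples = rownames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) abort("sample ids are required (rownames or `samples`)")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicated sample ids")
  if (nrow(calls) != length(samples)) {
    abort("calls has %d rows but %d sample ids given", nrow(calls), length(samples))
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) abort("sites lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (is.null(sites$locus_id)) sites$locus_id <- as.character(sites$chrom)
  sites$chrom <- as.character(sites$chrom)
  sites$locus_id <- as.character(sites$locus_id)
  sites$pos <- as.integer(sites$pos)
  if (ncol(calls) != nrow(sites)) {
    abort("calls has %d columns but %d site rows given", ncol(calls), nrow(sites))
  }
  if (nrow(sites)) {
    if (any(sites$ref == sites$alt)) abort("ref and alt allele identical at some site")
    keys <- paste(sites$chrom, sites$pos, sep = ":")
    if (anyDuplicated(keys)) abort("duplicated site keys (chrom:pos)")
  } else {
    keys <- character(0)
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  dimnames(calls) <- list(samples, keys)
  structure(list(calls = calls, samples = samples, sites = sites),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing)\n",
              n_samples(x), n_sites(x),
              if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0))
  invisible(x)
}

#' Numbers of samples and sites
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' Site keys (chrom:pos)
#' @param gm a [genotype_matrix()].
#' @return character vector of unique site keys.
#' @export
site_keys <- function(gm) paste(gm$sites$chrom, gm$sites$pos, sep = ":")

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples character vector of sample ids to keep (order respected).
#' @param sites integer or logical index over site columns.
#' @return a new `genotype_matrix`.
#' @export
subset_gm <- function(gm, samples = NULL, sites = NULL) {
  calls <- gm$calls
  meta <- gm$sites
  ids <- gm$samples
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, ids)
    if (length(missing_ids)) abort("unknown sample id(s): %s", paste(missing_ids, collapse = ", "))
    calls <- calls[samples, , drop = FALSE]
    ids <- samples
  }
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    meta <- meta[sites, , drop = FALSE]
    rownames(meta) <- NULL
  }
  genotype_matrix(calls, meta, ids)
}

#' Per-site alternate-allele frequency and call rate
#'
#' Frequencies are computed over non-missing calls only.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `key`, `call_rate`, `freq`, `maf`
#'   (`freq`/`maf` are `NaN` for sites with no calls).
#' @export
site_stats <- function(gm) {
  called <- !is.na(gm$calls)
  n_called <- colSums(called)
  freq <- colSums(gm$calls, na.rm = TRUE) / (2 * n_called)
  data.frame(key = site_keys(gm),
             call_rate = if (n_samples(gm)) n_called / n_samples(gm) else numeric(0),
             freq = freq,
             maf = pmin(freq, 1 - freq),
             row.names = NULL, stringsAsFactors = FALSE)
}
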