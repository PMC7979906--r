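#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix()].
#' Genotype codes are the number of alternate alleles in the GT field; both
#' phased (`|`) and unphased (`/`) separators are accepted, and any call with
#' a missing allele (`./.`, `.`, `./0`) becomes `NA`. Records that are not
#' biallelic SNPs (indels, multiallelic sites) are skipped with one summary
#' warning. Sample order follows the VCF header. A non-`.` ID field is used
#' as the RAD `locus_id`; otherwise the locus id defaults to CHROM (the
#' de novo RAD convention of one locus per "chromosome").
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort("VCF not found: %s", path)
  header <- read_vcf_header(path)
  if (header$n_records == 0L) {
    # header-only file: vcfR requires at least one record, so build the
    # empty matrix straight from the #CHROM line
    empty_sites <- data.frame(chrom = character(0), pos = integer(0),
                              ref = character(0), alt = character(0),
                              locus_id = character(0), stringsAsFactors = FALSE)
    calls <- matrix(integer(0), nrow = length(header$samples), ncol = 0,
                    dimnames = list(header$samples, NULL))
    return(genotype_matrix(calls, empty_sites, header$samples))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref != alt
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    warning(sprintf("skipped %d non-biallelic-SNP record(s)", n_skip), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field: %s", path)
  gt <- gt[snp, , drop = FALSE]
  codes <- gt_to_code(gt)          # sites x samples
  info <- vcfR::getINFO(vcf)[snp]
  lid <- sub("^.*(?:^|;)LID=([^;]+).*$", "\\1", info)
  lid[!grepl("(^|;)LID=", info)] <- NA
  id <- id[snp]
  locus <- ifelse(!is.na(lid), lid,
                  ifelse(is.na(id) | id == ".", chrom[snp], id))
  sites <- data.frame(chrom = chrom[snp], pos = pos[snp],
                      ref = ref[snp], alt = alt[snp],
                      locus_id = locus, stringsAsFactors = FALSE)
  genotype_matrix(t(codes), sites, colnames(gt))
}

# minimal header scan: sample names from the #CHROM line and a record count
read_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  samples <- NULL
  n_records <- 0L
  line_no <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) break
    line_no <- line_no + 1L
    if (startsWith(line, "#CHROM")) {
      cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(cols) < 9L) abort("malformed #CHROM header at line %d of %s", line_no, path)
      samples <- cols[-(1:9)]
    } else if (!startsWith(line, "#") && nzchar(line)) {
      if (is.null(samples)) abort("VCF record before #CHROM header at line %d of %s", line_no, path)
      n_records <- n_records + 1L
    }
  }
  if (is.null(samples)) abort("no #CHROM header line found in %s", path)
  list(samples = samples, n_records = n_records)
}

# GT strings -> alternate-allele counts; NA on any missing allele
gt_to_code <- function(gt) {
  core <- sub(":.*$", "", gt)
  core <- chartr("|", "/", core)
  u <- unique(as.vector(core))
  map <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(alleles == ".") || any(is.na(alleles)) || length(alleles) == 0) return(NA_integer_)
    av <- suppressWarnings(as.integer(alleles))
    if (any(is.na(av)) || any(av < 0L) || any(av > 1L)) return(NA_integer_)
    sum(av)
  }, integer(1))
  out <- map[match(as.vector(core), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 with a GT-only FORMAT, one record per site.
#' Missing calls are written as `./.`. The site `locus_id` is stored as an
#' `LID=` INFO key so that `read_vcf(write_vcf(gm))` reproduces `gm` exactly
#' (the ID column must stay unique for downstream VCF tooling, and several
#' sites can share one RAD locus).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radclone",
    "##INFO=<ID=LID,Number=1,Type=String,Description=\"RAD locus id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (n_sites(gm) > 0) {
    codes <- t(gm$calls)  # sites x samples
    gt <- matrix(gt_strings[as.character(codes)], nrow = nrow(codes))
    gt[is.na(codes)] <- "./."
    rec <- cbind(gm$sites$chrom, gm$sites$pos, ".",
                 gm$sites$ref, gm$sites$alt, ".", "PASS",
                 paste0("LID=", gm$sites$locus_id), "GT", gt)
    writeLines(apply(rec, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text with at least `sample_id` and `population` columns.
#'
#' @param path path to a tab- or comma-delimited table.
#' @return data.frame with a `sample_id` and `population` column (extra
#'   columns preserved).
#' @export
read_sample_metadata <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(md))) {
    abort("metadata must have columns sample_id and population: %s", path)
  }
  if (anyDuplicated(md$sample_id)) abort("duplicated sample_id in metadata")
  md
}

#' Site-filter configuration
#'
#' The three standard post-genotyping site filters for de novo RAD panels:
#' minimum per-site call rate (the share of individuals with a genotype;
#' 0.5 retains a site typed in at least half the panel), one SNP per RAD
#' locus (keep only the first, lowest-position SNP of each locus to thin
#' intra-locus linkage), and a minimum minor allele frequency computed over
#' non-missing calls (boundary inclusive).
#'
#' @param min_call_rate fraction in \[0, 1\]; default 0.5.
#' @param one_snp_per_locus logical; default TRUE.
#' @param min_maf fraction in \[0, 0.5\]; default 0.05.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_call_rate = 0.5, one_snp_per_locus = TRUE,
                          min_maf = 0.05) {
  if (min_call_rate < 0 || min_call_rate > 1) abort("min_call_rate must be in [0,1]")
  if (min_maf < 0 || min_maf > 0.5) abort("min_maf must be in [0,0.5]")
  structure(list(min_call_rate = min_call_rate,
                 one_snp_per_locus = isTRUE(one_snp_per_locus),
                 min_maf = min_maf),
            class = "filter_config")
}

#' Apply site filters to a genotype matrix
#'
#' Filters are applied in a fixed order so that the report's counts are
#' reproducible: (1) call rate, (2) one SNP per locus (lowest position wins,
#' ties broken by input order), (3) minor allele frequency (inclusive
#' boundary, computed over non-missing calls).
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return list with elements `gm` (filtered [genotype_matrix()]) and
#'   `report` (a `filter_report` with the per-step removal counts).
#' @export
apply_filters <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_sites(gm) == 0) abort("empty genotype matrix: no sites to filter")
  n_input <- n_sites(gm)

  stats <- site_stats(gm)
  keep <- stats$call_rate >= cfg$min_call_rate
  n_call_rate <- sum(!keep)
  gm <- subset_gm(gm, sites = keep)

  n_dedup <- 0L
  if (cfg$one_snp_per_locus && n_sites(gm) > 0) {
    s <- gm$sites
    ord <- order(factor(s$locus_id, levels = unique(s$locus_id)), s$pos)
    first_idx <- ord[!duplicated(s$locus_id[ord])]
    keep <- sort(first_idx)   # restore input site order
    n_dedup <- n_sites(gm) - length(keep)
    gm <- subset_gm(gm, sites = keep)
  }

  n_maf <- 0L
  if (n_sites(gm) > 0) {
    maf <- site_stats(gm)$maf
    keep <- !is.na(maf) & maf >= cfg$min_maf
    n_maf <- sum(!keep)
    gm <- subset_gm(gm, sites = keep)
  }

  if (n_sites(gm) == 0) {
    abort("all %d sites removed: empty matrix after filtering", n_input)
  }
  report <- structure(list(n_sites_input = n_input,
                           n_removed_call_rate = n_call_rate,
                           n_removed_locus_dedup = n_dedup,
                           n_removed_maf = n_maf,
                           n_sites_output = n_sites(gm)),
                      class = "filter_report")
  list(gm = gm, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("site filters: %d in -> %d out ",
                     "(call rate -%d, locus dedup -%d, MAF -%d)\n"),
              x$n_sites_input, x$n_sites_output, x$n_removed_call_rate,
              x$n_removed_locus_dedup, x$n_removed_maf))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(n_sites_input = x$n_sites_input,
             n_removed_call_rate = x$n_removed_call_rate,
             n_removed_locus_dedup = x$n_removed_locus_dedup,
             n_removed_maf = x$n_removed_maf,
             n_sites_output = x$n_sites_output)
}

#' Restrict a pair of samples to jointly called sites
#'
#' The pairwise-alignment view used by the clonality statistic: only sites
#' where both individuals have a genotype are kept (a per-pair call-rate
#' requirement of 1), preserving site order.
#'
#' @param gm a [genotype_matrix()].
#' @param a,b distinct sample ids present in `gm`.
#' @return a two-sample [genotype_matrix()] of the co-called sites.
#' @export
pairwise_shared_sites <- function(gm, a, b) {
  if (identical(a, b)) abort("a and b must be distinct samples")
  gm2 <- subset_gm(gm, samples = c(a, b))
  keep <- !is.na(gm2$calls[1, ]) & !is.na(gm2$calls[2, ])
  subset_gm(gm2, sites = keep)
}
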