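write_vcf_text <- function(lines, samples = c("s1", "s2", "s3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               lines), path)
  path
}

test_that("GT fields decode to alternate-allele counts", {
  path <- write_vcf_text(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./0\t.\t1/0"))
  gm <- read_vcf(path)
  expect_equal(gm$samples, c("s1", "s2", "s3"))
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L, 2L))
  # phased separator, half-missing and bare-dot calls
  expect_equal(unname(gm$calls[, 2]), c(1L, NA, 2L))
  expect_equal(unname(gm$calls[, 3]), c(NA, NA, 1L))
  # no LID key and "." ID: locus defaults to CHROM
  expect_equal(gm$sites$locus_id, rep("chr1", 3))
})

test_that("non-SNP records are skipped with a warning", {
  path <- write_vcf_text(c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t150\t.\tAT\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",   # indel
    "chr1\t180\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",  # multiallelic
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/1"))
  expect_warning(gm <- read_vcf(path), "skipped 2")
  expect_equal(n_sites(gm), 2)
  expect_equal(gm$sites$pos, c(100L, 200L))
})

test_that("VCF round trip is lossless, including empty and missing cases", {
  # empty matrix -> header-only VCF -> empty matrix
  empty <- make_gm(matrix(integer(0), nrow = 3, ncol = 0))
  f <- tempfile(fileext = ".vcf")
  write_vcf(empty, f)
  expect_false(any(!startsWith(readLines(f), "#")))
  back <- read_vcf(f)
  expect_equal(back$samples, empty$samples)
  expect_equal(n_sites(back), 0)

  # MISSING call becomes ./.
  gm <- make_gm(rbind(c(0L, NA), c(1L, 2L)))
  write_vcf(gm, f)
  expect_match(grep("^L002", readLines(f), value = TRUE)[1], "\\./\\.")

  # random 8 x 50 matrix with paired locus ids round-trips exactly
  gm <- random_gm(8, 50, missing = 0.15, seed = 42)
  write_vcf(gm, f)
  back <- read_vcf(f)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$sites, gm$sites)
  expect_identical(back$samples, gm$samples)
})

test_that("filters apply in order with correct per-step accounting", {
  # site 1: 1 of 4 called (0.25 < 0.5) -> removed by call rate
  # sites 2,3 share L001 at pos 10/40 -> pos 40 removed by dedup
  # site 4: monomorphic (MAF 0) -> removed by MAF
  calls <- rbind(c(0L, 0L, 1L, 0L),
                 c(NA, 1L, 1L, 0L),
                 c(NA, 1L, 0L, 0L),
                 c(NA, 0L, 1L, 0L))
  sites <- data.frame(chrom = c("L000", "L001", "L001", "L002"),
                      pos = c(10L, 10L, 40L, 10L), ref = "A", alt = "G")
  gm <- genotype_matrix(calls, sites, samples = sprintf("S%d", 1:4))
  res <- apply_filters(gm, filter_config(0.5, TRUE, 0.05))
  rep <- res$report
  expect_equal(rep$n_sites_input, 4)
  expect_equal(rep$n_removed_call_rate, 1)
  expect_equal(rep$n_removed_locus_dedup, 1)
  expect_equal(rep$n_removed_maf, 1)
  expect_equal(rep$n_sites_output, 1)
  expect_equal(site_keys(res$gm), "L001:10")
  expect_equal(rep$n_sites_output,
               rep$n_sites_input - rep$n_removed_call_rate -
                 rep$n_removed_locus_dedup - rep$n_removed_maf)
})

test_that("MAF boundary is inclusive and computed over non-missing calls", {
  # 10 samples, site A all het (MAF 0.5); site B one het (MAF 0.05)
  calls <- cbind(rep(1L, 10), c(1L, rep(0L, 9)))
  gm <- make_gm(calls)
  res <- apply_filters(gm, filter_config(0, FALSE, 0.05))
  expect_equal(n_sites(res$gm), 2)
  expect_true(all(site_stats(res$gm)$maf >= 0.05))
})

test_that("filtering is idempotent and all-removed is an explicit error", {
  gm <- random_gm(12, 80, missing = 0.3, seed = 9)
  cfg <- filter_config(0.6, TRUE, 0.1)
  once <- apply_filters(gm, cfg)
  twice <- apply_filters(once$gm, cfg)
  expect_identical(twice$gm$calls, once$gm$calls)
  expect_equal(twice$report$n_sites_output, once$report$n_sites_output)
  expect_equal(twice$report$n_sites_input, once$report$n_sites_output)
  # post-hoc invariants on the output
  st <- site_stats(once$gm)
  expect_true(all(st$call_rate >= 0.6))
  expect_true(all(st$maf >= 0.1))
  expect_true(!anyDuplicated(once$gm$sites$locus_id))

  mono <- make_gm(matrix(0L, nrow = 4, ncol = 3))
  expect_error(apply_filters(mono, filter_config(0, FALSE, 0.05)),
               "empty matrix after filtering")
})

test_that("pairwise_shared_sites keeps exactly the co-called sites in order", {
  calls <- rbind(a = c(0L, 1L, NA, 2L, 1L, NA, 0L, 1L, 2L, 0L),
                 b = c(1L, NA, 1L, 2L, 0L, NA, 0L, 1L, 2L, 1L),
                 c = rep(0L, 10))
  gm <- make_gm(calls, samples = c("a", "b", "c"))
  shared <- pairwise_shared_sites(gm, "a", "b")
  expect_equal(n_sites(shared), 7)  # drops sites 2, 3, 6
  expect_equal(shared$sites$chrom, gm$sites$chrom[-c(2, 3, 6)])
  # no missing data in the pair -> everything retained
  expect_equal(n_sites(pairwise_shared_sites(gm, "a", "c")), 8)
  expect_error(pairwise_shared_sites(gm, "a", "a"), "distinct")
  expect_error(pairwise_shared_sites(gm, "a", "zz"), "unknown sample")
})

test_that("sample metadata reader accepts TSV and CSV and validates columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tpopulation\tsite", "a\tP1\tx", "b\tP2\ty"), f)
  md <- read_sample_metadata(f)
  expect_equal(md$population, c("P1", "P2"))
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,population", "a,P1"), f2)
  expect_equal(read_sample_metadata(f2)$sample_id, "a")
  writeLines(c("id,pop", "a,P1"), f2)
  expect_error(read_sample_metadata(f2), "sample_id")
})
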