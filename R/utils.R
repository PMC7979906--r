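#' Round half away from zero
#'
#' Decimal rounding where exact halves round up in magnitude (so 48.55 ->
#' 48.6), matching the convention used when reporting percentages. Base
#' [round()] rounds half to even, which disagrees on ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# md5 of an R object via its serialization; used to stamp outputs with a
# config fingerprint (carried as comment headers / manifest lines).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 keeps the stream stable across R minor versions
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# write a data.frame as TSV with provenance comment lines
write_stamped_table <- function(df, path, stamp = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
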