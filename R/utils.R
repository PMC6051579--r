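#' @keywords internal
"_PACKAGE"

# round half away from zero (base round() is round-half-even, which would
# turn 28.5 into 28 and break reproduction of printed percentages)
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# derive an independent 31-bit sub-seed from a master seed and a stream name,
# so tree / sequence / spore / profile randomness can be regenerated alone
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "ganokey")
  if (!nzchar(p)) stop("shipped data file not found: ", file)
  p
}

read_tsv_strict <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA", ...)
}

write_tsv_strict <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}
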