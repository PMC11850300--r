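#' Define a genome from chromosome sizes
#'
#' A genome is the reference frame for every interval operation in the
#' package: a table of chromosome names and lengths in base pairs. All
#' coordinates throughout the package are 0-based, half-open (BED
#' convention).
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Numeric vector of chromosome lengths in bp (all `> 0`).
#'
#' @return A tibble with columns `chrom` and `length`, of class
#'   `triadr_genome`.
#' @examples
#' gen <- genome(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) != base::length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  if (anyDuplicated(chrom)) abort("chromosome names must be unique.")
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("all chromosome lengths must be finite and > 0.")
  }
  out <- tibble(chrom = chrom, length = length)
  class(out) <- c("triadr_genome", class(out))
  out
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp (the UCSC `chrom.sizes`
#' dialect).
#'
#' @param path Path to the file.
#' @return A [genome()] tibble.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  genome(x$chrom, x$length)
}

#' Write a chrom.sizes file
#' @param gen A [genome()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(gen, path) {
  readr::write_tsv(gen[, c("chrom", "length")], path, col_names = FALSE)
  invisible(path)
}

# length of one chromosome, with a clear error for unknown names
chrom_length <- function(gen, chrom) {
  i <- match(chrom, gen$chrom)
  if (anyNA(i)) {
    abort(paste0("unknown chromosome(s): ",
                 paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  gen$length[i]
}
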