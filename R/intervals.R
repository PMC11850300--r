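#' Genomic interval arithmetic on tibbles
#'
#' All interval tables in the package share the columns `chrom`, `start`,
#' `end` (0-based, half-open) and optionally `strand` (`"+"`, `"-"`, `"."`).
#' These helpers are vectorised over rows.
#'
#' @name interval-ops
NULL

# interval table -> GRanges (half-open 0-based -> 1-based closed)
as_granges <- function(x, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = x[[chrom]],
    ranges = IRanges::IRanges(start = x[[start]] + 1L, end = x[[end]])
  )
}

# overlap join between two interval tables; returns tibble of index pairs
# with the overlap length in bp; minoverlap in bp (>= 1)
overlap_pairs <- function(a, b, minoverlap = 1L,
                          a_cols = c("chrom", "start", "end"),
                          b_cols = c("chrom", "start", "end")) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(a_idx = integer(), b_idx = integer(), overlap = numeric()))
  }
  ga <- as_granges(a, a_cols[1], a_cols[2], a_cols[3])
  gb <- as_granges(b, b_cols[1], b_cols[2], b_cols[3])
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = minoverlap)
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a[[a_cols[3]]][ai], b[[b_cols[3]]][bi]) -
    pmax(a[[a_cols[2]]][ai], b[[b_cols[2]]][bi])
  tibble(a_idx = ai, b_idx = bi, overlap = as.numeric(ov))
}

#' Length of the intersection of two intervals
#'
#' Returns `max(0, min(ends) - max(starts))` when both intervals lie on the
#' same chromosome, and 0 otherwise. Vectorised; the shorter input is
#' recycled.
#'
#' @param a,b Interval tibbles (columns `chrom`, `start`, `end`), or
#'   single-row data frames.
#' @return Numeric vector of shared base pairs.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 150, end = 250)
#' intersect_length(a, b) # 50
#' @export
intersect_length <- function(a, b) {
  same <- a$chrom == b$chrom
  ifelse(same, pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start)), 0)
}

#' Extend intervals, clamped to chromosome bounds
#'
#' Widens each interval by `left` bp downstream of `start` and `right` bp
#' past `end`, clamping at 0 and at the chromosome length. Strand and all
#' other columns are preserved.
#'
#' @param x Interval tibble.
#' @param gen A [genome()] tibble; unknown chromosomes are an error.
#' @param left,right Non-negative extensions in bp.
#' @return `x` with updated `start`/`end`.
#' @export
extend_intervals <- function(x, gen, left = 0, right = 0) {
  stopifnot(left >= 0, right >= 0)
  len <- chrom_length(gen, x$chrom)
  x$start <- pmax(0, x$start - left)
  x$end <- pmin(len, x$end + right)
  x
}

# integer midpoint position of each interval (a point p in [start, end))
interval_midpoint <- function(x) {
  floor((x$start + x$end) / 2)
}

#' Label intervals by a labeled track
#'
#' Looks up, for the midpoint of each interval, the label of the track
#' interval containing it. Tracks are genome partitions such as A/B
#' compartments or grouped chromatin states: per-chromosome non-overlapping
#' intervals with a `label` column. A midpoint falling in a track gap gets
#' `default` if given, otherwise an error is raised. The midpoint rule makes
#' a peak's label stable under symmetric extension.
#'
#' @param x Interval tibble.
#' @param track Labeled track tibble (`chrom`, `start`, `end`, `label`).
#' @param default Optional gap label (e.g. `"."`).
#' @return Character vector of labels, one per row of `x`.
#' @export
label_of <- function(x, track, default = NULL) {
  if (nrow(x) == 0L) return(character())
  mids <- tibble(chrom = x$chrom, start = interval_midpoint(x))
  mids$end <- mids$start + 1
  labs <- rep(NA_character_, nrow(x))
  if (nrow(track) > 0L) {
    hits <- overlap_pairs(mids, track)
    labs[hits$a_idx] <- track$label[hits$b_idx]
  }
  if (anyNA(labs)) {
    if (is.null(default)) {
      abort("some interval midpoints fall in track gaps and no `default` label was given.")
    }
    labs[is.na(labs)] <- default
  }
  labs
}

#' Per-bin coverage of an interval set
#'
#' Merges overlapping intervals, then counts covered base pairs per fixed
#' genomic bin. Every chromosome of the genome is represented, including
#' those with no intervals; the sum of `covered_bp` equals the merged
#' coverage footprint.
#'
#' @param x Interval tibble (may be empty).
#' @param gen A [genome()] tibble.
#' @param bin_size Bin width in bp (> 0).
#' @return Tibble with `chrom`, `bin` (1-based index), `start`, `end`,
#'   `covered_bp`.
#' @export
binned_coverage <- function(x, gen, bin_size) {
  stopifnot(bin_size > 0)
  bins <- purrr::map(seq_len(nrow(gen)), function(i) {
    L <- gen$length[i]
    nb <- ceiling(L / bin_size)
    s <- (seq_len(nb) - 1) * bin_size
    tibble(chrom = gen$chrom[i], bin = seq_len(nb),
           start = s, end = pmin(s + bin_size, L), covered_bp = 0)
  }) |> list_rbind()
  if (nrow(x) == 0L) return(bins)
  merged <- merge_intervals(x)
  hits <- overlap_pairs(bins, merged)
  if (nrow(hits) > 0L) {
    per_bin <- hits |>
      group_by(.data$a_idx) |>
      summarise(cov = sum(.data$overlap), .groups = "drop")
    bins$covered_bp[per_bin$a_idx] <- per_bin$cov
  }
  bins
}

# merge overlapping/adjacent-overlap intervals per chromosome (union)
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  g <- GenomicRanges::reduce(as_granges(x))
  tibble(chrom = as.character(GenomicRanges::seqnames(g)),
         start = GenomicRanges::start(g) - 1,
         end = as.numeric(GenomicRanges::end(g)))
}
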