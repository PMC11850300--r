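#' Readers and writers for the file dialects the pipeline touches
#'
#' Coordinates are 0-based half-open on disk (BED convention) and in
#' memory, so readers pass them through unchanged. Peak q-values travel in
#' the BED score column as `-log10(q)` (MACS2 narrowPeak convention);
#' the native narrowPeak reader takes q from column 9.
#'
#' @name triadr-io
NULL

bed6_cols <- c("chrom", "start", "end", "name", "score", "strand")

#' Read a BED3/BED6 file of peaks
#'
#' @param path Path to a BED file (3 or 6 columns, no header).
#' @param kind Peak kind: `"PD"` (protein--DNA), `"PR"` (protein--RNA) or
#'   `"RD"` (RNA--DNA).
#' @param owner Owner identifier (protein or RNA) applied to every row; if
#'   `NULL`, the BED name column is used.
#' @param score_is_qlog If `TRUE` (default) the score column is interpreted
#'   as `-log10(q)` and converted back to a q-value.
#' @return A peak tibble: `chrom`, `start`, `end`, `strand`, `owner`,
#'   `q_value`, `kind`.
#' @export
read_peaks_bed <- function(path, kind = c("PD", "PR", "RD"), owner = NULL,
                           score_is_qlog = TRUE) {
  kind <- match.arg(kind)
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  ncol_x <- ncol(x)
  if (ncol_x < 3L) abort("BED file must have at least 3 columns.")
  names(x)[seq_len(min(6L, ncol_x))] <- bed6_cols[seq_len(min(6L, ncol_x))]
  out <- tibble(
    chrom = as.character(x$chrom),
    start = as.numeric(x$start),
    end = as.numeric(x$end),
    strand = if ("strand" %in% names(x)) as.character(x$strand) else ".",
    owner = if (!is.null(owner)) owner
            else if ("name" %in% names(x)) as.character(x$name) else NA_character_,
    q_value = if ("score" %in% names(x) && score_is_qlog)
                10^(-as.numeric(x$score)) else 1,
    kind = kind
  )
  out
}

#' Read a MACS2 narrowPeak file
#'
#' Ten columns; q-value is `-log10(q)` in column 9.
#'
#' @inheritParams read_peaks_bed
#' @return A peak tibble (see [read_peaks_bed()]).
#' @export
read_narrowpeak <- function(path, kind = "PD", owner = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  if (ncol(x) < 9L) abort("narrowPeak file must have at least 9 columns.")
  tibble(
    chrom = as.character(x[[1]]),
    start = as.numeric(x[[2]]),
    end = as.numeric(x[[3]]),
    strand = as.character(x[[6]]),
    owner = if (!is.null(owner)) owner else as.character(x[[4]]),
    q_value = 10^(-as.numeric(x[[9]])),
    kind = kind
  )
}

#' Write peaks as BED6
#'
#' The score column carries `-log10(q)`.
#'
#' @param x Peak tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(x, path) {
  out <- tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$owner %||% ".",
    score = if ("q_value" %in% names(x)) round(-log10(x$q_value), 5) else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a labeled track (A/B compartments, grouped chromatin states)
#'
#' BED with the label in the name column.
#'
#' @param path Path to a BED file (>= 4 columns).
#' @param alphabet Optional allowed label set; labels outside it are an
#'   error.
#' @return Tibble `chrom`, `start`, `end`, `label`, sorted, with
#'   per-chromosome non-overlap enforced.
#' @export
read_labeled_track <- function(path, alphabet = NULL) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(),
                       progress = FALSE)
  if (ncol(x) < 4L) abort("labeled track BED needs at least 4 columns (label in column 4).")
  out <- tibble(chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
                end = as.numeric(x[[3]]), label = as.character(x[[4]])) |>
    arrange(chrom, start)
  if (!is.null(alphabet) && !all(out$label %in% alphabet)) {
    abort("track labels outside the declared alphabet.")
  }
  bad <- out |>
    group_by(chrom) |>
    summarise(ov = any(start[-1] < end[-length(end)]), .groups = "drop")
  if (any(bad$ov)) abort("labeled track has overlapping intervals within a chromosome.")
  out
}

#' Write a labeled track as BED4
#' @param track Labeled track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled_track <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "label")], path,
                   col_names = FALSE)
  invisible(path)
}

contact_cols <- c("rna_chrom", "rna_start", "rna_end", "rna_strand",
                  "rna_id", "biotype", "dna_chrom", "dna_start", "dna_end",
                  "experiment")

#' Read RNA--DNA contacts
#'
#' BEDPE-like TSV with a header; one row per RNA--DNA contact: the RNA part
#' (stranded interval on the RNA's source gene, with gene ID and biotype)
#' and the DNA part (the chromatin locus), plus an experiment tag.
#'
#' @param path Path to the TSV.
#' @return Contact tibble with columns `rna_chrom`, `rna_start`, `rna_end`,
#'   `rna_strand`, `rna_id`, `biotype`, `dna_chrom`, `dna_start`, `dna_end`,
#'   `experiment`.
#' @export
read_contacts <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(contact_cols, names(x))
  if (length(missing) > 0L) {
    abort(paste0("contacts file lacks columns: ", paste(missing, collapse = ", ")))
  }
  as_tibble(x)
}

#' Write RNA--DNA contacts
#' @param x Contact tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(x, path) {
  readr::write_tsv(x[, intersect(c(contact_cols, "q_bardic"), names(x))], path)
  invisible(path)
}

triad_cols <- c("rna_id", "biotype", "protein", "dna_chrom", "dna_start",
                "dna_end", "overlap_pd", "overlap_pr", "q_piranha",
                "q_macs2", "q_bardic", "hmq")

#' Write triads
#' @param x Triad tibble from [build_triads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triads <- function(x, path) {
  readr::write_tsv(x[, intersect(triad_cols, names(x))], path)
  invisible(path)
}

#' Read triads written by [write_triads()]
#' @param path Path to the TSV.
#' @return Triad tibble.
#' @export
read_triads <- function(path) {
  as_tibble(readr::read_tsv(path, col_types = readr::cols(), progress = FALSE))
}

#' Read a raw-state to grouped-state mapping
#'
#' Two-column TSV (raw state name, group name), no header, used to collapse
#' ChromHMM/SPIN annotations into analysis groups.
#'
#' @param path Path to the TSV.
#' @return Tibble `state`, `group`.
#' @export
read_state_groups <- function(path) {
  readr::read_tsv(path, col_names = c("state", "group"), col_types = "cc",
                  progress = FALSE)
}
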