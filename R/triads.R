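#' Keep contacts that fall within RNA--DNA peaks of their own RNA
#'
#' RNA--chromatin interactome data are dominated by nonspecific contacts;
#' only contacts supported by a binomial RNA--DNA peak (BaRDIC-style, called
#' per RNA) are retained. A contact survives iff its DNA part overlaps
#' (>= `min_overlap` bp) a peak owned by the same RNA. The q-value of the
#' best-overlapping peak (tie: smaller start) is attached as `q_bardic`.
#'
#' @param contacts Contact tibble (see [read_contacts()]).
#' @param rd_peaks Peak tibble with `owner` = RNA gene ID and `q_value`.
#' @param min_overlap Minimum DNA-part overlap in bp (default 1).
#' @return The surviving contacts, input order preserved, with a `q_bardic`
#'   column added.
#' @export
filter_rd_by_peaks <- function(contacts, rd_peaks, min_overlap = 1L) {
  if (nrow(contacts) == 0L || nrow(rd_peaks) == 0L) {
    out <- contacts[integer(0), ]
    out$q_bardic <- numeric(0)
    return(out)
  }
  hits <- overlap_pairs(contacts, rd_peaks, minoverlap = min_overlap,
                        a_cols = c("dna_chrom", "dna_start", "dna_end"))
  hits <- hits[contacts$rna_id[hits$a_idx] == rd_peaks$owner[hits$b_idx], ]
  if (nrow(hits) == 0L) {
    out <- contacts[integer(0), ]
    out$q_bardic <- numeric(0)
    return(out)
  }
  best <- hits |>
    mutate(peak_start = rd_peaks$start[.data$b_idx]) |>
    group_by(.data$a_idx) |>
    arrange(dplyr::desc(.data$overlap), .data$peak_start) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$a_idx)
  out <- contacts[best$a_idx, ]
  out$q_bardic <- rd_peaks$q_value[best$b_idx]
  out
}

#' Extend protein--DNA (ChIP-seq) peaks
#'
#' Interactome protocols ligate at restriction sites that may lie away from
#' the true contact; ChIP peaks are therefore widened symmetrically
#' (default 2 kb each side) before intersection.
#'
#' @param peaks PD peak tibble.
#' @param gen A [genome()] tibble.
#' @param ext Extension in bp applied to both sides (default 2000).
#' @return Extended peaks, clamped at chromosome bounds.
#' @export
extend_pd_peaks <- function(peaks, gen, ext = 2000) {
  extend_intervals(peaks, gen, left = ext, right = ext)
}

#' Extend protein--RNA peaks toward the 3' end
#'
#' RNA--DNA ligation captures the RNA 3' end, so protein--RNA peaks are
#' extended downstream in transcript orientation (default 100 bp): `end` on
#' the `+` strand, `start` on the `-` strand.
#'
#' @param peaks Stranded PR peak tibble; strand `"."` is an error.
#' @param gen A [genome()] tibble.
#' @param ext Extension in bp (default 100).
#' @return Extended peaks, clamped at chromosome bounds.
#' @export
extend_pr_peaks <- function(peaks, gen, ext = 100) {
  if (nrow(peaks) == 0L) return(peaks)
  if (any(!peaks$strand %in% c("+", "-"))) {
    abort("PR peaks must be stranded (+/-): the 3' direction is undefined otherwise.")
  }
  len <- chrom_length(gen, peaks$chrom)
  plus <- peaks$strand == "+"
  peaks$end <- ifelse(plus, pmin(len, peaks$end + ext), peaks$end)
  peaks$start <- ifelse(plus, peaks$start, pmax(0, peaks$start - ext))
  peaks
}

#' Harmonic-mean q-value of a triad
#'
#' Aggregates the significance of the three pairwise peaks a triad is
#' assembled from (protein--RNA, protein--DNA, RNA--DNA) into
#' `HMQ = 3 / (1/q_PR + 1/q_PD + 1/q_RD)`. The harmonic mean is dominated
#' by the most significant component and always lies between the smallest
#' and largest of the three q-values.
#'
#' @param q_piranha,q_macs2,q_bardic q-values in `(0, 1]`; vectorised.
#' @return Numeric vector of HMQ values.
#' @examples
#' compute_hmq(0.01, 0.02, 0.04) # 3/175
#' @export
compute_hmq <- function(q_piranha, q_macs2, q_bardic) {
  if (any(c(q_piranha, q_macs2, q_bardic) <= 0)) {
    abort("q-values must be > 0.")
  }
  3 / (1 / q_piranha + 1 / q_macs2 + 1 / q_bardic)
}

# best hit per contact for one side of the triad; returns tibble
# (contact_idx, protein, peak_idx, overlap)
best_side_hits <- function(hits, peaks, by_protein = TRUE) {
  hits |>
    mutate(protein = peaks$owner[.data$b_idx],
           peak_start = peaks$start[.data$b_idx]) |>
    group_by(.data$a_idx, .data$protein) |>
    arrange(dplyr::desc(.data$overlap), .data$peak_start) |>
    dplyr::slice(1L) |>
    ungroup()
}

#' Build RNA--protein--DNA triads
#'
#' The core assembly step: a contact forms a triad with a protein iff its
#' DNA part overlaps an (extended) ChIP-seq peak of that protein by at
#' least `min_overlap` bp AND its RNA part overlaps an (extended)
#' protein--RNA peak of the same protein annotated to the contact's RNA by
#' at least `min_overlap` bp. Intersections shorter than 19 bases are
#' discarded by default: short touches are mostly incidental adjacency, not
#' evidence of mediation. When several peaks qualify on a side, the one
#' with maximal overlap is recorded (tie: smaller start). A contact may
#' seed triads with several proteins.
#'
#' @param contacts Contact tibble, ideally pre-filtered by
#'   [filter_rd_by_peaks()] so it carries `q_bardic`; if absent, `q_bardic`
#'   is taken as 1 (uninformative).
#' @param pd_peaks PD peak tibble (all proteins together, `owner` =
#'   protein), already extended via [extend_pd_peaks()].
#' @param pr_peaks PR peak tibble (`owner` = protein, `rna_id` = annotated
#'   gene), already extended via [extend_pr_peaks()].
#' @param min_overlap Minimum intersection in bp on each side (default 19).
#' @return Triad tibble: `rna_id`, `biotype`, `protein`, `dna_chrom`,
#'   `dna_start`, `dna_end`, `overlap_pd`, `overlap_pr`, `q_piranha`,
#'   `q_macs2`, `q_bardic`, `hmq`, plus `contact_idx` (row of `contacts`).
#'   Sorted by (`protein`, `contact_idx`) for reproducibility.
#' @export
build_triads <- function(contacts, pd_peaks, pr_peaks, min_overlap = 19L) {
  stopifnot(min_overlap >= 1L)
  empty <- tibble(
    rna_id = character(), biotype = character(), protein = character(),
    dna_chrom = character(), dna_start = numeric(), dna_end = numeric(),
    overlap_pd = numeric(), overlap_pr = numeric(),
    q_piranha = numeric(), q_macs2 = numeric(), q_bardic = numeric(),
    hmq = numeric(), contact_idx = integer()
  )
  if (nrow(contacts) == 0L || nrow(pd_peaks) == 0L || nrow(pr_peaks) == 0L) {
    return(empty)
  }
  qb <- if ("q_bardic" %in% names(contacts)) contacts$q_bardic else rep(1, nrow(contacts))

  pd_hits <- overlap_pairs(contacts, pd_peaks, minoverlap = min_overlap,
                           a_cols = c("dna_chrom", "dna_start", "dna_end"))
  if (nrow(pd_hits) == 0L) return(empty)
  pd_best <- best_side_hits(pd_hits, pd_peaks)

  pr_hits <- overlap_pairs(contacts, pr_peaks, minoverlap = min_overlap,
                           a_cols = c("rna_chrom", "rna_start", "rna_end"))
  pr_hits <- pr_hits[contacts$rna_id[pr_hits$a_idx] == pr_peaks$rna_id[pr_hits$b_idx], ]
  if (nrow(pr_hits) == 0L) return(empty)
  pr_best <- best_side_hits(pr_hits, pr_peaks)

  joined <- inner_join(
    pd_best |> select(a_idx = "a_idx", protein = "protein",
                      pd_idx = "b_idx", overlap_pd = "overlap"),
    pr_best |> select(a_idx = "a_idx", protein = "protein",
                      pr_idx = "b_idx", overlap_pr = "overlap"),
    by = c("a_idx", "protein")
  )
  if (nrow(joined) == 0L) return(empty)
  ci <- joined$a_idx
  tibble(
    rna_id = contacts$rna_id[ci],
    biotype = contacts$biotype[ci],
    protein = joined$protein,
    dna_chrom = contacts$dna_chrom[ci],
    dna_start = contacts$dna_start[ci],
    dna_end = contacts$dna_end[ci],
    overlap_pd = joined$overlap_pd,
    overlap_pr = joined$overlap_pr,
    q_piranha = pr_peaks$q_value[joined$pr_idx],
    q_macs2 = pd_peaks$q_value[joined$pd_idx],
    q_bardic = qb[ci],
    hmq = compute_hmq(pr_peaks$q_value[joined$pr_idx],
                      pd_peaks$q_value[joined$pd_idx], qb[ci]),
    contact_idx = ci
  ) |>
    arrange(protein, .data$contact_idx)
}

# do two record sets share a contact? same RNA + DNA-part overlap >= min bp
shared_contact_hits <- function(a, b, min_overlap = 1L) {
  hits <- overlap_pairs(a, b, minoverlap = min_overlap,
                        a_cols = c("dna_chrom", "dna_start", "dna_end"),
                        b_cols = c("dna_chrom", "dna_start", "dna_end"))
  hits[a$rna_id[hits$a_idx] == b$rna_id[hits$b_idx], ]
}

#' Remove triads shared with a non-protein-mediated control
#'
#' Proteinase-treated (NPM) RNA--DNA contacts capture ligation noise with
#' no protein mediation; 2FA triads whose contact also appears there are
#' discarded. Two records are "shared" when the RNA gene is identical and
#' the DNA parts overlap by at least `min_overlap` bp.
#'
#' @param triads_2fa Triad (or contact) tibble to clean; needs `rna_id`,
#'   `dna_chrom`, `dna_start`, `dna_end`.
#' @param triads_npm Control tibble with the same columns.
#' @param min_overlap Minimum DNA-part overlap in bp defining "shared"
#'   (default 1).
#' @return The cleaned subset of `triads_2fa`, order preserved.
#' @export
subtract_npm <- function(triads_2fa, triads_npm, min_overlap = 1L) {
  if (nrow(triads_2fa) == 0L || nrow(triads_npm) == 0L) return(triads_2fa)
  hits <- shared_contact_hits(triads_2fa, triads_npm, min_overlap)
  if (nrow(hits) == 0L) return(triads_2fa)
  triads_2fa[-sort(unique(hits$a_idx)), ]
}

#' Match shared triads between two datasets
#'
#' Pairs records whose RNA parts belong to the same transcript and whose
#' DNA parts overlap (>= `min_overlap` bp). A record may appear in several
#' pairs.
#'
#' @param set_a,set_b Triad (or contact) tibbles with `rna_id`,
#'   `dna_chrom`, `dna_start`, `dna_end`.
#' @param min_overlap Minimum DNA-part overlap in bp (default 1).
#' @return A list with `pairs` (tibble `a_idx`, `b_idx`, `overlap`),
#'   `shared_a` and `shared_b` (the deduplicated shared subsets).
#' @export
shared_triads <- function(set_a, set_b, min_overlap = 1L) {
  hits <- shared_contact_hits(set_a, set_b, min_overlap)
  list(
    pairs = hits |> rename(overlap_bp = "overlap"),
    shared_a = set_a[sort(unique(hits$a_idx)), ],
    shared_b = set_b[sort(unique(hits$b_idx)), ]
  )
}
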