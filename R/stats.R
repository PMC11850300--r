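#' Classify contacts as cis or trans
#'
#' A contact is trans when the chromosome of the DNA locus differs from
#' the RNA's chromosome of origin, following Hi-C conventions.
#'
#' @param contacts Tibble with `rna_chrom` and `dna_chrom`.
#' @return Character vector, `"cis"` or `"trans"`, one per row.
#' @export
cis_trans_label <- function(contacts) {
  ifelse(contacts$rna_chrom == contacts$dna_chrom, "cis", "trans")
}

#' Paired test for the cis/trans shift under triad filtering
#'
#' Triad construction is expected to deplete the nonspecific cis contacts
#' that distance scaling inflates. For each RNA present both before
#' (raw contacts) and after (triads), the trans-contact fraction is
#' computed in both sets and the paired fractions are compared with a
#' two-sided Wilcoxon signed-rank test (exact when no ties permit it).
#' RNAs with zero difference are dropped, per the standard signed-rank
#' convention; with no nonzero pairs the p-value is 1.
#'
#' @param before Contact tibble (`rna_id`, `rna_chrom`, `dna_chrom`).
#' @param after Triad or contact tibble with `rna_id` and `dna_chrom`;
#'   if it lacks `rna_chrom`, the RNA chromosome is taken from `before`.
#' @return Object of class `cis_trans_shift`: `statistic` (V), `p_value`,
#'   `pairs` (per-RNA tibble of fractions), `n_pairs`, `n_nonzero`.
#' @export
cis_trans_shift_test <- function(before, after) {
  if (!"rna_chrom" %in% names(after)) {
    map <- before |> distinct(.data$rna_id, .data$rna_chrom)
    after <- left_join(after, map, by = "rna_id")
  }
  frac <- function(x) {
    x |>
      group_by(.data$rna_id) |>
      summarise(trans_frac = mean(.data$dna_chrom != .data$rna_chrom),
                .groups = "drop")
  }
  pairs <- inner_join(frac(before), frac(after), by = "rna_id",
                      suffix = c("_before", "_after")) |>
    mutate(diff = .data$trans_frac_after - .data$trans_frac_before)
  if (nrow(pairs) == 0L) abort("no RNA is present in both sets.")
  d <- pairs$diff[pairs$diff != 0]
  if (length(d) == 0L) {
    res <- list(statistic = NA_real_, p_value = 1)
  } else {
    wt <- suppressWarnings(wilcox.test(d, alternative = "two.sided"))
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(c(res, list(pairs = pairs, n_pairs = nrow(pairs),
                        n_nonzero = length(d))),
            class = "cis_trans_shift")
}

#' @export
print.cis_trans_shift <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank test on per-RNA trans fractions\n")
  cat(sprintf("  pairs: %d (%d with nonzero difference)\n",
              x$n_pairs, x$n_nonzero))
  cat(sprintf("  V = %s, p = %.4g\n",
              ifelse(is.na(x$statistic), "NA", format(x$statistic)),
              x$p_value))
  invisible(x)
}

# default geometric distance bin edges: 1 kb to >= 100 Mb, factor 2,
# with a leading [0, 1 kb) bin
default_scaling_edges <- function(d_min = 1e3, d_max = 1e8, factor = 2) {
  k <- ceiling(log(d_max / d_min) / log(factor))
  c(0, d_min * factor^(0:k))
}

#' Distance-scaling weights for the cis contacts of one RNA
#'
#' Contact density declines with genomic distance from the source gene as
#' a power law (RD-scaling), so raw cis contact counts over-represent
#' gene-proximal loci. Contacts are binned by the distance between the
#' DNA-part midpoint and the nearest gene edge (0 inside the gene) using
#' geometric bins, and each contact in bin i receives the weight
#' `W = N(bin_i) / (L(bin_i) * sum(N)) * 1e9`, a per-bp contact density
#' rescaled to a fixed total mass: `sum(W * L)` over bins is always 1e9.
#'
#' @param contacts Contacts of a single RNA; all must be cis to the gene's
#'   chromosome (error otherwise).
#' @param gene_locus Single-row tibble (`chrom`, `start`, `end`) of the
#'   source gene.
#' @param edges Increasing numeric bin edges in bp; defaults to
#'   `[0, 1 kb)` then factor-2 geometric bins up to >= 100 Mb.
#' @return Tibble with one row per bin: `bin`, `lo`, `hi`, `bin_length`,
#'   `n_contacts`, `weight`.
#' @export
scaling_weights <- function(contacts, gene_locus,
                            edges = default_scaling_edges()) {
  if (any(contacts$dna_chrom != gene_locus$chrom)) {
    abort("scaling weights are defined for cis contacts only.")
  }
  m <- (contacts$dna_start + contacts$dna_end) / 2
  d <- pmax(0, gene_locus$start - m, m - gene_locus$end)
  d <- pmin(d, max(edges) - 1) # clamp into the last bin
  bin <- findInterval(d, edges, rightmost.closed = FALSE)
  n_tot <- length(d)
  nb <- length(edges) - 1L
  counts <- tabulate(bin, nbins = nb)
  tibble(
    bin = seq_len(nb),
    lo = edges[-length(edges)],
    hi = edges[-1],
    bin_length = diff(edges),
    n_contacts = counts,
    weight = counts / (diff(edges) * n_tot) * 1e9
  )
}

#' Split proteins by the median chi-squared p-value
#'
#' Proteins whose triad state distribution deviates from their ChIP peak
#' state distribution (small goodness-of-fit p) are candidates for genuine
#' association with the RNA--chromatin interactome. Proteins strictly
#' below the median p go to `"associated"`; the median element and above
#' go to `"other"`.
#'
#' @param p_values Tibble with `protein` and `p_value`.
#' @return The input with a `group` column added.
#' @export
split_by_median_p <- function(p_values) {
  if (nrow(p_values) < 2L) abort("need p-values for at least two proteins.")
  med <- median(p_values$p_value)
  p_values |>
    mutate(group = ifelse(.data$p_value < med, "associated", "other"))
}

#' Partition RNAs into common and specific
#'
#' RNAs forming triads with at least `threshold` distinct proteins are
#' "common" (promiscuous binders); the rest are "specific".
#'
#' @param triads Triad tibble (`rna_id`, `protein`).
#' @param threshold Minimum distinct-protein count for "common"
#'   (default 20).
#' @return Tibble `rna_id`, `n_proteins`, `rna_class`
#'   (`"common"`/`"specific"`).
#' @export
common_specific_split <- function(triads, threshold = 20L) {
  if (nrow(triads) == 0L) {
    return(tibble(rna_id = character(), n_proteins = integer(),
                  rna_class = character()))
  }
  triads |>
    group_by(.data$rna_id) |>
    summarise(n_proteins = dplyr::n_distinct(.data$protein), .groups = "drop") |>
    mutate(rna_class = ifelse(.data$n_proteins >= threshold,
                              "common", "specific"))
}

#' Fisher test of a protein's contact specificity
#'
#' Classifies every RD-contact by whether its RNA is specific (not in the
#' common set) and whether its DNA part overlaps at least one ChIP-seq
#' locus of the protein, and tests the 2x2 table (specific/common x
#' overlap/no overlap) with a two-sided Fisher exact test. A protein able
#' to form specific contacts shows an excess of specific RNAs at its own
#' DNA loci.
#'
#' @param contacts Contact tibble.
#' @param chip_peaks ChIP peak tibble of the protein under test.
#' @param common_rnas Character vector of common RNA ids (from
#'   [common_specific_split()]).
#' @param min_overlap Minimum DNA overlap in bp to count as overlapping
#'   (default 1).
#' @return List: `odds_ratio`, `p_value`, `table` (2x2 matrix). A table
#'   with an empty margin gives `p_value = 1` with a warning.
#' @export
fisher_specificity <- function(contacts, chip_peaks, common_rnas,
                               min_overlap = 1L) {
  specific <- !(contacts$rna_id %in% common_rnas)
  overlaps <- rep(FALSE, nrow(contacts))
  if (nrow(chip_peaks) > 0L && nrow(contacts) > 0L) {
    hits <- overlap_pairs(contacts, chip_peaks, minoverlap = min_overlap,
                          a_cols = c("dna_chrom", "dna_start", "dna_end"))
    overlaps[unique(hits$a_idx)] <- TRUE
  }
  tab <- matrix(c(sum(specific & overlaps), sum(specific & !overlaps),
                  sum(!specific & overlaps), sum(!specific & !overlaps)),
                nrow = 2, byrow = TRUE,
                dimnames = list(rna = c("specific", "common"),
                                dna = c("overlap", "no_overlap")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate margin in the specificity table; p = 1.")
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Jaccard similarity of triad datasets by shared RNAs
#'
#' @param triad_sets Named list; each element a triad tibble (its
#'   `rna_id` column is used) or a character vector of RNA ids.
#' @return Symmetric similarity matrix with unit diagonal; a pair of empty
#'   sets scores 0 (with a message).
#' @export
jaccard_rna_similarity <- function(triad_sets) {
  sets <- lapply(triad_sets, function(x) {
    if (is.data.frame(x)) unique(x$rna_id) else unique(as.character(x))
  })
  k <- length(sets)
  M <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0L) {
        inform("both RNA sets empty; Jaccard set to 0 by convention.")
        M[i, j] <- 0
      } else {
        M[i, j] <- length(intersect(sets[[i]], sets[[j]])) / u
      }
    }
  }
  M
}

#' Density of DNA loci per compartment
#'
#' Number of DNA parts whose midpoint lies in each compartment label,
#' normalised by the total length of that label -- loci per bp.
#'
#' @param dna_parts Interval tibble (`chrom`, `start`, `end`) or a triad
#'   tibble (its `dna_*` columns are used).
#' @param compartments Labeled track tibble.
#' @param gen A [genome()] tibble (unused lengths, kept for interface
#'   symmetry).
#' @return Tibble `label`, `n_parts`, `label_bp`, `density`. Zero-length
#'   labels are excluded.
#' @export
compartment_density <- function(dna_parts, compartments, gen) {
  dna_parts <- as_dna_parts(dna_parts)
  sizes <- compartments |>
    group_by(.data$label) |>
    summarise(label_bp = sum(.data$end - .data$start), .groups = "drop") |>
    filter(.data$label_bp > 0)
  labs <- if (nrow(dna_parts) > 0L) {
    label_of(dna_parts, compartments, default = ".")
  } else character()
  counts <- tibble(label = labs) |> count(.data$label, name = "n_parts")
  sizes |>
    left_join(counts, by = "label") |>
    mutate(n_parts = ifelse(is.na(.data$n_parts), 0L, .data$n_parts),
           density = .data$n_parts / .data$label_bp) |>
    select("label", "n_parts", "label_bp", "density")
}

# accept either a plain interval table or a triad/contact table
as_dna_parts <- function(x) {
  if (all(c("chrom", "start", "end") %in% names(x))) {
    tibble(chrom = x$chrom, start = x$start, end = x$end)
  } else if (all(c("dna_chrom", "dna_start", "dna_end") %in% names(x))) {
    tibble(chrom = x$dna_chrom, start = x$dna_start, end = x$dna_end)
  } else {
    abort("need columns chrom/start/end or dna_chrom/dna_start/dna_end.")
  }
}

#' Fold change of protein--RNA interaction per gene
#'
#' The binding signal of a gene is the ratio of its count fraction in the
#' immunoprecipitation replicate to that in the control replicate, each
#' stabilised with a pseudo-count added to the fractions: genes absent
#' from both replicates get FC = 1.
#'
#' @param gene_counts Tibble with `gene`, `count_exp`, `count_ctrl`.
#' @param pseudo Pseudo-count added to each fraction (default 0.01).
#' @return The input with `f_exp`, `f_ctrl` and `fold_change` columns.
#' @export
pr_fold_change <- function(gene_counts, pseudo = 0.01) {
  tot_e <- sum(gene_counts$count_exp)
  tot_c <- sum(gene_counts$count_ctrl)
  if (tot_e <= 0 || tot_c <= 0) abort("replicate totals must be > 0.")
  gene_counts |>
    mutate(f_exp = .data$count_exp / tot_e,
           f_ctrl = .data$count_ctrl / tot_c,
           fold_change = (.data$f_exp + pseudo) / (.data$f_ctrl + pseudo))
}

#' Format a percentage the way the consistency tables print it
#'
#' Round-half-even to two decimals, trailing zeros trimmed
#' (`2.9022 -> "2.9"`, `21.959 -> "21.96"`).
#'
#' @param x Numeric vector of percentages.
#' @return Character vector.
#' @export
format_pct <- function(x) {
  s <- formatC(round(x, 2), format = "f", digits = 2)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}
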