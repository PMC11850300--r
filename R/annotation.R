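#' Distribution of DNA parts over chromatin-state groups
#'
#' For each state group, the share of triad DNA parts falling in it and
#' the share of the covered genome it occupies; their ratio is the
#' normalized density (values > 1 mean enrichment). Two weighting modes:
#' `"bp"` divides the total annotated length of the DNA parts by the total
#' part length; `"count"` uses DNA-part midpoints, matching how ChIP peak
#' distributions are usually summarised.
#'
#' @param dna_parts Interval tibble or a triad tibble (`dna_*` columns).
#' @param states Labeled track tibble (grouped ChromHMM/SPIN states).
#' @param gen A [genome()] tibble.
#' @param weight `"bp"` or `"count"`.
#' @return Tibble of class `state_distribution`: `label`, `amount`,
#'   `fraction`, `genome_bp`, `genome_fraction`, `normalized_density`.
#'   States with zero genome bp are excluded with a warning; midpoints in
#'   track gaps are dropped from the numerator.
#' @export
state_distribution <- function(dna_parts, states, gen,
                               weight = c("bp", "count")) {
  weight <- match.arg(weight)
  dna_parts <- as_dna_parts(dna_parts)
  genome_tab <- states |>
    group_by(.data$label) |>
    summarise(genome_bp = sum(.data$end - .data$start), .groups = "drop")
  if (any(genome_tab$genome_bp == 0)) {
    warn("states with zero genome bp excluded.")
    genome_tab <- genome_tab |> filter(.data$genome_bp > 0)
  }
  if (weight == "bp") {
    hits <- overlap_pairs(dna_parts, states)
    amounts <- hits |>
      mutate(label = states$label[.data$b_idx]) |>
      group_by(.data$label) |>
      summarise(amount = sum(.data$overlap), .groups = "drop")
  } else {
    labs <- if (nrow(dna_parts) > 0L) {
      label_of(dna_parts, states, default = ".")
    } else character()
    amounts <- tibble(label = labs) |>
      filter(.data$label != ".") |>
      count(.data$label, name = "amount")
  }
  out <- genome_tab |>
    left_join(amounts, by = "label") |>
    mutate(amount = ifelse(is.na(.data$amount), 0, .data$amount))
  tot <- sum(out$amount)
  out <- out |>
    mutate(fraction = if (tot > 0) .data$amount / tot else 0,
           genome_fraction = .data$genome_bp / sum(.data$genome_bp),
           normalized_density = .data$fraction / .data$genome_fraction) |>
    select("label", "amount", "fraction", "genome_bp", "genome_fraction",
           "normalized_density")
  class(out) <- c("state_distribution", class(out))
  out
}

#' Chi-squared goodness-of-fit of triad states against ChIP states
#'
#' Triad construction samples from a protein's ChIP loci; if the protein
#' is not involved with the RNA interactome this sampling is random and
#' the state distribution of triad DNA parts should match that of its
#' ChIP peaks. The test compares observed per-state counts against
#' expected proportions taken from the ChIP distribution. States with an
#' expected count below `min_expected` are merged into `"other"` before
#' testing (standard chi-squared validity rule).
#'
#' @param triad_dist [state_distribution()] of the triad DNA parts
#'   (count-weighted recommended, so `amount` holds counts).
#' @param chip_dist [state_distribution()] of the protein's ChIP peaks;
#'   its `amount` column defines the expected proportions.
#' @param min_expected Merge threshold on expected counts (default 5).
#' @return List of class `state_chisq`: `statistic`, `p_value`, `df`,
#'   `table` (merged observed/expected tibble). Fewer than two categories
#'   after merging is an error.
#' @export
chisq_state_test <- function(triad_dist, chip_dist, min_expected = 5) {
  tab <- dplyr::full_join(
    tibble(label = triad_dist$label, observed = triad_dist$amount),
    tibble(label = chip_dist$label, expected_w = chip_dist$amount),
    by = "label"
  ) |>
    mutate(observed = ifelse(is.na(.data$observed), 0, .data$observed),
           expected_w = ifelse(is.na(.data$expected_w), 0, .data$expected_w))
  n <- sum(tab$observed)
  if (n <= 0) abort("no observed counts.")
  tab$expected <- n * tab$expected_w / sum(tab$expected_w)
  small <- tab$expected < min_expected
  if (any(small)) {
    merged <- tibble(label = "other",
                     observed = sum(tab$observed[small]),
                     expected_w = sum(tab$expected_w[small]),
                     expected = sum(tab$expected[small]))
    tab <- bind_rows(tab[!small, ], merged)
  }
  if (nrow(tab) < 2L) abort("fewer than two categories after merging.")
  ct <- suppressWarnings(
    chisq.test(x = tab$observed, p = tab$expected_w / sum(tab$expected_w))
  )
  structure(list(statistic = unname(ct$statistic),
                 p_value = ct$p.value,
                 df = unname(ct$parameter),
                 table = tab), class = "state_chisq")
}

#' @export
print.state_chisq <- function(x, ...) {
  cat(sprintf("Chi-squared goodness-of-fit: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# centered rolling Pearson correlation over `window` bins, per chromosome;
# returns per-bin correlation and a both-nonzero flag
rolling_window_stats <- function(cov_a, cov_b, window) {
  half <- floor(window / 2)
  n <- length(cov_a)
  corr <- rep(NA_real_, n)
  nonzero <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    wa <- cov_a[lo:hi]
    wb <- cov_b[lo:hi]
    nonzero[i] <- sum(wa) > 0 && sum(wb) > 0
    if (stats::sd(wa) > 0 && stats::sd(wb) > 0) {
      corr[i] <- cor(wa, wb)
    }
  }
  list(corr = corr, nonzero = nonzero)
}

#' Cross-protocol consistency of two triad datasets
#'
#' RNA--chromatin interactome protocols agree only over broad regions, so
#' the DNA parts of both datasets are extended (default +/-500 kb),
#' reduced to binned coverage tracks (default 10-kb bins), and compared by
#' a centered sliding-window Pearson correlation (default 50 bins). A
#' contact is consistent when its unextended DNA-part midpoint falls in a
#' bin whose window correlation reaches `corr_threshold` with both tracks
#' nonzero there. Percentages are rendered with [format_pct()].
#'
#' @param triads_a,triads_b Nonempty triad/contact tibbles.
#' @param gen A [genome()] tibble.
#' @param ext Extension applied to each DNA part, bp each side
#'   (default 5e5).
#' @param bin_size Coverage bin width in bp (default 1e4).
#' @param window Sliding window width in bins (default 50).
#' @param corr_threshold Consistency threshold on the local correlation
#'   (default 0.5).
#' @return List: `n_consistent_a`, `n_consistent_b`, `pct_a`, `pct_b`
#'   (formatted strings), `pct_a_num`, `pct_b_num`, and `windows` (per-bin
#'   tibble with `corr` and `nonzero`).
#' @export
cross_experiment_consistency <- function(triads_a, triads_b, gen,
                                         ext = 5e5, bin_size = 1e4,
                                         window = 50L,
                                         corr_threshold = 0.5) {
  if (nrow(triads_a) == 0L || nrow(triads_b) == 0L) {
    abort("both triad sets must be nonempty.")
  }
  pa <- as_dna_parts(triads_a)
  pb <- as_dna_parts(triads_b)
  cov_a <- binned_coverage(extend_intervals(pa, gen, ext, ext), gen, bin_size)
  cov_b <- binned_coverage(extend_intervals(pb, gen, ext, ext), gen, bin_size)

  win <- cov_a |> select("chrom", "bin", "start", "end")
  win$corr <- NA_real_
  win$nonzero <- FALSE
  for (cc in unique(win$chrom)) {
    idx <- which(win$chrom == cc)
    rs <- rolling_window_stats(cov_a$covered_bp[idx], cov_b$covered_bp[idx],
                               window)
    win$corr[idx] <- rs$corr
    win$nonzero[idx] <- rs$nonzero
  }
  win$consistent_bin <- !is.na(win$corr) & win$corr >= corr_threshold &
    win$nonzero

  is_consistent <- function(parts) {
    m <- interval_midpoint(parts)
    b <- floor(m / bin_size) + 1L
    key_parts <- paste(parts$chrom, b)
    key_win <- paste(win$chrom, win$bin)
    ok <- win$consistent_bin[match(key_parts, key_win)]
    ok[is.na(ok)] <- FALSE
    ok
  }
  ca <- is_consistent(pa)
  cb <- is_consistent(pb)
  list(
    n_consistent_a = sum(ca),
    n_consistent_b = sum(cb),
    pct_a = format_pct(100 * sum(ca) / nrow(pa)),
    pct_b = format_pct(100 * sum(cb) / nrow(pb)),
    pct_a_num = 100 * sum(ca) / nrow(pa),
    pct_b_num = 100 * sum(cb) / nrow(pb),
    windows = win
  )
}
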