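#' Compartment-preserving random shift of ChIP-seq peaks
#'
#' The permutation null for protein--DNA data must preserve two structural
#' features of real ChIP tracks: the peak profile (count and widths) and
#' each peak's A/B-compartment annotation, because open and closed
#' chromatin are unevenly accessible to interactome protocols. Each
#' chromosome draws one signed shift -- magnitude uniform on
#' `magnitudes` (default 1, 3, 5, 7 or 10 Mbp), sign uniform -- applied to
#' all its peaks with toroidal wrap at the ends. A peak whose shifted
#' midpoint lands in the opposite compartment is relocated (width
#' preserved) to the nearest position inside a compartment of its original
#' type: placed fully inside the nearest same-label interval when it fits,
#' midpoint-centred with overhang when the interval is narrower than the
#' peak.
#'
#' @param peaks PD peak tibble; every peak midpoint must lie inside
#'   `compartments`.
#' @param compartments Labeled track tibble with labels `A`/`B` (any
#'   two-letter alphabet works).
#' @param gen A [genome()] tibble.
#' @param magnitudes Candidate shift magnitudes in bp; per chromosome only
#'   magnitudes smaller than the chromosome are drawn from (all wrapped if
#'   none fit).
#' @return The shifted peaks, same columns plus `compartment` (the
#'   preserved label). Peak count, widths, chromosome assignment and
#'   compartment labels are conserved exactly; chromosomes lacking any
#'   interval of a required label keep the wrapped position with a warning.
#' @export
shift_pd_peaks <- function(peaks, compartments, gen,
                           magnitudes = c(1, 3, 5, 7, 10) * 1e6) {
  if (nrow(peaks) == 0L) return(peaks)
  labs <- label_of(peaks, compartments)
  w <- peaks$end - peaks$start
  L <- chrom_length(gen, peaks$chrom)

  chroms <- unique(peaks$chrom)
  shift_by <- setNames(numeric(length(chroms)), chroms)
  for (cc in chroms) {
    Lc <- chrom_length(gen, cc)
    feas <- magnitudes[magnitudes < Lc]
    if (length(feas) == 0L) feas <- magnitudes
    mag <- feas[sample.int(length(feas), 1L)]
    sgn <- sample(c(-1, 1), 1L)
    shift_by[cc] <- sgn * mag
  }
  mid <- (peaks$start + peaks$end) / 2
  new_mid <- (mid + unname(shift_by[peaks$chrom])) %% L
  new_start <- pmin(pmax(round(new_mid - w / 2), 0), L - w)
  out <- peaks
  out$start <- new_start
  out$end <- new_start + w

  new_labs <- label_of(out, compartments, default = ".")
  moved <- which(new_labs != labs)
  if (length(moved) > 0L) {
    comp_by_chrom <- split(compartments, compartments$chrom)
    for (i in moved) {
      cand <- comp_by_chrom[[out$chrom[i]]]
      cand <- cand[cand$label == labs[i], , drop = FALSE]
      if (is.null(cand) || nrow(cand) == 0L) {
        warn(paste0("no '", labs[i], "' compartment on ", out$chrom[i],
                    "; peak kept at wrapped position."))
        next
      }
      m <- (out$start[i] + out$end[i]) / 2
      wi <- w[i]
      fits <- (cand$end - cand$start) >= wi
      s_cand <- ifelse(fits,
                       pmin(pmax(m - wi / 2, cand$start), cand$end - wi),
                       (cand$start + cand$end) / 2 - wi / 2)
      cand_mid <- s_cand + wi / 2
      d <- abs(cand_mid - m)
      j <- which(d == min(d))
      j <- j[which.min(s_cand[j])]
      s_new <- pmin(pmax(round(s_cand[j]), 0), L[i] - wi)
      out$start[i] <- s_new
      out$end[i] <- s_new + wi
    }
  }
  out$compartment <- labs
  out
}

#' Protein relatedness from shared RNA repertoires
#'
#' Each protein is represented by the set of RNAs its protein--RNA peaks
#' annotate; the distance between two proteins is one minus the Jaccard
#' index of their RNA sets. For every protein, the "related" set is the
#' closest tercile of the other proteins (smallest distances -- proteins
#' sharing many RNA partners) plus the protein itself; the rest are
#' "unrelated".
#'
#' @param pr_peaks PR peak tibble with `owner` (protein) and `rna_id`.
#' @param side `"closest"` (default) takes the tercile of smallest
#'   distances as related; `"farthest"` the tercile of largest.
#' @return A list of class `relatedness_map`: `distance` (symmetric matrix,
#'   zero diagonal), `related` (named list of protein character vectors,
#'   each including the protein itself), `rna_sets`.
#' @export
protein_distance_matrix <- function(pr_peaks, side = c("closest", "farthest")) {
  side <- match.arg(side)
  rna_sets <- pr_peaks |>
    group_by(.data$owner) |>
    summarise(rnas = list(unique(.data$rna_id)), .groups = "drop")
  if (any(lengths(rna_sets$rnas) == 0L) || anyNA(unlist(rna_sets$rnas))) {
    abort("every protein must have a non-empty RNA list.")
  }
  prot <- rna_sets$owner
  np <- length(prot)
  if (np < 2L) abort("need at least two proteins.")
  D <- matrix(0, np, np, dimnames = list(prot, prot))
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      a <- rna_sets$rnas[[i]]
      b <- rna_sets$rnas[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      D[i, j] <- D[j, i] <- 1 - jac
    }
  }
  related <- lapply(prot, function(p) {
    d <- D[p, ]
    d <- d[names(d) != p]
    if (side == "closest") {
      thr <- quantile(d, 1 / 3, type = 1, names = FALSE)
      rel <- names(d)[d <= thr]
    } else {
      thr <- quantile(d, 2 / 3, type = 1, names = FALSE)
      rel <- names(d)[d >= thr]
    }
    c(p, rel)
  })
  names(related) <- prot
  structure(list(distance = D, related = related,
                 rna_sets = setNames(rna_sets$rnas, prot)),
            class = "relatedness_map")
}

#' Resample protein--RNA peaks from related and unrelated pools
#'
#' The permutation null for protein--RNA data preserves the biotype
#' composition of a protein's interaction repertoire while drawing peaks
#' from proteins with similar repertoires. Peaks of related proteins
#' (including the target's own) form one pool, all remaining peaks the
#' other; for each biotype with `n_b` original peaks, `round(ratio_related
#' * n_b)` peaks are drawn (with replacement) from the related pool and the
#' remainder from the unrelated pool -- a 4:1 ratio by default, so at most
#' 20% of the simulated repertoire (plus sub-peak rounding slack per
#' biotype) originates from unrelated proteins.
#'
#' @param protein Target protein.
#' @param pr_peaks PR peak tibble for all proteins (`owner`, `rna_id`,
#'   `biotype`, coordinates, `q_value`).
#' @param relmap A [protein_distance_matrix()] result.
#' @param ratio_related Fraction drawn from the related pool, in `(0, 1]`
#'   (default 0.8).
#' @return A peak tibble of exactly the original size and per-biotype
#'   histogram, `owner` set to `protein`, with `source_owner` and
#'   `source_pool` (`"related"`/`"unrelated"`) columns. A pool lacking a
#'   biotype has its quota drawn from the other pool, with a warning.
#' @export
shuffle_pr_peaks <- function(protein, pr_peaks, relmap, ratio_related = 0.8) {
  stopifnot(ratio_related > 0, ratio_related <= 1)
  own <- pr_peaks[pr_peaks$owner == protein, , drop = FALSE]
  if (nrow(own) == 0L) abort(paste0("no PR peaks for protein ", protein))
  rel_set <- relmap$related[[protein]]
  if (is.null(rel_set)) abort(paste0("protein ", protein, " missing from relatedness map."))
  pool_R <- pr_peaks[pr_peaks$owner %in% rel_set, , drop = FALSE]
  pool_U <- pr_peaks[!pr_peaks$owner %in% rel_set, , drop = FALSE]

  draw <- function(pool, b, k) {
    idx <- which(pool$biotype == b)
    if (k == 0L) return(pool[integer(0), , drop = FALSE])
    pool[idx[sample.int(length(idx), k, replace = TRUE)], , drop = FALSE]
  }
  pieces <- list()
  for (b in unique(own$biotype)) {
    n_b <- sum(own$biotype == b)
    n_rel <- as.integer(round(ratio_related * n_b))
    n_unr <- n_b - n_rel
    has_R <- any(pool_R$biotype == b)
    has_U <- any(pool_U$biotype == b)
    if (!has_R && !has_U) abort(paste0("no peaks of biotype ", b, " in any pool."))
    if (!has_R) {
      warn(paste0("related pool lacks biotype ", b, "; drawing all from unrelated."))
      n_unr <- n_b; n_rel <- 0L
    }
    if (!has_U && n_unr > 0L) {
      warn(paste0("unrelated pool lacks biotype ", b, "; drawing all from related."))
      n_rel <- n_b; n_unr <- 0L
    }
    from_R <- draw(pool_R, b, n_rel)
    from_U <- draw(pool_U, b, n_unr)
    if (nrow(from_R) > 0L) from_R$source_pool <- "related"
    if (nrow(from_U) > 0L) from_U$source_pool <- "unrelated"
    pieces[[b]] <- bind_rows(from_R, from_U)
  }
  out <- list_rbind(pieces)
  out$source_owner <- out$owner
  out$owner <- protein
  out
}

#' Empirical significance of an observed triad count
#'
#' Runs the full permutation null: in each replicate the protein's ChIP
#' peaks are shifted (compartment-preserving, [shift_pd_peaks()]) and its
#' protein--RNA peaks resampled ([shuffle_pr_peaks()]), triads are rebuilt
#' with the same configuration as the observed run, and the triad count is
#' recorded. RNA--DNA contacts are never shuffled: their distance-scaling
#' structure cannot be randomised adequately, and only the relative
#' placement of the protein tracks is under test. The empirical p-value
#' uses the add-one permutation estimator
#' `(1 + #(sim >= observed)) / (n_reps + 1)`, which is never zero.
#'
#' @param protein Target protein.
#' @param contacts Contact tibble (already RD-peak-filtered).
#' @param pd_peaks Extended PD peaks of all proteins.
#' @param pr_peaks Extended PR peaks of all proteins.
#' @param compartments A/B labeled track.
#' @param gen A [genome()] tibble.
#' @param relmap Optional [protein_distance_matrix()] result (computed from
#'   `pr_peaks` when `NULL`).
#' @param n_reps Number of permutation replicates (default 10000; scale
#'   down for exploratory runs).
#' @param min_overlap Triad intersection threshold in bp (default 19).
#' @param ratio_related Related-pool sampling fraction (default 0.8).
#' @param magnitudes Shift magnitudes in bp for [shift_pd_peaks()].
#' @param seed Optional integer seed; with a fixed seed results are
#'   reproducible.
#' @return An object of class `triad_sim`: `protein`, `observed`,
#'   `sim_counts` (length `n_reps`), `empirical_p`, `n_reps`, `seed`.
#' @export
simulate_null <- function(protein, contacts, pd_peaks, pr_peaks,
                          compartments, gen, relmap = NULL, n_reps = 10000,
                          min_overlap = 19L, ratio_related = 0.8,
                          magnitudes = c(1, 3, 5, 7, 10) * 1e6,
                          seed = NULL) {
  if (n_reps < 1L) abort("n_reps must be >= 1.")
  if (is.null(relmap)) relmap <- protein_distance_matrix(pr_peaks)
  own_pd <- pd_peaks[pd_peaks$owner == protein, , drop = FALSE]
  own_pr <- pr_peaks[pr_peaks$owner == protein, , drop = FALSE]
  observed <- nrow(build_triads(contacts, own_pd, own_pr, min_overlap))
  run <- function() {
    vapply(seq_len(n_reps), function(r) {
      pd_sim <- shift_pd_peaks(own_pd, compartments, gen, magnitudes)
      pr_sim <- shuffle_pr_peaks(protein, pr_peaks, relmap, ratio_related)
      nrow(build_triads(contacts, pd_sim, pr_sim, min_overlap))
    }, integer(1))
  }
  sim_counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(
    protein = protein,
    observed = observed,
    sim_counts = sim_counts,
    empirical_p = (1 + sum(sim_counts >= observed)) / (n_reps + 1),
    n_reps = n_reps,
    seed = seed
  ), class = "triad_sim")
}

#' @export
print.triad_sim <- function(x, ...) {
  cat("Triad permutation null for protein", x$protein, "\n")
  cat("  observed triads :", x$observed, "\n")
  cat(sprintf("  simulated       : mean %.2f, sd %.2f over %d reps\n",
              mean(x$sim_counts), stats::sd(x$sim_counts), x$n_reps))
  cat(sprintf("  empirical p     : %.4g\n", x$empirical_p))
  invisible(x)
}
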