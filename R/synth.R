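#' Configuration for the synthetic interactome generator
#'
#' Defaults mirror the statistical regime of real RNA--chromatin
#' interactome data: protein-coding RNAs dominate the contact pool
#' (`biotype_mix` ~70% mRNA), cis contact distances decline as a power law
#' away from the source gene (`scaling_exponent`), ChIP peaks are enriched
#' in the open A compartment (`a_enrichment` ~2x by bp), and a roster of
#' 47 proteins. Planted triads place a contact, a ChIP peak and a
#' protein--RNA peak in guaranteed mutual overlap so pipeline recovery can
#' be scored against a truth table.
#'
#' @param n_chroms,chrom_length Number and common length (bp) of
#'   chromosomes.
#' @param compartment_block_bp Width of alternating A/B compartment
#'   blocks.
#' @param state_group_proportions Named proportions of grouped chromatin
#'   states (must sum to 1).
#' @param state_block_bp Width of state blocks.
#' @param n_proteins Proteins in the roster.
#' @param pd_peaks_per_protein,pr_peaks_per_protein Background peak counts
#'   per protein.
#' @param a_enrichment Per-bp odds of placing a ChIP peak in A vs B.
#' @param n_rnas RNA genes.
#' @param biotype_mix Named biotype proportions of the RNA roster (sum 1).
#' @param contacts_per_rna Background contacts per RNA.
#' @param cis_fraction Fraction of background contacts placed in cis.
#' @param scaling_exponent Power-law exponent alpha of the cis distance
#'   density (`d^-alpha`).
#' @param n_planted Number of planted triads.
#' @param planted_proteins Proteins receiving planted triads (round-robin;
#'   default the first protein).
#' @param noise If `FALSE`, only planted support peaks and RD peaks are
#'   emitted, so the pipeline must recover exactly the truth table.
#' @param rd_peak_noise_fraction With noise on, the fraction of background
#'   contacts covered by an RNA--DNA peak.
#' @param seed Integer seed; generation is fully determined by it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_chroms = 4,
                         chrom_length = 2e7,
                         compartment_block_bp = 1e6,
                         state_group_proportions = c(
                           Promoter = 0.05, Enhancer = 0.10,
                           Transcribed = 0.25, Repressed = 0.30,
                           Quiescent = 0.30),
                         state_block_bp = 5e4,
                         n_proteins = 47,
                         pd_peaks_per_protein = 100,
                         pr_peaks_per_protein = 60,
                         a_enrichment = 2,
                         n_rnas = 100,
                         biotype_mix = c(mRNA = 0.70, lncRNA = 0.12,
                                         snoRNA = 0.06, XRNA = 0.06,
                                         pseudogene = 0.06),
                         contacts_per_rna = 50,
                         cis_fraction = 0.7,
                         scaling_exponent = 1,
                         n_planted = 0,
                         planted_proteins = NULL,
                         noise = TRUE,
                         rd_peak_noise_fraction = 0.5,
                         seed = 1L) {
  stopifnot(abs(sum(state_group_proportions) - 1) < 1e-8,
            abs(sum(biotype_mix) - 1) < 1e-8,
            scaling_exponent > 0,
            cis_fraction >= 0, cis_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# inverse-CDF sampler for density proportional to d^-alpha on [d_min, d_max]
sample_powerlaw <- function(n, alpha, d_min, d_max) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    d_min * (d_max / d_min)^u
  } else {
    (d_min^(1 - alpha) + u * (d_max^(1 - alpha) - d_min^(1 - alpha)))^(1 / (1 - alpha))
  }
}

rand_q <- function(n) runif(n, 0.001, 0.05)

# alternating-block labeled track over the whole genome
block_track <- function(gen, block_bp, labels_fun) {
  purrr::map(seq_len(nrow(gen)), function(i) {
    L <- gen$length[i]
    s <- seq(0, L - 1, by = block_bp)
    e <- pmin(s + block_bp, L)
    tibble(chrom = gen$chrom[i], start = s, end = e,
           label = labels_fun(length(s)))
  }) |> list_rbind()
}

#' Generate a synthetic interactome with planted triads
#'
#' Produces every input the pipeline consumes -- genome, A/B compartments,
#' grouped chromatin states, RNA gene roster, RNA--DNA contacts,
#' RNA--DNA peaks, ChIP (PD) peaks and protein--RNA (PR) peaks -- plus a
#' truth table of planted triads. All q-values are drawn uniformly from
#' (0.001, 0.05); output is fully determined by `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with elements `genome`, `compartments`, `states`,
#'   `rnas`, `contacts`, `rd_peaks`, `pd_peaks`, `pr_peaks`, `truth`,
#'   `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cf) {
  gen <- genome(paste0("chr", seq_len(cf$n_chroms)),
                rep(cf$chrom_length, cf$n_chroms))
  compartments <- block_track(gen, cf$compartment_block_bp, function(k) {
    rep_len(c("A", "B"), k)
  })
  states <- block_track(gen, cf$state_block_bp, function(k) {
    sample(names(cf$state_group_proportions), k, replace = TRUE,
           prob = cf$state_group_proportions)
  })

  # RNA gene roster
  n_r <- cf$n_rnas
  gene_len <- round(runif(n_r, 5e3, 5e4))
  gene_chrom <- sample(gen$chrom, n_r, replace = TRUE)
  gene_start <- vapply(seq_len(n_r), function(i) {
    round(runif(1, 0, cf$chrom_length - gene_len[i]))
  }, numeric(1))
  rnas <- tibble(
    rna_id = sprintf("RNA%03d", seq_len(n_r)),
    biotype = sample(names(cf$biotype_mix), n_r, replace = TRUE,
                     prob = cf$biotype_mix),
    chrom = gene_chrom,
    start = gene_start,
    end = gene_start + gene_len,
    strand = sample(c("+", "-"), n_r, replace = TRUE)
  )
  proteins <- sprintf("P%02d", seq_len(cf$n_proteins))

  # background contacts: cis distances power-law from the gene, trans uniform
  contacts <- purrr::map(seq_len(n_r), function(i) {
    g <- rnas[i, ]
    n_c <- cf$contacts_per_rna
    if (n_c == 0L) return(NULL)
    is_cis <- runif(n_c) < cf$cis_fraction
    dna_w <- 150
    dna_start <- numeric(n_c)
    dna_chrom <- character(n_c)
    d_max <- cf$chrom_length / 2
    d <- sample_powerlaw(n_c, cf$scaling_exponent, 1e3, d_max)
    side <- sample(c(-1, 1), n_c, replace = TRUE)
    for (k in seq_len(n_c)) {
      if (is_cis[k]) {
        dna_chrom[k] <- g$chrom
        pos <- if (side[k] > 0) g$end + d[k] else g$start - d[k] - dna_w
        # reflect back inside the chromosome if the draw fell off an end
        if (pos < 0) pos <- g$end + d[k]
        if (pos > cf$chrom_length - dna_w) pos <- max(0, g$start - d[k] - dna_w)
        dna_start[k] <- round(pmin(pmax(pos, 0), cf$chrom_length - dna_w))
      } else {
        dna_chrom[k] <- sample(setdiff(gen$chrom, g$chrom), 1)
        dna_start[k] <- round(runif(1, 0, cf$chrom_length - dna_w))
      }
    }
    rp_w <- 100
    rp_start <- round(runif(n_c, g$start, g$end - rp_w))
    tibble(
      rna_chrom = g$chrom, rna_start = rp_start, rna_end = rp_start + rp_w,
      rna_strand = g$strand, rna_id = g$rna_id, biotype = g$biotype,
      dna_chrom = dna_chrom, dna_start = dna_start,
      dna_end = dna_start + dna_w, experiment = "synthetic"
    )
  }) |> list_rbind()
  if (is.null(contacts)) contacts <- tibble()

  # background PD peaks, A-compartment enriched
  pd_peaks <- NULL
  pr_peaks <- NULL
  if (cf$noise) {
    comp_w <- (compartments$end - compartments$start) *
      ifelse(compartments$label == "A", cf$a_enrichment, 1)
    pd_peaks <- purrr::map(proteins, function(p) {
      k <- cf$pd_peaks_per_protein
      blk <- sample.int(nrow(compartments), k, replace = TRUE, prob = comp_w)
      w <- round(runif(k, 200, 1000))
      lo <- compartments$start[blk]
      hi <- pmax(lo + 1, compartments$end[blk] - w)
      s <- round(runif(k, lo, hi))
      tibble(chrom = compartments$chrom[blk], start = s, end = s + w,
             strand = ".", owner = p, q_value = rand_q(k), kind = "PD")
    }) |> list_rbind()

    pr_peaks <- purrr::map(proteins, function(p) {
      k <- cf$pr_peaks_per_protein
      ri <- sample.int(n_r, k, replace = TRUE)
      g <- rnas[ri, ]
      w <- pmin(round(runif(k, 50, 300)), g$end - g$start - 1)
      s <- round(runif(k, g$start, g$end - w))
      tibble(chrom = g$chrom, start = s, end = s + w, strand = g$strand,
             owner = p, q_value = rand_q(k), kind = "PR",
             rna_id = g$rna_id, biotype = g$biotype)
    }) |> list_rbind()
  }

  # planted triads: contact + PD peak + PR peak in guaranteed overlap
  truth <- tibble(rna_id = character(), protein = character(),
                  dna_chrom = character(), dna_start = numeric(),
                  dna_end = numeric())
  planted_contacts <- NULL
  planted_pd <- NULL
  planted_pr <- NULL
  planted_rd <- NULL
  if (cf$n_planted > 0) {
    pp <- cf$planted_proteins %||% proteins[1]
    plant <- tibble(
      protein = rep_len(pp, cf$n_planted),
      ri = sample.int(n_r, cf$n_planted, replace = TRUE)
    )
    g <- rnas[plant$ri, ]
    dna_w <- 150
    margin <- 5e3
    dna_chrom <- sample(gen$chrom, cf$n_planted, replace = TRUE)
    dna_start <- round(runif(cf$n_planted, margin,
                             cf$chrom_length - margin - dna_w))
    rp_w <- 100
    rp_start <- round(runif(cf$n_planted, g$start, g$end - rp_w))
    planted_contacts <- tibble(
      rna_chrom = g$chrom, rna_start = rp_start, rna_end = rp_start + rp_w,
      rna_strand = g$strand, rna_id = g$rna_id, biotype = g$biotype,
      dna_chrom = dna_chrom, dna_start = dna_start,
      dna_end = dna_start + dna_w, experiment = "synthetic"
    )
    planted_pd <- tibble(
      chrom = dna_chrom, start = dna_start - 200, end = dna_start + dna_w + 200,
      strand = ".", owner = plant$protein, q_value = rand_q(cf$n_planted),
      kind = "PD"
    )
    planted_pr <- tibble(
      chrom = g$chrom, start = pmax(0, rp_start - 50),
      end = pmin(cf$chrom_length, rp_start + rp_w + 50),
      strand = g$strand, owner = plant$protein, q_value = rand_q(cf$n_planted),
      kind = "PR", rna_id = g$rna_id, biotype = g$biotype
    )
    planted_rd <- tibble(
      chrom = dna_chrom, start = pmax(0, dna_start - 100),
      end = pmin(cf$chrom_length, dna_start + dna_w + 100),
      strand = ".", owner = g$rna_id, q_value = rand_q(cf$n_planted),
      kind = "RD"
    )
    truth <- tibble(rna_id = g$rna_id, protein = plant$protein,
                    dna_chrom = dna_chrom, dna_start = dna_start,
                    dna_end = dna_start + dna_w)
  }

  # RD peaks: all planted contacts, plus a noise fraction of background
  rd_noise <- NULL
  if (cf$noise && nrow(contacts) > 0 && cf$rd_peak_noise_fraction > 0) {
    take <- which(runif(nrow(contacts)) < cf$rd_peak_noise_fraction)
    if (length(take) > 0) {
      cc <- contacts[take, ]
      rd_noise <- tibble(
        chrom = cc$dna_chrom, start = pmax(0, cc$dna_start - 100),
        end = pmin(cf$chrom_length, cc$dna_end + 100), strand = ".",
        owner = cc$rna_id, q_value = rand_q(length(take)), kind = "RD"
      )
    }
  }

  empty_peaks <- tibble(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        owner = character(), q_value = numeric(),
                        kind = character())
  with_schema <- function(x) if (is.null(x) || ncol(x) == 0L) empty_peaks else x
  list(
    genome = gen,
    compartments = compartments,
    states = states,
    rnas = rnas,
    contacts = bind_rows(contacts, planted_contacts),
    rd_peaks = with_schema(bind_rows(rd_noise, planted_rd)),
    pd_peaks = with_schema(bind_rows(pd_peaks, planted_pd)),
    pr_peaks = with_schema(bind_rows(pr_peaks, planted_pr)),
    truth = truth,
    config = cf
  )
}

#' Score recovered triads against the planted truth table
#'
#' A truth record is recovered when some triad matches its RNA, protein
#' and DNA locus (>= `min_overlap` bp overlap); a triad is a true positive
#' when it matches some truth record. Recall is the fraction of truth
#' recovered; precision the fraction of triads that are true positives
#' (reported as 1 with a warning when there are no triads).
#'
#' @param triads Triad tibble from [build_triads()].
#' @param truth Truth tibble from [synth_generate()].
#' @param min_overlap Minimum DNA overlap in bp (default 1).
#' @return A list `recall`, `precision`, `n_truth`, `n_triads`.
#' @export
recovery_report <- function(triads, truth, min_overlap = 1L) {
  if (nrow(triads) == 0L) {
    if (nrow(truth) > 0L) warn("no triads recovered; precision reported as 1.")
    return(list(recall = if (nrow(truth) > 0L) 0 else 1, precision = 1,
                n_truth = nrow(truth), n_triads = 0L))
  }
  hits <- overlap_pairs(triads, truth, minoverlap = min_overlap,
                        a_cols = c("dna_chrom", "dna_start", "dna_end"),
                        b_cols = c("dna_chrom", "dna_start", "dna_end"))
  ok <- triads$rna_id[hits$a_idx] == truth$rna_id[hits$b_idx] &
    triads$protein[hits$a_idx] == truth$protein[hits$b_idx]
  hits <- hits[ok, ]
  list(
    recall = if (nrow(truth) > 0L) length(unique(hits$b_idx)) / nrow(truth) else 1,
    precision = length(unique(hits$a_idx)) / nrow(triads),
    n_truth = nrow(truth),
    n_triads = nrow(triads)
  )
}
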