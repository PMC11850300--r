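# small builders and independent brute-force oracles used across tests

library(tibble)
library(dplyr)

mk_genome <- function(n = 1, len = 1e6) {
  genome(paste0("chr", seq_len(n)), rep(len, n))
}

iv <- function(chrom, start, end, strand = ".") {
  tibble(chrom = chrom, start = start, end = end, strand = strand)
}

mk_pd <- function(chrom, start, end, owner, q = 0.01) {
  tibble(chrom = chrom, start = start, end = end, strand = ".",
         owner = owner, q_value = q, kind = "PD")
}

mk_pr <- function(chrom, start, end, owner, rna_id, q = 0.01,
                  strand = "+", biotype = "mRNA") {
  tibble(chrom = chrom, start = start, end = end, strand = strand,
         owner = owner, q_value = q, kind = "PR", rna_id = rna_id,
         biotype = biotype)
}

mk_contact <- function(rna_id, rna_chrom, rna_start, rna_end,
                       dna_chrom, dna_start, dna_end,
                       biotype = "mRNA", strand = "+", q_bardic = NULL) {
  out <- tibble(rna_chrom = rna_chrom, rna_start = rna_start,
                rna_end = rna_end, rna_strand = strand, rna_id = rna_id,
                biotype = biotype, dna_chrom = dna_chrom,
                dna_start = dna_start, dna_end = dna_end,
                experiment = "test")
  if (!is.null(q_bardic)) out$q_bardic <- q_bardic
  out
}

# shared-bp count by position enumeration (small intervals only)
oracle_intersect <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# all-pairs brute-force triad assembly mirroring the stated rules
oracle_build_triads <- function(contacts, pd_peaks, pr_peaks, min_overlap = 19) {
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    for (p in unique(pd_peaks$owner)) {
      pd <- pd_peaks[pd_peaks$owner == p, ]
      ov_pd <- mapply(function(cc, s, e) {
        if (cc != contacts$dna_chrom[i]) 0
        else max(0, min(e, contacts$dna_end[i]) - max(s, contacts$dna_start[i]))
      }, pd$chrom, pd$start, pd$end)
      keep <- which(ov_pd >= min_overlap)
      if (length(keep) == 0) next
      keep <- keep[order(-ov_pd[keep], pd$start[keep])][1]

      pr <- pr_peaks[pr_peaks$owner == p & pr_peaks$rna_id == contacts$rna_id[i], ]
      if (nrow(pr) == 0) next
      ov_pr <- mapply(function(cc, s, e) {
        if (cc != contacts$rna_chrom[i]) 0
        else max(0, min(e, contacts$rna_end[i]) - max(s, contacts$rna_start[i]))
      }, pr$chrom, pr$start, pr$end)
      keep_r <- which(ov_pr >= min_overlap)
      if (length(keep_r) == 0) next
      keep_r <- keep_r[order(-ov_pr[keep_r], pr$start[keep_r])][1]

      rows[[length(rows) + 1]] <- tibble(
        contact_idx = i, protein = p,
        overlap_pd = ov_pd[keep], overlap_pr = ov_pr[keep_r],
        q_macs2 = pd$q_value[keep], q_piranha = pr$q_value[keep_r]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(contact_idx = integer(), protein = character(),
                  overlap_pd = numeric(), overlap_pr = numeric(),
                  q_macs2 = numeric(), q_piranha = numeric()))
  }
  bind_rows(rows) |> arrange(protein, contact_idx)
}

# exact two-sided signed-rank p by enumeration of all sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(grid %*% r)
  min(1, 2 * min(mean(Wall >= W), mean(Wall <= W)))
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random triad-assembly instance for oracle-equivalence checks
random_instance <- function(seed) {
  withr::with_seed(seed, {
    gen <- mk_genome(2, 1e5)
    n_c <- sample(10:50, 1)
    n_pd <- sample(10:70, 1)
    n_pr <- sample(10:70, 1)
    rnas <- paste0("R", 1:6)
    prots <- paste0("P", 1:3)
    rchrom <- sample(gen$chrom, n_c, TRUE)
    rs <- sample.int(9e4, n_c)
    dchrom <- sample(gen$chrom, n_c, TRUE)
    ds <- sample.int(9e4, n_c)
    contacts <- tibble(
      rna_chrom = rchrom, rna_start = rs, rna_end = rs + sample(20:200, n_c, TRUE),
      rna_strand = "+", rna_id = sample(rnas, n_c, TRUE),
      biotype = "mRNA", dna_chrom = dchrom, dna_start = ds,
      dna_end = ds + sample(20:200, n_c, TRUE), experiment = "test",
      q_bardic = runif(n_c, 0.001, 0.05)
    )
    ps <- sample.int(9e4, n_pd)
    pd <- mk_pd(sample(gen$chrom, n_pd, TRUE), ps, ps + sample(10:400, n_pd, TRUE),
                sample(prots, n_pd, TRUE), runif(n_pd, 0.001, 0.05))
    qs <- sample.int(9e4, n_pr)
    pr <- mk_pr(sample(gen$chrom, n_pr, TRUE), qs, qs + sample(10:400, n_pr, TRUE),
                sample(prots, n_pr, TRUE), sample(rnas, n_pr, TRUE),
                runif(n_pr, 0.001, 0.05))
    list(contacts = contacts, pd = pd, pr = pr)
  })
}
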