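# contacts with a prescribed number of cis and trans rows per RNA
frac_contacts <- function(rna_id, n_cis, n_trans) {
  bind_rows(
    if (n_cis > 0) mk_contact(rna_id, "chr1", 0, 100, "chr1",
                              1000 * seq_len(n_cis), 1000 * seq_len(n_cis) + 100),
    if (n_trans > 0) mk_contact(rna_id, "chr1", 0, 100, "chr2",
                                1000 * seq_len(n_trans), 1000 * seq_len(n_trans) + 100)
  )
}

test_that("cis/trans labels follow chromosome identity", {
  x <- mk_contact(c("a", "b", "c"), c("chr1", "chr1", "chrX"), 0, 100,
                  c("chr1", "chr2", "chrX"), 1000, 1100)
  expect_equal(cis_trans_label(x), c("cis", "trans", "cis"))
})

test_that("cis/trans shift test: identity gives p = 1, one-sided shift is exact", {
  before <- bind_rows(lapply(paste0("R", 1:4), frac_contacts, n_cis = 3, n_trans = 1))
  expect_equal(cis_trans_shift_test(before, before)$p_value, 1)

  # 6 RNAs, trans fraction strictly higher after: exact two-sided p = 2/64
  before6 <- bind_rows(lapply(paste0("R", 1:6), function(r) {
    frac_contacts(r, n_cis = 5, n_trans = 1)
  }))
  after6 <- bind_rows(lapply(seq_len(6), function(i) {
    frac_contacts(paste0("R", i), n_cis = 5 - i %% 3, n_trans = 2 + i %% 2)
  }))
  res <- cis_trans_shift_test(before6, after6)
  expect_equal(res$n_nonzero, 6)
  expect_equal(res$p_value, 2 / 64)

  # single nonzero pair: p = 1
  one <- cis_trans_shift_test(frac_contacts("R1", 3, 1), frac_contacts("R1", 1, 3))
  expect_equal(one$p_value, 1)
  expect_error(cis_trans_shift_test(before, frac_contacts("Z", 1, 1)), "both sets")
})

test_that("cis/trans shift test matches exact signed-rank enumeration", {
  withr::with_seed(31, {
    for (k in 1:10) {
      n <- sample(3:10, 1)
      # distinct integer steps over denominator 40: no rank ties, no zeros,
      # so the exact signed-rank test applies
      steps <- sample(1:19, n)
      signs <- sample(c(-1, 1), n, TRUE)
      before <- bind_rows(lapply(seq_len(n), function(i) {
        frac_contacts(paste0("R", i), 20, 20) # trans frac 0.5
      }))
      after <- bind_rows(lapply(seq_len(n), function(i) {
        n_trans <- 20 + signs[i] * steps[i]
        frac_contacts(paste0("R", i), 40 - n_trans, n_trans)
      }))
      res <- cis_trans_shift_test(before, after)
      d_real <- res$pairs$diff
      expect_equal(res$p_value, oracle_signed_rank(d_real), tolerance = 1e-10)
    }
  })
})

test_that("scaling weights follow the density formula and conserve total mass", {
  gene <- tibble(chrom = "chr1", start = 1e6, end = 1.02e6)
  # 5 contacts in the 1-2 kb bin, 45 far away
  near <- mk_contact("R", "chr1", 0, 100, "chr1",
                     gene$end + seq(1100, 1900, length.out = 5),
                     gene$end + seq(1100, 1900, length.out = 5) + 1)
  far <- mk_contact("R", "chr1", 0, 100, "chr1",
                    gene$end + seq(5e5, 9e5, length.out = 45),
                    gene$end + seq(5e5, 9e5, length.out = 45) + 1)
  sw <- scaling_weights(bind_rows(near, far), gene)
  bin12 <- sw[sw$lo == 1000 & sw$hi == 2000, ]
  expect_equal(bin12$n_contacts, 5)
  expect_equal(bin12$weight, 5 / (1000 * 50) * 1e9)
  expect_equal(sum(sw$weight * sw$bin_length), 1e9)
  # contacts inside the gene have distance zero -> first bin
  inside <- mk_contact("R", "chr1", 0, 100, "chr1", 1.005e6, 1.006e6)
  sw2 <- scaling_weights(inside, gene)
  expect_equal(sw2$n_contacts[1], 1)
  expect_equal(sum(sw2$weight * sw2$bin_length), 1e9)
  expect_error(scaling_weights(mk_contact("R", "chr1", 0, 100, "chr2", 1, 2), gene),
               "cis")
})

test_that("mass conservation holds for random scaling inputs", {
  withr::with_seed(12, {
    gene <- tibble(chrom = "chr1", start = 5e7, end = 5.01e7)
    for (k in 1:5) {
      n <- sample(5:200, 1)
      pos <- runif(n, 0, 1.5e8)
      cc <- mk_contact("R", "chr1", 0, 100, "chr1", pos, pos + 150)
      sw <- scaling_weights(cc, gene)
      expect_equal(sum(sw$weight * sw$bin_length), 1e9)
    }
  })
})

test_that("median-p split sends strictly-below-median proteins to associated", {
  pv <- tibble(protein = paste0("P", 1:4), p_value = c(.1, .2, .3, .4))
  out <- split_by_median_p(pv)
  expect_equal(out$group, c("associated", "associated", "other", "other"))
  tied <- split_by_median_p(tibble(protein = paste0("P", 1:3), p_value = rep(.5, 3)))
  expect_true(all(tied$group == "other"))
  single_min <- split_by_median_p(tibble(protein = c("a", "b"), p_value = c(.01, .5)))
  expect_equal(single_min$group, c("associated", "other"))
})

test_that("common/specific split applies the >= 20 protein threshold", {
  tri20 <- tibble(rna_id = "R1", protein = paste0("P", 1:20))
  tri19 <- tibble(rna_id = "R2", protein = paste0("P", 1:19))
  out <- common_specific_split(bind_rows(tri20, tri19))
  expect_equal(out$rna_class[out$rna_id == "R1"], "common")
  expect_equal(out$rna_class[out$rna_id == "R2"], "specific")
  empty <- common_specific_split(tri20[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("Fisher specificity matches hypergeometric enumeration", {
  # perfect association: [[10,0],[0,10]]
  contacts <- bind_rows(
    mk_contact(paste0("S", 1:10), "chr1", 0, 100, "chr1",
               1000 * (1:10), 1000 * (1:10) + 100),
    mk_contact(paste0("C", 1:10), "chr1", 0, 100, "chr1",
               1e6 + 1000 * (1:10), 1e6 + 1000 * (1:10) + 100)
  )
  chip <- mk_pd("chr1", 0, 2e4, "P") # covers only the specific contacts
  res <- fisher_specificity(contacts, chip, common_rnas = paste0("C", 1:10))
  expect_equal(res$table, matrix(c(10, 0, 0, 10), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)

  # balanced table: no association
  chip_half <- mk_pd("chr1", c(0, 1e6), c(5500, 1e6 + 5500), "P")
  res2 <- fisher_specificity(contacts, chip_half, paste0("C", 1:10))
  expect_equal(res2$p_value, 1)

  # degenerate margin
  expect_warning(
    res3 <- fisher_specificity(contacts, chip[0, ], paste0("C", 1:10)),
    "degenerate")
  expect_equal(res3$p_value, 1)

  # random tables against the enumeration oracle
  withr::with_seed(77, {
    for (k in 1:20) {
      tab <- matrix(rbinom(4, 10, 0.5), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      got <- fisher.test(tab)$p.value
      expect_equal(got, oracle_fisher(tab), tolerance = 1e-9)
    }
  })
})

test_that("Jaccard RNA similarity has unit diagonal and set semantics", {
  sets <- list(a = c("x", "y", "z"), b = c("y", "z", "w"),
               c = character(), d = character())
  expect_message(M <- jaccard_rna_similarity(sets), "empty")
  expect_equal(diag(M), setNames(rep(1, 4), c("a", "b", "c", "d")))
  expect_equal(M["a", "b"], 0.5)
  expect_equal(M["a", "c"], 0)
  expect_equal(M["c", "d"], 0) # empty-vs-empty falls back to 0
  tri <- list(d1 = tibble(rna_id = c("x", "y")), d2 = tibble(rna_id = c("x", "y")))
  expect_equal(jaccard_rna_similarity(tri)["d1", "d2"], 1)
})

test_that("compartment density normalises midpoint counts by label length", {
  gen <- mk_genome(1, 2e6)
  comp <- tibble(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6),
                 label = c("A", "B"))
  parts <- iv("chr1", seq(1e4, 1e5, length.out = 10),
              seq(1e4, 1e5, length.out = 10) + 100) # all in A
  out <- compartment_density(parts, comp, gen)
  expect_equal(out$density[out$label == "A"], 10 / 1e6)
  expect_equal(out$density[out$label == "B"], 0)
  none <- compartment_density(parts[0, ], comp, gen)
  expect_true(all(none$density == 0))
  # equal counts, A twice as long as B -> density(A) = density(B)/2
  comp2 <- tibble(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 1.5e6),
                  label = c("A", "B"))
  parts2 <- iv("chr1", c(1e4, 1.2e6), c(1e4 + 100, 1.2e6 + 100))
  out2 <- compartment_density(parts2, comp2, gen)
  expect_equal(out2$density[out2$label == "A"],
               out2$density[out2$label == "B"] / 2)
})

test_that("fold change uses pseudo-counted fractions", {
  gc <- tibble(gene = c("g1", "g2", "g3"),
               count_exp = c(2, 98, 0), count_ctrl = c(1, 99, 0))
  out <- pr_fold_change(gc)
  expect_equal(out$fold_change[1], (0.02 + 0.01) / (0.01 + 0.01))
  expect_equal(out$fold_change[3], 1) # absent from both
  same <- pr_fold_change(tibble(gene = "g", count_exp = 5, count_ctrl = 5))
  expect_equal(same$fold_change, 1)
  expect_error(pr_fold_change(tibble(gene = "g", count_exp = 0, count_ctrl = 1)),
               "totals")
})

test_that("percentages are rendered with banker's rounding and trimmed zeros", {
  expect_equal(format_pct(2.9022), "2.9")
  expect_equal(format_pct(21.9595), "21.96")
  expect_equal(format_pct(100), "100")
  expect_equal(format_pct(0.005), "0") # half-even rounds to 0.00
  expect_equal(format_pct(3.125), "3.12")
})
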