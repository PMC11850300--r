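#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a triad permutation-null result
#'
#' @param x A `triad_sim` object from [simulate_null()].
#' @param ... Unused.
#' @return One row per replicate: `protein`, `rep`, `sim_count`.
#' @export
tidy.triad_sim <- function(x, ...) {
  tibble(protein = x$protein, rep = seq_along(x$sim_counts),
         sim_count = x$sim_counts)
}

#' One-row summary of a triad permutation-null result
#'
#' @inheritParams tidy.triad_sim
#' @return Tibble with `protein`, `observed`, `sim_mean`, `sim_sd`,
#'   `sim_q95`, `empirical_p`, `n_reps`.
#' @export
glance.triad_sim <- function(x, ...) {
  tibble(
    protein = x$protein,
    observed = x$observed,
    sim_mean = mean(x$sim_counts),
    sim_sd = stats::sd(x$sim_counts),
    sim_q95 = unname(quantile(x$sim_counts, 0.95, type = 1)),
    empirical_p = x$empirical_p,
    n_reps = x$n_reps
  )
}

#' Tidy a cis/trans shift test
#'
#' @param x A `cis_trans_shift` object from [cis_trans_shift_test()].
#' @param ... Unused.
#' @return The per-RNA pair table with fractions and differences.
#' @export
tidy.cis_trans_shift <- function(x, ...) x$pairs

#' One-row summary of a cis/trans shift test
#'
#' @inheritParams tidy.cis_trans_shift
#' @return Tibble with `statistic`, `p_value`, `n_pairs`, `n_nonzero`.
#' @export
glance.cis_trans_shift <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_pairs = x$n_pairs, n_nonzero = x$n_nonzero)
}

#' Tidy a chromatin-state goodness-of-fit test
#'
#' @param x A `state_chisq` object from [chisq_state_test()].
#' @param ... Unused.
#' @return The merged observed/expected table.
#' @export
tidy.state_chisq <- function(x, ...) x$table

#' One-row summary of a chromatin-state goodness-of-fit test
#'
#' @inheritParams tidy.state_chisq
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
glance.state_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}
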