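#' Mean pairwise inter-reader agreement
#'
#' For each case, the fraction of concordant reader pairs among all
#' `choose(R, 2)` pairs; the statistic is the mean of these fractions over
#' cases (the observed-agreement component of Fleiss-style multirater
#' statistics).
#'
#' @param calls Readers x cases call matrix with at least two readers.
#' @return Proportion in `[0, 1]`.
#' @examples
#' m <- rbind(a = c(x = "edema", y = "edema"), b = c(x = "edema", y = "no_edema"))
#' pairwise_agreement(m)  # 0.5
#' @export
pairwise_agreement <- function(calls) {
  check_call_matrix(calls)
  r <- nrow(calls)
  if (r < 2) abort_input("pairwise agreement needs at least two readers")
  per_case <- apply(calls, 2, function(col) {
    n_e <- sum(col == "edema")
    (choose(n_e, 2) + choose(r - n_e, 2)) / choose(r, 2)
  })
  mean(per_case)
}

#' Free-marginal multirater kappa
#'
#' Chance-corrected multirater agreement for raters who are free to assign
#' any number of cases to each of `k` categories, so the expected chance
#' agreement is `1/k`:  `kappa = (P0 - 1/k) / (1 - 1/k)`.  For two
#' categories this reduces to `2 * P0 - 1`.  Appropriate for reader studies
#' where no category quotas are imposed; Fleiss' kappa, which estimates
#' chance agreement from the observed marginals, is the fixed-marginal
#' alternative.
#'
#' @param p_overall Observed overall agreement proportion `P0` in `[0, 1]`,
#'   e.g. from [pairwise_agreement()].
#' @param k Number of rating categories (>= 2; default 2).
#' @return Kappa in `[-1/(k-1), 1]`.
#' @examples
#' free_marginal_kappa(0.84)  # 0.68
#' @export
free_marginal_kappa <- function(p_overall, k = 2L) {
  if (k < 2) abort_input("k must be at least 2")
  if (any(p_overall < 0 | p_overall > 1))
    abort_input("p_overall must lie in [0, 1]")
  (p_overall - 1 / k) / (1 - 1 / k)
}
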