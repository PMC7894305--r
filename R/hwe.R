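#' Exact two-sided Hardy-Weinberg test
#'
#' Exact test of Hardy-Weinberg proportions for a biallelic site. Conditional
#' on the number of diploids `n` and the minor-allele count `nA`, the number of
#' heterozygotes `h` has probability
#' `P(h) = 2^h n! nA! na! / (nAA! h! naa! (2n)!)` with
#' `nAA = (nA - h) / 2`, `naa = (na - h) / 2`. The two-sided p-value sums
#' `P(h')` over all attainable `h'` with `P(h') <= P(h_obs)` (no mid-p
#' correction), so `p` lies in (0, 1].
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative integers, not all zero).
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_p(1, 0, 1)  # 1/3
#' hwe_exact_p(0, 2, 0)  # 1
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(.check_count_scalar(n_AA, "n_AA"),
           .check_count_scalar(n_Aa, "n_Aa"),
           .check_count_scalar(n_aa, "n_aa"))
  if (sum(cnt) == 0L) stop("genotype counts must not all be zero")
  n <- sum(cnt)
  nA <- 2L * cnt[1] + cnt[2]
  na <- 2L * n - nA
  if (nA > na) { nA <- na; na <- 2L * n - nA }  # work with the minor allele
  if (nA == 0L) return(1)                        # monomorphic: single config
  h_all <- seq.int(nA %% 2L, nA, by = 2L)       # attainable het counts
  logp <- h_all * log(2) + lgamma(n + 1) + lgamma(nA + 1) + lgamma(na + 1) -
    lgamma((nA - h_all) / 2 + 1) - lgamma(h_all + 1) -
    lgamma((na - h_all) / 2 + 1) - lgamma(2 * n + 1)
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)                   # renormalize roundoff
  p_obs <- p_all[match(cnt[2], h_all)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele count")
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-12)]))
}

#' Vectorized HWE exact p-values
#'
#' @param n_AA,n_Aa,n_aa integer vectors of genotype counts per site.
#' @return numeric vector of exact p-values; `NA` where all three counts are 0
#'   (no data, treated as pass by the filter chain).
#' @export
hwe_exact_p_vec <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == length(n_Aa), length(n_Aa) == length(n_aa))
  out <- rep(NA_real_, length(n_AA))
  for (k in seq_along(out)) {
    if (n_AA[k] + n_Aa[k] + n_aa[k] > 0L)
      out[k] <- hwe_exact_p(n_AA[k], n_Aa[k], n_aa[k])
  }
  out
}
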