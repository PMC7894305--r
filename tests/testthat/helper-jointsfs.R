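# Shared fixtures and independent oracles used across the suite.

# Brute-force projection oracle: enumerate all subsets of n_target alleles
# out of n_obs (derived alleles occupy the first d_obs slots) and tally the
# derived count of each subset.
enumerate_projection <- function(d_obs, n_obs, n_target) {
  subsets <- utils::combn(n_obs, n_target)
  counts <- tabulate(colSums(subsets <= d_obs) + 1L, nbins = n_target + 1L)
  counts / ncol(subsets)
}

# Brute-force HWE oracle: enumerate all placements of the minor allele's nA
# copies among the 2n ordered allele slots of n diploids; every placement is
# equally likely under the exact-test null. Returns the pmf of the
# heterozygote count.
enumerate_hwe_pmf <- function(n, nA) {
  slots <- utils::combn(2L * n, nA)
  odd <- matrix(FALSE, 2L * n, ncol(slots))
  odd[cbind(as.vector(slots),
            rep(seq_len(ncol(slots)), each = nrow(slots)))] <- TRUE
  first <- odd[seq(1L, 2L * n, 2L), , drop = FALSE]
  second <- odd[seq(2L, 2L * n, 2L), , drop = FALSE]
  hets <- colSums(first != second)
  tab <- tabulate(hets + 1L, nbins = nA + 1L)
  stats::setNames(tab / ncol(slots), 0:nA)
}

brute_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- min(2L * n_AA + n_Aa, 2L * n_aa + n_Aa)
  if (nA == 0L) return(1)
  pmf <- enumerate_hwe_pmf(n, nA)
  pmf <- pmf[pmf > 0]
  p_obs <- pmf[[as.character(n_Aa)]]
  sum(pmf[pmf <= p_obs * (1 + 1e-12)])
}

# Small reusable models
model_si <- function() demographic_model("e1_n", "none")
model_im_asym <- function() demographic_model("e1_a", "asym")
model_im_sym <- function() demographic_model("e1_s", "sym")
model_sc <- function() demographic_model("e2_ns", c("none", "sym"))

# msprime-backed coalescent oracle (branch-mode joint AFS per unit theta).
# epochs: list (oldest first) of list(T, nu1, nu2, m12, m21); island models
# are simulated as a replicate-split mixture of the two locus classes.
oracle_script <- function() {
  system.file("oracle", "afs_oracle.py", package = "jointsfs")
}

run_afs_oracle <- function(n1, n2, epochs, reps, seed, anc = NULL,
                           m_factor = 1) {
  spec <- list(n1 = n1, n2 = n2, reps = reps, seed = seed, Nref = 1000,
               epochs = epochs, m_factor = m_factor)
  if (!is.null(anc)) spec$anc <- anc
  sj <- tempfile(fileext = ".json")
  oj <- tempfile(fileext = ".json")
  jsonlite::write_json(spec, sj, auto_unbox = TRUE, digits = NA)
  status <- system2("python", c(oracle_script(), sj, oj))
  if (status != 0L) stop("coalescent oracle failed")
  jsonlite::read_json(oj, simplifyVector = TRUE)
}

interior_mask <- function(n1, n2) {
  m <- matrix(TRUE, n1 + 1L, n2 + 1L)
  m[1L, 1L] <- FALSE
  m[n1 + 1L, n2 + 1L] <- FALSE
  m
}
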