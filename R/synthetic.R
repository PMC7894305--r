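#' Simulation configuration for synthetic genotype data
#'
#' Describes the generative process emulating the study design this package
#' targets: two diploid populations descending from a common ancestor under
#' a catalog demography, an outgroup individual carrying the ancestral
#' allele, read-depth and site-quality annotations, missing genotypes, and
#' physical positions of linked SNPs on scaffolds.
#'
#' @param model a [demographic_model].
#' @param values parameter vector for `model` (see [bind_parameters]).
#' @param n_dip1,n_dip2 diploid sample sizes per population.
#' @param n_loci number of independent loci (genealogies).
#' @param theta_locus population-scaled mutation rate per locus
#'   (`4 N_ref mu L_locus`).
#' @param locus_length locus span in bp (SNPs of one locus fall within it).
#' @param n_scaffolds,scaffold_length layout of loci on scaffolds.
#' @param miss_rate per-genotype missingness probability.
#' @param dp_mean,dp_size negative-binomial read-depth parameters.
#' @param qual_mean,qual_sd site quality distribution (normal, floored at 1).
#' @param p_ref_ancestral probability that the VCF REF allele is the
#'   ancestral state (otherwise REF is the derived allele).
#' @param outgroup_error probability of recording a wrong outgroup allele
#'   (polarization error; default 0, the outgroup is assumed diverged enough
#'   that ingroup polymorphism is never shared).
#' @param island_P fraction of loci in the reduced-migration island class
#'   (locus-level class; island loci scale all migration by `island_b`).
#' @param island_b island migration factor in `[0, 1]`.
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(model, values, n_dip1 = 27L, n_dip2 = 32L,
                       n_loci = 2000L, theta_locus = 1,
                       locus_length = 500L, n_scaffolds = 400L,
                       scaffold_length = 10000L, miss_rate = 0.05,
                       dp_mean = 20, dp_size = 5, qual_mean = 60,
                       qual_sd = 20, p_ref_ancestral = 0.5,
                       outgroup_error = 0, island_P = 0, island_b = 1,
                       seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(inherits(model, "demographic_model"),
            miss_rate >= 0, miss_rate <= 1,
            island_P >= 0, island_P <= 1, island_b >= 0, island_b <= 1,
            outgroup_error >= 0, outgroup_error <= 1)
  structure(list(model = model, values = values,
                 n_dip1 = as.integer(n_dip1), n_dip2 = as.integer(n_dip2),
                 n_loci = as.integer(n_loci), theta_locus = theta_locus,
                 locus_length = as.integer(locus_length),
                 n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(scaffold_length),
                 miss_rate = miss_rate, dp_mean = dp_mean, dp_size = dp_size,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 p_ref_ancestral = p_ref_ancestral,
                 outgroup_error = outgroup_error,
                 island_P = island_P, island_b = island_b,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Poisson-sampled joint SFS from a model expectation
#'
#' Draws each unmasked spectrum entry from a Poisson distribution with mean
#' `theta` times the model expectation — the sampling model under which the
#' composite likelihood is exact.
#'
#' @param model a [demographic_model].
#' @param values parameter vector.
#' @param n1,n2 haploid sample sizes.
#' @param theta scale `4 N_ref mu L`.
#' @param seed RNG seed.
#' @param control engine controls.
#' @return a [joint_sfs] of integer counts.
#' @export
simulate_sfs <- function(model, values, n1, n2, theta, seed,
                         control = sfs_engine_control()) {
  e <- expected_sfs(model, values, n1, n2, control)
  set.seed(seed)
  counts <- matrix(0, n1 + 1L, n2 + 1L)
  msk <- sfs_mask(e)
  counts[msk] <- rpois(sum(msk), theta * e$counts[msk])
  out <- joint_sfs(counts, polarized = TRUE, pop_labels = e$pop_labels)
  attr(out, "theta") <- theta
  out
}

# Structured-coalescent simulation of one locus under a piecewise two-deme
# demography. Time runs backwards in units of 2 N_ref generations; epochs are
# supplied newest first. Returns a list of derived-carrier haploid index sets,
# one per mutation (mutations subtending all samples are dropped: they are
# monomorphic within the ingroup).
.sim_locus <- function(n1h, n2h, epochs_bw, nuA, TA, theta_loc) {
  ntot <- n1h + n2h
  lineages <- as.list(seq_len(ntot))
  pop <- c(rep(1L, n1h), rep(2L, n2h))
  muts <- list()
  phase <- 1L  # index into epochs_bw, then ancestral phases
  t_left <- epochs_bw[[1]]$T
  repeat {
    k <- length(lineages)
    if (k <= 1L) break
    if (phase <= length(epochs_bw)) {
      pr <- epochs_bw[[phase]]
      nu <- c(pr$nu1, pr$nu2); M <- c(pr$m12, pr$m21)
    } else if (phase == length(epochs_bw) + 1L) {
      nu <- c(nuA, nuA); M <- c(0, 0)
    } else {
      nu <- c(1, 1); M <- c(0, 0)
    }
    k1 <- sum(pop == 1L); k2 <- k - k1
    rates <- c(k1 * (k1 - 1) / 2 / nu[1], k2 * (k2 - 1) / 2 / nu[2],
               k1 * M[1], k2 * M[2])
    R <- sum(rates)
    dt <- if (R > 0) rexp(1, R) else Inf
    dt_eff <- min(dt, t_left)
    if (is.finite(dt_eff) && dt_eff > 0 && theta_loc > 0) {
      nm <- rpois(1, theta_loc / 2 * dt_eff * k)
      if (nm > 0) {
        hit <- sample.int(k, nm, replace = TRUE)
        for (h in hit) muts[[length(muts) + 1L]] <- lineages[[h]]
      }
    }
    if (dt < t_left) {
      t_left <- t_left - dt
      ev <- sample.int(4L, 1L, prob = rates / R)
      if (ev <= 2L) {
        idx <- which(pop == ev)
        pair <- idx[sample.int(length(idx), 2L)]
        lineages[[pair[1]]] <- sort(c(lineages[[pair[1]]],
                                      lineages[[pair[2]]]))
        lineages[[pair[2]]] <- NULL
        pop <- pop[-pair[2]]
      } else {
        p_from <- ev - 2L
        idx <- which(pop == p_from)
        mv <- idx[sample.int(length(idx), 1L)]
        pop[mv] <- 3L - p_from
      }
    } else {
      # advance to the next phase boundary
      phase <- phase + 1L
      if (phase <= length(epochs_bw)) {
        t_left <- epochs_bw[[phase]]$T
      } else if (phase == length(epochs_bw) + 1L) {
        pop[] <- 1L  # populations merge into the ancestor
        t_left <- if (TA > 0) TA else 0
        if (TA <= 0) phase <- phase + 1L
        if (phase == length(epochs_bw) + 2L) t_left <- Inf
      } else {
        t_left <- Inf
      }
    }
  }
  muts[vapply(muts, length, integer(1)) < ntot]
}

#' Simulate genotype data with known truth
#'
#' Coalescent-samples genotypes for two populations under the configured
#' demography, adds an outgroup column carrying the ancestral allele, injects
#' depth, quality and missingness, and returns a standard VCF (as a
#' `vcfR::vcfR` object) plus a truth record with the generating parameters.
#'
#' @param config a [sim_config].
#' @return list with `vcf` (vcfR object; samples `p1_*`, `p2_*` and
#'   `outgroup`), `truth` (config, per-site ancestral/derived states, locus
#'   island classes), `populations` (named vector for the ingroup),
#'   `outgroup` (data frame scaffold/position/allele).
#' @export
simulate_vcf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  bound <- bind_parameters(config$model, config$values)
  epochs_bw <- rev(bound$epochs)   # newest first for backwards simulation
  n1h <- 2L * config$n_dip1
  n2h <- 2L * config$n_dip2

  island <- runif(config$n_loci) < config$island_P
  base <- c("A", "C", "G", "T")
  rows <- list()
  for (l in seq_len(config$n_loci)) {
    eb <- lapply(epochs_bw, function(e) {
      if (island[l]) { e$m12 <- e$m12 * config$island_b
                       e$m21 <- e$m21 * config$island_b }
      e
    })
    muts <- .sim_locus(n1h, n2h, eb, bound$nuA, bound$TA, config$theta_locus)
    if (!length(muts)) next
    scaf <- sample.int(config$n_scaffolds, 1L)
    start <- sample.int(max(config$scaffold_length - config$locus_length, 1L),
                        1L)
    pos <- start + sample.int(config$locus_length, length(muts))
    for (mm in seq_along(muts)) {
      anc <- sample(base, 1L)
      der <- sample(setdiff(base, anc), 1L)
      rows[[length(rows) + 1L]] <- list(
        scaffold = sprintf("scaffold_%04d", scaf), position = pos[mm],
        locus = l, island = island[l], anc = anc, der = der,
        carriers = muts[[mm]])
    }
  }
  if (!length(rows)) stop("no polymorphic sites simulated; increase n_loci ",
                          "or theta_locus")
  ord <- order(vapply(rows, `[[`, character(1), "scaffold"),
               vapply(rows, `[[`, integer(1), "position"))
  rows <- rows[ord]

  n_sites <- length(rows)
  sample_names <- c(sprintf("p1_%02d", seq_len(config$n_dip1)),
                    sprintf("p2_%02d", seq_len(config$n_dip2)))
  n_samp <- length(sample_names)
  fix <- matrix(NA_character_, n_sites, 8L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(NA_character_, n_sites, n_samp + 2L)
  colnames(gt) <- c("FORMAT", sample_names, "outgroup")
  truth_sites <- vector("list", n_sites)

  for (s in seq_len(n_sites)) {
    r <- rows[[s]]
    hap <- integer(n1h + n2h)
    hap[r$carriers] <- 1L
    dos <- hap[seq(1, length(hap), by = 2)] + hap[seq(2, length(hap), by = 2)]
    ref_is_anc <- runif(1) < config$p_ref_ancestral
    ref <- if (ref_is_anc) r$anc else r$der
    alt <- if (ref_is_anc) r$der else r$anc
    alt_dos <- if (ref_is_anc) dos else 2L - dos
    qual <- max(1, round(rnorm(1, config$qual_mean, config$qual_sd), 1))
    og_allele <- r$anc
    if (config$outgroup_error > 0 && runif(1) < config$outgroup_error)
      og_allele <- sample(setdiff(base, og_allele), 1L)
    fix[s, ] <- c(r$scaffold, as.character(r$position), NA, ref, alt,
                  sprintf("%.1f", qual), "PASS", paste0("AA=", og_allele))
    dp <- pmax(1L, rnbinom(n_samp, mu = config$dp_mean,
                            size = config$dp_size))
    miss <- runif(n_samp) < config$miss_rate
    cells <- character(n_samp)
    for (i in seq_len(n_samp)) {
      if (miss[i]) { cells[i] <- "./.:0:0,0"; next }
      g <- alt_dos[i]
      ad_alt <- if (g == 0L) 0L else if (g == 2L) dp[i]
                else rbinom(1, dp[i], 0.5)
      cells[i] <- sprintf("%s:%d:%d,%d",
                          c("0/0", "0/1", "1/1")[g + 1L], dp[i],
                          dp[i] - ad_alt, ad_alt)
    }
    og_dos <- if (og_allele == ref) 0L else if (og_allele == alt) 2L else NA
    og_dp <- pmax(1L, rnbinom(1, mu = config$dp_mean, size = config$dp_size))
    gt[s, ] <- c("GT:DP:AD",
                 cells,
                 if (is.na(og_dos)) "./.:0:0,0" else
                   sprintf("%s:%d:%d,%d", c("0/0", "0/1", "1/1")[og_dos + 1L],
                           og_dp, if (og_dos == 0L) og_dp else 0L,
                           if (og_dos == 0L) 0L else og_dp))
    truth_sites[[s]] <- data.frame(
      scaffold = r$scaffold, position = r$position, locus = r$locus,
      island = r$island, ancestral = r$anc, derived = r$der,
      ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_sites)
  meta <- c("##fileformat=VCFv4.2",
            "##source=jointsfs_simulate_vcf",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele (outgroup)\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  vcf <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  populations <- setNames(rep(c("pop1", "pop2"),
                              c(config$n_dip1, config$n_dip2)), sample_names)
  outgroup <- data.frame(scaffold = truth$scaffold,
                         position = truth$position,
                         allele = vapply(seq_len(nrow(truth)), function(s) {
                           sub("AA=", "", fix[s, "INFO"])
                         }, character(1)), stringsAsFactors = FALSE)
  list(vcf = vcf, truth = list(config = config, sites = truth,
                               island_loci = which(island)),
       populations = populations, outgroup = outgroup)
}

#' Write a vcfR object as plain-text VCF
#' @param vcf a `vcfR::vcfR` object.
#' @param path output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf_plain <- function(vcf, path) {
  fix <- vcf@fix
  fix[is.na(fix)] <- "."
  body <- cbind(fix, vcf@gt)
  body[is.na(body)] <- "."
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(vcf@meta, con)
  writeLines(paste0("#", paste(c(colnames(vcf@fix), colnames(vcf@gt)),
                               collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Hand-built fixture VCF exercising every filter rule
#'
#' A small deterministic VCF (two populations of 8 diploids plus one
#' deliberately under-sequenced individual) in which each record either
#' passes the whole filter chain or violates exactly one rule, together with
#' a manifest of the expected outcome per record and expected per-rule drop
#' counts. Pins the behaviour of [site_filters], [polarize], [thin_sites]
#' and [drop_undersequenced_individuals].
#'
#' @return list with `vcf` (vcfR object), `populations`, `manifest` (data
#'   frame record id -> expected outcome), `expected` (list of expected
#'   per-rule counts and survivors).
#' @export
fixture_vcf <- function() {
  p1 <- sprintf("p1_%02d", 1:12)
  p2 <- sprintf("p2_%02d", 1:12)
  bad <- "p1_bad"
  samples <- c(p1, p2, bad)
  populations <- setNames(rep(c("pop1", "pop2", "pop1"), c(12, 12, 1)),
                          samples)

  recs <- list()
  cell <- function(g, dp = 10L) {
    ad <- switch(g, "0/0" = sprintf("%d,0", dp), "0/1" = {
      a <- dp %/% 2L; sprintf("%d,%d", dp - a, a)
    }, "1/1" = sprintf("0,%d", dp), "./." = "0,0")
    if (g == "./.") "./.:0:0,0" else sprintf("%s:%d:%s", g, dp, ad)
  }
  std24 <- function(gts, dps = rep(10L, 24L))
    mapply(cell, gts, dps, USE.NAMES = FALSE)
  # per-population genotype template passing every rule: segregating and
  # compatible with Hardy-Weinberg proportions (3 hom-ref, 6 het, 3 hom-alt)
  hw_ok <- c(rep("0/0", 3), rep("0/1", 6), rep("1/1", 3))
  add <- function(id, chrom, pos, ref, alt, qual, info, gts24, bad_gt = "./.",
                  expected, note = "") {
    recs[[length(recs) + 1L]] <<- list(
      id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
      qual = qual, info = info, cells = c(gts24, cell(bad_gt)),
      expected = expected, note = note)
  }

  add("clean_1", "fx_s1", 1000L, "A", "G", "50.0", "AA=A",
      std24(c(hw_ok, hw_ok)), bad_gt = "0/0", expected = "retained")
  add("low_qual", "fx_s1", 3000L, "C", "T", "29.0", "AA=C",
      std24(c(hw_ok, hw_ok)), expected = "site_quality")
  add("triallelic", "fx_s1", 5000L, "G", "A,T", "50.0", "AA=G",
      std24(c(hw_ok, hw_ok)), expected = "biallelic_snp")
  add("indel", "fx_s2", 2000L, "ATTC", "A", "50.0", "AA=ATTC",
      std24(c(hw_ok, hw_ok)), expected = "biallelic_snp",
      note = "indel record; removed as non-SNP")
  add("near_indel", "fx_s2", 2028L, "T", "C", "50.0", "AA=T",
      std24(c(hw_ok, hw_ok)), expected = "indel_proximity",
      note = "25 bp from the indel footprint end (2003)")
  # every heterozygote at 9 ref / 1 alt reads: pooled balance 0.10 < 0.20
  skew_het <- function(gts) ifelse(gts == "0/1", "0/1:10:9,1",
                                   vapply(gts, cell, character(1)))
  add("bad_balance", "fx_s3", 1000L, "A", "C", "50.0", "AA=A",
      skew_het(c(hw_ok, hw_ok)), expected = "allele_balance")
  add("hwe_fail", "fx_s4", 1000L, "G", "T", "50.0", "AA=G",
      std24(c(rep("0/0", 6), rep("1/1", 6), hw_ok)), expected = "hwe_exact",
      note = "no heterozygotes among 12 pop1 diploids: exact p = 3.4e-4")
  add("pop2_missing", "fx_s5", 1000L, "A", "T", "50.0", "AA=A",
      std24(c(hw_ok, "./.", "./.", hw_ok[3:12])), expected = "pop_missingness",
      note = "2/12 missing in pop2: 83% called < 90%")
  add("low_dp", "fx_s6", 1000L, "C", "G", "50.0", "AA=C",
      std24(c(hw_ok, hw_ok), dps = c(rep(10L, 12), 3L, 3L, rep(10L, 10))),
      expected = "pop_missingness",
      note = "two pop2 genotypes at DP 3 masked by rule 3, then 83% < 90%")
  add("thin_a", "fx_s7", 100L, "A", "G", "50.0", "AA=A",
      std24(c(hw_ok, hw_ok)), bad_gt = "0/0", expected = "retained")
  add("thin_b", "fx_s7", 600L, "C", "T", "50.0", "AA=C",
      std24(c(hw_ok, hw_ok)), expected = "thinned",
      note = "500 bp from thin_a: dropped by 1000 bp thinning")
  add("thin_c", "fx_s7", 1150L, "G", "A", "50.0", "AA=G",
      std24(c(hw_ok, hw_ok)), expected = "retained",
      note = "1050 bp from thin_a: survives thinning")
  add("og_third", "fx_s8", 1000L, "A", "G", "50.0", "AA=T",
      std24(c(hw_ok, hw_ok)), expected = "unpolarizable_third")
  add("og_missing", "fx_s8", 3000L, "A", "G", "50.0", ".",
      std24(c(hw_ok, hw_ok)), expected = "unpolarizable_missing")
  add("og_alt", "fx_s9", 1000L, "A", "G", "50.0", "AA=G",
      std24(c(hw_ok, hw_ok)), expected = "retained",
      note = "outgroup carries ALT: derived counts are REF counts")

  fix <- do.call(rbind, lapply(recs, function(r)
    c(r$chrom, as.character(r$pos), r$id, r$ref, r$alt, r$qual, "PASS",
      r$info)))
  colnames(fix) <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO")
  gt <- do.call(rbind, lapply(recs, function(r) c("GT:DP:AD", r$cells)))
  colnames(gt) <- c("FORMAT", samples)
  meta <- c("##fileformat=VCFv4.2", "##source=jointsfs_fixture",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  manifest <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    expected = vapply(recs, `[[`, character(1), "expected"),
    stringsAsFactors = FALSE)
  drops <- table(manifest$expected)
  expected <- list(
    removed_individuals = bad,
    rule_drops = c(indel_proximity = 1L, biallelic_snp = 2L,
                   site_quality = 1L, pop_missingness = 2L,
                   allele_balance = 1L, hwe_exact = 1L),
    genotypes_masked = 2L,
    polarization = c(polarized = 5L, missing_outgroup = 1L,
                     third_allele = 1L),
    thinned_out = "thin_b",
    final_ids = c("clean_1", "thin_a", "thin_c", "og_alt"),
    og_alt_d1 = 24L - 12L  # 12 ALT copies in pop1 -> derived = REF = 12
  )
  stopifnot(sum(drops[names(expected$rule_drops)]) ==
              sum(expected$rule_drops))
  list(vcf = methods::new("vcfR", meta = meta, fix = fix, gt = gt),
       populations = populations, manifest = manifest, expected = expected)
}
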