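#' Filter configuration
#'
#' Thresholds for the deterministic SNP filter chain. Defaults reproduce a
#' conservative RNAseq SNP-filtering protocol: biallelic SNPs only, genotype
#' depth >= 5, site quality >= 30, >= 90% of genotypes called per population,
#' a 20-80% allele balance at heterozygous sites, exact Hardy-Weinberg
#' exclusion at p < 0.001 within each population, removal of SNPs within
#' 30 bp of indels, one SNP kept per 1000 bp, and removal of individuals
#' genotyped at < 50% of sites.
#'
#' @param min_dp minimum per-genotype read depth; genotypes below are set to
#'   missing.
#' @param min_q minimum site QUAL.
#' @param max_missing_frac_per_pop maximum fraction of missing genotypes
#'   tolerated per population (0.1 means >= 90% called).
#' @param ab_min allele-balance lower bound on pooled heterozygote reads.
#' @param hwe_p_threshold exact-test exclusion threshold, applied per
#'   population.
#' @param thin_bp minimum distance between retained SNPs within a scaffold.
#' @param indel_buffer_bp SNPs within this distance of an indel's reference
#'   footprint are removed.
#' @param indiv_missing_max maximum fraction of missing sites tolerated per
#'   individual.
#' @param biallelic_only keep biallelic SNPs only.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_dp = 5, min_q = 30,
                          max_missing_frac_per_pop = 0.1,
                          ab_min = 0.20, hwe_p_threshold = 0.001,
                          thin_bp = 1000, indel_buffer_bp = 30,
                          indiv_missing_max = 0.5, biallelic_only = TRUE) {
  stopifnot(min_dp >= 0, min_q >= 0,
            max_missing_frac_per_pop >= 0, max_missing_frac_per_pop <= 1,
            ab_min >= 0, ab_min <= 0.5,
            hwe_p_threshold >= 0, hwe_p_threshold <= 1,
            thin_bp >= 1, indel_buffer_bp >= 0,
            indiv_missing_max >= 0, indiv_missing_max <= 1)
  structure(list(min_dp = min_dp, min_q = min_q,
                 max_missing_frac_per_pop = max_missing_frac_per_pop,
                 ab_min = ab_min, hwe_p_threshold = hwe_p_threshold,
                 thin_bp = thin_bp, indel_buffer_bp = indel_buffer_bp,
                 indiv_missing_max = indiv_missing_max,
                 biallelic_only = biallelic_only),
            class = "filter_config")
}

# genotype dosage matrix (count of ALT alleles; NA = missing) from a vcfR gt
# slot; handles /, | separators and haploid calls
.gt_dosage <- function(vcf) {
  gt <- vcfR::extract.gt(vcf, element = "GT")
  al1 <- substr(gt, 1, 1)
  al2 <- substr(gt, 3, 3)
  d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt) & al1 %in% c("0", "1") & al2 %in% c("0", "1")
  d[ok] <- (al1[ok] == "1") + (al2[ok] == "1")
  d
}

#' Remove under-sequenced individuals
#'
#' Drops samples whose fraction of called genotypes across all sites is below
#' `1 - max_missing` (default: individuals with more than 50% missing).
#'
#' @param vcf a `vcfR::vcfR` object.
#' @param max_missing maximum tolerated missing fraction per individual.
#' @return list with `vcf` (subset), `removed` (sample names) and
#'   `call_rate` (named vector of per-sample call rates).
#' @export
drop_undersequenced_individuals <- function(vcf, max_missing = 0.5) {
  gt <- .gt_dosage(vcf)
  if (ncol(gt) < 1L) stop("VCF has no samples")
  call_rate <- colMeans(!is.na(gt))
  keep <- call_rate >= 1 - max_missing
  if (!any(keep)) stop("all samples removed as under-sequenced (empty cohort)")
  out <- vcf
  out@gt <- out@gt[, c(TRUE, keep), drop = FALSE]  # first column is FORMAT
  list(vcf = out, removed = names(call_rate)[!keep], call_rate = call_rate)
}

# indel footprint test: TRUE for SNP records within `buffer` bp of any
# indel's reference span (POS .. POS + nchar(REF) - 1) on the same scaffold
.near_indel <- function(chrom, pos, ref, alt, buffer) {
  alt_split <- strsplit(ifelse(is.na(alt), "", alt), ",")
  is_indel <- nchar(ref) > 1L |
    vapply(alt_split, function(a) any(nchar(a) > 1L & a != "*"), logical(1))
  flag <- rep(FALSE, length(pos))
  for (ch in unique(chrom[is_indel])) {
    idx_i <- which(is_indel & chrom == ch)
    lo <- pos[idx_i] - buffer
    hi <- pos[idx_i] + nchar(ref[idx_i]) - 1L + buffer
    idx_s <- which(chrom == ch & !is_indel)
    if (!length(idx_s)) next
    for (k in seq_along(idx_i)) {
      hit <- pos[idx_s] >= lo[k] & pos[idx_s] <= hi[k]
      flag[idx_s[hit]] <- TRUE
    }
  }
  flag
}

#' Site-level filter chain
#'
#' Applies, in order, with per-rule drop counts logged:
#' \enumerate{
#'   \item remove SNPs within `indel_buffer_bp` of an indel record (indel
#'     records themselves fall to rule 2);
#'   \item keep biallelic SNPs only;
#'   \item set genotypes with depth < `min_dp` to missing (genotype-level,
#'     not a site drop);
#'   \item drop sites with QUAL < `min_q`;
#'   \item drop sites with more than `max_missing_frac_per_pop` missing
#'     genotypes in either population;
#'   \item drop sites failing allele balance: pooled reads over heterozygous
#'     genotypes must support each allele with fraction >= `ab_min`;
#'   \item drop sites with an exact Hardy-Weinberg p-value below
#'     `hwe_p_threshold` in either population.
#' }
#'
#' @param vcf a `vcfR::vcfR` object.
#' @param populations named character vector mapping sample name to
#'   population; must cover all samples in the VCF.
#' @param config a [filter_config].
#' @param strict if `TRUE`, a missing DP or AD annotation needed by a rule is
#'   an error; if `FALSE`, the rule is skipped with a warning.
#' @return list with `vcf` (filtered), `log` (data frame rule/dropped/
#'   retained), `genotypes_masked` (count from rule 3).
#' @export
site_filters <- function(vcf, populations, config = filter_config(),
                         strict = TRUE) {
  samples <- colnames(vcf@gt)[-1]
  if (!all(samples %in% names(populations)))
    stop("population map does not cover samples: ",
         paste(setdiff(samples, names(populations)), collapse = ", "))
  pops <- populations[samples]
  pop_ids <- unique(unname(pops))
  if (length(pop_ids) != 2L) stop("exactly two populations are required")

  steps <- character(0); dropped <- integer(0); retained <- integer(0)
  note <- function(rule, n_before, n_after) {
    steps <<- c(steps, rule)
    dropped <<- c(dropped, n_before - n_after)
    retained <<- c(retained, n_after)
  }

  # rule 1: indel proximity
  n0 <- nrow(vcf@fix)
  near <- .near_indel(vcf@fix[, "CHROM"], as.integer(vcf@fix[, "POS"]),
                      vcf@fix[, "REF"], vcf@fix[, "ALT"],
                      config$indel_buffer_bp)
  vcf <- vcf[!near, ]
  note("indel_proximity", n0, nrow(vcf@fix))

  # rule 2: biallelic SNPs
  n0 <- nrow(vcf@fix)
  if (config$biallelic_only) {
    ref <- vcf@fix[, "REF"]; alt <- vcf@fix[, "ALT"]
    snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L &
      nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
      alt %in% c("A", "C", "G", "T")
    vcf <- vcf[snp, ]
  }
  note("biallelic_snp", n0, nrow(vcf@fix))

  # rule 3: genotype depth masking
  genotypes_masked <- 0L
  dp <- suppressWarnings(vcfR::extract.gt(vcf, "DP", as.numeric = TRUE))
  if (is.null(dp) || all(is.na(dp))) {
    if (strict) stop("DP genotype annotation required for depth masking")
    warning("DP missing; depth masking skipped")
  } else {
    called <- !is.na(.gt_dosage(vcf))
    mask <- called & !is.na(dp) & dp < config$min_dp
    genotypes_masked <- sum(mask)
    if (genotypes_masked > 0) {
      gt_body <- vcf@gt[, -1, drop = FALSE]
      gt_body[mask] <- NA_character_
      vcf@gt[, -1] <- gt_body
    }
  }
  note("genotype_depth_mask", nrow(vcf@fix), nrow(vcf@fix))

  # rule 4: site quality
  n0 <- nrow(vcf@fix)
  qual <- suppressWarnings(as.numeric(vcf@fix[, "QUAL"]))
  if (all(is.na(qual))) {
    if (strict) stop("QUAL required for the site-quality rule")
    warning("QUAL missing; quality rule skipped")
  } else {
    vcf <- vcf[!is.na(qual) & qual >= config$min_q, ]
  }
  note("site_quality", n0, nrow(vcf@fix))

  # rule 5: per-population missingness
  n0 <- nrow(vcf@fix)
  dos <- .gt_dosage(vcf)
  keep <- rep(TRUE, nrow(dos))
  for (p in pop_ids) {
    cols <- which(pops == p)
    called <- rowMeans(!is.na(dos[, cols, drop = FALSE]))
    keep <- keep & called >= 1 - config$max_missing_frac_per_pop
  }
  vcf <- vcf[keep, ]
  note("pop_missingness", n0, nrow(vcf@fix))

  # rule 6: allele balance on pooled heterozygote reads
  n0 <- nrow(vcf@fix)
  ad <- vcfR::extract.gt(vcf, "AD")
  if (is.null(ad) || all(is.na(ad))) {
    if (strict) stop("AD genotype annotation required for allele balance")
    warning("AD missing; allele-balance rule skipped")
  } else {
    dos <- .gt_dosage(vcf)
    het <- !is.na(dos) & dos == 1
    ref_reads <- suppressWarnings(
      as.numeric(vapply(strsplit(ad, ","), `[`, character(1), 1)))
    alt_reads <- suppressWarnings(
      as.numeric(vapply(strsplit(ad, ","), function(x)
        if (length(x) >= 2) x[2] else NA_character_, character(1))))
    dim(ref_reads) <- dim(ad); dim(alt_reads) <- dim(ad)
    ref_reads[!het] <- 0; alt_reads[!het] <- 0
    ref_reads[is.na(ref_reads)] <- 0; alt_reads[is.na(alt_reads)] <- 0
    tot <- rowSums(ref_reads) + rowSums(alt_reads)
    frac_ref <- ifelse(tot > 0, rowSums(ref_reads) / tot, 0.5)
    bal_ok <- tot == 0 |
      (frac_ref >= config$ab_min & frac_ref <= 1 - config$ab_min)
    vcf <- vcf[bal_ok, ]
  }
  note("allele_balance", n0, nrow(vcf@fix))

  # rule 7: Hardy-Weinberg exclusion per population
  n0 <- nrow(vcf@fix)
  dos <- .gt_dosage(vcf)
  keep <- rep(TRUE, nrow(dos))
  for (p in pop_ids) {
    cols <- which(pops == p)
    sub <- dos[, cols, drop = FALSE]
    nAA <- rowSums(sub == 0, na.rm = TRUE)
    nAa <- rowSums(sub == 1, na.rm = TRUE)
    naa <- rowSums(sub == 2, na.rm = TRUE)
    pv <- hwe_exact_p_vec(nAA, nAa, naa)
    keep <- keep & (is.na(pv) | pv >= config$hwe_p_threshold)
  }
  vcf <- vcf[keep, ]
  note("hwe_exact", n0, nrow(vcf@fix))

  list(vcf = vcf,
       log = data.frame(rule = steps, dropped = dropped,
                        retained = retained, stringsAsFactors = FALSE),
       genotypes_masked = genotypes_masked)
}

#' Thin sites to one per window
#'
#' Greedy distance-based thinning: within each scaffold the first site (in
#' position order) is kept, then the next site at least `thin_bp` away, and
#' so on. Output positions within a scaffold are pairwise `>= thin_bp` apart;
#' duplicated rows cannot re-enter.
#'
#' @param sites a [site_table] (any data frame with `scaffold`, `position`).
#' @param thin_bp minimum spacing in bp.
#' @return the thinned table, same class as the input.
#' @export
thin_sites <- function(sites, thin_bp = 1000) {
  if (nrow(sites) == 0L) return(sites)
  ord <- order(sites$scaffold, sites$position)
  if (any(ord != seq_len(nrow(sites)))) {
    warning("sites not sorted by (scaffold, position); sorting")
    sites <- sites[ord, , drop = FALSE]
  }
  keep <- logical(nrow(sites))
  last_scaf <- ""
  last_pos <- -Inf
  for (r in seq_len(nrow(sites))) {
    if (sites$scaffold[r] != last_scaf ||
        sites$position[r] >= last_pos + thin_bp) {
      if (!(sites$scaffold[r] == last_scaf &&
            sites$position[r] == last_pos)) keep[r] <- TRUE
      last_scaf <- sites$scaffold[r]
      if (keep[r]) last_pos <- sites$position[r]
    }
  }
  sites[keep, , drop = FALSE]
}

#' Polarize VCF sites against an outgroup
#'
#' Assigns derived/ancestral states from the outgroup allele: where the
#' outgroup matches REF, derived counts are ALT counts; where it matches ALT,
#' derived counts are REF counts; sites with a missing outgroup allele or a
#' third state are dropped and counted.
#'
#' @param vcf a `vcfR::vcfR` object of biallelic SNPs.
#' @param outgroup_alleles data frame with columns `scaffold`, `position`,
#'   `allele` (single base, NA = missing), or a named character vector keyed
#'   by `"scaffold:position"`. Alternatively `NULL` to read the `AA` INFO tag.
#' @param populations named character vector sample -> population (two
#'   populations; the first in sorted unique order is population 1 unless
#'   `pop_order` is given).
#' @param pop_order optional character vector of length 2 fixing which
#'   population is population 1.
#' @return list with `sites` (a [site_table]) and `log` (counts of
#'   polarizable / missing-outgroup / third-allele sites).
#' @export
polarize <- function(vcf, outgroup_alleles, populations, pop_order = NULL) {
  samples <- colnames(vcf@gt)[-1]
  pops <- populations[samples]
  pop_ids <- if (is.null(pop_order)) sort(unique(unname(pops))) else pop_order
  if (length(pop_ids) != 2L) stop("exactly two populations are required")
  chrom <- vcf@fix[, "CHROM"]
  pos <- as.integer(vcf@fix[, "POS"])
  ref <- vcf@fix[, "REF"]; alt <- vcf@fix[, "ALT"]

  og <- if (is.null(outgroup_alleles)) {
    aa <- vcfR::extract.info(vcf, "AA")
    toupper(ifelse(is.na(aa) | aa == ".", NA_character_, aa))
  } else if (is.data.frame(outgroup_alleles)) {
    key <- paste(outgroup_alleles$scaffold, outgroup_alleles$position,
                 sep = ":")
    toupper(outgroup_alleles$allele[match(paste(chrom, pos, sep = ":"), key)])
  } else {
    toupper(unname(outgroup_alleles[paste(chrom, pos, sep = ":")]))
  }

  status <- ifelse(is.na(og), "missing",
                   ifelse(og == ref, "ref_ancestral",
                          ifelse(og == alt, "alt_ancestral", "third_allele")))
  usable <- status %in% c("ref_ancestral", "alt_ancestral")

  dos <- .gt_dosage(vcf)
  d_list <- c_list <- list()
  for (p in pop_ids) {
    cols <- which(pops == p)
    sub <- dos[, cols, drop = FALSE]
    alt_cnt <- rowSums(sub, na.rm = TRUE)
    called <- 2L * rowSums(!is.na(sub))
    d_list[[p]] <- alt_cnt
    c_list[[p]] <- called
  }
  swap <- status == "alt_ancestral"
  d1 <- ifelse(swap, c_list[[1]] - d_list[[1]], d_list[[1]])
  d2 <- ifelse(swap, c_list[[2]] - d_list[[2]], d_list[[2]])

  sites <- site_table(
    scaffold = chrom[usable], position = pos[usable],
    d1 = d1[usable], c1 = c_list[[1]][usable],
    d2 = d2[usable], c2 = c_list[[2]][usable],
    ancestral = ifelse(swap, alt, ref)[usable],
    derived = ifelse(swap, ref, alt)[usable]
  )
  attr(sites, "pop_labels") <- pop_ids
  list(sites = sites,
       log = c(polarized = sum(usable),
               missing_outgroup = sum(status == "missing"),
               third_allele = sum(status == "third_allele")))
}

#' Read a two-column population map
#' @param path TSV with columns sample and population (no header or header
#'   `sample  population`).
#' @return named character vector sample -> population.
#' @export
read_population_map <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(as.character(x[1, ])), c("sample", "population")))
    x <- x[-1, , drop = FALSE]
  setNames(as.character(x[[2]]), as.character(x[[1]]))
}

#' Full VCF-to-site-table filter pipeline
#'
#' Convenience wrapper chaining [drop_undersequenced_individuals],
#' [site_filters], [polarize] and [thin_sites], collecting a JSON-ready
#' report.
#'
#' @param vcf a `vcfR::vcfR` object.
#' @param populations named character vector sample -> population.
#' @param outgroup_alleles see [polarize].
#' @param config a [filter_config].
#' @param pop_order optional, see [polarize].
#' @param strict see [site_filters].
#' @return list with `sites`, `vcf` (filtered), `report`.
#' @export
filter_pipeline <- function(vcf, populations, outgroup_alleles = NULL,
                            config = filter_config(), pop_order = NULL,
                            strict = TRUE) {
  samples <- colnames(vcf@gt)[-1]
  unmapped <- setdiff(samples, names(populations))
  if (length(unmapped)) {
    # samples outside the two focal populations (e.g. an outgroup column)
    # take no part in filtering
    vcf@gt <- vcf@gt[, c(TRUE, samples %in% names(populations)),
                     drop = FALSE]
  }
  ind <- drop_undersequenced_individuals(vcf, config$indiv_missing_max)
  sf <- site_filters(ind$vcf, populations, config, strict = strict)
  pol <- polarize(sf$vcf, outgroup_alleles, populations, pop_order)
  n_prethin <- nrow(pol$sites)
  sites <- thin_sites(pol$sites, config$thin_bp)
  report <- list(
    unmapped_samples_excluded = unmapped,
    individuals_removed = ind$removed,
    site_filter_log = sf$log,
    genotypes_masked = sf$genotypes_masked,
    polarization = as.list(pol$log),
    thinning = list(before = n_prethin, after = nrow(sites)),
    config = unclass(config)
  )
  list(sites = sites, vcf = sf$vcf, report = report)
}
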