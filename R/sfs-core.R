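#' Joint two-population site frequency spectrum
#'
#' Container for an (unfolded or folded) joint site frequency spectrum (SFS)
#' of two populations. Entry `counts[i + 1, j + 1]` holds the number (or
#' expected number) of sites with `i` derived alleles among `n1` sampled
#' alleles of population 1 and `j` derived alleles among `n2` of population 2.
#' The corner entries (0, 0) and (n1, n2) carry no polymorphism information;
#' they are retained in storage but excluded ("masked") from every statistic
#' computed by this package.
#'
#' @param counts numeric matrix, dimensions `(n1 + 1) x (n2 + 1)`, all entries
#'   non-negative and finite.
#' @param polarized logical; `TRUE` for an unfolded (ancestral state known)
#'   spectrum, `FALSE` for a folded (minor allele) spectrum.
#' @param L_effective total callable sequence length in bp used when scaling
#'   theta to demographic units; may be `NA` when unknown.
#' @param pop_labels character vector of two population names. Population 1 is
#'   always the first label and indexes rows of `counts`.
#' @return An object of class `joint_sfs` with fields `counts`, `n1`, `n2`,
#'   `polarized`, `L_effective`, `pop_labels`.
#' @examples
#' m <- matrix(0, 3, 3)
#' m[2, 1] <- 5
#' joint_sfs(m, pop_labels = c("Deep", "Shallow"))
#' @export
joint_sfs <- function(counts, polarized = TRUE, L_effective = NA_real_,
                      pop_labels = c("pop1", "pop2")) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("`counts` must be at least 2 x 2 (n1, n2 >= 1)")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("`counts` entries must be finite and non-missing")
  if (any(counts < 0))
    stop("`counts` entries must be non-negative")
  if (length(pop_labels) != 2L)
    stop("`pop_labels` must have length 2")
  x <- list(
    counts = unname(counts),
    n1 = nrow(counts) - 1L,
    n2 = ncol(counts) - 1L,
    polarized = isTRUE(polarized),
    L_effective = as.numeric(L_effective),
    pop_labels = as.character(pop_labels)
  )
  class(x) <- "joint_sfs"
  x
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf(
    "Joint SFS (%s): %s n1 = %d (%s), n2 = %d (%s)\n",
    if (x$polarized) "unfolded" else "folded",
    if (is.na(x$L_effective)) "" else sprintf("L = %g bp,", x$L_effective),
    x$n1, x$pop_labels[1], x$n2, x$pop_labels[2]
  ))
  cat(sprintf("Unmasked total mass: %.6g\n", sfs_total(x)))
  invisible(x)
}

#' Mask of informative spectrum entries
#'
#' Logical matrix marking the entries of a joint SFS that enter likelihoods and
#' summary statistics. The fixed corners (0, 0) and (n1, n2) are always
#' excluded; for a folded spectrum the redundant major-allele half is excluded
#' as well.
#'
#' @param sfs a [joint_sfs] object.
#' @return logical matrix of the same shape as `sfs$counts`; `TRUE` marks
#'   entries used in computations.
#' @export
sfs_mask <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  m <- matrix(TRUE, sfs$n1 + 1L, sfs$n2 + 1L)
  m[1L, 1L] <- FALSE
  m[sfs$n1 + 1L, sfs$n2 + 1L] <- FALSE
  if (!sfs$polarized) {
    for (i in 0:sfs$n1) for (j in 0:sfs$n2) {
      ic <- sfs$n1 - i; jc <- sfs$n2 - j
      if (i > ic || (i == ic && j > jc)) m[i + 1L, j + 1L] <- FALSE
    }
  }
  m
}

#' Total unmasked mass of a joint SFS
#' @param sfs a [joint_sfs] object.
#' @return scalar sum of counts over unmasked entries.
#' @export
sfs_total <- function(sfs) {
  sum(sfs$counts[sfs_mask(sfs)])
}

.check_count_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 ||
      abs(x - round(x)) > 1e-8)
    stop(sprintf("`%s` must be a single non-negative integer", name))
  as.integer(round(x))
}

#' Hypergeometric projection of one site
#'
#' Distributes a site with `d_obs` derived alleles among `n_obs` called alleles
#' over the derived-allele classes of a smaller sample of `n_target` alleles,
#' using the expectation under hypergeometric subsampling (every subset of
#' `n_target` alleles equally likely). Sites with fewer called alleles than the
#' target cannot be projected and contribute nothing.
#'
#' @param d_obs observed derived-allele count (integer, `0 <= d_obs <= n_obs`).
#' @param n_obs number of called alleles at the site.
#' @param n_target projected sample size in alleles (`>= 1`).
#' @return numeric vector of length `n_target + 1`; entry `d + 1` is the
#'   probability that the subsample carries `d` derived alleles. Sums to 1 when
#'   `n_obs >= n_target`, otherwise the all-zero vector (site dropped).
#' @examples
#' project_site(2, 4, 2)  # 1/6, 2/3, 1/6
#' @export
project_site <- function(d_obs, n_obs, n_target) {
  d_obs <- .check_count_scalar(d_obs, "d_obs")
  n_obs <- .check_count_scalar(n_obs, "n_obs")
  n_target <- .check_count_scalar(n_target, "n_target")
  if (n_target < 1L) stop("`n_target` must be >= 1")
  if (d_obs > n_obs) stop("`d_obs` must not exceed `n_obs`")
  if (n_obs < n_target) return(numeric(n_target + 1L))
  stats::dhyper(0:n_target, m = d_obs, n = n_obs - d_obs, k = n_target)
}

#' Projection matrix for all observed derived counts
#'
#' Row `d_obs + 1` is `project_site(d_obs, n_obs, n_target)`; used to project
#' whole spectra and site tables in one matrix product.
#'
#' @inheritParams project_site
#' @return `(n_obs + 1) x (n_target + 1)` matrix of projection weights.
#' @export
projection_matrix <- function(n_obs, n_target) {
  n_obs <- .check_count_scalar(n_obs, "n_obs")
  n_target <- .check_count_scalar(n_target, "n_target")
  t(vapply(0:n_obs, project_site, numeric(n_target + 1L),
           n_obs = n_obs, n_target = n_target))
}

#' Build a joint SFS from a polarized site table
#'
#' Each site contributes the outer product of its two per-population projection
#' vectors; sites with fewer called alleles than the target in either
#' population are dropped. The total unmasked-plus-corner mass equals the
#' number of projectable sites.
#'
#' @param sites a [site_table] (or data frame with columns `d1`, `c1`, `d2`,
#'   `c2`).
#' @param n1_target,n2_target projected haploid sample sizes for populations 1
#'   and 2.
#' @param L_effective,pop_labels stored on the result, see [joint_sfs].
#' @return a [joint_sfs]; attribute `n_dropped` counts sites lost to
#'   insufficient call depth.
#' @export
build_sfs <- function(sites, n1_target, n2_target,
                      L_effective = NA_real_, pop_labels = c("pop1", "pop2")) {
  n1_target <- .check_count_scalar(n1_target, "n1_target")
  n2_target <- .check_count_scalar(n2_target, "n2_target")
  counts <- matrix(0, n1_target + 1L, n2_target + 1L)
  if (nrow(sites) == 0L) {
    warning("empty site table; returning empty SFS")
    out <- joint_sfs(counts, polarized = TRUE, L_effective = L_effective,
                     pop_labels = pop_labels)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  stopifnot(all(c("d1", "c1", "d2", "c2") %in% names(sites)))
  keep <- sites$c1 >= n1_target & sites$c2 >= n2_target
  n_dropped <- sum(!keep)
  s <- sites[keep, , drop = FALSE]
  if (nrow(s) > 0L) {
    # one projection-matrix lookup per distinct called-allele count, then a
    # single crossproduct over sites
    P1 <- matrix(0, nrow(s), n1_target + 1L)
    P2 <- matrix(0, nrow(s), n2_target + 1L)
    for (c1 in unique(s$c1)) {
      pm <- projection_matrix(c1, n1_target)
      idx <- which(s$c1 == c1)
      P1[idx, ] <- pm[s$d1[idx] + 1L, , drop = FALSE]
    }
    for (c2 in unique(s$c2)) {
      pm <- projection_matrix(c2, n2_target)
      idx <- which(s$c2 == c2)
      P2[idx, ] <- pm[s$d2[idx] + 1L, , drop = FALSE]
    }
    counts <- crossprod(P1, P2)
  }
  out <- joint_sfs(counts, polarized = TRUE, L_effective = L_effective,
                   pop_labels = pop_labels)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Project a whole joint SFS to smaller sample sizes
#'
#' Exact hypergeometric projection applied to every entry; commutes with
#' projection of individual sites and with the expectation engine.
#'
#' @param sfs a [joint_sfs].
#' @param n1_new,n2_new new haploid sample sizes (`<=` current).
#' @return a [joint_sfs] at the new sample sizes.
#' @export
sfs_project <- function(sfs, n1_new, n2_new) {
  stopifnot(inherits(sfs, "joint_sfs"))
  n1_new <- .check_count_scalar(n1_new, "n1_new")
  n2_new <- .check_count_scalar(n2_new, "n2_new")
  if (n1_new > sfs$n1 || n2_new > sfs$n2)
    stop("cannot project a spectrum up to larger sample sizes")
  P1 <- projection_matrix(sfs$n1, n1_new)
  P2 <- projection_matrix(sfs$n2, n2_new)
  joint_sfs(crossprod(P1, sfs$counts %*% P2), polarized = sfs$polarized,
            L_effective = sfs$L_effective, pop_labels = sfs$pop_labels)
}

#' Fold an unfolded joint SFS
#'
#' Collapses derived/ancestral polarity onto minor-allele classes:
#' `folded[i, j] = unfolded[i, j] + unfolded[n1 - i, n2 - j]` over the
#' minor-allele half, with self-conjugate cells not double-counted. A
#' diagnostic utility; the inference pipeline itself works on unfolded spectra.
#'
#' @param sfs an unfolded [joint_sfs].
#' @return a folded [joint_sfs] with identical unmasked total mass.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (!sfs$polarized) stop("spectrum is already folded")
  n1 <- sfs$n1; n2 <- sfs$n2
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    ic <- n1 - i; jc <- n2 - j
    if (i < ic || (i == ic && j < jc)) {
      out[i + 1L, j + 1L] <- sfs$counts[i + 1L, j + 1L] +
        sfs$counts[ic + 1L, jc + 1L]
    } else if (i == ic && j == jc) {
      out[i + 1L, j + 1L] <- sfs$counts[i + 1L, j + 1L]
    }
  }
  joint_sfs(out, polarized = FALSE, L_effective = sfs$L_effective,
            pop_labels = sfs$pop_labels)
}

#' Marginal one-population SFS
#'
#' @param sfs a [joint_sfs].
#' @param which_pop 1 or 2.
#' @return numeric vector of length `n + 1` for the chosen population
#'   (entry `i + 1` = number of sites with `i` derived copies, summed over the
#'   other population's classes, corners included).
#' @export
marginal_sfs <- function(sfs, which_pop) {
  stopifnot(inherits(sfs, "joint_sfs"), which_pop %in% c(1L, 2L))
  if (which_pop == 1L) rowSums(sfs$counts) else colSums(sfs$counts)
}

#' Nucleotide diversity from a 1D SFS
#'
#' Average pairwise difference per base pair:
#' `pi = sum_i 2 i (n - i) / (n (n - 1)) * xi_i / L`, `i = 1 .. n - 1`.
#'
#' @param sfs_1d numeric vector of length `n + 1` (entry `i + 1` = count of
#'   sites with `i` derived or minor copies) or of length `n - 1` (polymorphic
#'   classes only).
#' @param n haploid sample size (`>= 2`).
#' @param L callable sequence length in bp (`> 0`).
#' @return scalar nucleotide diversity.
#' @export
nucleotide_diversity <- function(sfs_1d, n, L) {
  n <- .check_count_scalar(n, "n")
  if (n < 2L) stop("`n` must be >= 2")
  if (!is.numeric(L) || length(L) != 1L || is.na(L) || L <= 0)
    stop("`L` must be a positive scalar")
  if (length(sfs_1d) == n + 1L) {
    xi <- sfs_1d[2:n]
  } else if (length(sfs_1d) == n - 1L) {
    xi <- sfs_1d
  } else {
    stop("`sfs_1d` must have length n + 1 or n - 1")
  }
  i <- seq_len(n - 1L)
  sum(2 * i * (n - i) / (n * (n - 1)) * xi) / L
}

#' Hudson-style Fst from a joint SFS
#'
#' Ratio-of-averages estimator `1 - mean(pi_within) / pi_between` computed from
#' unmasked spectrum entries; used by engine diagnostics (expected Fst is
#' strictly decreasing in symmetric migration).
#'
#' @param sfs a [joint_sfs].
#' @return scalar Fst (NaN for an empty spectrum).
#' @export
fst_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  n1 <- sfs$n1; n2 <- sfs$n2
  i <- matrix(0:n1, n1 + 1L, n2 + 1L)
  j <- matrix(0:n2, n1 + 1L, n2 + 1L, byrow = TRUE)
  w <- sfs_mask(sfs) * sfs$counts
  pw1 <- if (n1 > 1) sum(w * i * (n1 - i)) / (n1 * (n1 - 1)) else 0
  pw2 <- if (n2 > 1) sum(w * j * (n2 - j)) / (n2 * (n2 - 1)) else 0
  pb <- sum(w * (i * (n2 - j) + j * (n1 - i))) / (2 * n1 * n2)
  1 - ((pw1 + pw2) / 2) / pb
}

#' Read a joint SFS in the dadi/moments flat-file format
#'
#' Format: optional `#` comment lines; a header line
#' `"<n1+1> <n2+1> <unfolded|folded> [\"pop1\" \"pop2\"]"`; the
#' `(n1+1)*(n2+1)` entries in row-major order (population 1 index varying
#' slowest); and a final line of `(n1+1)*(n2+1)` 0/1 mask flags (1 = masked).
#'
#' @param path file path.
#' @return a [joint_sfs]. Only the standard corner mask is representable; a
#'   mask line masking other entries raises an error.
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("malformed SFS file: need header, data, mask")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  if (is.na(d1) || is.na(d2)) stop("malformed SFS header")
  polarized <- TRUE
  labels <- c("pop1", "pop2")
  rest <- hdr[-(1:2)]
  if (length(rest) >= 1 && rest[1] %in% c("unfolded", "folded"))
    polarized <- rest[1] == "unfolded"
  q <- grep("^\"", rest, value = TRUE)
  if (length(q) == 2) labels <- gsub("\"", "", q)
  dat <- as.numeric(strsplit(trimws(paste(lines[2:(length(lines) - 1L)],
                                          collapse = " ")), "\\s+")[[1]])
  if (length(dat) != d1 * d2) stop("SFS data length does not match header")
  msk <- as.integer(strsplit(trimws(lines[length(lines)]), "\\s+")[[1]])
  if (length(msk) != d1 * d2) stop("SFS mask length does not match header")
  counts <- matrix(dat, nrow = d1, ncol = d2, byrow = TRUE)
  sfs <- joint_sfs(counts, polarized = polarized, pop_labels = labels)
  standard <- matrix(0L, d1, d2); standard[1, 1] <- 1L; standard[d1, d2] <- 1L
  got <- matrix(msk, d1, d2, byrow = TRUE)
  if (any(got > standard))
    stop("SFS file masks entries other than the fixed corners; not supported")
  sfs
}

#' Write a joint SFS in the dadi/moments flat-file format
#'
#' @param sfs a [joint_sfs].
#' @param path output file path.
#' @param comment optional comment line written at the top.
#' @return `path`, invisibly.
#' @seealso [read_sfs] for the format.
#' @export
write_sfs <- function(sfs, path, comment = NULL) {
  stopifnot(inherits(sfs, "joint_sfs"))
  d1 <- sfs$n1 + 1L; d2 <- sfs$n2 + 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(sprintf("%d %d %s \"%s\" \"%s\"", d1, d2,
                     if (sfs$polarized) "unfolded" else "folded",
                     sfs$pop_labels[1], sfs$pop_labels[2]), con)
  writeLines(paste(format(as.vector(t(sfs$counts)), digits = 17,
                          scientific = TRUE, trim = TRUE), collapse = " "), con)
  msk <- matrix(0L, d1, d2); msk[1, 1] <- 1L; msk[d1, d2] <- 1L
  writeLines(paste(as.vector(t(msk)), collapse = " "), con)
  invisible(path)
}
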