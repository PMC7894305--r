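#' @title Expected joint SFS under a demographic model
#' @description
#' The engine evolves the expected (per-theta) joint site frequency spectrum
#' of a two-population model forward in time with a moment system: genetic
#' drift acts on the sample spectrum through an exactly closed linear
#' operator, new mutations enter the single-copy classes at a constant rate
#' (infinite sites, no back-mutation), and migration couples the two
#' populations through terms one sample-order higher that are closed with a
#' quadratic-fit order-raising estimator. Within an epoch all coefficients
#' are constant, so each epoch is integrated by Crank-Nicolson steps with a
#' single matrix factorization. Spectra are scaled per unit
#' `theta = 4 N_ref mu L`; the observed/expected scale is restored
#' analytically during likelihood evaluation.
#' @name engine
NULL

.engine_env <- new.env(parent = emptyenv())

#' Engine numerical controls
#'
#' @param dt target Crank-Nicolson step in units of `2 N_ref` generations;
#'   each epoch uses `max(min_steps, ceiling(T / dt))` steps.
#' @param min_steps,max_steps bounds on steps per epoch; the cap keeps
#'   likelihood evaluations at extreme (long-duration) parameter draws
#'   affordable inside optimizer loops.
#' @param buffer integer number of extra alleles per population at which the
#'   system is integrated before exact hypergeometric projection down to the
#'   requested sizes; raising it sharpens the migration closure.
#' @param neg_tol negative entries larger than `-neg_tol * max(entry)` are
#'   clipped to zero; anything more negative raises an error.
#' @return list of control values.
#' @export
sfs_engine_control <- function(dt = 0.002, min_steps = 20L, buffer = 2L,
                               neg_tol = 1e-4, max_steps = 2000L) {
  list(dt = dt, min_steps = as.integer(min_steps),
       buffer = as.integer(buffer), neg_tol = neg_tol,
       max_steps = as.integer(max_steps))
}

# ---- operator construction -------------------------------------------------

# Closed drift operator on the sample spectrum, sample size n (entries 0..n):
# (D phi)_i = [(i-1)(n-i+1) phi_{i-1} - 2 i (n-i) phi_i
#              + (i+1)(n-i-1) phi_{i+1}] / 2,
# to be scaled by 1/nu.
.drift_matrix <- function(n) {
  D <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    if (i >= 1L) D[i + 1L, i] <- (i - 1) * (n - i + 1) / 2
    D[i + 1L, i + 1L] <- -i * (n - i)
    if (i + 1L <= n) D[i + 1L, i + 2L] <- (i + 1) * (n - i - 1) / 2
  }
  D
}

# Mutation influx (per unit theta): new derived singletons.
.mutation_vector_1d <- function(n) {
  B <- numeric(n + 1L)
  B[2L] <- n / 2
  B
}

# Exact one-order projection: order n -> n - 1.
.project_down_matrix <- function(n) {
  P <- matrix(0, n, n + 1L)
  for (i in 0:(n - 1L)) {
    P[i + 1L, i + 1L] <- (n - i) / n
    P[i + 1L, i + 2L] <- (i + 1) / n
  }
  P
}

# Order-raising estimator (n -> n + 1): entry i of the raised spectrum is a
# weighted sum of nearby entries of the order-n spectrum. In the interior the
# weights are exact for any underlying density that is locally quadratic in
# frequency. Near the boundaries the fit is augmented with a point mass at
# the adjacent boundary (frequency 0 or 1), because the boundary entries
# carry (quasi-)fixed mass that no polynomial density represents; without the
# atom terms the fixed-derived edge of the spectrum is badly extrapolated.
.raise_matrix <- function(n) {
  J <- matrix(0, n + 2L, n + 1L)
  phi_moment <- function(nn, j, k) {
    # value of spectrum entry j at order nn for density x^k
    exp(lchoose(nn, j) + lbeta(j + k + 1, nn - j + 1))
  }
  basis_value <- function(f, nn, j) {
    # entry j at order nn for basis function f
    if (f == "atom0") return(as.numeric(j == 0L))
    if (f == "atom1") return(as.numeric(j == nn))
    if (f == "xm1") {
      # density 1/x, the quasi-stationary low-frequency shape under
      # mutational influx; finite for entries j >= 1
      if (j == 0L) return(Inf)
      return(exp(lchoose(nn, j) + lbeta(j, nn - j + 1)))
    }
    phi_moment(nn, j, as.integer(sub("x", "", f)))
  }
  for (i in 1:(n + 1L)) {
    # raised entry 0 is never consumed by the migration operator; rows below
    # start at i = 1
    j0 <- round(i * n / (n + 1))
    if (j0 <= 3L) {               # low end: 1/x singularity + cubic
      S <- 1:min(5L, n - 1L)
      basis <- c("xm1", "x0", "x1", "x2", "x3")
    } else if (j0 >= n - 2L) {    # upper boundary: cubic + atom at x = 1
      S <- max(1L, n - 4L):n
      basis <- c("atom1", "x0", "x1", "x2", "x3")
    } else {                      # interior: local cubic + 1/x over 5 points
      S <- max(1L, j0 - 2L):min(n - 1L, j0 + 2L)
      basis <- c("xm1", "x0", "x1", "x2", "x3")
    }
    basis <- basis[seq_len(length(S))]
    Amat <- outer(basis, S, Vectorize(function(f, j) basis_value(f, n, j)))
    tvec <- vapply(basis, basis_value, numeric(1), nn = n + 1L, j = i)
    w <- solve(Amat, tvec)
    J[i + 1L, S + 1L] <- w
  }
  J
}

# Cached parameter-independent 2D operators for sample sizes (n1, n2):
# A = DX / nu1 + DY / nu2 + M12 * G12 + M21 * G21 acting on vec(Phi)
# (column-major; population 1 indexes rows).
.engine_operators <- function(n1, n2) {
  key <- paste(n1, n2, sep = "x")
  if (!is.null(.engine_env[[key]])) return(.engine_env[[key]])
  # plain dense operators: at these state sizes dense composition and
  # scaling is faster than sparse-class dispatch inside optimizer loops
  I1 <- diag(n1 + 1L)
  I2 <- diag(n2 + 1L)
  DX <- kronecker(I2, .drift_matrix(n1))
  DY <- kronecker(.drift_matrix(n2), I1)

  # same-order part of migration into population p: mass drifts toward the
  # unscaled term -i phi_i + (i+1) phi_{i+1}
  SA <- function(n) {
    S <- matrix(0, n + 1L, n + 1L)
    for (i in 0:n) {
      S[i + 1L, i + 1L] <- -i
      if (i + 1L <= n) S[i + 1L, i + 2L] <- i + 1
    }
    S
  }
  # difference stencil R (order n-1 -> n) used by the donor-frequency term
  Rdiff <- function(n) {
    R <- matrix(0, n + 1L, n)
    for (i in 0:n) {
      if (i >= 1L) R[i + 1L, i] <- 1
      if (i <= n - 1L) R[i + 1L, i + 1L] <- -1
    }
    R
  }
  # donor-side selector: column j of the output takes raised column j + 1
  # scaled by (j + 1) / (n + 1)
  Csel <- function(n) {
    C <- matrix(0, n + 1L, n + 2L)
    for (j in 0:n) C[j + 1L, j + 2L] <- (j + 1) / (n + 1)
    C
  }
  L1 <- Rdiff(n1) %*% .project_down_matrix(n1)   # (n1+1) x (n1+1)
  M2 <- Csel(n2) %*% .raise_matrix(n2)           # (n2+1) x (n2+1)
  L2 <- Rdiff(n2) %*% .project_down_matrix(n2)
  M1 <- Csel(n1) %*% .raise_matrix(n1)

  G12 <- kronecker(I2, SA(n1)) + n1 * kronecker(M2, L1)
  G21 <- kronecker(SA(n2), I1) + n2 * kronecker(L2, M1)

  B <- matrix(0, n1 + 1L, n2 + 1L)
  B[2L, 1L] <- n1 / 2
  B[1L, 2L] <- n2 / 2

  ops <- list(DX = DX, DY = DY, G12 = G12, G21 = G21, B = as.vector(B))
  .engine_env[[key]] <- ops
  ops
}

# ---- equilibrium and integration -------------------------------------------

#' Single-population equilibrium spectrum
#'
#' Solves the stationary moment system (drift balancing mutational influx)
#' exactly; at relative size `nu` the polymorphic entries are
#' `theta nu / i` for `theta = 1`.
#'
#' @param n haploid sample size.
#' @param nu relative population size.
#' @return numeric vector of length `n + 1` (per-theta densities; boundary
#'   entries zero).
#' @export
equilibrium_sfs_1d <- function(n, nu = 1) {
  n <- .check_count_scalar(n, "n")
  if (n < 2L) stop("`n` must be >= 2")
  D <- .drift_matrix(n) / nu
  B <- .mutation_vector_1d(n)
  interior <- 2:n
  phi <- numeric(n + 1L)
  phi[interior] <- solve(D[interior, interior], -B[interior])
  phi
}

.integrate_1d <- function(phi, nu, T, control) {
  n <- length(phi) - 1L
  max_steps <- if (is.null(control$max_steps)) 2000L else control$max_steps
  steps <- min(max_steps, max(control$min_steps, ceiling(T / control$dt)))
  .integrate_epoch_cpp(phi, .drift_matrix(n) / nu, .mutation_vector_1d(n),
                       T, as.integer(steps))
}

# Split an order-(n1+n2) ancestral spectrum into the joint spectrum:
# derived copies distribute hypergeometrically between subsamples.
.split_spectrum <- function(phi1d, n1, n2) {
  N <- n1 + n2
  stopifnot(length(phi1d) == N + 1L)
  Phi <- matrix(0, n1 + 1L, n2 + 1L)
  for (K in 0:N) {
    i <- max(0L, K - n2):min(n1, K)
    Phi[cbind(i + 1L, K - i + 1L)] <- Phi[cbind(i + 1L, K - i + 1L)] +
      phi1d[K + 1L] * exp(lchoose(n1, i) + lchoose(n2, K - i) - lchoose(N, K))
  }
  Phi
}

# epoch schedule matrix for the fused C++ integration: one row per epoch,
# columns nu1, nu2, m12, m21, T, steps, P, b
.epoch_schedule <- function(epochs, control) {
  max_steps <- if (is.null(control$max_steps)) 2000L else control$max_steps
  do.call(rbind, lapply(epochs, function(ep) {
    steps <- min(max_steps, max(control$min_steps,
                                ceiling(ep$T / control$dt)))
    c(ep$nu1, ep$nu2, ep$m12, ep$m21, ep$T, steps, ep$P, ep$b)
  }))
}

#' Expected joint SFS under a bound demographic model
#'
#' Starts from the exact single-population equilibrium of the ancestral
#' population, applies the optional ancestral size change, splits, and
#' integrates every epoch (oldest to newest). In models with a genomic-island
#' class the spectrum at the end of each epoch is the mixture
#' `(1 - P_e) * [epoch run at m] + P_e * [epoch run at b m]`, both branches
#' starting from the mixed state at the start of the epoch.
#'
#' @param model a [demographic_model].
#' @param values parameter vector (see [bind_parameters]).
#' @param n1,n2 haploid sample sizes of the returned spectrum (`>= 2`).
#' @param control numerical controls, see [sfs_engine_control].
#' @return a [joint_sfs] of expected per-theta site densities.
#' @export
expected_sfs <- function(model, values, n1, n2,
                         control = sfs_engine_control()) {
  n1 <- .check_count_scalar(n1, "n1")
  n2 <- .check_count_scalar(n2, "n2")
  if (n1 < 2L || n2 < 2L) stop("sample sizes must be >= 2")
  bound <- bind_parameters(model, values)
  n1b <- n1 + control$buffer
  n2b <- n2 + control$buffer
  ops <- .engine_operators(n1b, n2b)

  phi_anc <- equilibrium_sfs_1d(n1b + n2b, nu = 1)
  if (bound$TA > 0)
    phi_anc <- .integrate_1d(phi_anc, bound$nuA, bound$TA, control)
  Phi <- .split_spectrum(phi_anc, n1b, n2b)

  sched <- .epoch_schedule(bound$epochs, control)
  Phi <- matrix(.integrate_epochs_cpp(as.vector(Phi), ops$DX, ops$DY,
                                      ops$G12, ops$G21, ops$B, sched),
                n1b + 1L, n2b + 1L)

  mx <- max(Phi, 1e-12)
  if (min(Phi) < -control$neg_tol * mx)
    stop(sprintf(
      "expected_sfs: negative spectrum entries beyond tolerance (min %.3g)",
      min(Phi)))
  Phi[Phi < 0] <- 0

  out <- joint_sfs(Phi, polarized = TRUE)
  if (control$buffer > 0L) out <- sfs_project(out, n1, n2)
  out
}

#' Expected SFS of an island-mixture model
#'
#' Thin wrapper over [expected_sfs] that insists the model carries island
#' parameters; with `P_e = 0` everywhere (or `b = 1`) the result equals the
#' plain model's spectrum.
#'
#' @inheritParams expected_sfs
#' @return a [joint_sfs].
#' @export
mixture_sfs <- function(model, values, n1, n2,
                        control = sfs_engine_control()) {
  if (!isTRUE(model$islands))
    stop("mixture_sfs requires a model with island parameters")
  expected_sfs(model, values, n1, n2, control)
}

#' Poisson residuals between data and a fitted expectation
#'
#' Variance-stabilized residuals `(data - theta * model) / sqrt(theta *
#' model)` over unmasked entries; masked entries are `NA`. A zero model entry
#' with non-zero data yields an infinite residual (reported, not an error).
#'
#' @param data a [joint_sfs] of observed counts.
#' @param model_sfs a [joint_sfs] of expected per-theta densities.
#' @param theta scale factor (e.g. `theta_hat` from [poisson_loglik]).
#' @return matrix of residuals with masked entries `NA`.
#' @export
residuals_sfs <- function(data, model_sfs, theta) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model_sfs, "joint_sfs"))
  if (data$n1 != model_sfs$n1 || data$n2 != model_sfs$n2)
    stop("data and model spectra have different shapes")
  mu <- theta * model_sfs$counts
  r <- (data$counts - mu) / sqrt(mu)
  r[mu == 0 & data$counts > 0] <- Inf
  r[mu == 0 & data$counts == 0] <- 0
  r[!sfs_mask(data)] <- NA_real_
  r
}
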