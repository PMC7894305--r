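#' Poisson composite log-likelihood of a joint SFS
#'
#' Treats unmasked spectrum entries as independent Poisson counts with mean
#' `theta * model`. The scale `theta = 4 N_ref mu L` is profiled out
#' analytically: its maximizer is `theta_hat = sum(data) / sum(model)` over
#' unmasked entries.
#'
#' @param data a [joint_sfs] of observed counts.
#' @param model_sfs a [joint_sfs] of expected per-theta densities (same
#'   shape).
#' @return list with `LL` (log-likelihood at `theta_hat`) and `theta_hat`.
#' @export
poisson_loglik <- function(data, model_sfs) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model_sfs, "joint_sfs"))
  if (data$n1 != model_sfs$n1 || data$n2 != model_sfs$n2)
    stop("data and model spectra have different shapes")
  msk <- sfs_mask(data)
  if (!any(msk)) stop("all spectrum entries are masked")
  d <- data$counts[msk]
  m <- pmax(model_sfs$counts[msk], 1e-300)  # floor avoids -Inf from roundoff
  theta_hat <- sum(d) / sum(m)
  if (!is.finite(theta_hat) || theta_hat <= 0)
    stop("non-positive theta_hat; empty data spectrum?")
  mu <- theta_hat * m
  list(LL = sum(d * log(mu) - mu - lgamma(d + 1)), theta_hat = theta_hat)
}

#' Optimizer controls for model fitting
#'
#' @param n_starts number of optimization starts (defaults to 10).
#' @param maxit iteration cap per start (bounded quasi-Newton on
#'   log-parameters).
#' @param ll_tol convergence tolerance on the log-likelihood.
#' @param perturb_fold starts are drawn log-uniformly within this fold of
#'   the bound midpoint (in log space); `Inf` (the default) draws starts
#'   log-uniformly across the full bounds, which explores multimodal
#'   migration/island surfaces far more reliably.
#' @param n_refine number of triage survivors continued to the full
#'   iteration budget (successive-halving multistart).
#' @param engine engine controls for likelihood evaluations, see
#'   [sfs_engine_control]; the default trades some integration accuracy for
#'   speed, appropriate inside an optimizer loop.
#' @return list of control values.
#' @export
fit_control <- function(n_starts = 10L, maxit = 60L, ll_tol = 1e-6,
                        perturb_fold = Inf, n_refine = 3L,
                        engine = sfs_engine_control(dt = 0.02,
                                                    min_steps = 8L,
                                                    max_steps = 120L)) {
  list(n_starts = as.integer(n_starts), maxit = as.integer(maxit),
       ll_tol = ll_tol, perturb_fold = perturb_fold,
       n_refine = as.integer(n_refine), engine = engine)
}

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood over log-transformed parameters
#' within their bounds, from `n_starts` perturbed initializations (log-uniform
#' within `perturb_fold` of the bound midpoints). Fully reproducible given
#' `seed`.
#'
#' @param data a [joint_sfs] of observed counts.
#' @param model a [demographic_model].
#' @param seed integer seed governing the start draws.
#' @param control optimizer controls, see [fit_control].
#' @param p0 optional numeric vector used as the centre of the start
#'   distribution instead of the bound midpoints.
#' @return an object of class `sfs_fit`: `model`, `par` (natural scale, named),
#'   `LL`, `theta_hat`, `AIC`, `k`, per-start diagnostics (`starts` data
#'   frame), `seed`, and `on_boundary` flags.
#' @export
fit_model <- function(data, model, seed = 1L, control = fit_control(),
                      p0 = NULL) {
  stopifnot(inherits(data, "joint_sfs"), inherits(model, "demographic_model"))
  if (control$n_starts < 1L) stop("n_starts must be >= 1")
  lo <- log(model$params$lower)
  hi <- log(model$params$upper)
  centre <- if (is.null(p0)) (lo + hi) / 2 else {
    if (length(p0) != model$k) stop("p0 must have length ", model$k)
    pmin(pmax(log(p0), lo), hi)
  }
  negll <- function(x) {
    e <- try(expected_sfs(model, exp(x), data$n1, data$n2, control$engine),
             silent = TRUE)
    if (inherits(e, "try-error")) return(1e12)
    ll <- try(poisson_loglik(data, e)$LL, silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e12)
    -ll
  }
  # forward-difference gradient on the log scale: half the evaluations of
  # central differences, ample accuracy for a smooth deterministic objective
  fd_h <- 1e-6
  grad <- function(x) {
    f0 <- negll(x)
    vapply(seq_along(x), function(j) {
      xp <- x
      step <- if (xp[j] + fd_h <= hi[j]) fd_h else -fd_h
      xp[j] <- xp[j] + step
      (negll(xp) - f0) / step
    }, numeric(1))
  }
  set.seed(seed)
  starts <- lapply(seq_len(control$n_starts), function(s) {
    if (s == 1L) return(centre)
    if (is.finite(control$perturb_fold))
      return(pmin(pmax(centre + log(control$perturb_fold) *
                         runif(model$k, -1, 1), lo), hi))
    lo + runif(model$k) * (hi - lo)  # log-uniform across the full bounds
  })
  run_opt <- function(x0, maxit) {
    fit <- try(stats::optim(x0, negll, gr = grad,
                            method = "L-BFGS-B", lower = lo, upper = hi,
                            control = list(maxit = maxit,
                                           factr = control$ll_tol / 1e-15)),
               silent = TRUE)
    if (inherits(fit, "try-error"))
      return(list(ok = FALSE, msg = attr(fit, "condition")$message))
    list(ok = TRUE, par = fit$par, value = fit$value,
         convergence = fit$convergence)
  }
  # successive-halving multistart: every start gets a short triage run, the
  # leading few continue to the full iteration budget
  triage_maxit <- max(10L, control$maxit %/% 4L)
  runs <- lapply(starts, run_opt, maxit = triage_maxit)
  vals0 <- vapply(runs, function(r) if (r$ok) r$value else Inf, numeric(1))
  n_refine <- if (is.null(control$n_refine)) 3L else control$n_refine
  keep <- order(vals0)[seq_len(min(length(runs), max(1L, n_refine)))]
  for (s in keep) {
    if (!runs[[s]]$ok) next
    cont <- run_opt(runs[[s]]$par, control$maxit)
    if (cont$ok && cont$value <= runs[[s]]$value) runs[[s]] <- cont
  }
  ok <- vapply(runs, `[[`, logical(1), "ok")
  if (!any(ok))
    stop("no optimization start converged; messages: ",
         paste(unique(vapply(runs[!ok], `[[`, character(1), "msg")),
               collapse = "; "))
  vals <- vapply(runs, function(r) if (r$ok) r$value else Inf, numeric(1))
  best <- runs[[which.min(vals)]]
  # polish: restart the bounded quasi-Newton from the incumbent until the
  # log-likelihood stops improving; restarting resets the limited-memory
  # Hessian, which frequently escapes stalls on flat migration ridges
  for (round in seq_len(3L)) {
    pol <- try(stats::optim(best$par, negll, gr = grad,
                            method = "L-BFGS-B", lower = lo, upper = hi,
                            control = list(maxit = control$maxit,
                                           factr = control$ll_tol / 1e-15)),
               silent = TRUE)
    if (inherits(pol, "try-error")) break
    improved <- best$value - pol$value
    if (pol$value <= best$value)
      best <- list(ok = TRUE, par = pol$par, value = pol$value,
                   convergence = pol$convergence)
    if (improved < control$ll_tol * 10) break
  }
  par <- setNames(exp(best$par), model$params$name)
  e <- expected_sfs(model, par, data$n1, data$n2, control$engine)
  pl <- poisson_loglik(data, e)
  res <- list(
    model = model,
    par = par,
    LL = pl$LL,
    theta_hat = pl$theta_hat,
    k = model$k,
    AIC = 2 * model$k - 2 * pl$LL,
    seed = seed,
    n_starts = control$n_starts,
    on_boundary = setNames(abs(best$par - lo) < 1e-8 |
                             abs(best$par - hi) < 1e-8, model$params$name),
    starts = data.frame(
      start = seq_along(runs),
      ok = ok,
      negLL = vals,
      convergence = vapply(runs, function(r)
        if (r$ok) r$convergence else NA_integer_, integer(1))
    )
  )
  class(res) <- "sfs_fit"
  res
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat(sprintf("Fit of model '%s': LL = %.3f, theta_hat = %.4g, AIC = %.3f\n",
              x$model$id, x$LL, x$theta_hat, x$AIC))
  cat(sprintf("%d/%d starts converged; best parameters:\n",
              sum(x$starts$ok), nrow(x$starts)))
  print(signif(x$par, 4))
  if (any(x$on_boundary))
    cat("NOTE: parameters on bounds:",
        paste(names(x$par)[x$on_boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Rank fitted models by AIC
#'
#' Information-theoretic model selection: for each model, the AIC difference
#' to the best model, the relative likelihood `exp(-dAIC / 2)`, the Akaike
#' weight (model probability), and the evidence ratio of the best model over
#' it. Evidence ratios are computed in log space, so ratios of order 1e300
#' and beyond are reported without overflow via `log10_evidence_ratio`.
#'
#' @param fits list of `sfs_fit` objects with distinct model ids.
#' @return data frame of class `sfs_selection`, sorted by ascending AIC, with
#'   columns `model`, `k`, `LL`, `AIC`, `dAIC`, `rel_lik`, `weight`,
#'   `evidence_ratio`, `log10_evidence_ratio`.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 1L) stop("need at least one fit")
  ids <- vapply(fits, function(f) f$model$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate model ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  tab <- data.frame(
    model = ids,
    k = vapply(fits, `[[`, numeric(1), "k"),
    LL = vapply(fits, `[[`, numeric(1), "LL"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE
  )
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$rel_lik <- exp(-tab$dAIC / 2)
  tab$weight <- tab$rel_lik / sum(tab$rel_lik)
  # evidence ratio best/model; exact in log space
  log_w_corr <- -tab$dAIC / 2
  tab$log10_evidence_ratio <- (max(log_w_corr) - log_w_corr) / log(10)
  tab$evidence_ratio <- 10^tab$log10_evidence_ratio
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  class(tab) <- c("sfs_selection", "data.frame")
  tab
}

#' Nonparametric SNP bootstrap of a model fit
#'
#' Resamples sites with replacement to the original site count, rebuilds the
#' joint SFS and refits the model; reports per-parameter means and standard
#' deviations over replicates (as used for the uncertainty of date
#' estimates).
#'
#' @param sites a [site_table] of the polymorphic sites underlying the data
#'   spectrum.
#' @param model a [demographic_model].
#' @param n1,n2 projection sizes used to build each replicate spectrum.
#' @param n_reps number of bootstrap replicates (`>= 2`; default 5).
#' @param seed integer seed; replicate `r` uses `seed + r` for resampling and
#'   fitting.
#' @param control optimizer controls, see [fit_control].
#' @param L_effective,pop_labels passed to [build_sfs].
#' @return list with `par` (matrix, replicates x parameters), `mean`, `sd`,
#'   `theta_hat`, `fits`, and `n_failed`.
#' @export
bootstrap_fits <- function(sites, model, n1, n2, n_reps = 5L, seed = 1L,
                           control = fit_control(),
                           L_effective = NA_real_,
                           pop_labels = c("pop1", "pop2")) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  n_sites <- nrow(sites)
  if (n_sites < 1L) stop("empty site table")
  fits <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    sfs_r <- build_sfs(sites[idx, , drop = FALSE], n1, n2,
                       L_effective = L_effective, pop_labels = pop_labels)
    fits[[r]] <- try(fit_model(sfs_r, model, seed = seed + r,
                               control = control), silent = TRUE)
    if (inherits(fits[[r]], "try-error"))
      warning("bootstrap replicate ", r, " failed: ",
              attr(fits[[r]], "condition")$message)
  }
  ok <- !vapply(fits, inherits, logical(1), "try-error")
  if (sum(ok) < 2L) stop("fewer than 2 bootstrap replicates succeeded")
  par_mat <- do.call(rbind, lapply(fits[ok], `[[`, "par"))
  list(
    par = par_mat,
    mean = colMeans(par_mat),
    sd = apply(par_mat, 2, sd),
    theta_hat = vapply(fits[ok], `[[`, numeric(1), "theta_hat"),
    fits = fits[ok],
    n_failed = sum(!ok)
  )
}

#' Convert fitted parameters to individuals and years
#'
#' Scales the dimensionless fit to demographic units: the reference size is
#' `N_ref = theta_hat / (4 mu L)` diploid individuals, relative sizes scale
#' by it, a duration of `T` (in `2 N_ref` generations) spans
#' `2 N_ref T gen_time` years, and population-scaled migration `M = 2 N_ref m`
#' converts to the fraction of a population replaced per generation
#' (`M / (2 N_ref)`) and to immigrant individuals per generation
#' (`N * fraction`).
#'
#' @param fit an `sfs_fit`.
#' @param mu per-site per-generation mutation rate.
#' @param gen_time generation time in years.
#' @param L effective callable sequence length (bp) behind the SNP set.
#' @return list of class `scaled_params`: `N_ref`, `N_anc`, `split_years_bp`,
#'   and `epochs` (data frame, oldest first, with sizes in individuals, epoch
#'   start/end in years BP, migration in both units, island fractions as
#'   percentages).
#' @export
scale_to_natural_units <- function(fit, mu, gen_time, L) {
  stopifnot(inherits(fit, "sfs_fit"))
  if (!all(c(mu, gen_time, L) > 0)) stop("mu, gen_time and L must be positive")
  bound <- bind_parameters(fit$model, fit$par)
  N_ref <- fit$theta_hat / (4 * mu * L)
  k <- length(bound$epochs)
  dur_years <- vapply(bound$epochs, function(e)
    2 * N_ref * e$T * gen_time, numeric(1))
  # epoch e spans [start, end) in years BP, oldest first
  total <- sum(dur_years)
  start_bp <- total - c(0, cumsum(dur_years))[seq_len(k)]
  end_bp <- start_bp - dur_years
  ep <- do.call(rbind, lapply(seq_len(k), function(e) {
    b <- bound$epochs[[e]]
    data.frame(
      epoch = e,
      start_years_bp = start_bp[e],
      end_years_bp = end_bp[e],
      N1 = b$nu1 * N_ref,
      N2 = b$nu2 * N_ref,
      m12_frac_per_gen = b$m12 / (2 * N_ref),
      m21_frac_per_gen = b$m21 / (2 * N_ref),
      m12_migrants_per_gen = b$nu1 * N_ref * b$m12 / (2 * N_ref),
      m21_migrants_per_gen = b$nu2 * N_ref * b$m21 / (2 * N_ref),
      island_percent = 100 * b$P,
      island_factor = b$b
    )
  }))
  out <- list(
    model = fit$model$id,
    N_ref = N_ref,
    N_anc = bound$nuA * N_ref,
    split_years_bp = total,
    theta_hat = fit$theta_hat,
    mu = mu, gen_time = gen_time, L = L,
    epochs = ep
  )
  class(out) <- "scaled_params"
  out
}

#' @export
print.scaled_params <- function(x, ...) {
  cat(sprintf(
    "Model '%s': N_ref = %.0f individuals, split %.0f years BP\n",
    x$model, x$N_ref, x$split_years_bp))
  print(within(x$epochs, {
    N1 <- round(N1); N2 <- round(N2)
    start_years_bp <- round(start_years_bp)
    end_years_bp <- round(end_years_bp)
  }))
  invisible(x)
}
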