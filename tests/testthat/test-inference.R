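test_that("poisson_loglik profiles theta analytically", {
  m <- matrix(c(0, 1, 2, 0.5, 1, 0.25), 2, 3)
  model <- joint_sfs(m)
  data <- joint_sfs(2 * m)
  pl <- poisson_loglik(data, model)
  expect_equal(pl$theta_hat, 2, tolerance = 1e-12)

  # single informative cell: d = 3, m = 1 -> LL = 3 ln 3 - 3 - ln 6
  d1 <- matrix(0, 2, 2); d1[2, 1] <- 3
  m1 <- matrix(0, 2, 2); m1[2, 1] <- 1
  pl1 <- poisson_loglik(joint_sfs(d1), joint_sfs(m1))
  expect_equal(pl1$theta_hat, 3, tolerance = 1e-12)
  expect_equal(pl1$LL, 3 * log(3) - 3 - log(6), tolerance = 1e-10)

  # scale invariance: theta_hat absorbs any multiplicative model constant
  pl_scaled <- poisson_loglik(data, joint_sfs(7 * m))
  expect_equal(pl_scaled$LL, pl$LL, tolerance = 1e-10)
  expect_equal(pl_scaled$theta_hat, 2 / 7, tolerance = 1e-12)
})

test_that("model ranking reproduces Akaike arithmetic", {
  fk <- function(id, LL, k) structure(
    list(model = demographic_model(id, "sym"), LL = LL, k = k,
         AIC = 2 * k - 2 * LL, theta_hat = 1), class = "sfs_fit")
  # equal fits: equal weights, evidence ratio 1
  tab <- rank_models(list(fk("a", -100, 4), fk("b", -100, 4)))
  expect_equal(tab$weight, c(0.5, 0.5))
  expect_equal(tab$evidence_ratio, c(1, 1))

  # dAIC = (0, 2): weights (0.731, 0.269), evidence ratio e
  tab2 <- rank_models(list(fk("a", -100, 4), fk("b", -100, 5)))
  expect_equal(tab2$dAIC, c(0, 2))
  expect_equal(tab2$weight, c(0.731, 0.269), tolerance = 5e-4)
  expect_equal(tab2$evidence_ratio[2], exp(1), tolerance = 1e-10)
  expect_equal(sum(tab2$weight), 1, tolerance = 1e-12)

  # dAIC = 184.2: evidence ratio ~ 1.1e40, finite and exact in log10
  tab3 <- rank_models(list(fk("a", -100, 4), fk("b", -192.1, 4)))
  expect_equal(tab3$log10_evidence_ratio[2], 92.1 / log(10),
               tolerance = 1e-10)
  expect_equal(tab3$evidence_ratio[2], exp(92.1), tolerance = 1e-10)
  expect_gt(tab3$evidence_ratio[2], 1e39)

  # far beyond double overflow: log10 stays exact
  tab4 <- rank_models(list(fk("a", -100, 4), fk("b", -100 - 800 * log(10), 4)))
  expect_equal(tab4$log10_evidence_ratio[2], 800, tolerance = 1e-9)
  expect_true(is.finite(tab4$weight[1]))
  expect_error(rank_models(list(fk("a", -1, 4), fk("a", -2, 4))), "duplicate")
})

test_that("fitting is reproducible and recovers an easy truth", {
  m <- model_im_sym()
  truth <- c(T1 = 0.3, nu1_1 = 1.2, nu2_1 = 0.8, m1 = 1.5)
  data <- simulate_sfs(m, truth, 8, 8, theta = 2000, seed = 5)
  ctl <- fit_control(n_starts = 2, maxit = 40)
  f1 <- fit_model(data, m, seed = 9, control = ctl)
  f2 <- fit_model(data, m, seed = 9, control = ctl)
  expect_identical(f1$par, f2$par)  # bitwise determinism under a fixed seed
  expect_equal(f1$AIC, 2 * m$k - 2 * f1$LL, tolerance = 1e-10)
  expect_lt(max(abs(f1$par - truth) / truth), 0.25)
  expect_gt(f1$theta_hat, 0)

  # bounds that exclude the truth push the solution onto the boundary
  narrow <- demographic_model("narrow", "sym",
                              bounds = list(T1 = c(1e-3, 0.05)))
  f3 <- fit_model(data, narrow, seed = 9,
                  control = fit_control(n_starts = 1, maxit = 30))
  expect_true(f3$on_boundary[["T1"]])
})

test_that("the SNP bootstrap resamples to the original count", {
  m <- model_si()
  set.seed(21)
  sites <- site_table("s", seq_len(400),
                      d1 = sample(0:4, 400, TRUE), c1 = 4,
                      d2 = sample(0:4, 400, TRUE), c2 = 4)
  bs <- bootstrap_fits(sites, m, 4, 4, n_reps = 3, seed = 2,
                       control = fit_control(n_starts = 1, maxit = 15))
  expect_equal(nrow(bs$par), 3)
  expect_true(all(is.finite(bs$sd)))

  # a degenerate single-site table gives identical replicates, SD zero
  one <- site_table("s", 1, d1 = 1, c1 = 4, d2 = 2, c2 = 4)
  bs1 <- bootstrap_fits(one, m, 4, 4, n_reps = 2, seed = 3,
                        control = fit_control(n_starts = 1, maxit = 10))
  expect_equal(unname(bs1$sd), rep(0, m$k))
  expect_error(bootstrap_fits(sites, m, 4, 4, n_reps = 1, seed = 1),
               "n_reps")
})

test_that("scaling to natural units follows theta and generation time", {
  m <- model_im_sym()
  fit <- structure(list(
    model = m, par = c(T1 = 0.5, nu1_1 = 2, nu2_1 = 0.5, m1 = 1),
    LL = -10, k = m$k, AIC = 2 * m$k + 20, theta_hat = 2000),
    class = "sfs_fit")
  sc <- scale_to_natural_units(fit, mu = 1.02e-9, gen_time = 5, L = 1e7)
  expect_equal(sc$N_ref, 2000 / (4 * 1.02e-9 * 1e7), tolerance = 1e-9)
  expect_equal(sc$N_ref, 49019.6, tolerance = 1e-4)
  expect_equal(sc$split_years_bp, 2 * sc$N_ref * 0.5 * 5, tolerance = 1e-9)
  expect_equal(sc$split_years_bp, 245098, tolerance = 1e-4)
  expect_equal(sc$epochs$N1, 2 * sc$N_ref)
  expect_equal(sc$epochs$m12_frac_per_gen, 1 / (2 * sc$N_ref))
  expect_equal(sc$epochs$end_years_bp, 0)
  expect_error(scale_to_natural_units(fit, mu = -1, gen_time = 5, L = 1),
               "positive")

  # epoch boundaries decrease strictly toward the present
  m3 <- demographic_model("e3_sss", c("sym", "sym", "sym"))
  fit3 <- structure(list(
    model = m3, par = c(T1 = 0.2, nu1_1 = 1, nu2_1 = 1, m1 = 1,
                        T2 = 0.1, nu1_2 = 1, nu2_2 = 1, m2 = 1,
                        T3 = 0.05, nu1_3 = 1, nu2_3 = 1, m3 = 1),
    LL = -1, k = m3$k, AIC = 0, theta_hat = 1000), class = "sfs_fit")
  sc3 <- scale_to_natural_units(fit3, 1e-9, 5, 1e7)
  expect_true(all(diff(sc3$epochs$start_years_bp) < 0))
  expect_equal(sc3$epochs$start_years_bp[1], sc3$split_years_bp)
  expect_equal(sc3$epochs$end_years_bp[3], 0)
  expect_equal(sc3$epochs$start_years_bp[-1], sc3$epochs$end_years_bp[-3],
               tolerance = 1e-9)
})
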