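ctl_fast <- sfs_engine_control(dt = 0.005, min_steps = 10L, buffer = 2L)

test_that("stationary single-population spectrum is theta over i", {
  for (n in c(4, 10, 20)) {
    eq <- equilibrium_sfs_1d(n)
    expect_equal(eq[2:n], 1 / (1:(n - 1)), tolerance = 1e-10)
  }
  # at relative size nu the equilibrium scales to theta nu / i
  eq2 <- equilibrium_sfs_1d(8, nu = 2.5)
  expect_equal(eq2[2:8], 2.5 / (1:7), tolerance = 1e-10)
  # the integrator holds the stationary state
  phi <- jointsfs:::.integrate_1d(equilibrium_sfs_1d(12), 1, 0.5,
                                  sfs_engine_control())
  expect_equal(phi[2:12], 1 / (1:11), tolerance = 1e-6)
})

test_that("exchangeable models give exchangeable spectra", {
  m <- model_im_sym()
  s <- expected_sfs(m, c(T1 = 0.2, nu1_1 = 1, nu2_1 = 1, m1 = 1), 6, 6,
                    ctl_fast)
  expect_equal(s$counts, t(s$counts), tolerance = 1e-10)
  expect_true(all(s$counts >= 0))
})

test_that("island mixture degenerates correctly", {
  isl <- demographic_model("e1_s_i", "sym", islands = TRUE,
                           bounds = list(P1 = c(0, 1), b = c(0, 1)))
  plain <- model_im_sym()
  base <- c(T1 = 0.3, nu1_1 = 1, nu2_1 = 1, m1 = 2)

  s_plain <- expected_sfs(plain, base, 6, 6, ctl_fast)
  s_P0 <- expected_sfs(isl, c(base, P1 = 0, b = 0.2), 6, 6, ctl_fast)
  expect_equal(s_P0$counts, s_plain$counts, tolerance = 1e-12)

  s_b1 <- expected_sfs(isl, c(base, P1 = 0.6, b = 1), 6, 6, ctl_fast)
  expect_equal(s_b1$counts, s_plain$counts, tolerance = 1e-10)

  expect_error(mixture_sfs(plain, base, 6, 6, ctl_fast), "island")
})

test_that("a full-island class with b = 0 removes migration in the epoch", {
  isl <- demographic_model("full_isl", "sym", islands = TRUE,
                           bounds = list(P1 = c(0, 1), b = c(0, 1)))
  s_isl <- expected_sfs(isl, c(T1 = 0.25, nu1_1 = 1.5, nu2_1 = 0.8,
                               m1 = 3, P1 = 1, b = 0), 6, 6, ctl_fast)
  si <- model_si()
  s_si <- expected_sfs(si, c(T1 = 0.25, nu1_1 = 1.5, nu2_1 = 0.8), 6, 6,
                       ctl_fast)
  expect_equal(s_isl$counts, s_si$counts, tolerance = 1e-10)
})

test_that("a zero-duration middle epoch nests the two-epoch model", {
  m3 <- demographic_model("e3_nsa_nested", c("none", "sym", "asym"),
                          bounds = list(T2 = c(0, 10)))
  m2 <- demographic_model("e2_na", c("none", "asym"))
  v3 <- c(T1 = 0.3, nu1_1 = 1, nu2_1 = 1,
          T2 = 0, nu1_2 = 5, nu2_2 = 5, m2 = 9,
          T3 = 0.1, nu1_3 = 2, nu2_3 = 1, m12_3 = 1, m21_3 = 0.5)
  v2 <- c(T1 = 0.3, nu1_1 = 1, nu2_1 = 1,
          T2 = 0.1, nu1_2 = 2, nu2_2 = 1, m12_2 = 1, m21_2 = 0.5)
  expect_equal(expected_sfs(m3, v3, 6, 6, ctl_fast)$counts,
               expected_sfs(m2, v2, 6, 6, ctl_fast)$counts,
               tolerance = 1e-10)
})

test_that("engine expectation commutes with hypergeometric projection", {
  m <- model_im_asym()
  v <- c(T1 = 0.3, nu1_1 = 1.5, nu2_1 = 0.7, m12_1 = 1, m21_1 = 0.3)
  ctl0 <- sfs_engine_control(dt = 0.002, buffer = 0L)
  big <- expected_sfs(m, v, 10, 10, ctl0)
  small <- expected_sfs(m, v, 6, 6, ctl0)
  proj <- sfs_project(big, 6, 6)
  msk <- interior_mask(6, 6)
  rel <- abs(proj$counts - small$counts) / pmax(small$counts, 1e-6)
  expect_lt(max(rel[msk]), 0.02)
})

test_that("expected Fst decreases strictly with symmetric migration", {
  m <- model_im_sym()
  fst <- vapply(c(0.2, 0.5, 1, 2, 5), function(mig) {
    fst_sfs(expected_sfs(m, c(T1 = 0.4, nu1_1 = 1, nu2_1 = 1, m1 = mig),
                         8, 8, ctl_fast))
  }, numeric(1))
  expect_true(all(diff(fst) < 0))
})

test_that("Poisson residuals are centred with unit spread", {
  m <- model_im_sym()
  e <- expected_sfs(m, c(T1 = 0.2, nu1_1 = 1, nu2_1 = 1, m1 = 1), 8, 8,
                    ctl_fast)
  theta <- 500
  exact <- joint_sfs(theta * e$counts)
  r0 <- residuals_sfs(exact, e, theta)
  expect_equal(max(abs(r0[interior_mask(8, 8)])), 0, tolerance = 1e-10)

  shifted <- e$counts * theta + sqrt(e$counts * theta)
  r1 <- residuals_sfs(joint_sfs(shifted), e, theta)
  expect_equal(unname(r1[interior_mask(8, 8)]),
               rep(1, sum(interior_mask(8, 8))), tolerance = 1e-10)

  set.seed(11)
  msk <- interior_mask(8, 8)
  sds <- replicate(12, {
    counts <- matrix(0, 9, 9)
    counts[msk] <- rpois(sum(msk), theta * e$counts[msk])
    sd(residuals_sfs(joint_sfs(counts), e, theta)[msk])
  })
  expect_equal(mean(sds), 1, tolerance = 0.1)

  # zero expectation with observed data: infinite residual, not an error
  zero_model <- joint_sfs(matrix(c(0, 0, 1, 0), 2, 2))
  data2 <- joint_sfs(matrix(c(0, 2, 0, 0), 2, 2))
  r2 <- residuals_sfs(data2, zero_model, 1)
  expect_true(is.infinite(r2[2, 1]))
  expect_true(is.na(r2[1, 1]))  # masked corner
})

test_that("integration accuracy tightens under step refinement", {
  m <- model_im_asym()
  v <- c(T1 = 0.4, nu1_1 = 2, nu2_1 = 0.5, m12_1 = 2, m21_1 = 0.5)
  ref <- expected_sfs(m, v, 6, 6, sfs_engine_control(dt = 1e-4, buffer = 2L))
  err <- vapply(c(0.05, 0.01, 0.002), function(dt) {
    s <- expected_sfs(m, v, 6, 6, sfs_engine_control(dt = dt, buffer = 2L))
    max(abs(s$counts - ref$counts)[interior_mask(6, 6)])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-4)
})
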