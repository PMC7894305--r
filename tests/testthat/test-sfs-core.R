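test_that("project_site matches exhaustive subsampling and conserves mass", {
  expect_equal(project_site(2, 4, 2), c(1 / 6, 2 / 3, 1 / 6))
  expect_equal(project_site(2, 4, 2), enumerate_projection(2, 4, 2))
  expect_equal(project_site(0, 10, 4), c(1, 0, 0, 0, 0))
  expect_equal(project_site(3, 3, 5), numeric(6))  # cannot project up

  cases <- expand.grid(n_obs = c(4, 7, 10), n_target = c(2, 3, 5))
  cases <- cases[cases$n_target <= cases$n_obs, ]
  for (r in seq_len(nrow(cases))) {
    n_obs <- cases$n_obs[r]; n_target <- cases$n_target[r]
    for (d in 0:n_obs) {
      p <- project_site(d, n_obs, n_target)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, enumerate_projection(d, n_obs, n_target),
                   tolerance = 1e-12)
    }
  }
  expect_error(project_site(-1, 4, 2), "non-negative")
  expect_error(project_site(2.5, 4, 2), "non-negative integer")
  expect_error(project_site(5, 4, 2), "exceed")
})

test_that("projection composes: n -> m -> k equals n -> k", {
  P1 <- projection_matrix(12, 8) %*% projection_matrix(8, 5)
  P2 <- projection_matrix(12, 5)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("build_sfs distributes sites hypergeometrically and is additive", {
  s1 <- site_table("s1", 1, d1 = 1, c1 = 2, d2 = 0, c2 = 2)
  sfs <- build_sfs(s1, 2, 2)
  expect_equal(sfs$counts[2, 1], 1)
  expect_equal(sum(sfs$counts), 1)

  s2 <- site_table("s1", 2, d1 = 2, c1 = 4, d2 = 0, c2 = 2)
  sfs2 <- build_sfs(s2, 2, 2)
  expect_equal(sfs2$counts[, 1], c(1 / 6, 2 / 3, 1 / 6))
  s2b <- site_table("s1", 2, d1 = 1, c1 = 4, d2 = 0, c2 = 2)
  expect_equal(build_sfs(s2b, 2, 2)$counts[, 1], c(1 / 2, 1 / 2, 0))

  both <- rbind(s1, s1)
  expect_equal(build_sfs(both, 2, 2)$counts, 2 * sfs$counts)

  # mass = number of projectable sites; under-called sites drop out
  mix <- site_table("s1", 1:3, d1 = c(1, 1, 0), c1 = c(4, 1, 4),
                    d2 = c(0, 0, 1), c2 = c(2, 2, 4))
  sfs3 <- build_sfs(mix, 2, 2)
  expect_equal(sum(sfs3$counts), 2)
  expect_equal(attr(sfs3, "n_dropped"), 1L)
  expect_warning(empty <- build_sfs(site_table(character(0), integer(0),
                                               integer(0), integer(0),
                                               integer(0), integer(0)),
                                    2, 2), "empty")
  expect_equal(sum(empty$counts), 0)
})

test_that("folding conserves unmasked mass and maps conjugate cells", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- 3  # (1,0)
  m[2, 3] <- 5  # (1,2), conjugate of (1,0)
  sfs <- joint_sfs(m)
  f <- fold_sfs(sfs)
  expect_equal(f$counts[2, 1], 8)
  expect_false(f$polarized)
  expect_error(fold_sfs(f), "already folded")

  set.seed(1)
  r <- joint_sfs(matrix(runif(5 * 7), 5, 7))
  expect_equal(sfs_total(fold_sfs(r)), sfs_total(r), tolerance = 1e-12)

  corner <- matrix(0, 3, 3); corner[1, 1] <- 4
  fc <- fold_sfs(joint_sfs(corner))
  expect_equal(fc$counts[1, 1], 4)        # stays in the corner cell
  expect_equal(sfs_total(fc), 0)          # still masked
})

test_that("marginals sum the other axis and conserve mass", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- 1; m[2, 3] <- 1
  sfs <- joint_sfs(m)
  expect_equal(marginal_sfs(sfs, 1), c(0, 2, 0))
  expect_equal(marginal_sfs(sfs, 2), c(1, 0, 1))
  set.seed(2)
  r <- joint_sfs(matrix(runif(24), 4, 6))
  expect_equal(sum(marginal_sfs(r, 1)), sum(r$counts))
})

test_that("nucleotide diversity evaluates the pairwise-difference weights", {
  expect_equal(nucleotide_diversity(c(0, 5, 0), n = 2, L = 100), 0.05)
  expect_equal(nucleotide_diversity(c(0, 3, 0, 0, 0), n = 4, L = 60), 0.025)
  expect_equal(nucleotide_diversity(rep(0, 5), n = 4, L = 100), 0)
  expect_error(nucleotide_diversity(c(0, 1, 0), 2, 0), "positive")
})

test_that("SFS flat-file round-trips bit-compatibly", {
  set.seed(3)
  sfs <- joint_sfs(matrix(as.numeric(rpois(5 * 4, 8)), 5, 4),
                   pop_labels = c("Deep", "Shallow"))
  path <- withr::local_tempfile(fileext = ".fs")
  write_sfs(sfs, path, comment = "round-trip check")
  back <- read_sfs(path)
  expect_identical(back$counts, sfs$counts)
  expect_identical(back$pop_labels, sfs$pop_labels)
  expect_true(back$polarized)
})

test_that("whole-spectrum projection matches site-level projection", {
  set.seed(4)
  sites <- site_table("s", 1:40, d1 = sample(0:8, 40, TRUE), c1 = 8,
                      d2 = sample(0:6, 40, TRUE), c2 = 6)
  direct <- build_sfs(sites, 4, 4)
  via_big <- sfs_project(build_sfs(sites, 8, 6), 4, 4)
  expect_equal(via_big$counts, direct$counts, tolerance = 1e-12)
})
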