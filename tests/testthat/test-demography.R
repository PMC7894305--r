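test_that("the catalog holds 107 models including the published names", {
  cat107 <- catalog_list()
  expect_length(cat107, 107L)
  expect_false(anyDuplicated(names(cat107)) > 0)
  named <- c("sc3ielsm1", "sc3imlsm1", "iMi", "sc2ielsm2", "sc12il",
             "sc12imlsm2", "IMisc", "Sc2il", "Sc2ilsm", "Sc2i")
  expect_true(all(named %in% names(cat107)))
  # the alternate figure name of the 3-epoch secondary-contact model
  expect_true("sc3imilm1" %in% names(cat107))

  imi <- catalog_model("iMi")
  expect_equal(imi$n_epochs, 3L)
  expect_false(any(imi$mig_modes == "none"))  # no isolation epoch
  expect_error(catalog_model("zzz"), "not found")
})

test_that("every catalog model's k matches its free-parameter count", {
  for (m in catalog_list()) {
    expect_equal(m$k, nrow(m$params), label = m$id)
    expected_k <- 3 * m$n_epochs +
      sum(c(none = 0, sym = 1, asym = 2)[m$mig_modes]) +
      (if (m$islands) sum(m$mig_modes != "none") + 1 else 0) +
      (if (m$anc_change) 2 else 0)
    expect_equal(m$k, unname(expected_k), label = m$id)
    # binding the bound midpoints must succeed for every model
    mid <- sqrt(m$params$lower * m$params$upper)
    bound <- bind_parameters(m, mid)
    expect_length(bound$epochs, m$n_epochs)
  }
})

test_that("grammar ids parse and round-trip", {
  for (id in c("e1_s", "e2_na_i", "ae3_sna", "ae1_a_i", "e3_ssa_i")) {
    m <- model_grammar_parse(id)
    expect_identical(model_grammar_render(m), id)
  }
  p <- model_grammar_parse("ae2_ns_i")
  expect_true(p$anc_change)
  expect_true(p$islands)
  expect_identical(p$mig_modes, c("none", "sym"))
  expect_error(model_grammar_parse("e4_nnnn"), "grammar")
  expect_error(model_grammar_parse("e2_xy"), "grammar")
  # grammar members of the catalog round-trip through their own ids
  grammar_ids <- grep("^a?e[123]_", names(catalog_list()), value = TRUE)
  for (id in grammar_ids)
    expect_identical(model_grammar_render(catalog_list()[[id]]), id)
})

test_that("bind_parameters applies symmetry and isolation constraints", {
  sym <- demographic_model("e1_s", "sym")
  b <- bind_parameters(sym, c(T1 = 0.2, nu1_1 = 1, nu2_1 = 2, m1 = 0.5))
  expect_equal(b$epochs[[1]]$m12, 0.5)
  expect_equal(b$epochs[[1]]$m21, 0.5)

  sc <- model_sc()
  b2 <- bind_parameters(sc, c(T1 = 0.3, nu1_1 = 1, nu2_1 = 1,
                              T2 = 0.1, nu1_2 = 2, nu2_2 = 2, m2 = 1))
  expect_equal(b2$epochs[[1]]$m12, 0)   # isolation epoch
  expect_equal(b2$epochs[[1]]$m21, 0)
  expect_equal(b2$epochs[[2]]$m12, 1)

  isl <- demographic_model("e1_s_i", "sym", islands = TRUE)
  expect_error(
    bind_parameters(isl, c(T1 = 0.2, nu1_1 = 1, nu2_1 = 1, m1 = 1,
                           P1 = 1.2, b = 0.5)),
    "P1")
  expect_error(bind_parameters(sym, c(0.2, 1, 2)), "expected 4")
})

test_that("the catalog YAML export round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  sub <- catalog_list()[c("e1_s", "ae2_ns_i", "sc3ielsm1")]
  write_model_catalog(path, sub)
  back <- read_model_catalog(path)
  expect_setequal(names(back), names(sub))
  for (nm in names(sub)) {
    expect_identical(back[[nm]]$mig_modes, sub[[nm]]$mig_modes)
    expect_identical(back[[nm]]$islands, sub[[nm]]$islands)
    expect_identical(back[[nm]]$anc_change, sub[[nm]]$anc_change)
    expect_equal(back[[nm]]$params, sub[[nm]]$params)
  }
})

test_that("the shipped catalog file matches the built-in catalog", {
  shipped <- system.file("extdata", "model_catalog.yaml",
                         package = "jointsfs")
  expect_true(nzchar(shipped))
  back <- read_model_catalog(shipped)
  cat107 <- catalog_list()
  expect_setequal(names(back), names(cat107))
  for (nm in names(cat107))
    expect_identical(back[[nm]]$mig_modes, cat107[[nm]]$mig_modes)
})
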