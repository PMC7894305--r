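test_that("the fixture VCF reproduces its manifest exactly", {
  fx <- fixture_vcf()
  res <- filter_pipeline(fx$vcf, fx$populations, outgroup_alleles = NULL,
                         config = filter_config())
  exp <- fx$expected

  expect_identical(res$report$individuals_removed, exp$removed_individuals)
  log <- res$report$site_filter_log
  for (rule in names(exp$rule_drops)) {
    expect_equal(log$dropped[log$rule == rule],
                 unname(exp$rule_drops[rule]),
                 label = paste("drops at rule", rule))
  }
  expect_equal(res$report$genotypes_masked, exp$genotypes_masked)
  expect_equal(unlist(res$report$polarization),
               exp$polarization[names(unlist(res$report$polarization))])
  got_keys <- paste(res$sites$scaffold, res$sites$position)
  fxk <- fx$vcf@fix
  exp_keys <- paste(fxk[, "CHROM"], fxk[, "POS"])[
    fxk[, "ID"] %in% exp$final_ids]
  expect_setequal(got_keys, exp_keys)
  expect_equal(res$sites$d1[res$sites$scaffold == "fx_s9"], exp$og_alt_d1)
})

test_that("filter chain is idempotent on its own output", {
  fx <- fixture_vcf()
  cfg <- filter_config()
  r1 <- drop_undersequenced_individuals(fx$vcf, cfg$indiv_missing_max)
  s1 <- site_filters(r1$vcf, fx$populations, cfg)
  s2 <- site_filters(s1$vcf, fx$populations, cfg)
  expect_identical(s2$vcf@fix, s1$vcf@fix)
  expect_identical(s2$vcf@gt, s1$vcf@gt)
  expect_true(all(s2$log$dropped == 0))
  # per-rule drops plus retained reconstruct the count entering each rule
  entering <- c(nrow(fx$vcf@fix), s1$log$retained[-nrow(s1$log)])
  expect_equal(s1$log$dropped + s1$log$retained, entering)
})

test_that("under-sequenced individuals are dropped at the 50% default", {
  fx <- fixture_vcf()
  gt <- jointsfs:::.gt_dosage(fx$vcf)
  rates <- colMeans(!is.na(gt))
  res <- drop_undersequenced_individuals(fx$vcf, 0.5)
  expect_setequal(res$removed, names(rates)[rates < 0.5])
  # 3 samples at call rates (0.2, 0.6, 0.9): exactly one removed
  sub <- fx$vcf
  keep3 <- c("p1_01", "p1_02", "p1_03")
  sub@gt <- sub@gt[, c("FORMAT", keep3)]
  n <- nrow(sub@gt)
  mk <- function(rate) {
    g <- rep("0/1:10:5,5", n)
    g[seq_len(round((1 - rate) * n))] <- "./.:0:0,0"
    g
  }
  sub@gt[, keep3] <- cbind(mk(0.2), mk(0.6), mk(0.9))
  res3 <- drop_undersequenced_individuals(sub, 0.5)
  expect_equal(ncol(res3$vcf@gt) - 1L, 2L)
  expect_identical(res3$removed, "p1_01")
})

test_that("thinning keeps greedy 1-per-window sites and dedupes", {
  s <- site_table(rep("sc1", 3), c(100, 600, 1150),
                  d1 = 1, c1 = 4, d2 = 1, c2 = 4)
  th <- thin_sites(s, 1000)
  expect_equal(th$position, c(100, 1150))

  one_per <- site_table(c("a", "b", "c"), c(5, 5, 5),
                        d1 = 1, c1 = 4, d2 = 1, c2 = 4)
  expect_equal(nrow(thin_sites(one_per, 1000)), 3)

  empty <- s[0, ]
  expect_equal(nrow(thin_sites(empty, 1000)), 0)

  dup <- rbind(s, s[1, ])
  expect_warning(thd <- thin_sites(dup, 1000), "sorted")
  expect_equal(thd$position, c(100, 1150))
})

test_that("polarization maps outgroup states to derived counts", {
  fx <- fixture_vcf()
  cfg <- filter_config()
  piped <- site_filters(
    drop_undersequenced_individuals(fx$vcf, 0.5)$vcf,
    fx$populations, cfg)
  pol <- polarize(piped$vcf, NULL, fx$populations)
  # clean_1: outgroup = REF = A; derived are ALT copies (6 het + 3 hom per
  # population template = 12 copies of 24)
  cl <- pol$sites[pol$sites$scaffold == "fx_s1", ]
  expect_equal(cl$d1, 12); expect_equal(cl$c1, 24)
  expect_equal(cl$ancestral, "A"); expect_equal(cl$derived, "G")
  # explicit per-site table instead of the AA tag gives the same answer
  tab <- data.frame(scaffold = piped$vcf@fix[, "CHROM"],
                    position = as.integer(piped$vcf@fix[, "POS"]),
                    allele = sub("AA=", "",
                                 ifelse(piped$vcf@fix[, "INFO"] == ".",
                                        NA, piped$vcf@fix[, "INFO"])))
  pol2 <- polarize(piped$vcf, tab, fx$populations)
  expect_identical(pol$sites$d1, pol2$sites$d1)
  expect_identical(unname(pol$log), unname(pol2$log))
})
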