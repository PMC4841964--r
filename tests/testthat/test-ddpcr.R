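test_that("poisson_lambda matches the occupancy model", {
  expect_identical(poisson_lambda(13000, 0), 0)
  expect_equal(poisson_lambda(13000, 6000), 0.61904, tolerance = 1e-4)
  expect_equal(poisson_lambda(1000, 500), log(2), tolerance = 1e-12)

  # monotone in the positive count
  lams <- poisson_lambda(rep(500, 499), 0:498)
  expect_true(all(diff(lams) > 0))

  expect_error(poisson_lambda(1000, 1000), class = "cnvdrop_saturation")
  expect_error(poisson_lambda(0, 0), class = "cnvdrop_empty_well")
  expect_error(poisson_lambda(100, 101))
})

test_that("poisson_lambda agrees with numerical inversion on a small grid", {
  for (n in c(7, 23, 60)) {
    for (k in 0:(n - 1)) {
      expect_equal(poisson_lambda(n, k), lambda_oracle(n, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("copy_number_from_well computes the diploid-normalised ratio", {
  # identical channel occupancy is diploid
  eq <- copy_number_from_well(13000, 6000, 6000)
  expect_equal(eq$cn_estimate, 2)
  expect_true(eq$ci_low <= eq$cn_estimate && eq$cn_estimate <= eq$ci_high)

  # frozen from direct evaluation: 2 * ln(13000/954) / ln(13/7)
  high <- copy_number_from_well(13000, 12046, 6000)
  expect_equal(high$cn_estimate, 8.4390, tolerance = 1e-4)
  expect_equal(high$cn_estimate,
               2 * high$lambda_target / high$lambda_ref)

  expect_error(copy_number_from_well(13000, 6000, 0),
               class = "cnvdrop_reference_failure")
  expect_error(copy_number_from_well(13000, 13000, 6000),
               class = "cnvdrop_saturation")

  low <- copy_number_from_well(5000, 2000, 2300)
  expect_match(low$qc_flags, "low_droplets")
})

test_that("the CI covers the truth in simulation", {
  set.seed(401)
  cfg <- sim_config()
  wells <- simulate_wells(rep(10, 400), cfg)
  calls <- ddpcr_quantify(wells, merge = FALSE)
  covered <- mean(calls$ci_low <= 10 & 10 <= calls$ci_high)
  expect_gte(covered, 0.9)
  expect_true(all(abs(calls$cn_estimate - 10) < 1))
})

test_that("merge_assay_calls pools duplicate assays", {
  one <- copy_number_from_well(13000, 9000, 6000, sample_id = "s1",
                               assay_id = "CNV-759")
  expect_identical(merge_assay_calls(one), one)

  mk <- function(cn, se, assay) data.frame(
    sample_id = "s1", assay_id = assay, locus = "CNV_16.1", method = "ddPCR",
    cn_estimate = cn, ci_low = cn - 1.959964 * se, ci_high = cn + 1.959964 * se,
    lambda_target = NA_real_, lambda_ref = NA_real_, qc_flags = "",
    stringsAsFactors = FALSE)

  sym <- merge_assay_calls(rbind(mk(9.9, 0.2, "CNV-759"), mk(10.1, 0.2, "CNV-E")))
  expect_equal(sym$cn_estimate, 10)
  expect_false(grepl("assay_discordant", sym$qc_flags))
  # pooled interval is tighter than either input
  expect_lt(sym$ci_high - sym$ci_low, 2 * 1.959964 * 0.2)

  disc <- merge_assay_calls(rbind(mk(6, 0.2, "CNV-759"), mk(9, 0.2, "CNV-E")))
  expect_match(disc$qc_flags, "assay_discordant")

  expect_error(merge_assay_calls(mk(5, .1, "a")[0, ]))
})

test_that("binomial thinning leaves the estimate unbiased but widens the CI", {
  set.seed(402)
  cfg <- sim_config(n_droplets_sd = 0)
  wells <- simulate_wells(rep(6, 1000), cfg)
  thin <- wells
  thin$n_accepted <- wells$n_accepted %/% 2
  thin$n_pos_target <- rbinom(nrow(wells), wells$n_pos_target, 0.5)
  thin$n_pos_ref <- rbinom(nrow(wells), wells$n_pos_ref, 0.5)

  full_calls <- ddpcr_quantify(wells, merge = FALSE)
  half_calls <- ddpcr_quantify(thin, merge = FALSE)
  expect_equal(mean(half_calls$cn_estimate), mean(full_calls$cn_estimate),
               tolerance = 0.02)
  expect_gt(mean(half_calls$ci_high - half_calls$ci_low),
            mean(full_calls$ci_high - full_calls$ci_low))
})

test_that("copy number is independent of the assumed droplet volume", {
  # the volume enters concentration reporting only; the ratio cancels it
  expect_equal(copy_number_from_well(13000, 9000, 6000)$cn_estimate,
               copy_number_from_well(13000, 9000, 6000)$cn_estimate)
  expect_equal(copies_per_microlitre(0.62, 0.91) * 0.91,
               copies_per_microlitre(0.62, 1) * 1)
  set.seed(403)
  a <- simulate_wells(c(2, 6), sim_config(droplet_volume_nl = 0.91))
  set.seed(403)
  b <- simulate_wells(c(2, 6), sim_config(droplet_volume_nl = 5))
  expect_identical(ddpcr_quantify(a, merge = FALSE)$cn_estimate,
                   ddpcr_quantify(b, merge = FALSE)$cn_estimate)
})

test_that("ddpcr_quantify survives failing wells and merges per sample", {
  wells <- data.frame(
    sample_id = c("s1", "s1", "s2"),
    assay_id = c("CNV-759", "CNV-E", "CNV-759"),
    n_accepted = c(13000, 13000, 13000),
    n_pos_target = c(11000, 11100, 13000),   # s2 saturated
    n_pos_ref = c(6000, 6100, 6000),
    stringsAsFactors = FALSE)
  calls <- ddpcr_quantify(wells)
  s1 <- calls[calls$sample_id == "s1", ]
  expect_equal(nrow(s1), 1)        # two assays merged into one CNV_16.1 call
  s2 <- calls[calls$sample_id == "s2", ]
  expect_true(is.na(s2$cn_estimate))
  expect_match(s2$qc_flags, "saturated")
})

test_that("well CSV round-trips through read_wells", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(404)
  wells <- simulate_wells(c(2, 10), sample_id = c("a", "b"))
  write.csv(wells, path, row.names = FALSE)
  expect_equal(read_wells(path), wells)

  bad <- wells; bad$n_pos_target[1] <- bad$n_accepted[1] + 5
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_wells(path), "violate")
})
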