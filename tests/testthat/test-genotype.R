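test_that("locus models enumerate diploid classes from allele values", {
  m14 <- locus_model("CNV_14.3", c(1, 3))
  expect_equal(m14$genotype_classes, c(2, 4, 6))
  m16 <- locus_model("CNV_16.1", c(5, 1))
  expect_equal(m16$genotype_classes, c(2, 6, 10))
  expect_equal(m16$class_alleles[["6"]], c(5, 1))
  # ambiguous totals are rejected (1+3 == 2+2)
  expect_error(locus_model("bad", c(1, 2, 3)), "ambiguous")
})

test_that("call_genotype assigns the nearest class and decomposes alleles", {
  models <- builtin_locus_models()
  g <- call_genotype(5.9, models[["CNV_16.1"]])
  expect_equal(g$total_cn, 6)
  expect_equal(g$alleles, "5|1")

  g2 <- call_genotype(2.0, models[["CNV_14.3"]])
  expect_equal(g2$total_cn, 2)
  expect_equal(g2$alleles, "1|1")

  # 4.05 at CNV_16.1: 1.95 from 6 and 2.05 from 2, both beyond 1.5
  nc <- call_genotype(4.05, models[["CNV_16.1"]])
  expect_true(is.na(nc$total_cn))
  expect_match(nc$flags, "no_call")

  # exact midpoint between classes surfaces as a no-call
  mid <- call_genotype(3, models[["CNV_14.3"]])
  expect_true(is.na(mid$total_cn))
  expect_match(mid$flags, "midpoint_tie")
})

test_that("calls are stable under sub-half-gap perturbation", {
  models <- builtin_locus_models()
  for (locus in names(models)) {
    m <- models[[locus]]
    gap <- min(diff(m$genotype_classes))
    for (centre in m$genotype_classes) {
      for (eps in c(-0.49, -0.2, 0, 0.2, 0.49) * gap / 2 * 0.99) {
        g <- call_genotype(max(0, centre + eps), m)
        expect_equal(g$total_cn, centre)
      }
    }
  }
})

test_that("confidence reflects the estimate's uncertainty", {
  m <- builtin_locus_models()[["CNV_16.1"]]
  sharp <- call_genotype(6.2, m, sd = 0.1)
  expect_gt(sharp$confidence, 0.999)
  blurred <- call_genotype(5.0, m, sd = 2)
  expect_lt(blurred$confidence, 0.9)
  expect_match(blurred$flags, "ambiguous")
})

test_that("discover_clusters recovers the three canonical classes", {
  set.seed(421)
  truth <- rep(c(2, 6, 10), c(10, 60, 130))
  est <- cohort_ddpcr_estimates(truth)
  cl <- discover_clusters(est, locus = "CNV_16.1")
  expect_equal(cl$genotype_classes, c(2, 6, 10))
  expect_equal(cl$k, 3)

  expect_warning(one <- discover_clusters(rep(2, 40)), "degenerate")
  expect_equal(one$genotype_classes, 2)
})

test_that("clustering quality is lower for noisier qPCR estimates", {
  set.seed(422)
  truth <- rep(c(2, 6, 10), c(10, 60, 130))
  dd <- suppressWarnings(discover_clusters(cohort_ddpcr_estimates(truth)))
  qp <- suppressWarnings(discover_clusters(cohort_qpcr_estimates(truth)))
  expect_lt(qp$silhouette, dd$silhouette)
})

test_that("tabulate_counts reproduces the generator's bookkeeping", {
  set.seed(423)
  cohort <- simulate_cohort(sim_config(), n_cases = 60, n_controls = 25)
  tab <- tabulate_counts(cohort$genotypes, cohort$phenotypes)

  # genotype columns: spaid splits the cohort exactly
  g16 <- tab$genotype_counts[tab$genotype_counts$locus == "CNV_16.1", ]
  expect_equal(sum(g16$spaid_pos), 60)
  expect_equal(sum(g16$spaid_neg), 25)

  # allele linear map holds in every group column
  al <- tab$allele_counts[tab$allele_counts$locus == "CNV_16.1", ]
  for (col in setdiff(names(g16), c("locus", "level"))) {
    expect_equal(al[al$level == 5, col],
                 2 * g16[g16$level == 10, col] + g16[g16$level == 6, col])
    expect_equal(al[al$level == 1, col],
                 2 * g16[g16$level == 2, col] + g16[g16$level == 6, col])
  }

  # counts equal direct bookkeeping from the truth table
  spaid_pos_ids <- cohort$phenotypes$sample_id[cohort$phenotypes$spaid == 1]
  truth16 <- cohort$genotypes[cohort$genotypes$locus == "CNV_16.1", ]
  expect_equal(
    g16$spaid_pos,
    as.integer(vapply(c(2, 6, 10), function(k)
      sum(truth16$total_cn[truth16$sample_id %in% spaid_pos_ids] == k), 0)))
})

test_that("tabulate_counts handles empty cohorts and unknown samples", {
  empty <- tabulate_counts(
    data.frame(sample_id = character(0), locus = character(0),
               total_cn = integer(0), alleles = character(0)),
    data.frame(sample_id = "x", spaid = 0, fever = 0, arthritis = 0,
               vesicular = 0, otitis = 0, amyloidosis = NA, age_months = 70))
  expect_true(all(empty$genotype_counts$spaid_pos == 0))
  expect_true(all(empty$allele_counts$C1 == 0))

  set.seed(424)
  cohort <- simulate_cohort(sim_config(), 10, 5)
  orphan <- cohort$genotypes
  orphan$sample_id[orphan$sample_id == orphan$sample_id[1]] <- "ghost"
  expect_warning(tab <- tabulate_counts(orphan, cohort$phenotypes),
                 "missing from the phenotype")
  expect_equal(tab$excluded, "ghost")
})
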