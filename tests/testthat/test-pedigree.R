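trio_ped <- function(sire, dam, off) {
  as_pedigree(data.frame(
    family_id = "f", sample_id = c("s", "d", "o"),
    sire_id = c("0", "0", "s"), dam_id = c("0", "0", "d"),
    sex = c("1", "2", "1"), geno_CNV_16.1 = c(sire, dam, off),
    stringsAsFactors = FALSE))
}

test_that("check_mendelian validates allele transmission in trios", {
  ok <- check_mendelian(trio_ped("3|1", "3|1", "3|3"), "CNV_16.1")
  expect_equal(nrow(ok$violations), 0)
  expect_equal(ok$n_trios, 1)

  bad <- check_mendelian(trio_ped("5|5", "5|5", "5|1"), "CNV_16.1")
  expect_equal(nrow(bad$violations), 1)
  expect_equal(bad$violations$offspring, "o")

  skipped <- check_mendelian(trio_ped("0", "0", "5|1"), "CNV_16.1")
  expect_equal(skipped$n_skipped, 1)
  expect_equal(skipped$n_trios, 0)
})

test_that("half-genotyped trios are checked against the available parent", {
  half <- check_mendelian(trio_ped("5|5", "0", "1|1"), "CNV_16.1")
  expect_equal(half$n_half, 1)
  expect_equal(nrow(half$half_violations), 1)   # parent carries no 1-allele
  expect_equal(nrow(half$violations), 0)

  half_ok <- check_mendelian(trio_ped("5|1", "0", "1|1"), "CNV_16.1")
  expect_equal(nrow(half_ok$half_violations), 0)
})

test_that("pedigree invariants are enforced", {
  cyc <- data.frame(family_id = "f", sample_id = c("a", "b"),
                    sire_id = c("b", "a"), dam_id = c("0", "0"),
                    sex = c("1", "1"), stringsAsFactors = FALSE)
  expect_error(as_pedigree(cyc), "cycle")
  expect_error(as_pedigree(data.frame(sample_id = "a", sire_id = "zzz",
                                      dam_id = "0")), "unresolved")
})

test_that("the packaged example pedigree is Mendelian-consistent", {
  ped <- read_ped(system.file("extdata", "example_pedigree.ped",
                              package = "cnvdrop"))
  # generation-one male: CNV_14.3 3|1, CNV_16.1 5|1
  male <- ped[ped$sample_id == "M1", ]
  expect_equal(male$geno_CNV_14.3, "3|1")
  expect_equal(male$geno_CNV_16.1, "5|1")
  for (locus in c("CNV_14.3", "CNV_16.1")) {
    chk <- check_mendelian(ped, locus)
    expect_equal(nrow(chk$violations), 0)
    expect_equal(chk$n_skipped, 1)  # the ungenotyped offspring
  }
  two <- detect_two_locus_pairs(ped)
  expect_length(two$recombinants, 0)
})

test_that("recombination-free simulated pedigrees are clean", {
  set.seed(431)
  cfg <- sim_config(recombination_rate = 0)
  for (i in 1:3) {
    sim <- simulate_pedigree(cfg, generations = 4)
    expect_gte(nrow(sim$ped), 50)
    for (locus in c("CNV_14.3", "CNV_16.1")) {
      expect_equal(nrow(check_mendelian(sim$ped, locus)$violations), 0)
    }
    two <- detect_two_locus_pairs(sim$ped)
    expect_length(two$recombinants, 0)
    expect_true(all(paste(two$pair_freq$cn_14_3, two$pair_freq$cn_16_1) %in%
                      c("2 10", "4 6", "6 2")))
  }
})

test_that("an injected incompatible genotype is detected", {
  set.seed(432)
  sim <- simulate_pedigree(sim_config(recombination_rate = 0))
  ped <- sim$ped
  # corrupt the first offspring to an allele pair both parents lack;
  # such a genotype is incompatible with any transmission
  col <- "geno_CNV_16.1"
  corrupted <- NA_character_
  for (i in which(ped$sire_id != "0")) {
    parents <- c(ped[[col]][match(ped$sire_id[i], ped$sample_id)],
                 ped[[col]][match(ped$dam_id[i], ped$sample_id)])
    missing_allele <- setdiff(c(1, 5), unlist(lapply(parents, function(s)
      as.integer(strsplit(s, "|", fixed = TRUE)[[1]]))))
    if (length(missing_allele) > 0) {
      ped[[col]][i] <- paste(missing_allele[1], missing_allele[1], sep = "|")
      corrupted <- ped$sample_id[i]
      break
    }
  }
  expect_false(is.na(corrupted))
  chk <- check_mendelian(ped, "CNV_16.1")
  expect_true(corrupted %in% chk$violations$offspring)
})

test_that("two-locus screening flags non-canonical pairs", {
  g <- data.frame(
    sample_id = rep(c(paste0("s", 1:40), "rec"), each = 2),
    locus = rep(c("CNV_14.3", "CNV_16.1"), 41),
    total_cn = c(rep(c(2L, 10L), 30), rep(c(4L, 6L), 10), 4L, 2L),
    alleles = c(rep(c("1|1", "5|5"), 30), rep(c("3|1", "5|1"), 10),
                "3|1", "1|1"),
    stringsAsFactors = FALSE)
  res <- detect_two_locus_pairs(g)
  expect_equal(res$recombinants, "rec")          # the (4, 2) individual
  top <- res$pair_freq[1, ]
  expect_equal(c(top$cn_14_3, top$cn_16_1), c(2, 10))
  # phase inferred from co-segregation: 1 with 5, 3 with 1
  expect_true(all(res$haplotypes == cbind(c(1, 3), c(5, 1))))
})
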