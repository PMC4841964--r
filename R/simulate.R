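#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults
#' describe the study conditions the pipeline was built around: wells of
#' about 13,000 accepted droplets in which the reference channel averages
#' about 6,000 positives (reference occupancy `lambda = -ln(7/13) ~
#' 0.619` copies per droplet), Ct quadruplicates with 0.15 cycles of
#' replicate noise at perfect doubling efficiency, two canonical two-locus
#' haplotypes — 14.3-allele-1 coupled to 16.1-allele-5 at frequency 0.803
#' (the square root of the 64.5% modal-pair fraction) and 14.3-allele-3
#' coupled to 16.1-allele-1 — with rare recombination, and a disease model
#' in which the probability of the umbrella phenotype rises with the
#' dosage of the 16.1 5-copy allele. The penetrance defaults (0.045, 0.15,
#' 0.43 for dosage 0, 1, 2) were solved analytically so the expected
#' allele-level odds ratio under Hardy-Weinberg proportions is about 4,
#' the effect size the association stage is meant to recover.
#'
#' @param n_droplets_mean,n_droplets_sd Accepted droplets per well
#'   (Gaussian, truncated at 1000; defaults 13000 / 800).
#' @param droplet_volume_nl Droplet volume (nanolitres); only used for
#'   concentration reporting, never for copy number ratios.
#' @param lambda_ref_mean Mean reference-channel occupancy (copies per
#'   droplet) of the template load.
#' @param lambda_ref_cv Between-well coefficient of variation of the
#'   template load (lognormal, mean preserved); both channels of a well
#'   share the load, so the ratio is unaffected.
#' @param ct_noise_sd Per-replicate Ct noise SD in cycles.
#' @param qpcr_efficiency Amplification efficiency for the Ct model.
#' @param ct_ref_base,ct_target_base Baseline Ct of the reference assay
#'   and of the target assay at diploid copy number.
#' @param loci Named list of locus models (default built-ins).
#' @param haplotypes 2x2 matrix, rows = the two canonical haplotypes,
#'   columns = per-chromosome copy counts at the two loci.
#' @param hap_freq Frequencies of the two haplotypes (sum to 1).
#' @param recombination_rate Per-meiosis probability that a gamete
#'   couples alleles from the parent's two haplotypes. The true rate
#'   between the overlapping duplications is unknown; 0.01 is a
#'   placeholder large enough to surface rare recombinant pairs in big
#'   cohorts.
#' @param penetrance Disease probability by risk-allele dosage (0, 1, 2
#'   copies of the 16.1 5-copy allele).
#' @param subphenotype_rates Conditional probability of each clinical sign
#'   given disease (defaults follow the observed sign mix: fever 114/155,
#'   arthritis 79/155, vesicular 44/155, otitis 34/155, amyloidosis
#'   31/155).
#' @param control_min_age_months Minimum age for disease-free individuals
#'   to qualify as age-restricted controls.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_droplets_mean = 13000, n_droplets_sd = 800,
                       droplet_volume_nl = 0.91,
                       lambda_ref_mean = -log(7000 / 13000),
                       lambda_ref_cv = 0.10,
                       ct_noise_sd = 0.15, qpcr_efficiency = 2,
                       ct_ref_base = 24, ct_target_base = 25,
                       loci = builtin_locus_models(),
                       haplotypes = cbind(c(1, 3), c(5, 1)),
                       hap_freq = c(0.803, 0.197),
                       recombination_rate = 0.01,
                       penetrance = c(0.045, 0.15, 0.43),
                       subphenotype_rates = c(fever = 114 / 155,
                                              arthritis = 79 / 155,
                                              vesicular = 44 / 155,
                                              otitis = 34 / 155,
                                              amyloidosis = 31 / 155),
                       control_min_age_months = 60) {
  if (abs(sum(hap_freq) - 1) > 1e-8 || any(hap_freq < 0)) {
    stop("hap_freq must be non-negative and sum to 1")
  }
  if (any(penetrance < 0 | penetrance > 1) || length(penetrance) != 3) {
    stop("penetrance must be three probabilities (dosage 0, 1, 2)")
  }
  if (recombination_rate < 0 || recombination_rate > 0.5) {
    stop("recombination_rate must be in [0, 0.5]")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate one ddPCR well
#'
#' Droplet partitioning of digested template: the well's template load
#' sets the reference occupancy (lognormal around the configured mean);
#' the target occupancy is `lambda_ref * cn_truth / 2`; each channel's
#' positive count is binomial with per-droplet positive probability
#' `1 - exp(-lambda)`. Deterministic for a fixed RNG state (`set.seed`).
#'
#' @param cn_truth True copies per diploid genome (>= 0).
#' @param cfg A [sim_config()].
#' @param sample_id,assay_id Identifiers for the output row.
#' @return One-row data frame in [read_wells()] shape.
#' @export
simulate_well <- function(cn_truth, cfg = sim_config(),
                          sample_id = "sim", assay_id = "CNV-759") {
  simulate_wells(cn_truth, cfg, sample_id = sample_id, assay_id = assay_id)
}

#' Simulate many ddPCR wells at once
#'
#' Vectorised form of [simulate_well()]: one well per element of
#' `cn_truth`.
#'
#' @inheritParams simulate_well
#' @return Data frame with one row per well.
#' @export
simulate_wells <- function(cn_truth, cfg = sim_config(),
                           sample_id = paste0("sim", seq_along(cn_truth)),
                           assay_id = "CNV-759") {
  stopifnot(all(cn_truth >= 0))
  n_wells <- length(cn_truth)
  sdlog <- sqrt(log(1 + cfg$lambda_ref_cv^2))
  lam_r <- cfg$lambda_ref_mean * rlnorm(n_wells, -sdlog^2 / 2, sdlog)
  lam_t <- lam_r * cn_truth / 2
  n_acc <- pmax(1000, round(rnorm(n_wells, cfg$n_droplets_mean,
                                  cfg$n_droplets_sd)))
  data.frame(sample_id = rep_len(sample_id, n_wells),
             assay_id = rep_len(assay_id, n_wells),
             n_accepted = n_acc,
             n_pos_target = rbinom(n_wells, n_acc, 1 - exp(-lam_t)),
             n_pos_ref = rbinom(n_wells, n_acc, 1 - exp(-lam_r)),
             stringsAsFactors = FALSE)
}

#' Simulate qPCR Ct replicate sets for one sample
#'
#' Inverts the delta-delta-Ct model: the target Ct decreases by one cycle
#' (at efficiency 2) per doubling of copy number relative to the diploid
#' baseline, the reference Ct is flat, and independent Gaussian noise of
#' `ct_noise_sd` cycles is added per replicate. With zero noise,
#' [delta_delta_ct()] against a calibrator generated at `cn_truth = 2`
#' recovers `cn_truth` exactly.
#'
#' @param cn_truth True copy number (> 0).
#' @param cfg A [sim_config()].
#' @param sample_id,assay_id Identifiers.
#' @param n_replicates Replicates per reaction (default 4).
#' @return Data frame of two rows (dyes `FAM-target`, `VIC-reference`)
#'   with columns `ct1..ctN`, in [read_ct_table()] shape.
#' @export
simulate_ct <- function(cn_truth, cfg = sim_config(), sample_id = "sim",
                        assay_id = "CNV-759", n_replicates = 4) {
  stopifnot(cn_truth > 0)
  ct_t <- cfg$ct_target_base - log(cn_truth / 2, base = cfg$qpcr_efficiency) +
    rnorm(n_replicates, 0, cfg$ct_noise_sd)
  ct_r <- cfg$ct_ref_base + rnorm(n_replicates, 0, cfg$ct_noise_sd)
  out <- data.frame(sample_id = sample_id, assay_id = assay_id,
                    dye = c("FAM-target", "VIC-reference"),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_replicates)) out[[paste0("ct", j)]] <- c(ct_t[j], ct_r[j])
  out
}

# draw n individuals' haplotype pairs (indices into cfg$haplotypes)
draw_hap_pairs <- function(n, cfg) {
  matrix(sample.int(nrow(cfg$haplotypes), 2 * n, replace = TRUE,
                    prob = cfg$hap_freq), ncol = 2)
}

hap_genotype_strings <- function(h1, h2, cfg) {
  list(g1 = format_alleles(c(h1[1], h2[1])),
       g2 = format_alleles(c(h1[2], h2[2])))
}

# one gamete from a parent's two haplotypes (2-column matrix rows),
# with recombination at the configured rate
make_gamete <- function(hap_a, hap_b, cfg) {
  pick <- sample.int(2, 1)
  first <- if (pick == 1) hap_a else hap_b
  other <- if (pick == 1) hap_b else hap_a
  recombined <- runif(1) < cfg$recombination_rate
  if (recombined) c(first[1], other[2]) else first
}

#' Simulate a multi-generation pedigree with true CNV haplotypes
#'
#' Founders draw two haplotypes from the configured population
#' frequencies; each non-founder receives one (possibly recombined)
#' gamete per parent. Matings pair each generation's offspring with fresh
#' founder spouses, so the structure is an extended outbred pedigree.
#' True haplotypes are recorded per individual for oracle testing.
#'
#' @param cfg A [sim_config()].
#' @param generations Number of offspring generations (default 4).
#' @param n_founder_couples Couples in generation zero (default 4).
#' @param mean_litter Mean litter size (Poisson, at least 1; default 3).
#' @param family_id Family label for the PED rows.
#' @return List: `ped` (a [as_pedigree()] data frame with `geno_<locus>`
#'   columns) and `truth` (per individual: the four haplotype allele
#'   values `h1_l1, h1_l2, h2_l1, h2_l2` and whether either inherited
#'   gamete was `recombinant`).
#' @export
simulate_pedigree <- function(cfg = sim_config(), generations = 4,
                              n_founder_couples = 4, mean_litter = 3,
                              family_id = "fam1") {
  loci <- colnames(cfg$haplotypes)
  if (is.null(loci)) loci <- names(cfg$loci)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("%s_I%03d", family_id, counter)
  }
  rows <- list(); truth <- list()
  add_individual <- function(h1, h2, sire, dam, sex, recombinant) {
    id <- new_id()
    g <- hap_genotype_strings(h1, h2, cfg)
    rows[[id]] <<- data.frame(family_id = family_id, sample_id = id,
                              sire_id = sire, dam_id = dam, sex = sex,
                              g1 = g$g1, g2 = g$g2, stringsAsFactors = FALSE)
    truth[[id]] <<- data.frame(sample_id = id, h1_l1 = h1[1], h1_l2 = h1[2],
                               h2_l1 = h2[1], h2_l2 = h2[2],
                               recombinant = recombinant,
                               stringsAsFactors = FALSE)
    id
  }
  founder <- function(sex) {
    idx <- draw_hap_pairs(1, cfg)
    add_individual(cfg$haplotypes[idx[1], ], cfg$haplotypes[idx[2], ],
                   "0", "0", sex, FALSE)
  }
  get_haps <- function(id) {
    t <- truth[[id]]
    list(h1 = c(t$h1_l1, t$h1_l2), h2 = c(t$h2_l1, t$h2_l2))
  }
  mate <- function(sire, dam) {
    n_off <- max(1, rpois(1, mean_litter))
    vapply(seq_len(n_off), function(i) {
      hs <- get_haps(sire); hd <- get_haps(dam)
      g_s <- make_gamete(hs$h1, hs$h2, cfg)
      g_d <- make_gamete(hd$h1, hd$h2, cfg)
      canon <- apply(cfg$haplotypes, 1, paste, collapse = "-")
      rec <- !(paste(g_s, collapse = "-") %in% canon) ||
        !(paste(g_d, collapse = "-") %in% canon)
      add_individual(g_s, g_d, sire, dam, sample(c("1", "2"), 1), rec)
    }, character(1))
  }

  current <- lapply(seq_len(n_founder_couples), function(i) {
    list(sire = founder("1"), dam = founder("2"))
  })
  for (g in seq_len(generations)) {
    offspring <- unlist(lapply(current, function(cp) mate(cp$sire, cp$dam)))
    if (g == generations) break
    current <- lapply(offspring, function(id) {
      i <- match(id, names(rows))
      if (rows[[id]]$sex == "1") list(sire = id, dam = founder("2"))
      else list(sire = founder("1"), dam = id)
    })
  }

  ped <- do.call(rbind, rows)
  names(ped)[names(ped) == "g1"] <- paste0("geno_", loci[1])
  names(ped)[names(ped) == "g2"] <- paste0("geno_", loci[2])
  rownames(ped) <- NULL
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(ped = as_pedigree(ped), truth = truth)
}

#' Simulate a case/control cohort with genotype-dependent disease risk
#'
#' Individuals draw two haplotypes from the population frequencies;
#' disease status is Bernoulli with probability given by the penetrance of
#' their risk-allele dosage. Sampling continues until the requested case
#' and control quotas are filled (controls must be disease-free and older
#' than the configured age floor). Clinical signs are assigned to cases at
#' the configured conditional rates (at least one sign is guaranteed);
#' amyloidosis status for controls is known only for the subset with
#' histopathology. The realised allele-level odds ratio of the sampled
#' cohort is recorded so downstream recovery can be tested against it.
#'
#' @param cfg A [sim_config()].
#' @param n_cases,n_controls Cohort quotas (defaults 155 / 34).
#' @return List: `phenotypes` (data frame `sample_id, spaid, fever,
#'   arthritis, vesicular, otitis, amyloidosis, age_months`), `genotypes`
#'   (long truth table `sample_id, locus, total_cn, alleles`),
#'   `realised_or` (list from [odds_ratio()] on the cohort's true allele
#'   counts) and `allele_table` (the `a, b, c, d` counts behind it).
#' @export
simulate_cohort <- function(cfg = sim_config(), n_cases = 155,
                            n_controls = 34) {
  risk_locus <- 2L          # second column of cfg$haplotypes = CNV_16.1
  risk_allele <- max(cfg$haplotypes[, risk_locus])
  loci <- names(cfg$loci)

  cases <- list(); controls <- list(); i <- 0L
  while (length(cases) < n_cases || length(controls) < n_controls) {
    idx <- draw_hap_pairs(1, cfg)
    h1 <- cfg$haplotypes[idx[1], ]; h2 <- cfg$haplotypes[idx[2], ]
    dosage <- sum(c(h1[risk_locus], h2[risk_locus]) == risk_allele)
    diseased <- runif(1) < cfg$penetrance[dosage + 1]
    if (diseased && length(cases) >= n_cases) next
    if (!diseased && length(controls) >= n_controls) next
    i <- i + 1L
    id <- sprintf("dog%04d", i)
    rec <- list(id = id, h1 = h1, h2 = h2, diseased = diseased)
    if (diseased) cases[[id]] <- rec else controls[[id]] <- rec
  }

  indiv <- c(cases, controls)
  n <- length(indiv)
  sub <- cfg$subphenotype_rates
  pheno <- do.call(rbind, lapply(indiv, function(x) {
    if (x$diseased) {
      signs <- setNames(as.integer(runif(length(sub)) < sub), names(sub))
      if (all(signs == 0)) signs["fever"] <- 1L
      age <- round(runif(1, 6, 150))
    } else {
      # amyloid status known only with post-mortem histopathology (~half)
      signs <- setNames(rep(0L, length(sub)), names(sub))
      signs["amyloidosis"] <- if (runif(1) < 0.5) 0L else NA_integer_
      age <- round(runif(1, cfg$control_min_age_months + 1, 160))
    }
    data.frame(sample_id = x$id, spaid = as.integer(x$diseased),
               fever = signs[["fever"]], arthritis = signs[["arthritis"]],
               vesicular = signs[["vesicular"]], otitis = signs[["otitis"]],
               amyloidosis = signs[["amyloidosis"]], age_months = age,
               stringsAsFactors = FALSE)
  }))
  rownames(pheno) <- NULL

  genotypes <- do.call(rbind, lapply(indiv, function(x) {
    data.frame(sample_id = x$id, locus = loci,
               total_cn = c(x$h1[1] + x$h2[1], x$h1[2] + x$h2[2]),
               alleles = c(format_alleles(c(x$h1[1], x$h2[1])),
                           format_alleles(c(x$h1[2], x$h2[2]))),
               stringsAsFactors = FALSE)
  }))
  rownames(genotypes) <- NULL

  dos <- vapply(indiv, function(x)
    sum(c(x$h1[risk_locus], x$h2[risk_locus]) == risk_allele), 0)
  dis <- vapply(indiv, function(x) x$diseased, TRUE)
  a <- sum(dos[dis]); b <- 2 * sum(dis) - a
  cc <- sum(dos[!dis]); d <- 2 * sum(!dis) - cc
  realised <- odds_ratio(a, b, cc, d)

  list(phenotypes = pheno, genotypes = genotypes, realised_or = realised,
       allele_table = c(a = a, b = b, c = cc, d = d))
}
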