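# Independent oracle for the Poisson occupancy inversion: solve
# 1 - exp(-lambda) = p numerically instead of using the closed form.
lambda_oracle <- function(n_accepted, n_positive) {
  p <- n_positive / n_accepted
  if (p == 0) return(0)
  uniroot(function(l) (1 - exp(-l)) - p, c(1e-12, 60),
          tol = .Machine$double.eps^0.8)$root
}

# ddPCR-style well quantification for a whole cohort: one well per
# individual at the given truth, returning cn estimates (merged per
# sample when duplicate assays are given).
cohort_ddpcr_estimates <- function(cn_truth, cfg = sim_config()) {
  wells <- simulate_wells(cn_truth, cfg,
                          sample_id = sprintf("s%04d", seq_along(cn_truth)))
  calls <- ddpcr_quantify(wells, merge = FALSE)
  calls$cn_estimate
}

# qPCR estimates for a cohort against one freshly simulated diploid
# calibrator.
cohort_qpcr_estimates <- function(cn_truth, cfg = sim_config()) {
  cal <- simulate_ct(2, cfg, sample_id = "cal")
  cal_t <- as.numeric(cal[cal$dye == "FAM-target", paste0("ct", 1:4)])
  cal_r <- as.numeric(cal[cal$dye == "VIC-reference", paste0("ct", 1:4)])
  vapply(cn_truth, function(cn) {
    s <- simulate_ct(cn, cfg)
    st <- as.numeric(s[s$dye == "FAM-target", paste0("ct", 1:4)])
    sr <- as.numeric(s[s$dye == "VIC-reference", paste0("ct", 1:4)])
    delta_delta_ct(st, sr, cal_t, cal_r)$cn_estimate
  }, 1)
}

# draw true CNV_16.1 totals at the canonical class mix
draw_cn16_truth <- function(n, probs = c(0.043, 0.303, 0.645)) {
  sample(c(2, 6, 10), n, replace = TRUE, prob = probs)
}
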