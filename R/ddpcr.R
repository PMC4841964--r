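#' Mean template copies per droplet from droplet counts
#'
#' Inverts the Poisson occupancy model of droplet digital PCR. Template is
#' partitioned at random across droplets, so the number of copies in a
#' droplet is Poisson with mean `lambda` and the probability that a droplet
#' is negative (no amplification) is `exp(-lambda)`. Estimating that
#' probability by the observed negative fraction gives
#' `lambda = -ln((n_accepted - n_positive) / n_accepted)`.
#'
#' @param n_accepted Accepted droplet count(s), integer > 0.
#' @param n_positive Positive droplet count(s) in one fluorescence channel,
#'   `0 <= n_positive <= n_accepted`.
#' @return Mean copies per droplet (same length as the inputs).
#'   Monotonically increasing in `n_positive`; 0 when no droplet is
#'   positive.
#' @section Errors: all droplets positive (saturation, `lambda` undefined)
#'   raises a `cnvdrop_saturation` condition; `n_accepted = 0` raises
#'   `cnvdrop_empty_well`.
#' @examples
#' poisson_lambda(13000, 6000)   # ~0.619 copies per droplet
#' poisson_lambda(1000, 500)     # ln 2
#' @export
poisson_lambda <- function(n_accepted, n_positive) {
  if (any(n_accepted == 0)) {
    cnv_error("no accepted droplets: lambda is undefined for an empty well",
              "cnvdrop_empty_well")
  }
  if (any(n_positive < 0) || any(n_positive > n_accepted)) {
    stop("n_positive must lie in [0, n_accepted]")
  }
  if (any(n_positive == n_accepted)) {
    cnv_error("all droplets positive: channel saturated, lambda undefined",
              "cnvdrop_saturation")
  }
  log(n_accepted) - log(n_accepted - n_positive)
}

#' Copies per microlitre from copies per droplet
#'
#' Converts a per-droplet mean to a concentration. The droplet volume
#' enters only here: the diploid-normalised copy number ratio is a ratio
#' of lambdas and is independent of the assumed volume.
#'
#' @param lambda Mean copies per droplet.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.91).
#' @return Copies per microlitre of reaction mix.
#' @export
copies_per_microlitre <- function(lambda, droplet_volume_nl = 0.91) {
  lambda / (droplet_volume_nl * 1e-3)
}

# internal map from assay id to locus; CNV-759 and CNV-E are two
# independent assays on the same 16.1 kb variant
assay_locus <- function(assay_id) {
  map <- c("CNV-East" = "CNV_14.3", "CNV-759" = "CNV_16.1",
           "CNV-E" = "CNV_16.1")
  out <- unname(map[as.character(assay_id)])
  out
}

#' Absolute copy number call from one ddPCR well
#'
#' Duplex ddPCR measures the target CNV in the FAM channel and a diploid
#' housekeeper reference (C7orf28b) in the VIC channel of the same well.
#' The copy number per diploid genome is
#' `ploidy_copies * lambda_target / lambda_ref`. The 95% confidence
#' interval is obtained by the delta method on the log ratio, with
#' `var(lambda) = p / ((1 - p) * N)` for positive fraction `p` over `N`
#' droplets, channels independent.
#'
#' @param n_accepted Accepted droplets in the well.
#' @param n_pos_target FAM-positive (target) droplet count.
#' @param n_pos_ref VIC-positive (reference) droplet count.
#' @param sample_id,assay_id Identifiers carried into the call.
#' @param locus Locus name; defaults to the assay's locus
#'   (CNV-East -> CNV_14.3; CNV-759, CNV-E -> CNV_16.1).
#' @param ploidy_copies Copies of the reference per genome (default 2).
#' @param min_droplets QC floor for accepted droplets; below it the call
#'   is flagged `"low_droplets"`, not rejected (default 8000).
#' @return One-row data frame: `sample_id, assay_id, locus, method,
#'   cn_estimate, ci_low, ci_high, lambda_target, lambda_ref, qc_flags`.
#' @section Errors: a saturated channel raises `cnvdrop_saturation`; a
#'   reference channel with no positive droplets raises
#'   `cnvdrop_reference_failure` (nothing downstream can be normalised).
#' @examples
#' copy_number_from_well(13000, 6000, 6000)          # diploid: cn = 2
#' copy_number_from_well(13000, 12046, 6000)$cn_estimate  # ~8.44
#' @export
copy_number_from_well <- function(n_accepted, n_pos_target, n_pos_ref,
                                  sample_id = "sample", assay_id = NA_character_,
                                  locus = NULL, ploidy_copies = 2,
                                  min_droplets = 8000) {
  if (is.null(locus)) locus <- assay_locus(assay_id)
  if (n_pos_ref == 0) {
    cnv_error("reference channel has no positive droplets; well cannot be normalised",
              "cnvdrop_reference_failure")
  }
  lam_r <- poisson_lambda(n_accepted, n_pos_ref)
  lam_t <- poisson_lambda(n_accepted, n_pos_target)

  cn <- ploidy_copies * lam_t / lam_r
  flags <- character(0)
  if (n_accepted < min_droplets) flags <- c(flags, "low_droplets")

  p_r <- n_pos_ref / n_accepted
  var_lam_r <- p_r / ((1 - p_r) * n_accepted)
  if (n_pos_target == 0) {
    # zero-target well: cn = 0 exactly; upper bound from the Poisson
    # 95% bound on a zero count (~3 events) pushed through the ratio
    lam_up <- poisson_lambda(n_accepted, 3)
    ci <- c(0, ploidy_copies * lam_up / lam_r)
    flags <- c(flags, "zero_target")
  } else {
    p_t <- n_pos_target / n_accepted
    var_lam_t <- p_t / ((1 - p_t) * n_accepted)
    se_log <- sqrt(var_lam_t / lam_t^2 + var_lam_r / lam_r^2)
    ci <- cn * exp(c(-1, 1) * z95() * se_log)
  }

  data.frame(sample_id = sample_id, assay_id = assay_id, locus = locus,
             method = "ddPCR", cn_estimate = cn,
             ci_low = ci[1], ci_high = ci[2],
             lambda_target = lam_t, lambda_ref = lam_r,
             qc_flags = join_flags(flags), stringsAsFactors = FALSE)
}

#' Merge duplicate-assay copy number calls for one sample and locus
#'
#' Two assays interrogate CNV_16.1 (CNV-759 and CNV-E); their ddPCR
#' results are interchangeable, so a sample's calls are combined by an
#' inverse-variance-weighted mean (variances from the CI half-widths),
#' with the combined 95% interval from the pooled variance. Calls whose
#' estimates differ by more than `discordance_threshold` are flagged
#' `"assay_discordant"` — the default of 1.0 copy is about two standard
#' deviations of the inter-assay difference seen in practice for ddPCR
#' (0.01 +/- 0.52 copies).
#'
#' @param calls Data frame of calls (rows as returned by
#'   [copy_number_from_well()]) sharing one sample and locus.
#' @param discordance_threshold Maximum tolerated absolute difference
#'   between any two estimates before flagging (default 1.0 copy).
#' @return One-row data frame in the same shape; a single input call is
#'   returned unchanged.
#' @export
merge_assay_calls <- function(calls, discordance_threshold = 1) {
  if (nrow(calls) == 0) stop("no calls to merge")
  if (length(unique(calls$sample_id)) > 1 || length(unique(calls$locus)) > 1) {
    stop("merge_assay_calls expects calls for one sample at one locus")
  }
  if (nrow(calls) == 1) return(calls)

  se <- (calls$ci_high - calls$ci_low) / (2 * z95())
  w <- if (any(!is.finite(se)) || any(se <= 0)) {
    rep(1, nrow(calls))                       # equal weights fallback
  } else {
    1 / se^2
  }
  cn <- sum(w * calls$cn_estimate) / sum(w)
  se_comb <- sqrt(1 / sum(w))

  flags <- unlist(lapply(calls$qc_flags, split_flags))
  if (max(calls$cn_estimate) - min(calls$cn_estimate) > discordance_threshold) {
    flags <- c(flags, "assay_discordant")
  }

  data.frame(sample_id = calls$sample_id[1],
             assay_id = paste(sort(unique(calls$assay_id)), collapse = "+"),
             locus = calls$locus[1], method = calls$method[1],
             cn_estimate = cn,
             ci_low = max(0, cn - z95() * se_comb),
             ci_high = cn + z95() * se_comb,
             lambda_target = NA_real_, lambda_ref = NA_real_,
             qc_flags = join_flags(flags), stringsAsFactors = FALSE)
}

#' Quantify a table of ddPCR wells
#'
#' Applies [copy_number_from_well()] to each row of a well table and, when
#' `merge = TRUE`, combines duplicate-assay calls per sample and locus
#' with [merge_assay_calls()]. Wells that fail (saturation, reference
#' failure) are kept as rows with `NA` estimates and a QC flag naming the
#' failure, so one bad well does not abort a batch.
#'
#' @param wells Data frame with columns
#'   `sample_id, assay_id, n_accepted, n_pos_target, n_pos_ref`.
#' @param ploidy_copies,min_droplets Passed to [copy_number_from_well()].
#' @param merge Combine duplicate-assay calls per sample/locus (default
#'   TRUE).
#' @param discordance_threshold Passed to [merge_assay_calls()].
#' @return Data frame of copy number calls.
#' @export
ddpcr_quantify <- function(wells, ploidy_copies = 2, min_droplets = 8000,
                           merge = TRUE, discordance_threshold = 1) {
  needed <- c("sample_id", "assay_id", "n_accepted", "n_pos_target", "n_pos_ref")
  if (!all(needed %in% names(wells))) {
    stop("wells table must have columns: ", paste(needed, collapse = ", "))
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(wells)), function(i) {
    w <- wells[i, ]
    tryCatch(
      copy_number_from_well(w$n_accepted, w$n_pos_target, w$n_pos_ref,
                            sample_id = w$sample_id, assay_id = w$assay_id,
                            ploidy_copies = ploidy_copies,
                            min_droplets = min_droplets),
      cnvdrop_error = function(e) {
        flag <- if (inherits(e, "cnvdrop_saturation")) "saturated"
                else if (inherits(e, "cnvdrop_reference_failure")) "reference_failure"
                else "failed_well"
        data.frame(sample_id = w$sample_id, assay_id = w$assay_id,
                   locus = assay_locus(w$assay_id), method = "ddPCR",
                   cn_estimate = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, lambda_target = NA_real_,
                   lambda_ref = NA_real_, qc_flags = flag,
                   stringsAsFactors = FALSE)
      })
  }))
  if (!merge) return(calls)

  ok <- !is.na(calls$cn_estimate)
  merged <- do.call(rbind, lapply(
    split(calls[ok, ], interaction(calls$sample_id[ok], calls$locus[ok], drop = TRUE)),
    merge_assay_calls, discordance_threshold = discordance_threshold))
  out <- rbind(merged, calls[!ok, ])
  rownames(out) <- NULL
  out[order(out$sample_id, out$locus), ]
}

#' Read a ddPCR well table from CSV
#'
#' Expects a UTF-8 comma-separated file with header
#' `sample_id,assay_id,n_accepted,n_pos_target,n_pos_ref`, one row per
#' well.
#'
#' @param path File path.
#' @return Data frame of wells, count invariants checked.
#' @export
read_wells <- function(path) {
  wells <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "assay_id", "n_accepted", "n_pos_target", "n_pos_ref")
  if (!all(needed %in% names(wells))) {
    stop("well CSV must have header: ", paste(needed, collapse = ","))
  }
  bad <- wells$n_pos_target > wells$n_accepted | wells$n_pos_ref > wells$n_accepted |
    wells$n_pos_target < 0 | wells$n_pos_ref < 0 | wells$n_accepted < 0
  if (any(bad)) {
    stop("rows violate 0 <= n_positive <= n_accepted: ",
         paste(which(bad), collapse = ", "))
  }
  wells
}
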