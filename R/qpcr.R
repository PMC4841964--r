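#' Relative copy number by delta-delta-Ct
#'
#' Classic relative quantification of a target against a housekeeper
#' reference, normalised to a calibrator individual of known copy number:
#' `dCt = mean(Ct_target) - mean(Ct_ref)` for each individual,
#' `ddCt = dCt_sample - dCt_calibrator`, and
#' `cn = calibrator_cn * efficiency^(-ddCt)` (efficiency 2 assumes perfect
#' doubling per cycle). The error of the result is a composite of four
#' reactions — target and reference for both individuals — each measured
#' in replicate; the 95% CI combines the four standard errors of the mean
#' Ct in quadrature on the ddCt scale.
#'
#' @param sample_target,sample_ref Numeric Ct replicates (quadruplicates
#'   typically) for the sample's target and reference assays; `NA`s are
#'   dropped.
#' @param calibrator_target,calibrator_ref Ct replicates for the
#'   calibrator individual.
#' @param sample_id Identifier carried into the call.
#' @param assay_id,locus Assay/locus labels; the locus defaults to the
#'   assay's locus when recognised.
#' @param calibrator_cn Known copy number of the calibrator (default 2,
#'   a diploid reference individual).
#' @param efficiency Amplification efficiency, fold change per cycle
#'   (default 2).
#' @param sd_threshold Replicate standard deviation above which the call
#'   is flagged `"noisy_replicates"` (default 0.5 cycles).
#' @return One-row data frame in the same shape as
#'   [copy_number_from_well()] output, `method = "qPCR"`. If any replicate
#'   set has fewer than 2 values the CI is unavailable and the call is
#'   flagged `"no_ci"`.
#' @examples
#' # sample identical to the diploid calibrator: ddCt = 0, cn = 2
#' delta_delta_ct(c(25, 25.1), c(24, 24.1), c(25, 25.1), c(24, 24.1))
#' @export
delta_delta_ct <- function(sample_target, sample_ref,
                           calibrator_target, calibrator_ref,
                           sample_id = "sample", assay_id = NA_character_,
                           locus = NULL, calibrator_cn = 2, efficiency = 2,
                           sd_threshold = 0.5) {
  if (is.null(locus)) locus <- assay_locus(assay_id)
  sets <- list(sample_target, sample_ref, calibrator_target, calibrator_ref)
  sets <- lapply(sets, function(x) x[!is.na(x)])
  if (any(vapply(sets, length, 1L) == 0)) {
    cnv_error("each of the four replicate sets needs at least one Ct value",
              "cnvdrop_missing_replicates")
  }
  if (any(unlist(sets) <= 0) || any(unlist(sets) >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }

  means <- vapply(sets, mean, 1)
  ddct <- (means[1] - means[2]) - (means[3] - means[4])
  cn <- calibrator_cn * efficiency^(-ddct)

  flags <- character(0)
  sds <- vapply(sets, stats::sd, 1)
  ns <- vapply(sets, length, 1L)
  if (any(sds[!is.na(sds)] > sd_threshold)) flags <- c(flags, "noisy_replicates")
  if (any(ns < 2)) {
    flags <- c(flags, "no_ci")
    ci <- c(NA_real_, NA_real_)
  } else {
    se_ddct <- sqrt(sum(sds^2 / ns))
    ci <- calibrator_cn * efficiency^(-(ddct + c(1, -1) * z95() * se_ddct))
  }

  data.frame(sample_id = sample_id, assay_id = assay_id, locus = locus,
             method = "qPCR", cn_estimate = cn,
             ci_low = ci[1], ci_high = ci[2],
             lambda_target = NA_real_, lambda_ref = NA_real_,
             qc_flags = join_flags(flags), stringsAsFactors = FALSE)
}

#' Quantify a qPCR Ct replicate table
#'
#' Runs [delta_delta_ct()] for every sample/assay combination in a long
#' Ct table against the named calibrator individual.
#'
#' @param ct_table Data frame with columns
#'   `sample_id, assay_id, dye, ct1, ct2, ct3, ct4` (blank/`NA` cells are
#'   permitted for missing replicates). `dye` is `"FAM-target"` or
#'   `"VIC-reference"`.
#' @param calibrator Sample id of the reference individual with known
#'   copy number.
#' @param calibrator_cn,efficiency,sd_threshold Passed to
#'   [delta_delta_ct()].
#' @return Data frame of copy number calls (one row per sample x assay,
#'   calibrator excluded).
#' @export
qpcr_quantify <- function(ct_table, calibrator, calibrator_cn = 2,
                          efficiency = 2, sd_threshold = 0.5) {
  ct_cols <- grep("^ct[0-9]+$", names(ct_table), value = TRUE)
  if (length(ct_cols) == 0) stop("no ct columns (ct1..ctN) found")
  get_set <- function(sid, aid, dye_prefix) {
    rows <- ct_table$sample_id == sid & ct_table$assay_id == aid &
      startsWith(ct_table$dye, dye_prefix)
    if (!any(rows)) return(NULL)
    as.numeric(unlist(ct_table[rows, ct_cols]))
  }
  combos <- unique(ct_table[ct_table$sample_id != calibrator,
                            c("sample_id", "assay_id")])
  calls <- lapply(seq_len(nrow(combos)), function(i) {
    sid <- combos$sample_id[i]; aid <- combos$assay_id[i]
    st <- get_set(sid, aid, "FAM"); sr <- get_set(sid, aid, "VIC")
    kt <- get_set(calibrator, aid, "FAM"); kr <- get_set(calibrator, aid, "VIC")
    if (is.null(st) || is.null(sr) || is.null(kt) || is.null(kr)) {
      cnv_error(sprintf("sample %s assay %s: missing dye set (need FAM and VIC for sample and calibrator)",
                        sid, aid), "cnvdrop_missing_replicates")
    }
    delta_delta_ct(st, sr, kt, kr, sample_id = sid, assay_id = aid,
                   calibrator_cn = calibrator_cn, efficiency = efficiency,
                   sd_threshold = sd_threshold)
  })
  do.call(rbind, calls)
}

#' Read a qPCR Ct table from CSV
#'
#' Header `sample_id,assay_id,dye,ct1,ct2,ct3,ct4`; blank cells are read
#' as `NA` (missing replicates).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "assay_id", "dye")
  if (!all(needed %in% names(ct)) || !any(grepl("^ct[0-9]+$", names(ct)))) {
    stop("Ct CSV must have header sample_id,assay_id,dye,ct1,...")
  }
  ct
}
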