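#' Concordance between two copy number call sets
#'
#' Method-comparison summary for paired qPCR and ddPCR estimates on the
#' same samples: squared Pearson correlation (the regression r-squared,
#' identical whichever variable is regressed on which), and
#' Bland-Altman-style difference statistics. The sign convention is fixed
#' as `difference = ddPCR - qPCR`, so a negative mean difference means
#' ddPCR reads lower.
#'
#' @param cn_qpcr,cn_ddpcr Numeric vectors of paired estimates; pairs with
#'   any `NA` are dropped.
#' @return List: `n`, `r_squared` (`NA` with a message when either vector
#'   has zero variance), `mean_difference`, `sd_difference`,
#'   `limits_of_agreement` (mean +/- 1.96 * SD).
#' @examples
#' concordance(c(2, 6, 10), c(2.1, 5.9, 10.2))
#' @export
concordance <- function(cn_qpcr, cn_ddpcr) {
  stopifnot(length(cn_qpcr) == length(cn_ddpcr))
  keep <- !is.na(cn_qpcr) & !is.na(cn_ddpcr)
  x <- cn_qpcr[keep]; y <- cn_ddpcr[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")

  r2 <- if (var(x) == 0 || var(y) == 0) {
    message("zero variance in one call set: r-squared undefined")
    NA_real_
  } else {
    stats::cor(x, y)^2
  }
  diffs <- y - x
  m <- mean(diffs); s <- sd(diffs)
  list(n = length(x), r_squared = r2, mean_difference = m,
       sd_difference = s,
       limits_of_agreement = c(lower = m - z95() * s, upper = m + z95() * s))
}
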