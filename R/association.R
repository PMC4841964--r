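check_counts <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("contingency counts must be non-negative integers")
  }
}

haldane <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) list(a = a + 0.5, b = b + 0.5, c = c + 0.5,
                                    d = d + 0.5, corrected = TRUE)
  else list(a = a, b = b, c = c, d = d, corrected = FALSE)
}

#' Odds ratio with Woolf confidence interval
#'
#' For a 2x2 table with cells `a` (case, risk allele), `b` (case, other
#' allele), `c` (control, risk allele), `d` (control, other allele):
#' `OR = (a*d) / (b*c)`, 95% CI
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero the Haldane-Anscombe correction (+0.5 to all cells) is applied
#' and flagged.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return List: `estimate`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' odds_ratio(205, 23, 46, 22)  # ~4.26 (2.19, 8.30)
#' @export
odds_ratio <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  h <- haldane(a, b, c, d)
  if (h$b * h$c == 0) stop("odds ratio undefined: b*c = 0 after correction")
  or <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  ci <- exp(log(or) + c(-1, 1) * z95() * se)
  list(estimate = or, ci_low = ci[1], ci_high = ci[2], corrected = h$corrected)
}

#' Risk ratio with Katz confidence interval
#'
#' `RR = (a/(a+b)) / (c/(c+d))` — the risk-allele carriage frequency among
#' case alleles relative to control alleles. 95% CI by the Katz log
#' method: `exp(ln RR +/- 1.96 * sqrt(b/(a*(a+b)) + d/(c*(c+d))))`. A zero
#' among `a`, `b`, `d` triggers the flagged Haldane-Anscombe correction;
#' `c = 0` is an error (the baseline frequency is undefined).
#'
#' @inheritParams odds_ratio
#' @return List: `estimate`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' risk_ratio(205, 23, 46, 22)  # ~1.33 (1.12, 1.58)
#' @export
risk_ratio <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  if (a + b == 0 || c + d == 0) stop("risk ratio needs both row totals > 0")
  if (c == 0) stop("risk ratio undefined: zero risk-allele count in controls")
  h <- haldane(a, b, c, d)
  rr <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  se <- sqrt(h$b / (h$a * (h$a + h$b)) + h$d / (h$c * (h$c + h$d)))
  ci <- exp(log(rr) + c(-1, 1) * z95() * se)
  list(estimate = rr, ci_low = ci[1], ci_high = ci[2], corrected = h$corrected)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Enumerates the hypergeometric distribution over all tables with the
#' observed margins and sums the point probabilities of every table no
#' more probable than the observed one (with relative tolerance `1 + 1e-7`
#' on the comparison, so exact probability ties are included despite
#' floating point). The probabilities are computed from log binomial
#' coefficients.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_two_tailed(57, 5, 30, 4)  # ~0.716
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  check_counts(a, b, c, d)
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  p <- exp(logp)
  p_obs <- p[support == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Build per-phenotype 2x2 allele tables from a count tabulation
#'
#' From an allele-count tabulation (the output of [tabulate_counts()] or
#' [table1_counts()]), assembles one case/control table per phenotype for
#' the risk allele at one locus. Cases are each phenotype's positive
#' column; the control counts come from `control` for every phenotype
#' except amyloidosis, which is compared to `amyloid_control` — only
#' histopathology-assessed individuals can be called amyloid-free, so the
#' general control group is not a valid baseline there.
#'
#' @param counts Tabulation list with an `allele_counts` element.
#' @param locus Locus of the risk allele (default `"CNV_16.1"`).
#' @param risk_allele Per-chromosome copy count of the risk allele
#'   (default 5).
#' @param control Control group column for the five general phenotypes
#'   (default `"C1"`).
#' @param amyloid_control Control group for amyloidosis (default `"C3"`).
#' @param phenotypes Phenotype columns to process.
#' @return Data frame: `phenotype, control, a, b, c, d` where `a`/`b` are
#'   the case risk/other allele counts and `c`/`d` the control ones.
#'   Phenotypes with no case alleles are omitted with a warning.
#' @export
build_tables_from_counts <- function(counts, locus = "CNV_16.1",
                                     risk_allele = 5, control = "C1",
                                     amyloid_control = "C3",
                                     phenotypes = c("spaid", "fever",
                                                    "arthritis", "vesicular",
                                                    "otitis", "amyloidosis")) {
  al <- counts$allele_counts
  al <- al[al$locus == locus, , drop = FALSE]
  if (nrow(al) == 0) stop("no allele counts for locus ", locus)
  risk_row <- al$level == risk_allele
  if (!any(risk_row)) stop("risk allele ", risk_allele, " not in tabulation")
  other_row <- !risk_row
  pull <- function(col) {
    if (!col %in% names(al)) {
      stop("control counts unavailable: no column '", col, "' in tabulation")
    }
    c(risk = sum(al[[col]][risk_row]), other = sum(al[[col]][other_row]))
  }

  rows <- lapply(phenotypes, function(p) {
    col <- paste0(p, "_pos")
    if (!col %in% names(al)) {
      warning("phenotype '", p, "' absent from tabulation; omitted")
      return(NULL)
    }
    cases <- pull(col)
    if (sum(cases) == 0) {
      warning("phenotype '", p, "' has no case alleles; omitted")
      return(NULL)
    }
    ctrl_grp <- if (p == "amyloidosis") amyloid_control else control
    ctrl <- pull(ctrl_grp)
    data.frame(phenotype = p, control = ctrl_grp,
               a = cases["risk"], b = cases["other"],
               c = ctrl["risk"], d = ctrl["other"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no phenotype produced a table")
  out
}

#' Risk, odds and Fisher statistics for a set of 2x2 tables
#'
#' Applies [risk_ratio()], [odds_ratio()] and
#' [fisher_exact_two_tailed()] to each row of a table set from
#' [build_tables_from_counts()].
#'
#' @param tables Data frame with columns `phenotype, control, a, b, c, d`.
#' @return Data frame adding `risk_ratio, rr_ci_low, rr_ci_high,
#'   odds_ratio, or_ci_low, or_ci_high, fisher_p, corrected`. Estimates
#'   are unrounded; round to 2 decimals (ratios/CIs) and 4 (p-values) for
#'   presentation.
#' @export
association_report <- function(tables) {
  stats <- lapply(seq_len(nrow(tables)), function(i) {
    t <- tables[i, ]
    rr <- risk_ratio(t$a, t$b, t$c, t$d)
    or <- odds_ratio(t$a, t$b, t$c, t$d)
    data.frame(risk_ratio = rr$estimate, rr_ci_low = rr$ci_low,
               rr_ci_high = rr$ci_high,
               odds_ratio = or$estimate, or_ci_low = or$ci_low,
               or_ci_high = or$ci_high,
               fisher_p = fisher_exact_two_tailed(t$a, t$b, t$c, t$d),
               corrected = rr$corrected || or$corrected)
  })
  cbind(tables, do.call(rbind, stats))
}

#' Packaged case/control genotype and allele counts
#'
#' Loads the packaged count table for the age-limited disease cohort and
#' its five sub-phenotypes at both loci (genotype rows per diploid class,
#' allele rows per allele). Two integrity checks run at load: (i) the
#' genotype columns sum to the documented cohort sizes (SPAID 155/34,
#' Fever 114/51, Arthritis 79/46, Vesicular 44/58, Otitis 34/71,
#' Amyloidosis 31/17) and (ii) every allele row equals the linear map
#' `2 * n(hom) + n(het)` of its genotype rows. The phenotype-negative
#' SPAID column doubles as control group C1 and the histopathology-negative
#' amyloidosis column as C3 (aliased columns).
#'
#' @param path Path to the counts CSV; defaults to the packaged file.
#' @return List shaped like [tabulate_counts()] output:
#'   `genotype_counts`, `allele_counts`, plus `cohort_sizes`.
#' @export
table1_counts <- function(path = system.file("extdata", "table1_counts.csv",
                                             package = "cnvdrop")) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  group_cols <- setdiff(names(raw), c("row_type", "locus", "level"))
  gt <- raw[raw$row_type == "genotype", c("locus", "level", group_cols)]
  al <- raw[raw$row_type == "allele", c("locus", "level", group_cols)]

  cohort_sizes <- c(spaid_pos = 155, spaid_neg = 34, fever_pos = 114,
                    fever_neg = 51, arthritis_pos = 79, arthritis_neg = 46,
                    vesicular_pos = 44, vesicular_neg = 58, otitis_pos = 34,
                    otitis_neg = 71, amyloidosis_pos = 31, amyloidosis_neg = 17)
  for (locus in unique(gt$locus)) {
    g <- gt[gt$locus == locus, ]
    sums <- colSums(g[, group_cols])
    if (!all(sums == cohort_sizes[group_cols])) {
      stop("count fixture corrupt: ", locus,
           " genotype columns do not sum to the cohort sizes")
    }
    # bi-allelic linear map: allele counts follow from genotype counts
    a <- al[al$locus == locus, ]
    lo <- min(a$level); hi <- max(a$level)
    classes <- sort(g$level)
    n_ll <- as.numeric(g[g$level == classes[1], group_cols])
    n_lh <- as.numeric(g[g$level == classes[2], group_cols])
    n_hh <- as.numeric(g[g$level == classes[3], group_cols])
    ok_lo <- all(as.numeric(a[a$level == lo, group_cols]) == 2 * n_ll + n_lh)
    ok_hi <- all(as.numeric(a[a$level == hi, group_cols]) == 2 * n_hh + n_lh)
    if (!ok_lo || !ok_hi) {
      stop("count fixture corrupt: ", locus,
           " allele rows do not match 2*hom + het of the genotype rows")
    }
  }
  # alias control-group columns onto the fixture's negative columns
  gt$C1 <- gt$spaid_neg; gt$C3 <- gt$amyloidosis_neg
  al$C1 <- al$spaid_neg; al$C3 <- al$amyloidosis_neg
  rownames(gt) <- rownames(al) <- NULL
  list(genotype_counts = gt, allele_counts = al, cohort_sizes = cohort_sizes)
}
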