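#' Bi-allelic locus model
#'
#' A locus model records the per-chromosome copy counts its alleles carry
#' and the diploid totals (genotype classes) they generate — all pairwise
#' sums of two alleles. The built-in models are CNV_14.3 with alleles of
#' 1 or 3 copies (classes 2, 4, 6) and CNV_16.1 with alleles of 1 or 5
#' copies (classes 2, 6, 10).
#'
#' @param locus Locus name.
#' @param allele_copy_values Integer vector of per-chromosome copy counts.
#' @return An object of class `locus_model`: list with `locus`,
#'   `allele_copy_values`, `genotype_classes` (sorted, unique) and
#'   `class_alleles` (named list mapping each total to its allele pair,
#'   larger allele first).
#' @examples
#' locus_model("CNV_16.1", c(1, 5))$genotype_classes  # 2 6 10
#' @export
locus_model <- function(locus, allele_copy_values) {
  av <- sort(unique(as.integer(allele_copy_values)))
  if (length(av) < 1) stop("need at least one allele copy value")
  pairs <- expand.grid(a = av, b = av)
  pairs <- pairs[pairs$a >= pairs$b, , drop = FALSE]
  totals <- pairs$a + pairs$b
  ord <- order(totals)
  pairs <- pairs[ord, ]; totals <- totals[ord]
  if (anyDuplicated(totals)) {
    stop("allele copy values produce ambiguous diploid totals")
  }
  structure(list(
    locus = locus,
    allele_copy_values = av,
    genotype_classes = totals,
    class_alleles = setNames(lapply(seq_along(totals), function(i)
      c(pairs$a[i], pairs$b[i])), totals)
  ), class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Locus model:", x$locus, "\n",
      " alleles (copies/chromosome):", paste(x$allele_copy_values, collapse = ", "), "\n",
      " genotype classes (diploid):", paste(x$genotype_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in locus models for the two Shar-Pei duplications
#'
#' @return Named list of [locus_model()] objects for CNV_14.3 (alleles
#'   1/3) and CNV_16.1 (alleles 1/5).
#' @export
builtin_locus_models <- function() {
  list("CNV_14.3" = locus_model("CNV_14.3", c(1, 3)),
       "CNV_16.1" = locus_model("CNV_16.1", c(1, 5)))
}

format_alleles <- function(pair) paste(sort(pair, decreasing = TRUE), collapse = "|")

parse_alleles <- function(s) {
  if (is.na(s) || s == "0" || !nzchar(s)) return(NULL)
  as.integer(strsplit(s, "|", fixed = TRUE)[[1]])
}

#' Call a discrete CNV genotype from a continuous estimate
#'
#' Assigns the nearest genotype class of the locus model, provided the
#' estimate is close enough to any class. Confidence is the normalised
#' Gaussian weight of the estimate against the class centres, using the
#' call's CI-derived standard deviation; when the runner-up class carries
#' more than `ambiguity_threshold` of the weight the call is flagged
#' `"ambiguous"`. An estimate at the exact midpoint between two classes is
#' deliberately a no-call: in a breed where no off-model totals were ever
#' observed, genuine ambiguity should surface rather than be forced.
#'
#' @param cn_estimate Continuous copy number estimate.
#' @param model A [locus_model()].
#' @param sd Standard deviation of the estimate; if `NULL` it is derived
#'   from `ci_low`/`ci_high` as `(ci_high - ci_low) / (2 * 1.96)`, and if
#'   unavailable the confidence defaults to 1 for the assigned class.
#' @param ci_low,ci_high Optional 95% interval bounds.
#' @param sample_id Identifier carried through.
#' @param max_distance No-call when the estimate is further than this from
#'   every class (default 1.5 copies — half the smallest inter-class gap
#'   at CNV_16.1 plus margin).
#' @param ambiguity_threshold Normalised runner-up weight above which the
#'   call is flagged ambiguous (default 0.2).
#' @return One-row data frame:
#'   `sample_id, locus, total_cn, alleles, confidence, flags`. No-calls
#'   have `NA` total and alleles and flag `"no_call"` (plus
#'   `"midpoint_tie"` when caused by an exact tie).
#' @examples
#' m <- builtin_locus_models()[["CNV_16.1"]]
#' call_genotype(5.9, m)   # total 6, alleles "5|1"
#' @export
call_genotype <- function(cn_estimate, model, sd = NULL,
                          ci_low = NA, ci_high = NA,
                          sample_id = "sample",
                          max_distance = 1.5, ambiguity_threshold = 0.2) {
  stopifnot(inherits(model, "locus_model"), cn_estimate >= 0)
  classes <- model$genotype_classes
  d <- abs(cn_estimate - classes)
  nearest <- which.min(d)

  no_call <- function(flags) data.frame(
    sample_id = sample_id, locus = model$locus, total_cn = NA_integer_,
    alleles = NA_character_, confidence = 0, flags = join_flags(flags),
    stringsAsFactors = FALSE)

  if (d[nearest] > max_distance) return(no_call("no_call"))
  # exact midpoint between two classes: refuse to force a side
  ties <- which(abs(d - d[nearest]) < 1e-9)
  if (length(ties) > 1) return(no_call(c("no_call", "midpoint_tie")))

  if (is.null(sd) && !is.na(ci_low) && !is.na(ci_high)) {
    sd <- (ci_high - ci_low) / (2 * z95())
  }
  flags <- character(0)
  if (!is.null(sd) && is.finite(sd) && sd > 1e-8) {
    lw <- -0.5 * ((cn_estimate - classes) / sd)^2
    w <- exp(lw - max(lw)); w <- w / sum(w)
    confidence <- w[nearest]
    if (sort(w, decreasing = TRUE)[2] > ambiguity_threshold) {
      flags <- c(flags, "ambiguous")
    }
  } else {
    confidence <- 1
  }

  data.frame(sample_id = sample_id, locus = model$locus,
             total_cn = classes[nearest],
             alleles = format_alleles(model$class_alleles[[nearest]]),
             confidence = confidence, flags = join_flags(flags),
             stringsAsFactors = FALSE)
}

#' Call genotypes for a table of copy number calls
#'
#' @param calls Data frame of calls (from [ddpcr_quantify()] or
#'   [qpcr_quantify()]) with `sample_id, locus, cn_estimate, ci_low,
#'   ci_high`.
#' @param models Named list of locus models (default the built-ins).
#' @param ... Passed to [call_genotype()].
#' @return Data frame, one genotype row per input call; calls with `NA`
#'   estimates or unknown loci become flagged no-calls.
#' @export
call_genotypes <- function(calls, models = builtin_locus_models(), ...) {
  do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    m <- models[[as.character(cl$locus)]]
    if (is.null(m) || is.na(cl$cn_estimate)) {
      return(data.frame(sample_id = cl$sample_id, locus = cl$locus,
                        total_cn = NA_integer_, alleles = NA_character_,
                        confidence = 0,
                        flags = join_flags(c("no_call",
                                             if (is.null(m)) "unknown_locus" else "missing_estimate")),
                        stringsAsFactors = FALSE))
    }
    call_genotype(cl$cn_estimate, m, ci_low = cl$ci_low, ci_high = cl$ci_high,
                  sample_id = cl$sample_id, ...)
  }))
}

#' Discover copy number classes by one-dimensional clustering
#'
#' Clusters continuous copy number estimates with k-means (deterministic
#' quantile-based initial centres), choosing the number of classes by the
#' mean silhouette width over `k_range`. Centres within `integer_snap` of
#' an integer are rounded; otherwise the raw centres are reported with a
#' warning. A degenerate input (all estimates identical) yields a
#' single-class model with a warning.
#'
#' @param cn_estimates Numeric vector of estimates (at least 30 for a
#'   meaningful clustering).
#' @param locus Locus label carried through.
#' @param k_range Candidate class counts (default 2:5).
#' @param integer_snap Maximum distance from an integer for rounding a
#'   centre (default 0.35).
#' @return List of class `cnv_clusters`: `locus`, `k`, `centres` (raw,
#'   sorted), `genotype_classes` (snapped when possible), `silhouette`
#'   (mean width of the chosen clustering), `sizes`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(20, 2, .1), rnorm(60, 6, .1), rnorm(120, 10, .1))
#' discover_clusters(x)$genotype_classes  # 2 6 10
#' @export
discover_clusters <- function(cn_estimates, locus = "locus", k_range = 2:5,
                              integer_snap = 0.35) {
  x <- cn_estimates[!is.na(cn_estimates)]
  if (length(x) == 0) stop("no estimates")
  if (diff(range(x)) < 1e-9) {
    warning("degenerate input: all estimates identical; single-class model")
    cls <- if (abs(x[1] - round(x[1])) <= integer_snap) round(x[1]) else x[1]
    return(structure(list(locus = locus, k = 1L, centres = x[1],
                          genotype_classes = cls, silhouette = NA_real_,
                          sizes = length(x)), class = "cnv_clusters"))
  }
  if (length(x) < 30) stop("need at least 30 calls to discover clusters")

  dx <- dist(x)
  best <- NULL
  for (k in k_range) {
    # deterministic initial centres, evenly spaced over the data range so
    # that small classes at the extremes seed their own centre
    init <- seq(min(x), max(x), length.out = k)
    km <- tryCatch(kmeans(x, centers = matrix(init, ncol = 1)),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2) next
    sil <- mean(cluster::silhouette(km$cluster, dx)[, "sil_width"])
    if (is.null(best) || sil > best$sil) {
      best <- list(km = km, sil = sil, k = k)
    }
  }
  if (is.null(best)) stop("clustering failed for every k in k_range")

  ord <- order(best$km$centers[, 1])
  centres <- best$km$centers[ord, 1]
  sizes <- best$km$size[ord]
  snapped <- round(centres)
  if (all(abs(centres - snapped) <= integer_snap)) {
    classes <- as.integer(snapped)
  } else {
    warning("cluster centres not near integers; reporting raw centres")
    classes <- centres
  }
  structure(list(locus = locus, k = best$k, centres = unname(centres),
                 genotype_classes = unname(classes), silhouette = best$sil,
                 sizes = unname(sizes)), class = "cnv_clusters")
}

#' @export
print.cnv_clusters <- function(x, ...) {
  cat("CNV classes at", x$locus, "- k =", x$k,
      "(mean silhouette ", round(x$silhouette, 3), ")\n",
      " centres:", paste(round(x$centres, 3), collapse = ", "), "\n",
      " classes:", paste(x$genotype_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Genotype and allele counts per phenotype group
#'
#' Builds, for each locus, the per-phenotype positive/negative genotype
#' class counts and the allele counts (counted directly from the called
#' allele pairs, so that for a bi-allelic locus
#' `count(a) = 2 * n(a/a) + n(a/b)` holds by construction). Also tabulates
#' the three control groups: C1 (phenotype-free and older than
#' `age_limit_months`), C2 (phenotype-free at any age) and C3
#' (histopathology-confirmed amyloidosis-negative, i.e. `amyloidosis == 0`).
#'
#' @param genotypes Data frame from [call_genotypes()] (`sample_id, locus,
#'   total_cn, alleles`); no-calls are excluded.
#' @param phenotypes Data frame with `sample_id`, binary columns
#'   `spaid, fever, arthritis, vesicular, otitis, amyloidosis` (`NA`
#'   allowed; amyloidosis is non-missing only when histopathology was
#'   performed) and `age_months`.
#' @param models Named list of locus models (default built-ins).
#' @param age_limit_months Age floor for the C1 control group (default 60).
#' @return List with elements `genotype_counts` and `allele_counts` (wide
#'   data frames: `locus, level`, then one column per group
#'   `<phenotype>_pos/_neg, C1, C2, C3`) and `excluded` (sample ids with
#'   no phenotype row, dropped with a warning).
#' @export
tabulate_counts <- function(genotypes, phenotypes,
                            models = builtin_locus_models(),
                            age_limit_months = 60) {
  pheno_cols <- c("spaid", "fever", "arthritis", "vesicular", "otitis",
                  "amyloidosis")
  stopifnot(all(c("sample_id", pheno_cols) %in% names(phenotypes)))

  genotypes <- genotypes[!is.na(genotypes$total_cn), , drop = FALSE]
  unknown <- setdiff(genotypes$sample_id, phenotypes$sample_id)
  if (length(unknown) > 0) {
    warning(length(unknown), " genotyped sample(s) missing from the phenotype table; excluded: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    genotypes <- genotypes[!genotypes$sample_id %in% unknown, , drop = FALSE]
  }

  ph <- phenotypes[match(genotypes$sample_id, phenotypes$sample_id), ]
  groups <- list()
  for (p in pheno_cols) {
    groups[[paste0(p, "_pos")]] <- !is.na(ph[[p]]) & ph[[p]] == 1
    groups[[paste0(p, "_neg")]] <- !is.na(ph[[p]]) & ph[[p]] == 0
  }
  age <- if ("age_months" %in% names(ph)) ph$age_months else rep(NA, nrow(ph))
  spaid_free <- !is.na(ph$spaid) & ph$spaid == 0
  groups[["C1"]] <- spaid_free & !is.na(age) & age > age_limit_months
  groups[["C2"]] <- spaid_free
  groups[["C3"]] <- !is.na(ph$amyloidosis) & ph$amyloidosis == 0

  count_block <- function(locus, levels, value_of) {
    in_locus <- genotypes$locus == locus
    cols <- lapply(groups, function(g) {
      vals <- value_of(genotypes[in_locus & g, , drop = FALSE])
      vapply(levels, function(l) sum(vals == l), 0L)
    })
    cbind(data.frame(locus = locus, level = levels, stringsAsFactors = FALSE),
          as.data.frame(cols, check.names = FALSE))
  }

  gt <- list(); al <- list()
  for (locus in names(models)) {
    m <- models[[locus]]
    gt[[locus]] <- count_block(locus, m$genotype_classes,
                               function(g) g$total_cn)
    al[[locus]] <- count_block(locus, m$allele_copy_values, function(g)
      unlist(lapply(g$alleles, parse_alleles)))
  }
  list(genotype_counts = do.call(rbind, c(gt, list(make.row.names = FALSE))),
       allele_counts = do.call(rbind, c(al, list(make.row.names = FALSE))),
       excluded = unknown)
}
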