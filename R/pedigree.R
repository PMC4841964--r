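#' Read a PED-like pedigree file with CNV genotype columns
#'
#' Whitespace-separated, one row per individual:
#' `family_id  sample_id  sire_id  dam_id  sex  geno_CNV_14.3  geno_CNV_16.1`
#' where `0` marks a missing parent or genotype and genotype strings are
#' unordered allele pairs such as `5|1`. Extra genotype columns are kept
#' under the names given in `loci`.
#'
#' @param path File path.
#' @param loci Locus names for the genotype columns, in order (default the
#'   two built-in loci).
#' @return A `pedigree` data frame (see [as_pedigree()]).
#' @export
read_ped <- function(path, loci = c("CNV_14.3", "CNV_16.1")) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  base_cols <- c("family_id", "sample_id", "sire_id", "dam_id", "sex")
  if (ncol(ped) < length(base_cols) + length(loci)) {
    stop("PED file needs ", length(base_cols) + length(loci), " columns")
  }
  names(ped)[seq_along(base_cols)] <- base_cols
  names(ped)[length(base_cols) + seq_along(loci)] <- paste0("geno_", loci)
  as_pedigree(ped)
}

#' Validate a pedigree table
#'
#' Checks that parent ids resolve within the pedigree or are founder
#' markers (`"0"`), and that the parent-offspring graph is acyclic (no
#' individual is its own ancestor), by iterated founder stripping.
#'
#' @param ped Data frame with at least `sample_id, sire_id, dam_id`;
#'   genotype columns named `geno_<locus>` hold allele-pair strings
#'   (`"0"` = missing).
#' @return The validated data frame with class `pedigree` prepended.
#' @export
as_pedigree <- function(ped) {
  stopifnot(all(c("sample_id", "sire_id", "dam_id") %in% names(ped)))
  if (anyDuplicated(ped$sample_id)) stop("duplicate sample ids in pedigree")
  for (col in c("sire_id", "dam_id")) {
    unresolved <- !(ped[[col]] %in% c("0", ped$sample_id))
    if (any(unresolved)) {
      stop("unresolved ", col, " for: ",
           paste(ped$sample_id[unresolved], collapse = ", "))
    }
  }
  # founder stripping: if the graph is acyclic, repeatedly removing
  # individuals whose parents are all removed empties the table
  remaining <- ped$sample_id
  repeat {
    removable <- vapply(remaining, function(id) {
      i <- match(id, ped$sample_id)
      all(!c(ped$sire_id[i], ped$dam_id[i]) %in% remaining)
    }, TRUE)
    if (!any(removable)) break
    remaining <- remaining[!removable]
  }
  if (length(remaining) > 0) {
    stop("pedigree contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}

ped_geno <- function(ped, locus, id) {
  col <- paste0("geno_", locus)
  if (!col %in% names(ped)) stop("pedigree has no genotypes for ", locus)
  if (id == "0") return(NULL)
  parse_alleles(ped[[col]][match(id, ped$sample_id)])
}

# can parents with allele pairs p1, p2 produce offspring pair o?
mendel_consistent <- function(o, p1, p2) {
  (o[1] %in% p1 && o[2] %in% p2) || (o[2] %in% p1 && o[1] %in% p2)
}

#' Check Mendelian transmission of CNV alleles through a pedigree
#'
#' For every offspring with both parents genotyped at `locus`, verifies
#' that some assignment of one allele from each parent reproduces the
#' offspring's pair. Offspring with exactly one genotyped parent are
#' checked against that parent only (at least one offspring allele must be
#' carried by the parent) and reported separately; trios where the
#' offspring or both parents lack genotypes are skipped and counted.
#'
#' @param ped A [as_pedigree()] data frame with `geno_<locus>` columns.
#' @param locus Locus name.
#' @return List: `violations` (data frame of offspring/parent ids and
#'   genotypes from full trios), `half_violations` (same, single-parent
#'   checks), `n_trios`, `n_half`, `n_skipped`.
#' @examples
#' ped <- data.frame(family_id = "f", sample_id = c("s", "d", "o"),
#'                   sire_id = c("0", "0", "s"), dam_id = c("0", "0", "d"),
#'                   sex = c("1", "2", "1"),
#'                   geno_CNV_16.1 = c("5|5", "5|5", "5|1"))
#' check_mendelian(as_pedigree(ped), "CNV_16.1")$violations  # impossible allele 1
#' @export
check_mendelian <- function(ped, locus) {
  stopifnot(inherits(ped, "pedigree"))
  viol <- list(); half_viol <- list()
  n_trios <- 0L; n_half <- 0L; n_skipped <- 0L

  for (i in seq_len(nrow(ped))) {
    sire <- ped$sire_id[i]; dam <- ped$dam_id[i]
    if (sire == "0" && dam == "0") next   # founder
    o <- ped_geno(ped, locus, ped$sample_id[i])
    gs <- ped_geno(ped, locus, sire)
    gd <- ped_geno(ped, locus, dam)
    if (is.null(o) || (is.null(gs) && is.null(gd))) {
      n_skipped <- n_skipped + 1L
      next
    }
    rec <- data.frame(offspring = ped$sample_id[i], sire = sire, dam = dam,
                      offspring_geno = format_alleles(o),
                      sire_geno = if (is.null(gs)) NA else format_alleles(gs),
                      dam_geno = if (is.null(gd)) NA else format_alleles(gd),
                      stringsAsFactors = FALSE)
    if (!is.null(gs) && !is.null(gd)) {
      n_trios <- n_trios + 1L
      if (!mendel_consistent(o, gs, gd)) viol[[length(viol) + 1L]] <- rec
    } else {
      n_half <- n_half + 1L
      parent <- if (is.null(gs)) gd else gs
      if (!any(o %in% parent)) half_viol[[length(half_viol) + 1L]] <- rec
    }
  }
  empty <- data.frame(offspring = character(0), sire = character(0),
                      dam = character(0), offspring_geno = character(0),
                      sire_geno = character(0), dam_geno = character(0),
                      stringsAsFactors = FALSE)
  list(violations = if (length(viol)) do.call(rbind, viol) else empty,
       half_violations = if (length(half_viol)) do.call(rbind, half_viol) else empty,
       n_trios = n_trios, n_half = n_half, n_skipped = n_skipped)
}

# all two-locus haplotype phasings of two bi-allelic loci: each is a pair
# of (locus1 allele, locus2 allele) chromosomes
candidate_phasings <- function(av1, av2) {
  list(rbind(c(av1[1], av2[1]), c(av1[2], av2[2])),
       rbind(c(av1[1], av2[2]), c(av1[2], av2[1])))
}

# is an individual's two-locus genotype expressible as two haplotypes from
# the given set? haps is a 2-column matrix of (allele_l1, allele_l2) rows
pair_consistent <- function(g1, g2, haps) {
  for (i in seq_len(nrow(haps))) for (j in seq_len(nrow(haps))) {
    h <- c(haps[i, 1], haps[j, 1]); k <- c(haps[i, 2], haps[j, 2])
    if (setequal_count(h, g1) && setequal_count(k, g2)) return(TRUE)
  }
  FALSE
}

setequal_count <- function(a, b) identical(sort(a), sort(b))

#' Two-locus genotype-pair frequencies and recombinant carriers
#'
#' Tabulates the observed (CNV_14.3 total, CNV_16.1 total) pairs and flags
#' individuals whose two-locus genotype cannot be assembled from the two
#' canonical haplotypes. By default the phase is inferred from the data:
#' of the two possible phasings of two bi-allelic loci, the one explaining
#' the larger number of individuals is taken (co-segregation logic). The
#' expected canonical phase couples the 14.3 1-copy allele with the 16.1
#' 5-copy allele and the 3-copy with the 1-copy, making (2,10), (4,6) and
#' (6,2) the consistent totals; carriers of rare recombinant haplotypes,
#' e.g. the pair (4,2), are flagged.
#'
#' @param genotypes Data frame with `sample_id, locus, alleles` for both
#'   loci (long format, as from [call_genotypes()]), or a `pedigree` with
#'   `geno_<locus>` columns.
#' @param loci The two locus names (default the built-ins).
#' @param models Named list of locus models.
#' @param haplotypes Optional 2x2 matrix of haplotypes (rows =
#'   chromosomes, columns = loci) to use instead of inferring the phase;
#'   `cbind(c(1, 3), c(5, 1))` is the canonical configuration.
#' @return List: `pair_freq` (data frame `cn_14_3, cn_16_1, n, pct`),
#'   `recombinants` (flagged sample ids), `haplotypes` (the matrix used),
#'   `n` (individuals genotyped at both loci).
#' @export
detect_two_locus_pairs <- function(genotypes, loci = c("CNV_14.3", "CNV_16.1"),
                                   models = builtin_locus_models(),
                                   haplotypes = NULL) {
  if (inherits(genotypes, "pedigree")) {
    ids <- genotypes$sample_id
    g1 <- lapply(genotypes[[paste0("geno_", loci[1])]], parse_alleles)
    g2 <- lapply(genotypes[[paste0("geno_", loci[2])]], parse_alleles)
  } else {
    ids <- unique(genotypes$sample_id)
    pick <- function(locus) lapply(ids, function(id) {
      row <- genotypes$locus == locus & genotypes$sample_id == id
      if (!any(row)) NULL else parse_alleles(genotypes$alleles[which(row)[1]])
    })
    g1 <- pick(loci[1]); g2 <- pick(loci[2])
  }
  both <- !vapply(g1, is.null, TRUE) & !vapply(g2, is.null, TRUE)
  ids <- ids[both]; g1 <- g1[both]; g2 <- g2[both]
  if (length(ids) == 0) stop("no individuals genotyped at both loci")

  if (is.null(haplotypes)) {
    cands <- candidate_phasings(models[[loci[1]]]$allele_copy_values,
                                models[[loci[2]]]$allele_copy_values)
    explained <- vapply(cands, function(h)
      sum(mapply(pair_consistent, g1, g2, MoreArgs = list(haps = h))), 0)
    haplotypes <- cands[[which.max(explained)]]
  }

  consistent <- mapply(pair_consistent, g1, g2,
                       MoreArgs = list(haps = haplotypes))
  t1 <- vapply(g1, sum, 0); t2 <- vapply(g2, sum, 0)
  tab <- as.data.frame(table(cn_14_3 = t1, cn_16_1 = t2),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  pair_freq <- data.frame(cn_14_3 = as.integer(tab$cn_14_3),
                          cn_16_1 = as.integer(tab$cn_16_1),
                          n = tab$Freq, pct = 100 * tab$Freq / length(ids))
  pair_freq <- pair_freq[order(-pair_freq$n), ]
  rownames(pair_freq) <- NULL
  list(pair_freq = pair_freq, recombinants = ids[!consistent],
       haplotypes = haplotypes, n = length(ids))
}
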