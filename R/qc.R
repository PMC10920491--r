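#' Marker-level QC filter
#'
#' A marker is removed when its heterozygote fraction (among non-missing
#' calls) exceeds `hetMax`, its missing fraction (over all genotypes)
#' exceeds `missingMax`, or fewer than `minMinorHom` genotypes are
#' homozygous for the minor allele. Boundary values are retained: a
#' minor-homozygote count of exactly `minMinorHom` passes.
#'
#' @param geno [GenotypeData-class].
#' @param hetMax maximum tolerated heterozygote fraction (default 0.10).
#' @param missingMax maximum tolerated missing fraction (default 0.10).
#' @param minMinorHom minimum minor-allele homozygote count (default 15).
#' @param report optional [QcReport-class] to append to.
#' @return list: `geno` (filtered), `report`.
#' @export
filterMarkers <- function(geno, hetMax = 0.10, missingMax = 0.10,
                          minMinorHom = 15, report = NULL) {
  d <- dosages(geno)
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  nonmiss <- colSums(!is.na(d))
  het <- colSums(d == 1L, na.rm = TRUE) / pmax(nonmiss, 1L)
  miss <- colMeans(is.na(d))
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  minorHom <- pmin(n0, n2)
  keep <- het <= hetMax & miss <= missingMax & minorHom >= minMinorHom
  report <- qcAppend(report, "filter_markers", "marker",
                     sum(!keep), sum(keep),
                     detail = data.frame(marker = markerIds(geno),
                                         het = het, missing = miss,
                                         minor_hom = minorHom,
                                         removed = !keep))
  list(geno = geno[, keep], report = report)
}

#' Genotype-level QC filter
#'
#' Removes genotypes whose heterozygous fraction among non-missing calls
#' exceeds `hetMax`. Missingness alone never removes a genotype.
#'
#' @inheritParams filterMarkers
#' @export
filterGenotypes <- function(geno, hetMax = 0.10, report = NULL) {
  d <- dosages(geno)
  het <- rowSums(d == 1L, na.rm = TRUE) / pmax(rowSums(!is.na(d)), 1L)
  keep <- het <= hetMax
  report <- qcAppend(report, "filter_genotypes", "genotype",
                     sum(!keep), sum(keep),
                     detail = data.frame(genotype = genotypeIds(geno),
                                         het = het, removed = !keep))
  list(geno = geno[keep, ], report = report)
}

#' Flag duplicated genotypes by pairwise dosage correlation
#'
#' Computes all pairwise Pearson correlations between genotype dosage
#' vectors (pairwise-complete) and flags pairs that look like accidental
#' duplicates: correlation above an absolute cutoff (`rAbs`) or above a
#' distribution-based cutoff, mean + `k` standard deviations of the
#' within-population pair correlations. The removal policy drops the
#' member of a flagged pair with more missing data (ties: the
#' lexicographically later id).
#'
#' @param geno [GenotypeData-class] with >= 2 genotypes.
#' @param rAbs absolute correlation cutoff (default 0.99).
#' @param k multiplier for the distribution-based cutoff (default 6).
#' @param apply drop flagged genotypes from the returned matrix?
#' @param report optional [QcReport-class].
#' @return list: `geno`, `pairs` (`data.frame`: g1, g2, r, drop), `report`.
#' @export
detectDuplicates <- function(geno, rAbs = 0.99, k = 6, apply = TRUE,
                             report = NULL) {
  d <- dosages(geno)
  if (nrow(d) < 2) stop("need >= 2 genotypes")
  sds <- apply(d, 1, stats::sd, na.rm = TRUE)
  const <- which(is.na(sds) | sds == 0)
  use <- setdiff(seq_len(nrow(d)), const)
  cc <- suppressWarnings(stats::cor(t(d[use, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  pop <- as.character(populations(geno))[use]
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  r <- cc[ut]
  same <- !is.na(pop[ut[, 1]]) & !is.na(pop[ut[, 2]]) &
          pop[ut[, 1]] == pop[ut[, 2]]
  cutDist <- if (any(same)) mean(r[same], na.rm = TRUE) +
                            k * stats::sd(r[same], na.rm = TRUE) else Inf
  flag <- !is.na(r) & (r >= rAbs | r > cutDist)
  ids <- rownames(d)[use]
  pairs <- data.frame(g1 = ids[ut[flag, 1]], g2 = ids[ut[flag, 2]],
                      r = r[flag])
  miss <- rowSums(is.na(d))
  pairs$drop <- vapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$g1[i]; g2 <- pairs$g2[i]
    if (miss[[g1]] > miss[[g2]]) g1
    else if (miss[[g2]] > miss[[g1]]) g2
    else max(g1, g2)  # tie: lexicographically later id
  }, character(1))
  dropIds <- unique(pairs$drop)
  out <- if (apply && length(dropIds))
    geno[setdiff(rownames(d), dropIds), ] else geno
  report <- qcAppend(report, "detect_duplicates", "genotype",
                     if (apply) length(dropIds) else 0L,
                     nGenotypes(out),
                     detail = list(pairs = pairs,
                                   constant_genotypes = rownames(d)[const],
                                   distribution_cutoff = cutDist))
  list(geno = out, pairs = pairs, report = report)
}

#' Flag genotypes carrying non-parental alleles
#'
#' For each nested population, markers at which the recurrent parent and
#' that population's donor carry the same homozygous dosage must be
#' monomorphic in the offspring. The fraction of such markers where an
#' offspring call disagrees with the shared parental dosage measures
#' contamination; genotypes above `threshold` are flagged.
#'
#' @param geno [GenotypeData-class] whose metadata names the recurrent
#'   parent (`recurrent`) and per-population donors (`donors`), or pass
#'   them explicitly.
#' @param recurrent,donors override metadata: recurrent genotype id and a
#'   named vector population -> donor genotype id.
#' @param threshold disagreement fraction above which a genotype is
#'   flagged (default 0.05).
#' @param apply drop flagged genotypes?
#' @param report optional [QcReport-class].
#' @return list: `geno`, `flagged` (`data.frame`: genotype, population,
#'   disagreement), `report`.
#' @export
nonparentalAlleleCheck <- function(geno, recurrent = NULL, donors = NULL,
                                   threshold = 0.05, apply = TRUE,
                                   report = NULL) {
  recurrent <- recurrent %||% geno@metadata$recurrent
  donors <- donors %||% geno@metadata$donors
  if (is.null(recurrent) || is.null(donors))
    stop("recurrent parent and donor map required")
  d <- dosages(geno)
  pop <- populations(geno)
  flagged <- list()
  for (p in levels(geno@population)) {
    donor <- donors[[p]]
    if (is.null(donor) || !(donor %in% rownames(d)) ||
        !(recurrent %in% rownames(d))) {
      warning("population ", p, " skipped: parent not genotyped")
      next
    }
    rp <- d[recurrent, ]; dp <- d[donor, ]
    mono <- !is.na(rp) & !is.na(dp) & rp == dp & rp != 1L
    if (!any(mono)) next
    kids <- which(!is.na(pop) & pop == p)
    sub <- d[kids, mono, drop = FALSE]
    disag <- rowSums(sub != rep(rp[mono], each = length(kids)), na.rm = TRUE) /
             pmax(rowSums(!is.na(sub)), 1L)
    hit <- disag > threshold
    if (any(hit))
      flagged[[p]] <- data.frame(genotype = rownames(d)[kids][hit],
                                 population = p,
                                 disagreement = disag[hit])
  }
  flagged <- if (length(flagged)) do.call(rbind, c(flagged, make.row.names = FALSE))
             else data.frame(genotype = character(), population = character(),
                             disagreement = numeric())
  out <- if (apply && nrow(flagged))
    geno[setdiff(genotypeIds(geno), flagged$genotype), ] else geno
  report <- qcAppend(report, "nonparental_check", "genotype",
                     if (apply) nrow(flagged) else 0L, nGenotypes(out),
                     detail = flagged)
  list(geno = out, flagged = flagged, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
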