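#' Estimate the LD-decay window
#'
#' Pools within-chromosome pairwise dosage R-squared across chromosomes,
#' bins pairs by physical distance (1 Mb bins), fits a monotone
#' non-increasing curve to the bin means (isotonic regression), and
#' returns the smallest distance at which the fitted curve falls to the
#' critical R-squared, rounded up to a whole Mb. Used as the QTL
#' peak-suppression window.
#'
#' @param geno [GenotypeData-class] with mapped markers.
#' @param criticalR2 decay target (default 0.2).
#' @param maxDistMb only pairs closer than this enter the fit
#'   (default 200).
#' @param binMb bin width in Mb (default 1).
#' @return list: `windowMb`, `profile` (`data.frame`: mid_mb, mean_r2,
#'   fitted, n_pairs).
#' @export
ldDecayWindow <- function(geno, criticalR2 = 0.2, maxDistMb = 200, binMb = 1) {
  map <- markerMap(geno)
  d <- dosages(geno)
  dist <- r2 <- list()
  for (ch in unique(stats::na.omit(map$chrom))) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(d[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    ut <- which(upper.tri(cc), arr.ind = TRUE)
    dd <- abs(map$bp[idx[ut[, 1]]] - map$bp[idx[ut[, 2]]]) / 1e6
    keep <- dd <= maxDistMb & !is.na(cc[ut])
    dist[[ch]] <- dd[keep]; r2[[ch]] <- cc[ut][keep]
  }
  dist <- unlist(dist); r2 <- unlist(r2)
  if (!length(dist)) stop("no within-chromosome marker pairs")
  bin <- floor(dist / binMb)
  prof <- stats::aggregate(r2, list(bin = bin), mean)
  cnt <- as.vector(table(bin))
  prof <- data.frame(mid_mb = (prof$bin + 0.5) * binMb,
                     mean_r2 = prof$x, n_pairs = cnt)
  iso <- stats::isoreg(prof$mid_mb, -prof$mean_r2)
  prof$fitted <- -iso$yf
  hit <- which(prof$fitted <= criticalR2)
  if (!length(hit))
    stop("fitted LD never decays to R^2 = ", criticalR2,
         " within ", maxDistMb, " Mb; raise the critical value or extend maxDistMb")
  list(windowMb = ceiling(prof$mid_mb[hit[1]]), profile = prof)
}

#' Greedy peak calling within an LD window
#'
#' Takes the highest-scoring marker at or above the threshold, suppresses
#' every marker within `windowMb` on the same chromosome, and repeats
#' until no significant markers remain. Ties are broken toward the
#' smaller bp position. The result depends only on scores and positions,
#' not input order.
#'
#' @param scan [GwasScan-class].
#' @param threshold significance threshold on the -log10(P) scale
#'   (default: the scan's stored threshold).
#' @param windowMb suppression window in Mb (the LD-decay window).
#' @return `data.frame`: marker, chrom, bp, score, effect.
#' @export
callPeaks <- function(scan, threshold = NULL, windowMb = 18) {
  threshold <- threshold %||% scanMeta(scan)$threshold
  if (is.null(threshold)) stop("no threshold available")
  tab <- scanTable(scan)
  tab <- tab[!is.na(tab$score) & tab$score >= threshold & !is.na(tab$chrom), ]
  peaks <- list()
  while (nrow(tab)) {
    ord <- order(-tab$score, tab$bp)
    top <- tab[ord[1], ]
    peaks[[length(peaks) + 1L]] <- top[c("marker", "chrom", "bp", "score", "effect")]
    tab <- tab[!(tab$chrom == top$chrom &
                 abs(tab$bp - top$bp) <= windowMb * 1e6), ]
  }
  if (!length(peaks))
    return(data.frame(marker = character(), chrom = character(),
                      bp = numeric(), score = numeric(), effect = numeric()))
  out <- do.call(rbind, peaks)
  rownames(out) <- NULL
  out
}

#' Support interval around a called peak
#'
#' Extends left and right from the peak through consecutive significant
#' markers, confined to the peak's suppression window, and returns the bp
#' of the first and last such flanking markers. An isolated significant
#' peak gets a zero-width interval at its own position.
#'
#' @param scan [GwasScan-class].
#' @param peakMarker peak marker id (must be significant).
#' @param threshold -log10(P) significance threshold.
#' @param windowMb suppression window in Mb.
#' @return numeric length-2: interval start and end bp.
#' @export
qtlInterval <- function(scan, peakMarker, threshold = NULL, windowMb = 18) {
  threshold <- threshold %||% scanMeta(scan)$threshold
  stopifnot(length(peakMarker) == 1, !is.na(peakMarker))
  tab <- scanTable(scan)
  pk <- tab[tab$marker == peakMarker, ]
  if (!nrow(pk)) stop("peak marker not in scan")
  if (is.na(pk$score) || pk$score < threshold) stop("peak is not significant")
  ch <- tab[tab$chrom == pk$chrom & !is.na(tab$score) &
            abs(tab$bp - pk$bp) <= windowMb * 1e6, ]
  ch <- ch[order(ch$bp), ]
  i <- which(ch$marker == peakMarker)
  sig <- ch$score >= threshold
  lo <- i; while (lo > 1 && sig[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < nrow(ch) && sig[hi + 1]) hi <- hi + 1
  c(start = ch$bp[lo], end = ch$bp[hi])
}

#' Merge per-trial peaks into named QTLs
#'
#' Peaks from different trials describe one QTL when they share the
#' trait, the chromosome and the effect direction and lie within the
#' merge window of each other (default 3x the LD window, accommodating
#' cross-trial peak shifts). Merging is single-linkage along the
#' chromosome; conflicting effect signs at the same position stay
#' separate and are flagged. Names follow the
#' `Q{trait}.{lab}-{chrom}.{index}` convention, indexed by chromosome
#' then bp.
#'
#' @param peakSets named list (name = trial id) of peak tables from
#'   [callPeaks()], each with an added `trait` column (or supply
#'   uniform `trait`).
#' @param windowMb LD window in Mb.
#' @param mergeMultiplier merge window = `windowMb * mergeMultiplier`
#'   (default 3).
#' @param trait trait label applied to peak tables lacking one.
#' @param lab laboratory token used in QTL names (default `"lab"`).
#' @return `data.frame`: qtl (name), trait, chrom, peak bp (highest-score
#'   trial), score, effect, trials (semicolon-joined), n_trials,
#'   sign_conflict.
#' @export
mergeQtls <- function(peakSets, windowMb = 18, mergeMultiplier = 3,
                      trait = NULL, lab = "lab") {
  rows <- list()
  for (tr in names(peakSets)) {
    ps <- peakSets[[tr]]
    if (!nrow(ps)) next
    if (!"trait" %in% names(ps)) {
      if (is.null(trait)) stop("peak set ", tr, " lacks a trait column")
      ps$trait <- trait
    }
    ps$trial <- tr
    rows[[tr]] <- ps
  }
  if (!length(rows))
    return(data.frame(qtl = character(), trait = character(),
                      chrom = character(), bp = numeric(), score = numeric(),
                      effect = numeric(), trials = character(),
                      n_trials = integer(), sign_conflict = logical()))
  all <- do.call(rbind, c(rows, make.row.names = FALSE))
  all$sign <- sign(all$effect)
  win <- windowMb * mergeMultiplier * 1e6
  out <- list()
  for (key in unique(paste(all$trait, all$chrom, all$sign))) {
    sub <- all[paste(all$trait, all$chrom, all$sign) == key, ]
    sub <- sub[order(sub$bp), ]
    grp <- cumsum(c(1, diff(sub$bp) > win))
    for (g in unique(grp)) {
      m <- sub[grp == g, ]
      best <- m[which.max(m$score), ]
      out[[length(out) + 1L]] <- data.frame(
        trait = best$trait, chrom = best$chrom, bp = best$bp,
        marker = best$marker, score = best$score, effect = best$effect,
        trials = paste(sort(unique(m$trial)), collapse = ";"),
        n_trials = length(unique(m$trial)))
    }
  }
  res <- do.call(rbind, out)
  ## flag opposite-sign groups sharing a position
  res$sign_conflict <- FALSE
  for (i in seq_len(nrow(res))) {
    same <- res$trait == res$trait[i] & res$chrom == res$chrom[i] &
            abs(res$bp - res$bp[i]) <= win & sign(res$effect) != sign(res$effect[i])
    if (any(same)) res$sign_conflict[i] <- TRUE
  }
  res <- res[order(res$trait, res$chrom, res$bp), ]
  idx <- stats::ave(seq_len(nrow(res)), res$trait, res$chrom, FUN = seq_along)
  res$qtl <- sprintf("Q%s.%s-%s.%d", res$trait, lab, res$chrom, idx)
  rownames(res) <- NULL
  res[c("qtl", "trait", "chrom", "bp", "marker", "score", "effect",
        "trials", "n_trials", "sign_conflict")]
}

#' Multi-QTL variance partitioning
#'
#' Fits the joint mixed model with every peak marker as a fixed additive
#' covariate alongside the population factor and the polygenic kinship
#' term (variance components from the null model, P3D), and reports each
#' QTL's phenotypic variance explained as the partial R-squared from
#' dropping that peak from the joint model, in percent. Collinear peaks
#' are pooled with a warning (reported once under the first member).
#'
#' @param y named phenotype vector.
#' @param geno [GenotypeData-class] (imputed).
#' @param peakMarkers character vector of peak marker ids.
#' @param Q population factor (default from `geno`).
#' @param K kinship (default [computeKinship()]).
#' @return `data.frame`: marker, var_explained_pct, collinear_with.
#' @export
multiQtlVariance <- function(y, geno, peakMarkers, Q = NULL, K = NULL) {
  ids <- intersect(names(y), genotypeIds(geno))
  ids <- ids[!is.na(y[ids])]
  geno <- geno[ids, ]
  y <- y[ids]
  if (is.null(Q)) Q <- populations(geno) else Q <- Q[ids]
  Q <- droplevels(factor(Q))
  d <- dosages(geno)
  if (is.null(K)) K <- computeKinship(geno)
  if (is.null(rownames(K))) dimnames(K) <- list(ids, ids)
  K <- K[ids, ids]
  X0 <- if (nlevels(Q) > 1) stats::model.matrix(~Q)
        else matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
  ## prune collinear peaks
  keep <- character(0); pooled <- stats::setNames(rep("", 0), character(0))
  Xc <- X0
  for (mk in peakMarkers) {
    Xtry <- cbind(Xc, d[, mk])
    if (qr(Xtry)$rank > qr(Xc)$rank) {
      Xc <- Xtry; keep <- c(keep, mk)
    } else {
      warning("peak ", mk, " collinear with earlier peaks; pooled")
      pooled[mk] <- if (length(keep)) keep[length(keep)] else ""
    }
  }
  null <- nullReml(y, X0, K)
  w <- null$lam + null$delta
  tr <- function(M) crossprod(null$U, M)
  ys <- tr(y)
  whiten <- function(M) M / sqrt(w)
  yw <- whiten(ys)
  rss <- function(Xw) {
    q <- qr(Xw)
    sum(stats::resid(stats::lm.fit(Xw, yw))^2)
  }
  Xfull <- cbind(X0, d[, keep, drop = FALSE])
  rssFull <- rss(whiten(tr(Xfull)))
  tss <- sum((yw - mean(yw))^2)
  ve <- vapply(keep, function(mk) {
    Xr <- cbind(X0, d[, setdiff(keep, mk), drop = FALSE])
    100 * (rss(whiten(tr(Xr))) - rssFull) / tss
  }, numeric(1))
  data.frame(marker = keep, var_explained_pct = ve,
             collinear_with = vapply(keep, function(mk)
               paste(names(pooled)[pooled == mk], collapse = ";"),
               character(1)))
}
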