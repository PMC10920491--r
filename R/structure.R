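#' Skim markers by pairwise correlation
#'
#' Greedy left-to-right scan in map order (chromosome, then bp; unplaced
#' markers last in input order): a marker is dropped when its absolute
#' Pearson correlation with any already-retained marker reaches the
#' threshold, so the retained set has all pairwise |r| below it. The
#' first-seen member of a correlated pair is kept, making the result
#' deterministic given the map order.
#'
#' @param geno [GenotypeData-class].
#' @param rThreshold drop threshold on |r| (default 0.8; use 1 to drop
#'   exact duplicates only).
#' @return character vector of retained marker ids.
#' @export
skimMarkers <- function(geno, rThreshold = 0.8) {
  stopifnot(rThreshold > 0, rThreshold <= 1)
  d <- dosages(geno)
  map <- markerMap(geno)
  ord <- order(is.na(map$chrom), map$chrom, map$bp)
  cc <- abs(suppressWarnings(stats::cor(d, use = "pairwise.complete.obs")))
  keep <- integer(0)
  for (j in ord) {
    r <- cc[j, keep]
    if (!length(keep) || all(is.na(r) | r < rThreshold))
      keep <- c(keep, j)
  }
  markerIds(geno)[sort(keep)]
}

#' Principal coordinate analysis of genotype distances
#'
#' Classical metric scaling on a genotype distance matrix (default:
#' Euclidean distance on dosages; `"simple_matching"` uses one minus the
#' proportion of matching calls). Percent variance per axis uses the sum
#' of positive eigenvalues as denominator (negative eigenvalues
#' truncated). A D-sub-genome-only view is available via `chromosomes`.
#'
#' @param geno [GenotypeData-class], or a `dist`/symmetric matrix.
#' @param nAxes number of coordinate axes to return.
#' @param method `"euclidean"` or `"simple_matching"` (ignored when a
#'   distance is supplied).
#' @param chromosomes optional chromosome subset (e.g. `c("1D", ..., "7D")`)
#'   applied before computing distances.
#' @return list: `coordinates` (genotypes x axes), `eigenvalues`,
#'   `percentVariance`.
#' @export
runPcoa <- function(geno, nAxes = 2, method = c("euclidean", "simple_matching"),
                    chromosomes = NULL) {
  method <- match.arg(method)
  if (is(geno, "GenotypeData")) {
    if (!is.null(chromosomes)) {
      keep <- markerMap(geno)$chrom %in% chromosomes
      geno <- geno[, keep]
    }
    d <- dosages(geno)
    if (nrow(d) < 2) stop("need >= 2 genotypes")
    dm <- if (method == "euclidean") {
      stats::dist(d)
    } else {
      n <- nrow(d)
      sm <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ok <- !is.na(d[i, ]) & !is.na(d[j, ])
        sm[i, j] <- sm[j, i] <- 1 - mean(d[i, ok] == d[j, ok])
      }
      stats::as.dist(sm)
    }
  } else {
    dm <- geno
    if (is.matrix(dm)) {
      if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric")
      dm <- stats::as.dist(dm)
    }
  }
  n <- attr(dm, "Size")
  nAxes <- min(nAxes, n - 1)
  if (all(dm < 1e-12)) {  # degenerate: identical genotypes
    coords <- matrix(0, n, nAxes,
                     dimnames = list(attr(dm, "Labels"),
                                     paste0("PCo", seq_len(nAxes))))
    return(list(coordinates = coords, eigenvalues = rep(0, n),
                percentVariance = rep(0, nAxes)))
  }
  fit <- ape::pcoa(dm)
  ev <- fit$values$Eigenvalues
  pos <- ev[ev > 1e-8 * max(abs(ev))]
  coords <- fit$vectors[, seq_len(min(nAxes, ncol(fit$vectors))), drop = FALSE]
  if (ncol(coords) < nAxes)  # degenerate: pad zero axes
    coords <- cbind(coords, matrix(0, n, nAxes - ncol(coords)))
  colnames(coords) <- paste0("PCo", seq_len(nAxes))
  pct <- 100 * ev[seq_len(nAxes)] / sum(pos)
  pct[ev[seq_len(nAxes)] < 0] <- 0
  list(coordinates = coords, eigenvalues = ev,
       percentVariance = pct)
}
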