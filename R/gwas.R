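#' Per-trial marker preparation for association scanning
#'
#' Removes markers with fewer than `minMinorHom` minor-allele homozygotes
#' *in the supplied genotype subset* (so different trials keep different
#' sets), then skims exact duplicates (|r| = 1), keeping the first marker
#' in map order.
#'
#' @param geno [GenotypeData-class], already subset to the trial's
#'   genotypes.
#' @param minMinorHom minimum minor-homozygote count (default 15).
#' @return character vector of scan-ready marker ids.
#' @export
prepareScanMarkers <- function(geno, minMinorHom = 15) {
  d <- dosages(geno)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  keep <- pmin(n0, n2) >= minMinorHom
  if (!any(keep)) stop("no markers pass the minor-homozygote filter")
  sub <- geno[, keep]
  skimMarkers(sub, rThreshold = 1)
}

#' Realized-relationship kinship matrix
#'
#' Markers are first skimmed at |r| = `skimR` (default 0.80) so that
#' blocks of high LD do not dominate the estimate; the kinship is then the
#' centered cross-product of dosages scaled by the marker count:
#' \eqn{K = Z Z^T / m} with Z the column-centered dosage matrix.
#' Zero-variance markers are excluded.
#'
#' @param geno [GenotypeData-class] (imputed; no missing calls).
#' @param skimR skim threshold for the kinship marker set.
#' @param markers optional explicit marker set (skim skipped).
#' @return symmetric genotypes x genotypes matrix.
#' @export
computeKinship <- function(geno, skimR = 0.80, markers = NULL) {
  if (is.null(markers)) markers <- skimMarkers(geno, rThreshold = skimR)
  d <- dosages(geno)[, markers, drop = FALSE]
  v <- apply(d, 2, stats::var)
  d <- d[, !is.na(v) & v > 0, drop = FALSE]
  if (ncol(d) < 2) stop("need >= 2 variable markers for kinship")
  z <- scale(d, center = TRUE, scale = FALSE)
  tcrossprod(z) / ncol(z)
}

## internal: REML profile of the one-random-effect mixed model on the
## eigenbasis of K. Returns delta = Ve/Vg, sigma_g^2 and the rotation.
nullReml <- function(y, X, K) {
  n <- length(y)
  eig <- eigen(K, symmetric = TRUE)
  U <- eig$vectors
  lam <- pmax(eig$values, 0)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  p <- qr(X)$rank
  remlNegLL <- function(logDelta) {
    delta <- exp(logDelta)
    w <- lam + delta
    xtwx <- crossprod(Xs / w, Xs)
    beta <- solve(xtwx, crossprod(Xs / w, ys))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 / w)
    sg <- rss / (n - p)
    0.5 * ((n - p) * log(sg) + sum(log(w)) +
           determinant(xtwx, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(remlNegLL, c(-10, 10))
  delta <- exp(opt$minimum)
  w <- lam + delta
  xtwx <- crossprod(Xs / w, Xs)
  beta <- solve(xtwx, crossprod(Xs / w, ys))
  rss <- sum((ys - Xs %*% beta)^2 / w)
  list(U = U, lam = lam, delta = delta, sigmaG = rss / (n - p),
       logLik = -opt$objective)
}

## internal: GLS test of the last column of X given fixed weights w
glsLastColTest <- function(ys, Xs, w) {
  q <- qr(Xs / sqrt(w))
  p <- q$rank
  n <- length(ys)
  if (p < ncol(Xs)) return(c(NA, NA, NA))
  xtwx <- crossprod(Xs / w, Xs)
  xi <- chol2inv(chol(xtwx))
  beta <- xi %*% crossprod(Xs / w, ys)
  rss <- sum((ys - Xs %*% beta)^2 / w)
  df <- n - p
  s2 <- rss / df
  k <- ncol(Xs)
  se <- sqrt(s2 * xi[k, k])
  tval <- beta[k] / se
  pval <- stats::pf(tval^2, 1, df, lower.tail = FALSE)
  c(beta[k], se, pval)
}

#' Single-marker Q+K mixed-model association scan
#'
#' Fits the null model \eqn{y = Q\beta + u + e}, \eqn{u \sim N(0, K
#' \sigma_g^2)}, once by REML on the eigenbasis of K, then tests each
#' marker's additive dosage effect by generalized least squares with the
#' variance components held fixed (the population-parameters-previously-
#' determined approximation). Effects are signed per donor-allele dose
#' with the recurrent parent as reference; p-values are F-tests with
#' residual degrees of freedom, so with K = identity and a single
#' population the scan reduces exactly to per-marker OLS. Markers whose
#' dosage is constant within every population (confounded with Q) are
#' reported `NA`.
#'
#' @param y named numeric: one phenotype (e.g. BLUE) per genotype.
#' @param geno [GenotypeData-class] (imputed) covering the names of `y`.
#' @param Q factor of nested-population ids per genotype (default: taken
#'   from `geno`); coded as fixed-effect dummies, first population as
#'   reference.
#' @param K kinship matrix covering the genotypes (default:
#'   [computeKinship()] on the scan subset).
#' @param markers marker set to test (default: [prepareScanMarkers()]).
#' @param covariates optional marker ids whose dosages join the fixed
#'   effects (see [covariateScan()]).
#' @param alpha significance level for the LD-aware threshold stored in
#'   the scan metadata.
#' @return A [GwasScan-class] object.
#' @export
gwasScan <- function(y, geno, Q = NULL, K = NULL, markers = NULL,
                     covariates = NULL, alpha = 0.05) {
  ids <- intersect(names(y), genotypeIds(geno))
  if (!length(ids)) stop("y and genotype data share no ids")
  ids <- ids[!is.na(y[ids])]
  geno <- geno[ids, ]
  y <- y[ids]
  if (is.null(Q)) Q <- populations(geno) else Q <- Q[ids]
  Q <- droplevels(factor(Q))
  if (is.null(markers)) markers <- prepareScanMarkers(geno)
  d <- dosages(geno)
  if (anyNA(d[, markers])) stop("scan requires imputed (complete) dosages")
  X <- if (nlevels(Q) > 1) stats::model.matrix(~Q)
       else matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
  dropCov <- character(0)
  if (length(covariates)) {
    cmat <- d[, covariates, drop = FALSE]
    keepc <- logical(ncol(cmat))
    for (j in seq_len(ncol(cmat))) {
      Xtry <- cbind(X, cmat[, j])
      keepc[j] <- qr(Xtry)$rank > qr(X)$rank
      if (keepc[j]) X <- Xtry
    }
    dropCov <- covariates[!keepc]
    if (length(dropCov))
      warning("collinear/constant covariates pruned: ",
              paste(dropCov, collapse = ", "))
    if (sum(keepc))
      colnames(X)[(ncol(X) - sum(keepc) + 1):ncol(X)] <- covariates[keepc]
  }
  if (is.null(K)) K <- computeKinship(geno)
  if (is.null(rownames(K))) {
    stopifnot(nrow(K) == length(ids))
    dimnames(K) <- list(ids, ids)
  }
  K <- K[ids, ids]
  null <- nullReml(y, X, K)
  w <- null$lam + null$delta
  ys <- crossprod(null$U, y)
  Xs <- crossprod(null$U, X)
  baseRank <- qr(X)$rank
  map <- markerMap(geno)
  res <- matrix(NA_real_, length(markers), 3)
  for (i in seq_along(markers)) {
    mk <- markers[i]
    if (mk %in% covariates) next  # covariates are not re-tested
    x <- d[, mk]
    ## confounded with Q: constant within every population
    if (all(tapply(x, Q, function(v) length(unique(v))) == 1L)) next
    xs <- crossprod(null$U, x)
    res[i, ] <- glsLastColTest(ys, cbind(Xs, xs), w)
  }
  n0 <- colSums(d[, markers, drop = FALSE] == 0L)
  n2 <- colSums(d[, markers, drop = FALSE] == 2L)
  tab <- data.frame(
    marker = markers,
    chrom = map[markers, "chrom"],
    bp = map[markers, "bp"],
    effect = res[, 1], se = res[, 2], pvalue = res[, 3],
    score = -log10(res[, 3]),
    minor_hom = pmin(n0, n2))
  tab <- tab[order(is.na(tab$chrom), tab$chrom, tab$bp), ]
  rownames(tab) <- NULL
  thr <- tryCatch(
    significanceThreshold(geno[, markers], alpha = alpha),
    error = function(e) NULL)
  lam <- tryCatch(inflationFactor(tab$pvalue[!is.na(tab$pvalue)]),
                  error = function(e) NA_real_)
  new("GwasScan", table = tab,
      meta = list(n = length(ids), threshold = thr$threshold,
                  mEff = thr$mEff, lambda = lam, alpha = alpha,
                  deltaReml = null$delta, sigmaG = null$sigmaG,
                  covariates = setdiff(covariates, dropCov),
                  method = "Q+K mixed model, P3D/EMMAX approximation, Li-Ji effective markers"))
}

#' Re-scan with major-hit covariates
#'
#' Identical to [gwasScan()] with the covariate markers' dosages appended
#' to the fixed effects; the covariate markers themselves are reported
#' `NA`. Collinear covariates are pruned with a warning.
#'
#' @inheritParams gwasScan
#' @export
covariateScan <- function(y, geno, covariates, Q = NULL, K = NULL,
                          markers = NULL, alpha = 0.05) {
  gwasScan(y, geno, Q = Q, K = K, markers = markers,
           covariates = covariates, alpha = alpha)
}

#' LD-aware Bonferroni-type significance threshold
#'
#' Estimates the effective number of independent tests per chromosome
#' from the eigenvalues of the marker correlation matrix (Li-Ji style:
#' each eigenvalue contributes its fractional part plus one when >= 1),
#' sums across chromosomes (unmapped markers are excluded with a
#' warning), and returns \eqn{-\log_{10}(\alpha / M_{eff})}.
#'
#' @param geno [GenotypeData-class] restricted to the scan marker set.
#' @param alpha corrected significance level (default 0.05).
#' @return list: `threshold` (-log10 scale), `mEff`, `perChrom`.
#' @export
significanceThreshold <- function(geno, alpha = 0.05) {
  map <- markerMap(geno)
  if (anyNA(map$chrom)) {
    warning(sum(is.na(map$chrom)), " unmapped markers excluded from threshold")
    geno <- geno[, !is.na(map$chrom)]
    map <- markerMap(geno)
  }
  d <- dosages(geno)
  per <- vapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    if (length(idx) == 1L) return(1)
    cc <- suppressWarnings(stats::cor(d[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
    ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    sum(as.numeric(ev >= 1) + (ev - floor(ev)))
  }, numeric(1))
  mEff <- sum(per)
  list(threshold = -log10(alpha / mEff), mEff = mEff,
       perChrom = stats::setNames(per, unique(map$chrom)))
}

#' Genomic inflation factor
#'
#' Devlin-Roeder lambda: the median of the 1-df chi-squared quantiles of
#' the p-values divided by the null median 0.4549.
#'
#' @param p vector of p-values in (0, 1].
#' @return lambda (numeric).
#' @export
inflationFactor <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10) stop("need >= 10 p-values")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
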