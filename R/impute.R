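#' Iterative random-forest imputation of missing dosages
#'
#' Missing calls are imputed marker-by-marker with random-forest
#' classifiers (200 trees by default), sweeping markers in order of
#' increasing missingness and using all other markers as predictors.
#' Sweeps repeat until the number of imputed calls that change between
#' consecutive sweeps rises (the classic iterative-forest stopping rule)
#' or `maxIter` is reached, and the imputation from the last improving
#' sweep is kept. Classification keeps outputs in \{0, 1, 2\}; observed
#' cells are never altered. An out-of-bag error estimate (tree-vote
#' misclassification averaged over imputed markers) is attached.
#'
#' @param geno [GenotypeData-class]; every marker needs >= 1 non-missing
#'   call.
#' @param nTrees trees per forest (default 200).
#' @param maxIter maximum sweeps (default 10).
#' @param maxPredictors per target marker, the forest is grown on the
#'   `maxPredictors` markers most correlated with it (default 50; `Inf`
#'   uses all markers). Screening exploits the strong local LD of
#'   inbred mapping panels and keeps the sweep time linear in marker
#'   count.
#' @param seed RNG seed; imputation is deterministic given the seed.
#' @return list: `geno` (completed matrix), `oobError` (mean out-of-bag
#'   misclassification across imputed markers), `iterations` (sweeps run).
#' @export
imputeMissing <- function(geno, nTrees = 200, maxIter = 10,
                          maxPredictors = 50, seed = 1) {
  d <- dosages(geno)
  if (!any(is.na(d)))
    return(list(geno = geno, oobError = 0, iterations = 0L))
  allmiss <- colSums(!is.na(d)) == 0L
  if (any(allmiss))
    stop("marker(s) with no observed calls: ",
         paste(utils::head(markerIds(geno)[allmiss], 3), collapse = ", "))
  set.seed(seed)
  missCount <- colSums(is.na(d))
  targets <- order(missCount)[missCount[order(missCount)] > 0]
  naMask <- is.na(d)
  ## initialise missing cells with the marker mode
  cur <- d
  for (j in which(missCount > 0)) {
    tab <- tabulate(d[, j] + 1L, 3L)
    cur[naMask[, j], j] <- which.max(tab) - 1L
  }
  prev <- cur
  lastChange <- Inf
  oob <- numeric(0)
  iters <- 0L
  ## predictor screen: markers most correlated with each target (on the
  ## mode-initialised matrix; fixed across sweeps for determinism)
  preds <- NULL
  if (is.finite(maxPredictors) && ncol(cur) - 1L > maxPredictors) {
    cc <- abs(suppressWarnings(stats::cor(cur)))
    diag(cc) <- -Inf
    cc[is.na(cc)] <- -Inf
    preds <- lapply(targets, function(j)
      order(cc[, j], decreasing = TRUE)[seq_len(maxPredictors)])
    names(preds) <- as.character(targets)
  }
  for (it in seq_len(maxIter)) {
    oobIt <- numeric(0)
    for (j in targets) {
      obs <- !naMask[, j]
      xs <- if (is.null(preds)) cur[, -j, drop = FALSE]
            else cur[, preds[[as.character(j)]], drop = FALSE]
      ytr <- factor(d[obs, j], levels = 0:2)
      if (nlevels(droplevels(ytr)) < 2L) {
        cur[naMask[, j], j] <- as.integer(as.character(ytr[1]))
        oobIt <- c(oobIt, 0)
        next
      }
      fit <- suppressWarnings(ranger::ranger(
        x = xs[obs, , drop = FALSE], y = ytr,
        num.trees = nTrees, num.threads = 1,
        seed = seed + it * 10000L + j, verbose = FALSE))
      pred <- stats::predict(fit, data = xs[naMask[, j], , drop = FALSE],
                             num.threads = 1)$predictions
      cur[naMask[, j], j] <- as.integer(as.character(pred))
      oobIt <- c(oobIt, fit$prediction.error)
    }
    iters <- it
    changed <- sum(cur[naMask] != prev[naMask])
    if (changed >= lastChange) { cur <- prev; break }
    oob <- oobIt
    if (changed == 0L) break
    lastChange <- changed
    prev <- cur
  }
  out <- geno
  out@dosage <- cur
  validObject(out)
  list(geno = out, oobError = if (length(oob)) mean(oob) else 0,
       iterations = iters)
}
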