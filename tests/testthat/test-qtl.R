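## dosage chains whose adjacent-allele correlation is exp(-d / (2*tau)) so
## pairwise dosage R^2 decays as exp(-d / tau) with distance d in Mb
ldChainGeno <- function(n = 600, nmk = 150, tauMb = 10, lenBp = 3e8,
                        chrom = "1A", seed = 1) {
  set.seed(seed)
  bp <- sort(sample.int(lenBp, nmk))
  s <- exp(-diff(bp) / 1e6 / (2 * tauMb))
  hap <- function() {
    h <- matrix(0L, n, nmk)
    h[, 1] <- rbinom(n, 1, 0.5)
    for (j in 2:nmk) {
      keep <- rbinom(n, 1, s[j - 1]) == 1
      h[, j] <- ifelse(keep, h[, j - 1], rbinom(n, 1, 0.5))
    }
    h
  }
  d <- hap() + hap()
  storage.mode(d) <- "integer"
  dimnames(d) <- list(sprintf("g%03d", 1:n), sprintf("%s_m%03d", chrom, 1:nmk))
  GenotypeData(d, map = data.frame(chrom = chrom, bp = bp, source = "curated",
                                   row.names = colnames(d)))
}

test_that("the LD window matches the closed-form decay crossing", {
  ## R^2(d) = exp(-d/10Mb) crosses 0.2 at 10 ln 5 = 16.1 -> window 17 +/- 1
  g <- ldChainGeno(seed = 110)
  w <- ldDecayWindow(g)
  expect_true(abs(w$windowMb - 17) <= 1)
  expect_true(all(diff(w$profile$fitted) <= 1e-12))
  ## pooling two homogeneous chromosomes gives the same answer +/- 1
  g2 <- ldChainGeno(chrom = "2B", seed = 111)
  d <- cbind(dosages(g), dosages(g2))
  mp <- rbind(markerMap(g), markerMap(g2))
  pooled <- ldDecayWindow(GenotypeData(d, map = mp))
  expect_lte(abs(pooled$windowMb - w$windowMb), 1)
})

test_that("perfect LD never decays and errors with guidance", {
  set.seed(112)
  x <- rbinom(200, 2, 0.5)
  d <- matrix(rep(x, 10), 200, 10,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("m%02d", 1:10)))
  storage.mode(d) <- "integer"
  g <- GenotypeData(d, map = data.frame(chrom = "1A",
                                        bp = seq(1e6, 100e6, length.out = 10),
                                        source = "curated",
                                        row.names = colnames(d)))
  expect_error(ldDecayWindow(g), "raise the critical value")
})

test_that("peak calling respects the suppression window and thresholds", {
  expect_equal(nrow(callPeaks(makeScan(c(10e6, 40e6), c(6, 5)), windowMb = 18)), 2)
  one <- callPeaks(makeScan(c(10e6, 20e6), c(6, 5)), windowMb = 18)
  expect_equal(nrow(one), 1)
  expect_equal(one$bp, 10e6)   # higher score wins
  expect_equal(nrow(callPeaks(makeScan(c(10e6), 2), windowMb = 18)), 0)
  ## invariant to marker shuffling
  sc <- makeScan(c(5e6, 12e6, 40e6, 90e6, 95e6), c(5, 7, 6, 4.5, 5.5))
  tab <- scanTable(sc)
  perm <- new("GwasScan", table = tab[c(3, 1, 5, 2, 4), ],
              meta = list(threshold = 4))
  p1 <- callPeaks(sc, windowMb = 18)
  p2 <- callPeaks(perm, windowMb = 18)
  expect_equal(p1$marker, p2$marker)
})

test_that("QTL intervals span consecutive significant flanking markers", {
  sc <- makeScan(c(1:5 * 1e6, 30e6), c(5, 6, 7, 6, 5, 1))
  expect_equal(unname(qtlInterval(sc, "x03", windowMb = 18)), c(1e6, 5e6))
  iso <- makeScan(c(10e6, 40e6), c(6, 1))
  expect_equal(unname(qtlInterval(iso, "x01", windowMb = 18)), c(10e6, 10e6))
  ## interval covers a planted locus in most runs
  hits <- 0L
  for (s in 1:10) {
    g <- ldChainGeno(n = 400, nmk = 80, seed = 120 + s)
    mid <- markerIds(g)[40]
    y <- plantTrait(g, mid, 0.10, seed = 130 + s)
    K <- diag(400); dimnames(K) <- list(genotypeIds(g), genotypeIds(g))
    Q <- stats::setNames(factor(rep("P", 400)), genotypeIds(g))
    sc2 <- gwasScan(y, g, Q = Q, K = K, markers = markerIds(g), alpha = 0.05)
    thr <- scanMeta(sc2)$threshold
    pk <- callPeaks(sc2, windowMb = 18)
    if (!nrow(pk)) next
    iv <- qtlInterval(sc2, pk$marker[1], windowMb = 18)
    bpTrue <- markerMap(g)[mid, "bp"]
    if (iv[1] <= bpTrue && bpTrue <= iv[2]) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("cross-trial merging unifies consistent peaks and splits conflicts", {
  pk <- data.frame(marker = "AX1", chrom = "4D", bp = 1.4e6, score = 13,
                   effect = -1, trait = "Yr")
  m <- mergeQtls(list(Core17 = pk, Core18 = pk, Full21 = pk), windowMb = 18)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_trials, 3)
  expect_match(m$trials, "Core17;Core18;Full21")
  expect_match(m$qtl, "^QYr\\.")
  ## opposite signs 60 Mb apart stay separate
  pa <- data.frame(marker = "A", chrom = "1A", bp = 10e6, score = 6,
                   effect = 1, trait = "Ft")
  pb <- data.frame(marker = "B", chrom = "1A", bp = 70e6, score = 6,
                   effect = -1, trait = "Ft")
  m2 <- mergeQtls(list(t1 = pa, t2 = pb), windowMb = 18)
  expect_equal(nrow(m2), 2)
  ## same position, opposite sign: kept separate and flagged
  pc <- pb; pc$bp <- 10e6
  m3 <- mergeQtls(list(t1 = pa, t2 = pc), windowMb = 18)
  expect_equal(nrow(m3), 2)
  expect_true(all(m3$sign_conflict))
  ## single-trial peak with peak shift within 3x window merges
  pd <- pa; pd$bp <- 45e6
  m4 <- mergeQtls(list(t1 = pa, t2 = pd), windowMb = 18)
  expect_equal(nrow(m4), 1)
  expect_equal(m4$n_trials, 2)
  m5 <- mergeQtls(list(t1 = pa), windowMb = 18)
  expect_equal(m5$n_trials, 1)
})

test_that("joint models partition variance to the planted QTL", {
  g <- ldChainGeno(n = 800, nmk = 100, seed = 140)
  mkA <- markerIds(g)[20]; mkB <- markerIds(g)[80]
  y <- plantTrait(g, mkA, 0.10, seed = 141)
  K <- diag(800); dimnames(K) <- list(genotypeIds(g), genotypeIds(g))
  Q <- stats::setNames(factor(rep(c("P1", "P2"), each = 400)), genotypeIds(g))
  mv <- multiQtlVariance(y, g, peakMarkers = c(mkA, mkB), Q = Q, K = K)
  expect_lt(abs(mv$var_explained_pct[mv$marker == mkA] - 10), 3)
  expect_lt(mv$var_explained_pct[mv$marker == mkB], 1)
  ## a duplicated peak is reported collinear
  expect_warning(
    mv2 <- multiQtlVariance(y, g, peakMarkers = c(mkA, mkA), Q = Q, K = K),
    "collinear")
  expect_equal(nrow(mv2), 1)
  expect_match(mv2$collinear_with[1], mkA)
})

test_that("variance shares never exceed the total model fit", {
  g <- ldChainGeno(n = 400, nmk = 60, seed = 142)
  mks <- markerIds(g)[c(10, 30, 50)]
  y <- plantTrait(g, mks[1:2], c(0.08, 0.05), seed = 143)
  K <- diag(400); dimnames(K) <- list(genotypeIds(g), genotypeIds(g))
  Q <- stats::setNames(factor(rep("P", 400)), genotypeIds(g))
  mv <- multiQtlVariance(y, g, peakMarkers = mks, Q = Q, K = K)
  fullR2 <- summary(stats::lm(y ~ dosages(g)[, mks]))$r.squared
  expect_lte(sum(mv$var_explained_pct) / 100, fullR2 + 1e-8)
})

test_that("scan-to-merge recovers the two larger of three planted QTLs across two trials", {
  nam <- namPower()
  g <- nam$geno
  mks <- nam$markers
  map <- markerMap(g)
  ## three planted loci on distinct chromosomes (8%, 5%, 3% of variance)
  picks <- mks[match(c("3A", "5B", "7D"), map[mks, "chrom"])]
  shares <- c(0.08, 0.05, 0.03)
  hits2 <- 0L
  runs <- 6
  for (r in seq_len(runs)) {
    peaks <- list()
    for (tr in 1:2) {
      y <- plantTrait(g, picks, shares, seed = 5000 + 10 * r + tr)
      sc <- gwasScan(y, g, K = nam$K, markers = mks)
      pk <- callPeaks(sc, windowMb = 18)
      if (nrow(pk)) pk$trait <- "Ft"
      peaks[[paste0("trial", tr)]] <- pk
    }
    merged <- mergeQtls(peaks, windowMb = 18)
    foundBoth <- all(vapply(picks[1:2], function(mk) {
      any(merged$chrom == map[mk, "chrom"] &
          abs(merged$bp - map[mk, "bp"]) <= 54e6)
    }, logical(1)))
    ## each recovered QTL carries a single merged name per locus
    perLocus <- vapply(picks[1:2], function(mk)
      sum(merged$chrom == map[mk, "chrom"] &
          abs(merged$bp - map[mk, "bp"]) <= 54e6), numeric(1))
    if (foundBoth && all(perLocus == 1)) hits2 <- hits2 + 1L
  }
  expect_gte(hits2, runs - 1)
})
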