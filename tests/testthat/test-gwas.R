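test_that("scan marker preparation filters rare homozygotes and exact duplicates", {
  nam <- namPower()
  g <- nam$geno
  d <- dosages(g)
  mks <- prepareScanMarkers(g)
  n0 <- colSums(d[, mks] == 0L); n2 <- colSums(d[, mks] == 2L)
  expect_true(all(pmin(n0, n2) >= 15))
  cc <- abs(stats::cor(d[, mks]))
  diag(cc) <- 0
  expect_lt(max(cc), 1 - 1e-10)
  ## a 14-minor-homozygote marker is dropped
  one <- names(which(pmin(colSums(d == 0L), colSums(d == 2L)) == 14))
  if (length(one)) expect_false(one[1] %in% mks)
  ## subset dependence: half the genotypes give a different set
  mksHalf <- prepareScanMarkers(g[1:400, ])
  expect_false(setequal(mks, mksHalf))
})

test_that("kinship reflects relatedness structure", {
  nam <- namPower()
  K <- nam$K
  expect_true(isSymmetric(K, tol = 1e-8))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-6 * max(ev))
  expect_true(all(diag(K) > 0))
  ## same-population pairs are more related than cross-population pairs
  pop <- populations(nam$geno)
  same <- outer(pop, pop, "==") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[!same & upper.tri(K)]))
  ## duplicated genotype rows show identical kinship to third parties
  g <- nam$geno[1:50, ]
  d <- rbind(dosages(g), copy1 = dosages(g)[1, ])
  g2 <- GenotypeData(d, map = markerMap(g))
  K2 <- computeKinship(g2, markers = markerIds(g2))
  expect_equal(K2["copy1", 3:50], K2[1, 3:50], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("full sibs are about twice as related as half sibs", {
  map <- makeGeneticMap(10, 40, 6e8, 150)
  set.seed(100)
  nmk <- nrow(map)
  founder <- function() { h <- rbinom(nmk, 1, 0.5); list(h1 = h, h2 = h) }
  A <- founder(); B <- founder(); C <- founder()
  child <- function(p1, p2) list(h1 = simulateMeiosis(p1$h1, p1$h2, map),
                                 h2 = simulateMeiosis(p2$h1, p2$h2, map))
  kids <- c(list(child(A, B), child(A, B)),       # full sibs
            list(child(A, C)),                    # half sib to the first two
            replicate(40, child(founder(), founder()), simplify = FALSE))
  d <- t(vapply(kids, function(k) as.integer(k$h1 + k$h2), integer(nmk)))
  dimnames(d) <- list(sprintf("i%02d", seq_len(nrow(d))), rownames(map))
  g <- GenotypeData(d, map = data.frame(chrom = map$chrom, bp = map$bp,
                                        source = "curated",
                                        row.names = rownames(map)))
  K <- computeKinship(g, markers = markerIds(g))
  full <- K["i01", "i02"]
  half <- mean(c(K["i01", "i03"], K["i02", "i03"]))
  expect_gt(full, 0)
  expect_equal(full / half, 2, tolerance = 0.5)
})

test_that("with identity kinship and one population the scan equals OLS", {
  nam <- namPower()
  g <- nam$geno[1:100, ]
  d <- dosages(g)
  set.seed(101)
  y <- stats::setNames(rnorm(100) + 0.5 * d[, 30], genotypeIds(g))
  K <- diag(100)
  Q <- stats::setNames(factor(rep("P", 100)), genotypeIds(g))
  mks <- prepareScanMarkers(g, minMinorHom = 5)
  sc <- gwasScan(y, g, Q = Q, K = K, markers = mks)
  tab <- scanTable(sc)
  ols <- vapply(mks, function(m) {
    x <- d[, m]
    if (stats::var(x) == 0) return(NA_real_)
    summary(stats::lm(y ~ x))$coefficients["x", "Pr(>|t|)"]
  }, numeric(1))
  del <- abs(-log10(ols) - tab$score[match(mks, tab$marker)])
  expect_lt(max(del, na.rm = TRUE), 0.01)
})

test_that("swapping the reference allele negates effects and keeps p-values", {
  nam <- namPower()
  g <- nam$geno[1:200, seq(1, 1050, by = 8)]
  set.seed(102)
  y <- stats::setNames(rnorm(200), genotypeIds(g))
  mks <- prepareScanMarkers(g, minMinorHom = 10)
  K <- nam$K[1:200, 1:200]
  s1 <- gwasScan(y, g, K = K, markers = mks)
  gFlip <- GenotypeData(2L - dosages(g), map = markerMap(g),
                        population = populations(g))
  s2 <- gwasScan(y, gFlip, K = K, markers = mks)
  t1 <- scanTable(s1); t2 <- scanTable(s2)
  expect_equal(t1$effect, -t2$effect, tolerance = 1e-8)
  expect_equal(t1$pvalue, t2$pvalue, tolerance = 1e-8)
})

test_that("the scan is invariant to genotype row order", {
  nam <- namPower()
  g <- nam$geno[1:150, seq(1, 1050, by = 10)]
  set.seed(103)
  y <- stats::setNames(rnorm(150), genotypeIds(g))
  mks <- prepareScanMarkers(g, minMinorHom = 8)
  K <- nam$K[1:150, 1:150]
  s1 <- gwasScan(y, g, K = K, markers = mks)
  perm <- sample(genotypeIds(g))
  s2 <- gwasScan(y[perm], g[perm, ], K = K[perm, perm], markers = mks)
  expect_equal(scanTable(s1)$score, scanTable(s2)$score, tolerance = 1e-6)
})

test_that("markers confounded with the population factor come back NA", {
  nam <- namPower()
  g <- nam$geno[, 1:100]
  d <- dosages(g)
  ## make marker 1 constant within every population
  pop <- populations(g)
  d[, 1] <- as.integer(as.integer(pop) %% 2L) * 2L
  g2 <- GenotypeData(d, map = markerMap(g), population = pop)
  set.seed(104)
  y <- stats::setNames(rnorm(nrow(d)), rownames(d))
  sc <- gwasScan(y, g2, K = nam$K, markers = markerIds(g2)[1:20])
  tab <- scanTable(sc)
  expect_true(is.na(tab$pvalue[tab$marker == markerIds(g2)[1]]))
})

test_that("covariate scans suppress the covariate's own QTL window", {
  nam <- namPower()
  g <- nam$geno
  mks <- nam$markers
  set.seed(105)
  y <- plantTrait(g, mks[200], shares = 0.10, seed = 106)
  sc <- gwasScan(y, g, K = nam$K, markers = mks)
  tab <- scanTable(sc)
  peakRegion <- tab$chrom == markerMap(g)[mks[200], "chrom"] &
                abs(tab$bp - markerMap(g)[mks[200], "bp"]) < 18e6
  expect_gt(max(tab$score[peakRegion], na.rm = TRUE), scanMeta(sc)$threshold)
  sc2 <- covariateScan(y, g, covariates = mks[200], K = nam$K, markers = mks)
  tab2 <- scanTable(sc2)
  expect_true(is.na(tab2$score[tab2$marker == mks[200]]))
  expect_lt(max(tab2$score[peakRegion], na.rm = TRUE), scanMeta(sc)$threshold)
  ## an all-zero covariate changes nothing; a duplicate covariate is pruned
  d0 <- dosages(g); d0[, 1] <- 0L
  g0 <- GenotypeData(d0, map = markerMap(g), population = populations(g))
  expect_warning(
    sc3 <- covariateScan(y, g0, covariates = markerIds(g)[1], K = nam$K,
                         markers = mks[2:50]),
    "pruned")
  base <- gwasScan(y, g0, K = nam$K, markers = mks[2:50])
  expect_equal(scanTable(sc3)$score, scanTable(base)$score, tolerance = 1e-8)
  expect_warning(
    covariateScan(y, g, covariates = c(mks[200], mks[200]), K = nam$K,
                  markers = mks[2:20]),
    "pruned")
})

test_that("significance thresholds follow effective marker counts", {
  set.seed(107)
  ## independent markers: threshold approaches plain Bonferroni
  d <- matrix(rbinom(400 * 120, 2, 0.5), 400, 120,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("m%03d", 1:120)))
  map <- data.frame(chrom = rep(c("1A", "1B"), each = 60),
                    bp = rep(seq(1e6, 60e6, by = 1e6), 2),
                    source = "curated", row.names = colnames(d))
  g <- GenotypeData(d, map = map)
  th <- significanceThreshold(g)
  expect_equal(th$mEff, 120, tolerance = 0.03)
  expect_equal(th$threshold, -log10(0.05 / 120), tolerance = 0.02)
  ## all markers identical: one effective test
  d2 <- d; for (j in 2:60) d2[, j] <- d2[, 1]
  for (j in 62:120) d2[, j] <- d2[, 61]
  g2 <- GenotypeData(d2, map = map)
  th2 <- significanceThreshold(g2)
  expect_equal(th2$mEff, 2)
  g3 <- GenotypeData(d2[, 1:60], map = map[1:60, ])
  expect_equal(significanceThreshold(g3)$threshold, -log10(0.05), tolerance = 1e-6)
  ## unmapped markers excluded with a warning
  map$chrom[1] <- NA
  g4 <- GenotypeData(d, map = map)
  expect_warning(significanceThreshold(g4), "unmapped")
})

test_that("genomic inflation is calibrated", {
  expect_equal(inflationFactor(rep(0.5, 50)), 1)
  set.seed(108)
  p <- runif(1e4)
  expect_equal(inflationFactor(p), 1, tolerance = 0.03)
  chi2 <- stats::qchisq(p, 1, lower.tail = FALSE) * 2
  expect_equal(inflationFactor(stats::pchisq(chi2, 1, lower.tail = FALSE)),
               2, tolerance = 0.06)
  expect_error(inflationFactor(c(0.5, 1.2, rep(0.3, 10))), "lie in")
  expect_error(inflationFactor(rep(0.4, 5)), ">= 10")
})
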