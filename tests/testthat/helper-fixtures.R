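## Shared fixtures, built lazily once per test session.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

## Genome-scale NAM: 21 chromosomes x 100 markers, 3 populations of 96
## BC1F5 genotypes (no attrition), parents included.
nam21 <- function() cached("nam21", function() {
  map <- makeGeneticMap(nChrom = 21, markersPerChrom = 100,
                        lengthBp = 6e8, lengthCM = 150)
  founders <- makeFounders(map, nDonors = 3, seed = 101)
  plan <- defaultCrossPlan(nPopulations = 3, targetSize = NA)
  nam <- buildNam(plan, founders, map, seed = 102)
  nam$map <- map
  nam$founders <- founders
  nam
})

## Small dense-LD NAM used by QC/imputation/positioning tests:
## 5 chromosomes x 40 markers, 2 populations of 96.
namDense <- function() cached("namDense", function() {
  map <- makeGeneticMap(nChrom = 5, markersPerChrom = 40,
                        lengthBp = 6e8, lengthCM = 100)
  founders <- makeFounders(map, nDonors = 2, polymorphRate = 0.8, seed = 201)
  plan <- defaultCrossPlan(nPopulations = 2, targetSize = NA)
  nam <- buildNam(plan, founders, map, seed = 202)
  nam$map <- map
  nam$founders <- founders
  nam
})

## Large NAM for association power checks: 10 populations x 80 genotypes,
## 21 chromosomes x 50 markers, with its kinship matrix.
namPower <- function() cached("namPower", function() {
  map <- makeGeneticMap(nChrom = 21, markersPerChrom = 50,
                        lengthBp = 6e8, lengthCM = 150)
  founders <- makeFounders(map, nDonors = 10, seed = 301)
  plan <- defaultCrossPlan(nPopulations = 10, targetSize = 80)
  nam <- buildNam(plan, founders, map, seed = 302, includeParents = FALSE)
  nam$markers <- prepareScanMarkers(nam$geno)
  nam$K <- computeKinship(nam$geno)
  nam
})

## Perfect alignment hits reconstructed from a map (70 bp probes).
hitsFromMap <- function(map, markers = rownames(map)) {
  idx <- match(markers, rownames(map))
  data.frame(query = markers, subject = map$chrom[idx],
             pident = 100, length = 70, mismatch = 0, gapopen = 0,
             qstart = 1, qend = 70,
             sstart = map$bp[idx] - 35, send = map$bp[idx] + 35,
             evalue = 0, bitscore = 140)
}

## Hand-built scan object for QTL-calling logic tests.
makeScan <- function(bp, score, chrom = "1A", effect = 1, threshold = 4,
                     marker = NULL) {
  if (is.null(marker)) marker <- sprintf("x%02d", seq_along(bp))
  tab <- data.frame(marker = marker, chrom = chrom, bp = bp,
                    effect = effect, se = 0.1, pvalue = 10^-score,
                    score = score, minor_hom = 20L)
  new("GwasScan", table = tab, meta = list(threshold = threshold))
}

## Phenotype vector with planted marker effects + polygenic noise.
plantTrait <- function(geno, markers, shares, sigma2 = 1, seed = 1) {
  set.seed(seed)
  d <- dosages(geno)
  varTot <- sigma2 / (1 - sum(shares))
  y <- stats::rnorm(nrow(d), 0, sqrt(sigma2))
  for (i in seq_along(markers)) {
    v <- stats::var(d[, markers[i]])
    y <- y + sqrt(shares[i] * varTot / v) * d[, markers[i]]
  }
  stats::setNames(y, rownames(d))
}
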