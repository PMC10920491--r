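oneHit <- function(query, subject, sstart, send, bitscore = 100,
                   evalue = 1e-30, length = abs(send - sstart) + 1) {
  data.frame(query = query, subject = subject, pident = 99, length = length,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 70,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore)
}

test_that("hit positions are alignment midpoints, orientation-independent", {
  h <- rbind(oneHit("a", "1A", 100, 200),
             oneHit("b", "2B", 500, 500),
             oneHit("c", "3D", 200, 100))
  res <- positionFromHits(h)
  expect_equal(res$bp[res$marker == "a"], 150)
  expect_equal(res$bp[res$marker == "b"], 500)
  expect_equal(res$bp[res$marker == "c"], 150)
  expect_true(all(res$source == "hit_median"))
})

test_that("the best hit wins by bitscore, then e-value, then length", {
  h <- rbind(oneHit("a", "1A", 100, 200, bitscore = 80),
             oneHit("a", "2A", 1000, 1100, bitscore = 140),
             oneHit("b", "1A", 10, 110, bitscore = 90, evalue = 1e-10),
             oneHit("b", "5D", 900, 1000, bitscore = 90, evalue = 1e-20))
  res <- positionFromHits(h)
  expect_equal(res$chrom[res$marker == "a"], "2A")
  expect_equal(res$chrom[res$marker == "b"], "5D")
})

test_that("correlation placement adopts the hit nearest the best-correlated guide", {
  nam <- namDense()
  g <- nam$geno[!is.na(populations(nam$geno)), 1:30]
  map <- markerMap(g)
  target <- rownames(map)[10]
  truthChrom <- map$chrom[10]; truthBp <- map$bp[10]
  map$chrom[10] <- NA; map$bp[10] <- NA; map$source[10] <- NA
  markerMap(g) <- map
  hits <- rbind(oneHit(target, truthChrom, truthBp - 35, truthBp + 35),
                oneHit(target, truthChrom, truthBp + 5e7, truthBp + 5e7 + 70))
  res <- positionByCorrelation(g, hits)
  newmap <- markerMap(res$geno)
  expect_equal(newmap$chrom[10], truthChrom)
  expect_equal(newmap$bp[10], truthBp)           # nearest hit midpoint
  expect_equal(newmap$source[10], "correlation")
  expect_equal(res$placed$marker, target)
})

test_that("correlation placement has no cross-chromosome fallback and an R2 floor", {
  nam <- namDense()
  g <- nam$geno[!is.na(populations(nam$geno)), 1:30]
  map <- markerMap(g)
  target <- rownames(map)[10]
  map$chrom[10] <- NA; map$bp[10] <- NA
  markerMap(g) <- map
  ## only hit on a chromosome that is not the guide's
  hits <- oneHit(target, "7D", 1000, 1100)
  res <- positionByCorrelation(g, hits)
  expect_true(is.na(markerMap(res$geno)$chrom[10]))
  ## an uncorrelated marker stays unplaced even with a matching hit
  set.seed(70)
  d <- dosages(g)
  d[, 10] <- sample(c(0L, 2L), nrow(d), replace = TRUE)
  g2 <- GenotypeData(d, map = map, population = populations(g))
  res2 <- positionByCorrelation(g2, hitsFromMap(markerMap(nam$geno), target))
  expect_true(is.na(markerMap(res2$geno)$chrom[10]))
})

test_that("LD-bin repositioning restores planted chromosome errors and fixes nothing on clean maps", {
  nam <- namDense()
  ## repositioning runs on the QC-passed matrix, as in the pipeline order
  g <- filterMarkers(nam$geno[!is.na(populations(nam$geno)), ])$geno
  hits <- hitsFromMap(markerMap(g))
  clean <- ldBinReposition(g, hits)
  expect_equal(clean$repositioned, 0)
  ## corrupt 5% of marker chromosome assignments
  set.seed(71)
  map <- markerMap(g)
  victims <- sample(nrow(map), round(0.05 * nrow(map)))
  truth <- map$chrom[victims]
  for (v in victims)
    map$chrom[v] <- sample(setdiff(unique(map$chrom), map$chrom[v]), 1)
  gg <- g; markerMap(gg) <- map
  before <- adjacentLdSummary(gg)
  res <- ldBinReposition(gg, hits)
  recovered <- mean(markerMap(res$geno)$chrom[victims] == truth)
  expect_gte(recovered, 0.9)
  ## untouched markers stay put; nothing gets unplaced
  expect_false(anyNA(markerMap(res$geno)$chrom))
  after <- adjacentLdSummary(res$geno)
  expect_gt(mean(after$mean_adjacent_r2), mean(before$mean_adjacent_r2))
})

test_that("a two-marker bin with no majority follows the highest-LD partner", {
  ## markers in perfect LD on 'different' chromosomes; only m2 has a 1A hit
  set.seed(72)
  x <- rbinom(120, 2, 0.5)
  d <- cbind(m1 = x, m2 = x)
  storage.mode(d) <- "integer"
  rownames(d) <- sprintf("g%03d", 1:120)
  map <- data.frame(chrom = c("1A", "6D"), bp = c(5e6, 8e6),
                    source = "curated", row.names = c("m1", "m2"))
  g <- GenotypeData(d, map = map)
  hits <- oneHit("m2", "1A", 5.1e6 - 35, 5.1e6 + 35)
  res <- ldBinReposition(g, hits, iterations = 1)
  expect_equal(markerMap(res$geno)["m2", "chrom"], "1A")
  expect_equal(res$repositioned, 1)
})
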