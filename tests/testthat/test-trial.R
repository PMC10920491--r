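test_that("full-scale augmented layout reports a 24% check-entry fraction", {
  checks <- data.frame(id = c("Robigus", "KWS_Santiago", "Theodore"),
                       reps = c(295, 285, 444))
  repl <- data.frame(id = sprintf("SHW%02d", 1:51),
                     reps = c(rep(3, 49), 1, 1))
  lay <- buildTrialLayout(sprintf("g%04d", 1:2978), checks = checks,
                          replicated = repl, nPlots = 2100, seed = 31)
  expect_equal(nrow(lay$units), 4200)
  expect_equal(round(100 * lay$checkFraction), 24)
  ## block sizes within the configured range
  plotBlocks <- lay$units$block[lay$units$half == 1]
  expect_true(all(table(plotBlocks) >= 100 & table(plotBlocks) <= 156))
})

test_that("replicated genotypes never share both halves of a plot", {
  checks <- data.frame(id = c("A", "B"), reps = c(20, 20))
  lay <- buildTrialLayout(sprintf("g%02d", 1:40), checks = checks, seed = 32)
  u <- lay$units
  byPlot <- split(u$genotype, u$plot)
  dup <- vapply(byPlot, function(g) g[1] == g[2] && g[1] %in% checks$id,
                logical(1))
  expect_false(any(dup))
  expect_true(all(vapply(byPlot, length, integer(1)) == 2))
})

test_that("degenerate layouts behave", {
  lay1 <- buildTrialLayout(c("g1"), checks = data.frame(id = "c1", reps = 1),
                           seed = 33)
  u <- lay1$units
  expect_equal(nrow(u), 2)
  expect_false(u$genotype[1] == u$genotype[2])
  lay0 <- buildTrialLayout(sprintf("g%d", 1:10), seed = 34)
  expect_false(any(lay0$units$is_check))
  expect_equal(lay0$checkFraction, 0)
})

test_that("phenotypes reduce to the trait mean when all variances are zero", {
  nam <- namDense()
  kids <- genotypeIds(nam$geno)[!is.na(populations(nam$geno))][1:30]
  lay <- buildTrialLayout(kids, blockRange = c(5, 10), seed = 35)
  model <- defaultTraitModel(
    polygenicVar = c(Ft = 0, Ph = 0, Yr = 0),
    residualVar = c(Ft = 0, Ph = 0, Yr = 0),
    trialVar = stats::setNames(rep(list(c(block = 0, row = 0, column = 0,
                                          scorer = 0, lid = 0)), 3),
                               c("Ft", "Ph", "Yr")))
  ph <- simulatePhenotypes(nam$geno, model, lay, seed = 36)
  expect_equal(ph$value[ph$trait == "Ft"], rep(215.9, 30))
  expect_equal(ph$value[ph$trait == "Ph"], rep(71.8, 30))
})

test_that("a planted QTL shifts carrier phenotypes by its dosage effect", {
  nam <- namDense()
  g <- nam$geno
  kids <- genotypeIds(g)[!is.na(populations(g))]
  d <- dosages(g)[kids, ]
  mk <- names(which.max(apply(d, 2, stats::var)))
  lay <- buildTrialLayout(kids, blockRange = c(20, 30), seed = 37)
  model <- defaultTraitModel(
    qtls = list(Ft = data.frame(marker = mk, effect = -1),
                Ph = data.frame(marker = character(), effect = numeric()),
                Yr = data.frame(marker = character(), effect = numeric())),
    polygenicVar = c(Ft = 0.25, Ph = 0, Yr = 0),
    residualVar = c(Ft = 0.25, Ph = 0, Yr = 0))
  ph <- simulatePhenotypes(g, model, lay, seed = 38)
  ft <- ph[ph$trait == "Ft" & !ph$is_check, ]
  dos <- d[ft$genotype, mk]
  diff <- mean(ft$value[dos == 2]) - mean(ft$value[dos == 0])
  se <- sqrt(stats::var(ft$value[dos == 2]) / sum(dos == 2) +
             stats::var(ft$value[dos == 0]) / sum(dos == 0))
  expect_lt(abs(diff - (-2)) , 3 * se)
})

test_that("phenotype simulation is reproducible and validates inputs", {
  nam <- namDense()
  kids <- genotypeIds(nam$geno)[!is.na(populations(nam$geno))][1:20]
  lay <- buildTrialLayout(kids, blockRange = c(5, 10), seed = 39)
  model <- defaultTraitModel()
  p1 <- simulatePhenotypes(nam$geno, model, lay, seed = 40)
  p2 <- simulatePhenotypes(nam$geno, model, lay, seed = 40)
  expect_identical(p1, p2)
  lay$units$genotype[1] <- "not_a_genotype"
  expect_error(simulatePhenotypes(nam$geno, model, lay, seed = 40),
               "absent")
})

test_that("missingness injection hits its target rate and reproduces", {
  nam <- namDense()
  g0 <- nam$geno
  expect_identical(dosages(injectMissingAndErrors(g0, 0, 0, seed = 41)),
                   dosages(g0))
  big <- GenotypeData(matrix(0L, 1000, 1000,
                             dimnames = list(sprintf("g%04d", 1:1000),
                                             sprintf("m%04d", 1:1000))))
  gm <- injectMissingAndErrors(big, missingRate = 0.06, seed = 42)
  expect_lt(abs(mean(is.na(dosages(gm))) - 0.06), 0.001)
  gm2 <- injectMissingAndErrors(big, missingRate = 0.06, seed = 42)
  expect_identical(dosages(gm), dosages(gm2))
  ## errors move dosage by one step
  ge <- injectMissingAndErrors(g0, errorRate = 0.5, seed = 43)
  delta <- abs(dosages(ge) - dosages(g0))
  expect_true(all(delta[!is.na(delta)] <= 1))
})
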