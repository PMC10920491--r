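#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline, with the defaults used
#' throughout the package. Configurations round-trip losslessly through
#' YAML ([readPipelineConfig()]); unknown keys are rejected.
#'
#' @param seed master RNG seed.
#' @param out output directory.
#' @return nested named list.
#' @export
defaultPipelineConfig <- function(seed = 1, out = "namqtl_out") {
  list(
    seed = seed,
    out = out,
    stages = c("simulate", "qc", "reposition", "structure", "blues",
               "gwas", "qtl", "select"),
    simulate = list(
      n_populations = 4, n_streams = 12, n_per_stream = 8,
      selfing_generations = 4, target_size = 60,
      n_chrom = 21, markers_per_chrom = 40,
      length_bp = 6e8, length_cm = 150, polymorph_rate = 0.6,
      missing_rate = 0.02, error_rate = 0.002,
      qtl_var_shares = c(0.08, 0.05, 0.03),
      polygenic_var = 1, residual_var = 1,
      checks = 2, check_reps = 24),
    qc = list(
      het_max = 0.10, missing_max = 0.10, min_minor_hom = 15,
      dup_r_abs = 0.99, dup_k = 6, nonparental_threshold = 0.05,
      impute_trees = 200, impute_max_iter = 10),
    reposition = list(r2_bin = 0.5, iterations = 2),
    structure = list(skim_r = 0.8, n_axes = 2),
    blues = list(alpha_elim = 0.10),
    gwas = list(min_minor_hom = 15, kinship_skim_r = 0.8, alpha = 0.05),
    qtl = list(critical_r2 = 0.2, merge_multiplier = 3, lab = "lab"),
    select = list(carrier_mode = "homozygous")
  )
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML configuration, overlays it on [defaultPipelineConfig()],
#' and rejects keys not present in the defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  overlay <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base))
        stop("unknown configuration key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]]))
        base[[k]] <- overlay(base[[k]], upd[[k]], paste0(prefix, k, "."))
      else base[[k]] <- upd[[k]]
    }
    base
  }
  overlay(def, user)
}

## internal: stable hash of the resolved configuration; the output path is
## not part of the analysis, so identical settings hash identically
configHash <- function(config) {
  config$out <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

## internal: TSV with a provenance header line
writeArtifact <- function(x, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  close(con)
  suppressWarnings(utils::write.table(x, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the configured stages in fixed order: simulate the NAM panel,
#' genotype QC (marker filter, genotype filter, duplicate detection,
#' non-parental check, imputation), LD-bin repositioning, PCoA structure,
#' trial BLUEs, Q+K association scans, LD-window QTL calling with merging,
#' and selection summaries. Each stage writes headered TSV artifacts
#' carrying the configuration hash and seed, plus a machine-readable JSON
#' report of input/output counts. A stage failure halts the run with the
#' stage name.
#'
#' @param config configuration from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @return the output directory path, invisibly; the `report.json` inside
#'   summarises per-stage bookkeeping.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  seed <- config$seed
  writeLines(yaml::as.yaml(config), file.path(config$out, "config.yaml"))
  report <- list(config_hash = hash, seed = seed)
  stage <- function(name) name %in% config$stages
  state <- new.env(parent = emptyenv())

  runStage <- function(name, fun) {
    if (!stage(name)) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     stop("pipeline stage '", name, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    invisible(ok)
  }

  runStage("simulate", function() {
    sc <- config$simulate
    set.seed(seed)
    map <- makeGeneticMap(sc$n_chrom, sc$markers_per_chrom,
                          sc$length_bp, sc$length_cm)
    founders <- makeFounders(map, nDonors = max(sc$n_populations, 2),
                             polymorphRate = sc$polymorph_rate)
    plan <- defaultCrossPlan(nPopulations = sc$n_populations,
                             nStreams = sc$n_streams,
                             nPerStream = sc$n_per_stream,
                             selfingGenerations = sc$selfing_generations,
                             targetSize = sc$target_size)
    nam <- buildNam(plan, founders, map)
    ## plant QTLs sized by variance share
    d <- dosages(nam$geno)
    kids <- !is.na(populations(nam$geno))
    shares <- sc$qtl_var_shares
    vtot <- sc$polygenic_var + sc$residual_var
    segOk <- which(apply(d[kids, ], 2, stats::var) > 0.1)
    qloc <- segOk[round(seq(1, length(segOk), length.out = length(shares) + 2))][
      seq_along(shares) + 1]
    qmk <- markerIds(nam$geno)[qloc]
    eff <- sqrt(shares / (1 - sum(shares)) * vtot /
                apply(d[kids, qloc, drop = FALSE], 2, stats::var))
    model <- defaultTraitModel(
      qtls = list(Ft = data.frame(marker = qmk, effect = -eff),
                  Ph = data.frame(marker = character(), effect = numeric()),
                  Yr = data.frame(marker = character(), effect = numeric())),
      polygenicVar = c(Ft = sc$polygenic_var, Ph = sc$polygenic_var,
                       Yr = sc$polygenic_var),
      residualVar = c(Ft = sc$residual_var, Ph = sc$residual_var,
                      Yr = sc$residual_var))
    entries <- genotypeIds(nam$geno)[kids]
    checks <- data.frame(id = sprintf("CHK%d", seq_len(sc$checks)),
                         reps = sc$check_reps)
    layout <- buildTrialLayout(entries, checks = checks)
    pheno <- simulatePhenotypes(nam$geno, model, layout)
    gobs <- injectMissingAndErrors(nam$geno, sc$missing_rate, sc$error_rate)
    state$truthQtls <- data.frame(marker = qmk, effect = -eff,
                                  share = shares)
    state$geno <- gobs
    state$pheno <- pheno
    state$pedigree <- nam$pedigree
    writeGenotypes(gobs, file.path(config$out, "genotypes.csv"))
    writeArtifact(pheno, file.path(config$out, "phenotypes.tsv"), hash, seed)
    writeArtifact(layout$units, file.path(config$out, "layout.tsv"), hash, seed)
    writeArtifact(state$truthQtls, file.path(config$out, "planted_qtls.tsv"),
                  hash, seed)
    report$simulate <<- list(genotypes = nGenotypes(gobs),
                             markers = nMarkers(gobs),
                             trial_units = nrow(layout$units),
                             check_fraction = layout$checkFraction)
  })

  runStage("qc", function() {
    qc <- config$qc
    rep0 <- NULL
    s1 <- filterMarkers(state$geno, qc$het_max, qc$missing_max,
                        qc$min_minor_hom, report = rep0)
    s2 <- filterGenotypes(s1$geno, qc$het_max, report = s1$report)
    s3 <- detectDuplicates(s2$geno, rAbs = qc$dup_r_abs, k = qc$dup_k,
                           report = s2$report)
    s4 <- nonparentalAlleleCheck(s3$geno, threshold = qc$nonparental_threshold,
                                 report = s3$report)
    imp <- imputeMissing(s4$geno, nTrees = qc$impute_trees,
                         maxIter = qc$impute_max_iter, seed = seed)
    state$geno <- imp$geno
    writeGenotypes(imp$geno, file.path(config$out, "genotypes_qc.csv"))
    writeArtifact(qcSteps(s4$report), file.path(config$out, "qc_report.tsv"),
                  hash, seed)
    report$qc <<- list(steps = qcSteps(s4$report),
                       oob_error = imp$oobError,
                       markers = nMarkers(imp$geno),
                       genotypes = nGenotypes(imp$geno))
  })

  runStage("reposition", function() {
    ## alignment hits for the simulated panel come from the map itself
    map <- markerMap(state$geno)
    hits <- data.frame(query = rownames(map), subject = map$chrom,
                       pident = 100, length = 70, mismatch = 0, gapopen = 0,
                       qstart = 1, qend = 70, sstart = map$bp - 35,
                       send = map$bp + 35, evalue = 0, bitscore = 140)
    rp <- ldBinReposition(state$geno, hits,
                          r2Bin = config$reposition$r2_bin,
                          iterations = config$reposition$iterations)
    state$geno <- rp$geno
    writeArtifact(rp$log, file.path(config$out, "repositioning.tsv"),
                  hash, seed)
    report$reposition <<- list(repositioned = rp$repositioned)
  })

  runStage("structure", function() {
    kids <- !is.na(populations(state$geno))
    sub <- state$geno[kids, ]
    skim <- skimMarkers(sub, config$structure$skim_r)
    pc <- runPcoa(sub[, skim], nAxes = config$structure$n_axes)
    out <- data.frame(genotype = rownames(pc$coordinates), pc$coordinates)
    writeArtifact(out, file.path(config$out, "pcoa.tsv"), hash, seed)
    report$structure <<- list(markers_used = length(skim),
                              pct_variance = pc$percentVariance)
  })

  runStage("blues", function() {
    blues <- list()
    for (tr in unique(state$pheno$trait)) {
      fit <- fitBlues(state$pheno, trait = tr,
                      alpha = config$blues$alpha_elim)
      h2 <- heritability(state$pheno, trait = tr,
                         alpha = config$blues$alpha_elim)
      blues[[tr]] <- data.frame(trait = tr, fit$blues, H2 = h2$H2)
    }
    state$blues <- do.call(rbind, blues)
    writeArtifact(state$blues, file.path(config$out, "blues.tsv"), hash, seed)
    report$blues <<- list(traits = unique(state$pheno$trait),
                          H2 = unique(state$blues[c("trait", "H2")]))
  })

  runStage("gwas", function() {
    kids <- !is.na(populations(state$geno))
    sub <- state$geno[kids, ]
    scans <- list()
    for (tr in unique(state$blues$trait)) {
      b <- state$blues[state$blues$trait == tr, ]
      y <- stats::setNames(b$blue, b$genotype)
      scans[[tr]] <- gwasScan(y, sub, alpha = config$gwas$alpha)
      writeArtifact(scanTable(scans[[tr]]),
                    file.path(config$out, paste0("gwas_", tr, ".tsv")),
                    hash, seed)
    }
    state$scans <- scans
    report$gwas <<- lapply(scans, function(s)
      list(n = scanMeta(s)$n, threshold = scanMeta(s)$threshold,
           lambda = scanMeta(s)$lambda))
  })

  runStage("qtl", function() {
    kids <- !is.na(populations(state$geno))
    sub <- state$geno[kids, ]
    win <- tryCatch(
      ldDecayWindow(sub, criticalR2 = config$qtl$critical_r2)$windowMb,
      error = function(e) 18)
    peaks <- lapply(state$scans, function(s)
      callPeaks(s, windowMb = win))
    for (tr in names(peaks)) if (nrow(peaks[[tr]])) peaks[[tr]]$trait <- tr
    qtls <- mergeQtls(stats::setNames(peaks, paste0("trial1_", names(peaks))),
                      windowMb = win,
                      mergeMultiplier = config$qtl$merge_multiplier,
                      lab = config$qtl$lab)
    state$qtls <- qtls
    writeArtifact(qtls, file.path(config$out, "qtls.tsv"), hash, seed)
    report$qtl <<- list(window_mb = win, n_qtls = nrow(qtls))
  })

  runStage("select", function() {
    ## synthetic selection flags: without breeder data, mark the better
    ## (earlier-flowering) half as selected to exercise the summaries
    b <- state$blues[state$blues$trait == state$blues$trait[1], ]
    sel <- b$blue <= stats::median(b$blue, na.rm = TRUE)
    ped <- state$pedigree[match(b$genotype, state$pedigree$genotype), ]
    tabsel <- data.frame(genotype = b$genotype, selected = sel,
                         tetraploid = ped$tetraploid, diploid = ped$diploid,
                         population = ped$population)
    tabsel <- tabsel[!is.na(tabsel$tetraploid), ]
    summ <- summarizeByBackground(tabsel)
    writeArtifact(summ$byTetraploid,
                  file.path(config$out, "selection_by_tetraploid.tsv"),
                  hash, seed)
    writeArtifact(summ$byLineage,
                  file.path(config$out, "selection_by_diploid.tsv"),
                  hash, seed)
    report$select <<- list(n_selected = sum(tabsel$selected),
                           n_total = nrow(tabsel))
  })

  jsonlite::write_json(report, file.path(config$out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(config$out)
}
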