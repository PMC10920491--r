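#' Fit the augmented-trial mixed model and extract genotype BLUEs
#'
#' Fits, by REML, the half-plot model
#' \deqn{y = \mu + g_i + b_j + r_{jk} + c_{jl} + d_m + t_n + e}
#' with genotype fixed and block, row-in-block, column-in-block, scorer
#' and nursery-lid random. Random terms are then pruned by backward
#' elimination: at each step the term whose removal is least supported by
#' a REML likelihood-ratio test is dropped while its p-value exceeds
#' `alpha` (default 0.10). BLUEs are the estimated genotype fixed effects
#' on the response scale (intercept plus treatment-coded coefficient,
#' reference = `refGenotype` when present). The scorer term is included
#' only when more than one scorer is recorded.
#'
#' @param phenotypes long table from [simulatePhenotypes()] (or the same
#'   shape: genotype, block, row, column, scorer, lid, trait, value).
#' @param trait trait to fit (default: first trait present).
#' @param alpha backward-elimination significance level for random terms.
#' @param refGenotype reference level for the genotype factor (e.g. the
#'   recurrent parent); defaults to the first level.
#' @param includePlotTerm add a random plot term (off by default: halves
#'   are treated as independent units).
#' @return list: `blues` (`data.frame`: genotype, blue, se),
#'   `varianceComponents` (named numeric, incl. `residual`),
#'   `retainedTerms`, `eliminated` (`data.frame`: term, pvalue), `model`
#'   (the final `lmerMod`/`lm` fit).
#' @export
fitBlues <- function(phenotypes, trait = NULL, alpha = 0.10,
                     refGenotype = NULL, includePlotTerm = FALSE) {
  dat <- preparePheno(phenotypes, trait, refGenotype)
  if (nlevels(dat$genotype) < 2) stop("need >= 2 genotypes")
  terms <- c(block = "(1 | block)", row = "(1 | block:row)",
             column = "(1 | block:column)", scorer = "(1 | scorer)",
             lid = "(1 | lid)")
  if (length(unique(dat$scorer)) < 2) terms <- terms[names(terms) != "scorer"]
  if (includePlotTerm) terms <- c(terms, plot = "(1 | plot)")
  sel <- backwardEliminate(dat, terms, alpha)
  fit <- sel$fit
  if (inherits(fit, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    comps <- stats::setNames(vc$vcov, vc$grp)
    names(comps)[names(comps) == "Residual"] <- "residual"
    fe <- lme4::fixef(fit)
    vcovm <- as.matrix(stats::vcov(fit))
  } else {
    comps <- c(residual = stats::sigma(fit)^2)
    fe <- stats::coef(fit)
    vcovm <- stats::vcov(fit)
  }
  lev <- levels(dat$genotype)
  coefName <- paste0("genotype", lev)
  blue <- se <- rep(NA_real_, length(lev))
  inter <- fe[["(Intercept)"]]
  vi <- vcovm["(Intercept)", "(Intercept)"]
  for (i in seq_along(lev)) {
    cn <- coefName[i]
    if (i == 1L) { blue[i] <- inter; se[i] <- sqrt(vi) }
    else if (cn %in% names(fe) && !is.na(fe[[cn]]) && cn %in% rownames(vcovm)) {
      blue[i] <- inter + fe[[cn]]
      se[i] <- sqrt(vi + vcovm[cn, cn] + 2 * vcovm["(Intercept)", cn])
    }
  }
  skipped <- lev[is.na(blue)]
  if (length(skipped))
    warning("non-estimable genotypes skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  list(blues = data.frame(genotype = lev, blue = blue, se = se),
       varianceComponents = comps,
       retainedTerms = sel$retained,
       eliminated = sel$eliminated,
       model = fit)
}

## internal: long-table prep shared by fitBlues/heritability
preparePheno <- function(phenotypes, trait, refGenotype) {
  if (is.null(trait)) trait <- phenotypes$trait[1]
  dat <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ]
  if (!nrow(dat)) stop("no observations for trait ", trait)
  dat$genotype <- factor(dat$genotype)
  if (!is.null(refGenotype) && refGenotype %in% levels(dat$genotype))
    dat$genotype <- stats::relevel(dat$genotype, refGenotype)
  for (f in c("block", "row", "column", "scorer", "lid", "plot"))
    if (f %in% names(dat)) dat[[f]] <- factor(dat[[f]])
  dat
}

## internal: drop random terms whose grouping factor has < 2 levels
estimableTerms <- function(dat, terms) {
  lev <- c(block = length(unique(dat$block)),
           row = length(unique(paste(dat$block, dat$row))),
           column = length(unique(paste(dat$block, dat$column))),
           scorer = length(unique(dat$scorer)),
           lid = length(unique(dat$lid)),
           plot = if ("plot" %in% names(dat)) length(unique(dat$plot)) else 0)
  terms[lev[names(terms)] > 1]
}

## internal: REML backward elimination of random terms (LRT, 1 df)
backwardEliminate <- function(dat, terms, alpha, fixed = "genotype") {
  terms <- estimableTerms(dat, terms)
  fitWith <- function(tms) {
    if (!length(tms)) {
      stats::lm(stats::reformulate(fixed, "value"), data = dat)
    } else {
      f <- stats::as.formula(paste("value ~", fixed, "+",
                                   paste(tms, collapse = " + ")))
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = dat, REML = TRUE,
                   control = lme4::lmerControl(check.conv.singular = "ignore",
                                               calc.derivs = FALSE))))
    }
  }
  current <- terms
  fit <- fitWith(current)
  elim <- data.frame(term = character(), pvalue = numeric())
  while (length(current)) {
    ll <- as.numeric(stats::logLik(fit))
    pv <- vapply(names(current), function(nm) {
      red <- fitWith(current[names(current) != nm])
      stat <- max(0, 2 * (ll - as.numeric(stats::logLik(red))))
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }, numeric(1))
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    elim <- rbind(elim, data.frame(term = names(current)[worst],
                                   pvalue = pv[worst]))
    current <- current[-worst]
    fit <- fitWith(current)
  }
  list(fit = fit, retained = names(current), eliminated = elim)
}

#' Broad-sense heritability from the final trial model
#'
#' Refits the backward-eliminated model with genotype as a random term and
#' returns \eqn{H^2 = V_g / (V_g + V_e)}, the genotypic variance over the
#' sum of genotypic and residual variance.
#'
#' @inheritParams fitBlues
#' @return list: `H2`, `Vg`, `Ve`, `retainedTerms`.
#' @export
heritability <- function(phenotypes, trait = NULL, alpha = 0.10) {
  dat <- preparePheno(phenotypes, trait, NULL)
  terms <- c(block = "(1 | block)", row = "(1 | block:row)",
             column = "(1 | block:column)", scorer = "(1 | scorer)",
             lid = "(1 | lid)")
  if (length(unique(dat$scorer)) < 2) terms <- terms[names(terms) != "scorer"]
  sel <- backwardEliminate(dat, terms, alpha)
  tms <- c("(1 | genotype)", unname(terms[sel$retained]))
  f <- stats::as.formula(paste("value ~ 1 +", paste(tms, collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(f, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vg <- vc$vcov[vc$grp == "genotype"]
  ve <- vc$vcov[vc$grp == "Residual"]
  if (vg + ve <= 0) stop("Vg + Ve is zero; heritability undefined")
  list(H2 = vg / (vg + ve), Vg = vg, Ve = ve, retainedTerms = sel$retained)
}

#' Cross-trial trait correlations
#'
#' Pairwise-complete Pearson correlations between trait/trial series over
#' shared genotypes, with two-sided tests; cells with p > `maskAlpha` are
#' flagged for masking in displays.
#'
#' @param tables named list of `data.frame`s with columns `genotype` and
#'   `value` (one per trait-trial series, e.g. BLUE tables).
#' @param maskAlpha significance level for the display mask (default 0.05).
#' @return list of matrices: `r`, `p`, `n`, `masked` (logical).
#' @export
crossTrialCorrelation <- function(tables, maskAlpha = 0.05) {
  k <- length(tables)
  nm <- names(tables)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    m <- merge(tables[[i]], tables[[j]], by = "genotype")
    n[i, j] <- n[j, i] <- nrow(m)
    if (nrow(m) < 3) next
    if (stats::sd(m$value.x) == 0 || stats::sd(m$value.y) == 0)
      stop("zero-variance series: ", nm[i], " vs ", nm[j])
    ct <- stats::cor.test(m$value.x, m$value.y)
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = n, masked = !is.na(p) & p > maskAlpha)
}

#' Welch two-sample t-test between genotype groups
#'
#' Used both for selected-versus-unselected genotype comparisons and for
#' contrasting homozygous allele classes at a QTL.
#'
#' @param values numeric vector.
#' @param mask logical vector: `TRUE` = group 1, `FALSE` = group 2.
#' @return list: `t`, `df`, `p`, `means` (group means).
#' @export
compareGroups <- function(values, mask) {
  stopifnot(length(values) == length(mask))
  g1 <- values[mask & !is.na(values)]
  g2 <- values[!mask & !is.na(values)]
  if (length(g1) < 2 || length(g2) < 2) stop("both groups need >= 2 members")
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0 && mean(g1) == mean(g2))
    return(list(t = 0, df = length(g1) + length(g2) - 2, p = 1,
                means = c(mean(g1), mean(g2))))
  tt <- stats::t.test(g1, g2)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = unname(tt$estimate))
}
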