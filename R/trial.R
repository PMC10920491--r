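#' Build an augmented half-plot trial layout
#'
#' Lays out a field trial in which every six-row plot is split into two
#' independently sown experimental units (half-plots). Replicated check
#' varieties (and any other replicated entries) are distributed randomly
#' across incomplete blocks first; unreplicated entries fill the remaining
#' units; a replicated genotype never occupies both halves of one plot.
#' If the entry list falls short of the available units the shortfall is
#' padded with filler units of a designated variety, flagged `is_fill`
#' (fillers are excluded from the reported check-entry fraction).
#'
#' @param entryIds character vector of unreplicated genotype ids.
#' @param checks `data.frame` with columns `id` and `reps` (replicate count
#'   per check variety); may have zero rows.
#' @param replicated optional extra replicated (non-check) entries,
#'   `data.frame` with `id` and `reps`.
#' @param nPlots number of two-unit plots; defaults to the smallest count
#'   that fits all entries.
#' @param blockRange integer length-2: min/max plots per block
#'   (default `c(144, 156)`, shrunk automatically for small trials).
#' @param nScorers number of scorers; units are split into contiguous
#'   scorer stints.
#' @param lidSize plots per nursery drilling lid (default 20).
#' @param fillId variety used for filler units (default: last check id, or
#'   `"FILL"` when there are no checks).
#' @param seed optional RNG seed.
#' @return list with `units` (`data.frame`: unit_id, plot, half, block,
#'   row, column, lid, scorer, genotype, is_check, is_fill) and
#'   `checkFraction` (check units / total units, fillers excluded).
#' @examples
#' lay <- buildTrialLayout(sprintf("g%02d", 1:18),
#'                         checks = data.frame(id = "CHK", reps = 6),
#'                         seed = 1)
#' lay$checkFraction
#' @export
buildTrialLayout <- function(entryIds, checks = data.frame(id = character(), reps = integer()),
                             replicated = NULL, nPlots = NULL,
                             blockRange = c(144, 156), nScorers = 1,
                             lidSize = 20, fillId = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repTab <- checks
  if (!is.null(replicated) && nrow(replicated))
    repTab <- rbind(repTab, replicated)
  if (nrow(repTab) && any(repTab$reps < 1)) stop("replicate counts must be >= 1")
  nRep <- if (nrow(repTab)) sum(repTab$reps) else 0L
  nEntries <- length(entryIds) + nRep
  if (is.null(nPlots)) nPlots <- ceiling(nEntries / 2)
  nUnits <- 2L * nPlots
  if (nEntries > nUnits) stop("more entries than available half-plot units")
  if (nrow(repTab) && max(repTab$reps) > nPlots)
    stop("infeasible replicate counts: more replicates than plots")
  if (is.null(fillId))
    fillId <- if (nrow(checks)) checks$id[nrow(checks)] else "FILL"

  ## blocks of plots within the configured size range
  br <- pmin(blockRange, nPlots)
  nBlocks <- max(1L, round(nPlots / mean(br)))
  sizes <- rep(floor(nPlots / nBlocks), nBlocks)
  extra <- nPlots - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  block <- rep(seq_len(nBlocks), sizes)
  ## rows/columns as a grid within each block
  rowcol <- lapply(sizes, function(s) {
    nr <- max(1L, floor(sqrt(s)))
    idx <- seq_len(s) - 1L
    data.frame(row = idx %/% nr + 1L, column = idx %% nr + 1L)
  })
  rowcol <- do.call(rbind, rowcol)

  labels <- c(if (nrow(repTab)) rep(repTab$id, repTab$reps), entryIds)
  labels <- c(labels, rep(fillId, nUnits - length(labels)))
  isCheck <- labels %in% checks$id
  isFill <- seq_along(labels) > nEntries

  ord <- sample.int(nUnits)
  labels <- labels[ord]; isCheck <- isCheck[ord]; isFill <- isFill[ord]
  plot <- rep(seq_len(nPlots), each = 2L)
  ## repair plots whose two halves carry the same replicated genotype
  repIds <- unique(repTab$id)
  mate <- function(j) ifelse(j %% 2L == 0L, j - 1L, j + 1L)
  for (tries in 1:100) {
    a <- seq(1L, nUnits, by = 2L)
    bad <- a[labels[a] == labels[a + 1L] & labels[a] %in% repIds]
    if (!length(bad)) break
    for (j in bad + 1L) {
      ## swap the second half with a unit whose plot-mate differs
      cand <- which(labels != labels[j] & labels[mate(seq_len(nUnits))] != labels[j])
      cand <- setdiff(cand, c(j, j - 1L))
      cand <- cand[labels[mate(cand)] != labels[cand] |
                   !(labels[cand] %in% repIds)]
      if (!length(cand)) stop("infeasible replicate counts: cannot separate replicates")
      k <- if (length(cand) == 1L) cand else sample(cand, 1L)
      tmp <- labels[j]; labels[j] <- labels[k]; labels[k] <- tmp
      tmpc <- isCheck[j]; isCheck[j] <- isCheck[k]; isCheck[k] <- tmpc
      tmpf <- isFill[j]; isFill[j] <- isFill[k]; isFill[k] <- tmpf
    }
  }
  units <- data.frame(
    unit_id = sprintf("U%05d", seq_len(nUnits)),
    plot = plot,
    half = rep(1:2, nPlots),
    block = block[plot],
    row = rowcol$row[plot],
    column = rowcol$column[plot],
    lid = (plot - 1L) %/% lidSize + 1L,
    scorer = paste0("S", pmin(nScorers, (plot - 1L) %/%
                      max(1L, ceiling(nPlots / nScorers)) + 1L)),
    genotype = labels,
    is_check = isCheck,
    is_fill = isFill)
  list(units = units,
       checkFraction = sum(units$is_check & !units$is_fill) / nUnits)
}

#' Default trait model for phenotype simulation
#'
#' Trait means follow the recurrent parent's observed values in the
#' motivating panel: flowering time (`Ft`) 215.9 days, plant height (`Ph`)
#' 71.8 cm, yellow-rust cover (`Yr`) 2 percent. Each trait carries planted
#' QTLs (additive effect per donor-allele dose), a polygenic genotype
#' variance and trial-effect variances for block, row, column, scorer,
#' lid and residual.
#'
#' @param qtls named list per trait: `data.frame` with columns `marker`
#'   and `effect` (may be empty).
#' @param mu named numeric of trait means.
#' @param polygenicVar,residualVar named numerics per trait.
#' @param trialVar named list per trait of variances for `block`, `row`,
#'   `column`, `scorer`, `lid`.
#' @return list (trait model).
#' @export
defaultTraitModel <- function(qtls = NULL,
                              mu = c(Ft = 215.9, Ph = 71.8, Yr = 2),
                              polygenicVar = c(Ft = 4, Ph = 16, Yr = 4),
                              residualVar = c(Ft = 1, Ph = 4, Yr = 4),
                              trialVar = NULL) {
  traits <- names(mu)
  if (is.null(qtls)) qtls <- stats::setNames(
    rep(list(data.frame(marker = character(), effect = numeric())),
        length(traits)), traits)
  if (is.null(trialVar)) trialVar <- stats::setNames(rep(list(
    c(block = 1, row = 0.25, column = 0.25, scorer = 0, lid = 0.25)),
    length(traits)), traits)
  list(traits = traits, mu = mu, qtls = qtls,
       polygenicVar = polygenicVar, residualVar = residualVar,
       trialVar = trialVar)
}

#' Simulate half-plot phenotypes over a trial layout
#'
#' Unit value = trait mean + planted QTL effects x dosage + polygenic
#' genotype value + block + row-in-block + column-in-block + scorer + lid
#' random effects + residual, each random term drawn from its configured
#' variance. Check varieties receive fixed true genetic values
#' (`checkValues`, defaulting to the trait mean), so checks inform the
#' spatial terms only.
#'
#' @param geno [GenotypeData-class] covering every non-check layout entry.
#' @param model trait model from [defaultTraitModel()].
#' @param layout trial layout from [buildTrialLayout()].
#' @param checkValues optional named list per trait of named check values.
#' @param seed optional RNG seed.
#' @return long `data.frame`: unit_id, plot, half, block, row, column,
#'   lid, scorer, genotype, is_check, trait, value.
#' @export
simulatePhenotypes <- function(geno, model, layout, checkValues = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- layout$units
  isChk <- units$is_check | units$is_fill
  missing <- setdiff(units$genotype[!isChk], genotypeIds(geno))
  if (length(missing))
    stop("layout genotypes absent from genotype data: ",
         paste(utils::head(missing, 5), collapse = ", "))
  d <- dosages(geno)
  out <- list()
  for (tr in model$traits) {
    g <- units$genotype
    base <- rep(model$mu[[tr]], nrow(units))
    q <- model$qtls[[tr]]
    if (nrow(q)) {
      bad <- setdiff(q$marker, markerIds(geno))
      if (length(bad)) stop("planted QTL marker not in map: ", bad[1])
      for (i in seq_len(nrow(q))) {
        dos <- d[, q$marker[i]]
        base[!isChk] <- base[!isChk] + q$effect[i] * dos[g[!isChk]]
      }
    }
    ids <- unique(g[!isChk])
    poly <- stats::setNames(stats::rnorm(length(ids), 0,
                    sqrt(model$polygenicVar[[tr]])), ids)
    base[!isChk] <- base[!isChk] + poly[g[!isChk]]
    if (!is.null(checkValues[[tr]])) {
      cv <- checkValues[[tr]]
      hit <- isChk & g %in% names(cv)
      base[hit] <- cv[g[hit]]
    }
    v <- model$trialVar[[tr]]
    ranef <- function(f, var) {
      lev <- unique(f)
      stats::setNames(stats::rnorm(length(lev), 0, sqrt(var)), lev)[f]
    }
    base <- base +
      ranef(paste0("b", units$block), v[["block"]]) +
      ranef(paste(units$block, units$row), v[["row"]]) +
      ranef(paste(units$block, units$column), v[["column"]]) +
      ranef(units$scorer, v[["scorer"]]) +
      ranef(paste0("l", units$lid), v[["lid"]]) +
      stats::rnorm(nrow(units), 0, sqrt(model$residualVar[[tr]]))
    out[[tr]] <- data.frame(units[c("unit_id", "plot", "half", "block",
                                    "row", "column", "lid", "scorer",
                                    "genotype", "is_check")],
                            trait = tr, value = base)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
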