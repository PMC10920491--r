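#' Build a genetic/physical marker map
#'
#' Creates a marker map over a configurable set of chromosomes with both
#' physical (bp, 1-based) and genetic (cM) coordinates. By default markers
#' are uniformly spaced in bp and cM is linearly interpolated from bp;
#' a per-chromosome cM profile can be supplied to emulate pericentromeric
#' recombination suppression.
#'
#' @param nChrom number of chromosomes (max 21; named 1A..7D in wheat order).
#' @param markersPerChrom markers per chromosome (>= 2), scalar or vector.
#' @param lengthBp physical chromosome length in bp, scalar or vector.
#' @param lengthCM genetic chromosome length in cM, scalar or vector.
#' @param chromNames optional chromosome names; defaults to the hexaploid
#'   wheat convention `1A, 1B, 1D, ..., 7D`.
#' @param cmProfile optional function `f(relbp) -> relcM` mapping relative
#'   physical position in `[0, 1]` to relative genetic position in `[0, 1]`,
#'   monotone non-decreasing with `f(0)=0`, `f(1)=1`; applied to every
#'   chromosome (e.g. a sigmoid for centromeric suppression).
#' @return `data.frame` with columns `marker`, `chrom`, `bp`, `cM` and
#'   attribute `chromLen` (per-chromosome bp/cM lengths).
#' @examples
#' map <- makeGeneticMap(nChrom = 1, markersPerChrom = 3,
#'                       lengthBp = 3e8, lengthCM = 150)
#' map$bp  # 1, 150000001, 300000000
#' @export
makeGeneticMap <- function(nChrom = 21, markersPerChrom = 100,
                           lengthBp = 6e8, lengthCM = 150,
                           chromNames = NULL, cmProfile = NULL) {
  if (nChrom < 1 || nChrom > 21) stop("nChrom must be in 1..21")
  if (any(lengthBp <= 0) || any(lengthCM <= 0))
    stop("chromosome lengths must be positive")
  if (any(markersPerChrom < 2)) stop("need >= 2 markers per chromosome")
  if (is.null(chromNames)) {
    chromNames <- as.vector(t(outer(1:7, c("A", "B", "D"), paste0)))[seq_len(nChrom)]
  }
  if (anyDuplicated(chromNames)) stop("chromosome names must be unique")
  m <- rep_len(markersPerChrom, nChrom)
  lb <- rep_len(lengthBp, nChrom)
  lc <- rep_len(lengthCM, nChrom)
  rows <- lapply(seq_len(nChrom), function(k) {
    bp <- round(seq(1, lb[k], length.out = m[k]))
    if (anyDuplicated(bp)) stop("chromosome too short for requested marker count")
    rel <- (bp - 1) / (lb[k] - 1)
    relc <- if (is.null(cmProfile)) rel else cmProfile(rel)
    if (is.unsorted(relc)) stop("cmProfile must be monotone non-decreasing")
    data.frame(
      marker = sprintf("M%s_%04d", chromNames[k], seq_len(m[k])),
      chrom = chromNames[k], bp = bp, cM = relc * lc[k])
  })
  map <- do.call(rbind, rows)
  rownames(map) <- map$marker
  attr(map, "chromLen") <- data.frame(chrom = chromNames, bp = lb, cM = lc)
  map
}

#' Simulate one meiotic gamete under the Haldane model
#'
#' Crossovers occur as a Poisson process along the genetic map with no
#' interference, so the recombination fraction between loci `d` cM apart is
#' Haldane's \eqn{\frac{1}{2}(1 - e^{-2d/100})} in expectation. The gamete
#' starts from a random parental haplotype per chromosome and switches at
#' each crossover.
#'
#' @param hap1,hap2 numeric/integer allele vectors (one entry per map
#'   marker, map order).
#' @param map marker map with columns `chrom` and `cM` covering the
#'   haplotypes.
#' @return Integer vector: the gamete's allele at every marker.
#' @examples
#' map <- makeGeneticMap(1, 10, 1e8, 100)
#' g <- simulateMeiosis(rep(0L, 10), rep(1L, 10), map)
#' @export
simulateMeiosis <- function(hap1, hap2, map) {
  stopifnot(length(hap1) == nrow(map), length(hap2) == nrow(map))
  phase <- gametePhase(map)
  ifelse(phase == 0L, hap1, hap2)
}

## internal: phase vector (0 = hap1, 1 = hap2) for one gamete across the map
gametePhase <- function(map) {
  phase <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    cm <- map$cM[idx]
    L <- max(cm) - min(cm)
    nxo <- stats::rpois(1, L / 100)
    start <- sample.int(2L, 1L) - 1L
    if (nxo == 0L) {
      phase[idx] <- start
    } else {
      xo <- sort(stats::runif(nxo, min(cm), max(cm)))
      crossed <- vapply(cm, function(p) sum(xo < p), numeric(1))
      phase[idx] <- (start + crossed) %% 2L
    }
  }
  as.integer(phase)
}
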