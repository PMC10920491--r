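#' @import methods
NULL

#' Genotype dosage data with marker map and population assignments
#'
#' The central container of the package: a genotypes-by-markers matrix of
#' biallelic SNP dosages together with the physical marker map and the
#' nested-population membership of every genotype. Dosage is the count of
#' the donor (alternative) allele, with the recurrent parent ('Robigus' in
#' the motivating panel) as the reference: 0 = homozygous recurrent,
#' 2 = homozygous donor, 1 = heterozygous, `NA` = missing.
#'
#' @slot dosage integer matrix, genotypes in rows, markers in columns.
#' @slot map `data.frame` with one row per marker (rownames = marker ids)
#'   and columns `chrom` (character), `bp` (1-based physical position),
#'   optional `cM`, and `source` (placement provenance: one of
#'   `"curated"`, `"hit_median"`, `"correlation"`, `"ld_bin"`, or `NA`
#'   for unplaced markers).
#' @slot population factor of length `nrow(dosage)`; nested-population id
#'   per genotype, `NA` for parents/checks.
#' @slot metadata list; recognised entries include `recurrent` (genotype id
#'   of the recurrent parent), `donors` (named character vector mapping
#'   population id to donor genotype id), and free-form provenance.
#'
#' @seealso [GenotypeData()], [dosages()], [markerMap()], [populations()]
#' @export
setClass("GenotypeData",
  slots = c(
    dosage = "matrix",
    map = "data.frame",
    population = "factor",
    metadata = "list"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosage
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage matrix must have genotype rownames and marker colnames")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "genotype ids must be unique")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "marker ids must be unique")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (nrow(object@map) != ncol(d))
    msg <- c(msg, "map must have one row per marker")
  if (nrow(object@map) && !identical(rownames(object@map), colnames(d)))
    msg <- c(msg, "map rownames must equal marker ids in column order")
  if (length(object@population) != nrow(d))
    msg <- c(msg, "population must have one entry per genotype")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage genotypes x markers matrix of 0/1/2/NA dosages.
#' @param map marker map `data.frame` (see [GenotypeData-class]); if `NULL`
#'   an unplaced map is created.
#' @param population factor/character of nested-population ids per genotype
#'   (`NA` for parents); recycled `NA` if omitted.
#' @param metadata list of provenance entries.
#' @return A [GenotypeData-class] object.
#' @examples
#' d <- matrix(c(0L, 2L, 1L, 0L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("m1", "m2")))
#' GenotypeData(d)
#' @export
GenotypeData <- function(dosage, map = NULL, population = NULL, metadata = list()) {
  storage.mode(dosage) <- "integer"
  if (is.null(map)) {
    map <- data.frame(chrom = rep(NA_character_, ncol(dosage)),
                      bp = rep(NA_real_, ncol(dosage)),
                      source = rep(NA_character_, ncol(dosage)),
                      row.names = colnames(dosage))
  }
  if (!"source" %in% names(map)) map$source <- "curated"
  if (is.null(population)) population <- rep(NA_character_, nrow(dosage))
  population <- as.factor(population)
  new("GenotypeData", dosage = dosage, map = map,
      population = population, metadata = metadata)
}

#' Per-filter bookkeeping for a genotype QC cascade
#'
#' Records, for each QC stage, how many markers/genotypes were removed and
#' retained, plus stage-specific detail (flagged pairs, flagged genotypes).
#'
#' @slot steps `data.frame` with columns `stage`, `axis` ("marker" or
#'   "genotype"), `removed`, `retained`.
#' @slot details named list of per-stage detail objects.
#' @export
setClass("QcReport",
  slots = c(steps = "data.frame", details = "list"),
  prototype = prototype(
    steps = data.frame(stage = character(), axis = character(),
                       removed = integer(), retained = integer()),
    details = list()
  )
)

setValidity("QcReport", function(object) {
  need <- c("stage", "axis", "removed", "retained")
  if (!all(need %in% names(object@steps)))
    return("steps must have columns stage, axis, removed, retained")
  TRUE
})

#' Result of a single-trait mixed-model association scan
#'
#' @slot table `data.frame` with one row per tested marker: `marker`,
#'   `chrom`, `bp`, `effect` (additive effect of one donor-allele dose,
#'   recurrent parent as reference), `se`, `pvalue`, `score`
#'   (-log10 p-value), `minor_hom` (minor-homozygote count).
#' @slot meta list: `n` genotypes, `threshold` (-log10 scale), `lambda`
#'   (genomic inflation factor), `trait`, `trial`, `method` notes.
#' @export
setClass("GwasScan", slots = c(table = "data.frame", meta = "list"))

setValidity("GwasScan", function(object) {
  need <- c("marker", "chrom", "bp", "effect", "pvalue", "score")
  if (!all(need %in% names(object@table)))
    return("scan table missing required columns")
  sc <- object@table$score
  if (any(!is.na(sc) & sc < 0)) return("scores must be >= 0")
  TRUE
})
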