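#' @include AllGenerics.R
NULL

#' @rdname GenotypeData-accessors
setMethod("dosages", "GenotypeData", function(x) x@dosage)

#' @rdname GenotypeData-accessors
setMethod("markerMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData-accessors
setMethod("markerMap<-", "GenotypeData", function(x, value) {
  stopifnot(nrow(value) == ncol(x@dosage),
            identical(rownames(value), colnames(x@dosage)))
  x@map <- value
  validObject(x)
  x
})

#' @rdname GenotypeData-accessors
setMethod("populations", "GenotypeData", function(x) {
  stats::setNames(x@population, rownames(x@dosage))
})

#' @rdname GenotypeData-accessors
setMethod("genotypeIds", "GenotypeData", function(x) rownames(x@dosage))

#' @rdname GenotypeData-accessors
setMethod("markerIds", "GenotypeData", function(x) colnames(x@dosage))

#' @rdname GenotypeData-accessors
setMethod("nGenotypes", "GenotypeData", function(x) nrow(x@dosage))

#' @rdname GenotypeData-accessors
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@dosage))

#' Subset a GenotypeData object
#'
#' `x[i, j]` subsets genotypes (`i`) and markers (`j`) keeping map and
#' population assignments aligned.
#'
#' @param x A [GenotypeData-class].
#' @param i,j genotype and marker indices (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; the result is always `GenotypeData`.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  d <- x@dosage[i, j, drop = FALSE]
  new("GenotypeData",
      dosage = d,
      map = x@map[j, , drop = FALSE],
      population = droplevels(x@population[i]),
      metadata = x@metadata)
})

setMethod("show", "GenotypeData", function(object) {
  d <- object@dosage
  miss <- mean(is.na(d))
  npop <- nlevels(object@population)
  placed <- sum(!is.na(object@map$chrom))
  cat("GenotypeData:", nrow(d), "genotypes x", ncol(d), "markers\n")
  cat(sprintf("  placed markers: %d/%d; missing calls: %.2f%%\n",
              placed, ncol(d), 100 * miss))
  cat("  nested populations:", npop, "\n")
  if (!is.null(object@metadata$recurrent))
    cat("  recurrent parent:", object@metadata$recurrent, "\n")
  invisible(object)
})

#' @rdname scan-accessors
setMethod("scanTable", "GwasScan", function(x) x@table)

#' @rdname scan-accessors
setMethod("scanMeta", "GwasScan", function(x) x@meta)

setMethod("show", "GwasScan", function(object) {
  tab <- object@table
  cat("GwasScan:", nrow(tab), "markers")
  if (!is.null(object@meta$trait)) cat(", trait", object@meta$trait)
  if (!is.null(object@meta$n)) cat(",", object@meta$n, "genotypes")
  cat("\n")
  if (!is.null(object@meta$threshold))
    cat(sprintf("  threshold (-log10 P): %.2f; markers above: %d\n",
                object@meta$threshold,
                sum(tab$score >= object@meta$threshold, na.rm = TRUE)))
  if (!is.null(object@meta$lambda))
    cat(sprintf("  genomic inflation lambda: %.3f\n", object@meta$lambda))
  invisible(object)
})

#' @rdname scan-accessors
setMethod("qcSteps", "QcReport", function(x) x@steps)

setMethod("show", "QcReport", function(object) {
  cat("QcReport with", nrow(object@steps), "stages\n")
  if (nrow(object@steps)) print(object@steps, row.names = FALSE)
  invisible(object)
})

## internal: append one stage to a QcReport
qcAppend <- function(report, stage, axis, removed, retained, detail = NULL) {
  if (is.null(report)) report <- new("QcReport")
  report@steps <- rbind(report@steps, data.frame(
    stage = stage, axis = axis,
    removed = as.integer(removed), retained = as.integer(retained)))
  if (!is.null(detail)) report@details[[stage]] <- detail
  report
}
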