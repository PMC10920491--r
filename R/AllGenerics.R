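#' @include AllClasses.R
NULL

#' Accessors for GenotypeData
#'
#' `dosages()` returns the genotypes-by-markers dosage matrix, `markerMap()`
#' the marker map, `populations()` the nested-population factor,
#' `genotypeIds()`/`markerIds()` the dimension names, and
#' `nGenotypes()`/`nMarkers()` the dimensions.
#'
#' @param x A [GenotypeData-class] object.
#' @param value Replacement value.
#' @return The requested component.
#' @name GenotypeData-accessors
#' @aliases dosages markerMap populations genotypeIds markerIds nGenotypes
#'   nMarkers markerMap<-
NULL

#' @rdname GenotypeData-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerMap<-", function(x, value) standardGeneric("markerMap<-"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("nGenotypes", function(x) standardGeneric("nGenotypes"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' Scan-result accessors
#'
#' `scanTable()` returns the per-marker result table of a [GwasScan-class];
#' `scanMeta()` its metadata list; `qcSteps()` the stage table of a
#' [QcReport-class].
#'
#' @param x A [GwasScan-class] or [QcReport-class] object.
#' @return A `data.frame` or list.
#' @name scan-accessors
#' @aliases scanTable scanMeta qcSteps
NULL

#' @rdname scan-accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))

#' @rdname scan-accessors
#' @export
setGeneric("scanMeta", function(x) standardGeneric("scanMeta"))

#' @rdname scan-accessors
#' @export
setGeneric("qcSteps", function(x) standardGeneric("qcSteps"))
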