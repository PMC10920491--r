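#' Summarize breeder selections by donor background
#'
#' Tabulates, for each tetraploid donor and each diploid lineage, how many
#' genotypes were available, how many were selected by at least one
#' breeder, and the percent selected (one decimal). Unknown backgrounds
#' are bucketed as `"unknown"`.
#'
#' @param table selection table: `data.frame` with columns `genotype`,
#'   `selected` (logical or selected-by count), `tetraploid`, and either
#'   `lineage` or `diploid`.
#' @return list of `data.frame`s `byTetraploid` and `byLineage`, each:
#'   background, n_available, n_selected, pct_selected.
#' @export
summarizeByBackground <- function(table) {
  sel <- if (is.logical(table$selected)) table$selected else table$selected > 0
  one <- function(bg) {
    bg <- as.character(bg)
    bg[is.na(bg) | bg == ""] <- "unknown"
    agg <- stats::aggregate(sel, list(background = bg),
                            function(s) c(n = length(s), k = sum(s)))
    data.frame(background = agg$background,
               n_available = agg$x[, "n"],
               n_selected = agg$x[, "k"],
               pct_selected = round(100 * agg$x[, "k"] / agg$x[, "n"], 1))
  }
  out <- list(byTetraploid = one(table$tetraploid))
  lin <- if ("lineage" %in% names(table)) table$lineage else table$diploid
  out$byLineage <- one(lin)
  out
}

#' Allele enrichment among selected genotypes
#'
#' Cross-tabulates carrier status at a marker against selection status,
#' restricted to populations segregating at the locus, and reports carrier
#' proportions per selection class. "Carrier" defaults to homozygous for
#' the donor allele (dosage 2); `mode = "dominant"` counts dosage >= 1.
#' Optionally contrasts trait means between homozygous allele classes via
#' [compareGroups()].
#'
#' @param table selection table (`genotype`, `selected`, optional
#'   `population`).
#' @param dosage named dosage vector at the marker (0/1/2).
#' @param mode `"homozygous"` (dosage 2; default) or `"dominant"`
#'   (dosage >= 1).
#' @param restrictSegregating drop populations monomorphic at the locus
#'   (default `TRUE` when `population` present).
#' @param traitValues optional named trait vector for the allele-class
#'   t-test (homozygous classes only).
#' @return list: `counts` (2x2 matrix carriers x selection), `proportions`
#'   (percent carriers among selected / unselected, one decimal),
#'   `nSegregatingPopulations`, optional `traitTest`.
#' @export
alleleEnrichment <- function(table, dosage, mode = c("homozygous", "dominant"),
                             restrictSegregating = TRUE, traitValues = NULL) {
  mode <- match.arg(mode)
  tab <- table[table$genotype %in% names(dosage), ]
  dos <- dosage[tab$genotype]
  if (length(unique(stats::na.omit(dos))) < 2)
    stop("marker is monomorphic in the supplied genotypes")
  nseg <- NA_integer_
  if (restrictSegregating && "population" %in% names(tab)) {
    segPop <- tapply(dos, tab$population,
                     function(v) length(unique(stats::na.omit(v))) > 1)
    segPop <- names(segPop)[segPop %in% TRUE]
    nseg <- length(segPop)
    keep <- tab$population %in% segPop
    tab <- tab[keep, ]; dos <- dos[keep]
  }
  sel <- if (is.logical(tab$selected)) tab$selected else tab$selected > 0
  carrier <- if (mode == "homozygous") dos == 2L else dos >= 1L
  counts <- matrix(c(sum(carrier & sel, na.rm = TRUE),
                     sum(!carrier & sel, na.rm = TRUE),
                     sum(carrier & !sel, na.rm = TRUE),
                     sum(!carrier & !sel, na.rm = TRUE)), 2, 2,
                   dimnames = list(c("carrier", "non_carrier"),
                                   c("selected", "unselected")))
  props <- round(100 * counts["carrier", ] / colSums(counts), 1)
  out <- list(counts = counts, proportions = props,
              nSegregatingPopulations = nseg)
  if (!is.null(traitValues)) {
    hom <- dos %in% c(0L, 2L)
    out$traitTest <- compareGroups(traitValues[tab$genotype][hom],
                                   (dos == 2L)[hom])
  }
  out
}
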