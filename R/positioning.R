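#' Position markers from tabular alignment hits
#'
#' For each query marker the best hit is chosen by bitscore (ties: lower
#' e-value, then longer alignment, then lexicographic chromosome) and the
#' position is the midpoint of the alignment,
#' `floor((start + stop) / 2)` — orientation-independent. Markers with no
#' hits stay unplaced.
#'
#' @param hits hit table from [readHits()] (12-column tabular alignment
#'   format).
#' @param map optional existing marker map `data.frame` to update (rows =
#'   markers); entries are only filled where `chrom` is `NA` unless
#'   `overwrite = TRUE`.
#' @param overwrite replace existing placements?
#' @return If `map` is `NULL`, a `data.frame` (marker, chrom, bp, source);
#'   otherwise the updated map.
#' @export
positionFromHits <- function(hits, map = NULL, overwrite = FALSE) {
  if (!nrow(hits)) {
    res <- data.frame(marker = character(), chrom = character(),
                      bp = numeric(), source = character())
  } else {
    ord <- order(hits$query, -hits$bitscore, hits$evalue,
                 -hits$length, hits$subject)
    best <- hits[ord, ][!duplicated(hits$query[ord]), ]
    res <- data.frame(marker = best$query, chrom = best$subject,
                      bp = floor((best$sstart + best$send) / 2),
                      source = "hit_median")
  }
  if (is.null(map)) return(res)
  idx <- match(res$marker, rownames(map))
  ok <- !is.na(idx) & (overwrite | is.na(map$chrom[idx]))
  map$chrom[idx[ok]] <- res$chrom[ok]
  map$bp[idx[ok]] <- res$bp[ok]
  map$source[idx[ok]] <- "hit_median"
  map
}

## internal: squared Pearson correlation between one marker and a set,
## pairwise-complete
r2With <- function(d, j, cols) {
  suppressWarnings(stats::cor(d[, j], d[, cols, drop = FALSE],
                              use = "pairwise.complete.obs"))[1, ]^2
}

#' Place unmapped markers by correlation with mapped markers
#'
#' For each unplaced marker, the placed marker with the highest dosage
#' R-squared is its guide; if the unplaced marker has any alignment hit on
#' the guide's chromosome, it adopts the hit (midpoint) nearest to the
#' guide's position. A minimum-R-squared floor guards against placing by
#' noise; markers with no qualifying hit remain unplaced (no fallback to
#' other chromosomes).
#'
#' @param geno [GenotypeData-class] carrying the map to repair.
#' @param hits hit table from [readHits()].
#' @param minR2 minimum R-squared with the best guide (default 0.2).
#' @return list: `geno` (updated map), `placed` (`data.frame`: marker,
#'   chrom, bp, guide, r2).
#' @export
positionByCorrelation <- function(geno, hits, minR2 = 0.2) {
  map <- markerMap(geno)
  d <- dosages(geno)
  unplaced <- which(is.na(map$chrom))
  placed <- which(!is.na(map$chrom))
  res <- list()
  if (length(unplaced) && length(placed)) {
    for (j in unplaced) {
      r2 <- r2With(d, j, placed)
      if (all(is.na(r2))) next
      best <- placed[which.max(r2)]
      if (is.na(max(r2, na.rm = TRUE)) || max(r2, na.rm = TRUE) < minR2) next
      gchrom <- map$chrom[best]
      h <- hits[hits$query == rownames(map)[j] & hits$subject == gchrom, ,
                drop = FALSE]
      if (!nrow(h)) next
      mid <- floor((h$sstart + h$send) / 2)
      pos <- mid[which.min(abs(mid - map$bp[best]))]
      map$chrom[j] <- gchrom; map$bp[j] <- pos; map$source[j] <- "correlation"
      res[[length(res) + 1L]] <- data.frame(
        marker = rownames(map)[j], chrom = gchrom, bp = pos,
        guide = rownames(map)[best], r2 = max(r2, na.rm = TRUE))
    }
  }
  markerMap(geno) <- map
  list(geno = geno,
       placed = if (length(res)) do.call(rbind, res)
                else data.frame(marker = character(), chrom = character(),
                                bp = numeric(), guide = character(),
                                r2 = numeric()))
}

#' Two-pass LD-bin chromosome repositioning
#'
#' Markers are grouped into bins as connected components of the
#' R-squared > `r2Bin` linkage-disequilibrium graph. Within a bin, a
#' marker sitting on a different chromosome from the bin's strict modal
#' chromosome (computed over the *other* bin members) is repositioned
#' using its best alignment hit on the modal chromosome; when no strict
#' mode exists, the chromosome of the single highest-LD partner guides
#' instead. Markers without a hit on the guide chromosome are left
#' unchanged; repositioning never unplaces a marker. The procedure runs
#' for a fixed number of passes (default 2).
#'
#' @param geno [GenotypeData-class].
#' @param hits hit table from [readHits()].
#' @param r2Bin R-squared threshold defining bin membership (default 0.5).
#' @param iterations number of passes (default 2).
#' @param majority `"strict"` (> half of other members; default) or
#'   `"plurality"` (most represented chromosome).
#' @return list: `geno` (updated map), `repositioned` (count over all
#'   passes), `log` (`data.frame` of moves).
#' @export
ldBinReposition <- function(geno, hits, r2Bin = 0.5, iterations = 2,
                            majority = c("strict", "plurality")) {
  majority <- match.arg(majority)
  d <- dosages(geno)
  moves <- list()
  total <- 0L
  cc <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  diag(cc) <- 0
  cc[is.na(cc)] <- 0
  for (pass in seq_len(iterations)) {
    map <- markerMap(geno)
    adj <- cc > r2Bin
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    newmap <- map
    for (b in unique(comp)) {
      members <- which(comp == b)
      if (length(members) < 2) next
      for (j in members) {
        others <- setdiff(members, j)
        chroms <- map$chrom[others]
        chroms <- chroms[!is.na(chroms)]
        if (!length(chroms)) next
        tab <- sort(table(chroms), decreasing = TRUE)
        guide <- NA_character_
        if (majority == "strict") {
          if (tab[1] > length(chroms) / 2) guide <- names(tab)[1]
        } else if (length(tab) == 1L || tab[1] > tab[2]) {
          guide <- names(tab)[1]
        }
        if (is.na(guide)) {
          ## no consensus: chromosome of the highest-LD partner
          top <- others[which.max(cc[j, others])]
          guide <- map$chrom[top]
        }
        if (is.na(guide) || (!is.na(map$chrom[j]) && map$chrom[j] == guide))
          next
        h <- hits[hits$query == rownames(map)[j] & hits$subject == guide, ,
                  drop = FALSE]
        if (!nrow(h)) next
        h <- h[order(-h$bitscore, h$evalue), ][1, ]
        newmap$chrom[j] <- guide
        newmap$bp[j] <- floor((h$sstart + h$send) / 2)
        newmap$source[j] <- "ld_bin"
        total <- total + 1L
        moves[[length(moves) + 1L]] <- data.frame(
          pass = pass, marker = rownames(map)[j],
          from = map$chrom[j], to = guide, bp = newmap$bp[j])
      }
    }
    markerMap(geno) <- newmap
  }
  list(geno = geno, repositioned = total,
       log = if (length(moves)) do.call(rbind, moves)
             else data.frame(pass = integer(), marker = character(),
                             from = character(), to = character(),
                             bp = numeric()))
}

#' Mean adjacent-marker LD per chromosome
#'
#' Quantifies map quality: for each chromosome, markers are sorted by bp
#' and the mean R-squared between physically adjacent markers is
#' reported. Successful chromosome repositioning raises this summary on a
#' corrupted map. Doubles as the data export behind within-chromosome LD
#' heatmaps.
#'
#' @param geno [GenotypeData-class] with placed markers.
#' @return `data.frame`: chrom, n_markers, mean_adjacent_r2.
#' @export
adjacentLdSummary <- function(geno) {
  map <- markerMap(geno)
  d <- dosages(geno)
  out <- lapply(unique(stats::na.omit(map$chrom)), function(ch) {
    idx <- which(map$chrom == ch)
    idx <- idx[order(map$bp[idx])]
    if (length(idx) < 2)
      return(data.frame(chrom = ch, n_markers = length(idx),
                        mean_adjacent_r2 = NA_real_))
    r2 <- vapply(seq_len(length(idx) - 1), function(i) {
      suppressWarnings(stats::cor(d[, idx[i]], d[, idx[i + 1]],
                                  use = "pairwise.complete.obs"))^2
    }, numeric(1))
    data.frame(chrom = ch, n_markers = length(idx),
               mean_adjacent_r2 = mean(r2, na.rm = TRUE))
  })
  do.call(rbind, out)
}
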