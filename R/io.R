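#' Read a genotype matrix from CSV or VCF
#'
#' CSV dialect: header row of marker ids, first column genotype ids,
#' cells 0/1/2/NA. VCF: biallelic sites only (others skipped with a
#' count); the GT field becomes the alternative-allele dosage, and when
#' `referenceSample` is given, dosages are recoded so that sample's
#' allele is dose 0. Positions stay 1-based.
#'
#' @param path file path.
#' @param format `"csv"` or `"vcf"` (default: from the file extension).
#' @param referenceSample optional sample id whose (homozygous) allele
#'   becomes the reference in the recoded dosages.
#' @param population optional named vector of population ids per genotype.
#' @return A [GenotypeData-class]; VCF import fills the marker map from
#'   CHROM/POS.
#' @export
readGenotypes <- function(path, format = NULL, referenceSample = NULL,
                          population = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (format == "csv") {
    raw <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                           colClasses = "character")
    m <- as.matrix(raw)
    bad <- which(!(m %in% c("0", "1", "2", "NA", "")) & !is.na(m))
    if (length(bad)) {
      rc <- arrayInd(bad[1], dim(m))
      stop(sprintf("malformed dosage '%s' at row %s, column %s",
                   m[bad[1]], rownames(m)[rc[1]], colnames(m)[rc[2]]))
    }
    m[m == "" | m == "NA"] <- NA
    storage.mode(m) <- "integer"
    geno <- GenotypeData(m, population = population)
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "."
    nskip <- sum(!biallelic)
    if (nskip) message(nskip, " non-biallelic VCF record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
    dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dose[clean %in% c("0/0")] <- 0L
    dose[clean %in% c("0/1", "1/0")] <- 1L
    dose[clean %in% c("1/1")] <- 2L
    ids <- fix[biallelic, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[biallelic, "CHROM"], "_",
                                           fix[biallelic, "POS"])[is.na(ids) | ids == "."]
    rownames(dose) <- ids
    m <- t(dose)
    if (!is.null(referenceSample)) {
      if (!referenceSample %in% rownames(m))
        stop("reference sample not in VCF: ", referenceSample)
      flip <- which(m[referenceSample, ] == 2L)
      m[, flip] <- 2L - m[, flip]
    }
    map <- data.frame(chrom = fix[biallelic, "CHROM"],
                      bp = as.numeric(fix[biallelic, "POS"]),
                      source = "curated", row.names = ids)
    geno <- GenotypeData(m, map = map, population = population)
  }
  geno
}

#' Write a genotype matrix to the package CSV dialect
#'
#' @param geno [GenotypeData-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(geno, path) {
  d <- dosages(geno)
  df <- data.frame(genotype = rownames(d), d, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a 12-column tabular alignment hit file
#'
#' Parses the standard tab-separated alignment output (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bitscore). Reverse-orientation hits
#' (sstart > send) are retained with `orientation = "-"`. An empty file
#' yields an empty table with a warning.
#'
#' @param path file path.
#' @return `data.frame` with the 12 named columns plus `orientation`,
#'   best-hit-first per query (by bitscore).
#' @export
readHits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    warning("empty hit file: ", path)
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), 12), cols))
    empty$orientation <- character(0)
    return(empty)
  }
  h <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(h) != 12) stop("expected 12 tab-separated columns, found ", ncol(h))
  names(h) <- cols
  h$orientation <- ifelse(h$sstart > h$send, "-", "+")
  h[order(h$query, -h$bitscore), ]
}

#' Write a hit table back to tabular format (12 columns)
#' @param hits hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  utils::write.table(hits[, 1:12], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype table
#'
#' Columns: genotype, trial, plot, half, block, row, column, lid, scorer,
#' trait, value (flexible: missing design columns are tolerated).
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
readPhenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE)
}

## internal: headered TSV writer used by the pipeline
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
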