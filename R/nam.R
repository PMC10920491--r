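#' Founder haplotypes for a backcross NAM panel
#'
#' Generates fully homozygous founders: one recurrent (elite) parent whose
#' allele is the reference everywhere, and a set of donor parents whose
#' A/B sub-genome haplotypes come from a pool of tetraploid parents and
#' whose D sub-genome haplotypes come from a pool of diploid parents —
#' mirroring how synthetic hexaploid wheat donors are resynthesised from
#' *T. durum* (AABB) x *Ae. tauschii* (DD) crosses. Donors sharing a
#' sub-genome parent share that sub-genome's haplotype.
#'
#' @param map marker map from [makeGeneticMap()]; the last character of
#'   each chromosome name ("A"/"B"/"D") determines the sub-genome.
#' @param nDonors number of donor parents (default 54).
#' @param nTetraploid,nDiploid sizes of the tetraploid and diploid parent
#'   pools (defaults 15 and 47).
#' @param polymorphRate per-marker probability that a sub-genome parent
#'   carries the non-reference allele.
#' @param seed optional RNG seed.
#' @return list with `recurrent` (0 haplotype), `donorAllele`
#'   (markers x donors 0/1 matrix of donor alleles, 1 = differs from the
#'   recurrent parent), and `parents` (`data.frame`: donor, tetraploid,
#'   diploid ids).
#' @export
makeFounders <- function(map, nDonors = 54, nTetraploid = 15, nDiploid = 47,
                         polymorphRate = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subg <- substring(map$chrom, nchar(map$chrom))
  ab <- subg %in% c("A", "B")
  tetHap <- matrix(rbinom(sum(ab) * nTetraploid, 1, polymorphRate),
                   ncol = nTetraploid)
  dipHap <- matrix(rbinom(sum(!ab) * nDiploid, 1, polymorphRate),
                   ncol = nDiploid)
  tet <- sample(rep_len(seq_len(nTetraploid), nDonors))
  dip <- sample(rep_len(seq_len(nDiploid), nDonors))
  donorAllele <- matrix(0L, nrow(map), nDonors,
                        dimnames = list(rownames(map),
                                        sprintf("SHW%03d", seq_len(nDonors))))
  for (j in seq_len(nDonors)) {
    donorAllele[ab, j] <- tetHap[, tet[j]]
    donorAllele[!ab, j] <- dipHap[, dip[j]]
  }
  list(recurrent = rep(0L, nrow(map)),
       donorAllele = donorAllele,
       parents = data.frame(donor = colnames(donorAllele),
                            tetraploid = sprintf("TD%02d", tet),
                            diploid = sprintf("AT%02d", dip)))
}

#' Default backcross crossing plan
#'
#' One backcross to the recurrent parent followed by single-seed descent:
#' each population starts from 12 BC1F1 streams contributing 8 BC1F2
#' genotypes each (96 initial genotypes), selfed to BC1F5 (4 selfing
#' generations), then thinned by uniform random attrition to the target
#' population size (default 60, the panel-wide average).
#'
#' @param nPopulations number of nested populations.
#' @param nStreams BC1F1 plants per population.
#' @param nPerStream BC1F2 genotypes kept per stream.
#' @param selfingGenerations number of self-fertilisations after BC1F1
#'   (4 = BC1F5).
#' @param targetSize per-population size after attrition (`NA` = no
#'   attrition).
#' @return list (cross plan).
#' @export
defaultCrossPlan <- function(nPopulations = 54, nStreams = 12, nPerStream = 8,
                             selfingGenerations = 4, targetSize = 60) {
  stopifnot(selfingGenerations >= 0, nStreams >= 1, nPerStream >= 1)
  list(nPopulations = nPopulations, nStreams = nStreams,
       nPerStream = nPerStream, selfingGenerations = selfingGenerations,
       targetSize = targetSize)
}

#' Simulate a backcross NAM panel
#'
#' Executes the crossing scheme: F1 = recurrent x donor; BC1F1 = F1 pollen
#' onto the recurrent parent; per BC1F1 stream, BC1F2 progeny by selfing;
#' then single-seed descent for the remaining selfing generations; finally
#' uniform random attrition to the plan's target size. Dosages count the
#' donor (alternative) allele with the recurrent parent as reference.
#'
#' @param plan cross plan from [defaultCrossPlan()].
#' @param founders founder set from [makeFounders()]; must provide at least
#'   `plan$nPopulations` donors.
#' @param map marker map from [makeGeneticMap()].
#' @param seed optional RNG seed.
#' @param includeParents include the recurrent parent and each donor as
#'   extra rows (population `NA`)?
#' @return list with elements
#'   \describe{
#'     \item{geno}{[GenotypeData-class] of observed dosages.}
#'     \item{pedigree}{`data.frame`: genotype, population, stream, donor,
#'       tetraploid, diploid.}
#'     \item{recurrentFraction}{named vector: per-genotype fraction of the
#'       genome inherited from the recurrent parent (pedigree truth,
#'       computed over all markers).}
#'     \item{hetFraction}{named vector: per-genotype heterozygous fraction
#'       over that population's donor-polymorphic markers.}
#'   }
#' @export
buildNam <- function(plan, founders, map, seed = NULL, includeParents = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  nPop <- plan$nPopulations
  if (nPop > ncol(founders$donorAllele)) stop("donor index out of range")
  nm <- nrow(map)
  rows <- list(); ped <- list(); rfrac <- list(); hfrac <- list()
  popIds <- sprintf("P%02d", seq_len(nPop))
  for (p in seq_len(nPop)) {
    poly <- founders$donorAllele[, p] == 1L
    ## F1: one recurrent haplotype (all 0 origin) and one donor haplotype
    f1 <- list(h1 = rep(0L, nm), h2 = rep(1L, nm))  # origin coding
    inds <- list(); k <- 0L
    for (s in seq_len(plan$nStreams)) {
      bc1f1 <- list(h1 = simulateMeiosis(f1$h1, f1$h2, map),
                    h2 = rep(0L, nm))  # maternal gamete is pure recurrent
      if (plan$selfingGenerations == 0L) {
        k <- k + 1L; inds[[k]] <- c(bc1f1, stream = s)
      } else {
        for (r in seq_len(plan$nPerStream)) {
          ind <- list(h1 = simulateMeiosis(bc1f1$h1, bc1f1$h2, map),
                      h2 = simulateMeiosis(bc1f1$h1, bc1f1$h2, map))
          for (g in seq_len(plan$selfingGenerations - 1L)) {
            ind <- list(h1 = simulateMeiosis(ind$h1, ind$h2, map),
                        h2 = simulateMeiosis(ind$h1, ind$h2, map))
          }
          k <- k + 1L; inds[[k]] <- c(ind, stream = s)
        }
      }
    }
    if (!is.na(plan$targetSize) && plan$targetSize < length(inds))
      inds <- inds[sort(sample.int(length(inds), plan$targetSize))]
    for (i in seq_along(inds)) {
      id <- sprintf("%s_G%03d", popIds[p], i)
      h1 <- inds[[i]]$h1; h2 <- inds[[i]]$h2
      rows[[id]] <- as.integer((h1 + h2) * poly)  # observed donor-allele dosage
      rfrac[[id]] <- 1 - mean(h1 + h2) / 2
      hfrac[[id]] <- if (any(poly)) mean((h1 != h2)[poly]) else NA_real_
      ped[[id]] <- data.frame(genotype = id, population = popIds[p],
                              stream = inds[[i]]$stream,
                              donor = founders$parents$donor[p],
                              tetraploid = founders$parents$tetraploid[p],
                              diploid = founders$parents$diploid[p])
    }
  }
  dosage <- do.call(rbind, rows)
  colnames(dosage) <- rownames(map)
  pop <- vapply(ped, function(x) x$population, character(1))
  meta <- list()
  if (includeParents) {
    donors <- founders$parents$donor[seq_len(nPop)]
    pr <- rbind(Recurrent = rep(0L, nm),
                t(founders$donorAllele[, seq_len(nPop), drop = FALSE] * 2L))
    rownames(pr) <- c("Recurrent", donors)
    dosage <- rbind(dosage, pr)
    pop <- c(pop, rep(NA_character_, nrow(pr)))
    meta <- list(recurrent = "Recurrent",
                 donors = stats::setNames(donors, popIds))
  }
  mp <- data.frame(chrom = map$chrom, bp = map$bp, cM = map$cM,
                   source = "curated", row.names = rownames(map))
  geno <- GenotypeData(dosage, map = mp, population = pop, metadata = meta)
  list(geno = geno,
       pedigree = do.call(rbind, c(ped, make.row.names = FALSE)),
       recurrentFraction = unlist(rfrac),
       hetFraction = unlist(hfrac))
}

#' Inject missingness and genotyping error into a dosage matrix
#'
#' Creates the conditions the QC cascade is designed for: MCAR missing
#' calls at a configured rate and random genotyping errors that shift a
#' dosage by one step (0 or 2 become 1; 1 becomes 0 or 2), which inflates
#' apparent heterozygosity.
#'
#' @param geno [GenotypeData-class].
#' @param missingRate probability a call is set missing.
#' @param errorRate probability a non-missing call is perturbed by one
#'   dosage step.
#' @param seed optional RNG seed.
#' @return A new [GenotypeData-class] with the corrupted dosages.
#' @export
injectMissingAndErrors <- function(geno, missingRate = 0, errorRate = 0,
                                   seed = NULL) {
  stopifnot(missingRate >= 0, missingRate <= 1, errorRate >= 0, errorRate <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- dosages(geno)
  if (errorRate > 0) {
    hit <- which(!is.na(d) & runif(length(d)) < errorRate)
    if (length(hit)) {
      cur <- d[hit]
      new <- ifelse(cur == 1L, ifelse(runif(length(cur)) < 0.5, 0L, 2L), 1L)
      d[hit] <- new
    }
  }
  if (missingRate > 0) d[runif(length(d)) < missingRate] <- NA_integer_
  new("GenotypeData", dosage = d, map = geno@map,
      population = geno@population, metadata = geno@metadata)
}
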