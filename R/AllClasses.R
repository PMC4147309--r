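#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats median quantile rgamma rpois runif sd setNames aggregate
#' @importFrom utils read.delim write.table
NULL

setClassUnion("data.frameORNULL", c("data.frame", "NULL"))

#' RepeatMasker name -> class/family catalog
#'
#' Maps a RepeatMasker repeat name (e.g. \code{"L1PB4"}) to its repeat class
#' and family (\code{"LINE"}, \code{"L1"}). Lookups of names absent from the
#' catalog resolve to the sentinel \code{"Unknown"}/\code{"Unknown"}, so
#' un-annotated repeat loci are retained and reported under an
#' \emph{Unknown} category rather than dropped.
#'
#' @slot table a \code{data.frame} with columns \code{name}, \code{class},
#'   \code{family}; one row per repeat name.
#'
#' @seealso [loadRepeatCatalog()], [repeatLookup()]
#' @export
setClass("RepeatCatalog", representation(table = "data.frame"))

setValidity("RepeatCatalog", function(object) {
  tb <- object@table
  if (!all(c("name", "class", "family") %in% names(tb)))
    return("catalog table must have columns 'name', 'class', 'family'")
  if (nrow(tb) > 0L && any(!nzchar(tb$name) | is.na(tb$name)))
    return("repeat names must be non-empty")
  if (anyDuplicated(tb$name))
    return("repeat names must be unique after override resolution")
  TRUE
})

#' In-memory bundle of all pipeline reference sets
#'
#' Holds the three miRNA sub-references (mature, mature-star, hairpin
#' precursors), the piRNA reference, the sense and antisense
#' repeat-associated RNA references with their parsed locus annotations,
#' and the [RepeatCatalog-class]. All sequences are stored DNA upper-case
#' (RNA references are converted U->T on load).
#'
#' @slot mature,matureStar,hairpin,pirna,repeatSense,repeatAntisense named
#'   [Biostrings::DNAStringSet] objects (names are the reference ids).
#' @slot repeatAnnoSense,repeatAnnoAntisense \code{data.frame}s with columns
#'   \code{accession}, \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{repeat_name}, one row per repeat locus, aligned with the
#'   corresponding \code{DNAStringSet}.
#' @slot catalog a [RepeatCatalog-class].
#'
#' @seealso [readReferenceBundle()], [generateReferences()]
#' @export
setClass("ReferenceBundle", representation(
  mature = "DNAStringSet",
  matureStar = "DNAStringSet",
  hairpin = "DNAStringSet",
  pirna = "DNAStringSet",
  repeatSense = "DNAStringSet",
  repeatAntisense = "DNAStringSet",
  repeatAnnoSense = "data.frame",
  repeatAnnoAntisense = "data.frame",
  catalog = "RepeatCatalog"
))

.annoCols <- c("accession", "chrom", "start", "end", "strand", "repeat_name")

setValidity("ReferenceBundle", function(object) {
  ids <- c(names(object@mature), names(object@matureStar), names(object@hairpin))
  if (anyDuplicated(ids))
    return("mature, mature-star and hairpin reference ids must be disjoint")
  for (ori in c("Sense", "Antisense")) {
    anno <- slot(object, paste0("repeatAnno", ori))
    seqs <- slot(object, paste0("repeat", ori))
    if (!all(.annoCols %in% names(anno)))
      return(sprintf("repeatAnno%s must have columns %s", ori,
                     paste(.annoCols, collapse = ", ")))
    if (nrow(anno) != length(seqs))
      return(sprintf("repeatAnno%s rows must match repeat%s sequences", ori, ori))
    if (nrow(anno) > 0L && any(!nzchar(anno$repeat_name)))
      return("repeat_name must be non-empty for every repeat locus")
  }
  TRUE
})

#' Collapsed unique reads of one library
#'
#' A distinct insert sequence together with the number of times it was
#' observed in one library; the unit that flows through every mapping stage.
#'
#' @slot sequence character vector of distinct DNA sequences.
#' @slot count integer vector of per-sequence occurrence counts (>= 1).
#'
#' @seealso [collapseAndFilter()], [lengthHistogram()]
#' @export
setClass("UniqueReads", representation(sequence = "character", count = "integer"))

setValidity("UniqueReads", function(object) {
  if (length(object@sequence) != length(object@count))
    return("sequence and count must have equal length")
  if (anyDuplicated(object@sequence))
    return("sequences must be unique within a library")
  if (length(object@count) && any(object@count < 1L))
    return("counts must be >= 1")
  TRUE
})

#' Read-disposition ledger of the preprocessing stage
#'
#' Every raw read ends up in exactly one disposition category, so the
#' categories sum to the input count — an exact conservation law enforced by
#' the class validity.
#'
#' @slot nInputReads,nAdapterRejected,nSpikeRemoved,nSingletonsRemoved,nShortRemoved,nReadsRetained,nUniqueRetained
#'   single non-negative integers.
#'
#' @seealso [preprocessReads()], [collapseAndFilter()]
#' @export
setClass("FilterReport", representation(
  nInputReads = "integer", nAdapterRejected = "integer",
  nSpikeRemoved = "integer", nSingletonsRemoved = "integer",
  nShortRemoved = "integer", nReadsRetained = "integer",
  nUniqueRetained = "integer"
))

setValidity("FilterReport", function(object) {
  v <- c(object@nInputReads, object@nAdapterRejected, object@nSpikeRemoved,
         object@nSingletonsRemoved, object@nShortRemoved,
         object@nReadsRetained, object@nUniqueRetained)
  if (length(v) != 7L || any(is.na(v)) || any(v < 0L))
    return("all ledger fields must be single non-negative integers")
  if (object@nInputReads != object@nAdapterRejected + object@nSpikeRemoved +
        object@nSingletonsRemoved + object@nShortRemoved + object@nReadsRetained)
    return("disposition categories must sum exactly to the input read count")
  TRUE
})

.cascadeCategories <- c("mature", "ambiguous_mature", "mature_star",
                        "ambiguous_mature_star", "hairpin", "ambiguous_hairpin")

#' Result of the sequential miRNA annotation cascade
#'
#' Per-category assignments from the three-stage cascade (mature, then
#' mature-star, then hairpin; unique and ambiguous matches recorded and
#' removed between stages). Every input unique read lands in exactly one of
#' the six categories or in the leftover set.
#'
#' @slot categories named list over the six categories; each element a
#'   \code{data.frame} with columns \code{refId}, \code{uniqueReads},
#'   \code{readCount} (read counts of ambiguous reads are credited to every
#'   tied reference; the per-category totals in \code{stats} count each read
#'   once).
#' @slot stats \code{data.frame} with one row per category: \code{category},
#'   \code{uniqueReads}, \code{readCount}, \code{speciesDetected}.
#' @slot leftover a [UniqueReads-class] of unassigned reads.
#' @slot nInput number of unique reads fed to the cascade.
#'
#' @seealso [runMirnaCascade()]
#' @export
setClass("CascadeResult", representation(
  categories = "list", stats = "data.frame",
  leftover = "UniqueReads", nInput = "integer"
))

setValidity("CascadeResult", function(object) {
  if (!identical(names(object@categories), .cascadeCategories))
    return("categories must be the six cascade categories, in order")
  if (sum(object@stats$uniqueReads) + length(object@leftover@sequence) !=
        object@nInput)
    return("cascade categories plus leftover must partition the input reads")
  TRUE
})

#' Per-species counts from a piRNA or repeat mapping branch
#'
#' @slot counts \code{data.frame} with columns \code{refId},
#'   \code{readCount}, \code{ambiguous} (logical: the species received reads
#'   tied across several references). A read tied across references
#'   contributes its count to every tied species but is counted once in
#'   \code{nReadsMapped}.
#' @slot nReadsMapped total read count mapped (each read counted once).
#' @slot nSpeciesDetected number of species with mapped count >= 1.
#'
#' @seealso [mapBranch()]
#' @export
setClass("BranchCounts", representation(
  counts = "data.frame", nReadsMapped = "numeric", nSpeciesDetected = "integer"
))

setValidity("BranchCounts", function(object) {
  if (!all(c("refId", "readCount", "ambiguous") %in% names(object@counts)))
    return("counts must have columns refId, readCount, ambiguous")
  if (nrow(object@counts) != object@nSpeciesDetected)
    return("nSpeciesDetected must equal the number of species rows")
  TRUE
})

#' Two-library species count table
#'
#' The substrate for normalization, fold change and aggregation: one row per
#' species, raw or normalized counts for library A and library B.
#'
#' @slot species character vector of unique species ids.
#' @slot countsA,countsB non-negative numeric vectors (integers before
#'   normalization).
#' @slot normalized logical flag.
#' @slot sizeFactors numeric of length 2 (\code{sA}, \code{sB}); \code{NA}
#'   until [normalizeCounts()] is applied.
#'
#' @seealso [buildCountTable()], [medianRatioFactors()], [normalizeCounts()]
#' @export
setClass("CountTable", representation(
  species = "character", countsA = "numeric", countsB = "numeric",
  normalized = "logical", sizeFactors = "numeric"
))

setValidity("CountTable", function(object) {
  n <- length(object@species)
  if (length(object@countsA) != n || length(object@countsB) != n)
    return("species and count vectors must have equal length")
  if (anyDuplicated(object@species))
    return("species ids must be unique")
  if (n && (any(object@countsA < 0) || any(object@countsB < 0)))
    return("counts must be non-negative")
  TRUE
})
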