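# Annotation: ungapped mismatch-tolerant alignment, unique/ambiguous read
# classification, the sequential miRNA cascade, and the length-routed
# piRNA / repeat-RNA branches.

#' Ungapped alignment policy
#'
#' Mismatch tolerance is either a fixed maximum (\code{maxMismatches}) or
#' identity-derived (\code{byIdentity = TRUE}): a read of length L is
#' allowed \code{floor((1 - minIdentity) * L)} mismatches, e.g. 2 for a
#' 22-nt read at 90\% identity. Alignment is always ungapped, and
#' strand-specific: reads are compared only in their given orientation
#' (antisense transcripts are represented by an antisense reference set,
#' never by reverse-complementing reads).
#'
#' @param maxMismatches fixed mismatch maximum (ignored when
#'   \code{byIdentity})
#' @param byIdentity derive the allowance from \code{minIdentity}
#' @param minIdentity minimum identity fraction in (0, 1]
#' @param strandSpecific must remain \code{TRUE}; present for explicitness
#' @return an \code{AlignmentPolicy} object
#' @export
alignmentPolicy <- function(maxMismatches = 2L, byIdentity = FALSE,
                            minIdentity = 0.9, strandSpecific = TRUE) {
  stopifnot(isTRUE(strandSpecific), minIdentity > 0, minIdentity <= 1,
            maxMismatches >= 0)
  structure(list(maxMismatches = as.integer(maxMismatches),
                 byIdentity = isTRUE(byIdentity),
                 minIdentity = minIdentity, strandSpecific = TRUE),
            class = "AlignmentPolicy")
}

#' @describeIn alignmentPolicy mismatch allowance for a read length
#' @param policy an \code{AlignmentPolicy}
#' @param readLength integer read length
#' @export
mismatchAllowance <- function(policy, readLength) {
  # the epsilon keeps floor() exact where (1 - id) * L is a whole number
  # up to binary floating-point error (e.g. 0.1 * 30)
  if (policy$byIdentity)
    floor((1 - policy$minIdentity) * readLength + 1e-9)
  else policy$maxMismatches
}

# All in-bounds hits of `read` in `refs` (character vector) with exactly
# the minimal mismatch count within `allow`; thin wrapper around the
# compiled scan. Returns NULL or list(mismatches, refIndex, start).
.bestHits <- function(read, refs, allow) {
  .bestHitsC(read, unname(refs), as.integer(allow))
}

# Coerce a reference set to the named character form used by the scanners.
.refChars <- function(references) {
  if (is(references, "DNAStringSet")) {
    s <- as.character(references)  # keeps names for XStringSet
  } else {
    s <- references
  }
  if (is.null(names(s))) stop("references must be named")
  s
}

#' Align one read against one reference, ungapped
#'
#' Scans every offset of the read within the reference (equal length or
#' substring) and returns the hit with the fewest mismatches within the
#' policy allowance; ties are broken by the lowest offset. Strand-specific:
#' the read is compared only in its given orientation.
#'
#' @param read read sequence (character)
#' @param reference reference sequence (character, may be named)
#' @param policy an [alignmentPolicy()]
#' @return list with elements \code{refId}, \code{mismatches},
#'   \code{offset} (0-based start of the read within the reference), or
#'   \code{NULL} when there is no hit within the allowance
#' @export
alignUngapped <- function(read, reference, policy = alignmentPolicy()) {
  refId <- if (!is.null(names(reference))) names(reference)[1L] else NA_character_
  reference <- if (is.character(reference)) unname(reference)[1L]
               else as.character(reference)[1L]
  if (!nchar(read) || nchar(read) > nchar(reference)) return(NULL)
  allow <- mismatchAllowance(policy, nchar(read))
  hits <- .bestHits(read, reference, allow)
  if (is.null(hits)) return(NULL)
  list(refId = refId, mismatches = hits$mismatches,
       offset = min(hits$start) - 1L)
}

#' Classify a read against a reference set
#'
#' Collects the best (minimal-mismatch) hits of the read across all
#' references and offsets. Exactly one best (reference, offset) pair makes
#' the read a unique match; two or more equally good pairs — to different
#' references, or to different positions of the same reference — make it
#' ambiguous; no hit within the allowance leaves it unmapped.
#'
#' @param read read sequence (character)
#' @param references named [Biostrings::DNAStringSet] (or named character)
#' @param policy an [alignmentPolicy()]
#' @return list with elements \code{status} (\code{"unique"},
#'   \code{"ambiguous"} or \code{"unmapped"}), \code{refs} (tied reference
#'   ids, deduplicated), \code{mismatches}, and \code{nHits} (number of
#'   tied (reference, offset) pairs)
#' @export
classifyRead <- function(read, references, policy = alignmentPolicy()) {
  references <- .refChars(references)
  allow <- mismatchAllowance(policy, nchar(read))
  hits <- .bestHits(read, references, allow)
  if (is.null(hits))
    return(list(status = "unmapped", refs = character(0),
                mismatches = NA_integer_, nHits = 0L))
  refs <- unique(names(references)[hits$refIndex])
  nHits <- length(hits$refIndex)
  list(status = if (nHits == 1L) "unique" else "ambiguous",
       refs = refs, mismatches = hits$mismatches, nHits = nHits)
}

.stageCategories <- list(
  mature = c("mature", "ambiguous_mature"),
  mature_star = c("mature_star", "ambiguous_mature_star"),
  hairpin = c("hairpin", "ambiguous_hairpin")
)

#' Run the sequential miRNA annotation cascade
#'
#' Three sequential stages — mature, then mature-star, then hairpin
#' precursors. At each stage every remaining unique read is classified
#' against the stage's reference set; unique and ambiguous assignments are
#' recorded with their read counts and the assigned reads are removed
#' before the next stage, so a read equal to a mature miRNA is never
#' re-detected inside its hairpin. Survivors of all stages form the
#' leftover set.
#'
#' @param reads a [UniqueReads-class] (already filtered)
#' @param bundle a [ReferenceBundle-class]
#' @param policy an [alignmentPolicy()]; the default derives the mismatch
#'   allowance from 90\% identity
#' @param stageOrder stage execution order; reordering (e.g. hairpin first)
#'   is supported to demonstrate why sequential removal matters
#' @return a [CascadeResult-class]
#' @export
runMirnaCascade <- function(reads, bundle,
                            policy = alignmentPolicy(byIdentity = TRUE,
                                                     minIdentity = 0.9),
                            stageOrder = c("mature", "mature_star", "hairpin")) {
  stopifnot(all(stageOrder %in% names(.stageCategories)),
            !anyDuplicated(stageOrder))
  stageRefs <- list(mature = as.character(bundle@mature),
                    mature_star = as.character(bundle@matureStar),
                    hairpin = as.character(bundle@hairpin))
  remaining <- seq_along(reads@sequence)
  categories <- setNames(vector("list", length(.cascadeCategories)),
                         .cascadeCategories)
  catStats <- setNames(vector("list", length(.cascadeCategories)),
                       .cascadeCategories)
  for (cat in .cascadeCategories) {
    categories[[cat]] <- data.frame(refId = character(0),
                                    uniqueReads = integer(0),
                                    readCount = numeric(0),
                                    stringsAsFactors = FALSE)
    catStats[[cat]] <- c(uniqueReads = 0L, readCount = 0,
                         speciesDetected = 0L)
  }
  for (stage in stageOrder) {
    refs <- stageRefs[[stage]]
    if (!length(refs)) {
      warning("empty reference set for stage '", stage, "'; stage skipped")
      next
    }
    assigned <- logical(length(remaining))
    acc <- list(unique = list(), ambiguous = list())
    for (ii in seq_along(remaining)) {
      i <- remaining[ii]
      cl <- classifyRead(reads@sequence[i], refs, policy)
      if (cl$status == "unmapped") next
      assigned[ii] <- TRUE
      key <- cl$status
      acc[[key]][[length(acc[[key]]) + 1L]] <-
        list(refs = cl$refs, count = reads@count[i])
    }
    catNames <- .stageCategories[[stage]]
    for (k in 1:2) {
      kind <- c("unique", "ambiguous")[k]
      hits <- acc[[kind]]
      catName <- catNames[k]
      if (length(hits)) {
        refVec <- unlist(lapply(hits, `[[`, "refs"))
        cntVec <- unlist(lapply(hits, function(h)
          rep(h$count, length(h$refs))))
        df <- aggregate(cbind(readCount = cntVec),
                        by = list(refId = refVec), FUN = sum)
        urc <- aggregate(cbind(uniqueReads = rep(1L, length(refVec))),
                         by = list(refId = refVec), FUN = sum)
        df <- merge(urc, df, by = "refId")
        df <- df[order(df$refId), c("refId", "uniqueReads", "readCount")]
        rownames(df) <- NULL
        categories[[catName]] <- df
        catStats[[catName]] <- c(
          uniqueReads = length(hits),
          readCount = sum(vapply(hits, `[[`, numeric(1), "count")),
          speciesDetected = nrow(df))
      }
    }
    remaining <- remaining[!assigned]
  }
  stats <- data.frame(
    category = .cascadeCategories,
    uniqueReads = vapply(catStats, `[[`, numeric(1), "uniqueReads"),
    readCount = vapply(catStats, `[[`, numeric(1), "readCount"),
    speciesDetected = vapply(catStats, `[[`, numeric(1), "speciesDetected"),
    stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  new("CascadeResult", categories = categories, stats = stats,
      leftover = UniqueReads(reads@sequence[remaining],
                             reads@count[remaining]),
      nInput = length(reads@sequence))
}

#' Partition reads by length
#'
#' Reads longer than \code{boundary} go to the long branch (piRNA mapping);
#' reads of length \code{boundary} or less go to the short branch
#' (repeat-RNA mapping). The partition is exhaustive and disjoint; with the
#' default boundary of 23 nt, a 23-nt read is routed to the short branch.
#'
#' @param reads a [UniqueReads-class]
#' @param boundary length boundary (default 23)
#' @return list with [UniqueReads-class] elements \code{long} and
#'   \code{short}
#' @export
routeByLength <- function(reads, boundary = 23L) {
  lens <- nchar(reads@sequence)
  long <- lens > boundary
  list(long = UniqueReads(reads@sequence[long], reads@count[long]),
       short = UniqueReads(reads@sequence[!long], reads@count[!long]))
}

#' Map a read subset against a piRNA or repeat reference set
#'
#' Each read is classified against the reference set; a uniquely matching
#' read credits its count to the single best reference, and a read tied
#' across several references credits its count to every tied species (each
#' flagged ambiguous) while being counted once in the mapped-read total.
#' Species with no mapped reads are absent from the output.
#'
#' @param reads a [UniqueReads-class] (the appropriate length partition)
#' @param references named [Biostrings::DNAStringSet]
#' @param policy an [alignmentPolicy()]; default allows 2 mismatches,
#'   strand-specific
#' @return a [BranchCounts-class]
#' @export
mapBranch <- function(reads, references,
                      policy = alignmentPolicy(maxMismatches = 2L)) {
  references <- .refChars(references)
  refVec <- character(0); cntVec <- numeric(0); ambVec <- logical(0)
  nMapped <- 0
  for (i in seq_along(reads@sequence)) {
    cl <- classifyRead(reads@sequence[i], references, policy)
    if (cl$status == "unmapped") next
    nMapped <- nMapped + reads@count[i]
    refVec <- c(refVec, cl$refs)
    cntVec <- c(cntVec, rep(reads@count[i], length(cl$refs)))
    ambVec <- c(ambVec, rep(cl$status == "ambiguous", length(cl$refs)))
  }
  if (length(refVec)) {
    counts <- aggregate(cbind(readCount = cntVec),
                        by = list(refId = refVec), FUN = sum)
    amb <- aggregate(cbind(ambiguous = ambVec),
                     by = list(refId = refVec), FUN = any)
    counts <- merge(counts, amb, by = "refId")
    counts <- counts[order(counts$refId), ]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(refId = character(0), readCount = numeric(0),
                         ambiguous = logical(0), stringsAsFactors = FALSE)
  }
  new("BranchCounts", counts = counts, nReadsMapped = nMapped,
      nSpeciesDetected = nrow(counts))
}
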