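# Accessor generics and show methods for the core classes.

#' @describeIn RepeatCatalog-class number of catalogued repeat names
#' @param x,object a \code{RepeatCatalog}
#' @export
setMethod("length", "RepeatCatalog", function(x) nrow(x@table))

#' Resolve repeat names to RepeatMasker class and family
#'
#' Unknown names resolve to the sentinel \code{"Unknown"}/\code{"Unknown"}.
#'
#' @param catalog a [RepeatCatalog-class]
#' @param names character vector of repeat names
#' @return \code{data.frame} with columns \code{repeat_name},
#'   \code{repeat_class}, \code{repeat_family}, one row per input name.
#' @examples
#' cat <- RepeatCatalog(data.frame(name = "L1PB4", class = "LINE", family = "L1"))
#' repeatLookup(cat, c("L1PB4", "NOT_A_NAME"))
#' @export
repeatLookup <- function(catalog, names) {
  stopifnot(is(catalog, "RepeatCatalog"), is.character(names))
  i <- match(names, catalog@table$name)
  data.frame(
    repeat_name = names,
    repeat_class = ifelse(is.na(i), "Unknown", catalog@table$class[i]),
    repeat_family = ifelse(is.na(i), "Unknown", catalog@table$family[i]),
    stringsAsFactors = FALSE
  )
}

#' Construct a RepeatCatalog from a name/class/family table
#'
#' @param table \code{data.frame} with columns \code{name}, \code{class},
#'   \code{family}. Later duplicate names override earlier ones (a warning
#'   is emitted).
#' @return a [RepeatCatalog-class]
#' @export
RepeatCatalog <- function(table = data.frame(name = character(),
                                             class = character(),
                                             family = character())) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  dup <- duplicated(table$name, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate repeat name(s) in catalog; keeping the last entry: ",
            paste(unique(table$name[dup]), collapse = ", "))
    table <- table[!dup, , drop = FALSE]
  }
  rownames(table) <- NULL
  new("RepeatCatalog", table = table)
}

setMethod("show", "RepeatCatalog", function(object) {
  cat("RepeatCatalog with", nrow(object@table), "repeat names\n")
  if (nrow(object@table)) {
    cat("  classes:", paste(unique(object@table$class), collapse = ", "), "\n")
  }
})

# ---- ReferenceBundle accessors ------------------------------------------

#' @describeIn ReferenceBundle-class mature miRNA reference sequences
#' @param bundle,object a \code{ReferenceBundle}
#' @export
matureRef <- function(bundle) bundle@mature

#' @describeIn ReferenceBundle-class mature-star miRNA reference sequences
#' @export
matureStarRef <- function(bundle) bundle@matureStar

#' @describeIn ReferenceBundle-class hairpin precursor reference sequences
#' @export
hairpinRef <- function(bundle) bundle@hairpin

#' @describeIn ReferenceBundle-class piRNA reference sequences (DNA alphabet)
#' @export
pirnaRef <- function(bundle) bundle@pirna

#' @describeIn ReferenceBundle-class repeat-RNA reference sequences for one
#'   orientation
#' @param orientation \code{"sense"} or \code{"antisense"}
#' @export
repeatRef <- function(bundle, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  if (orientation == "sense") bundle@repeatSense else bundle@repeatAntisense
}

#' @describeIn ReferenceBundle-class parsed repeat locus annotations for one
#'   orientation
#' @export
repeatAnnotation <- function(bundle, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  if (orientation == "sense") bundle@repeatAnnoSense else bundle@repeatAnnoAntisense
}

#' @describeIn ReferenceBundle-class the repeat name catalog
#' @export
repeatCatalog <- function(bundle) bundle@catalog

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle\n")
  cat(sprintf("  mature: %d  mature-star: %d  hairpin: %d\n",
              length(object@mature), length(object@matureStar),
              length(object@hairpin)))
  cat(sprintf("  piRNA: %d  repeat sense: %d  repeat antisense: %d\n",
              length(object@pirna), length(object@repeatSense),
              length(object@repeatAntisense)))
  cat(sprintf("  catalog: %d repeat names\n", length(object@catalog)))
})

# ---- UniqueReads ---------------------------------------------------------

#' Construct a UniqueReads object
#'
#' @param sequence character vector of distinct sequences
#' @param count integer vector of occurrence counts
#' @return a [UniqueReads-class]
#' @export
UniqueReads <- function(sequence = character(), count = integer()) {
  new("UniqueReads", sequence = as.character(sequence),
      count = as.integer(count))
}

#' @describeIn UniqueReads-class number of distinct sequences
#' @param x,object a \code{UniqueReads}
#' @export
setMethod("length", "UniqueReads", function(x) length(x@sequence))

#' @describeIn UniqueReads-class the distinct sequences
#' @param reads a \code{UniqueReads}
#' @export
readSequences <- function(reads) reads@sequence

#' @describeIn UniqueReads-class the per-sequence occurrence counts, named by
#'   sequence
#' @export
readCounts <- function(reads) setNames(reads@count, reads@sequence)

setMethod("show", "UniqueReads", function(object) {
  cat(sprintf("UniqueReads: %d distinct sequences, %d reads total\n",
              length(object@sequence), sum(object@count)))
})

# ---- FilterReport --------------------------------------------------------

#' @describeIn FilterReport-class ledger fields as a named integer vector
#' @param report a \code{FilterReport}
#' @export
filterLedger <- function(report) {
  c(nInputReads = report@nInputReads,
    nAdapterRejected = report@nAdapterRejected,
    nSpikeRemoved = report@nSpikeRemoved,
    nSingletonsRemoved = report@nSingletonsRemoved,
    nShortRemoved = report@nShortRemoved,
    nReadsRetained = report@nReadsRetained,
    nUniqueRetained = report@nUniqueRetained)
}

setMethod("show", "FilterReport", function(object) {
  v <- filterLedger(object)
  cat("FilterReport\n")
  for (nm in names(v)) cat(sprintf("  %-20s %d\n", nm, v[[nm]]))
})

# ---- CascadeResult -------------------------------------------------------

#' @describeIn CascadeResult-class per-reference counts of one category
#' @param result a \code{CascadeResult}
#' @param category one of the six cascade categories
#' @export
cascadeCategory <- function(result, category = .cascadeCategories) {
  category <- match.arg(category)
  result@categories[[category]]
}

#' @describeIn CascadeResult-class per-category totals
#' @export
cascadeStats <- function(result) result@stats

#' @describeIn CascadeResult-class unassigned reads surviving all stages
#' @export
cascadeLeftover <- function(result) result@leftover

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult: %d unique reads in, %d unassigned\n",
              object@nInput, length(object@leftover@sequence)))
  print(object@stats, row.names = FALSE)
})

# ---- BranchCounts --------------------------------------------------------

#' @describeIn BranchCounts-class the per-species count table
#' @param branch,object a \code{BranchCounts}
#' @export
branchCounts <- function(branch) branch@counts

#' @describeIn BranchCounts-class total mapped read count (each read once)
#' @export
branchReadsMapped <- function(branch) branch@nReadsMapped

#' @describeIn BranchCounts-class number of species with mapped count >= 1
#' @export
branchSpeciesDetected <- function(branch) branch@nSpeciesDetected

setMethod("show", "BranchCounts", function(object) {
  cat(sprintf("BranchCounts: %d species detected, %s reads mapped\n",
              object@nSpeciesDetected,
              format(object@nReadsMapped, big.mark = ",")))
})

# ---- CountTable ----------------------------------------------------------

#' Construct a two-library CountTable
#'
#' @param species character vector of species ids
#' @param countsA,countsB non-negative counts per species
#' @param normalized logical; whether the counts are already normalized
#' @param sizeFactors numeric length-2 size factors (NA for raw tables)
#' @return a [CountTable-class]
#' @export
CountTable <- function(species, countsA, countsB, normalized = FALSE,
                       sizeFactors = c(NA_real_, NA_real_)) {
  new("CountTable", species = as.character(species),
      countsA = as.numeric(countsA), countsB = as.numeric(countsB),
      normalized = normalized, sizeFactors = as.numeric(sizeFactors))
}

#' @describeIn CountTable-class number of species rows
#' @param x,object a \code{CountTable}
#' @export
setMethod("length", "CountTable", function(x) length(x@species))

#' @describeIn CountTable-class counts as a data.frame (species, countA,
#'   countB)
#' @param table a \code{CountTable}
#' @export
countFrame <- function(table) {
  data.frame(species = table@species, countA = table@countsA,
             countB = table@countsB, stringsAsFactors = FALSE)
}

#' @describeIn CountTable-class whether the table holds normalized counts
#' @export
isNormalized <- function(table) table@normalized

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d species (%s)\n", length(object@species),
              if (object@normalized) "normalized" else "raw"))
  if (!anyNA(object@sizeFactors))
    cat(sprintf("  size factors: sA = %.4f, sB = %.4f\n",
                object@sizeFactors[1], object@sizeFactors[2]))
})
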