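# Repeat annotation merging, RepeatMasker class/family accumulation,
# sense/antisense ratios, "Unknown" breakdowns, and Table-style summaries.

#' Annotate a per-locus repeat count table
#'
#' Joins a two-library per-locus count table with the repeat locus
#' annotations of the reference bundle and resolves each RepeatMasker name
#' through the catalog (unknown names resolve to \code{"Unknown"}).
#'
#' @param table a [CountTable-class] keyed by locus accession (raw or
#'   normalized)
#' @param bundle a [ReferenceBundle-class]
#' @param orientation \code{"sense"} or \code{"antisense"} (selects the
#'   annotation set and is recorded per row)
#' @return \code{data.frame} with columns \code{accession},
#'   \code{repeat_name}, \code{repeat_class}, \code{repeat_family},
#'   \code{orientation}, \code{countA}, \code{countB}
#' @export
annotateCounts <- function(table, bundle,
                           orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  anno <- repeatAnnotation(bundle, orientation)
  i <- match(table@species, anno$accession)
  if (anyNA(i))
    stop("accession(s) absent from the ", orientation,
         " repeat reference: ",
         paste(utils::head(table@species[is.na(i)], 3L), collapse = ", "))
  look <- repeatLookup(repeatCatalog(bundle), anno$repeat_name[i])
  orientation <- rep(orientation, length(table@species))
  data.frame(accession = table@species,
             repeat_name = look$repeat_name,
             repeat_class = look$repeat_class,
             repeat_family = look$repeat_family,
             orientation = orientation,
             countA = table@countsA, countB = table@countsB,
             stringsAsFactors = FALSE)
}

#' Accumulate annotated locus counts by repeat class, family or name
#'
#' Sums locus counts per (group, orientation, library) and derives the
#' antisense/sense expression ratio per (group, library): the ratio is the
#' antisense total over the sense total, reported as 0 when the antisense
#' total is 0 and as \code{NA} (absent) when the sense total is 0.
#'
#' @param annotated \code{data.frame} from [annotateCounts()] (sense and
#'   antisense rows may be combined with \code{rbind})
#' @param level grouping level: \code{"class"}, \code{"family"} or
#'   \code{"name"}
#' @return list with \code{data.frame} elements \code{totals} (group,
#'   orientation, countA, countB) and \code{ratios} (group, ratioA,
#'   ratioB)
#' @export
accumulateCounts <- function(annotated, level = c("class", "family", "name")) {
  level <- match.arg(level)
  key <- switch(level, class = "repeat_class", family = "repeat_family",
                name = "repeat_name")
  if (nrow(annotated) == 0L)
    return(list(totals = data.frame(group = character(0),
                                    orientation = character(0),
                                    countA = numeric(0), countB = numeric(0)),
                ratios = data.frame(group = character(0), ratioA = numeric(0),
                                    ratioB = numeric(0))))
  totals <- aggregate(cbind(countA, countB) ~ group + orientation,
                      data = data.frame(group = annotated[[key]],
                                        orientation = annotated$orientation,
                                        countA = annotated$countA,
                                        countB = annotated$countB),
                      FUN = sum)
  totals <- totals[order(totals$group, totals$orientation), ]
  rownames(totals) <- NULL
  groups <- unique(totals$group)
  pick <- function(g, ori, col) {
    v <- totals[totals$group == g & totals$orientation == ori, col]
    if (length(v)) v else 0
  }
  ratio <- function(anti, sen) {
    if (sen == 0) NA_real_ else anti / sen
  }
  ratios <- data.frame(
    group = groups,
    ratioA = vapply(groups, function(g)
      ratio(pick(g, "antisense", "countA"), pick(g, "sense", "countA")),
      numeric(1)),
    ratioB = vapply(groups, function(g)
      ratio(pick(g, "antisense", "countB"), pick(g, "sense", "countB")),
      numeric(1)),
    stringsAsFactors = FALSE)
  rownames(ratios) <- NULL
  list(totals = totals, ratios = ratios)
}

#' Breakdown of the "Unknown" repeat category
#'
#' Restricts to loci whose RepeatMasker family resolved to
#' \code{"Unknown"}, accumulates per (orientation, repeat name)
#' subcategory, and keeps subcategories with a total accumulated count over
#' both libraries greater than \code{minTotal} and a fold change (the
#' larger library count over the smaller; infinite when the smaller is 0)
#' greater than \code{minFc}.
#'
#' @param annotated \code{data.frame} from [annotateCounts()]
#' @param minTotal total-count filter (default 10)
#' @param minFc fold-change filter (default 2)
#' @return \code{data.frame} with columns \code{orientation},
#'   \code{repeat_name}, \code{countA}, \code{countB}, \code{foldChange}
#' @export
unknownBreakdown <- function(annotated, minTotal = 10, minFc = 2) {
  unk <- annotated[annotated$repeat_family == "Unknown" |
                     annotated$repeat_class == "Unknown", , drop = FALSE]
  if (nrow(unk) == 0L)
    return(data.frame(orientation = character(0), repeat_name = character(0),
                      countA = numeric(0), countB = numeric(0),
                      foldChange = numeric(0)))
  acc <- aggregate(cbind(countA, countB) ~ orientation + repeat_name,
                   data = unk, FUN = sum)
  lo <- pmin(acc$countA, acc$countB)
  hi <- pmax(acc$countA, acc$countB)
  acc$foldChange <- ifelse(lo == 0, ifelse(hi > 0, Inf, NA_real_), hi / lo)
  keep <- (acc$countA + acc$countB) > minTotal &
    !is.na(acc$foldChange) & acc$foldChange > minFc
  acc <- acc[keep, c("orientation", "repeat_name", "countA", "countB",
                     "foldChange")]
  acc <- acc[order(acc$orientation, -(acc$countA + acc$countB)), ]
  rownames(acc) <- NULL
  acc
}

#' Table-style per-category summary with derived fractions
#'
#' Computes, for each annotation category and library, the fraction of the
#' known reference universe detected, the fraction of the library's unique
#' reads, and the fraction of the library's total filtered read count —
#' the derived quantities of a mapping-overview table. All fractions are
#' reported in percent.
#'
#' @param categoryStats \code{data.frame} with columns \code{category},
#'   \code{library} (\code{"A"} or \code{"B"}), \code{speciesDetected},
#'   \code{uniqueReads}, \code{readCount}
#' @param totals \code{data.frame} with columns \code{library},
#'   \code{totalReads} (filtered read count, the denominator of the total
#'   fraction) and optionally \code{totalUnique}
#' @param knownSizes named numeric vector mapping category to the size of
#'   its known reference universe (categories absent from it get \code{NA}
#'   known-fractions)
#' @return \code{data.frame}: the input stats plus \code{knownSize},
#'   \code{fractionKnownPct}, \code{fractionUniquePct},
#'   \code{fractionTotalPct}
#' @export
summarizeReport <- function(categoryStats, totals, knownSizes = numeric(0)) {
  cs <- as.data.frame(categoryStats, stringsAsFactors = FALSE)
  need <- c("category", "library", "speciesDetected", "uniqueReads",
            "readCount")
  stopifnot(all(need %in% names(cs)))
  ti <- match(cs$library, totals$library)
  if (anyNA(ti)) stop("totals missing for library: ",
                      paste(unique(cs$library[is.na(ti)]), collapse = ", "))
  totalReads <- totals$totalReads[ti]
  totalUnique <- if ("totalUnique" %in% names(totals))
    totals$totalUnique[ti] else rep(NA_real_, nrow(cs))
  known <- unname(knownSizes[cs$category])
  pct <- function(num, den) ifelse(is.na(den) | den == 0, NA_real_,
                                   100 * num / den)
  out <- cbind(cs, data.frame(
    knownSize = known,
    fractionKnownPct = pct(cs$speciesDetected, known),
    fractionUniquePct = pct(cs$uniqueReads, totalUnique),
    fractionTotalPct = pct(cs$readCount, totalReads)))
  rownames(out) <- NULL
  out
}

#' Round a percentage or ratio for display
#'
#' Full-precision values are authoritative; this applies R's round-half-to-
#' even at the displayed precision (1 decimal for percentages of known,
#' 2 for ratios), for direct comparison with published tables.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return numeric vector
#' @export
displayRound <- function(x, digits = 2L) round(x, digits)
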