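# Two-library statistics: median-of-ratios normalization, posterior
# generalized fold change (no-replicate design), DE calls and Bland-Altman
# summaries.

#' Build a two-library count table from per-species counts
#'
#' Full outer join on species id; species absent from one library get count
#' zero there.
#'
#' @param countsA,countsB named numeric vectors (names are species ids), or
#'   \code{data.frame}s with columns \code{refId} and \code{readCount}
#' @return a raw [CountTable-class]
#' @export
buildCountTable <- function(countsA, countsB) {
  asVec <- function(x) {
    if (is.data.frame(x)) setNames(x$readCount, x$refId) else x
  }
  a <- asVec(countsA); b <- asVec(countsB)
  species <- sort(union(names(a), names(b)))
  CountTable(species,
             ifelse(is.na(a[species]), 0, a[species]),
             ifelse(is.na(b[species]), 0, b[species]))
}

#' Median-of-ratios size factors
#'
#' A reference sample is formed by the geometric mean of the two libraries'
#' counts for each species (\code{sqrt(a_i * b_i)}); species with a zero
#' count in either library are excluded, since their reference is zero or
#' undefined. Each library's size factor is the median over included
#' species of the quotient of its count to the reference (median of an
#' even-length list: mean of the central pair). This median-based scaling
#' is robust to a few highly differentially expressed species that would
#' bias total-count scaling.
#'
#' @param table a raw [CountTable-class]
#' @return list with elements \code{sA}, \code{sB} (positive size factors)
#'   and \code{nReferenceSpecies} (species forming the reference). When no
#'   species is nonzero in both libraries the factors fall back to 1 with a
#'   prominent warning.
#' @examples
#' tb <- CountTable(c("s1", "s2", "s3"), c(100, 200, 300), c(200, 400, 600))
#' medianRatioFactors(tb)  # sA = 1/sqrt(2), sB = sqrt(2)
#' @export
medianRatioFactors <- function(table) {
  stopifnot(is(table, "CountTable"))
  if (table@normalized)
    stop("size factors must be computed from raw counts")
  inc <- table@countsA > 0 & table@countsB > 0
  if (!any(inc)) {
    warning("NORMALIZATION FALLBACK: no species with nonzero counts in ",
            "both libraries; size factors set to 1")
    return(list(sA = 1, sB = 1, nReferenceSpecies = 0L))
  }
  ref <- sqrt(table@countsA[inc] * table@countsB[inc])
  list(sA = median(table@countsA[inc] / ref),
       sB = median(table@countsB[inc] / ref),
       nReferenceSpecies = sum(inc))
}

#' Apply size factors to a count table
#'
#' @param table a raw [CountTable-class]
#' @param factors a list as returned by [medianRatioFactors()] (computed
#'   from \code{table} when omitted)
#' @return a normalized [CountTable-class] with counts divided by the
#'   library size factors
#' @export
normalizeCounts <- function(table, factors = medianRatioFactors(table)) {
  if (table@normalized) stop("count table is already normalized")
  stopifnot(factors$sA > 0, factors$sB > 0)
  CountTable(table@species, table@countsA / factors$sA,
             table@countsB / factors$sB, normalized = TRUE,
             sizeFactors = c(factors$sA, factors$sB))
}

#' Drop species with low normalized counts
#'
#' Removes species whose normalized count is at or below \code{threshold}
#' in \emph{both} libraries; a species clearly expressed in one library is
#' never deleted.
#'
#' @param table a normalized [CountTable-class]
#' @param threshold normalized count threshold (default 1)
#' @return the filtered [CountTable-class]
#' @export
dropLow <- function(table, threshold = 1) {
  if (!table@normalized) stop("dropLow expects a normalized count table")
  keep <- table@countsA > threshold | table@countsB > threshold
  CountTable(table@species[keep], table@countsA[keep], table@countsB[keep],
             normalized = TRUE, sizeFactors = table@sizeFactors)
}

#' Posterior generalized fold change for one species
#'
#' Fold changes of species with low read counts are less reliable than
#' those of highly expressed species. This estimator therefore reports a
#' conservative fold change from the posterior of the log2 ratio: with a
#' Poisson likelihood and flat prior on each library's expression rate, the
#' posterior of the rate is Gamma(count + 1, size factor). Paired Monte
#' Carlo draws give the posterior of \code{d = log2(rateB) - log2(rateA)};
#' the generalized fold change is the c-quantile of d when it is positive,
#' the (1-c)-quantile when that is negative, and 0 when the two quantiles
#' straddle zero (the posterior cannot rule out "no change").
#'
#' @param countA,countB raw (integer) read counts
#' @param sA,sB positive library size factors
#' @param c posterior tail fraction in (0, 0.5); default 0.01
#' @param nDraws Monte Carlo sample size (default 10000)
#' @param seed RNG seed for the draws (the caller's RNG state is preserved)
#' @return list with elements \code{gfold} and \code{rawLog2fc}
#'   (\code{log2((countB/sB + 1)/(countA/sA + 1))}, with the pseudocount
#'   for display only — it never enters the posterior)
#' @export
gfold <- function(countA, countB, sA = 1, sB = 1, c = 0.01,
                  nDraws = 10000L, seed = 1L) {
  if (countA != round(countA) || countB != round(countB))
    stop("gfold operates on raw integer counts, not normalized values")
  stopifnot(countA >= 0, countB >= 0, c > 0, c < 0.5, sA > 0, sB > 0)
  d <- withSeed(seed, {
    lamA <- rgamma(nDraws, shape = countA + 1, rate = sA)
    lamB <- rgamma(nDraws, shape = countB + 1, rate = sB)
    log2(lamB) - log2(lamA)
  })
  q <- quantile(d, c(c, 1 - c), names = FALSE)
  g <- if (q[1] > 0) q[1] else if (q[2] < 0) q[2] else 0
  list(gfold = g,
       rawLog2fc = log2((countB / sB + 1) / (countA / sA + 1)))
}

#' Generalized fold change for every species of a count table
#'
#' Applies [gfold()] to each species of a raw count table using the
#' median-of-ratios size factors, with per-species seeds derived from the
#' master seed so the result does not depend on table order.
#'
#' @param table a raw [CountTable-class]
#' @param factors size factors (computed from \code{table} when omitted)
#' @param c posterior tail fraction (default 0.01)
#' @param nDraws Monte Carlo draws per species
#' @param seed master seed
#' @return \code{data.frame} with columns \code{species}, \code{countA},
#'   \code{countB}, \code{rawLog2fc}, \code{gfold}
#' @export
gfoldTable <- function(table, factors = medianRatioFactors(table), c = 0.01,
                       nDraws = 10000L, seed = 1L) {
  if (table@normalized)
    stop("gfold operates on raw counts; pass the unnormalized table")
  n <- length(table@species)
  g <- numeric(n); raw <- numeric(n)
  for (i in seq_len(n)) {
    # per-species seed keyed to the id, invariant under row reordering
    u <- utf8ToInt(table@species[i])
    h <- sum(u * seq_along(u)) %% 100000
    r <- gfold(table@countsA[i], table@countsB[i], factors$sA, factors$sB,
               c = c, nDraws = nDraws,
               seed = (as.numeric(seed) * 100003 + h) %% 2147483646 + 1)
    g[i] <- r$gfold; raw[i] <- r$rawLog2fc
  }
  data.frame(species = table@species, countA = table@countsA,
             countB = table@countsB, rawLog2fc = raw, gfold = g,
             stringsAsFactors = FALSE)
}

#' Call differential expression from generalized fold changes
#'
#' Thresholds are inclusive: up-regulated species have
#' \code{gfold >= upThreshold}, down-regulated \code{gfold <=
#' downThreshold}. Lists are sorted by decreasing |gfold|.
#'
#' @param records a \code{data.frame} as returned by [gfoldTable()]
#' @param upThreshold positive threshold (default 2.0)
#' @param downThreshold negative threshold (default -0.5)
#' @return list with \code{data.frame} elements \code{up} and \code{down}
#' @export
callDE <- function(records, upThreshold = 2.0, downThreshold = -0.5) {
  stopifnot(upThreshold > 0, downThreshold < 0)
  up <- records[records$gfold >= upThreshold, , drop = FALSE]
  down <- records[records$gfold <= downThreshold, , drop = FALSE]
  up <- up[order(-abs(up$gfold)), , drop = FALSE]
  down <- down[order(-abs(down$gfold)), , drop = FALSE]
  rownames(up) <- rownames(down) <- NULL
  list(up = up, down = down)
}

#' Bland-Altman summary of a normalized count table
#'
#' For each species the difference of normalized counts (B - A) is paired
#' with their mean ((A + B) / 2). The limits of agreement are
#' \code{mean(diff) +/- 2 * SD(diff)} (sample SD, denominator n - 1); the
#' center line sits at 0, where species with identical normalized counts in
#' both libraries fall. Species far outside the limits are the candidates
#' for differential expression.
#'
#' @param table a normalized [CountTable-class]
#' @return list with elements \code{points} (\code{data.frame}: species,
#'   meanAB, diffBA), \code{limits} (numeric lower/upper, \code{NA} when
#'   fewer than 2 species) and \code{center} (0)
#' @export
blandAltman <- function(table) {
  if (!table@normalized) stop("blandAltman expects a normalized count table")
  d <- table@countsB - table@countsA
  m <- (table@countsA + table@countsB) / 2
  limits <- if (length(d) >= 2L) {
    s <- sd(d)
    c(lower = mean(d) - 2 * s, upper = mean(d) + 2 * s)
  } else c(lower = NA_real_, upper = NA_real_)
  list(points = data.frame(species = table@species, meanAB = m, diffBA = d,
                           stringsAsFactors = FALSE),
       limits = limits, center = 0)
}
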