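# Preprocessing: 3'-adapter trimming, spike-in removal, read collapsing
# with singleton and length filters, and the length histogram.

#' Trim the 3' adapter from read sequences
#'
#' Finds, for each read, the leftmost position at which the remainder of the
#' read matches the start of the adapter exactly: either a read suffix that
#' equals an adapter prefix of length >= \code{minOverlap}, or a full
#' internal adapter occurrence (trailing bases after the adapter are
#' discarded). The read prefix before that position is returned. Reads with
#' no adapter match of at least \code{minOverlap} bases are rejected
#' (returned as \code{NA}), as are empty reads.
#'
#' @param reads character vector of read sequences
#' @param adapter3 3' adapter sequence
#' @param minOverlap minimum matched adapter prefix length (default 6)
#' @return character vector: trimmed sequences, \code{NA} where rejected
#' @examples
#' trimAdapter("TGAGGTAGTAGGTTGTATAGTTATCTCGTATGCCGT",
#'             "ATCTCGTATGCCGTCTTCTGCTTG")
#' @export
trimAdapter <- function(reads, adapter3, minOverlap = 6L) {
  adapter3 <- toupper(adapter3)
  alen <- nchar(adapter3)
  if (alen < minOverlap) stop("adapter must be at least minOverlap long")
  out <- rep(NA_character_, length(reads))
  if (!length(reads)) return(out)
  lens <- nchar(reads)
  for (n in unique(lens)) {
    idx <- which(lens == n)
    pending <- idx
    maxStart <- n - minOverlap + 1L
    if (maxStart < 1L) next
    for (i in seq_len(maxStart)) {
      if (!length(pending)) break
      cmpLen <- min(n - i + 1L, alen)
      hit <- substr(reads[pending], i, i + cmpLen - 1L) ==
        substr(adapter3, 1L, cmpLen)
      if (any(hit)) {
        matched <- pending[hit]
        out[matched] <- substr(reads[matched], 1L, i - 1L)
        pending <- pending[!hit]
      }
    }
  }
  out
}

#' Remove spike-in reads
#'
#' Removes every read whose full-length, equal-length, ungapped alignment to
#' any spike sequence has at most \code{maxMismatch} mismatches. Reads whose
#' length differs from every spike are always retained (length-changing
#' matches would risk removing genuine small RNAs).
#'
#' @param reads character vector of (trimmed) read sequences, or a
#'   [UniqueReads-class]
#' @param spikes character vector of spike-in sequences (must be non-empty)
#' @param maxMismatch mismatch tolerance (default 1)
#' @return list with elements \code{reads} (same type as the input, spikes
#'   removed) and \code{nRemoved} (total read count removed)
#' @export
removeSpikes <- function(reads, spikes, maxMismatch = 1L) {
  if (!length(spikes)) stop("spike removal enabled with an empty spike list")
  spikes <- toupper(spikes)
  isUR <- is(reads, "UniqueReads")
  seqs <- if (isUR) reads@sequence else reads
  counts <- if (isUR) reads@count else rep(1L, length(seqs))
  drop <- rep(FALSE, length(seqs))
  lens <- nchar(seqs)
  for (sp in spikes) {
    cand <- which(lens == nchar(sp) & !drop)
    if (!length(cand)) next
    ok <- grepl("^[ACGTN]*$", seqs[cand])
    cand <- cand[ok]
    if (!length(cand)) next
    hit <- Biostrings::vcountPattern(
      sp, Biostrings::DNAStringSet(seqs[cand]),
      max.mismatch = maxMismatch) > 0L
    drop[cand[hit]] <- TRUE
  }
  kept <- if (isUR) UniqueReads(seqs[!drop], counts[!drop]) else seqs[!drop]
  list(reads = kept, nRemoved = sum(counts[drop]))
}

#' Collapse reads and apply singleton/length filters
#'
#' Groups identical trimmed sequences into unique reads with occurrence
#' counts, then removes sequences shorter than \code{minLen} (counting all
#' their occurrences) and, when \code{dropSingletons} is set, distinct
#' sequences whose total library count is 1. A sequence that is both short
#' and a singleton is accounted as short-removed, so the disposition ledger
#' partitions the input exactly.
#'
#' @param sequences character vector of trimmed read sequences
#' @param minLen minimum retained sequence length (default 17)
#' @param dropSingletons remove count-1 sequences (default TRUE)
#' @param nAdapterRejected,nSpikeRemoved read counts disposed of by earlier
#'   stages, carried into the ledger
#' @return list with elements \code{reads} (a [UniqueReads-class]) and
#'   \code{report} (a [FilterReport-class])
#' @export
collapseAndFilter <- function(sequences, minLen = 17L, dropSingletons = TRUE,
                              nAdapterRejected = 0L, nSpikeRemoved = 0L) {
  tab <- table(sequences)
  seqs <- names(tab)
  counts <- as.integer(tab)
  short <- nchar(seqs) < minLen
  singleton <- !short & counts == 1L & dropSingletons
  keep <- !short & !singleton
  reads <- UniqueReads(seqs[keep], counts[keep])
  report <- new("FilterReport",
    nInputReads = as.integer(length(sequences) + nAdapterRejected +
                               nSpikeRemoved),
    nAdapterRejected = as.integer(nAdapterRejected),
    nSpikeRemoved = as.integer(nSpikeRemoved),
    nSingletonsRemoved = as.integer(sum(counts[singleton])),
    nShortRemoved = as.integer(sum(counts[short])),
    nReadsRetained = as.integer(sum(counts[keep])),
    nUniqueRetained = as.integer(sum(keep)))
  list(reads = reads, report = report)
}

#' Count-weighted read length histogram
#'
#' @param reads a [UniqueReads-class]
#' @return named integer vector mapping length to total read count, in
#'   increasing length order; sums to the total retained read count
#' @export
lengthHistogram <- function(reads) {
  if (!length(reads@sequence)) return(setNames(integer(0), character(0)))
  h <- tapply(reads@count, nchar(reads@sequence), sum)
  v <- as.integer(h)
  names(v) <- names(h)
  v[order(as.integer(names(v)))]
}

# Read a FASTQ or FASTA file into a character vector of sequences.
readReadFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(character(0))
  if (startsWith(lines[1L], "@")) {
    if (length(lines) %% 4L != 0L)
      stop("malformed FASTQ (line count not a multiple of 4): ", path)
    toupper(lines[seq(2L, length(lines), by = 4L)])
  } else if (startsWith(lines[1L], ">")) {
    toupper(as.character(Biostrings::readBStringSet(path)))
  } else {
    stop("unrecognized read file format (expected FASTA or FASTQ): ", path)
  }
}

#' Preprocess a raw read library
#'
#' Runs the full preprocessing chain on a FASTQ/FASTA file or an in-memory
#' read vector: 3'-adapter trimming, spike-in removal (skipped when
#' \code{spikes} is empty), collapsing, and singleton/length filtering, with
#' an exact read-disposition ledger.
#'
#' @param input path to a FASTQ/FASTA file, or a character vector of reads
#' @param adapter3 3' adapter sequence
#' @param spikes character vector of spike-in insert sequences (may be
#'   empty to disable the stage)
#' @param minLen minimum retained insert length (default 17)
#' @param dropSingletons remove count-1 sequences (default TRUE)
#' @param minOverlap minimum adapter overlap for trimming (default 6)
#' @param maxSpikeMismatch mismatch tolerance for spike removal (default 1)
#' @return list with elements \code{reads} (a [UniqueReads-class]) and
#'   \code{report} (a [FilterReport-class])
#' @export
preprocessReads <- function(input, adapter3, spikes = character(),
                            minLen = 17L, dropSingletons = TRUE,
                            minOverlap = 6L, maxSpikeMismatch = 1L) {
  raw <- if (length(input) == 1L && file.exists(input)) readReadFile(input)
         else as.character(input)
  trimmed <- trimAdapter(raw, adapter3, minOverlap = minOverlap)
  rejected <- is.na(trimmed)
  trimmed <- trimmed[!rejected]
  nSpike <- 0L
  if (length(spikes)) {
    sr <- removeSpikes(trimmed, spikes, maxMismatch = maxSpikeMismatch)
    trimmed <- sr$reads
    nSpike <- sr$nRemoved
  }
  collapseAndFilter(trimmed, minLen = minLen, dropSingletons = dropSingletons,
                    nAdapterRejected = sum(rejected), nSpikeRemoved = nSpike)
}
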