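# Reference-set IO: FASTA references, repeat locus headers, RepeatMasker
# catalog, and the assembled ReferenceBundle.

#' @importFrom Biostrings readBStringSet DNAStringSet vcountPattern width
#' @useDynLib smallRNAcascade, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Load a FASTA reference set
#'
#' Reads a (possibly multi-line) FASTA file into a named
#' [Biostrings::DNAStringSet]. Sequences are upper-cased; with
#' \code{convertRna = TRUE} the RNA alphabet is converted to DNA (U -> T),
#' as required for references distributed as RNA (e.g. piRNA databases).
#' The record id is the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file
#' @param convertRna convert U/u to T/t before validation
#' @return named \code{DNAStringSet}, one element per FASTA entry
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1", "UGAGGUAG"), fa)
#' loadFasta(fa, convertRna = TRUE)
#' @export
loadFasta <- function(path, convertRna = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(raw) == 0L)) {
    bad <- names(raw)[Biostrings::width(raw) == 0L][1L]
    stop("malformed FASTA: entry '", bad, "' has a header but no sequence (",
         path, ")")
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate id(s) in reference set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (convertRna) seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop("non-ACGT characters in entry '", ids[which(bad)[1L]],
         "' (did you mean convertRna = TRUE?)")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a reference set to FASTA
#'
#' The inverse of [loadFasta()]: ids become headers, sequences are written
#' as given; with \code{rna = TRUE} sequences are emitted in the RNA
#' alphabet (T -> U), mirroring RNA-alphabet source databases.
#'
#' @param seqs named \code{DNAStringSet} or named character vector
#' @param path output path
#' @param rna emit RNA alphabet
#' @return \code{path}, invisibly
#' @export
writeReferenceFasta <- function(seqs, path, rna = FALSE) {
  # as.character() would strip the names of a plain character vector
  s <- if (is.character(seqs)) seqs else as.character(seqs)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("all sequences must be named")
  if (rna) s <- chartr("T", "U", s)
  writeLines(paste0(">", names(s), "\n", s), path)
  invisible(path)
}

#' Parse a repeat-reference FASTA header
#'
#' Repeat-RNA reference headers carry the locus accession, genomic
#' coordinates and RepeatMasker repeat name in a pipe-delimited layout:
#' \code{accession|chrom|start|end|strand|repeat_name}. Coordinates are
#' 1-based inclusive on the forward strand and are used for labeling only.
#'
#' @param header character vector of headers
#' @return \code{data.frame} with columns \code{accession}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{repeat_name}
#' @examples
#' parseRepeatHeader("hgur000839476|chr5|1000|1021|+|L1PB4")
#' @export
parseRepeatHeader <- function(header) {
  parts <- strsplit(header, "|", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 6L))
    stop("cannot parse repeat header (expected 6 pipe-delimited fields): '",
         header[which(n != 6L)[1L]], "'")
  m <- do.call(rbind, parts)
  out <- data.frame(
    accession = m[, 1L], chrom = m[, 2L],
    start = suppressWarnings(as.integer(m[, 3L])),
    end = suppressWarnings(as.integer(m[, 4L])),
    strand = m[, 5L], repeat_name = m[, 6L],
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end))
    stop("non-numeric coordinates in repeat header: '",
         header[which(is.na(out$start) | is.na(out$end))[1L]], "'")
  if (any(out$start > out$end))
    stop("start > end in repeat header: '",
         header[which(out$start > out$end)[1L]], "'")
  if (any(!out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in repeat header: '",
         header[which(!out$strand %in% c("+", "-"))[1L]], "'")
  out
}

#' Format repeat locus annotations as FASTA headers
#'
#' Inverse of [parseRepeatHeader()].
#'
#' @param anno \code{data.frame} with the [parseRepeatHeader()] columns
#' @return character vector of headers
#' @export
formatRepeatHeader <- function(anno) {
  paste(anno$accession, anno$chrom, anno$start, anno$end, anno$strand,
        anno$repeat_name, sep = "|")
}

#' Load a RepeatMasker name/class/family catalog
#'
#' Tab-separated file with a header line \code{name<TAB>class<TAB>family}.
#' Later duplicate rows override earlier ones (with a warning). Lookups of
#' names absent from the catalog resolve to \code{"Unknown"}.
#'
#' @param path path to the catalog TSV
#' @return a [RepeatCatalog-class]
#' @export
loadRepeatCatalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, sep = "\t")
  missing <- setdiff(c("name", "class", "family"), names(tb))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  RepeatCatalog(tb[, c("name", "class", "family")])
}

#' Write a RepeatCatalog to TSV
#'
#' @param catalog a [RepeatCatalog-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeRepeatCatalog <- function(catalog, path) {
  utils::write.table(catalog@table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.bundleFiles <- c(
  mature = "mature.fa", matureStar = "mature_star.fa", hairpin = "hairpin.fa",
  pirna = "pirna.fa", repeatSense = "repeat_sense.fa",
  repeatAntisense = "repeat_antisense.fa", catalog = "repeat_catalog.tsv"
)

#' Read a complete reference bundle from a directory
#'
#' Expects the file layout written by [writeReferenceBundle()]:
#' \code{mature.fa}, \code{mature_star.fa}, \code{hairpin.fa},
#' \code{pirna.fa} (RNA alphabet allowed), \code{repeat_sense.fa} /
#' \code{repeat_antisense.fa} (headers in the [parseRepeatHeader()] dialect)
#' and \code{repeat_catalog.tsv}.
#'
#' @param dir directory containing the reference files
#' @return a [ReferenceBundle-class]
#' @export
readReferenceBundle <- function(dir) {
  path <- function(f) file.path(dir, f)
  for (f in .bundleFiles)
    if (!file.exists(path(f))) stop("missing reference file: ", path(f))
  readRepeats <- function(f) {
    raw <- Biostrings::readBStringSet(path(f))
    anno <- parseRepeatHeader(names(raw))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(raw)))
    names(seqs) <- anno$accession
    list(seqs = seqs, anno = anno)
  }
  sense <- readRepeats(.bundleFiles[["repeatSense"]])
  anti <- readRepeats(.bundleFiles[["repeatAntisense"]])
  new("ReferenceBundle",
      mature = loadFasta(path(.bundleFiles[["mature"]])),
      matureStar = loadFasta(path(.bundleFiles[["matureStar"]])),
      hairpin = loadFasta(path(.bundleFiles[["hairpin"]])),
      pirna = loadFasta(path(.bundleFiles[["pirna"]]), convertRna = TRUE),
      repeatSense = sense$seqs, repeatAnnoSense = sense$anno,
      repeatAntisense = anti$seqs, repeatAnnoAntisense = anti$anno,
      catalog = loadRepeatCatalog(path(.bundleFiles[["catalog"]])))
}

#' Write a reference bundle to a directory
#'
#' piRNA sequences are emitted in the RNA alphabet (as piRNA databases
#' distribute them); repeat references carry pipe-delimited locus headers.
#'
#' @param bundle a [ReferenceBundle-class]
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeReferenceBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  writeReferenceFasta(bundle@mature, path(.bundleFiles[["mature"]]))
  writeReferenceFasta(bundle@matureStar, path(.bundleFiles[["matureStar"]]))
  writeReferenceFasta(bundle@hairpin, path(.bundleFiles[["hairpin"]]))
  writeReferenceFasta(bundle@pirna, path(.bundleFiles[["pirna"]]), rna = TRUE)
  for (ori in c("Sense", "Antisense")) {
    seqs <- as.character(slot(bundle, paste0("repeat", ori)))
    names(seqs) <- formatRepeatHeader(slot(bundle, paste0("repeatAnno", ori)))
    writeReferenceFasta(seqs, path(.bundleFiles[[paste0(
      "repeat", ori)]]))
  }
  writeRepeatCatalog(bundle@catalog, path(.bundleFiles[["catalog"]]))
  invisible(dir)
}
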