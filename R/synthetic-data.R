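# Synthetic two-library experiment generator: species truth table,
# references, seeded read simulation and ground-truth IO.

#' @importFrom stats rlnorm
NULL

.speciesCategories <- c("mature", "mature_star", "hairpin_only", "pirna",
                        "repeat_sense", "repeat_antisense", "noise")

#' Specification of a synthetic two-library experiment
#'
#' Bundles the species truth table with the experiment-level constants: the
#' master seed, the 3' adapter, and the two spike-in sequences (a silencing
#' construct analogue added to library B and a scrambled control analogue
#' added to library A, emulating introduced siRNA sequences that must be
#' removed before mapping).
#'
#' @param specs \code{data.frame} with columns \code{species_id},
#'   \code{category} (one of mature, mature_star, hairpin_only, pirna,
#'   repeat_sense, repeat_antisense, noise), \code{sequence} (DNA),
#'   \code{base_abundance} (expected read count in library A),
#'   \code{log2_fc} (true log2 fold change of B over A) and
#'   \code{repeat_name} (NA except for repeat categories).
#' @param seed master seed; per-library streams are derived from it
#' @param adapter3 3' adapter sequence appended to every insert
#' @param spikeA,spikeB spike-in insert sequences (20-25 nt, distinct);
#'   \code{spikeA} is added to library A only, \code{spikeB} to library B
#' @param readLength sequencing read length (cycles)
#' @param spikeDepth expected spike-in read count per library
#' @return an object of class \code{ExperimentTruth}
#' @export
ExperimentTruth <- function(specs, seed = 1L,
                            adapter3 = "ATCTCGTATGCCGTCTTCTGCTTG",
                            spikeA = "TGCATCGTAACGTTAGCCTAGA",
                            spikeB = "AGGTCAATCGGTAGCTTACCGT",
                            readLength = 36L, spikeDepth = 3000) {
  specs <- as.data.frame(specs, stringsAsFactors = FALSE)
  new("ExperimentTruth", specs = specs, seed = as.integer(seed),
      adapter3 = toupper(adapter3), spikeA = toupper(spikeA),
      spikeB = toupper(spikeB), readLength = as.integer(readLength),
      spikeDepth = as.numeric(spikeDepth))
}

#' @rdname ExperimentTruth
#' @slot specs species truth table (see constructor)
#' @slot seed master seed
#' @slot adapter3,spikeA,spikeB experiment constants (see constructor)
#' @slot readLength,spikeDepth simulation parameters
#' @export
setClass("ExperimentTruth", representation(
  specs = "data.frame", seed = "integer", adapter3 = "character",
  spikeA = "character", spikeB = "character", readLength = "integer",
  spikeDepth = "numeric"
))

setValidity("ExperimentTruth", function(object) {
  sp <- object@specs
  need <- c("species_id", "category", "sequence", "base_abundance", "log2_fc",
            "repeat_name")
  if (!all(need %in% names(sp)))
    return(paste("specs must have columns", paste(need, collapse = ", ")))
  if (nrow(sp) == 0L) return("specs must be non-empty")
  if (anyDuplicated(sp$species_id)) return("species ids must be unique")
  if (anyDuplicated(sp$sequence))
    return("spec sequences collide across species")
  if (any(!sp$category %in% .speciesCategories))
    return("unknown species category")
  if (any(sp$base_abundance < 0)) return("base_abundance must be >= 0")
  len <- nchar(sp$sequence)
  short <- sp$category %in% c("mature", "mature_star", "repeat_sense",
                              "repeat_antisense")
  if (any(len[short] < 18L | len[short] > 23L))
    return("mature/mature-star/repeat sequences must be 18-23 nt")
  if (any(len[sp$category == "pirna"] < 24L |
            len[sp$category == "pirna"] > 31L))
    return("piRNA sequences must be 24-31 nt")
  if (object@spikeA == object@spikeB) return("spikeA and spikeB must differ")
  if (any(nchar(c(object@spikeA, object@spikeB)) < 20L) ||
        any(nchar(c(object@spikeA, object@spikeB)) > 25L))
    return("spike sequences must be 20-25 nt")
  if (any(sp$sequence %in% c(object@spikeA, object@spikeB)))
    return("spec sequences collide with spike sequences")
  TRUE
})

setMethod("show", "ExperimentTruth", function(object) {
  cat(sprintf("ExperimentTruth: %d species, seed %d\n",
              nrow(object@specs), object@seed))
  print(table(object@specs$category))
})

#' @describeIn ExperimentTruth the species truth table
#' @param truth an \code{ExperimentTruth}
#' @export
truthSpecs <- function(truth) truth@specs

.repeatFamilyMap <- data.frame(
  name = c("L1PB4", "L1M5", "L1M7", "L1MC5", "MIRc", "L2", "AluY", "LTR33"),
  class = c("LINE", "LINE", "LINE", "LINE", "SINE", "LINE", "SINE", "LTR"),
  family = c("L1", "L1", "L1", "L1", "MIR", "L2", "Alu", "ERVL"),
  stringsAsFactors = FALSE
)
# Names deliberately absent from the catalog, to exercise the "Unknown"
# class/family route (scRNA/snoRNA/tRNA-like entries).
.uncataloguedNames <- c("HY1", "U3", "tRNA-like")

#' Default experiment preset
#'
#' Builds a species truth table that qualitatively mirrors the structure of
#' an L1-active vs L1-silenced two-library small RNA experiment: ~200
#' expressed miRNA species with a length mode at 22-23 nt, a five-member
#' near-identical let-7-like mature family strongly up-regulated in library
#' B (true log2 fold changes between 2 and 4), additional up- and
#' down-regulated miRNAs, mature-star and hairpin-only species, ~50
#' expressed piRNA species (24-30 nt) with a few strong changes in both
#' directions, ~100 repeat loci in both orientations across several
#' RepeatMasker families (L1 loci more abundant than L2), repeat names with
#' no catalog entry (routed to "Unknown"), zero-abundance species that
#' enlarge the known reference universe, and singleton noise reads.
#'
#' @param seed master seed; the preset is fully deterministic given it
#' @param nNoise number of singleton noise species per library
#' @return an [ExperimentTruth] object
#' @export
paperlikeTruth <- function(seed = 1L, nNoise = 400L) {
  withSeed(seed * 13L + 7L, {
    rows <- list()
    used <- character()
    addRow <- function(id, category, sequence, ab, fc, rep_name = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        species_id = id, category = category, sequence = sequence,
        base_abundance = ab, log2_fc = fc, repeat_name = rep_name,
        stringsAsFactors = FALSE)
      used <<- c(used, sequence)
    }

    # let-7-like family: five mature species within Hamming distance <= 1
    # of a shared archetype, all strongly up in library B.
    let7 <- "TGAGGTAGTAGGTTGTATAGTT"
    pos <- c(17L, 9L, 13L, 20L)
    alt <- c(G = "A", A = "G", C = "T", T = "C")
    fam <- c(let7, vapply(pos, function(p) {
      s <- strsplit(let7, "")[[1]]
      s[p] <- alt[[s[p]]]
      paste(s, collapse = "")
    }, character(1)))
    famFc <- c(3.5, 3.0, 4.0, 2.5, 2.2)
    famAb <- c(2000, 1200, 800, 600, 400)
    for (i in seq_along(fam))
      addRow(sprintf("let7-like-%d", i), "mature", fam[i], famAb[i], famFc[i])

    # remaining expressed mature miRNAs: mostly null, 10 up (fc 2-4),
    # 5 down (fc -3..-1.5)
    nMat <- 195L
    matSeq <- randomSequences(nMat, sample(21:23, nMat, replace = TRUE,
                                           prob = c(0.2, 0.5, 0.3)),
                              avoid = used)
    matAb <- pmax(5, round(rlnorm(nMat, log(150), 1)))
    matFc <- rep(0, nMat)
    matFc[1:10] <- round(runif(10, 2, 4), 2)
    matFc[11:15] <- round(runif(5, -3, -1.5), 2)
    for (i in seq_len(nMat))
      addRow(sprintf("mir-%03d", i), "mature", matSeq[i], matAb[i], matFc[i])

    # zero-abundance mature species: known in the reference, never expressed
    nExtra <- 150L
    extraSeq <- randomSequences(nExtra, sample(21:23, nExtra, replace = TRUE),
                                avoid = used)
    for (i in seq_len(nExtra))
      addRow(sprintf("mir-x%03d", i), "mature", extraSeq[i], 0, 0)

    # mature-star species for a subset of the expressed miRNAs
    nStar <- 30L
    starSeq <- randomSequences(nStar, sample(21:22, nStar, replace = TRUE),
                               avoid = used)
    starFc <- rep(0, nStar)
    starFc[1:3] <- c(2.5, -2.5, 3.0)
    for (i in seq_len(nStar))
      addRow(sprintf("mir-%03d-star", i), "mature_star", starSeq[i],
             sample(5:50, 1), starFc[i])

    # hairpin-only species (loop-spanning reads seen only at the hairpin
    # stage)
    nHp <- 10L
    hpSeq <- randomSequences(nHp, sample(20:23, nHp, replace = TRUE),
                             avoid = used)
    for (i in seq_len(nHp))
      addRow(sprintf("hp-only-%02d", i), "hairpin_only", hpSeq[i],
             sample(10:60, 1), 0)

    # piRNAs: 24-30 nt (31-nt inserts are unrecoverable at 36 cycles with
    # the 6 nt minimum adapter overlap, and the library gel window tops out
    # at 30 nt); a few strong changes in both directions
    nPi <- 50L
    piSeq <- randomSequences(nPi, sample(24:30, nPi, replace = TRUE,
                                         prob = c(1, 2, 3, 3, 2, 1, 1)),
                             avoid = used)
    piAb <- pmax(5, round(rlnorm(nPi, log(60), 0.8)))
    piFc <- rep(0, nPi)
    piFc[1:4] <- round(runif(4, 3, 4.5), 2)
    piFc[5:8] <- round(runif(4, -4.5, -3), 2)
    for (i in seq_len(nPi))
      addRow(sprintf("piR-%05d", i), "pirna", piSeq[i], piAb[i], piFc[i])
    nPiExtra <- 100L
    piExtra <- randomSequences(nPiExtra, sample(24:30, nPiExtra, replace = TRUE),
                               avoid = used)
    for (i in seq_len(nPiExtra))
      addRow(sprintf("piR-x%04d", i), "pirna", piExtra[i], 0, 0)

    # repeat loci, both orientations; L1 families dominate L2 in abundance
    repNames <- c(.repeatFamilyMap$name, .uncataloguedNames)
    nRep <- 100L
    repName <- sample(rep(repNames, length.out = nRep))
    repOri <- rep(c("repeat_sense", "repeat_antisense"), length.out = nRep)
    repSeq <- randomSequences(nRep, sample(18:23, nRep, replace = TRUE,
                                           prob = c(1, 1, 2, 3, 4, 3)),
                              avoid = used)
    isL1 <- repName %in% c("L1PB4", "L1M5", "L1M7", "L1MC5")
    isL2 <- repName == "L2"
    repAb <- pmax(3, round(rlnorm(nRep, log(30), 0.7)))
    repAb[isL1] <- pmax(50, round(rlnorm(sum(isL1), log(250), 0.6)))
    repAb[isL2] <- pmax(3, round(rlnorm(sum(isL2), log(10), 0.5)))
    repFc <- rep(0, nRep)
    # a few sense L1 loci down in B, a couple of antisense MIRc loci up,
    # and scRNA/snoRNA/tRNA-like loci (no catalog entry) up 2.6-4x in B
    dn <- which(isL1 & repOri == "repeat_sense")[1:3]
    repFc[dn] <- c(-2.5, -3, -2)
    up <- which(repName == "MIRc" & repOri == "repeat_antisense")
    repFc[up[seq_len(min(2, length(up)))]] <- 2.5
    unc <- which(repName %in% .uncataloguedNames)
    repFc[unc] <- round(runif(length(unc), log2(2.6), 2), 2)
    repAb[unc] <- pmax(repAb[unc], 15)
    for (i in seq_len(nRep))
      addRow(sprintf("hgur%09d", i), repOri[i], repSeq[i], repAb[i],
             repFc[i], rep_name = repName[i])

    # singleton noise species (count exactly 1 in each library)
    noiseSeq <- randomSequences(nNoise, sample(17:28, nNoise, replace = TRUE),
                                avoid = used)
    for (i in seq_len(nNoise))
      addRow(sprintf("noise-%04d", i), "noise", noiseSeq[i], 1, 0)

    specs <- do.call(rbind, rows)
    ExperimentTruth(specs, seed = seed)
  })
}

#' Generate the reference bundle implied by an experiment truth
#'
#' Emits mature and mature-star records for the miRNA species, a hairpin
#' precursor per mature species containing the mature (and, where present,
#' the star) sequence verbatim, dedicated hairpins containing each
#' hairpin-only species, piRNA records, repeat records with pipe-delimited
#' locus headers, and the repeat-name catalog (names like HY1/U3/tRNA-like
#' are deliberately left out of the catalog so they resolve to "Unknown").
#'
#' @param truth an [ExperimentTruth]
#' @return a [ReferenceBundle-class]
#' @export
generateReferences <- function(truth) {
  sp <- truth@specs
  withSeed(truth@seed * 13L + 101L, {
    mat <- sp[sp$category == "mature", ]
    star <- sp[sp$category == "mature_star", ]
    hpOnly <- sp[sp$category == "hairpin_only", ]

    mature <- setNames(mat$sequence, mat$species_id)
    matureStar <- setNames(star$sequence, star$species_id)

    # hairpins: flank5 + mature (+ loop + star) + flank3
    starParent <- sub("-star$", "", star$species_id)
    hairpin <- character(0)
    for (i in seq_len(nrow(mat))) {
      flank5 <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      flank3 <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
      j <- match(mat$species_id[i], starParent)
      body <- if (!is.na(j)) {
        loop <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
        paste0(mat$sequence[i], loop, star$sequence[j])
      } else mat$sequence[i]
      hairpin[paste0("hp-", mat$species_id[i])] <-
        paste0(flank5, body, flank3)
    }
    for (i in seq_len(nrow(hpOnly))) {
      flank5 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
      flank3 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
      hairpin[paste0("hp-", hpOnly$species_id[i])] <-
        paste0(flank5, hpOnly$sequence[i], flank3)
    }

    pir <- sp[sp$category == "pirna", ]
    pirna <- setNames(pir$sequence, pir$species_id)

    makeRepeat <- function(category) {
      rr <- sp[sp$category == category, ]
      n <- nrow(rr)
      st <- sample(1e4:1e6, n, replace = TRUE)
      anno <- data.frame(
        accession = rr$species_id,
        chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
        start = st,
        end = st + nchar(rr$sequence) - 1L,
        strand = sample(c("+", "-"), n, replace = TRUE),
        repeat_name = rr$repeat_name,
        stringsAsFactors = FALSE)
      seqs <- Biostrings::DNAStringSet(setNames(rr$sequence, rr$species_id))
      list(seqs = seqs, anno = anno)
    }
    sen <- makeRepeat("repeat_sense")
    ant <- makeRepeat("repeat_antisense")

    new("ReferenceBundle",
        mature = Biostrings::DNAStringSet(mature),
        matureStar = Biostrings::DNAStringSet(matureStar),
        hairpin = Biostrings::DNAStringSet(hairpin),
        pirna = Biostrings::DNAStringSet(pirna),
        repeatSense = sen$seqs, repeatAnnoSense = sen$anno,
        repeatAntisense = ant$seqs, repeatAnnoAntisense = ant$anno,
        catalog = RepeatCatalog(.repeatFamilyMap))
  })
}

#' Simulate the reads of one library
#'
#' For each species the realized read count is Poisson with mean
#' \code{base_abundance} (library A) or \code{base_abundance * 2^log2_fc}
#' (library B); noise species contribute exactly one read each. Every read
#' is the insert followed by the 3' adapter, truncated to the read length.
#' The library A spike (scrambled control analogue) is added to library A
#' only; the library B spike to library B only. Deterministic given the
#' seed: per-library streams are derived as master seed + library index.
#'
#' @param truth an [ExperimentTruth]
#' @param library \code{"A"} or \code{"B"}
#' @param seed master seed (defaults to the truth's seed)
#' @param path optional output file; when given, reads are written as FASTQ
#'   (constant quality \code{"I"}) or FASTA according to \code{format}
#' @param format \code{"fastq"} or \code{"fasta"}
#' @return character vector of read sequences, invisibly when \code{path}
#'   is given
#' @export
generateLibrary <- function(truth, library = c("A", "B"), seed = truth@seed,
                            path = NULL, format = c("fastq", "fasta")) {
  library <- match.arg(library)
  format <- match.arg(format)
  sp <- truth@specs
  streamSeed <- as.integer(seed) * 2L + (library == "B")
  reads <- withSeed(streamSeed, {
    mean <- sp$base_abundance * if (library == "B") 2^sp$log2_fc else 1
    counts <- rpois(nrow(sp), mean)
    counts[sp$category == "noise"] <- 1L
    inserts <- c(rep(sp$sequence, counts),
                 rep(if (library == "A") truth@spikeA else truth@spikeB,
                     rpois(1L, truth@spikeDepth)))
    if (!length(inserts)) character(0)
    else substr(paste0(inserts, truth@adapter3), 1L, truth@readLength)
  })
  if (!is.null(path)) {
    ids <- sprintf("read%07d", seq_along(reads))
    if (format == "fastq") {
      qual <- strrep("I", nchar(reads))
      writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), path)
    } else {
      writeLines(paste0(">", ids, "\n", reads), path)
    }
    return(invisible(reads))
  }
  reads
}

#' Write the ground-truth species table
#'
#' @param truth an [ExperimentTruth]
#' @param path output TSV path
#' @param excludeNoise drop noise species from the table
#' @return \code{path}, invisibly
#' @export
writeGroundTruth <- function(truth, path, excludeNoise = FALSE) {
  sp <- truth@specs[, c("species_id", "category", "base_abundance",
                        "log2_fc", "repeat_name")]
  if (excludeNoise) sp <- sp[sp$category != "noise", ]
  writeTsv(sp, path)
}

#' Read a ground-truth species table written by [writeGroundTruth()]
#'
#' @param path TSV path
#' @return \code{data.frame}
#' @export
readGroundTruth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Simulate a complete experiment to disk
#'
#' Writes the reference bundle, both read libraries and the ground truth
#' under \code{outdir}.
#'
#' @param outdir output directory
#' @param seed master seed
#' @param preset currently only \code{"paperlike"} (see [paperlikeTruth()])
#' @param format read file format, \code{"fastq"} or \code{"fasta"}
#' @return named list of output paths, with the truth attached as
#'   attribute \code{"truth"}, invisibly
#' @export
simulateExperiment <- function(outdir, seed = 1L, preset = "paperlike",
                               format = c("fastq", "fasta")) {
  preset <- match.arg(preset, "paperlike")
  format <- match.arg(format)
  truth <- paperlikeTruth(seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  refdir <- file.path(outdir, "references")
  writeReferenceBundle(generateReferences(truth), refdir)
  ext <- if (format == "fastq") ".fastq" else ".fasta"
  pathA <- file.path(outdir, paste0("reads_A", ext))
  pathB <- file.path(outdir, paste0("reads_B", ext))
  generateLibrary(truth, "A", seed = seed, path = pathA, format = format)
  generateLibrary(truth, "B", seed = seed, path = pathB, format = format)
  truthPath <- file.path(outdir, "ground_truth.tsv")
  writeGroundTruth(truth, truthPath)
  out <- list(references = refdir, readsA = pathA, readsB = pathB,
              groundTruth = truthPath)
  attr(out, "truth") <- truth
  invisible(out)
}
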