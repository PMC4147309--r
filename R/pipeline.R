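# End-to-end orchestration: preprocess -> annotate -> destats ->
# aggregate/report, for both libraries, with TSV artifacts and a
# machine-readable run log.

#' @importFrom jsonlite write_json
NULL

.defaultConfig <- list(
  adapter3 = "ATCTCGTATGCCGTCTTCTGCTTG", spikes = character(),
  minLen = 17L, minOverlap = 6L, maxSpikeMismatch = 1L,
  boundary = 23L, branchFromLeftover = FALSE,
  gfoldC = 0.01, nDraws = 10000L, upThreshold = 2.0, downThreshold = -0.5,
  dropLowThreshold = 1, seed = 1L
)

# Assemble the per-category stats table consumed by summarizeReport() from
# the per-library cascade and branch results.
.categoryStats <- function(cascade, pirna, repSense, repAnti, library) {
  cs <- cascadeStats(cascade)
  rows <- data.frame(category = cs$category, library = library,
                     speciesDetected = cs$speciesDetected,
                     uniqueReads = cs$uniqueReads, readCount = cs$readCount,
                     stringsAsFactors = FALSE)
  branchRow <- function(branch, category) {
    data.frame(category = category, library = library,
               speciesDetected = branchSpeciesDetected(branch),
               uniqueReads = NA_real_,
               readCount = branchReadsMapped(branch),
               stringsAsFactors = FALSE)
  }
  rbind(rows, branchRow(pirna, "pirna"), branchRow(repSense, "repeat_sense"),
        branchRow(repAnti, "repeat_antisense"))
}

#' Run the full two-library analysis pipeline
#'
#' Executes preprocessing, the sequential miRNA cascade, the length-routed
#' piRNA and repeat branches, per-universe median-of-ratios normalization,
#' generalized fold changes with DE calls, Bland-Altman summaries, and
#' RepeatMasker aggregation for both libraries, writing all tabular
#' artifacts and a machine-readable run log to \code{config$outdir}.
#' Identical configuration and seed produce identical outputs.
#'
#' @param config named list (or path to a YAML file) with required fields
#'   \code{readsA}, \code{readsB} (FASTQ/FASTA paths), \code{references}
#'   (bundle directory for [readReferenceBundle()]) and \code{outdir}, and
#'   optional fields \code{adapter3}, \code{spikes} (character vector),
#'   \code{minLen}, \code{minOverlap}, \code{maxSpikeMismatch},
#'   \code{boundary}, \code{branchFromLeftover}, \code{gfoldC},
#'   \code{nDraws}, \code{upThreshold}, \code{downThreshold},
#'   \code{dropLowThreshold}, \code{seed}
#' @return named list of all intermediate and final objects, invisibly
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  for (field in c("readsA", "readsB", "references", "outdir"))
    if (is.null(config[[field]]))
      stop("configuration error: missing required field '", field, "'")
  for (field in c("readsA", "readsB", "references"))
    if (!file.exists(config[[field]]))
      stop("configuration error: '", field, "' path does not exist: ",
           config[[field]])
  cfg <- utils::modifyList(.defaultConfig, config)

  bundle <- readReferenceBundle(cfg$references)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  libs <- list(A = cfg$readsA, B = cfg$readsB)
  pre <- lapply(names(libs), function(lib) stage(
    paste0("preprocess/", lib),
    preprocessReads(libs[[lib]], adapter3 = cfg$adapter3,
                    spikes = cfg$spikes, minLen = cfg$minLen,
                    minOverlap = cfg$minOverlap,
                    maxSpikeMismatch = cfg$maxSpikeMismatch)))
  names(pre) <- names(libs)

  cascade <- lapply(names(libs), function(lib) stage(
    paste0("cascade/", lib), runMirnaCascade(pre[[lib]]$reads, bundle)))
  names(cascade) <- names(libs)

  branchInput <- lapply(names(libs), function(lib)
    if (isTRUE(cfg$branchFromLeftover)) cascadeLeftover(cascade[[lib]])
    else pre[[lib]]$reads)
  names(branchInput) <- names(libs)
  routed <- lapply(branchInput, routeByLength, boundary = cfg$boundary)
  branchPolicy <- alignmentPolicy(maxMismatches = 2L)
  pirna <- lapply(routed, function(r)
    mapBranch(r$long, pirnaRef(bundle), branchPolicy))
  repSense <- lapply(routed, function(r)
    mapBranch(r$short, repeatRef(bundle, "sense"), branchPolicy))
  repAnti <- lapply(routed, function(r)
    mapBranch(r$short, repeatRef(bundle, "antisense"), branchPolicy))

  # per-universe count tables (each annotation universe is normalized
  # independently)
  matureCounts <- lapply(cascade, function(cr)
    cascadeCategory(cr, "mature")[, c("refId", "readCount")])
  tables <- list(
    mirna = buildCountTable(matureCounts$A, matureCounts$B),
    pirna = buildCountTable(branchCounts(pirna$A)[, c("refId", "readCount")],
                            branchCounts(pirna$B)[, c("refId", "readCount")]),
    repeat_sense = buildCountTable(
      branchCounts(repSense$A)[, c("refId", "readCount")],
      branchCounts(repSense$B)[, c("refId", "readCount")]),
    repeat_antisense = buildCountTable(
      branchCounts(repAnti$A)[, c("refId", "readCount")],
      branchCounts(repAnti$B)[, c("refId", "readCount")]))
  factors <- lapply(tables, function(tb) stage("normalize",
                                               medianRatioFactors(tb)))
  normTables <- mapply(normalizeCounts, tables, factors, SIMPLIFY = FALSE)
  normTables$pirna <- dropLow(normTables$pirna, cfg$dropLowThreshold)

  de <- lapply(c(mirna = "mirna", pirna = "pirna"), function(u) {
    recs <- stage(paste0("gfold/", u),
                  gfoldTable(tables[[u]], factors[[u]], c = cfg$gfoldC,
                             nDraws = cfg$nDraws, seed = cfg$seed))
    c(list(records = recs),
      callDE(recs, cfg$upThreshold, cfg$downThreshold))
  })

  ba <- lapply(normTables, blandAltman)

  annotated <- rbind(
    annotateCounts(normTables$repeat_sense, bundle, "sense"),
    annotateCounts(normTables$repeat_antisense, bundle, "antisense"))
  classSummary <- accumulateCounts(annotated, "class")
  familySummary <- accumulateCounts(annotated, "family")
  unknown <- unknownBreakdown(annotated)

  knownSizes <- c(mature = length(matureRef(bundle)),
                  mature_star = length(matureStarRef(bundle)),
                  hairpin = length(hairpinRef(bundle)),
                  pirna = length(pirnaRef(bundle)))
  catStats <- rbind(
    .categoryStats(cascade$A, pirna$A, repSense$A, repAnti$A, "A"),
    .categoryStats(cascade$B, pirna$B, repSense$B, repAnti$B, "B"))
  totals <- data.frame(
    library = c("A", "B"),
    totalReads = c(pre$A$report@nReadsRetained, pre$B$report@nReadsRetained),
    totalUnique = c(pre$A$report@nUniqueRetained,
                    pre$B$report@nUniqueRetained))
  summary <- summarizeReport(catStats, totals, knownSizes)

  # artifacts
  writeTsv(summary, out("summary_report.tsv"))
  writeTsv(classSummary$totals, out("class_summary.tsv"))
  writeTsv(classSummary$ratios, out("class_ratios.tsv"))
  writeTsv(familySummary$totals, out("family_summary.tsv"))
  writeTsv(unknown, out("unknown_breakdown.tsv"))
  writeTsv(de$mirna$records, out("gfold_mirna.tsv"))
  writeTsv(de$pirna$records, out("gfold_pirna.tsv"))
  writeTsv(de$mirna$up, out("de_mirna_up.tsv"))
  writeTsv(de$mirna$down, out("de_mirna_down.tsv"))
  writeTsv(de$pirna$up, out("de_pirna_up.tsv"))
  writeTsv(de$pirna$down, out("de_pirna_down.tsv"))
  for (u in names(ba))
    writeTsv(ba[[u]]$points, out(paste0("bland_altman_", u, ".tsv")))
  for (u in names(tables))
    writeTsv(countFrame(normTables[[u]]), out(paste0("counts_", u, ".tsv")))

  runLog <- list(
    parameters = cfg[setdiff(names(cfg), "outdir")],
    sizeFactors = lapply(factors, function(f)
      list(sA = f$sA, sB = f$sB, nReferenceSpecies = f$nReferenceSpecies)),
    filterLedgers = lapply(pre, function(p)
      as.list(filterLedger(p$report))),
    cascadeConservation = lapply(cascade, function(cr) list(
      nInput = cr@nInput,
      assigned = sum(cascadeStats(cr)$uniqueReads),
      leftover = length(cascadeLeftover(cr))))
  )
  jsonlite::write_json(runLog, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(config = cfg, bundle = bundle, preprocess = pre,
                 cascade = cascade, pirna = pirna, repeatSense = repSense,
                 repeatAntisense = repAnti, tables = tables,
                 factors = factors, normTables = normTables, de = de,
                 blandAltman = ba, annotated = annotated,
                 classSummary = classSummary, familySummary = familySummary,
                 unknownBreakdown = unknown, summary = summary))
}
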