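makeAnno <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(accession = r[[1]], repeat_name = r[[2]], repeat_class = r[[3]],
               repeat_family = r[[4]], orientation = r[[5]],
               countA = as.numeric(r[[6]]), countB = as.numeric(r[[7]]),
               stringsAsFactors = FALSE)))
}

test_that("locus counts are annotated through the catalog", {
  truth <- makeTinyTruth(seed = 30)
  bundle <- generateReferences(truth)
  anno <- repeatAnnotation(bundle, "sense")
  tb <- CountTable(anno$accession, seq_len(nrow(anno)), rev(seq_len(nrow(anno))))
  ann <- annotateCounts(tb, bundle, "sense")
  expect_equal(nrow(ann), nrow(anno))
  # catalogued names resolve to their class/family
  l1 <- ann[ann$repeat_name == "L1PB4", ]
  expect_true(all(l1$repeat_class == "LINE" & l1$repeat_family == "L1"))
  # uncatalogued names resolve to Unknown
  unk <- ann[ann$repeat_name %in% c("HY1", "U3", "tRNA-like"), ]
  expect_true(nrow(unk) > 0)
  expect_true(all(unk$repeat_family == "Unknown"))
  # unknown accessions are reported by name
  bad <- CountTable("not-an-accession", 1, 1)
  expect_error(annotateCounts(bad, bundle, "sense"), "not-an-accession")
  # empty counts give an empty annotation
  expect_equal(nrow(annotateCounts(CountTable(character(0), numeric(0),
                                              numeric(0)), bundle, "sense")), 0)
})

test_that("accumulation sums exactly and ratios follow the zero rules", {
  ann <- makeAnno(
    list("x1", "L1PB4", "LINE", "L1", "sense", 4050, 4614),
    list("x2", "L2",    "LINE", "L2", "sense", 0, 0),
    list("x3", "L1M5",  "LINE", "L1", "antisense", 15165, 15052),
    list("x4", "AluY",  "SINE", "Alu", "sense", 100, 50))
  acc <- accumulateCounts(ann, "class")
  tot <- acc$totals
  expect_equal(tot$countA[tot$group == "LINE" & tot$orientation == "sense"],
               4050)
  expect_equal(tot$countA[tot$group == "LINE" & tot$orientation == "antisense"],
               15165)
  r <- acc$ratios
  expect_equal(r$ratioA[r$group == "LINE"], 15165 / 4050)  # = 3.7444
  expect_equal(displayRound(r$ratioA[r$group == "LINE"], 2), 3.74)
  expect_equal(r$ratioB[r$group == "LINE"], 15052 / 4614)
  # no antisense loci -> ratio 0
  expect_equal(r$ratioA[r$group == "SINE"], 0)
  # sense total 0 -> ratio absent
  annZ <- makeAnno(list("z1", "MIRc", "SINE", "MIR", "antisense", 10, 10))
  expect_true(is.na(accumulateCounts(annZ, "class")$ratios$ratioA))

  # accumulation conservation: class totals equal the sum of locus counts
  expect_equal(sum(tot$countA), sum(ann$countA))
  expect_equal(sum(tot$countB), sum(ann$countB))

  # family-level accumulation re-summed to class equals direct class totals
  fam <- accumulateCounts(ann, "family")$totals
  famToClass <- c(L1 = "LINE", L2 = "LINE", Alu = "SINE")
  re <- aggregate(cbind(countA, countB) ~ cls + orientation,
                  data = transform(fam, cls = famToClass[fam$group]), FUN = sum)
  for (i in seq_len(nrow(re))) {
    j <- tot$group == re$cls[i] & tot$orientation == re$orientation[i]
    expect_equal(tot$countA[j], re$countA[i])
    expect_equal(tot$countB[j], re$countB[i])
  }
})

test_that("class totals agree with a per-read brute-force tally", {
  truth <- makeTinyTruth(seed = 31)
  bundle <- generateReferences(truth)
  sp <- truthSpecs(truth)
  reads <- generateLibrary(truth, "A", seed = 31)
  pre <- preprocessReads(reads, truth@adapter3,
                         spikes = c(truth@spikeA, truth@spikeB))
  short <- routeByLength(pre$reads)$short
  bc <- mapBranch(short, repeatRef(bundle, "sense"))
  tb <- buildCountTable(branchCounts(bc)[, c("refId", "readCount")],
                        branchCounts(bc)[, c("refId", "readCount")])
  ann <- annotateCounts(tb, bundle, "sense")
  acc <- accumulateCounts(ann, "class")

  # oracle: tally trimmed reads read-by-read against the sense spec table
  trimmed <- trimAdapter(reads, truth@adapter3)
  trimmed <- trimmed[!is.na(trimmed)]
  sense <- sp[sp$category == "repeat_sense", ]
  cls <- repeatLookup(repeatCatalog(bundle), sense$repeat_name)$repeat_class
  # per-read tally, with the same singleton rule the preprocessor applies
  oracle <- tapply(vapply(sense$sequence, function(s) {
    n <- sum(trimmed == s)
    if (n == 1) 0 else n
  }, numeric(1)), cls, sum)
  for (g in names(oracle)) {
    got <- acc$totals$countA[acc$totals$group == g &
                               acc$totals$orientation == "sense"]
    expect_equal(if (length(got)) got else 0, unname(oracle[[g]]))
  }
})

test_that("the Unknown breakdown applies total and fold-change filters", {
  ann <- makeAnno(
    list("u1", "HY1", "Unknown", "Unknown", "sense", 5, 4),    # total 9: out
    list("u2", "U3", "Unknown", "Unknown", "sense", 10, 26),   # in, fc 2.6
    list("u3", "HY3", "Unknown", "Unknown", "sense", 0, 12),   # in, fc Inf
    list("u4", "U8", "Unknown", "Unknown", "sense", 30, 40),   # fc 1.3: out
    list("u5", "L1PB4", "LINE", "L1", "sense", 1000, 9000))    # not Unknown
  bd <- unknownBreakdown(ann)
  expect_setequal(bd$repeat_name, c("U3", "HY3"))
  expect_equal(bd$foldChange[bd$repeat_name == "U3"], 2.6)
  expect_true(is.infinite(bd$foldChange[bd$repeat_name == "HY3"]))
  expect_false("L1PB4" %in% bd$repeat_name)
})

test_that("summary fractions reproduce hand-checkable percentages", {
  cs <- data.frame(category = c("mature", "mature"), library = c("A", "B"),
                   speciesDetected = c(407, 460),
                   uniqueReads = c(16156, 18913),
                   readCount = c(3882279, 8076212))
  totals <- data.frame(library = c("A", "B"),
                       totalReads = c(21266358, 22745765))
  out <- summarizeReport(cs, totals, knownSizes = c(mature = 1032))
  expect_equal(displayRound(out$fractionKnownPct, 1), c(39.4, 44.6))
  expect_equal(displayRound(out$fractionTotalPct, 1), c(18.3, 35.5))
  expect_true(all(is.na(out$fractionUniquePct)))
  # all-zero category reports 0 percent
  cs0 <- data.frame(category = "pirna", library = "A", speciesDetected = 0,
                    uniqueReads = 0, readCount = 0)
  out0 <- summarizeReport(cs0, totals, c(pirna = 100))
  expect_equal(out0$fractionKnownPct, 0)
  expect_equal(out0$fractionTotalPct, 0)
  # zero filtered total -> fractions absent
  outz <- summarizeReport(cs0, data.frame(library = "A", totalReads = 0),
                          c(pirna = 100))
  expect_true(is.na(outz$fractionTotalPct))
  expect_error(summarizeReport(cs0, data.frame(library = "B", totalReads = 1)),
               "missing for library")
})

test_that("the end-to-end pipeline is complete, balanced and deterministic", {
  truth <- makeTinyTruth(seed = 33)
  dir <- withr::local_tempdir()
  refdir <- file.path(dir, "refs")
  writeReferenceBundle(generateReferences(truth), refdir)
  fqA <- file.path(dir, "A.fastq"); fqB <- file.path(dir, "B.fastq")
  generateLibrary(truth, "A", path = fqA)
  generateLibrary(truth, "B", path = fqB)
  cfg <- list(readsA = fqA, readsB = fqB, references = refdir,
              outdir = file.path(dir, "out1"),
              spikes = c(truth@spikeA, truth@spikeB), seed = 3,
              nDraws = 2000L)
  res <- runPipeline(cfg)

  expect_true(file.exists(file.path(dir, "out1", "summary_report.tsv")))
  expect_true(file.exists(file.path(dir, "out1", "run_log.json")))
  # conservation ledger balanced for both libraries
  for (lib in c("A", "B")) {
    rep <- res$preprocess[[lib]]$report
    expect_true(validObject(rep))
    cr <- res$cascade[[lib]]
    expect_equal(sum(cascadeStats(cr)$uniqueReads) +
                   length(cascadeLeftover(cr)), cr@nInput)
  }
  # strongly up-regulated truth species are recovered in the up list
  expect_true(all(c("fam-1", "fam-2") %in% res$de$mirna$up$species))
  # L1 dominates L2 in both libraries (sense+antisense families)
  fam <- res$familySummary$totals
  l1 <- fam[fam$group == "L1", ]
  l2 <- fam[fam$group == "L2", ]
  expect_gt(sum(l1$countA), sum(l2$countA))
  expect_gt(sum(l1$countB), sum(l2$countB))

  # re-running the identical config gives byte-identical DE lists
  cfg2 <- cfg; cfg2$outdir <- file.path(dir, "out2")
  runPipeline(cfg2)
  expect_identical(readLines(file.path(dir, "out1", "de_mirna_up.tsv")),
                   readLines(file.path(dir, "out2", "de_mirna_up.tsv")))
  expect_identical(readLines(file.path(dir, "out1", "summary_report.tsv")),
                   readLines(file.path(dir, "out2", "summary_report.tsv")))

  # configuration errors precede any computation
  expect_error(runPipeline(list(readsA = fqA, readsB = fqB,
                                outdir = "x")), "references")
  expect_error(runPipeline(list(readsA = "/nope", readsB = fqB,
                                references = refdir, outdir = "x")),
               "does not exist")
})
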