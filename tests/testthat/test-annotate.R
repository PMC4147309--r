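let7x <- "TGAGGTAGTAGGTTGTATAGTT"
let7y <- "TGAGGTAGTAGGTTGTGTAGTT"  # Hamming distance 1 from let7x

test_that("identity-derived mismatch allowance follows floor((1-id)*L)", {
  pol <- alignmentPolicy(byIdentity = TRUE, minIdentity = 0.9)
  expect_equal(mismatchAllowance(pol, 22L), 2)
  expect_equal(mismatchAllowance(pol, 19L), 1)
  expect_equal(mismatchAllowance(pol, 30L), 3)
  expect_equal(mismatchAllowance(alignmentPolicy(maxMismatches = 2), 22L), 2L)
  expect_error(alignmentPolicy(strandSpecific = FALSE))
})

test_that("ungapped alignment returns the best in-bounds hit", {
  ref <- c(m1 = let7x)
  hit <- alignUngapped(let7x, ref)
  expect_equal(hit$refId, "m1")
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$offset, 0)

  # substring containment inside a hairpin at offset 10
  hp <- c(hp1 = paste0(strrep("C", 10), let7x, strrep("G", 8)))
  hit2 <- alignUngapped(let7x, hp)
  expect_equal(hit2$offset, 10)
  expect_equal(hit2$mismatches, 0)

  # 3 substitutions vs a 2-mismatch allowance -> no hit
  withSeed(41, {
    mut3 <- mutateSeq(let7x, 3)
    expect_null(alignUngapped(mut3, ref, alignmentPolicy(maxMismatches = 2)))
  })
  # read longer than the reference -> no hit
  expect_null(alignUngapped(paste0(let7x, "AAAA"), ref))
})

test_that("classification separates unique, ambiguous and unmapped reads", {
  refs <- c(let7x = let7x, let7y = let7y)
  # exact to one family member, 1 mismatch to the other -> unique
  cl <- classifyRead(let7x, refs, alignmentPolicy(maxMismatches = 2))
  expect_equal(cl$status, "unique")
  expect_equal(cl$refs, "let7x")

  # equidistant (1 mismatch to both) -> ambiguous, both listed
  mid <- let7x
  substr(mid, 17, 17) <- "C"  # position where x has A and y has G
  clm <- classifyRead(mid, refs, alignmentPolicy(maxMismatches = 2))
  expect_equal(clm$status, "ambiguous")
  expect_setequal(clm$refs, c("let7x", "let7y"))
  expect_equal(clm$mismatches, 1)

  # same reference, two offsets -> ambiguous by the same-quality rule
  hp <- c(hp1 = paste0(let7x, "CCCC", let7x))
  cl2 <- classifyRead(let7x, hp, alignmentPolicy(maxMismatches = 0))
  expect_equal(cl2$status, "ambiguous")
  expect_equal(cl2$refs, "hp1")
  expect_equal(cl2$nHits, 2L)

  # nothing within allowance -> unmapped
  expect_equal(classifyRead(strrep("A", 22), refs)$status, "unmapped")
})

test_that("classifyRead agrees exactly with exhaustive enumeration", {
  withSeed(42, {
    for (rep in 1:4) {
      refs <- setNames(rseq(20, sample(20:60, 20, TRUE)), paste0("r", 1:20))
      reads <- character(50)
      for (i in 1:50) {
        src <- sample(refs, 1)
        reads[i] <- switch(sample(4, 1),
          src[[1]],
          mutateSeq(src[[1]], sample(1:3, 1)),
          { n <- nchar(src[[1]]); st <- sample(n - 19, 1)
            substr(src[[1]], st, st + 19) },
          paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""))
      }
      pol <- alignmentPolicy(maxMismatches = 2)
      for (rd in reads) {
        got <- classifyRead(rd, refs, pol)
        want <- oracleClassify(rd, refs, 2L)
        expect_identical(got$status, want$status)
        expect_setequal(got$refs, want$refs)
        expect_equal(got$mismatches, want$mismatches)
        expect_equal(got$nHits, want$nHits)
      }
    }
  })
})

test_that("the cascade assigns sequentially and conserves every read", {
  truth <- makeTinyTruth(seed = 20)
  run <- runCascadeFor(truth)
  cr <- run$cascade$A
  st <- cascadeStats(cr)

  # conservation: categories + leftover partition the input
  expect_equal(sum(st$uniqueReads) + length(cascadeLeftover(cr)), cr@nInput)

  # a read equal to a mature miRNA is counted at mature, never at hairpin
  matIds <- cascadeCategory(cr, "mature")$refId
  expect_true("fam-1" %in% matIds)
  hpIds <- cascadeCategory(cr, "hairpin")$refId
  expect_false(any(paste0("hp-", matIds) %in% hpIds))

  # hairpin-only (loop-spanning) species appear at the hairpin stage
  expect_true(any(grepl("^hp-ho-", hpIds)))

  # star species are assigned at the mature-star stage
  expect_true(any(grepl("-star$", cascadeCategory(cr, "mature_star")$refId)))
})

test_that("reversing the stage order inflates hairpin counts", {
  truth <- makeTinyTruth(seed = 21)
  run <- runCascadeFor(truth)
  fwd <- run$cascade$A
  pre <- run$pre$A
  rev <- runMirnaCascade(pre$reads, run$bundle,
                         stageOrder = c("hairpin", "mature_star", "mature"))
  fwdHp <- cascadeStats(fwd)
  revHp <- cascadeStats(rev)
  expect_gt(revHp$readCount[revHp$category == "hairpin"],
            fwdHp$readCount[fwdHp$category == "hairpin"])
  # with hairpin first, mature reads are swallowed by their precursors
  expect_lt(revHp$readCount[revHp$category == "mature"],
            fwdHp$readCount[fwdHp$category == "mature"])
  # conservation holds in either order
  expect_equal(sum(revHp$uniqueReads) + length(cascadeLeftover(rev)),
               rev@nInput)
})

test_that("ambiguous reads are removed before the next stage", {
  refsM <- Biostrings::DNAStringSet(c(let7x = let7x, let7y = let7y))
  hp <- Biostrings::DNAStringSet(c(hp1 = paste0("ACGTACGT", let7x, "TTGGCC")))
  bundle <- new("ReferenceBundle", mature = refsM,
                matureStar = Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 5))),
                hairpin = hp,
                pirna = Biostrings::DNAStringSet(),
                repeatSense = Biostrings::DNAStringSet(),
                repeatAntisense = Biostrings::DNAStringSet(),
                repeatAnnoSense = data.frame(accession = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), repeat_name = character()),
                repeatAnnoAntisense = data.frame(accession = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), repeat_name = character()),
                catalog = RepeatCatalog())
  mid <- let7x
  substr(mid, 17, 17) <- "C"
  reads <- UniqueReads(c(let7x, mid), c(10L, 4L))
  cr <- runMirnaCascade(reads, bundle)
  st <- cascadeStats(cr)
  expect_equal(st$readCount[st$category == "mature"], 10)
  expect_equal(st$readCount[st$category == "ambiguous_mature"], 4)
  # the ambiguous read credits both tied references but is counted once
  amb <- cascadeCategory(cr, "ambiguous_mature")
  expect_setequal(amb$refId, c("let7x", "let7y"))
  expect_equal(sum(amb$readCount), 8)  # credited to each of the two ties
  expect_equal(st$readCount[st$category == "hairpin"], 0)
  expect_equal(length(cascadeLeftover(cr)), 0)
})

test_that("length routing is an exhaustive, boundary-inclusive partition", {
  withSeed(43, {
    r <- UniqueReads(rseq(30, sample(17:31, 30, TRUE)), rep(1L, 30))
    parts <- routeByLength(r)
    expect_equal(length(parts$long) + length(parts$short), length(r))
    expect_length(intersect(readSequences(parts$long),
                            readSequences(parts$short)), 0)
    expect_true(all(nchar(readSequences(parts$long)) > 23))
    expect_true(all(nchar(readSequences(parts$short)) <= 23))
    # a 23-nt read goes short; 24-nt goes long; stricter boundary flips 23
    r23 <- UniqueReads(c(rseq(1, 23), rseq(1, 24), rseq(1, 17)), rep(1L, 3))
    p <- routeByLength(r23)
    expect_equal(nchar(readSequences(p$long)), 24L)
    p22 <- routeByLength(r23, boundary = 22L)
    expect_setequal(nchar(readSequences(p22$long)), c(23L, 24L))
  })
})

test_that("branch mapping is strand-specific and mismatch-tolerant", {
  pi1 <- "TGAACCGTAGGCATTACCGTAGGCATTA"  # 28 nt
  refs <- c(p1 = pi1, p2 = rseq(1, 28, avoid = pi1))
  r <- UniqueReads(pi1, 5L)
  bc <- mapBranch(r, refs)
  expect_equal(branchCounts(bc)$refId, "p1")
  expect_equal(branchCounts(bc)$readCount, 5)
  expect_equal(branchReadsMapped(bc), 5)

  # two mismatches still map; three do not
  withSeed(44, {
    bc2 <- mapBranch(UniqueReads(mutateSeq(pi1, 2), 3L), refs)
    expect_equal(branchCounts(bc2)$refId, "p1")
    bc3 <- mapBranch(UniqueReads(mutateSeq(pi1, 3), 3L), refs)
    expect_equal(branchSpeciesDetected(bc3), 0L)
  })

  # reverse complement does not map (strand-specific)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pi1)))
  expect_equal(branchSpeciesDetected(mapBranch(UniqueReads(rc, 2L), refs)), 0L)

  # a tie credits both species once in the read total
  twin <- c(a = pi1, b = paste0(substr(pi1, 1, 27), "C"))
  tie <- substr(pi1, 1, 27)  # 27-nt prefix matches both at 0 mismatches
  bct <- mapBranch(UniqueReads(tie, 7L), twin)
  ct <- branchCounts(bct)
  expect_setequal(ct$refId, c("a", "b"))
  expect_true(all(ct$ambiguous))
  expect_equal(sum(ct$readCount), 14)
  expect_equal(branchReadsMapped(bct), 7)
})
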