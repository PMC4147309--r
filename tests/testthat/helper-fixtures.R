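# Shared fixtures: a desk-size synthetic truth, an independent brute-force
# alignment oracle, and small utilities.

rseq <- function(n, lengths, avoid = character()) {
  smallRNAcascade:::randomSequences(n, lengths, avoid)
}

withSeed <- smallRNAcascade:::withSeed

# A small but structurally complete experiment: every annotation category,
# a Hamming-1 mature pair, strong true changes in both directions, known
# but unexpressed species, noise singletons and spike-ins.
makeTinyTruth <- function(seed = 1L, nNoise = 25L) {
  withSeed(seed * 7L + 555L, {
    used <- character()
    add <- function(df, id, cat, seq, ab, fc, rn = NA_character_) {
      used <<- c(used, seq)
      rbind(df, data.frame(species_id = id, category = cat, sequence = seq,
                           base_abundance = ab, log2_fc = fc,
                           repeat_name = rn, stringsAsFactors = FALSE))
    }
    sp <- NULL
    # Hamming-1 mature pair (family), both up in B
    m1 <- "TGAGGTAGTAGGTTGTATAGTT"
    m2 <- sub("ATAGTT$", "GTAGTT", m1)
    sp <- add(sp, "fam-1", "mature", m1, 300, 3)
    sp <- add(sp, "fam-2", "mature", m2, 150, 3.5)
    mseq <- rseq(8, sample(21:23, 8, TRUE), used)
    for (i in 1:8)
      sp <- add(sp, sprintf("m-%02d", i), "mature", mseq[i],
                sample(20:120, 1), 0)
    xtra <- rseq(2, 22, used)
    for (i in 1:2) sp <- add(sp, sprintf("mx-%d", i), "mature", xtra[i], 0, 0)
    sseq <- rseq(3, 21, used)
    for (i in 1:3)
      sp <- add(sp, sprintf("m-%02d-star", i), "mature_star", sseq[i],
                sample(5:30, 1), 0)
    hseq <- rseq(2, 22, used)
    for (i in 1:2)
      sp <- add(sp, sprintf("ho-%d", i), "hairpin_only", hseq[i], 15, 0)
    pseq <- rseq(6, sample(24:30, 6, TRUE), used)
    pfc <- c(3, -3, 0, 0, 0, 0)
    for (i in 1:6)
      sp <- add(sp, sprintf("pi-%02d", i), "pirna", pseq[i],
                sample(20:80, 1), pfc[i])
    rnames <- c("L1PB4", "L1M5", "L2", "MIRc", "AluY", "LTR33", "HY1", "U3")
    rseqs <- rseq(8, sample(18:23, 8, TRUE), used)
    rori <- rep(c("repeat_sense", "repeat_antisense"), 4)
    rab <- c(120, 100, 10, 30, 25, 20, 40, 35)
    rfc <- c(-2, 0, 0, 2.5, 0, 0, 2, 1.8)
    for (i in 1:8)
      sp <- add(sp, sprintf("hgur%09d", i), rori[i], rseqs[i], rab[i],
                rfc[i], rnames[i])
    nseq <- rseq(nNoise, sample(17:28, nNoise, TRUE), used)
    for (i in seq_len(nNoise))
      sp <- add(sp, sprintf("noise-%03d", i), "noise", nseq[i], 1, 0)
    ExperimentTruth(sp, seed = seed, spikeDepth = 40)
  })
}

# Exhaustive (reference, offset) mismatch enumeration in plain R: the
# independent oracle for classifyRead.
oracleClassify <- function(read, refs, allow) {
  n <- nchar(read)
  best <- allow + 1L
  hits <- list()
  rb <- charToRaw(read)
  for (j in seq_along(refs)) {
    m <- nchar(refs[[j]])
    if (m < n) next
    refb <- charToRaw(refs[[j]])
    for (s in seq_len(m - n + 1L)) {
      mm <- sum(refb[s:(s + n - 1L)] != rb)
      if (mm < best) {
        best <- mm
        hits <- list(c(j, s))
      } else if (mm == best && best <= allow) {
        hits <- c(hits, list(c(j, s)))
      }
    }
  }
  if (best > allow)
    return(list(status = "unmapped", refs = character(0),
                mismatches = NA_integer_, nHits = 0L))
  refIdx <- vapply(hits, `[`, numeric(1), 1L)
  list(status = if (length(hits) == 1L) "unique" else "ambiguous",
       refs = unique(names(refs)[refIdx]), mismatches = best,
       nHits = length(hits))
}

# Mutate `k` distinct positions of a DNA sequence.
mutateSeq <- function(seq, k) {
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), k)
  s[pos] <- alt[s[pos]]
  paste(s, collapse = "")
}

# Preprocess + cascade for a simulated truth, in memory.
runCascadeFor <- function(truth, seed = truth@seed) {
  bundle <- generateReferences(truth)
  pre <- lapply(c(A = "A", B = "B"), function(lib)
    preprocessReads(generateLibrary(truth, lib, seed = seed),
                    adapter3 = truth@adapter3,
                    spikes = c(truth@spikeA, truth@spikeB)))
  cascade <- lapply(pre, function(p) runMirnaCascade(p$reads, bundle))
  list(bundle = bundle, pre = pre, cascade = cascade)
}

# miRNA differential-expression pass over a simulated paperlike experiment:
# preprocess both libraries, run the cascade, build the mature count table
# and call DE from the posterior generalized fold change.
runMirnaDE <- function(truth, seed) {
  bundle <- generateReferences(truth)
  pre <- lapply(c(A = "A", B = "B"), function(lib)
    preprocessReads(generateLibrary(truth, lib, seed = seed),
                    adapter3 = truth@adapter3,
                    spikes = c(truth@spikeA, truth@spikeB)))
  cascade <- lapply(pre, function(p) runMirnaCascade(p$reads, bundle))
  tb <- buildCountTable(
    cascadeCategory(cascade$A, "mature")[, c("refId", "readCount")],
    cascadeCategory(cascade$B, "mature")[, c("refId", "readCount")])
  recs <- gfoldTable(tb, seed = seed)
  callDE(recs)
}
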