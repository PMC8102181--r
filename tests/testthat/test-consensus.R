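test_that("UMI extraction trims the tag and rejects too-short reads", {
    rd <- S4Vectors::DataFrame(id = c("a", "b", "c"),
                               sequence = c("ACGTACGTTTTTCCCC", "ACGTACGT",
                                            "GGGGTTTTAAAACGCG"))
    ex <- extractUmi(rd, umiLength = 8L)
    expect_identical(ex$nRejected, 1L)
    expect_identical(ex$reads$umi, c("ACGTACGT", "GGGGTTTT"))
    expect_identical(ex$reads$sequence, c("TTTTCCCC", "AAAACGCG"))
    # UMIs containing N still form a key
    rdN <- S4Vectors::DataFrame(id = "n", sequence = "ACGTNCGTAAAA")
    expect_identical(extractUmi(rdN, 8L)$reads$umi, "ACGTNCGT")
})

test_that("family grouping matches a dictionary oracle and discards singletons", {
    rd <- S4Vectors::DataFrame(
        target = "targetA",
        umi = c("AAAAAAAA", "AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "TTTTTTTT"),
        sequence = "ACGT")
    g <- groupFamilies(rd)
    expect_identical(nrow(g$families), 1L)
    expect_identical(g$families$size, 2L)
    expect_identical(g$nDiscardedReads, 3L)
    expect_identical(g$nSingletonKeys, 3L)

    # all-unique UMIs: no families at all
    rd2 <- S4Vectors::DataFrame(target = "t", umi = as.character(1:6),
                                sequence = "AC")
    expect_identical(nrow(groupFamilies(rd2)$families), 0L)
    expect_identical(nrow(groupFamilies(rd2[0, ])$families), 0L)

    # random case vs brute-force table()
    withr::with_seed(13, {
        rd3 <- S4Vectors::DataFrame(
            target = sample(c("t1", "t2"), 400, replace = TRUE),
            umi = sample(sprintf("U%02d", 1:40), 400, replace = TRUE),
            sequence = "A")
    })
    g3 <- groupFamilies(rd3)
    oracle <- table(paste(rd3$target, rd3$umi))
    expect_identical(sort(g3$families$size),
                     sort(as.integer(oracle[oracle >= 2])))
    expect_identical(g3$nDiscardedReads, sum(oracle == 1L))
    # every retained family's members share the key
    key <- paste(g3$reads$target, g3$reads$umi)
    expect_true(all(tapply(key, g3$reads$family,
                           function(k) length(unique(k)) == 1L)))
})

test_that("retained-read fraction equals the truth table's non-singleton fraction", {
    ref <- randomRef(40, seed = 7)
    s <- simulateSample(simConfig(c(T1 = ref), nFamilies = 3000, seed = 31))
    g <- groupFamilies(reads(s))
    tt <- truthTable(s)
    expect_identical(nrow(g$reads), sum(tt$size[tt$size >= 2]))
    expect_identical(g$nSingletonKeys, sum(tt$size == 1L))
    expect_identical(sort(g$families$size), sort(tt$size[tt$size >= 2]))
})

test_that("single-family consensus follows quorum rules", {
    expect_identical(consensusFamily(c("ACGT", "ACGT", "ACGT"))$sequence,
                     "ACGT")
    expect_identical(consensusFamily(c("ACGT", "ACGT", "ACGT"))$nFraction, 0)
    # 2/3 < 0.7 at position 3 (maxNFraction lifted: these 4-mers are
    # about the consensus value, not family dropping)
    expect_identical(consensusFamily(c("ACGT", "ACGT", "ACTT"),
                                     quorum = 0.7,
                                     maxNFraction = 1)$sequence, "ACNT")
    # a 2-read tie is N for any quorum > 0.5
    expect_identical(consensusFamily(c("ACGT", "AGGT"), quorum = 0.51,
                                     maxNFraction = 1)$sequence, "ANGT")
    expect_identical(consensusFamily(c("AC", "ACA"))$status,
                     "rejected_length")
    expect_error(consensusFamily("ACGT"), "size >= 2")
    # heavily damaged family is dropped
    r <- consensusFamily(c("ACGT", "TGCA"), maxNFraction = 0.2)
    expect_identical(r$status, "dropped_n_fraction")
})

test_that("vectorized consensus equals the per-family reference implementation", {
    withr::with_seed(41, {
        fams <- lapply(1:25, function(i) {
            L <- 15L
            base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                          collapse = "")
            n <- sample(2:6, 1)
            seqs <- rep(base, n)
            for (j in seq_len(sample(0:4, 1))) {
                r <- sample(n, 1); p <- sample(L, 1)
                substr(seqs[r], p, p) <- sample(c("A", "C", "G", "T"), 1)
            }
            seqs
        })
    })
    rd <- S4Vectors::DataFrame(
        family = rep(seq_along(fams), lengths(fams)),
        target = "T1", umi = sprintf("U%02d", rep(seq_along(fams),
                                                  lengths(fams))),
        sequence = unlist(fams))
    fast <- buildConsensus(rd, quorum = 0.7, maxNFraction = 1)$consensus
    slow <- vapply(fams, function(x)
        consensusFamily(x, quorum = 0.7, maxNFraction = 1)$sequence,
        character(1))
    expect_identical(fast$sequence, slow)
    expect_identical(fast$size, lengths(fams))
})

test_that("mixed-length families are rejected, not padded", {
    rd <- S4Vectors::DataFrame(family = c(1L, 1L, 2L, 2L), target = "T1",
                               umi = c("U1", "U1", "U2", "U2"),
                               sequence = c("ACGT", "ACGTA", "GGGG", "GGGG"))
    bc <- buildConsensus(rd)
    expect_identical(bc$nRejected, 1L)
    expect_identical(bc$consensus$sequence, "GGGG")
})

test_that("pileups conserve depth and respect the no-noise identity", {
    cons <- S4Vectors::DataFrame(family = 1L, target = "T1", umi = "U",
                                 size = 2L, sequence = "ACGT",
                                 nFraction = 0)
    pl <- buildPileup(cons, c(T1 = "ACGT"))
    st <- pileupSites(pl)
    expect_identical(st$depth, rep(1L, 4))
    expect_identical(diag(as.matrix(st[, strsplit("ACGT", "")[[1]]])),
                     rep(1L, 4))

    # error-free simulated sample: zero non-reference counts off the spike
    ref <- randomRef(40, seed = 8)
    sp <- spikeAlleles(ref)
    s <- simulateSample(snvSpikeConfig(ref, 2000, 0.05, seed = 17,
                                       errorRates = zeroErrorRates()))
    pl2 <- consensusPileup(s)
    st2 <- pileupSites(pl2)
    expect_true(methods::validObject(pl2))   # depth conservation
    m <- as.matrix(st2[, c("A", "C", "G", "T")])
    refCount <- m[cbind(seq_len(nrow(m)),
                        match(st2$ref, c("A", "C", "G", "T")))]
    nonref <- rowSums(m) - refCount
    offSpike <- st2$pos != sp$pos
    expect_true(all(nonref[offSpike] == 0))
    expect_identical(st2$N, rep(0L, 40))
})

test_that("pileup alt fraction recovers the truth mutant-family fraction", {
    ref <- randomRef(40, seed = 9)
    sp <- spikeAlleles(ref)
    s <- simulateSample(snvSpikeConfig(ref, 10000, 0.01, seed = 23))
    tt <- truthTable(s)
    g <- groupFamilies(reads(s))
    truthFrac <- sum(tt$haplotype != "ref" & tt$size >= 2) / nrow(g$families)
    st <- pileupSites(consensusPileup(s))
    i <- which(st$pos == sp$pos)
    obs <- st[[sp$alt]][i] / st$depth[i]
    se <- sqrt(truthFrac * (1 - truthFrac) / st$depth[i])
    expect_lt(abs(obs - truthFrac), 3 * se + 1e-9)
})

test_that("indel-bearing molecules appear as keyed insertions and deletions", {
    ref <- randomRef(40, seed = 10)
    spikes <- data.frame(
        target = "T1", pos = c(10L, 25L),
        ref = c(substr(ref, 10, 10), substr(ref, 25, 28)),
        alt = c(paste0(substr(ref, 10, 10), "ACTG"), substr(ref, 25, 25)),
        vaf = c(0.10, 0.10), id = c("ins4", "del3"))
    cfg <- simConfig(c(T1 = ref), nFamilies = 3000, seed = 19,
                     errorRates = zeroErrorRates(), spikeIns = spikes)
    s <- simulateSample(cfg)
    pl <- consensusPileup(s)
    expect_true(methods::validObject(pl))    # depth conserved despite indels
    tt <- truthTable(s)
    g <- groupFamilies(reads(s))
    ins <- pileupInsertions(pl)
    nInsTruth <- sum(tt$haplotype == "ins4" & tt$size >= 2)
    expect_identical(sum(ins$count), nInsTruth)
    expect_identical(unique(nchar(ins$seq)), 4L)
    st <- pileupSites(pl)
    nDelTruth <- sum(tt$haplotype == "del3" & tt$size >= 2)
    expect_identical(max(st$del), nDelTruth)
})

test_that("consensus suppresses a 1% per-read error rate below 0.05%", {
    ref <- randomRef(40, seed = 11)
    cfg <- simConfig(c(T1 = ref), nFamilies = 3600, familySizeMean = 4,
                     errorRates = uniformErrorRates(0.01), seed = 29)
    s <- simulateSample(cfg)
    g <- groupFamilies(reads(s))
    cons <- buildConsensus(g$reads, quorum = 0.7)$consensus
    cons <- cons[cons$size >= 3, ]
    expect_gt(sum(nchar(cons$sequence)), 1e5)
    consChars <- unlist(strsplit(cons$sequence, ""))
    refChars <- rep(strsplit(ref, "")[[1]], nrow(cons))
    mism <- consChars != refChars & consChars != "N"
    expect_lt(mean(mism), 5e-4)
})

test_that("identical inputs give byte-identical pileups", {
    ref <- randomRef(30, seed = 12)
    cfg <- snvSpikeConfig(ref, 800, 0.02, seed = 37)
    p1 <- consensusPileup(simulateSample(cfg))
    p2 <- consensusPileup(simulateSample(cfg))
    expect_identical(as.data.frame(pileupSites(p1)),
                     as.data.frame(pileupSites(p2)))
    expect_identical(as.data.frame(pileupInsertions(p1)),
                     as.data.frame(pileupInsertions(p2)))
})

test_that("consensus reads on unknown targets are counted and excluded", {
    cons <- S4Vectors::DataFrame(family = 1:2, target = c("T1", "T9"),
                                 umi = c("U1", "U2"), size = 2L,
                                 sequence = "ACGT", nFraction = 0)
    pl <- buildPileup(cons, c(T1 = "ACGT"))
    expect_identical(pl@nExcluded, 1L)
    expect_identical(unique(pileupSites(pl)$depth), 1L)
})

test_that("probe-arm prefixes assign reads to their targets", {
    refs <- c(T1 = randomRef(30, seed = 13), T2 = randomRef(30, seed = 14))
    seqs <- c(refs[["T1"]], refs[["T2"]], refs[["T1"]])
    substr(seqs[3], 2, 2) <- "N"  # one mismatch in the arm still assigns
    expect_identical(assignTargets(seqs, refs), c("T1", "T2", "T1"))
    expect_true(is.na(assignTargets(strrep("N", 30), refs)))
})
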