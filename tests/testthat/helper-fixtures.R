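# Shared fixture builders; everything is generated in code, seeded.

zeroErrorRates <- function() {
    r <- defaultErrorRates()
    r[] <- 0
    r
}

# A deterministic random target reference.
randomRef <- function(len = 40L, seed = 99L) {
    withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = ""))
}

# Config with one SNV spike at the target midpoint.
snvSpikeConfig <- function(refSeq, nFamilies, vaf, seed,
                           errorRates = defaultErrorRates(), pos = NULL) {
    if (is.null(pos)) pos <- ceiling(nchar(refSeq) / 2)
    rb <- substr(refSeq, pos, pos)
    ab <- setdiff(c("A", "C", "G", "T"), rb)[1L]
    simConfig(stats::setNames(refSeq, "T1"), nFamilies = nFamilies,
              errorRates = errorRates, seed = seed,
              spikeIns = data.frame(target = "T1", pos = pos, ref = rb,
                                    alt = ab, vaf = vaf, id = "snv1"))
}

spikeAlleles <- function(refSeq, pos = NULL) {
    if (is.null(pos)) pos <- ceiling(nchar(refSeq) / 2)
    rb <- substr(refSeq, pos, pos)
    list(pos = pos, ref = rb, alt = setdiff(c("A", "C", "G", "T"), rb)[1L])
}

# Hand-built single-site pileup for error-model arithmetic tests.
handPileup <- function(refSeq = "ACGT", counts) {
    L <- nchar(refSeq)
    refBases <- strsplit(refSeq, "")[[1L]]
    s <- S4Vectors::DataFrame(target = "T1", pos = seq_len(L),
                              ref = refBases, A = 0L, C = 0L, G = 0L,
                              T = 0L, N = 0L, del = 0L, depth = 0L)
    for (i in seq_len(L)) {
        row <- counts[[i]]
        for (b in names(row)) s[[b]][i] <- row[[b]]
        s$depth[i] <- sum(unlist(row))
    }
    methods::new("SitePileup", sites = s,
                 insertions = S4Vectors::DataFrame(target = character(),
                                                   pos = integer(),
                                                   seq = character(),
                                                   count = integer()),
                 references = Biostrings::DNAStringSet(c(T1 = refSeq)),
                 nExcluded = 0L)
}

# Uniform per-class error rates giving a chosen total per-base rate.
uniformErrorRates <- function(total) {
    r <- defaultErrorRates()
    r[] <- total / 3
    r
}
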