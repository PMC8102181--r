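#' Default substitution error spectrum
#'
#' Per-base, per-class substitution probabilities used by the read
#' simulator. The spectrum mirrors what error modeling of control samples
#' from hybrid-capture UMI assays shows: C>T and G>A changes (oxidative
#' guanine damage read on either strand) dominate, at roughly four times
#' the transversion rate, with the remaining transitions (A>G, T>C)
#' intermediate. The total per-base error is about 1e-3, consistent with
#' Q30 base calls.
#'
#' @param transversion Per-base rate for each transversion class.
#' @param transition Per-base rate for A>G and T>C.
#' @param damage Per-base rate for C>T and G>A.
#' @return Named numeric vector over the 12 substitution classes.
#' @examples
#' defaultErrorRates()
#' @export
defaultErrorRates <- function(transversion = 1e-4, transition = 2e-4,
                              damage = 4 * transversion) {
    classes <- outer(DNA_BASES, DNA_BASES, function(a, b) paste0(a, ">", b))
    classes <- classes[row(classes) != col(classes)]
    r <- stats::setNames(rep(transversion, 12L), sort(classes))
    r[c("A>G", "T>C")] <- transition
    r[c("C>T", "G>A")] <- damage
    r
}

#' Construct a smMIPS simulation configuration
#'
#' @param targets Named character vector or [Biostrings::DNAStringSet] of
#'   target reference sequences.
#' @param nFamilies Number of captured molecules (UMI families) per target.
#' @param familySizeMean Mean reads per molecule; family sizes are drawn as
#'   \code{1 + Poisson(familySizeMean - 1)}. Default 1.296, the ratio of
#'   the assay's median raw to consensus coverage (14,728x / 11,363x).
#' @param umiLength UMI length in bases (default 8).
#' @param errorRates Named per-base substitution probabilities; see
#'   [defaultErrorRates()].
#' @param spikeIns \code{NULL} or a data.frame/DataFrame with columns
#'   \code{target}, \code{pos} (1-based), \code{ref}, \code{alt} (VCF-style
#'   alleles, so indels are length differences), \code{vaf}, and optional
#'   \code{id}. Spike-ins are assigned at the molecule level and propagate
#'   to every read of the family: MRD VAF is a molecule fraction.
#' @param seed Integer seed; all randomness in [simulateSample()] derives
#'   from it.
#' @return A validated [MipsSimConfig-class] object.
#' @examples
#' cfg <- simConfig(c(T1 = "ACGTACGTACGTACGTACGT"), nFamilies = 100, seed = 1)
#' @export
simConfig <- function(targets, nFamilies, familySizeMean = 14728 / 11363,
                      umiLength = 8L, errorRates = defaultErrorRates(),
                      spikeIns = NULL, seed = 1L) {
    if (!methods::is(targets, "DNAStringSet"))
        targets <- Biostrings::DNAStringSet(targets)
    if (is.null(spikeIns)) {
        spikeIns <- DataFrame(target = character(), pos = integer(),
                              ref = character(), alt = character(),
                              vaf = numeric(), id = character())
    } else {
        spikeIns <- as(as.data.frame(spikeIns), "DataFrame")
        if (is.null(spikeIns$id))
            spikeIns$id <- sprintf("%s:%d%s>%s", spikeIns$target,
                                   spikeIns$pos, spikeIns$ref, spikeIns$alt)
        spikeIns$pos <- as.integer(spikeIns$pos)
    }
    methods::new("MipsSimConfig", targets = targets,
                 nFamilies = as.integer(nFamilies),
                 familySizeMean = familySizeMean,
                 umiLength = as.integer(umiLength),
                 errorRates = errorRates, spikeIns = spikeIns,
                 seed = as.integer(seed))
}

## Apply a VCF-style edit to a reference string.
applyEdit <- function(refSeq, pos, ref, alt) {
    stopifnot(substr(refSeq, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr(refSeq, 1L, pos - 1L), alt,
           substr(refSeq, pos + nchar(ref), nchar(refSeq)))
}

## Inject substitution errors in place into a read matrix whose rows are
## copies of known haplotypes (plus the errors drawn here). Per cell of
## reference base X, at most one substitution occurs, to Y with the
## configured per-class probability; cells are drawn by index arithmetic
## per (haplotype, base) block rather than scanning the matrix. Returns
## the modified matrix plus an error record (row, col, from, to).
injectErrors <- function(m, readHap, hapChars, errorRates) {
    recs <- list()
    for (h in rownames(hapChars)) {
        rows <- which(readHap == h)
        if (!length(rows)) next
        for (from in DNA_BASES) {
            cols <- which(hapChars[h, ] == from)
            if (!length(cols)) next
            toB <- substr(names(errorRates), 1L, 1L) == from
            rTo <- errorRates[toB]
            names(rTo) <- substr(names(rTo), 3L, 3L)
            rTot <- sum(rTo)
            if (rTot <= 0) next
            nCells <- length(rows) * length(cols)
            k <- stats::rbinom(1L, nCells, rTot)
            if (k == 0L) next
            sel <- sample.int(nCells, k)
            row <- rows[(sel - 1L) %% length(rows) + 1L]
            col <- cols[(sel - 1L) %/% length(rows) + 1L]
            to <- sample(names(rTo), k, replace = TRUE, prob = rTo)
            recs[[paste0(h, from)]] <- data.frame(
                row = row, col = col, from = from, to = to)
        }
    }
    if (length(recs)) {                  # apply all substitutions at once
        e <- do.call(rbind, recs)
        m[cbind(e$row, e$col)] <- e$to
    }
    list(m = m, errors = if (length(recs)) do.call(rbind, recs)
                         else data.frame(row = integer(), col = integer(),
                                         from = character(), to = character()))
}

#' Simulate one UMI-tagged smMIPS sample
#'
#' Generates molecules (UMI families) per target, assigns each molecule a
#' haplotype (reference, or one spike-in variant by an independent
#' Bernoulli draw at the configured VAF), replicates it into
#' \code{1 + Poisson(mean - 1)} reads, and injects substitution errors
#' per the configured spectrum. Reads are merged payload sequences; the
#' UMI each read carries is recorded alongside. Every read maps to
#' exactly one truth record and the emitted read count equals the sum of
#' family sizes (validity-enforced).
#'
#' UMIs are drawn without replacement within a target, so each molecule
#' owns a distinct (target, UMI) key; see the methods vignette for why
#' exact-key simulation stands in for the fragment-coordinate diversity
#' real pipelines use alongside UMIs.
#'
#' @param config A [MipsSimConfig-class].
#' @return A [SimulatedSample-class].
#' @examples
#' cfg <- simConfig(c(T1 = "ACGTACGTACGTACGTACGT"), nFamilies = 50, seed = 7)
#' s <- simulateSample(cfg)
#' nrow(reads(s)) == sum(truthTable(s)$size)
#' @export
simulateSample <- function(config) {
    methods::validObject(config)
    withr::with_seed(config@seed, simulateSampleImpl(config))
}

simulateSampleImpl <- function(config) {
    tnames <- names(config@targets)
    readParts <- list(); truthParts <- list(); errParts <- list()
    rowOffset <- 0L; famOffset <- 0L
    for (t in tnames) {
        refSeq <- as.character(config@targets[[t]])
        nFam <- config@nFamilies
        sizes <- 1L + stats::rpois(nFam, config@familySizeMean - 1)
        umis <- randomUmis(nFam, config@umiLength)
        hap <- rep("ref", nFam)
        si <- config@spikeIns[config@spikeIns$target == t, , drop = FALSE]
        hapSeqs <- c(ref = refSeq)
        for (i in seq_len(nrow(si))) {
            if (si$vaf[i] * nFam < 1)
                message(sprintf(
                    "spike-in %s: expected mutant families %.2f < 1 at vaf=%g",
                    si$id[i], si$vaf[i] * nFam, si$vaf[i]))
            free <- which(hap == "ref")
            hit <- free[stats::runif(length(free)) < si$vaf[i]]
            hap[hit] <- si$id[i]
            hapSeqs[[si$id[i]]] <- applyEdit(refSeq, si$pos[i], si$ref[i], si$alt[i])
        }
        famid <- rep.int(seq_len(nFam), sizes)
        readHap <- hap[famid]
        hapLen <- nchar(hapSeqs)[match(readHap, names(hapSeqs))]
        seqs <- character(length(famid))
        errAll <- list()
        for (L in unique(hapLen)) {
            grp <- which(hapLen == L)
            hapChars <- do.call(rbind, strsplit(
                hapSeqs[nchar(hapSeqs) == L], "", fixed = TRUE))
            m <- hapChars[match(readHap[grp], rownames(hapChars)), , drop = FALSE]
            inj <- injectErrors(m, readHap[grp], hapChars, config@errorRates)
            seqs[grp] <- matrixToSeqs(inj$m)
            if (nrow(inj$errors)) {
                inj$errors$row <- grp[inj$errors$row]
                errAll[[as.character(L)]] <- inj$errors
            }
        }
        err <- if (length(errAll)) do.call(rbind, errAll)
               else data.frame(row = integer(), col = integer(),
                               from = character(), to = character())
        readParts[[t]] <- DataFrame(
            id = sprintf("sim:%s:f%06d:r%d", t, famid,
                         sequence(sizes)),
            target = t, family = famOffset + famid,
            umi = umis[famid], sequence = seqs)
        truthParts[[t]] <- DataFrame(
            target = t, family = famOffset + seq_len(nFam), umi = umis,
            haplotype = hap, size = sizes)
        if (nrow(err))
            errParts[[t]] <- DataFrame(read = rowOffset + err$row,
                                       pos = err$col, from = err$from,
                                       to = err$to)
        rowOffset <- rowOffset + length(famid)
        famOffset <- famOffset + nFam
    }
    emptyErr <- DataFrame(read = integer(), pos = integer(),
                          from = character(), to = character())
    methods::new("SimulatedSample",
                 reads = do.call(rbind, readParts),
                 truth = do.call(rbind, truthParts),
                 errors = if (length(errParts)) do.call(rbind, errParts)
                          else emptyErr,
                 config = config)
}

#' Write a simulated sample as FASTQ
#'
#' Read 1 carries the UMI as its first \code{umiLength} bases followed by
#' the merged payload; if \code{r2} is given, read 2 is the reverse
#' complement of the payload. Base qualities are constant Q30.
#'
#' @param sample A [SimulatedSample-class].
#' @param r1,r2 Output paths (gzip applied when the path ends in
#'   \code{.gz}); \code{r2} may be \code{NULL} for merged single-end
#'   output.
#' @return Invisibly, the path(s) written.
#' @export
writeFastq <- function(sample, r1, r2 = NULL) {
    rd <- sample@reads
    writeFastqRecords(rd$id, paste0(rd$umi, rd$sequence), r1)
    if (!is.null(r2)) {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(rd$sequence)))
        writeFastqRecords(rd$id, rc, r2)
    }
    invisible(c(r1, r2))
}

writeFastqRecords <- function(ids, seqs, path, quality = "?") {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(strrep(quality, Biostrings::width(x)))
    qx <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(
        qx, path, compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Read FASTQ into a reads table
#'
#' @param path FASTQ path (plain or gzipped).
#' @return A [S4Vectors::DataFrame] with columns \code{id}, \code{sequence}.
#' @export
readFastqReads <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    DataFrame(id = unname(sub(" .*", "", names(x))),
              sequence = unname(as.character(x)))
}

#' Write a truth table as TSV
#'
#' Emits a commented header recording the seed and configuration, then one
#' row per UMI family.
#'
#' @param sample A [SimulatedSample-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeTruth <- function(sample, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# smMRD truth table; seed=%d; targets=%s; nFamilies=%d",
                       sample@config@seed,
                       paste(names(sample@config@targets), collapse = ","),
                       sample@config@nFamilies), con)
    utils::write.table(as.data.frame(sample@truth), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Simulate ultra-deep single-amplicon reads with an internal tandem
#' duplication
#'
#' Emulates the one-step PCR FLT3-ITD assay: all reads are full-length
#' copies of the amplicon; a fixed fraction carry a tandem duplication of
#' the reference block ending at \code{itdPos} (the duplicated copy is
#' inserted immediately after it), lengthening the read by the ITD
#' length. Exactly \code{round(fraction * nReads)} reads carry the ITD.
#'
#' @param reference Amplicon reference sequence (character).
#' @param nReads Total reads to emit.
#' @param itdPos 1-based position of the last base of the duplicated block.
#' @param itdLen Duplication length in bases (>= 3).
#' @param fraction Fraction of reads carrying the ITD, in \[0, 1).
#' @param errorRate Uniform per-base substitution probability (default 0;
#'   substitutions never change read length, which is what the detector
#'   keys on).
#' @param seed Integer seed.
#' @param anchorK Anchor k-mer size the downstream detector will use; the
#'   ITD must fit with an anchor on each side (\code{itdLen <=
#'   nchar(reference) - 2 * anchorK}).
#' @return A [S4Vectors::DataFrame] with columns \code{id},
#'   \code{sequence}, \code{isItd}; metadata records the ITD truth.
#' @examples
#' ref <- flt3AmpliconDemo(200)
#' rd <- simulateItdReads(ref, 5000, itdPos = 100, itdLen = 30,
#'                        fraction = 0.002, seed = 1)
#' sum(rd$isItd)  # exactly round(0.002 * 5000) = 10
#' @export
simulateItdReads <- function(reference, nReads, itdPos, itdLen, fraction,
                             errorRate = 0, seed = 1L, anchorK = 12L) {
    L <- nchar(reference)
    if (itdLen < 3L) stop("ITD length must be >= 3")
    if (itdLen > L - 2L * anchorK)
        stop("ITD length ", itdLen, " exceeds read length ", L,
             " minus two ", anchorK, "-base anchors")
    if (itdPos < itdLen || itdPos > L)
        stop("ITD position ", itdPos, " incompatible with duplication of ",
             itdLen, " bases ending there (target length ", L, ")")
    if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
    dupSeq <- substr(reference, itdPos - itdLen + 1L, itdPos)
    itdSeq <- paste0(substr(reference, 1L, itdPos), dupSeq,
                     substr(reference, itdPos + 1L, L))
    nItd <- as.integer(round(fraction * nReads))
    withr::with_seed(as.integer(seed), {
        isItd <- rep(FALSE, nReads)
        if (nItd > 0L) isItd[sample.int(nReads, nItd)] <- TRUE
        seqs <- ifelse(isItd, itdSeq, reference)
        if (errorRate > 0) {
            for (w in unique(nchar(seqs))) {
                grp <- which(nchar(seqs) == w)
                m <- seqsToMatrix(seqs[grp])
                nerr <- stats::rbinom(1L, length(m), errorRate)
                if (nerr > 0L) {
                    idx <- sample.int(length(m), nerr)
                    m[idx] <- vapply(m[idx], function(b)
                        sample(setdiff(DNA_BASES, b), 1L), character(1))
                }
                seqs[grp] <- matrixToSeqs(m)
            }
        }
        rd <- DataFrame(id = sprintf("amp:r%07d", seq_len(nReads)),
                        sequence = seqs, isItd = isItd)
        metadata(rd) <- list(itdPos = itdPos, itdLen = itdLen,
                             dupSeq = dupSeq, fraction = fraction,
                             nItd = nItd, seed = as.integer(seed))
        rd
    })
}

#' Deterministic synthetic FLT3-like amplicon reference
#'
#' A reproducible random nucleotide sequence standing in for the FLT3
#' exon-14/15 amplicon in examples, simulations, and tests. It is
#' synthetic: no real FLT3 sequence is shipped; detector behavior depends
#' only on amplicon structure, not on the particular bases.
#'
#' @param length Amplicon length in bases (default 260).
#' @param seed Seed for the sequence draw (default 104; fixed so the demo
#'   amplicon is stable across sessions).
#' @return Character reference sequence.
#' @export
flt3AmpliconDemo <- function(length = 260L, seed = 104L) {
    withr::with_seed(as.integer(seed),
        paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [simConfig()] arguments: \code{targets} (name:
#' sequence map), \code{nFamilies}, optional \code{familySizeMean},
#' \code{umiLength}, \code{errorRates} (class: rate map, merged over the
#' defaults), \code{spikeIns} (list of records), \code{seed}.
#'
#' @param path YAML file path.
#' @return A [MipsSimConfig-class].
#' @export
readSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    er <- defaultErrorRates()
    if (!is.null(y$errorRates))
        er[names(y$errorRates)] <- unlist(y$errorRates)
    spikes <- if (!is.null(y$spikeIns))
        do.call(rbind, lapply(y$spikeIns, as.data.frame)) else NULL
    simConfig(targets = unlist(y$targets),
              nFamilies = y$nFamilies,
              familySizeMean = y$familySizeMean %||% (14728 / 11363),
              umiLength = y$umiLength %||% 8L,
              errorRates = er, spikeIns = spikes, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
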