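#' Limit-of-detection experiment for the tracked-mutation pipeline
#'
#' Runs the full simulate -> consensus -> call chain over a grid of
#' spike-in VAFs with independent seeded replicates, and derives the
#' limit of detection as the lowest VAF whose empirical detection rate
#' reaches \code{rateThreshold} (default 0.90; "reliably detected" is
#' undefined in clinical LoD parlance, so the threshold is explicit and
#' reported with the table).
#'
#' The background error model is fitted once from \code{nControls}
#' spike-free control simulations under the same conditions. The number
#' of raw molecules is set so the expected retained (size >= 2) family
#' count equals \code{consensusDepth}, the assay's median consensus
#' coverage by default.
#'
#' @param vafGrid Numeric vector of spike-in VAFs (proportions), any
#'   order.
#' @param class \code{"SNV"} or \code{"insertion"} (an NPM1-type 4-bp
#'   duplication).
#' @param consensusDepth Target retained-family depth (default 11363).
#' @param reps Replicates per grid point (>= 10; default 50).
#' @param seed Master seed; every control and replicate derives an
#'   independent sub-seed from it (recorded in the output for replay).
#' @param errorRates Per-read substitution spectrum for the simulator.
#' @param thresholds Caller thresholds, see [mrdThresholds()].
#' @param rateThreshold Detection-rate threshold defining the LoD.
#' @param nControls Control samples for the error model (default 3).
#' @param targetLength Simulated target length in bases (default 40).
#' @param familySizeMean Reads per molecule (default 14728/11363).
#' @param quorum,maxNFraction Consensus parameters.
#' @return A [S4Vectors::DataFrame] with one row per grid point:
#'   \code{class}, \code{vaf}, \code{vafPercent}, \code{reps},
#'   \code{nDetected}, \code{rate}, \code{meanAltFamilies},
#'   \code{meanDepth}; \code{metadata()} carries \code{lod} (proportion),
#'   \code{lodPercent}, \code{rateThreshold}, \code{seeds}, and the
#'   thresholds used.
#' @export
lodExperiment <- function(vafGrid = c(0.005, 0.001, 5e-4, 1e-4),
                          class = c("SNV", "insertion"),
                          consensusDepth = 11363L, reps = 50L, seed = 1L,
                          errorRates = defaultErrorRates(),
                          thresholds = mrdThresholds(),
                          rateThreshold = 0.90, nControls = 3L,
                          targetLength = 40L,
                          familySizeMean = 14728 / 11363,
                          quorum = 0.70, maxNFraction = 0.20) {
    class <- match.arg(class)
    stopifnot(length(vafGrid) >= 1L, reps >= 10L, nControls >= 1L)
    vafGrid <- sort(vafGrid)
    pRetained <- 1 - exp(-(familySizeMean - 1))
    nRaw <- as.integer(round(consensusDepth / pRetained))
    seeds <- deriveSeeds(seed, nControls + length(vafGrid) * reps + 1L)
    refSeq <- withr::with_seed(seeds[length(seeds)],
        paste(sample(DNA_BASES, targetLength, replace = TRUE),
              collapse = ""))
    pos <- as.integer(ceiling(targetLength / 2))
    refBase <- substr(refSeq, pos, pos)
    if (class == "SNV") {
        altAllele <- setdiff(DNA_BASES, refBase)[1L]
        refAllele <- refBase
    } else {
        dup <- substr(refSeq, pos - 3L, pos)   # 4-bp tandem duplication
        refAllele <- refBase
        altAllele <- paste0(refBase, dup)
    }
    tracked <- trackedMutations(patient = "LOD", gene = "SIM",
                                target = "T1", pos = pos,
                                ref = refAllele, alt = altAllele,
                                diagnosticVaf = 0.5, class = NULL)
    baseCfg <- function(spikeVaf, s) {
        spikes <- if (is.null(spikeVaf)) NULL else
            data.frame(target = "T1", pos = pos, ref = refAllele,
                       alt = altAllele, vaf = spikeVaf, id = "spike")
        simConfig(stats::setNames(refSeq, "T1"), nFamilies = nRaw,
                  familySizeMean = familySizeMean,
                  errorRates = errorRates, spikeIns = spikes, seed = s)
    }
    runOne <- function(spikeVaf, s) {
        smp <- simulateSample(baseCfg(spikeVaf, s))
        consensusPileup(smp, quorum = quorum, maxNFraction = maxNFraction)
    }
    model <- fitErrorModel(lapply(seeds[seq_len(nControls)],
                                  function(s) runOne(NULL, s)))
    res <- lapply(seq_along(vafGrid), function(gi) {
        det <- logical(reps); alt <- numeric(reps); dep <- numeric(reps)
        for (r in seq_len(reps)) {
            s <- seeds[nControls + (gi - 1L) * reps + r]
            pl <- runOne(vafGrid[gi], s)
            call <- callTrackedMutations(pl, tracked, model, thresholds)
            det[r] <- call$status[1L] == "detected"
            alt[r] <- call$altFamilies[1L]
            dep[r] <- call$consensusDepth[1L]
        }
        DataFrame(class = class, vaf = vafGrid[gi],
                  vafPercent = 100 * vafGrid[gi], reps = reps,
                  nDetected = sum(det), rate = mean(det),
                  meanAltFamilies = mean(alt), meanDepth = mean(dep))
    })
    tab <- do.call(rbind, res)
    hitIdx <- which(tab$rate >= rateThreshold)
    lod <- if (length(hitIdx)) tab$vaf[min(hitIdx)] else NA_real_
    metadata(tab) <- list(lod = lod,
                          lodPercent = if (is.na(lod)) NA_real_
                                       else 100 * lod,
                          rateThreshold = rateThreshold, seeds = seeds,
                          thresholds = thresholds,
                          consensusDepth = consensusDepth, nRaw = nRaw)
    tab
}
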