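#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Configuration for a simulated smMIPS capture
#'
#' Holds everything needed to generate one UMI-tagged smMIPS-like sample:
#' the target reference sequences, the number of captured molecules per
#' target, the family-size (reads per molecule) distribution, the
#' substitution error spectrum, and any spike-in variants with their
#' variant allele fractions (VAFs).
#'
#' @slot targets A named [Biostrings::DNAStringSet] of target reference
#'   sequences (target-local coordinates, 1-based).
#' @slot nFamilies Integer, number of captured molecules (UMI families,
#'   including future singletons) per target.
#' @slot familySizeMean Numeric mean of the shifted-Poisson family-size
#'   distribution (reads per molecule); sizes are \code{1 + Poisson(mean - 1)}.
#' @slot umiLength Integer UMI length in bases (assay default 8).
#' @slot errorRates Named numeric vector of per-base substitution
#'   probabilities, one per class \code{"X>Y"} (12 classes).
#' @slot spikeIns A [S4Vectors::DataFrame] with columns \code{target},
#'   \code{pos}, \code{ref}, \code{alt}, \code{vaf}, \code{id}; \code{ref}
#'   and \code{alt} use VCF-style alleles so insertions/deletions are
#'   expressed as length differences.
#' @slot seed Integer seed governing all randomness of the simulation.
#' @seealso [simConfig()], [simulateSample()]
#' @export
setClass("MipsSimConfig", slots = c(
    targets = "DNAStringSet",
    nFamilies = "integer",
    familySizeMean = "numeric",
    umiLength = "integer",
    errorRates = "numeric",
    spikeIns = "DataFrame",
    seed = "integer"
))

setValidity("MipsSimConfig", function(object) {
    msg <- character()
    if (length(object@targets) == 0L)
        msg <- c(msg, "at least one target sequence is required")
    if (is.null(names(object@targets)) || anyDuplicated(names(object@targets)))
        msg <- c(msg, "targets must have unique names")
    if (object@umiLength < 4L)
        msg <- c(msg, "umiLength must be >= 4")
    if (object@familySizeMean < 1)
        msg <- c(msg, "familySizeMean must be >= 1 (sizes are >= 1 read)")
    if (any(object@errorRates < 0) || any(object@errorRates >= 1))
        msg <- c(msg, "error rates must lie in [0, 1)")
    si <- object@spikeIns
    if (nrow(si)) {
        if (any(si$vaf <= 0 | si$vaf >= 1))
            msg <- c(msg, "spike-in VAFs must lie in (0, 1)")
        bad <- !(si$target %in% names(object@targets))
        if (any(bad))
            msg <- c(msg, paste0("spike-in target(s) not in panel: ",
                                 paste(unique(si$target[bad]), collapse = ", ")))
        for (i in seq_len(nrow(si))) {
            if (!si$target[i] %in% names(object@targets)) next
            L <- Biostrings::width(object@targets[si$target[i]])
            end <- si$pos[i] + nchar(si$ref[i]) - 1L
            if (si$pos[i] < 1L || end > L)
                msg <- c(msg, sprintf(
                    "spike-in at %s:%d (ref '%s') lies outside target of length %d",
                    si$target[i], si$pos[i], si$ref[i], L))
        }
    }
    if (length(msg)) msg else TRUE
})

#' A simulated smMIPS sample with ground truth
#'
#' Returned by [simulateSample()]. Reads are merged (paired-end assembled)
#' payload sequences; the UMI a read would carry as its first
#' \code{umiLength} bases on read 1 is recorded per read. The truth table
#' records, per UMI family, the target, UMI, true haplotype and family
#' size; injected sequencing errors are recorded per read.
#'
#' @slot reads A [S4Vectors::DataFrame] with columns \code{id},
#'   \code{target}, \code{family}, \code{umi}, \code{sequence}.
#' @slot truth A [S4Vectors::DataFrame] with one row per family: columns
#'   \code{target}, \code{family}, \code{umi}, \code{haplotype}
#'   (\code{"ref"} or a spike-in id), \code{size}.
#' @slot errors A [S4Vectors::DataFrame] of injected per-read substitution
#'   errors: \code{read} (row index into \code{reads}), \code{pos}
#'   (1-based payload position), \code{from}, \code{to}.
#' @slot config The [MipsSimConfig-class] used.
#' @export
setClass("SimulatedSample", slots = c(
    reads = "DataFrame",
    truth = "DataFrame",
    errors = "DataFrame",
    config = "MipsSimConfig"
))

setValidity("SimulatedSample", function(object) {
    msg <- character()
    if (nrow(object@reads) != sum(object@truth$size))
        msg <- c(msg, "read count must equal the sum of truth family sizes")
    if (!all(object@reads$family %in% object@truth$family))
        msg <- c(msg, "every read must map to a truth family record")
    if (length(msg)) msg else TRUE
})

#' Per-site consensus base counts over a target panel
#'
#' The unit consumed by the error model and the MRD caller: for every
#' (target, 1-based position), counts of consensus bases A/C/G/T, N,
#' and per-molecule deletion calls, plus insertion counts keyed by the
#' inserted sequence. At every site
#' \code{A + C + G + T + N + del == depth} (validity-enforced);
#' insertions do not consume a base slot.
#'
#' @slot sites A [S4Vectors::DataFrame] with columns \code{target},
#'   \code{pos}, \code{ref}, \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{N}, \code{del}, \code{depth}.
#' @slot insertions A [S4Vectors::DataFrame] with columns \code{target},
#'   \code{pos} (insertion follows this position), \code{seq},
#'   \code{count}.
#' @slot references Named [Biostrings::DNAStringSet] of target references.
#' @slot nExcluded Integer, consensus reads that matched no target.
#' @seealso [buildPileup()]
#' @export
setClass("SitePileup", slots = c(
    sites = "DataFrame",
    insertions = "DataFrame",
    references = "DNAStringSet",
    nExcluded = "integer"
))

setValidity("SitePileup", function(object) {
    s <- object@sites
    need <- c("target", "pos", "ref", "A", "C", "G", "T", "N", "del", "depth")
    if (!all(need %in% colnames(s)))
        return(paste("sites must have columns:", paste(need, collapse = ", ")))
    tot <- s$A + s$C + s$G + s$T + s$N + s$del
    if (any(tot != s$depth))
        return("base + N + del counts must equal depth at every site")
    TRUE
})

#' Site- and mutation-specific background error model
#'
#' Fitted from control-sample pileups by [fitErrorModel()]. For every
#' (target, position, alternate allele) the model pools alternate-allele
#' and depth counts across controls and stores the pseudocounted rate
#' \code{(alt + pc) / (depth + 2 pc)}. Indel alleles never observed in
#' the controls receive pseudocount-only rates against the pooled site
#' depth. Sites with zero pooled depth are unmodeled: the caller must
#' refuse to call there rather than silently report a p-value.
#'
#' @slot substitutions [S4Vectors::DataFrame] with columns \code{target},
#'   \code{pos}, \code{ref}, \code{alt}, \code{altCount}, \code{depth},
#'   \code{rate}.
#' @slot indels [S4Vectors::DataFrame] with columns \code{target},
#'   \code{pos}, \code{type} (\code{"ins"}/\code{"del"}), \code{allele},
#'   \code{count}, \code{depth}, \code{rate} (observed indel alleles only).
#' @slot siteDepth [S4Vectors::DataFrame] of pooled depth per site, used
#'   for pseudocount-only rates of unobserved indel alleles.
#' @slot pseudocount Numeric pseudocount (default 0.5).
#' @slot nControls Integer, number of control samples pooled.
#' @export
setClass("ErrorModel", slots = c(
    substitutions = "DataFrame",
    indels = "DataFrame",
    siteDepth = "DataFrame",
    pseudocount = "numeric",
    nControls = "integer"
))

setValidity("ErrorModel", function(object) {
    msg <- character()
    if (object@nControls < 1L)
        msg <- c(msg, "at least one control sample is required")
    if (object@pseudocount <= 0)
        msg <- c(msg, "pseudocount must be > 0")
    r <- object@substitutions$rate
    if (length(r) && (any(r < 0, na.rm = TRUE) || any(r >= 1, na.rm = TRUE)))
        msg <- c(msg, "rates must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' MRD status of one sample at one time point
#'
#' Returned by [classifySample()]. \code{status} is one of
#' \code{"MRD-positive"}, \code{"MRD-negative"}, \code{"untestable"};
#' \code{basis} names the tracked mutations that drove positivity.
#'
#' @slot patient Character patient identifier.
#' @slot timePoint \code{"PI"} (post induction) or \code{"PC"}
#'   (post consolidation).
#' @slot tissue \code{"BM"} or \code{"PB"} (metadata only; no numerical
#'   adjustment is applied between sources).
#' @slot calls The [S4Vectors::DataFrame] of per-mutation calls from
#'   [callTrackedMutations()].
#' @slot status Character sample-level MRD status.
#' @slot basis Character vector of mutation ids that drove positivity.
#' @slot dtaPolicy The DTA policy applied (see [classifySample()]).
#' @export
setClass("SampleMrdResult", slots = c(
    patient = "character",
    timePoint = "character",
    tissue = "character",
    calls = "DataFrame",
    status = "character",
    basis = "character",
    dtaPolicy = "character"
))
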