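#' Genes whose persistent mutations commonly reflect clonal hematopoiesis
#'
#' DNMT3A, TET2 and ASXL1 ("DTA" genes). Their persistence at MRD time
#' points often traces an ancestral clonal-hematopoiesis clone rather
#' than residual leukemia, so sample classification treats them
#' specially; see [classifySample()].
#' @export
DTA_GENES <- c("DNMT3A", "TET2", "ASXL1")

#' Detection thresholds for tracked-mutation MRD calling
#'
#' A mutation is \emph{detected} when its BH-adjusted binomial p-value
#' against the site background is below \code{qMax}, it is supported by
#' at least \code{minFamilies} consensus families for its variant class,
#' and its VAF is at least the per-class \code{vafFloor}. Sites with
#' consensus depth below \code{minDepth}, absent from the panel, or
#' unmodeled are \emph{untestable} — a first-class status distinct from
#' negative, because silent negatives at low depth are the main MRD
#' failure mode.
#'
#' The published supplementary calling criteria are not reproduced here;
#' these defaults are this package's own, power-analyzed choices (methods
#' vignette): \code{qMax = 0.05}, \code{minFamilies = 2} for every class,
#' \code{minDepth = 1000} consensus families, \code{vafFloor = 0}. The
#' assay-validated class LoDs (0.05\% SNV, 0.03\% NPM1-type indel) are
#' results of [lodExperiment()], not caller gates.
#'
#' @param qMax Maximum BH-adjusted p-value.
#' @param minFamilies Named integer vector of minimum supporting
#'   consensus families per class (\code{SNV}, \code{insertion},
#'   \code{deletion}, \code{ITD}).
#' @param minDepth Minimum consensus depth for a site to be testable.
#' @param vafFloor Named per-class minimum VAF (proportions).
#' @return A named list of thresholds, recorded in every caller output.
#' @export
mrdThresholds <- function(qMax = 0.05,
                          minFamilies = c(SNV = 2L, insertion = 2L,
                                          deletion = 2L, ITD = 2L),
                          minDepth = 1000L,
                          vafFloor = c(SNV = 0, insertion = 0,
                                       deletion = 0, ITD = 0)) {
    list(qMax = qMax, minFamilies = minFamilies, minDepth = minDepth,
         vafFloor = vafFloor)
}

#' Assemble a tracked-mutation table
#'
#' Tracked mutations are the patient's diagnostic mutations to be
#' monitored at MRD time points (typically 1-6 per patient). Alleles are
#' VCF-style, so insertions/deletions are length differences between
#' \code{ref} and \code{alt}.
#'
#' @param patient Patient id.
#' @param gene Gene symbol per mutation.
#' @param target Panel target name per mutation.
#' @param pos 1-based position on the target.
#' @param ref,alt VCF-style alleles.
#' @param diagnosticVaf VAF at diagnosis, in (0, 1].
#' @param class Optional variant class (\code{SNV}, \code{insertion},
#'   \code{deletion}, \code{ITD}); inferred from allele lengths when
#'   missing.
#' @return A [S4Vectors::DataFrame] with an \code{isDta} column set from
#'   membership in [DTA_GENES].
#' @export
trackedMutations <- function(patient, gene, target, pos, ref, alt,
                             diagnosticVaf, class = NULL) {
    if (is.null(class))
        class <- ifelse(nchar(ref) == nchar(alt), "SNV",
                        ifelse(nchar(alt) > nchar(ref), "insertion",
                               "deletion"))
    stopifnot(all(diagnosticVaf > 0 & diagnosticVaf <= 1))
    DataFrame(patient = patient, gene = gene, target = target,
              pos = as.integer(pos), ref = ref, alt = alt, class = class,
              diagnosticVaf = diagnosticVaf,
              isDta = gene %in% DTA_GENES,
              id = sprintf("%s_%s:%d_%s>%s", gene, target, pos, ref, alt))
}

## Locate the supporting-count and depth for one tracked mutation in a
## pileup; returns list(altCount, depth, modelAlt, modelPos) or NULL when
## the site is absent.
lookupTracked <- function(pileup, target, pos, ref, alt, class) {
    s <- pileup@sites
    refSeq <- if (target %in% names(pileup@references))
        as.character(pileup@references[[target]]) else return(NULL)
    if (class == "SNV") {
        i <- which(s$target == target & s$pos == pos)
        if (!length(i)) return(NULL)
        list(altCount = s[[alt]][i[1L]], depth = s$depth[i[1L]],
             modelAlt = alt, modelPos = pos)
    } else if (class == "insertion") {
        mutant <- applyEdit(refSeq, pos, ref, alt)
        canon <- normalizeInsertion(refSeq, mutant)
        anchorPos <- max(canon$pos, 1L)
        i <- which(s$target == target & s$pos == anchorPos)
        if (!length(i)) return(NULL)
        p <- pileup@insertions
        j <- which(p$target == target & p$pos == canon$pos &
                   p$seq == canon$seq)
        list(altCount = if (length(j)) p$count[j[1L]] else 0L,
             depth = s$depth[i[1L]],
             modelAlt = paste0("ins:", canon$seq), modelPos = canon$pos)
    } else if (class == "deletion") {
        mutant <- applyEdit(refSeq, pos, ref, alt)
        canon <- normalizeDeletion(refSeq, mutant)
        delIdx <- canon$pos + seq_len(canon$len)
        i <- which(s$target == target & s$pos %in% delIdx)
        if (length(i) < canon$len) return(NULL)
        list(altCount = min(s$del[i]), depth = s$depth[i[1L]],
             modelAlt = "del", modelPos = delIdx[1L])
    } else NULL
}

#' Quantify tracked mutations in an MRD sample
#'
#' For every tracked mutation, counts supporting consensus families and
#' depth in the pileup, computes the one-sided binomial p-value against
#' the site- and mutation-specific background ([sitePValue()]), adjusts
#' across the sample's tracked set (Benjamini-Hochberg; MRD tracking
#' tests few prespecified sites, so correction is within-sample, not
#' panel-wide), and applies the detection thresholds. Tracked sites
#' absent from the panel, unmodeled, or below the depth floor are
#' reported \code{untestable}, never silently negative. \code{ITD}-class
#' entries are untestable here: they belong to the deep-amplicon path
#' ([detectItd()]).
#'
#' @param pileup A [SitePileup-class] for the MRD sample.
#' @param tracked A tracked-mutation table from [trackedMutations()].
#' @param model A fitted [ErrorModel-class].
#' @param thresholds See [mrdThresholds()].
#' @return A [S4Vectors::DataFrame] of calls: the tracked columns plus
#'   \code{altFamilies}, \code{consensusDepth}, \code{vaf},
#'   \code{pValue}, \code{qValue}, \code{status} (\code{detected} /
#'   \code{not-detected} / \code{untestable}) and \code{reason};
#'   thresholds are recorded in \code{metadata()}.
#' @export
callTrackedMutations <- function(pileup, tracked, model,
                                 thresholds = mrdThresholds()) {
    n <- nrow(tracked)
    altFam <- integer(n); depth <- integer(n)
    p <- rep(NA_real_, n); reason <- rep(NA_character_, n)
    testable <- logical(n)
    for (i in seq_len(n)) {
        cls <- tracked$class[i]
        if (cls == "ITD") {
            reason[i] <- "ITD class is tracked by the deep-amplicon assay"
            next
        }
        hit <- lookupTracked(pileup, tracked$target[i], tracked$pos[i],
                             tracked$ref[i], tracked$alt[i], cls)
        if (is.null(hit)) {
            reason[i] <- "tracked site absent from panel pileup"
            next
        }
        altFam[i] <- hit$altCount; depth[i] <- hit$depth
        if (hit$depth < thresholds$minDepth) {
            reason[i] <- sprintf("consensus depth %d below minimum %d",
                                 hit$depth, thresholds$minDepth)
            next
        }
        rate <- errorRate(model, tracked$target[i], hit$modelPos,
                          hit$modelAlt)
        if (is.na(rate)) {
            reason[i] <- "site unmodeled in control error model"
            next
        }
        p[i] <- sitePValue(model, tracked$target[i], hit$modelPos,
                           hit$modelAlt, hit$altCount, hit$depth)
        testable[i] <- TRUE
    }
    q <- rep(NA_real_, n)
    q[testable] <- stats::p.adjust(p[testable], method = "BH")
    vaf <- ifelse(depth > 0L, altFam / depth, 0)
    minFam <- thresholds$minFamilies[tracked$class]
    floorV <- thresholds$vafFloor[tracked$class]
    detected <- testable & q < thresholds$qMax & altFam >= minFam &
        vaf >= floorV
    status <- ifelse(!testable, "untestable",
                     ifelse(detected, "detected", "not-detected"))
    out <- tracked
    out$altFamilies <- altFam
    out$consensusDepth <- depth
    out$vaf <- vaf
    out$pValue <- p
    out$qValue <- q
    out$status <- status
    out$reason <- reason
    metadata(out) <- list(thresholds = thresholds)
    out
}

#' Classify a sample's MRD status with the DTA-gene policy
#'
#' A sample is MRD-positive when any detected tracked mutation outside
#' the DTA genes persists. DTA-only positivity is time-point dependent:
#' at end of consolidation (PC) persistence of a DTA mutation alone never
#' makes a sample positive; at end of induction (PI), when no other
#' mutation is trackable, a persistent DTA clone may be accepted as
#' evidence under the \code{"pi-permissive"} policy (the default;
#' \code{"strict"} never accepts DTA-only positivity). A sample with no
#' testable calls is untestable, not negative.
#'
#' @param calls Output of [callTrackedMutations()] for one sample.
#' @param patient Patient id (defaults to the tracked table's).
#' @param timePoint \code{"PI"} or \code{"PC"}.
#' @param tissue \code{"BM"} or \code{"PB"}; metadata only, no numerical
#'   adjustment between sources.
#' @param dtaPolicy \code{"pi-permissive"} or \code{"strict"}.
#' @return A [SampleMrdResult-class].
#' @export
classifySample <- function(calls, patient = NULL,
                           timePoint = c("PI", "PC"), tissue = "BM",
                           dtaPolicy = c("pi-permissive", "strict")) {
    timePoint <- match.arg(timePoint)
    dtaPolicy <- match.arg(dtaPolicy)
    if (is.null(patient))
        patient <- if (nrow(calls)) calls$patient[1L] else NA_character_
    det <- calls$status == "detected"
    if (nrow(calls) == 0L || all(calls$status == "untestable")) {
        status <- "untestable"; basis <- character()
    } else if (any(det & !calls$isDta)) {
        status <- "MRD-positive"; basis <- calls$id[det & !calls$isDta]
    } else if (any(det) && timePoint == "PI" &&
               dtaPolicy == "pi-permissive") {
        status <- "MRD-positive"; basis <- calls$id[det]
    } else {
        status <- "MRD-negative"; basis <- character()
    }
    methods::new("SampleMrdResult", patient = as.character(patient),
                 timePoint = timePoint, tissue = tissue, calls = calls,
                 status = status, basis = basis, dtaPolicy = dtaPolicy)
}

#' MRD kinetics between the two assessment time points
#'
#' Compares post-induction (PI) and post-consolidation (PC) results of
#' one patient: the sample-level category (\code{neg/neg},
#' \code{pos->neg}, \code{neg->pos}, \code{pos/pos}) plus the
#' per-mutation gain/loss lists between the time points.
#'
#' @param pi,pc [SampleMrdResult-class] objects for the same patient at
#'   PI and PC.
#' @return A list with \code{category}, \code{gained}, \code{lost}
#'   (mutation ids), and \code{changed} (logical).
#' @export
mrdKinetics <- function(pi, pc) {
    if (!identical(pi@patient, pc@patient))
        stop("PI and PC results are for different patients: ",
             pi@patient, " vs ", pc@patient)
    if (pi@status == "untestable" || pc@status == "untestable")
        stop("kinetics require testable results at both time points")
    lab <- function(x) if (x@status == "MRD-positive") "pos" else "neg"
    category <- switch(paste(lab(pi), lab(pc)),
                       "neg neg" = "neg/neg", "pos pos" = "pos/pos",
                       "pos neg" = "pos->neg", "neg pos" = "neg->pos")
    detIds <- function(x) x@calls$id[x@calls$status == "detected"]
    gained <- setdiff(detIds(pc), detIds(pi))
    lost <- setdiff(detIds(pi), detIds(pc))
    list(category = category, gained = gained, lost = lost,
         changed = length(gained) + length(lost) > 0L)
}
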