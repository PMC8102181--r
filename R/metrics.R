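#' Dual-modality MRD concordance from a 2x2 contingency table
#'
#' Given counts of patients cross-classified by NGS-MRD and FCM-MRD
#' status, computes each modality's capture rate of the other's positives
#' and the overall agreement. Zero denominators yield \code{NA}
#' (undefined), never 0.
#'
#' @param ppCount NGS+ / FCM+ count.
#' @param pnCount NGS+ / FCM- count.
#' @param npCount NGS- / FCM+ count.
#' @param nnCount NGS- / FCM- count.
#' @param timePoint Optional label carried through (e.g. \code{"PI"}).
#' @return A list with proportions \code{ngsCaptureOfFcm}
#'   (NGS+FCM+ / FCM+), \code{fcmCaptureOfNgs} (NGS+FCM+ / NGS+),
#'   \code{agreement}, the corresponding \code{*Percent} fields rounded
#'   half-up to one decimal, the marginals, and \code{timePoint}.
#' @examples
#' cc <- concordance(68, 70, 17, 40)   # post-induction worked example
#' cc$ngsCaptureOfFcmPercent            # 80.0
#' cc$fcmCaptureOfNgsPercent            # 49.3
#' @export
concordance <- function(ppCount, pnCount, npCount, nnCount,
                        timePoint = NA_character_) {
    counts <- c(ppCount, pnCount, npCount, nnCount)
    stopifnot(all(counts >= 0), sum(counts) > 0)
    fcmPos <- ppCount + npCount
    ngsPos <- ppCount + pnCount
    total <- sum(counts)
    safeDiv <- function(num, den) if (den > 0) num / den else NA_real_
    ngsCap <- safeDiv(ppCount, fcmPos)
    fcmCap <- safeDiv(ppCount, ngsPos)
    agree <- (ppCount + nnCount) / total
    list(ngsCaptureOfFcm = ngsCap, fcmCaptureOfNgs = fcmCap,
         agreement = agree,
         ngsCaptureOfFcmPercent = roundHalfUp(100 * ngsCap),
         fcmCaptureOfNgsPercent = roundHalfUp(100 * fcmCap),
         agreementPercent = roundHalfUp(100 * agree),
         fcmPositive = fcmPos, ngsPositive = ngsPos, total = total,
         timePoint = timePoint)
}

#' Read a 4-field contingency counts file
#'
#' Tab-separated with a header naming the four cells
#' \code{pp}, \code{pn}, \code{np}, \code{nn} (NGS first, FCM second).
#'
#' @param path TSV path.
#' @return Named numeric vector of the four counts.
#' @export
readContingency <- function(path) {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
    stopifnot(all(c("pp", "pn", "np", "nn") %in% colnames(x)))
    c(pp = x$pp[1L], pn = x$pn[1L], np = x$np[1L], nn = x$nn[1L])
}

#' Predictive metrics of MRD status against outcome
#'
#' Sensitivity, specificity, prevalence, PPV, NPV and accuracy from a
#' confusion table of MRD status against the outcome it predicts.
#' Accuracy uses the prevalence-weighted identity
#' \deqn{accuracy = sensitivity \times prevalence +
#'       specificity \times (1 - prevalence)}
#' which on raw counts equals \eqn{(tp + tn) / total}; the equality is
#' verified internally on every call. Undefined denominators are
#' reported as \code{NA} and named in \code{undefined}.
#'
#' @param tp,fp,fn,tn Confusion-table counts.
#' @return A list with \code{sensitivity}, \code{specificity},
#'   \code{prevalence}, \code{ppv}, \code{npv}, \code{accuracy},
#'   \code{undefined}.
#' @examples
#' m <- predictiveMetrics(tp = 30, fp = 10, fn = 20, tn = 40)
#' m$accuracy  # 0.7, equal to (30 + 40) / 100
#' @export
predictiveMetrics <- function(tp, fp, fn, tn) {
    stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
    if (tp + fn == 0) stop("no outcome-positive cases: tp + fn must be > 0")
    if (tn + fp == 0) stop("no outcome-negative cases: tn + fp must be > 0")
    total <- tp + fp + fn + tn
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    prev <- (tp + fn) / total
    ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    acc <- sens * prev + spec * (1 - prev)
    stopifnot(isTRUE(all.equal(acc, (tp + tn) / total)))
    undef <- c("ppv", "npv")[c(is.na(ppv), is.na(npv))]
    list(sensitivity = sens, specificity = spec, prevalence = prev,
         ppv = ppv, npv = npv, accuracy = acc, undefined = undef)
}
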