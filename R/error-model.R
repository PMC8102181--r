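#' Fit the site- and mutation-specific background error model
#'
#' For every (target, position, alternate allele) the alternate and total
#' consensus-family counts are pooled across the control samples and
#' converted to a pseudocounted background rate
#' \deqn{rate = (alt + pc) / (depth + 2 pc)}
#' with pseudocount \eqn{pc = 0.5} by default (a Jeffreys-style prior, so
#' channels with zero observed events still get a finite, testable rate).
#' Substitution channels are modeled at every site; insertion/deletion
#' alleles observed in the controls get their own rates, and unobserved
#' indel alleles fall back to the pseudocount-only rate against the
#' pooled site depth. Sites with zero pooled depth are unmodeled and the
#' caller refuses to call there.
#'
#' Controls are pooled rather than modeled per-sample; this is the
#' minimal model consistent with site- and mutation-specific background
#' and is the default (see the methods vignette for the overdispersion
#' discussion).
#'
#' @param controlPileups A list of [SitePileup-class] from control
#'   (variant-free) samples; at least one.
#' @param pseudocount Pseudocount added to alternate counts (default 0.5).
#' @return An [ErrorModel-class].
#' @export
fitErrorModel <- function(controlPileups, pseudocount = 0.5) {
    if (!is.list(controlPileups)) controlPileups <- list(controlPileups)
    if (length(controlPileups) == 0L)
        stop("at least one control sample is required")
    stopifnot(all(vapply(controlPileups, methods::is, TRUE, "SitePileup")))
    allSites <- do.call(rbind, lapply(controlPileups, methods::slot, "sites"))
    key <- paste(allSites$target, allSites$pos, sep = "\r")
    u <- !duplicated(key)
    agg <- allSites[u, c("target", "pos", "ref"), drop = FALSE]
    for (cl in c(DNA_BASES, "N", "del", "depth"))
        agg[[cl]] <- as.integer(rowsum(allSites[[cl]], key)[key[u], 1L])
    subs <- do.call(rbind, lapply(DNA_BASES, function(b) {
        sel <- agg$ref != b
        DataFrame(target = agg$target[sel], pos = agg$pos[sel],
                  ref = agg$ref[sel], alt = b,
                  altCount = agg[[b]][sel], depth = agg$depth[sel])
    }))
    subs$rate <- ifelse(subs$depth > 0L,
                        (subs$altCount + pseudocount) /
                            (subs$depth + 2 * pseudocount), NA_real_)
    allIns <- do.call(rbind, lapply(controlPileups, methods::slot,
                                    "insertions"))
    siteDepth <- agg[, c("target", "pos", "depth")]
    insKey <- paste(allIns$target, allIns$pos, allIns$seq, sep = "\r")
    ui <- !duplicated(insKey)
    ins <- allIns[ui, , drop = FALSE]
    if (nrow(ins)) {
        ins$count <- as.integer(rowsum(allIns$count, insKey)[insKey[ui], 1L])
        ins <- DataFrame(target = ins$target, pos = ins$pos, type = "ins",
                         allele = ins$seq, count = ins$count)
    } else {
        ins <- DataFrame(target = character(), pos = integer(),
                         type = character(), allele = character(),
                         count = integer())
    }
    del <- agg[agg$del > 0L, , drop = FALSE]
    del <- DataFrame(target = del$target, pos = del$pos,
                     type = rep("del", nrow(del)),
                     allele = rep("*", nrow(del)), count = del$del)
    indels <- rbind(ins, del)
    indels$depth <- siteDepth$depth[match(paste(indels$target, indels$pos),
                                          paste(siteDepth$target,
                                                siteDepth$pos))]
    indels$rate <- ifelse(indels$depth > 0L,
                          (indels$count + pseudocount) /
                              (indels$depth + 2 * pseudocount), NA_real_)
    methods::new("ErrorModel", substitutions = subs, indels = indels,
                 siteDepth = siteDepth, pseudocount = pseudocount,
                 nControls = length(controlPileups))
}

#' Background rate for an allele at a site
#'
#' @param model An [ErrorModel-class].
#' @param target,pos Site (1-based position).
#' @param alt Alternate allele: one of \code{"A"}, \code{"C"}, \code{"G"},
#'   \code{"T"}; \code{"ins:<SEQ>"} for a specific insertion; \code{"del"}.
#' @return The background rate, or \code{NA} if the site is unmodeled
#'   (zero pooled control depth) or absent from the panel.
#' @export
errorRate <- function(model, target, pos, alt) {
    if (alt %in% DNA_BASES) {
        s <- model@substitutions
        i <- which(s$target == target & s$pos == pos & s$alt == alt)
        if (!length(i)) return(NA_real_)
        return(s$rate[i[1L]])
    }
    type <- if (identical(alt, "del")) "del" else "ins"
    allele <- if (type == "ins") sub("^ins:", "", alt) else "*"
    d <- model@indels
    i <- which(d$target == target & d$pos == pos & d$type == type &
               d$allele == allele)
    if (length(i)) return(d$rate[i[1L]])
    sd <- model@siteDepth
    j <- which(sd$target == target & sd$pos == pos)
    if (!length(j) || sd$depth[j[1L]] == 0L) return(NA_real_)
    model@pseudocount / (sd$depth[j[1L]] + 2 * model@pseudocount)
}

#' One-sided binomial p-value against the background error rate
#'
#' Upper-tail exact binomial test of the observed alternate family count
#' against the fitted background: \eqn{p = P(X \ge altCount)} with
#' \eqn{X \sim Binom(depth, rate)}. \code{altCount = 0} gives \eqn{p = 1};
#' the p-value is monotone non-increasing in \code{altCount} at fixed
#' depth. Unmodeled sites are refused explicitly, never reported as
#' \eqn{p = 0}.
#'
#' @inheritParams errorRate
#' @param altCount Observed alternate consensus-family count.
#' @param depth Consensus depth at the site.
#' @param rho Overdispersion in \[0, 1): with \code{rho > 0} the tail is
#'   computed under a beta-binomial with the same mean rate and
#'   intra-class correlation \code{rho}, for panels whose background
#'   varies between runs more than binomial sampling allows. The
#'   default 0 is the pooled binomial model.
#' @return A p-value in (0, 1].
#' @export
sitePValue <- function(model, target, pos, alt, altCount, depth, rho = 0) {
    stopifnot(altCount >= 0, depth >= 0, altCount <= depth,
              rho >= 0, rho < 1)
    rate <- errorRate(model, target, pos, alt)
    if (is.na(rate))
        stop("site ", target, ":", pos, " allele ", alt,
             " is unmodeled (no control depth); refusing to compute a p-value")
    if (rho == 0)
        return(stats::pbinom(altCount - 1L, depth, rate,
                             lower.tail = FALSE))
    if (altCount == 0L) return(1)
    s <- (1 - rho) / rho                 # beta prior sample size
    a <- rate * s
    b <- (1 - rate) * s
    k <- 0:(altCount - 1L)
    logpmf <- lchoose(depth, k) + lbeta(k + a, depth - k + b) -
        lbeta(a, b)
    max(1 - sum(exp(logpmf)), .Machine$double.xmin)
}

#' Serialize an error model to TSV
#'
#' Writes a versioned TSV with a commented provenance header (controls
#' pooled, pseudocount, date). Counts and depths are stored; rates are
#' recomputed on load, so a round-trip reproduces the model exactly.
#'
#' @param model An [ErrorModel-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @seealso [readErrorModel()]
#' @export
writeErrorModel <- function(model, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# smMRD error model v1",
                 sprintf("# nControls=%d pseudocount=%g date=%s",
                         model@nControls, model@pseudocount,
                         format(Sys.Date()))), con)
    s <- as.data.frame(model@substitutions)
    s <- data.frame(type = "sub", target = s$target, pos = s$pos,
                    ref = s$ref, allele = s$alt, count = s$altCount,
                    depth = s$depth)
    i <- as.data.frame(model@indels)
    if (nrow(i))
        i <- data.frame(type = i$type, target = i$target, pos = i$pos,
                        ref = ".", allele = i$allele, count = i$count,
                        depth = i$depth)
    else i <- s[0, ]
    sd <- as.data.frame(model@siteDepth)
    sd <- data.frame(type = "site", target = sd$target, pos = sd$pos,
                     ref = ".", allele = ".", count = 0L, depth = sd$depth)
    utils::write.table(rbind(s, i, sd), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a serialized error model
#'
#' @param path Path written by [writeErrorModel()].
#' @return An [ErrorModel-class].
#' @export
readErrorModel <- function(path) {
    hdr <- readLines(path, n = 2L)
    if (!grepl("^# smMRD error model", hdr[1L]))
        stop("not an smMRD error model file: ", path)
    nControls <- as.integer(sub(".*nControls=(\\d+).*", "\\1", hdr[2L]))
    pc <- as.numeric(sub(".*pseudocount=([0-9.eE+-]+) .*", "\\1", hdr[2L]))
    x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = c("character", "character", "integer",
                                          "character", "character", "integer",
                                          "integer"))
    s <- x[x$type == "sub", ]
    subs <- DataFrame(target = s$target, pos = s$pos, ref = s$ref,
                      alt = s$allele, altCount = s$count, depth = s$depth)
    subs$rate <- ifelse(subs$depth > 0L,
                        (subs$altCount + pc) / (subs$depth + 2 * pc),
                        NA_real_)
    i <- x[x$type %in% c("ins", "del"), ]
    indels <- DataFrame(target = i$target, pos = i$pos, type = i$type,
                        allele = i$allele, count = i$count, depth = i$depth)
    indels$rate <- ifelse(indels$depth > 0L,
                          (indels$count + pc) / (indels$depth + 2 * pc),
                          NA_real_)
    sd <- x[x$type == "site", ]
    methods::new("ErrorModel", substitutions = subs, indels = indels,
                 siteDepth = DataFrame(target = sd$target, pos = sd$pos,
                                       depth = sd$depth),
                 pseudocount = pc, nControls = nControls)
}
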