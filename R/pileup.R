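## Canonical (left-aligned) placement of a pure insertion read vs its
## reference: returns list(pos, seq) where the insertion follows `pos`
## (0 allowed), or NULL if the read is not a clean single insertion.
normalizeInsertion <- function(refSeq, readSeq) {
    L <- nchar(refSeq); d <- nchar(readSeq) - L
    if (d <= 0L) return(NULL)
    p <- commonPrefixLen(readSeq, refSeq)
    s <- commonSuffixLen(readSeq, refSeq)
    if (p + s < L) return(NULL)          # substitutions besides the indel
    pos <- L - min(s, L)                 # leftmost valid placement
    list(pos = pos, seq = substr(readSeq, pos + 1L, pos + d))
}

## Canonical placement of a pure deletion: deleted reference block is
## ref[(pos+1) .. (pos+d)].
normalizeDeletion <- function(refSeq, readSeq) {
    L <- nchar(refSeq); d <- L - nchar(readSeq)
    if (d <= 0L) return(NULL)
    p <- commonPrefixLen(readSeq, refSeq)
    s <- commonSuffixLen(readSeq, refSeq)
    if (p + s < nchar(readSeq)) return(NULL)
    pos <- nchar(readSeq) - min(s, nchar(readSeq))
    list(pos = pos, len = d)
}

#' Build per-site consensus pileups over a target panel
#'
#' Consensus reads of reference length contribute one base (or N) per
#' site. Length-discordant consensus reads are interpreted as a single
#' clean insertion or deletion by maximal prefix/suffix matching,
#' left-aligned: insertions are counted under their inserted sequence at
#' the preceding position (without consuming a base slot), deletions add
#' to the \code{del} count at each deleted position, and the read's
#' remaining bases are counted normally. Reads that cannot be explained
#' as one clean indel contribute N at every site, preserving depth
#' conservation without an allele claim. Consensus reads on targets
#' absent from \code{references} are counted and excluded.
#'
#' @param consensus Consensus reads, the \code{consensus} element of
#'   [buildConsensus()].
#' @param references Named [Biostrings::DNAStringSet] (or named character
#'   vector) of target reference sequences.
#' @return A [SitePileup-class]; 1-based positions.
#' @export
buildPileup <- function(consensus, references) {
    if (!methods::is(references, "DNAStringSet"))
        references <- Biostrings::DNAStringSet(references)
    siteParts <- list(); insParts <- list()
    known <- consensus$target %in% names(references)
    nExcluded <- sum(!known)
    consensus <- consensus[known, , drop = FALSE]
    for (t in unique(consensus$target)) {
        refSeq <- as.character(references[[t]])
        L <- nchar(refSeq)
        refBases <- strsplit(refSeq, "", fixed = TRUE)[[1L]]
        seqs <- consensus$sequence[consensus$target == t]
        counts <- matrix(0L, nrow = L, ncol = 6L,
                         dimnames = list(NULL, c(DNA_BASES, "N", "del")))
        insRec <- list()
        same <- nchar(seqs) == L
        if (any(same)) {
            m <- seqsToMatrix(seqs[same])
            for (b in c(DNA_BASES, "N"))
                counts[, b] <- counts[, b] + colSums(m == b)
        }
        for (rs in seqs[!same]) {
            hit <- if (nchar(rs) > L) normalizeInsertion(refSeq, rs)
                   else normalizeDeletion(refSeq, rs)
            if (is.null(hit)) {          # complex; no allele claim
                counts[, "N"] <- counts[, "N"] + 1L
                next
            }
            if (nchar(rs) > L) {
                key <- paste0(hit$pos, "\r", hit$seq)
                insRec[[key]] <- (insRec[[key]] %||% 0L) + 1L
                aligned <- paste0(substr(rs, 1L, hit$pos),
                                  substr(rs, hit$pos + nchar(hit$seq) + 1L,
                                         nchar(rs)))
            } else {
                delIdx <- hit$pos + seq_len(hit$len)
                counts[delIdx, "del"] <- counts[delIdx, "del"] + 1L
                aligned <- NA
            }
            if (nchar(rs) > L) {
                v <- substring(aligned, seq_len(L), seq_len(L))
                for (b in c(DNA_BASES, "N"))
                    counts[, b] <- counts[, b] + (v == b)
            } else {
                keepIdx <- setdiff(seq_len(L), hit$pos + seq_len(hit$len))
                v <- substring(rs, seq_len(nchar(rs)), seq_len(nchar(rs)))
                for (b in c(DNA_BASES, "N"))
                    counts[keepIdx, b] <- counts[keepIdx, b] +
                        (v == b)[seq_along(keepIdx)]
            }
        }
        siteParts[[t]] <- DataFrame(
            target = t, pos = seq_len(L), ref = refBases,
            A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
            G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
            N = as.integer(counts[, "N"]),
            del = as.integer(counts[, "del"]), depth = length(seqs))
        if (length(insRec)) {
            ks <- strsplit(names(insRec), "\r", fixed = TRUE)
            insParts[[t]] <- DataFrame(
                target = t,
                pos = as.integer(vapply(ks, `[`, "", 1L)),
                seq = vapply(ks, `[`, "", 2L),
                count = as.integer(unlist(insRec)))
        }
    }
    emptyIns <- DataFrame(target = character(), pos = integer(),
                          seq = character(), count = integer())
    methods::new("SitePileup",
                 sites = if (length(siteParts)) do.call(rbind, siteParts)
                         else DataFrame(target = character(), pos = integer(),
                                        ref = character(), A = integer(),
                                        C = integer(), G = integer(),
                                        T = integer(), N = integer(),
                                        del = integer(), depth = integer()),
                 insertions = if (length(insParts)) do.call(rbind, insParts)
                              else emptyIns,
                 references = references, nExcluded = nExcluded)
}

#' Assign reads to panel targets by probe-arm prefix
#'
#' Target-local mapping stands in for genome alignment: in a smMIPS
#' capture the read start is fixed by the extension arm, so the target is
#' identified by the best-matching reference prefix (fewest mismatches
#' over the first \code{k} bases; ties broken by panel order).
#'
#' @param sequences Character vector of payload sequences.
#' @param references Named [Biostrings::DNAStringSet] or character vector.
#' @param k Prefix length compared (default 12).
#' @param maxMismatch Maximum mismatches tolerated; beyond it the read is
#'   unassigned (\code{NA}).
#' @return Character vector of target names (NA where unassigned).
#' @export
assignTargets <- function(sequences, references, k = 12L, maxMismatch = 2L) {
    refs <- if (methods::is(references, "DNAStringSet"))
        as.character(references) else references
    pref <- substr(refs, 1L, k)
    readPref <- substr(sequences, 1L, k)
    hit <- match(readPref, pref)          # exact fast path
    todo <- which(is.na(hit))
    for (i in todo) {
        d <- vapply(pref, hammingDist, 0, a = readPref[i])
        j <- which.min(d)
        if (d[j] <= maxMismatch) hit[i] <- j
    }
    names(refs)[hit]
}

#' Consensus pileup of a simulated sample
#'
#' Convenience chain for a [SimulatedSample-class]: group the sample's
#' UMI-annotated reads into families, discard singletons, build quorum
#' consensus reads, and pile them up against the configured target
#' references.
#'
#' @param sample A [SimulatedSample-class].
#' @inheritParams consensusFamily
#' @return A [SitePileup-class].
#' @export
consensusPileup <- function(sample, quorum = 0.70, maxNFraction = 0.20) {
    grp <- groupFamilies(sample@reads)
    cons <- buildConsensus(grp$reads, quorum = quorum,
                           maxNFraction = maxNFraction)
    buildPileup(cons$consensus, sample@config@targets)
}

#' Serialize a site pileup to TSV
#'
#' One row per site with columns target, pos, ref, A, C, G, T, N, del,
#' ins_json (insertion counts keyed by sequence, JSON), depth; reference
#' sequences are carried in commented header lines so the pileup is
#' self-contained.
#'
#' @param pileup A [SitePileup-class].
#' @param path Output TSV path.
#' @return Invisibly, \code{path}.
#' @seealso [readSitePileup()]
#' @export
writeSitePileup <- function(pileup, path) {
    s <- as.data.frame(pileup@sites)
    ins <- pileup@insertions
    insJson <- vapply(seq_len(nrow(s)), function(i) {
        j <- which(ins$target == s$target[i] & ins$pos == s$pos[i])
        if (!length(j)) return("{}")
        as.character(jsonlite::toJSON(
            as.list(stats::setNames(ins$count[j], ins$seq[j])),
            auto_unbox = TRUE))
    }, character(1))
    s$ins_json <- insJson
    s <- s[, c("target", "pos", "ref", "A", "C", "G", "T", "N", "del",
               "ins_json", "depth")]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# smMRD site pileup v1",
                 sprintf("# reference %s %s", names(pileup@references),
                         as.character(pileup@references)),
                 sprintf("# nExcluded=%d", pileup@nExcluded)), con)
    utils::write.table(s, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a serialized site pileup
#'
#' @param path Path written by [writeSitePileup()].
#' @return A [SitePileup-class].
#' @export
readSitePileup <- function(path) {
    hdr <- grep("^#", readLines(path), value = TRUE)
    if (!grepl("smMRD site pileup", hdr[1L]))
        stop("not an smMRD pileup file: ", path)
    refLines <- grep("^# reference ", hdr, value = TRUE)
    parts <- strsplit(sub("^# reference ", "", refLines), " ")
    refs <- Biostrings::DNAStringSet(
        stats::setNames(vapply(parts, `[`, "", 2L),
                        vapply(parts, `[`, "", 1L)))
    nEx <- as.integer(sub(".*nExcluded=(\\d+).*", "\\1",
                          grep("nExcluded=", hdr, value = TRUE)[1L]))
    x <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", quote = "",
                           colClasses = c("character", "integer",
                                          "character", rep("integer", 6L),
                                          "character", "integer"))
    insParts <- list()
    hasIns <- which(x$ins_json != "{}")
    for (i in hasIns) {
        v <- unlist(jsonlite::fromJSON(x$ins_json[i]))
        insParts[[as.character(i)]] <- DataFrame(
            target = x$target[i], pos = x$pos[i], seq = names(v),
            count = as.integer(v))
    }
    methods::new(
        "SitePileup",
        sites = DataFrame(target = x$target, pos = x$pos, ref = x$ref,
                          A = x$A, C = x$C, G = x$G, T = x$T, N = x$N,
                          del = x$del, depth = x$depth),
        insertions = if (length(insParts)) do.call(rbind, insParts)
                     else DataFrame(target = character(), pos = integer(),
                                    seq = character(), count = integer()),
        references = refs, nExcluded = nEx)
}
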