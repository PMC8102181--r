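#' Extract UMIs from raw read-1 sequences
#'
#' The UMI is carried as the first \code{umiLength} bases of read 1 (the
#' assay attaches an 8 bp UMI per probe; placement is configurable).
#' Extraction moves the UMI into its own column and trims it from the
#' payload. Reads not longer than the UMI are rejected and counted.
#' UMIs containing N are kept: N is a distinct symbol and such families
#' are formed normally under exact-key grouping.
#'
#' @param reads A [S4Vectors::DataFrame] with columns \code{id},
#'   \code{sequence} (raw read 1), e.g. from [readFastqReads()].
#' @param umiLength UMI length in bases (default 8).
#' @return A list with \code{reads} (columns \code{id}, \code{umi},
#'   \code{sequence}; ids suffixed \code{_UMI:<umi>}) and
#'   \code{nRejected} (reads shorter than or equal to the UMI).
#' @export
extractUmi <- function(reads, umiLength = 8L) {
    ok <- nchar(reads$sequence) > umiLength
    kept <- reads[ok, , drop = FALSE]
    umi <- substr(kept$sequence, 1L, umiLength)
    DataFrame(id = paste0(kept$id, "_UMI:", umi), umi = umi,
              sequence = substr(kept$sequence, umiLength + 1L,
                                nchar(kept$sequence))) -> out
    list(reads = out, nRejected = sum(!ok))
}

#' Group reads into UMI families and discard singletons
#'
#' Families are formed by exact match on the (target, UMI) key; no
#' edit-distance merging of UMIs is attempted (conservative, and exactly
#' testable against a dictionary oracle). Singleton families — reads
#' originating from a single observation of a UMI — are discarded, since
#' a lone read cannot be error-corrected by consensus.
#'
#' @param reads A [S4Vectors::DataFrame] with columns \code{target},
#'   \code{umi} (plus any payload columns, carried through).
#' @return A list with \code{reads} (retained reads, with an integer
#'   \code{family} column), \code{families} (one row per retained family:
#'   \code{family}, \code{target}, \code{umi}, \code{size}),
#'   \code{nDiscardedReads} and \code{nSingletonKeys}.
#' @examples
#' rd <- S4Vectors::DataFrame(
#'   target = "T1", umi = c("AAAA", "AAAA", "CCCC", "GGGG", "TTTT"),
#'   sequence = "ACGT")
#' groupFamilies(rd)$families$size  # one family of 2; 3 reads discarded
#' @export
groupFamilies <- function(reads) {
    if (nrow(reads) == 0L)
        return(list(reads = reads, families = DataFrame(
                        family = integer(), target = character(),
                        umi = character(), size = integer()),
                    nDiscardedReads = 0L, nSingletonKeys = 0L))
    key <- paste(reads$target, reads$umi, sep = "\r")
    idx <- match(key, unique(key))
    size <- tabulate(idx)
    retainedKey <- which(size >= 2L)
    keep <- idx %in% retainedKey
    kept <- reads[keep, , drop = FALSE]
    fam <- match(idx[keep], retainedKey)
    kept$family <- fam
    first <- kept[!duplicated(fam), , drop = FALSE]
    ord <- order(first$family)
    fams <- DataFrame(family = first$family[ord],
                      target = first$target[ord], umi = first$umi[ord],
                      size = size[retainedKey][first$family[ord]])
    list(reads = kept, families = fams,
         nDiscardedReads = sum(!keep),
         nSingletonKeys = sum(size == 1L))
}

#' Quorum consensus of one UMI family
#'
#' At each position the consensus base is the modal base if its fraction
#' reaches the quorum, else N. Families whose N fraction exceeds
#' \code{maxNFraction} are dropped as too damaged to represent one
#' molecule. Members of unequal length cannot be stacked positionally
#' (paired-end assembly happens upstream) and the family is rejected.
#'
#' @param sequences Character vector of the family's member sequences
#'   (length >= 2).
#' @param quorum Minimum modal-base fraction (default 0.70, so a 2-read
#'   disagreement yields N).
#' @param maxNFraction Maximum tolerated N fraction (default 0.20).
#' @return A list with \code{status} (\code{"ok"},
#'   \code{"dropped_n_fraction"}, or \code{"rejected_length"}), and for
#'   non-rejected families \code{sequence} and \code{nFraction}.
#' @examples
#' consensusFamily(c("ACGT", "ACGT", "ACTT"))$sequence  # "ACNT"
#' @export
consensusFamily <- function(sequences, quorum = 0.70, maxNFraction = 0.20) {
    if (length(sequences) < 2L)
        stop("consensus requires a family of size >= 2")
    if (length(unique(nchar(sequences))) > 1L)
        return(list(status = "rejected_length"))
    m <- seqsToMatrix(sequences)
    n <- nrow(m)
    cons <- vapply(seq_len(ncol(m)), function(j) {
        cnt <- c(sum(m[, j] == "A"), sum(m[, j] == "C"),
                 sum(m[, j] == "G"), sum(m[, j] == "T"))
        mx <- max(cnt)
        if (mx / n >= quorum) DNA_BASES[which.max(cnt)] else "N"
    }, character(1))
    nf <- mean(cons == "N")
    if (nf > maxNFraction)
        return(list(status = "dropped_n_fraction", nFraction = nf))
    list(status = "ok", sequence = paste(cons, collapse = ""), nFraction = nf)
}

#' Build consensus reads for all families of a sample
#'
#' Vectorized equivalent of applying [consensusFamily()] to every family
#' (tested for equality against it): per-family, per-position base counts
#' are accumulated by grouped row sums, the modal base is kept where its
#' fraction reaches the quorum, N elsewhere, and families breaching the
#' N-fraction ceiling are dropped. Families whose members have unequal
#' lengths (possible only when two different molecules collide on one
#' (target, UMI) key) are rejected and counted.
#'
#' @param reads Retained reads from [groupFamilies()]: a
#'   [S4Vectors::DataFrame] with columns \code{family}, \code{target},
#'   \code{umi}, \code{sequence}.
#' @inheritParams consensusFamily
#' @return A list with \code{consensus} (DataFrame: \code{family},
#'   \code{target}, \code{umi}, \code{size}, \code{sequence},
#'   \code{nFraction}), \code{nDropped} (N-fraction), \code{nRejected}
#'   (unequal length).
#' @export
buildConsensus <- function(reads, quorum = 0.70, maxNFraction = 0.20) {
    empty <- DataFrame(family = integer(), target = character(),
                       umi = character(), size = integer(),
                       sequence = character(), nFraction = numeric())
    if (nrow(reads) == 0L)
        return(list(consensus = empty, nDropped = 0L, nRejected = 0L))
    len <- nchar(reads$sequence)
    firstLen <- len[match(reads$family, reads$family)]
    mixed <- unique(reads$family[len != firstLen])
    nRejected <- length(mixed)
    ok <- !(reads$family %in% mixed)
    reads <- reads[ok, , drop = FALSE]
    len <- len[ok]
    out <- list()
    for (L in unique(len)) {
        grp <- len == L
        rg <- reads[grp, , drop = FALSE]
        m <- seqsToMatrix(rg$sequence)
        fams <- sort(unique(rg$family))
        fidx <- match(rg$family, fams)
        size <- tabulate(fidx, nbins = length(fams))
        cnt <- lapply(DNA_BASES, function(b) rowsum(+(m == b), fidx))
        mx <- pmax(cnt[[1L]], cnt[[2L]], cnt[[3L]], cnt[[4L]])
        pass <- (mx / size) >= quorum
        cm <- matrix("N", nrow = length(fams), ncol = L)
        unassigned <- pass
        for (b in seq_along(DNA_BASES)) {
            pick <- unassigned & (cnt[[b]] == mx)
            cm[pick] <- DNA_BASES[b]
            unassigned[pick] <- FALSE
        }
        nf <- rowMeans(cm == "N")
        firstRow <- rg[match(fams, rg$family), , drop = FALSE]
        out[[as.character(L)]] <- DataFrame(
            family = fams, target = firstRow$target, umi = firstRow$umi,
            size = size, sequence = matrixToSeqs(cm), nFraction = nf)
    }
    cons <- do.call(rbind, unname(out))
    cons <- cons[order(cons$family), , drop = FALSE]
    drop <- cons$nFraction > maxNFraction
    list(consensus = cons[!drop, , drop = FALSE],
         nDropped = sum(drop), nRejected = nRejected)
}
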