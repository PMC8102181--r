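#' Read a BED-like panel design
#'
#' Tab-separated design file in BED convention (0-based, half-open):
#' columns chrom/target, start, end, name. Returned as 1-based inclusive
#' [GenomicRanges::GRanges], matching pileup coordinates.
#'
#' @param path Design TSV path (no header; \code{#} comments allowed).
#' @return A [GenomicRanges::GRanges] with a \code{name} metadata column.
#' @export
readPanelDesign <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#",
                           col.names = c("chrom", "start", "end", "name"))
    GenomicRanges::GRanges(x$chrom,
                           IRanges::IRanges(x$start + 1L, x$end),
                           name = x$name)
}

#' Read tracked mutations from a VCF
#'
#' One tracked mutation per record; the gene symbol is taken from the
#' \code{GENE} INFO key, the diagnostic VAF from \code{DVAF}, and the
#' patient id from the \code{PATIENT} INFO key unless given. CHROM is
#' interpreted as the panel target name and POS as the 1-based
#' target-local position.
#'
#' @param path VCF path.
#' @param patient Patient id overriding the \code{PATIENT} INFO key.
#' @return A tracked-mutation table as from [trackedMutations()].
#' @export
readTrackedVcf <- function(path, patient = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("reading VCF requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    info <- VariantAnnotation::info(v)
    alt <- as.character(unlist(rr$ALT))
    unpack <- function(x) vapply(as.list(x), function(e)
        as.character(e)[1L], character(1))
    trackedMutations(
        patient = patient %||%
            (if ("PATIENT" %in% colnames(info)) unpack(info$PATIENT)
             else NA_character_),
        gene = unpack(info$GENE),
        target = as.character(GenomicRanges::seqnames(rr)),
        pos = GenomicRanges::start(rr),
        ref = as.character(rr$REF), alt = alt,
        diagnosticVaf = as.numeric(unpack(info$DVAF)))
}

#' Write MRD calls as TSV (and optionally VCF / JSON)
#'
#' The TSV carries a commented header recording the caller thresholds.
#' The VCF (via VariantAnnotation) writes one record per call with INFO
#' keys \code{ALTFAM}, \code{CONSDEPTH}, \code{VAF}, \code{P}, \code{Q},
#' \code{STATUS}, \code{GENE}.
#'
#' @param calls Output of [callTrackedMutations()].
#' @param tsv Output TSV path.
#' @param vcf Optional output VCF path.
#' @param json Optional output JSON path.
#' @return Invisibly, the paths written.
#' @export
writeMrdCalls <- function(calls, tsv, vcf = NULL, json = NULL) {
    th <- metadata(calls)$thresholds
    con <- file(tsv, "w")
    writeLines(c("# smMRD tracked-mutation calls",
                 sprintf("# qMax=%g minDepth=%d minFamilies=%s vafFloor=%s",
                         th$qMax, th$minDepth,
                         paste(names(th$minFamilies), th$minFamilies,
                               sep = ":", collapse = ","),
                         paste(names(th$vafFloor), th$vafFloor,
                               sep = ":", collapse = ","))), con)
    utils::write.table(as.data.frame(calls), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    if (!is.null(json))
        jsonlite::write_json(as.data.frame(calls), json, digits = NA,
                             na = "null", auto_unbox = FALSE)
    if (!is.null(vcf)) {
        if (!requireNamespace("VariantAnnotation", quietly = TRUE))
            stop("writing VCF requires the VariantAnnotation package")
        gr <- GenomicRanges::GRanges(
            calls$target,
            IRanges::IRanges(calls$pos, calls$pos + nchar(calls$ref) - 1L))
        fixedDF <- DataFrame(
            REF = Biostrings::DNAStringSet(calls$ref),
            ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
            QUAL = rep(NA_real_, nrow(calls)),
            FILTER = rep("PASS", nrow(calls)))
        info <- DataFrame(ALTFAM = calls$altFamilies,
                          CONSDEPTH = calls$consensusDepth,
                          VAF = calls$vaf, P = calls$pValue,
                          Q = calls$qValue, STATUS = calls$status,
                          GENE = calls$gene, PATIENT = calls$patient)
        ihdr <- DataFrame(
            Number = rep("1", 8L),
            Type = c("Integer", "Integer", "Float", "Float", "Float",
                     "String", "String", "String"),
            Description = c("Supporting consensus families",
                            "Consensus depth at site",
                            "Variant allele fraction",
                            "Binomial p-value vs site background",
                            "BH-adjusted p-value within tracked set",
                            "Call status", "Gene symbol", "Patient id"),
            row.names = c("ALTFAM", "CONSDEPTH", "VAF", "P", "Q",
                          "STATUS", "GENE", "PATIENT"))
        hdr <- VariantAnnotation::VCFHeader(samples = character())
        VariantAnnotation::info(hdr) <- ihdr
        v <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixedDF,
                                    info = info,
                                    exptData = list(header = hdr),
                                    collapsed = TRUE)
        VariantAnnotation::writeVcf(v, vcf)
    }
    invisible(c(tsv, vcf, json))
}

#' Write a sample MRD result as JSON
#'
#' @param result A [SampleMrdResult-class].
#' @param path Output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleResult <- function(result, path) {
    jsonlite::write_json(list(
        patient = result@patient, timePoint = result@timePoint,
        tissue = result@tissue, status = result@status,
        basis = result@basis, dtaPolicy = result@dtaPolicy,
        calls = as.data.frame(result@calls)), path,
        auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' Write a run manifest
#'
#' JSON record of package version, seed, configuration hash and files
#' produced, for reproducibility of command-line runs.
#'
#' @param path Output JSON path.
#' @param seed Integer seed used.
#' @param config Arbitrary configuration object (hashed after
#'   serialization).
#' @param outputs Character vector of files produced.
#' @return Invisibly, \code{path}.
#' @export
writeRunManifest <- function(path, seed = NA_integer_, config = NULL,
                             outputs = character()) {
    cfgHash <- if (is.null(config)) NA_character_ else
        substr(tools::md5sum(files = {
            tf <- tempfile(); saveRDS(config, tf); tf
        }), 1L, 12L)
    jsonlite::write_json(list(
        package = "smMRD",
        version = as.character(utils::packageVersion("smMRD")),
        date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed, configHash = unname(cfgHash), outputs = outputs),
        path, auto_unbox = TRUE, na = "null")
    invisible(path)
}
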