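#' @rdname SimulatedSample-class
#' @param x Object.
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname SimulatedSample-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname SimulatedSample-class
#' @export
setGeneric("simErrors", function(x) standardGeneric("simErrors"))

#' @rdname SitePileup-class
#' @export
setGeneric("pileupSites", function(x) standardGeneric("pileupSites"))

#' @rdname SitePileup-class
#' @export
setGeneric("pileupInsertions", function(x) standardGeneric("pileupInsertions"))

#' @rdname SampleMrdResult-class
#' @export
setGeneric("mrdStatus", function(x) standardGeneric("mrdStatus"))

#' @rdname SampleMrdResult-class
#' @export
setGeneric("mrdCalls", function(x) standardGeneric("mrdCalls"))

#' @rdname SampleMrdResult-class
#' @export
setGeneric("mrdBasis", function(x) standardGeneric("mrdBasis"))

#' @describeIn SimulatedSample-class Per-read table (id, target, family,
#'   umi, sequence).
#' @export
setMethod("reads", "SimulatedSample", function(x) x@reads)

#' @describeIn SimulatedSample-class Per-family ground truth.
#' @export
setMethod("truthTable", "SimulatedSample", function(x) x@truth)

#' @describeIn SimulatedSample-class Injected per-read errors.
#' @export
setMethod("simErrors", "SimulatedSample", function(x) x@errors)

#' @describeIn SitePileup-class Per-site base/N/del counts and depth.
#' @export
setMethod("pileupSites", "SitePileup", function(x) x@sites)

#' @describeIn SitePileup-class Insertion counts keyed by sequence.
#' @export
setMethod("pileupInsertions", "SitePileup", function(x) x@insertions)

#' @describeIn SampleMrdResult-class Sample-level status string.
#' @export
setMethod("mrdStatus", "SampleMrdResult", function(x) x@status)

#' @describeIn SampleMrdResult-class Per-mutation call table.
#' @export
setMethod("mrdCalls", "SampleMrdResult", function(x) x@calls)

#' @describeIn SampleMrdResult-class Mutation ids that drove positivity.
#' @export
setMethod("mrdBasis", "SampleMrdResult", function(x) x@basis)

setMethod("show", "MipsSimConfig", function(object) {
    cat("MipsSimConfig:", length(object@targets), "target(s),",
        object@nFamilies, "families/target, family-size mean",
        sprintf("%.3f", object@familySizeMean), "\n")
    cat("  UMI length:", object@umiLength, " spike-ins:",
        nrow(object@spikeIns), " seed:", object@seed, "\n")
})

setMethod("show", "SimulatedSample", function(object) {
    cat("SimulatedSample:", nrow(object@reads), "reads in",
        nrow(object@truth), "UMI families over",
        length(object@config@targets), "target(s)\n")
    cat("  injected errors:", nrow(object@errors),
        " seed:", object@config@seed, "\n")
})

setMethod("show", "SitePileup", function(object) {
    cat("SitePileup:", nrow(object@sites), "sites over",
        length(unique(object@sites$target)), "target(s); median depth",
        stats::median(object@sites$depth), "\n")
    cat("  insertion alleles:", nrow(object@insertions),
        " excluded reads:", object@nExcluded, "\n")
})

setMethod("show", "ErrorModel", function(object) {
    cat("ErrorModel:", nrow(object@substitutions),
        "substitution channels,", nrow(object@indels),
        "observed indel channels;", object@nControls,
        "control(s), pseudocount", object@pseudocount, "\n")
    r <- object@substitutions$rate
    if (length(r))
        cat(sprintf("  substitution rate: median %.2e, max %.2e\n",
                    stats::median(r, na.rm = TRUE), max(r, na.rm = TRUE)))
})

setMethod("show", "SampleMrdResult", function(object) {
    cat(sprintf("SampleMrdResult: patient %s, %s (%s): %s\n",
                object@patient, object@timePoint, object@tissue,
                object@status))
    if (length(object@basis))
        cat("  basis:", paste(object@basis, collapse = ", "), "\n")
    tab <- table(object@calls$status)
    if (length(tab))
        cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "),
            "\n")
})
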