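#' Accessors for plastidSV classes
#'
#' Small accessor generics: `genomeSeq` / `genomeId` / `seqLength` for
#' [CircularGenome-class]; region accessors (`lscRange`, `ir1Range`,
#' `sscRange`, `ir2Range`), `irLength`, `irMismatches` and
#' `canonicalOffset` for [QuadripartiteStructure-class]; `hapF` / `hapR` for
#' [HaplotypePair-class]; `hspScore` and `hspRanges` for [HSP-class];
#' `alignmentIdentity` and `alignedReadFraction` for [ReadAlignment-class].
#'
#' @param x an object of the matching class.
#' @return the slot value (ranges as [IRanges::IRanges], lengths as integer,
#'   fractions as numeric).
#' @examples
#' st <- quadripartiteStructure(10, 10, 10)
#' lscRange(st); irLength(st)
#' @name plastidSV-accessors
NULL

#' @rdname plastidSV-accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname plastidSV-accessors
#' @export
setMethod("genomeSeq", "CircularGenome", function(x) x@seq)

#' @rdname plastidSV-accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname plastidSV-accessors
#' @export
setMethod("genomeId", "CircularGenome", function(x) x@id)

#' @rdname plastidSV-accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))
#' @rdname plastidSV-accessors
#' @export
setMethod("seqLength", "CircularGenome", function(x) length(x@seq))

#' @rdname plastidSV-accessors
#' @export
setGeneric("lscRange", function(x) standardGeneric("lscRange"))
#' @rdname plastidSV-accessors
#' @export
setMethod("lscRange", "QuadripartiteStructure", function(x) x@regions["lsc"])

#' @rdname plastidSV-accessors
#' @export
setGeneric("ir1Range", function(x) standardGeneric("ir1Range"))
#' @rdname plastidSV-accessors
#' @export
setMethod("ir1Range", "QuadripartiteStructure", function(x) x@regions["ir1"])

#' @rdname plastidSV-accessors
#' @export
setGeneric("sscRange", function(x) standardGeneric("sscRange"))
#' @rdname plastidSV-accessors
#' @export
setMethod("sscRange", "QuadripartiteStructure", function(x) x@regions["ssc"])

#' @rdname plastidSV-accessors
#' @export
setGeneric("ir2Range", function(x) standardGeneric("ir2Range"))
#' @rdname plastidSV-accessors
#' @export
setMethod("ir2Range", "QuadripartiteStructure", function(x) x@regions["ir2"])

#' @rdname plastidSV-accessors
#' @export
setGeneric("irLength", function(x) standardGeneric("irLength"))
#' @rdname plastidSV-accessors
#' @export
setMethod("irLength", "QuadripartiteStructure", function(x) x@irLen)

#' @rdname plastidSV-accessors
#' @export
setGeneric("irMismatches", function(x) standardGeneric("irMismatches"))
#' @rdname plastidSV-accessors
#' @export
setMethod("irMismatches", "QuadripartiteStructure", function(x) x@irMismatches)

#' @rdname plastidSV-accessors
#' @export
setGeneric("canonicalOffset", function(x) standardGeneric("canonicalOffset"))
#' @rdname plastidSV-accessors
#' @export
setMethod("canonicalOffset", "QuadripartiteStructure", function(x) x@offset)

#' @rdname plastidSV-accessors
#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))
#' @rdname plastidSV-accessors
#' @export
setMethod("regionWidths", "QuadripartiteStructure", function(x) {
    w <- width(x@regions); names(w) <- names(x@regions); w
})

#' @rdname plastidSV-accessors
#' @export
setGeneric("hapF", function(x) standardGeneric("hapF"))
#' @rdname plastidSV-accessors
#' @export
setMethod("hapF", "HaplotypePair", function(x) x@seqF)

#' @rdname plastidSV-accessors
#' @export
setGeneric("hapR", function(x) standardGeneric("hapR"))
#' @rdname plastidSV-accessors
#' @export
setMethod("hapR", "HaplotypePair", function(x) x@seqR)

#' @rdname plastidSV-accessors
#' @export
setGeneric("hapStructure", function(x) standardGeneric("hapStructure"))
#' @rdname plastidSV-accessors
#' @export
setMethod("hapStructure", "HaplotypePair", function(x) x@structure)

#' @rdname plastidSV-accessors
#' @export
setGeneric("hspScore", function(x) standardGeneric("hspScore"))
#' @rdname plastidSV-accessors
#' @export
setMethod("hspScore", "HSP", function(x) x@score)

#' @rdname plastidSV-accessors
#' @export
setGeneric("hspRanges", function(x) standardGeneric("hspRanges"))
#' @rdname plastidSV-accessors
#' @export
setMethod("hspRanges", "HSP",
    function(x) list(a = x@rangeA, b = x@rangeB))

#' @rdname plastidSV-accessors
#' @export
setGeneric("alignmentIdentity", function(x) standardGeneric("alignmentIdentity"))
#' @rdname plastidSV-accessors
#' @export
setMethod("alignmentIdentity", "ReadAlignment", function(x) {
    if (x@ncols == 0) return(NA_real_)
    x@nmatch / x@ncols
})

#' @rdname plastidSV-accessors
#' @export
setGeneric("alignedReadFraction",
           function(x) standardGeneric("alignedReadFraction"))
#' @rdname plastidSV-accessors
#' @export
setMethod("alignedReadFraction", "ReadAlignment", function(x) {
    if (x@readLength == 0L) return(0)
    sum(width(x@blocksRead)) / x@readLength
})

setMethod("show", "CircularGenome", function(object) {
    cat(sprintf("CircularGenome '%s': %d bp, %s\n", object@id,
                length(object@seq),
                if (object@circular) "circular" else "linear"))
})

setMethod("show", "QuadripartiteStructure", function(object) {
    w <- width(object@regions)
    cat(sprintf(
        "QuadripartiteStructure: %d bp | LSC %d, IR1 %d, SSC %d, IR2 %d\n",
        object@genomeLength, w[1L], w[2L], w[3L], w[4L]))
    cat(sprintf("  IR mismatches: %d; rotation offset to canonical: %d\n",
                object@irMismatches, object@offset))
    for (i in seq_len(4L))
        cat(sprintf("  %-4s %8d..%8d (%d bp)\n",
                    toupper(names(object@regions))[i],
                    start(object@regions)[i], end(object@regions)[i], w[i]))
})

setMethod("show", "HaplotypePair", function(object) {
    cat(sprintf("HaplotypePair of '%s' (%d bp): SSC-F and SSC-R haplotypes\n",
                object@seqF@id, length(object@seqF@seq)))
})

setMethod("show", "HSP", function(object) {
    if (width(object@rangeA) == 0L)
        cat("HSP: empty (score 0)\n")
    else
        cat(sprintf("HSP: a[%d..%d] ~ b[%d..%d], score %g\n",
                    start(object@rangeA), end(object@rangeA),
                    start(object@rangeB), end(object@rangeB), object@score))
})

setMethod("show", "ReadAlignment", function(object) {
    cat(sprintf(
        "ReadAlignment %s -> %s (%s): %d block(s), %.1f%% of read, id %.4f\n",
        object@readId, object@refId, object@strand,
        length(object@blocksRead), 100 * alignedReadFraction(object),
        alignmentIdentity(object)))
})

setMethod("show", "OrientationReport", function(object) {
    cat("OrientationReport (SSC orientation among junction reads)\n")
    cat(sprintf("  forward (SSC-F): %d   reverse (SSC-R): %d\n",
                object@nForward, object@nReverse))
    cat(sprintf("  ambiguous: %d   non-junction: %d\n",
                object@nAmbiguous, object@nNonJunction))
    if (is.na(object@ratio)) {
        cat("  proportions/ratio undefined (no classified reads)\n")
    } else {
        cat(sprintf("  prop F/R: %.4f / %.4f; SSC/ssc ratio %.4f (printed-style %.2f)\n",
                    object@propForward, object@propReverse, object@ratio,
                    object@ratioPrinted))
        cat(sprintf("  %s %.0f%% CI for prop F: [%.4f, %.4f]\n",
                    object@ciMethod, 100 * object@ciLevel,
                    object@ciLow, object@ciHigh))
    }
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: LSC %d, IR %d, SSC %d bp; pReverse %.2f, pIrDup %.2f\n",
        object@lscLen, object@irLen, object@sscLen, object@pReverse,
        object@pIrDup))
    cat(sprintf(
        "  %d molecules, %d reads (lognormal median %g, sigma %g, min %d)\n",
        object@nMolecules, object@nReads, object@readLenMedian,
        object@readLenSigma, object@minReadLen))
    cat(sprintf("  errors sub/ins/del: %g/%g/%g; motifs: %s; planted STRs: %d\n",
                object@errSub, object@errIns, object@errDel,
                object@embedMotifs, nrow(object@plantedStrs)))
})

setMethod("show", "SVSpec", function(object) {
    cat(sprintf("SVSpec: d1 %d bp, prefix '%s', i1 %d bp + full IR copy\n",
                object@d1Len, object@insertPrefix, object@i1Len))
})
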