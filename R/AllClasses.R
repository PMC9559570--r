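#' @import methods
#' @import Biostrings
#' @import IRanges
#' @import S4Vectors
#' @importFrom stats qnorm rbinom rlnorm runif setNames
#' @importFrom utils write.table read.table
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' CircularGenome: a circular nucleotide sequence
#'
#' Container for an assembled plastome (or any circular replicon): an
#' uppercase nucleotide sequence over A, C, G, T, N together with a label and
#' a topology flag. All plastidSV operations treat the sequence as circular
#' unless stated otherwise.
#'
#' @slot id single character label.
#' @slot seq a [Biostrings::DNAString] restricted to A/C/G/T/N.
#' @slot circular logical topology flag.
#'
#' @seealso [circularGenome()], [findInvertedRepeats()]
#' @name CircularGenome-class
#' @aliases CircularGenome
#' @exportClass CircularGenome
setClass("CircularGenome",
    representation(id = "character", seq = "DNAString", circular = "logical"))

setValidity("CircularGenome", function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id))
        msg <- c(msg, "'id' must be a single non-NA string")
    if (length(object@seq) == 0L)
        msg <- c(msg, "'seq' must be non-empty")
    bad <- setdiff(uniqueLetters(object@seq), c("A", "C", "G", "T", "N"))
    if (length(bad))
        msg <- c(msg, paste0("alphabet restricted to A/C/G/T/N; found: ",
                             paste(bad, collapse = ",")))
    if (length(object@circular) != 1L || is.na(object@circular))
        msg <- c(msg, "'circular' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct a CircularGenome
#'
#' @param seq a [Biostrings::DNAString], a character string, or anything
#'   coercible to `DNAString`. Lowercase input is uppercased.
#' @param id label for the genome (default `"genome"`).
#' @param circular logical topology flag (default `TRUE`).
#' @return a [CircularGenome-class] object.
#' @examples
#' g <- circularGenome("ACGTACGTAC", id = "toy")
#' seqLength(g)
#' @export
circularGenome <- function(seq, id = "genome", circular = TRUE) {
    if (is.character(seq)) seq <- DNAString(toupper(seq))
    if (!is(seq, "DNAString")) seq <- as(seq, "DNAString")
    new("CircularGenome", id = as.character(id), seq = seq,
        circular = circular)
}

#' QuadripartiteStructure: the LSC/IR1/SSC/IR2 partition of a plastome
#'
#' Describes the canonical quadripartite partition of a circular plastome:
#' contiguous regions LSC, IR1, SSC, IR2 (in that order, covering the genome
#' exactly) on the canonical linearization in which LSC begins at position 1.
#' `offset` records the rotation (0-based, number of leading bases moved to
#' the end) that carries the linearization the structure was detected on into
#' the canonical one.
#'
#' Coordinates are 1-based closed [IRanges::IRanges], the Bioconductor
#' convention; all reports are therefore 1-based.
#'
#' @slot regions an `IRanges` of length 4 named lsc, ir1, ssc, ir2.
#' @slot irLen integer, common length of the two inverted repeats.
#' @slot irMismatches integer, Hamming distance between IR1 and the reverse
#'   complement of IR2.
#' @slot offset integer rotation from the source linearization to canonical.
#' @slot genomeLength integer.
#'
#' @seealso [findInvertedRepeats()], [canonicalizeGenome()]
#' @name QuadripartiteStructure-class
#' @aliases QuadripartiteStructure
#' @exportClass QuadripartiteStructure
setClass("QuadripartiteStructure",
    representation(regions = "IRanges", irLen = "integer",
                   irMismatches = "integer", offset = "integer",
                   genomeLength = "integer"))

setValidity("QuadripartiteStructure", function(object) {
    msg <- character()
    r <- object@regions
    if (length(r) != 4L || !identical(names(r), c("lsc", "ir1", "ssc", "ir2")))
        msg <- c(msg, "'regions' must be 4 ranges named lsc, ir1, ssc, ir2")
    else {
        if (start(r)[1L] != 1L)
            msg <- c(msg, "LSC must start at position 1 (canonical rotation)")
        if (any(start(r)[-1L] != end(r)[-4L] + 1L))
            msg <- c(msg, "regions must be contiguous in order LSC,IR1,SSC,IR2")
        if (end(r)[4L] != object@genomeLength)
            msg <- c(msg, "regions must cover the genome exactly")
        w <- width(r); names(w) <- names(r)
        if (w["ir1"] != object@irLen || w["ir2"] != object@irLen)
            msg <- c(msg, "|IR1| and |IR2| must both equal irLen")
        if (w["lsc"] < w["ssc"])
            msg <- c(msg, "|LSC| must be >= |SSC|")
    }
    if (object@irMismatches < 0L)
        msg <- c(msg, "irMismatches must be >= 0")
    if (object@offset < 0L || object@offset >= object@genomeLength)
        msg <- c(msg, "offset must be in [0, genomeLength)")
    if (length(msg)) msg else TRUE
})

#' Construct a QuadripartiteStructure from region widths
#'
#' @param lscLen,irLen,sscLen widths in bp of LSC, each IR, and SSC.
#' @param irMismatches Hamming distance between IR1 and revcomp(IR2).
#' @param offset rotation (0-based) from the source linearization to the
#'   canonical one.
#' @return a [QuadripartiteStructure-class].
#' @examples
#' quadripartiteStructure(10, 10, 10)
#' @export
quadripartiteStructure <- function(lscLen, irLen, sscLen,
                                   irMismatches = 0L, offset = 0L) {
    lscLen <- as.integer(lscLen); irLen <- as.integer(irLen)
    sscLen <- as.integer(sscLen)
    w <- c(lsc = lscLen, ir1 = irLen, ssc = sscLen, ir2 = irLen)
    s <- cumsum(c(1L, w[-4L])); names(s) <- names(w)
    new("QuadripartiteStructure",
        regions = IRanges(start = unname(s), width = unname(w), names = names(w)),
        irLen = irLen, irMismatches = as.integer(irMismatches),
        offset = as.integer(offset), genomeLength = sum(w))
}

#' HaplotypePair: the two SSC orientation haplotypes of one plastome
#'
#' The SSC-forward (`seqF`, organization LSC-IR1-SSC-IR2) and SSC-reverse
#' (`seqR`, LSC-IR1-ssc-IR2) versions of one plastome, identical outside the
#' SSC interval, with their shared quadripartite structure.
#'
#' @slot seqF,seqR [CircularGenome-class] objects of equal length.
#' @slot structure the shared [QuadripartiteStructure-class].
#' @seealso [buildHaplotypePair()], [flipSsc()]
#' @name HaplotypePair-class
#' @aliases HaplotypePair
#' @exportClass HaplotypePair
setClass("HaplotypePair",
    representation(seqF = "CircularGenome", seqR = "CircularGenome",
                   structure = "QuadripartiteStructure"))

setValidity("HaplotypePair", function(object) {
    msg <- character()
    f <- object@seqF@seq; r <- object@seqR@seq
    if (length(f) != length(r))
        msg <- c(msg, "seqF and seqR must have equal length")
    st <- object@structure
    if (length(f) != st@genomeLength)
        msg <- c(msg, "sequence length must match structure genomeLength")
    else {
        ssc <- st@regions["ssc"]
        out <- setdiff(IRanges(1L, st@genomeLength), ssc)
        if (!all(extractAt(f, out) == extractAt(r, out)))
            msg <- c(msg, "seqF and seqR must agree outside the SSC interval")
        if (as.character(subseq(r, start(ssc), end(ssc))) !=
            as.character(reverseComplement(subseq(f, start(ssc), end(ssc)))))
            msg <- c(msg, "SSC of seqR must be revcomp of SSC of seqF")
    }
    if (length(msg)) msg else TRUE
})

#' SVSpec: parameters of the inverted-repeat duplication rearrangement
#'
#' Describes the IR-gain structural variant produced by asymmetric
#' recombination: a deletion of `d1Len` bases from the 3' end of IR1 together
#' with an insertion, at the same point, of a de novo prefix, the first
#' `i1Len` bases of LSC, and a full extra copy of IR1 (junction organization
#' IR1d - prefix - i1 - IR1). The insert length is
#' `nchar(insertPrefix) + i1Len + irLen`.
#'
#' @slot d1Len integer, bases deleted from the 3' end of IR1.
#' @slot i1Len integer, length of the LSC segment reused in the insert.
#' @slot insertPrefix character, de novo bases synthesized at the junction.
#' @seealso [applyIRDuplication()], [insertLength()]
#' @name SVSpec-class
#' @aliases SVSpec
#' @exportClass SVSpec
setClass("SVSpec",
    representation(d1Len = "integer", i1Len = "integer",
                   insertPrefix = "character"))

setValidity("SVSpec", function(object) {
    msg <- character()
    if (object@d1Len < 0L) msg <- c(msg, "d1Len must be >= 0")
    if (object@i1Len < 0L) msg <- c(msg, "i1Len must be >= 0")
    if (length(object@insertPrefix) != 1L ||
        grepl("[^ACGTN]", object@insertPrefix))
        msg <- c(msg, "insertPrefix must be a single A/C/G/T/N string (may be empty)")
    if (length(msg)) msg else TRUE
})

#' Construct an SVSpec
#'
#' Defaults are the values observed in Dongxiang wild rice: a 319-bp deletion
#' from the 3' end of IR1 and an insert of "ATTTT" plus a 2,000-bp LSC
#' segment plus a whole IR1.
#'
#' @param d1Len bases deleted from the 3' end of IR1.
#' @param i1Len length of the LSC segment reused in the insert.
#' @param insertPrefix de novo bases synthesized at the junction.
#' @return an [SVSpec-class].
#' @examples
#' sv <- svSpec()
#' insertLength(sv, irLen = 20805)   # 22810
#' @export
svSpec <- function(d1Len = 319L, i1Len = 2000L, insertPrefix = "ATTTT") {
    new("SVSpec", d1Len = as.integer(d1Len), i1Len = as.integer(i1Len),
        insertPrefix = toupper(as.character(insertPrefix)))
}

#' HSP: a high-score segment pair
#'
#' The best-scoring local alignment between two sequences, as used to look
#' for candidate recombination sites. An empty HSP (no segment pair scores
#' above zero) has zero-width ranges and score 0.
#'
#' @slot rangeA,rangeB [IRanges::IRanges] of length 1 (possibly zero-width)
#'   giving the matched segments in the two inputs.
#' @slot score alignment score of the reported pair.
#' @slot scoring named numeric: match, mismatch, gapOpen, gapExt.
#' @seealso [findHsp()]
#' @name HSP-class
#' @aliases HSP
#' @exportClass HSP
setClass("HSP",
    representation(rangeA = "IRanges", rangeB = "IRanges",
                   score = "numeric", scoring = "numeric"))

setValidity("HSP", function(object) {
    msg <- character()
    if (object@score < 0) msg <- c(msg, "score must be >= 0")
    if (length(object@rangeA) != 1L || length(object@rangeB) != 1L)
        msg <- c(msg, "rangeA and rangeB must each have length 1")
    if (length(msg)) msg else TRUE
})

#' ReadAlignment: block-structured alignment of one read to one reference
#'
#' The alignment of a read against one reference haplotype as a list of
#' paired gap-free blocks (read interval vs reference interval). Reference
#' coordinates may run up to twice the reference length because circular
#' references are internally doubled; use them modulo the reference length.
#'
#' @slot readId,refId character labels.
#' @slot strand `"+"` or `"-"` (strand of the read that aligned).
#' @slot blocksRead,blocksRef parallel [IRanges::IRanges]; block i of the
#'   read aligns gap-free to block i of the reference.
#' @slot nmatch,ncols numbers of matching columns and of aligned columns
#'   (matches + mismatches + gap columns in filled gaps).
#' @slot readLength full read length including unaligned/clipped bases.
#' @seealso [mapRead()], [alignedReadFraction()], [alignmentIdentity()]
#' @name ReadAlignment-class
#' @aliases ReadAlignment
#' @exportClass ReadAlignment
setClass("ReadAlignment",
    representation(readId = "character", refId = "character",
                   strand = "character", blocksRead = "IRanges",
                   blocksRef = "IRanges", nmatch = "numeric",
                   ncols = "numeric", readLength = "integer"))

setValidity("ReadAlignment", function(object) {
    msg <- character()
    if (length(object@blocksRead) != length(object@blocksRef))
        msg <- c(msg, "blocksRead and blocksRef must be parallel")
    if (length(object@blocksRead) > 1L) {
        s <- start(object@blocksRead)
        if (is.unsorted(s, strictly = TRUE))
            msg <- c(msg, "blocks must be monotone on the read")
    }
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' OrientationReport: summary of SSC orientation among junction reads
#'
#' Counts of junction reads by SSC orientation label, the SSC-F/SSC-R
#' proportions among classified reads, the SSC/ssc ratio (both at full
#' precision and in the printed style, i.e. computed from proportions rounded
#' to two decimals), and a Wilson score interval for the forward proportion.
#'
#' @slot nForward,nReverse,nAmbiguous,nNonJunction integer counts.
#' @slot propForward,propReverse fractions of classified (F+R) reads.
#' @slot ratio unrounded `propForward / propReverse`.
#' @slot ratioPrinted ratio of the two-decimal proportions, itself rounded
#'   to two decimals (the convention used when quoting e.g. 0.82 = 0.45/0.55).
#' @slot ciLow,ciHigh Wilson interval bounds for `propForward`.
#' @slot ciLevel confidence level; @slot ciMethod interval method name.
#' @seealso [summarizeOrientation()]
#' @name OrientationReport-class
#' @aliases OrientationReport
#' @exportClass OrientationReport
setClass("OrientationReport",
    representation(nForward = "integer", nReverse = "integer",
                   nAmbiguous = "integer", nNonJunction = "integer",
                   propForward = "numeric", propReverse = "numeric",
                   ratio = "numeric", ratioPrinted = "numeric",
                   ciLow = "numeric", ciHigh = "numeric",
                   ciLevel = "numeric", ciMethod = "character"))

#' SimConfig: parameters of the synthetic plastome/read generator
#'
#' Region lengths default to a ~1/10 scaling of the Dongxiang wild rice
#' plastome (80,553 / 20,805 / 12,346 bp); the orientation mixture defaults
#' to the observed 45:55 SSC-F:SSC-R proportion. Read lengths are lognormal
#' (median, sigma on the log scale); errors are positionally uniform
#' substitution/insertion/deletion rates.
#'
#' @slot lscLen,irLen,sscLen region widths in bp.
#' @slot pReverse probability a molecule is SSC-reverse.
#' @slot pIrDup probability a molecule carries the IR-duplication variant.
#' @slot nMolecules,nReads pool and read counts.
#' @slot readLenMedian,readLenSigma lognormal read-length parameters.
#' @slot errSub,errIns,errDel per-base error rates in [0, 0.2].
#' @slot embedMotifs plant the rice junction signatures at the IR1-SSC and
#'   SSC-IR2 boundaries.
#' @slot plantedStrs data.frame(position, unit, refCopies, choices) of STR
#'   loci written into the reference; `choices` is a comma-separated set of
#'   copy numbers molecules draw from uniformly.
#' @slot sv the scaled [SVSpec-class] used for IR-duplication molecules.
#' @slot minReadLen reads shorter than this are discarded (0 = keep all;
#'   the full-scale preset uses 20,000 bp).
#' @seealso [simConfig()], [simulateGenome()], [simulateReads()]
#' @name SimConfig-class
#' @aliases SimConfig
#' @exportClass SimConfig
setClass("SimConfig",
    representation(lscLen = "integer", irLen = "integer", sscLen = "integer",
                   pReverse = "numeric", pIrDup = "numeric",
                   nMolecules = "integer", nReads = "integer",
                   readLenMedian = "numeric", readLenSigma = "numeric",
                   errSub = "numeric", errIns = "numeric", errDel = "numeric",
                   embedMotifs = "logical", plantedStrs = "data.frame",
                   sv = "SVSpec", minReadLen = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@lscLen <= object@sscLen)
        msg <- c(msg, "lscLen must exceed sscLen")
    if (min(object@lscLen, object@irLen, object@sscLen) < 30L)
        msg <- c(msg, "region lengths must be >= 30 bp")
    for (p in c("pReverse", "pIrDup"))
        if (slot(object, p) < 0 || slot(object, p) > 1)
            msg <- c(msg, paste0(p, " must lie in [0, 1]"))
    for (p in c("errSub", "errIns", "errDel"))
        if (slot(object, p) < 0 || slot(object, p) > 0.2)
            msg <- c(msg, paste0(p, " must lie in [0, 0.2]"))
    ps <- object@plantedStrs
    if (nrow(ps)) {
        need <- c("position", "unit", "refCopies", "choices")
        if (!all(need %in% names(ps)))
            msg <- c(msg, paste0("plantedStrs needs columns: ",
                                 paste(need, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param lscLen,irLen,sscLen region widths in bp.
#' @param pReverse probability a molecule is SSC-reverse (default 0.55, the
#'   observed SSC-R proportion).
#' @param pIrDup probability a molecule carries the IR-duplication variant.
#' @param nMolecules,nReads pool and read counts.
#' @param readLenMedian,readLenSigma lognormal read-length parameters.
#' @param errSub,errIns,errDel per-base error rates.
#' @param embedMotifs plant the rice junction signatures (default TRUE).
#' @param plantedStrs data.frame(position, unit, refCopies, choices); see
#'   [SimConfig-class].
#' @param sv [SVSpec-class] for IR-duplication molecules (default the rice
#'   values scaled ~1/10: d1 = 32, i1 = 200, prefix "ATTTT").
#' @param minReadLen discard reads shorter than this.
#' @param preset `"scaled"` (default) or `"paper"`; `"paper"` sets the
#'   full-scale region lengths 80,553/20,805/12,346, the unscaled SVSpec,
#'   the 20,000-bp read-length screen and a 25-kb read-length median.
#' @return a [SimConfig-class].
#' @examples
#' simConfig()
#' simConfig(preset = "paper")
#' @export
simConfig <- function(lscLen = 8000, irLen = 2000, sscLen = 1200,
                      pReverse = 0.55, pIrDup = 0,
                      nMolecules = 200, nReads = 2000,
                      readLenMedian = 4000, readLenSigma = 0.35,
                      errSub = 0, errIns = 0, errDel = 0,
                      embedMotifs = TRUE,
                      plantedStrs = data.frame(),
                      sv = svSpec(d1Len = 32, i1Len = 200,
                                  insertPrefix = "ATTTT"),
                      minReadLen = 0,
                      preset = c("scaled", "paper")) {
    preset <- match.arg(preset)
    if (preset == "paper") {
        if (missing(lscLen)) lscLen <- 80553
        if (missing(irLen)) irLen <- 20805
        if (missing(sscLen)) sscLen <- 12346
        if (missing(sv)) sv <- svSpec()
        if (missing(minReadLen)) minReadLen <- 20000
        if (missing(readLenMedian)) readLenMedian <- 25000
    }
    new("SimConfig", lscLen = as.integer(lscLen), irLen = as.integer(irLen),
        sscLen = as.integer(sscLen), pReverse = pReverse, pIrDup = pIrDup,
        nMolecules = as.integer(nMolecules), nReads = as.integer(nReads),
        readLenMedian = readLenMedian, readLenSigma = readLenSigma,
        errSub = errSub, errIns = errIns, errDel = errDel,
        embedMotifs = embedMotifs, plantedStrs = plantedStrs, sv = sv,
        minReadLen = as.integer(minReadLen))
}
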