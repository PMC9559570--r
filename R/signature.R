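#' Screen an assembly by its IR1-SSC junction signature
#'
#' Classifies an assembled plastome as SSC-F or SSC-R by which of the two
#' conserved 24-nt junction signatures it carries. When the quadripartite
#' structure is available (supplied, or detectable from the assembly), the
#' assembly is first canonicalized (LSC first on the presented strand) and
#' only the canonical plus strand is scanned: because IR2 is the reverse
#' complement of IR1, a coherent F-type genome always carries the R motif on
#' its minus strand at the SSC-IR2 junction (and vice versa), so a
#' position-blind both-strand scan cannot be conclusive for a complete
#' genome. For fragments without a detectable structure, both strands are
#' scanned circularly and the conservative rule applies: one matching motif
#' type gives the verdict, both or neither give `unknown`.
#'
#' @param assembly a [CircularGenome-class] (or character sequence).
#' @param structure optional [QuadripartiteStructure-class] for the
#'   assembly; when `NULL` detection is attempted with
#'   [findInvertedRepeats()] (`minIrLen`, rate 0.001).
#' @param motifF,motifR equal-length signature strings (defaults: the rice
#'   signatures of [riceJunctionMotifs()]).
#' @param maxMismatch mismatches allowed in a motif match (default 0).
#' @param minIrLen minimum IR length for internal structure detection.
#' @return a one-row `data.frame`: junctionType (`"F"`, `"R"` or
#'   `"unknown"`), motif (matched string or `NA`), position (1-based start
#'   on the canonical plus strand, `NA` if none), strand, mismatches.
#' @examples
#' screenJunctionSignature(circularGenome(paste0(
#'     strrep("A", 10), "TGGAAAAAATCGGCAAATAGGAAA", strrep("C", 10))))
#' @export
screenJunctionSignature <- function(assembly, structure = NULL,
                                    motifF = riceJunctionMotifs()[["F"]],
                                    motifR = riceJunctionMotifs()[["R"]],
                                    maxMismatch = 0L, minIrLen = 1000L) {
    if (!is(assembly, "CircularGenome")) assembly <- circularGenome(assembly)
    if (nchar(motifF) != nchar(motifR))
        stop("motifF and motifR must have equal length")
    if (is.null(structure))
        structure <- tryCatch(
            findInvertedRepeats(assembly, minLen = minIrLen),
            noIRError = function(e) NULL,
            palindromeError = function(e) NULL,
            error = function(e) NULL)
    if (!is.null(structure)) {
        can <- canonicalizeGenome(assembly, structure)
        s <- .seqChr(can$genome)
        hitF <- .circMotifHits(s, motifF, maxMismatch)
        hitR <- .circMotifHits(s, motifR, maxMismatch)
        if (length(hitF$pos) && !length(hitR$pos))
            return(.sigVerdict("F", motifF, hitF$pos[1L], "+",
                               hitF$mism[1L]))
        if (length(hitR$pos) && !length(hitF$pos))
            return(.sigVerdict("R", motifR, hitR$pos[1L], "+",
                               hitR$mism[1L]))
        return(.sigVerdict("unknown", NA_character_, NA_integer_,
                           NA_character_, NA_integer_))
    }
    ## fallback: no quadripartite structure; scan both strands
    s <- .seqChr(assembly)
    rc <- .revcompChr(s)
    fPlus <- .circMotifHits(s, motifF, maxMismatch)
    fMinus <- .circMotifHits(rc, motifF, maxMismatch)
    rPlus <- .circMotifHits(s, motifR, maxMismatch)
    rMinus <- .circMotifHits(rc, motifR, maxMismatch)
    hasF <- length(fPlus$pos) || length(fMinus$pos)
    hasR <- length(rPlus$pos) || length(rMinus$pos)
    if (hasF && !hasR) {
        if (length(fPlus$pos))
            return(.sigVerdict("F", motifF, fPlus$pos[1L], "+",
                               fPlus$mism[1L]))
        return(.sigVerdict("F", motifF, fMinus$pos[1L], "-",
                           fMinus$mism[1L]))
    }
    if (hasR && !hasF) {
        if (length(rPlus$pos))
            return(.sigVerdict("R", motifR, rPlus$pos[1L], "+",
                               rPlus$mism[1L]))
        return(.sigVerdict("R", motifR, rMinus$pos[1L], "-",
                           rMinus$mism[1L]))
    }
    .sigVerdict("unknown", NA_character_, NA_integer_, NA_character_,
                NA_integer_)
}

# circular motif scan of the plus strand of `s`; returns 1-based starts
.circMotifHits <- function(s, motif, maxMismatch) {
    n <- nchar(s); m <- nchar(motif)
    subj <- if (n >= m) paste0(s, substr(s, 1L, m - 1L)) else s
    hits <- matchPattern(DNAString(motif), DNAString(subj),
                         max.mismatch = maxMismatch)
    pos <- start(hits)
    pos <- pos[pos <= n]
    if (!length(pos)) return(list(pos = integer(0), mism = integer(0)))
    mm <- vapply(seq_along(pos), function(i) {
        sum(utf8ToInt(substr(subj, pos[i], pos[i] + m - 1L)) !=
            utf8ToInt(motif))
    }, integer(1))
    list(pos = pos, mism = mm)
}

.sigVerdict <- function(type, motif, position, strand, mismatches) {
    data.frame(junctionType = type, motif = motif, position = position,
               strand = strand, mismatches = mismatches,
               stringsAsFactors = FALSE)
}

#' Flag a chimeric assembly by junction/body disagreement
#'
#' An assembly is chimeric when its IR1-SSC junction signature and the
#' orientation of its SSC body derive from different haplotypes (the pattern
#' reported for some database rice plastomes assembled from mixed
#' orientation data). The junction type comes from
#' [screenJunctionSignature()]; the body orientation is the strand of the
#' higher-scoring local alignment ([findHsp()]) of the assembly's SSC region
#' against a reference SSC of known forward orientation, required to win by
#' at least `minMargin` of the winning score.
#'
#' @param assembly a [CircularGenome-class].
#' @param structure its [QuadripartiteStructure-class] (canonical).
#' @param refSsc reference SSC sequence (character or `DNAString`) in known
#'   forward orientation.
#' @param minMargin minimum relative score margin between the two strands
#'   (default 0.1); below it the body orientation is `unknown` and the
#'   assembly is not called chimeric.
#' @param ... passed to [screenJunctionSignature()].
#' @return a one-row `data.frame`: junctionType, bodyOrientation,
#'   isChimeric, bodyScoreMargin, scoreF, scoreR.
#' @export
callChimera <- function(assembly, structure, refSsc, minMargin = 0.1, ...) {
    stopifnot(is(assembly, "CircularGenome"))
    .checkStructure(assembly, structure)
    refSsc <- .seqChr(refSsc)
    if (!nchar(refSsc)) stop("refSsc must be non-empty")
    ssc <- structure@regions["ssc"]
    body <- substr(.seqChr(assembly), start(ssc), end(ssc))
    scoreF <- hspScore(findHsp(body, refSsc))
    scoreR <- hspScore(findHsp(body, .revcompChr(refSsc)))
    top <- max(scoreF, scoreR)
    margin <- if (top > 0) abs(scoreF - scoreR) / top else 0
    bodyOrientation <- if (top == 0 || margin < minMargin) "unknown"
                       else if (scoreF > scoreR) "F" else "R"
    junction <- screenJunctionSignature(assembly, structure = structure,
                                        ...)$junctionType
    isChimeric <- junction != "unknown" && bodyOrientation != "unknown" &&
        junction != bodyOrientation
    data.frame(junctionType = junction, bodyOrientation = bodyOrientation,
               isChimeric = isChimeric, bodyScoreMargin = margin,
               scoreF = scoreF, scoreR = scoreR, stringsAsFactors = FALSE)
}
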