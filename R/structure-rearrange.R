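#' Invert the SSC in place (SSC switching)
#'
#' Replaces the SSC interval of a canonical genome with its reverse
#' complement, converting an SSC-forward (LSC-IR1-SSC-IR2) molecule into an
#' SSC-reverse (LSC-IR1-ssc-IR2) one and vice versa. All positions outside
#' the SSC are untouched; the operation is an involution.
#'
#' @param genome a canonical [CircularGenome-class].
#' @param structure its [QuadripartiteStructure-class] (offset 0).
#' @return a [CircularGenome-class] of the same length.
#' @examples
#' g <- circularGenome(paste0("ACGTACGTAC", "AAGGCTAGCT",
#'                            "TTTTACCCCA", "AGCTAGCCTT"))
#' st <- quadripartiteStructure(10, 10, 10)
#' flipSsc(g, st)
#' @export
flipSsc <- function(genome, structure) {
    .checkStructure(genome, structure)
    ssc <- structure@regions["ssc"]
    s <- genomeSeq(genome)
    flipped <- replaceAt(s, ssc,
                         reverseComplement(subseq(s, start(ssc), end(ssc))))
    circularGenome(flipped, id = genomeId(genome),
                   circular = genome@circular)
}

#' Build the SSC-F / SSC-R haplotype pair
#'
#' @param genome a canonical [CircularGenome-class] taken as the SSC-forward
#'   haplotype.
#' @param structure its [QuadripartiteStructure-class].
#' @return a [HaplotypePair-class] with `seqF` the input and `seqR` its
#'   [flipSsc()] image; the member ids are suffixed `_F` and `_R`.
#' @export
buildHaplotypePair <- function(genome, structure) {
    .checkStructure(genome, structure)
    f <- circularGenome(genomeSeq(genome),
                        id = paste0(genomeId(genome), "_F"),
                        circular = genome@circular)
    r <- flipSsc(genome, structure)
    r@id <- paste0(genomeId(genome), "_R")
    new("HaplotypePair", seqF = f, seqR = r, structure = structure)
}

#' Insert length implied by an SVSpec
#'
#' The IR-duplication insert is `insertPrefix` + the first `i1Len` bases of
#' LSC + a full IR copy, so its length is
#' `nchar(insertPrefix) + i1Len + irLen`.
#'
#' @param sv an [SVSpec-class].
#' @param irLen IR length in bp.
#' @return integer insert length.
#' @examples
#' insertLength(svSpec(), irLen = 20805)  # 5 + 2000 + 20805 = 22810
#' @export
insertLength <- function(sv, irLen) {
    stopifnot(is(sv, "SVSpec"))
    nchar(sv@insertPrefix) + sv@i1Len + as.integer(irLen)
}

#' Apply the IR-duplication rearrangement (IR gain)
#'
#' Produces the IR-gain mutant of the asymmetric-recombination model: the
#' last `d1Len` bases of IR1 are deleted (leaving the truncated copy IR1d)
#' and, at the same point, `insertPrefix` + the first `i1Len` bases of LSC +
#' a full copy of IR1 are inserted, yielding the junction organization
#' IR1d - prefix - i1 - IR1. The net length change is
#' `insertLength(sv, irLen) - d1Len`.
#'
#' @param genome a canonical [CircularGenome-class].
#' @param structure its [QuadripartiteStructure-class].
#' @param sv an [SVSpec-class]; requires `d1Len < irLen` and `i1Len < |LSC|`.
#' @return a [CircularGenome-class] (id suffixed `_irdup`).
#' @examples
#' g <- circularGenome(paste0("ACGTACGTAC", "AAGGCTAGCT",
#'                            "TTTTACCCCA", "AGCTAGCCTT"))
#' st <- quadripartiteStructure(10, 10, 10)
#' mut <- applyIRDuplication(g, st, svSpec(2, 3, "ATTTT"))
#' seqLength(mut) - seqLength(g)  # 5 + 3 + 10 - 2 = 16
#' @export
applyIRDuplication <- function(genome, structure, sv) {
    .checkStructure(genome, structure)
    stopifnot(is(sv, "SVSpec"))
    if (sv@d1Len >= structure@irLen)
        stop("d1Len must be smaller than the IR length")
    lsc <- structure@regions["lsc"]
    if (sv@i1Len >= width(lsc))
        stop("i1Len must be smaller than the LSC length")
    s <- .seqChr(genome)
    ir1 <- structure@regions["ir1"]
    ir1Seq <- substr(s, start(ir1), end(ir1))
    ir1d <- substr(ir1Seq, 1L, structure@irLen - sv@d1Len)
    i1 <- substr(s, start(lsc), start(lsc) + sv@i1Len - 1L)
    mutant <- paste0(substr(s, 1L, start(ir1) - 1L),
                     ir1d, sv@insertPrefix, i1, ir1Seq,
                     substr(s, end(ir1) + 1L, nchar(s)))
    circularGenome(mutant, id = paste0(genomeId(genome), "_irdup"),
                   circular = genome@circular)
}

#' Apply the IR-loss rearrangement
#'
#' Produces the IR-lacking mutant of the asymmetric-recombination model: one
#' full IR copy is removed, leaving the organization LSC-IR-SSC. The copy
#' removed is IR2 (the copy after the SSC); which copy is lost is not
#' observable from the product, so this choice is fixed and documented.
#'
#' @param genome a canonical [CircularGenome-class].
#' @param structure its [QuadripartiteStructure-class].
#' @return a [CircularGenome-class] shorter by `irLength(structure)`
#'   (id suffixed `_irloss`).
#' @export
applyIRLoss <- function(genome, structure) {
    .checkStructure(genome, structure)
    ir2 <- structure@regions["ir2"]
    s <- .seqChr(genome)
    mutant <- paste0(substr(s, 1L, start(ir2) - 1L),
                     substr(s, end(ir2) + 1L, nchar(s)))
    circularGenome(mutant, id = paste0(genomeId(genome), "_irloss"),
                   circular = genome@circular)
}
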