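#' Find the high-score segment pair (HSP) between two sequences
#'
#' Returns the maximal-scoring local alignment between `a` and `b` under the
#' scoring scheme match = +2, mismatch = -3, gap of length g = -(5 + 2(g-1))
#' (i.e. opening a gap costs 5 and each additional gapped base 2). N matches
#' nothing and scores as a mismatch. If no segment pair scores above zero,
#' an empty HSP with score 0 is returned.
#'
#' The dynamic programming is done by
#' [Biostrings::pairwiseAlignment()] (`type = "local"`); among equal-scoring
#' segment pairs the aligner's deterministic traceback decides which is
#' reported.
#'
#' @param a,b nucleotide sequences (character or
#'   [Biostrings::DNAString]), non-empty.
#' @param match,mismatch,gapOpen,gapExt scoring parameters; `gapOpen` is the
#'   total cost of a length-1 gap and `gapExt` the cost of each additional
#'   gapped base.
#' @return an [HSP-class] with the matched segments (1-based ranges in `a`
#'   and `b`) and the score.
#' @examples
#' findHsp("GGTACCTTG", "TTTACCTAA")   # TACCT vs TACCT, score 10
#' hspScore(findHsp("AAAA", "CCCC"))   # 0 (empty)
#' @export
findHsp <- function(a, b, match = 2, mismatch = -3,
                    gapOpen = -5, gapExt = -2) {
    a <- .seqChr(a); b <- .seqChr(b)
    if (!nchar(a) || !nchar(b))
        stop("both sequences must be non-empty")
    scoring <- c(match = match, mismatch = mismatch,
                 gapOpen = gapOpen, gapExt = gapExt)
    letters <- c("A", "C", "G", "T", "N")
    mat <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
    diag(mat) <- match
    mat["N", "N"] <- mismatch   # N matches nothing
    ## Biostrings costs a length-g gap gapOpening + g*gapExtension
    aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "local",
                             substitutionMatrix = mat,
                             gapOpening = abs(gapOpen) - abs(gapExt),
                             gapExtension = abs(gapExt))
    sc <- score(aln)
    if (sc <= 0)
        return(new("HSP", rangeA = IRanges(1L, width = 0L),
                   rangeB = IRanges(1L, width = 0L),
                   score = 0, scoring = scoring))
    pr <- pattern(aln); sr <- subject(aln)
    new("HSP",
        rangeA = IRanges(start(pr), end(pr)),
        rangeB = IRanges(start(sr), end(sr)),
        score = sc, scoring = scoring)
}
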