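#' Detect the inverted-repeat pair and partition a circular plastome
#'
#' Finds the highest-scoring pair of disjoint segments on the circular
#' genome such that one equals the reverse complement of the other up to
#' `maxMismatchRate`, searching over all rotations. "Highest-scoring" means
#' longest, with ties broken by fewest mismatches and then by smallest start
#' position on the input linearization. The two single-copy gaps between the
#' pair become the LSC (longer gap) and SSC (shorter gap); the IR copy
#' immediately following the LSC (clockwise, on the presented strand) is
#' labelled IR1. The returned structure is expressed on the canonical
#' rotation (LSC starting at position 1) with `canonicalOffset()` recording
#' the rotation from the input linearization.
#'
#' Detection seeds exact `k`-mer matches between the genome and its reverse
#' complement, clusters them on circular anti-diagonals (paired positions
#' `p + q` constant modulo the genome length), and greedily extends the
#' seeded match runs under the mismatch budget
#' `ceil(maxMismatchRate * length)`.
#'
#' @param genome a [CircularGenome-class]; must be circular.
#' @param minLen minimum acceptable IR length in bp.
#' @param maxMismatchRate maximum fraction of mismatching positions between
#'   IR1 and revcomp(IR2) (default 0.001; plastome IRs are near-identical).
#' @param k seed k-mer length (default 15; reduced to `minLen` when
#'   `minLen < k`).
#' @param maxSeedOcc seeds occurring more often than this (low-complexity
#'   k-mers) are ignored.
#' @return a [QuadripartiteStructure-class].
#' @section Errors:
#' If no disjoint pair of length >= `minLen` exists, a condition of class
#' `noIRError` is signalled (an IR-lacking genome, as reported in
#' \emph{Onobrychis}); if the only candidates pair a segment with an
#' overlapping copy of itself, a `palindromeError` is signalled.
#' @examples
#' g <- circularGenome(paste0("ACGTACGTAC", "AAGGCTAGCT",
#'                            "TTTTACCCCA", "AGCTAGCCTT"))
#' findInvertedRepeats(g, minLen = 8)
#' @export
findInvertedRepeats <- function(genome, minLen = 1000L,
                                maxMismatchRate = 0.001, k = 15L,
                                maxSeedOcc = 50L) {
    stopifnot(is(genome, "CircularGenome"))
    if (!genome@circular)
        stop("findInvertedRepeats() requires a circular genome")
    s <- .seqChr(genome)
    L <- nchar(s)
    minLen <- as.integer(minLen)
    if (L < 2L * minLen)
        .noIRError(sprintf(
            "genome (%d bp) too short for a disjoint inverted pair of length >= %d",
            L, minLen))
    k <- max(4L, min(as.integer(k), minLen))

    si <- .seqToInt(s)
    ci <- .compInt(si)

    ## seed k-mer matches between the genome and its reverse complement.
    ## Query-side k-mers are strided: any complementary run of length
    ## >= minLen still contains a strided seed start.
    stride <- max(1L, (minLen - k + 1L) %/% 2L)
    s2 <- paste0(s, substr(s, 1L, k - 1L))
    iPos <- seq.int(1L, L, by = stride)
    A <- substring(s2, iPos, iPos + k - 1L)
    rc2 <- .revcompChr(s2)
    B <- substring(rc2, seq_len(L), seq_len(L) + k - 1L)
    shared <- intersect(A[!grepl("N", A, fixed = TRUE)],
                        B[!grepl("N", B, fixed = TRUE)])
    seedP <- integer(0)
    seedD <- integer(0)
    if (length(shared)) {
        selA <- A %in% shared
        selB <- B %in% shared
        gA <- split(iPos[selA], A[selA])
        gB <- split(which(selB), B[selB])
        gB <- gB[names(gA)]
        nA <- lengths(gA); nB <- lengths(gB)
        ok <- nA <= maxSeedOcc & nB <= maxSeedOcc
        if (any(ok)) {
            ## cross product per shared k-mer
            ii <- unlist(mapply(function(a, b) rep(a, each = length(b)),
                                gA[ok], gB[ok], SIMPLIFY = FALSE),
                         use.names = FALSE)
            mm <- unlist(mapply(function(a, b) rep(b, times = length(a)),
                                gA[ok], gB[ok], SIMPLIFY = FALSE),
                         use.names = FALSE)
            ## anti-diagonal (0-based): the k-mer at i matches the revcomp
            ## of the k-mer at j = L - m + 1; D = (i-1) + (j-1) + (k-1) mod L
            j <- L - mm + 1L
            seedP <- ii - 1L
            seedD <- (ii + j + k - 3L) %% L
        }
    }
    if (!length(seedP))
        .noIRError(sprintf("no inverted repeat of length >= %d found", minLen))

    budget <- function(len) as.integer(ceiling(maxMismatchRate * len))
    best <- NULL
    sawPalindrome <- FALSE
    halfL <- L %/% 2L

    for (D in unique(seedD)) {
        q <- ((D - (seq_len(L) - 1L)) %% L) + 1L
        mv <- si == ci[q] & si > 0L
        mv2 <- c(mv, mv)
        r <- rle(mv2)
        rend <- cumsum(r$lengths)
        rstart <- rend - r$lengths + 1L
        ## runs (1-based in mv2 coords) containing a seed position; both
        ## circular instances are considered so that greedy extension has
        ## full context on each side wherever the origin falls
        ps <- unique(seedP[seedD == D]) + 1L
        ps <- c(ps, ps + L)
        runIdx <- unique(findInterval(ps, rstart))
        runIdx <- runIdx[r$values[runIdx]]
        if (!length(runIdx)) next
        nRuns <- length(r$lengths)
        for (ri in runIdx) {
            lo <- ri; hi <- ri
            len <- r$lengths[ri]; mism <- 0L
            repeat {
                extended <- FALSE
                ## try absorbing the next gap+run on the right, then left
                ## absorb a mismatch gap only when the run beyond it more
                ## than offsets it (match +1, mismatch -3), so that window
                ## ends always land on exact-match boundaries
                for (side in c("right", "left")) {
                    if (side == "right" && hi + 2L <= nRuns) {
                        g <- r$lengths[hi + 1L]; add <- r$lengths[hi + 2L]
                        newLen <- len + g + add
                        if (newLen <= halfL && add > 3L * g &&
                            mism + g <= budget(newLen)) {
                            hi <- hi + 2L; len <- newLen; mism <- mism + g
                            extended <- TRUE
                        }
                    } else if (side == "left" && lo - 2L >= 1L) {
                        g <- r$lengths[lo - 1L]; add <- r$lengths[lo - 2L]
                        newLen <- len + g + add
                        if (newLen <= halfL && add > 3L * g &&
                            mism + g <= budget(newLen)) {
                            lo <- lo - 2L; len <- newLen; mism <- mism + g
                            extended <- TRUE
                        }
                    }
                }
                if (!extended) break
            }
            len <- min(len, halfL)
            if (len < minLen) next
            p1 <- rstart[lo] - 1L          # 0-based, possibly >= L
            a1 <- p1 %% L
            b1 <- (D - (p1 + len - 1L)) %% L
            if (.arcsOverlap(a1, len, b1, len, L)) {
                sawPalindrome <- TRUE
                next
            }
            cand <- list(a1 = a1, b1 = b1, len = len, mism = mism)
            if (is.null(best) ||
                cand$len > best$len ||
                (cand$len == best$len && cand$mism < best$mism) ||
                (cand$len == best$len && cand$mism == best$mism &&
                 min(cand$a1, cand$b1) < min(best$a1, best$b1))) {
                best <- cand
            }
        }
    }

    if (is.null(best)) {
        if (sawPalindrome)
            .palindromeError(paste0(
                "only palindromic candidates found: the two inverted copies",
                " would overlap"))
        .noIRError(sprintf("no inverted repeat of length >= %d found", minLen))
    }

    ## the two single-copy gaps between the IR copies (0-based starts)
    a1 <- best$a1; b1 <- best$b1; len <- best$len
    ## order the two copies so that copyX end -> gap -> copyY start
    gapAfterA <- (b1 - ((a1 + len) %% L)) %% L   # gap from end of A to start of B
    gapAfterB <- (a1 - ((b1 + len) %% L)) %% L
    if (gapAfterA == gapAfterB)
        stop(structure(class = c("tieError", "noIRError", "error", "condition"),
                       list(message = paste0(
                           "LSC/SSC assignment unresolvable: the two ",
                           "single-copy gaps have equal length"),
                           call = sys.call())))
    if (gapAfterA > gapAfterB) {
        ## gap after copy A is the LSC, so IR1 is copy B (follows the LSC)
        lscStart <- (a1 + len) %% L
        lscLen <- gapAfterA
        sscLen <- gapAfterB
    } else {
        lscStart <- (b1 + len) %% L
        lscLen <- gapAfterB
        sscLen <- gapAfterA
    }
    quadripartiteStructure(lscLen, len, sscLen,
                           irMismatches = best$mism,
                           offset = lscStart)
}

#' Rotate a genome and its structure to the canonical linearization
#'
#' Returns the rotation of the genome in which the LSC begins at position 1
#' and is immediately followed by IR1, together with the structure updated to
#' offset 0. Idempotent: canonicalizing a canonical genome is a no-op.
#'
#' @param genome a [CircularGenome-class].
#' @param structure the matching [QuadripartiteStructure-class] (possibly
#'   with a non-zero `canonicalOffset()`).
#' @return a list with elements `genome` and `structure`.
#' @examples
#' g <- circularGenome(paste0("ACGTACGTAC", "AAGGCTAGCT",
#'                            "TTTTACCCCA", "AGCTAGCCTT"))
#' st <- findInvertedRepeats(g, minLen = 8)
#' can <- canonicalizeGenome(g, st)
#' canonicalOffset(can$structure)   # 0
#' @export
canonicalizeGenome <- function(genome, structure) {
    stopifnot(is(genome, "CircularGenome"),
              is(structure, "QuadripartiteStructure"))
    if (seqLength(genome) != structure@genomeLength)
        stop("genome length does not match structure genomeLength")
    off <- structure@offset
    if (off == 0L) return(list(genome = genome, structure = structure))
    s <- .rotateLeft(.seqChr(genome), off)
    g2 <- circularGenome(s, id = genomeId(genome),
                         circular = genome@circular)
    st2 <- structure
    st2@offset <- 0L
    list(genome = g2, structure = st2)
}

#' Verify a structure against a genome sequence
#'
#' Recomputes the Hamming distance between IR1 and the reverse complement of
#' IR2 on the canonical rotation and checks it equals the recorded
#' `irMismatches`.
#'
#' @param genome a canonical [CircularGenome-class] (offset 0).
#' @param structure its [QuadripartiteStructure-class].
#' @return invisibly `TRUE`; errors otherwise.
#' @keywords internal
.checkStructure <- function(genome, structure) {
    if (structure@offset != 0L)
        stop("structure must be canonical (offset 0); ",
             "use canonicalizeGenome() first")
    if (seqLength(genome) != structure@genomeLength)
        stop("genome length does not match structure")
    invisible(TRUE)
}
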