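# Independent oracles used by the tests. These deliberately use different
# algorithms from the package implementation: exhaustive anti-diagonal scans
# for inverted repeats, a plain dynamic-programming Smith-Waterman for local
# alignment, and direct string enumeration for ungapped segment pairs.

.oracleCode <- local({
    v <- integer(256)
    v[utf8ToInt("A")] <- 1L; v[utf8ToInt("C")] <- 2L
    v[utf8ToInt("G")] <- 3L; v[utf8ToInt("T")] <- 4L
    v[utf8ToInt("N")] <- 5L
    v
})

# Exhaustive search for the longest pair of disjoint inverted segments on a
# circular sequence (exact matches only). Scans every circular anti-diagonal
# and every maximal complementary run on it; returns the best pair with the
# same tie-breaks as the package (longest, then smallest start), plus the
# derived region widths, or NULL if no pair of length >= minLen exists.
oracleInvertedRepeat <- function(s, minLen) {
    L <- nchar(s)
    code <- .oracleCode[utf8ToInt(s)]
    comp <- integer(length(code))
    comp[code == 1L] <- 4L; comp[code == 4L] <- 1L
    comp[code == 2L] <- 3L; comp[code == 3L] <- 2L
    halfL <- L %/% 2L
    best <- NULL
    idx <- seq_len(L) - 1L
    for (D in 0:(L - 1L)) {
        q <- ((D - idx) %% L) + 1L
        mv <- code == comp[q] & code > 0L
        if (!any(mv)) next
        r <- rle(c(mv, mv))
        rend <- cumsum(r$lengths)
        rstart <- rend - r$lengths + 1L
        for (ri in which(r$values & rstart <= L)) {
            len <- min(r$lengths[ri], halfL)
            if (len < minLen) next
            a1 <- (rstart[ri] - 1L) %% L
            b1 <- (D - (rstart[ri] - 1L + len - 1L)) %% L
            # disjointness of the two arcs on the circle
            if (((a1 - b1) %% L) < len || ((b1 - a1) %% L) < len) next
            cand <- list(a1 = a1, b1 = b1, len = len)
            if (is.null(best) || cand$len > best$len ||
                (cand$len == best$len &&
                 min(cand$a1, cand$b1) < min(best$a1, best$b1)))
                best <- cand
        }
    }
    if (is.null(best)) return(NULL)
    gapAfterA <- (best$b1 - ((best$a1 + best$len) %% L)) %% L
    gapAfterB <- (best$a1 - ((best$b1 + best$len) %% L)) %% L
    if (gapAfterA == gapAfterB) return(list(tie = TRUE, irLen = best$len))
    if (gapAfterA > gapAfterB) {
        lscStart <- (best$a1 + best$len) %% L
        lscLen <- gapAfterA; sscLen <- gapAfterB
    } else {
        lscStart <- (best$b1 + best$len) %% L
        lscLen <- gapAfterB; sscLen <- gapAfterA
    }
    list(tie = FALSE, irLen = best$len, lscLen = lscLen, sscLen = sscLen,
         offset = lscStart)
}

# Plain affine-gap Smith-Waterman returning only the optimal local score.
# Gap of length g costs abs(gapOpen) + (g-1)*abs(gapExt).
swOracleScore <- function(a, b, match = 2, mismatch = -3,
                          gapOpen = -5, gapExt = -2) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    open <- abs(gapOpen); ext <- abs(gapExt)
    NEG <- -1e9
    H <- matrix(0, n + 1L, m + 1L)   # best ending in (i,j)
    E <- matrix(NEG, n + 1L, m + 1L) # gap in b (deletion from a)
    F <- matrix(NEG, n + 1L, m + 1L) # gap in a
    bestScore <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            sub <- if (a[i] == b[j] && a[i] != "N") match else mismatch
            E[i + 1L, j + 1L] <- max(H[i, j + 1L] - open,
                                     E[i, j + 1L] - ext)
            F[i + 1L, j + 1L] <- max(H[i + 1L, j] - open,
                                     F[i + 1L, j] - ext)
            H[i + 1L, j + 1L] <- max(0, H[i, j] + sub,
                                     E[i + 1L, j + 1L], F[i + 1L, j + 1L])
            if (H[i + 1L, j + 1L] > bestScore)
                bestScore <- H[i + 1L, j + 1L]
        }
    }
    bestScore
}

# Exhaustive enumeration of all ungapped segment pairs (for small inputs).
ungappedOracle <- function(a, b, match = 2, mismatch = -3) {
    n <- nchar(a); m <- nchar(b)
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    best <- list(score = 0, a = NULL, b = NULL)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        len <- min(n - i, m - j) + 1L
        sc <- cumsum(ifelse(av[i:(i + len - 1L)] == bv[j:(j + len - 1L)] &
                            av[i:(i + len - 1L)] != "N", match, mismatch))
        w <- which.max(sc)
        if (sc[w] > best$score)
            best <- list(score = sc[w], a = c(i, i + w - 1L),
                         b = c(j, j + w - 1L))
    }
    best
}

randomSeqChr <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random circular genome with one planted exact IR pair; returns the rotated
# sequence and the planted (post-rotation-unknown) region lengths
plantIRGenome <- function(lscLen, irLen, sscLen) {
    lsc <- randomSeqChr(lscLen)
    ir <- randomSeqChr(irLen)
    ssc <- randomSeqChr(sscLen)
    ir2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ir)))
    s <- paste0(lsc, ir, ssc, ir2)
    rot <- sample(0:(nchar(s) - 1L), 1L)
    plastidSV:::.rotateLeft(s, rot)
}

toyQuadGenome <- function() {
    # LSC 12, IR1 10, SSC 8, IR2 10; the planted IR pair is maximal and the
    # two single-copy gaps differ, so the partition is unambiguous
    circularGenome(paste0("ACGTACGTACGA", "AAGGCTAGCT",
                          "GTTTACCG", "AGCTAGCCTT"), id = "toy")
}
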