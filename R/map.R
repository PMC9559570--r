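# Long-read mapping against a circular reference: exact k-mer seeding on the
# doubled reference, diagonal-band selection, greedy co-linear chaining,
# exact-block merging with direct mismatch counting on a shared diagonal,
# small dynamic-programming fills across diagonal shifts, and X-drop end
# extension. Deterministic for fixed inputs and parameters.

#' Build a k-mer index of a circular reference
#'
#' Indexes the doubled reference sequence so that reads crossing the origin
#' still align contiguously; reference coordinates in downstream alignments
#' therefore run up to twice the reference length and are interpreted
#' modulo `refLength(index)`.
#'
#' @param ref a [CircularGenome-class].
#' @param k k-mer length (default 15).
#' @param maxOcc k-mers occurring more than this many times in the doubled
#'   reference are dropped from the index (low-complexity masking).
#' @return an opaque index object for [mapRead()].
#' @export
buildMapIndex <- function(ref, k = 15L, maxOcc = 50L) {
    stopifnot(is(ref, "CircularGenome"))
    s <- .seqChr(ref)
    L <- nchar(s)
    k <- as.integer(k)
    s2 <- paste0(s, s)
    n2 <- 2L * L - k + 1L
    km <- substring(s2, seq_len(n2), seq_len(n2) + k - 1L)
    pos <- split(seq_len(n2), km)
    pos <- pos[lengths(pos) <= maxOcc]
    env <- list2env(pos, hash = TRUE, size = length(pos))
    structure(list(id = genomeId(ref), L = L, k = k, s2 = s2, env = env),
              class = "plastidSVMapIndex")
}

# fixed scoring for gap-fill alignments: a plain matrix avoids the costly
# quality-based substitution machinery pairwiseAlignment uses by default
.FILL_MAT <- local({
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(-2, 5L, 5L, dimnames = list(letters, letters))
    diag(m) <- 1
    m["N", "N"] <- -2
    m
})

# X-drop extension: mv is a logical match vector ordered from the block edge
# outward. Returns c(length, matches) of the maximal-score prefix
# (match +1, mismatch -2), abandoning once the score drops `xdrop` below the
# running maximum.
.xdropExtend <- function(mv, xdrop = 10L) {
    if (!length(mv)) return(c(0L, 0L))
    sc <- cumsum(ifelse(mv, 1L, -2L))
    run <- cummax(sc)
    stopAt <- which(run - sc > xdrop)
    lim <- if (length(stopAt)) stopAt[1L] else length(mv)
    best <- which.max(sc[seq_len(lim)])
    if (sc[best] <= 0L) return(c(0L, 0L))
    c(best, sum(mv[seq_len(best)]))
}

.emptyAlignment <- function(readId, refId, readLength, strand = "+") {
    new("ReadAlignment", readId = readId, refId = refId, strand = strand,
        blocksRead = IRanges(), blocksRef = IRanges(),
        nmatch = 0, ncols = 0, readLength = as.integer(readLength))
}

# map one strand of a read against the index; returns a ReadAlignment
.mapStrand <- function(r, index, readId, strand, readLength,
                       band, minChainAnchors, qstride, maxGapFill) {
    L <- index$L; k <- index$k
    rl <- nchar(r)
    if (rl < k) return(.emptyAlignment(readId, index$id, readLength, strand))
    qPos <- unique(c(seq.int(1L, rl - k + 1L, by = qstride), rl - k + 1L))
    km <- substring(r, qPos, qPos + k - 1L)
    hits <- mget(km, envir = index$env, ifnotfound = list(NULL))
    nh <- lengths(hits)
    if (!sum(nh)) return(.emptyAlignment(readId, index$id, readLength, strand))
    q <- rep.int(qPos, nh)
    t <- unlist(hits, use.names = FALSE)
    ## diagonal class on the circle (0-based)
    d0 <- (t - q) %% L
    ## modal band
    bin <- d0 %/% band
    tab <- tabulate(bin + 1L)
    bestBin <- which.max(tab) - 1L
    dref <- d0[bin == bestBin][1L]
    ## signed deviation from the reference diagonal, wrapped
    dev <- ((d0 - dref + L %/% 2L) %% L) - L %/% 2L
    sel <- abs(dev) <= band
    if (sum(sel) < minChainAnchors)
        return(.emptyAlignment(readId, index$id, readLength, strand))
    q <- q[sel]; dev <- dev[sel]
    tAdj <- q + dref + dev       # unwrapped reference start (1-based)
    o <- order(q, tAdj)
    q <- q[o]; tAdj <- tAdj[o]
    ## greedy co-linear chain: strictly increasing reference positions,
    ## one anchor per read position
    keep <- logical(length(q))
    lastQ <- -1L; lastT <- -.Machine$integer.max
    for (i in seq_along(q)) {
        if (q[i] == lastQ) next
        if (tAdj[i] > lastT) {
            keep[i] <- TRUE
            lastQ <- q[i]; lastT <- tAdj[i]
        }
    }
    q <- q[keep]; tAdj <- tAdj[keep]
    if (!length(q)) return(.emptyAlignment(readId, index$id, readLength, strand))

    s2 <- index$s2
    ## assemble blocks: merge anchors on a shared diagonal when the
    ## intervening bases mostly match (counting mismatches by direct
    ## comparison); low-identity stretches and diagonal shifts close the
    ## current block. Diagonal-shift gaps are filled by a small global
    ## alignment and kept as their own (possibly unequal-width) block when
    ## they align decently, so reference coverage stays contiguous across
    ## small indels but never bridges non-homologous sequence.
    bQ <- integer(0); bW <- integer(0); bT <- integer(0); bTW <- integer(0)
    nm <- 0; nc <- 0
    qs <- q[1L]; qe <- q[1L] + k - 1L
    ts <- tAdj[1L]; te <- tAdj[1L] + k - 1L
    blkMatch <- k; blkCols <- k
    closeBlock <- function() {
        bQ <<- c(bQ, qs); bW <<- c(bW, qe - qs + 1L)
        bT <<- c(bT, ts); bTW <<- c(bTW, te - ts + 1L)
        nm <<- nm + blkMatch; nc <<- nc + blkCols
    }
    fillGap <- function(q1, q2, t1, t2) {
        gq <- q2 - q1 + 1L; gt <- t2 - t1 + 1L
        if (gq <= 0L || gt <= 0L || max(gq, gt) > maxGapFill) return()
        pa <- pairwiseAlignment(DNAString(substr(r, q1, q2)),
                                DNAString(substr(s2, t1, t2)),
                                type = "global",
                                substitutionMatrix = .FILL_MAT,
                                gapOpening = 2, gapExtension = 1)
        if (nmatch(pa) / nchar(pa) >= 0.5) {
            bQ <<- c(bQ, q1); bW <<- c(bW, gq)
            bT <<- c(bT, t1); bTW <<- c(bTW, gt)
            nm <<- nm + nmatch(pa); nc <<- nc + nchar(pa)
        }
    }
    for (i in seq_along(q)[-1L]) {
        qi <- q[i]; ti <- tAdj[i]
        sameDiag <- (ti - qi) == (te - qe)
        g <- qi - qe - 1L
        if (sameDiag && g <= 0L) {
            add <- qi + k - 1L - qe
            if (add > 0L) { blkMatch <- blkMatch + add; blkCols <- blkCols + add }
            qe <- max(qe, qi + k - 1L); te <- max(te, ti + k - 1L)
        } else if (sameDiag) {
            a <- utf8ToInt(substr(r, qe + 1L, qi - 1L))
            b <- utf8ToInt(substr(s2, te + 1L, ti - 1L))
            mg <- sum(a == b)
            if (g <= 10L || mg / g >= 0.5) {
                blkMatch <- blkMatch + mg + k
                blkCols <- blkCols + g + k
                qe <- qi + k - 1L; te <- ti + k - 1L
            } else {
                closeBlock()
                qs <- qi; qe <- qi + k - 1L; ts <- ti; te <- ti + k - 1L
                blkMatch <- k; blkCols <- k
            }
        } else {
            closeBlock()
            fillGap(qe + 1L, qi - 1L, te + 1L, ti - 1L)
            qs <- qi; qe <- qi + k - 1L; ts <- ti; te <- ti + k - 1L
            blkMatch <- k; blkCols <- k
        }
    }
    closeBlock()

    ## X-drop extension of the outer ends along their diagonals
    firstQ <- bQ[1L]; firstT <- bT[1L]
    ext <- min(firstQ - 1L, firstT - 1L)
    if (ext > 0L) {
        a <- rev(utf8ToInt(substr(r, firstQ - ext, firstQ - 1L)))
        b <- rev(utf8ToInt(substr(s2, firstT - ext, firstT - 1L)))
        e <- .xdropExtend(a == b)
        if (e[1L] > 0L) {
            bQ[1L] <- firstQ - e[1L]; bT[1L] <- firstT - e[1L]
            bW[1L] <- bW[1L] + e[1L]; bTW[1L] <- bTW[1L] + e[1L]
            nm <- nm + e[2L]; nc <- nc + e[1L]
        }
    }
    nb <- length(bQ)
    lastQe <- bQ[nb] + bW[nb] - 1L
    lastTe <- bT[nb] + bTW[nb] - 1L
    ext <- min(rl - lastQe, nchar(s2) - lastTe)
    if (ext > 0L) {
        a <- utf8ToInt(substr(r, lastQe + 1L, lastQe + ext))
        b <- utf8ToInt(substr(s2, lastTe + 1L, lastTe + ext))
        e <- .xdropExtend(a == b)
        if (e[1L] > 0L) {
            bW[nb] <- bW[nb] + e[1L]; bTW[nb] <- bTW[nb] + e[1L]
            nm <- nm + e[2L]; nc <- nc + e[1L]
        }
    }

    new("ReadAlignment", readId = readId, refId = index$id, strand = strand,
        blocksRead = IRanges(start = bQ, width = bW),
        blocksRef = IRanges(start = bT, width = bTW),
        nmatch = nm, ncols = nc, readLength = as.integer(readLength))
}

#' Map a long read to a circular reference
#'
#' Seeds exact k-mers against the reference treated circularly, selects the
#' best diagonal band, chains co-linear anchors, merges them into gap-free
#' blocks (substitution mismatches counted by direct comparison, diagonal
#' shifts filled by a small global alignment), and extends the alignment
#' ends with an X-drop rule. Both strands of the read are tried and the
#' higher-scoring one returned. Deterministic for fixed inputs and
#' parameters; a read with no seed hits yields an empty alignment
#' (`alignedReadFraction` 0), not an error.
#'
#' @param read character or [Biostrings::DNAString] read sequence.
#' @param ref a [CircularGenome-class] or an index from [buildMapIndex()].
#' @param readId label stored in the result.
#' @param k seed length (used only when `ref` is not already an index).
#' @param band diagonal band half-width in bp.
#' @param minChainAnchors minimum anchors in the winning band.
#' @param qstride stride between query seed positions.
#' @param maxGapFill largest inter-block gap filled by dynamic programming.
#' @return a [ReadAlignment-class]. Reference block coordinates are on the
#'   doubled reference; interpret them modulo the reference length.
#' @export
mapRead <- function(read, ref, readId = "read", k = 15L, band = 100L,
                    minChainAnchors = 2L, qstride = 5L, maxGapFill = 2000L) {
    index <- if (inherits(ref, "plastidSVMapIndex")) ref
             else buildMapIndex(ref, k = k)
    r <- .seqChr(read)
    rl <- nchar(r)
    if (rl < index$k)
        stop("read shorter than the seed length k")
    plus <- .mapStrand(r, index, readId, "+", rl, band, minChainAnchors,
                       qstride, maxGapFill)
    minus <- .mapStrand(.revcompChr(r), index, readId, "-", rl, band,
                        minChainAnchors, qstride, maxGapFill)
    if (minus@nmatch > plus@nmatch) minus else plus
}
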