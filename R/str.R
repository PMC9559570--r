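# Short tandem repeat (STR) detection, copy-number calling from spanning
# reads, and the pos[unit]min-max notation.

# lexicographically least rotation of a repeat unit
.leastRotation <- function(unit) {
    n <- nchar(unit)
    if (n == 1L) return(unit)
    rots <- vapply(seq_len(n) - 1L, function(i) .rotateLeft(unit, i), "")
    sort(rots)[1L]
}

# minimal period of a string (1..nchar)
.minPeriod <- function(unit) {
    n <- nchar(unit)
    ch <- strsplit(unit, "")[[1L]]
    for (p in seq_len(n - 1L)) {
        if (n %% p == 0L && all(ch == rep_len(ch[seq_len(p)], n))) return(p)
    }
    n
}

#' Detect short tandem repeat loci in a sequence
#'
#' Finds all maximal tandem runs with unit length between `minUnit` and
#' `maxUnit` and at least the per-unit-length minimum number of full copies
#' (defaults: >= 6 copies for homopolymers, >= 3 for units of 2-6 bp). Runs
#' that are equivalent to a smaller-unit run are suppressed (a run of 12 A's
#' is reported once as position[A]12, never as [AA]6), by skipping any unit
#' whose minimal period is shorter than the unit. Units are canonicalized to
#' their lexicographically least rotation; positions are 1-based on the
#' given strand.
#'
#' @param seq character or [Biostrings::DNAString]; a
#'   [CircularGenome-class] is scanned on its linear representation.
#' @param minUnit,maxUnit unit length bounds in bp.
#' @param minCopies integer vector of length `maxUnit` giving the minimum
#'   copy number per unit length (recycled from the default `c(6, 3, 3, 3,
#'   3, 3)` when lengths differ).
#' @return a `data.frame`: position, unit, refCopies, length (run length in
#'   bp), notation (e.g. `"11291[T]7"`).
#' @examples
#' findSTRLoci("GGAAAAAATC")                 # 3[A]6
#' findSTRLoci("ACACACAC", minCopies = c(6, 3))
#' @export
findSTRLoci <- function(seq, minUnit = 1L, maxUnit = 6L,
                        minCopies = c(6L, 3L, 3L, 3L, 3L, 3L)) {
    s <- .seqChr(seq)
    L <- nchar(s)
    minCopies <- rep_len(as.integer(minCopies), maxUnit)
    ch <- utf8ToInt(s)
    out <- list()
    for (u in seq.int(minUnit, maxUnit)) {
        if (L < 2L * u) next
        eq <- ch[seq_len(L - u)] == ch[seq_len(L - u) + u]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (i in which(r$values)) {
            runLen <- r$lengths[i] + u       # total repeat region in bp
            copies <- runLen %/% u
            if (copies < minCopies[u]) next
            p <- starts[i]
            unit <- substr(s, p, p + u - 1L)
            if (.minPeriod(unit) < u) next   # smaller-unit equivalent
            out[[length(out) + 1L]] <-
                data.frame(position = p, unit = .leastRotationKeepPhase(unit),
                           refCopies = copies, length = copies * u,
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(position = integer(0), unit = character(0),
                          refCopies = integer(0), length = integer(0),
                          notation = character(0), stringsAsFactors = FALSE))
    df <- do.call(rbind, out)
    df <- df[order(df$position, nchar(df$unit)), , drop = FALSE]
    rownames(df) <- NULL
    df$notation <- formatStrNotation(df)
    df
}

# canonical unit: the least rotation. The run itself starts at `position`
# with the observed phase; the canonical label is rotation-invariant.
.leastRotationKeepPhase <- function(unit) .leastRotation(unit)

#' Format / parse the pos[unit]min-max STR notation
#'
#' `formatStrNotation` renders loci as `position[unit]copyMin-copyMax`
#' (a single copy number when the bounds agree), e.g. `"11291[T]7-8"`;
#' `parseStrNotation` inverts it. The subscript typography used in print is
#' flattened to plain text. Round trip: `parseStrNotation(formatStrNotation(x))`
#' reproduces position, unit and copy bounds.
#'
#' @param loci a `data.frame` with columns position, unit, and either
#'   copyMin/copyMax or refCopies.
#' @return `formatStrNotation`: character vector; `parseStrNotation`: a
#'   `data.frame` with position, unit, copyMin, copyMax.
#' @examples
#' parseStrNotation("49216[T]10-15")
#' formatStrNotation(data.frame(position = 11291, unit = "T",
#'                              copyMin = 7, copyMax = 8))
#' @export
formatStrNotation <- function(loci) {
    stopifnot(is.data.frame(loci))
    cmin <- if ("copyMin" %in% names(loci)) loci$copyMin else loci$refCopies
    cmax <- if ("copyMax" %in% names(loci)) loci$copyMax else loci$refCopies
    ifelse(cmin == cmax,
           sprintf("%d[%s]%d", loci$position, loci$unit, cmin),
           sprintf("%d[%s]%d-%d", loci$position, loci$unit, cmin, cmax))
}

#' @param text character vector of notation strings (for
#'   `parseStrNotation`).
#' @rdname formatStrNotation
#' @export
parseStrNotation <- function(text) {
    text <- trimws(as.character(text))
    ## flatten subscript-style markup such as 11291[T]_7-8_
    text <- gsub("_", "", text, fixed = TRUE)
    m <- regmatches(text,
                    regexec("^(\\d+)\\[([ACGT]+)\\](\\d+)(?:-(\\d+))?$",
                            text))
    bad <- vapply(m, length, 1L) == 0L
    if (any(bad))
        stop("malformed STR notation: ",
             paste(sQuote(text[bad]), collapse = ", "))
    df <- do.call(rbind, lapply(m, function(g) {
        cmin <- as.integer(g[4L])
        cmax <- if (nzchar(g[5L])) as.integer(g[5L]) else cmin
        data.frame(position = as.integer(g[2L]), unit = g[3L],
                   copyMin = cmin, copyMax = cmax, stringsAsFactors = FALSE)
    }))
    if (any(df$copyMin > df$copyMax))
        stop("malformed STR notation: copyMin exceeds copyMax")
    rownames(df) <- NULL
    df
}

#' Call STR copy numbers from spanning reads
#'
#' For each locus, every read whose alignment spans the locus with at least
#' `flank` anchored reference bases on both sides is inspected: the two
#' flanking reference sequences are located in the read (near the positions
#' implied by the alignment blocks) and the unit copies between them are
#' counted. Counting is anchor-based rather than alignment-gap based, so it
#' is robust to how an aligner places gaps inside homopolymers. A copy
#' number is reported only when supported by at least `minSupport` reads;
#' `copyMin < copyMax` constitutes a copy-number-variation call.
#'
#' @param loci `data.frame` from [findSTRLoci()] (columns position, unit,
#'   refCopies).
#' @param reads named [Biostrings::DNAStringSet] (or character vector).
#' @param alignments list of [ReadAlignment-class] of these reads against
#'   `ref` (e.g. from [mapRead()] against the F haplotype).
#' @param ref the reference [CircularGenome-class] the loci were detected
#'   on.
#' @param flank anchored bases required on each side (default 10).
#' @param minSupport minimum reads per distinct copy number (default 3).
#' @param searchSlop how far (bp) around the expected position the flanks
#'   are searched for in the read.
#' @return `loci` with added columns copyMin, copyMax, nSpanning, support
#'   (comma-separated `copies:count`), callable, isCnv, notation.
#' @export
strCopyNumbers <- function(loci, reads, alignments, ref, flank = 10L,
                           minSupport = 3L, searchSlop = 50L) {
    stopifnot(is.data.frame(loci))
    if (is.character(reads)) reads <- DNAStringSet(reads)
    refSeq <- .seqChr(ref)
    L <- nchar(refSeq)
    readSeqs <- as.character(reads)
    alnByRead <- split(alignments,
                       vapply(alignments, function(a) a@readId, ""))
    res <- loci
    res$copyMin <- NA_integer_; res$copyMax <- NA_integer_
    res$nSpanning <- 0L; res$support <- ""
    res$callable <- FALSE; res$isCnv <- FALSE
    for (li in seq_len(nrow(loci))) {
        p <- loci$position[li]
        unit <- loci$unit[li]
        u <- nchar(unit)
        refLen <- u * loci$refCopies[li]
        lf <- substr(refSeq, p - flank, p - 1L)
        rf <- substr(refSeq, p + refLen, p + refLen + flank - 1L)
        if (nchar(lf) < flank || nchar(rf) < flank) next
        counts <- integer(0)
        for (id in names(alnByRead)) {
            if (!id %in% names(readSeqs)) next
            for (aln in alnByRead[[id]]) {
                ## minus-strand alignments refer to the reverse complement
                rs <- if (aln@strand == "-")
                    .revcompChr(readSeqs[[id]]) else readSeqs[[id]]
                cc <- .countCopiesInRead(aln, rs, p, refLen, lf, rf, unit,
                                         flank, L, searchSlop)
                if (!is.na(cc)) { counts <- c(counts, cc); break }
            }
        }
        res$nSpanning[li] <- length(counts)
        if (!length(counts)) next
        tab <- table(counts)
        res$support[li] <- paste(sprintf("%s:%d", names(tab),
                                         as.integer(tab)), collapse = ",")
        good <- as.integer(names(tab))[tab >= minSupport]
        if (!length(good)) next
        res$callable[li] <- TRUE
        res$copyMin[li] <- min(good)
        res$copyMax[li] <- max(good)
        res$isCnv[li] <- res$copyMin[li] < res$copyMax[li]
    }
    res$notation <- ifelse(res$callable,
                           formatStrNotation(res),
                           formatStrNotation(
                               data.frame(position = res$position,
                                          unit = res$unit,
                                          copyMin = res$refCopies,
                                          copyMax = res$refCopies)))
    res
}

# locate both flanks of one locus in one read and count unit copies between
# them; NA when the read does not span the locus cleanly
.countCopiesInRead <- function(aln, readSeq, p, refLen, lf, rf, unit,
                               flank, L, searchSlop) {
    if (!length(aln@blocksRef)) return(NA_integer_)
    ## reference positions of the flanks (try both circular instances)
    for (o in c(0L, L)) {
        lfStart <- p - flank + o
        rfEnd <- p + refLen + flank - 1L + o
        ## a block must anchor the left flank and the alignment must reach
        ## past the right flank (indels inside the repeat may split blocks)
        hit <- which(start(aln@blocksRef) <= lfStart &
                     end(aln@blocksRef) >= lfStart)
        if (!length(hit) || max(end(aln@blocksRef)) < rfEnd) next
        b <- hit[1L]
        ## expected read position of the left flank from the block offset
        expL <- start(aln@blocksRead)[b] + (lfStart - start(aln@blocksRef)[b])
        readLf <- .findNear(readSeq, lf, expL, searchSlop)
        if (is.na(readLf)) next
        expR <- expL + flank + refLen
        readRf <- .findNear(readSeq, rf, expR, searchSlop + 3L * nchar(unit))
        if (is.na(readRf)) next
        gap <- readRf - (readLf + flank)
        if (gap < 0L || gap %% nchar(unit) != 0L) next
        seg <- substr(readSeq, readLf + flank, readRf - 1L)
        if (gap > 0L && seg != strrep(unit, gap %/% nchar(unit))) next
        return(gap %/% nchar(unit))
    }
    NA_integer_
}

# exact search for `pat` in `s` within +/- slop of expected position `exp`;
# returns the match start closest to `exp`, or NA
.findNear <- function(s, pat, exp, slop) {
    lo <- max(1L, exp - slop)
    hi <- min(nchar(s), exp + slop + nchar(pat) - 1L)
    if (hi - lo + 1L < nchar(pat)) return(NA_integer_)
    win <- substr(s, lo, hi)
    m <- gregexpr(pat, win, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NA_integer_)
    pos <- as.integer(m) + lo - 1L
    pos[which.min(abs(pos - exp))]
}
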