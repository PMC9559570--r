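#' Classify one read as an SSC-orientation junction read
#'
#' Applies the junction-read criteria to the read's alignments against the
#' SSC-F and SSC-R haplotypes: a haplotype is satisfied iff the read aligns
#' with more than `minReadFrac` of its length, covers at least `minIrCover`
#' of IR1, and extends contiguously at least `minOverhang` aligned bases
#' into the LSC at the 5' end of IR1 and into the SSC (or ssc) at its 3'
#' end. The read is labelled `forward` if only the F haplotype is satisfied,
#' `reverse` if only R, `ambiguous` if both, `non_junction` if neither.
#'
#' Overhangs are measured in aligned reference bases immediately flanking
#' IR1, from the merged block structure, so clipped or unaligned read bases
#' never count as spanning evidence.
#'
#' @param alignF,alignR [ReadAlignment-class] objects of the same read
#'   against the F and R haplotypes.
#' @param structure the shared canonical [QuadripartiteStructure-class].
#' @param minReadFrac minimum aligned fraction of the read (strict `>`).
#' @param minIrCover minimum fraction of IR1 covered (default 1: all of it).
#' @param minOverhang minimum aligned bases flanking IR1 on each side (bp).
#' @param useIr2 also accept reads spanning the SSC-IR2-LSC junctions under
#'   the mirrored rule (disabled by default).
#' @return a one-row `data.frame`: readId, label, winningRef, irCoverage,
#'   leftOverhang, rightOverhang, alignedFracF, alignedFracR.
#' @export
classifyJunctionRead <- function(alignF, alignR, structure,
                                 minReadFrac = 0.90, minIrCover = 1.00,
                                 minOverhang = 200L, useIr2 = FALSE) {
    stopifnot(is(alignF, "ReadAlignment"), is(alignR, "ReadAlignment"))
    if (alignF@readId != alignR@readId)
        stop("alignF and alignR must refer to the same read")
    evF <- .junctionEvidence(alignF, structure, minReadFrac, minIrCover,
                             minOverhang, useIr2)
    evR <- .junctionEvidence(alignR, structure, minReadFrac, minIrCover,
                             minOverhang, useIr2)
    label <- if (evF$ok && evR$ok) "ambiguous"
             else if (evF$ok) "forward"
             else if (evR$ok) "reverse"
             else "non_junction"
    winning <- switch(label, forward = "F", reverse = "R", "none")
    ev <- if (evR$ok && !evF$ok) evR else evF
    data.frame(readId = alignF@readId, label = label, winningRef = winning,
               irCoverage = ev$irCov, leftOverhang = ev$left,
               rightOverhang = ev$right,
               alignedFracF = alignedReadFraction(alignF),
               alignedFracR = alignedReadFraction(alignR),
               stringsAsFactors = FALSE)
}

# evaluate the junction criteria for one alignment; considers both circular
# instances of IR1 on the doubled reference (and of IR2 when useIr2)
.junctionEvidence <- function(aln, structure, minReadFrac, minIrCover,
                              minOverhang, useIr2) {
    best <- list(ok = FALSE, irCov = 0, left = 0L, right = 0L)
    frac <- alignedReadFraction(aln)
    if (frac == 0) return(best)
    covered <- reduce(aln@blocksRef)
    L <- structure@genomeLength
    w <- regionWidths(structure)
    jobs <- list(list(ir = structure@regions["ir1"],
                      leftW = w[["lsc"]], rightW = w[["ssc"]]))
    if (useIr2)
        jobs <- c(jobs, list(list(ir = structure@regions["ir2"],
                                  leftW = w[["ssc"]], rightW = w[["lsc"]])))
    for (job in jobs) {
        s0 <- start(job$ir); e0 <- end(job$ir); irW <- width(job$ir)
        for (o in c(0L, L)) {
            s <- s0 + o; e <- e0 + o
            cov <- sum(width(intersect(covered, IRanges(s, e)))) / irW
            hitL <- which(start(covered) <= s & end(covered) >= s)
            left <- if (length(hitL))
                min(s - start(covered)[hitL[1L]], job$leftW) else 0L
            hitR <- which(start(covered) <= e & end(covered) >= e)
            right <- if (length(hitR))
                min(end(covered)[hitR[1L]] - e, job$rightW) else 0L
            ok <- frac > minReadFrac && cov >= minIrCover &&
                left >= minOverhang && right >= minOverhang
            cand <- list(ok = ok, irCov = cov, left = left, right = right)
            better <- (ok && !best$ok) || (ok == best$ok &&
                (cand$irCov > best$irCov ||
                 (cand$irCov == best$irCov &&
                  min(left, right) > min(best$left, best$right))))
            if (better) best <- cand
        }
    }
    best
}

#' Classify a set of reads against a haplotype pair
#'
#' Maps every read to both orientation haplotypes and applies
#' [classifyJunctionRead()]. Reads shorter than `minReadLen` are dropped
#' first (the full-scale convention screens at 20,000 bp; the scaled
#' default keeps all reads).
#'
#' @param reads a [Biostrings::DNAStringSet] (or named character vector).
#' @param pair a [HaplotypePair-class].
#' @param minReadLen pre-filter on read length in bp (default 0: off).
#' @param k,band,qstride,maxGapFill mapping parameters, see [mapRead()].
#' @param minReadFrac,minIrCover,minOverhang,useIr2 classification
#'   parameters, see [classifyJunctionRead()].
#' @return a `data.frame` with one row per (retained) read, the columns of
#'   [classifyJunctionRead()].
#' @examples
#' \donttest{
#' sim <- simulateGenome(simConfig(nReads = 50), seed = 1)
#' pair <- buildHaplotypePair(sim$genome, sim$structure)
#' mols <- simulateMolecules(sim$genome, sim$structure,
#'                           simConfig(nReads = 50), seed = 2)
#' rd <- simulateReads(mols, simConfig(nReads = 50), seed = 3)
#' calls <- classifyReads(rd$reads, pair)
#' summarizeOrientation(calls)
#' }
#' @export
classifyReads <- function(reads, pair, minReadLen = 0L, k = 15L,
                          band = 100L, qstride = 5L, maxGapFill = 2000L,
                          minReadFrac = 0.90, minIrCover = 1.00,
                          minOverhang = 200L, useIr2 = FALSE) {
    stopifnot(is(pair, "HaplotypePair"))
    if (is.character(reads)) reads <- DNAStringSet(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    reads <- reads[width(reads) >= max(minReadLen, k)]
    idxF <- buildMapIndex(hapF(pair), k = k)
    idxR <- buildMapIndex(hapR(pair), k = k)
    st <- hapStructure(pair)
    rows <- vector("list", length(reads))
    for (i in seq_along(reads)) {
        r <- as.character(reads[[i]])
        id <- names(reads)[i]
        aF <- mapRead(r, idxF, readId = id, band = band, qstride = qstride,
                      maxGapFill = maxGapFill)
        aR <- mapRead(r, idxR, readId = id, band = band, qstride = qstride,
                      maxGapFill = maxGapFill)
        rows[[i]] <- classifyJunctionRead(aF, aR, st,
                                          minReadFrac = minReadFrac,
                                          minIrCover = minIrCover,
                                          minOverhang = minOverhang,
                                          useIr2 = useIr2)
    }
    do.call(rbind, rows)
}

#' Wilson score interval for a binomial proportion
#'
#' @param x successes, @param n trials, @param level confidence level.
#' @return numeric `c(low, high)`.
#' @export
wilsonInterval <- function(x, n, level = 0.95) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, centre - half), min(1, centre + half))
}

#' Summarize SSC orientation among classified junction reads
#'
#' Counts junction reads by label and computes the SSC-F/SSC-R proportions
#' over classified (forward + reverse) reads, the SSC/ssc ratio both
#' unrounded and in the printed style (each proportion rounded to two
#' decimals before dividing, then the ratio rounded to two decimals — the
#' convention under which 82 and 99 reads give 0.45/0.55 = 0.82), and a
#' Wilson score interval for the forward proportion. Ambiguous reads are
#' excluded from the proportions.
#'
#' @param calls a `data.frame` from [classifyReads()], or `NULL` when
#'   passing counts directly.
#' @param nForward,nReverse,nAmbiguous,nNonJunction direct counts
#'   (used when `calls` is `NULL`).
#' @param ciLevel confidence level for the Wilson interval.
#' @return an [OrientationReport-class]. With no classified reads the
#'   proportions and ratio are `NA` (undefined), not an error.
#' @examples
#' summarizeOrientation(nForward = 82, nReverse = 99)
#' @export
summarizeOrientation <- function(calls = NULL, nForward = 0L, nReverse = 0L,
                                 nAmbiguous = 0L, nNonJunction = 0L,
                                 ciLevel = 0.95) {
    if (!is.null(calls)) {
        stopifnot(is.data.frame(calls), "label" %in% names(calls))
        nForward <- sum(calls$label == "forward")
        nReverse <- sum(calls$label == "reverse")
        nAmbiguous <- sum(calls$label == "ambiguous")
        nNonJunction <- sum(calls$label == "non_junction")
    }
    n <- nForward + nReverse
    if (n > 0L) {
        pF <- nForward / n
        pR <- nReverse / n
        ratio <- if (pR > 0) pF / pR else NA_real_
        rF <- round(pF, 2); rR <- round(pR, 2)
        ratioPrinted <- if (rR > 0) round(rF / rR, 2) else NA_real_
        ci <- wilsonInterval(nForward, n, ciLevel)
    } else {
        pF <- pR <- ratio <- ratioPrinted <- NA_real_
        ci <- c(NA_real_, NA_real_)
    }
    new("OrientationReport",
        nForward = as.integer(nForward), nReverse = as.integer(nReverse),
        nAmbiguous = as.integer(nAmbiguous),
        nNonJunction = as.integer(nNonJunction),
        propForward = pF, propReverse = pR, ratio = ratio,
        ratioPrinted = ratioPrinted, ciLow = ci[1L], ciHigh = ci[2L],
        ciLevel = ciLevel, ciMethod = "wilson")
}
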