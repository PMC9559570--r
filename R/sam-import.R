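#' Import read alignments from a SAM file
#'
#' Reads primary and supplementary alignment records whose reference is one
#' of the given haplotype names and merges them per (read, reference) into
#' block-structured [ReadAlignment-class] objects. Aligned blocks are the
#' M/=/X CIGAR stretches; soft- and hard-clipped bases count toward the read
#' length but never toward the aligned fraction. Secondary alignments are
#' skipped. Records naming an unknown reference are dropped with one
#' warning. Identity is taken from the NM tag when present (`NA` otherwise).
#'
#' @param samPath path to a SAM (or BAM) file.
#' @param refNames character vector of acceptable reference names, e.g.
#'   the ids of the two haplotypes (default: all references in the header).
#' @return a list of [ReadAlignment-class] objects, one per (read,
#'   reference) pair seen.
#' @export
importAlignments <- function(samPath, refNames = NULL) {
    stopifnot(file.exists(samPath))
    bam <- samPath
    if (!grepl("\\.bam$", samPath, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        bam <- Rsamtools::asBam(samPath, destination = dest,
                                indexDestination = FALSE, overwrite = TRUE)
    }
    param <- Rsamtools::ScanBamParam(
        flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                      isUnmappedQuery = FALSE),
        what = c("qname", "flag", "rname", "strand", "pos", "cigar", "qwidth"),
        tag = "NM")
    ga <- GenomicAlignments::readGAlignments(bam, use.names = FALSE,
                                             param = param)
    md <- S4Vectors::mcols(ga)
    if (!length(ga)) return(list())
    rn <- as.character(GenomicAlignments::seqnames(ga))
    if (is.null(refNames)) refNames <- unique(rn)
    bad <- !(rn %in% refNames)
    if (any(bad)) {
        warning(sum(bad), " record(s) with reference names outside ",
                paste(refNames, collapse = "/"), " were skipped")
        ga <- ga[!bad]; md <- md[!bad, , drop = FALSE]; rn <- rn[!bad]
    }
    if (!length(ga)) return(list())
    cig <- GenomicAlignments::cigar(ga)
    refBlocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cig, ops = c("M", "=", "X"), pos = start(ga))
    readBlocks <- GenomicAlignments::cigarRangesAlongQuerySpace(
        cig, ops = c("M", "=", "X"), before.hard.clipping = TRUE)
    ## full read length including soft and hard clips
    fullLen <- GenomicAlignments::cigarWidthAlongQuerySpace(
        cig, before.hard.clipping = TRUE)
    key <- paste(md$qname, rn, sep = "\r")
    out <- lapply(split(seq_along(ga), key), function(idx) {
        rb <- unlist(readBlocks[idx])
        tb <- unlist(refBlocks[idx])
        o <- order(start(rb))
        rb <- rb[o]; tb <- tb[o]
        ## drop read-overlapping duplicates across records
        keep <- rep(TRUE, length(rb))
        lastEnd <- 0L
        for (i in seq_along(rb)) {
            if (start(rb)[i] <= lastEnd) keep[i] <- FALSE
            else lastEnd <- end(rb)[i]
        }
        rb <- rb[keep]; tb <- tb[keep]
        aligned <- sum(width(rb))
        nmTag <- suppressWarnings(sum(as.integer(md$NM[idx])))
        nmatch <- if (!is.na(nmTag)) max(0L, aligned - nmTag) else NA_real_
        i1 <- idx[1L]
        new("ReadAlignment",
            readId = md$qname[i1], refId = rn[i1],
            strand = as.character(GenomicAlignments::strand(ga)[i1]),
            blocksRead = rb, blocksRef = tb,
            nmatch = if (is.na(nmatch)) 0 else nmatch,
            ncols = if (is.na(nmatch)) 0 else aligned,
            readLength = as.integer(max(fullLen[idx])))
    })
    names(out) <- NULL
    out
}
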