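#' Rice IR1-SSC junction signature motifs
#'
#' The two highly conserved 24-nt sequences straddling the IR1-SSC junction
#' that distinguish SSC-F from SSC-R rice plastomes: the shared last 12 nt of
#' IR1 followed by the first 12 nt of SSC (F) or of ssc (R).
#'
#' @return named character vector with elements `F` and `R`.
#' @examples
#' riceJunctionMotifs()
#' @export
riceJunctionMotifs <- function() {
    c(F = "TGGAAAAAATCGGCAAATAGGAAA",
      R = "TGGAAAAAATCGCGGAAAACCGAA")
}

.IR1_TAIL <- "TGGAAAAAATCG"
.SSC_HEAD_F <- "GCAAATAGGAAA"
## last 12 nt of SSC, chosen so that flipping the SSC puts the R motif head
## (CGGAAAACCGAA = revcomp of this) right after IR1
.SSC_TAIL_F <- "TTCGGTTTTCCG"

.randBases <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.otherBase <- function(avoid) {
    setdiff(c("A", "C", "G", "T"), avoid)[1L]
}

.parseChoices <- function(x) {
    if (is.list(x)) return(lapply(x, as.integer))
    lapply(strsplit(as.character(x), ","), function(v) as.integer(trimws(v)))
}

#' Simulate a quadripartite circular plastome
#'
#' Draws i.i.d. uniform A/C/G/T single-copy regions and one IR, sets
#' IR2 = revcomp(IR1), optionally embeds the rice junction signatures (last
#' 12 nt of IR1 and first/last 12 nt of SSC fixed so that the F motif sits
#' at the IR1-SSC boundary and flipping the SSC produces the R motif), and
#' writes any planted STR loci into the LSC. Region boundaries are adjusted
#' (one base where needed) so the planted IR pair is maximal and the planted
#' STR runs cannot extend, making the planted structure the unique ground
#' truth. Deterministic for a fixed seed.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return list with elements `genome` ([CircularGenome-class]) and
#'   `structure` ([QuadripartiteStructure-class], canonical).
#' @examples
#' sim <- simulateGenome(simConfig(), seed = 1)
#' sim$structure
#' @export
simulateGenome <- function(config, seed = 1L) {
    stopifnot(is(config, "SimConfig"))
    if (config@embedMotifs && (config@irLen < 24L || config@sscLen < 24L))
        stop("irLen and sscLen must be >= 24 bp to embed the junction motifs")
    withr::with_seed(as.integer(seed), {
        lsc <- .randBases(config@lscLen)
        ir1 <- .randBases(config@irLen)
        ssc <- .randBases(config@sscLen)
        if (config@embedMotifs) {
            substr(ir1, config@irLen - 11L, config@irLen) <- .IR1_TAIL
            substr(ssc, 1L, 12L) <- .SSC_HEAD_F
            substr(ssc, config@sscLen - 11L, config@sscLen) <- .SSC_TAIL_F
        } else {
            ## keep the planted IR maximal at the SSC side
            if (substr(ssc, 1L, 1L) ==
                .revcompChr(substr(ssc, config@sscLen, config@sscLen)))
                substr(ssc, 1L, 1L) <- .otherBase(c(
                    substr(ssc, 1L, 1L)))
        }
        ## keep the planted IR maximal at the LSC side (circular junctions
        ## LSC|IR1 and IR2|LSC pair the LSC's last base with its first)
        if (substr(lsc, config@lscLen, config@lscLen) ==
            .revcompChr(substr(lsc, 1L, 1L)))
            substr(lsc, config@lscLen, config@lscLen) <-
                .otherBase(substr(lsc, config@lscLen, config@lscLen))
        ps <- config@plantedStrs
        if (nrow(ps)) {
            choices <- .parseChoices(ps$choices)
            for (i in seq_len(nrow(ps))) {
                p <- as.integer(ps$position[i])
                unit <- toupper(as.character(ps$unit[i]))
                copies <- as.integer(ps$refCopies[i])
                u <- nchar(unit)
                runLen <- u * copies
                maxCopies <- max(c(copies, choices[[i]]))
                if (p < 2L || p + u * maxCopies > config@lscLen)
                    stop("planted STR at position ", p,
                         " does not fit inside the LSC with its flanks")
                substr(lsc, p, p + runLen - 1L) <- strrep(unit, copies)
                ## block run extension on either side
                if (substr(lsc, p - 1L, p - 1L) == substr(unit, u, u))
                    substr(lsc, p - 1L, p - 1L) <-
                        .otherBase(substr(unit, u, u))
                after <- p + runLen
                if (substr(lsc, after, after) == substr(unit, 1L, 1L))
                    substr(lsc, after, after) <-
                        .otherBase(substr(unit, 1L, 1L))
            }
        }
        s <- paste0(lsc, ir1, ssc, .revcompChr(ir1))
        list(genome = circularGenome(s, id = "simulated"),
             structure = quadripartiteStructure(config@lscLen, config@irLen,
                                                config@sscLen))
    })
}

#' Simulate a pool of plastome molecules with known provenance
#'
#' Each molecule is independently SSC-reverse with probability `pReverse`
#' (via [flipSsc()]) and carries the IR-duplication variant with probability
#' `pIrDup` (via [applyIRDuplication()] with the configured scaled
#' [SVSpec-class]); the two flags are independent. Planted STR loci draw
#' their per-molecule copy number uniformly from the configured choices.
#' Provenance (orientation, SV status, STR copies) is recorded per molecule.
#'
#' @param genome,structure a canonical genome and its structure, typically
#'   from [simulateGenome()].
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return list with `seqs` (a [Biostrings::DNAStringSet]) and `info` (a
#'   `data.frame`: moleculeId, orientation, hasIrDup, one `strCopies.<pos>`
#'   column per planted locus).
#' @export
simulateMolecules <- function(genome, structure, config, seed = 1L) {
    stopifnot(is(config, "SimConfig"))
    .checkStructure(genome, structure)
    withr::with_seed(as.integer(seed) + 1L, {
        n <- config@nMolecules
        isR <- runif(n) < config@pReverse
        isDup <- runif(n) < config@pIrDup
        ps <- config@plantedStrs
        choices <- if (nrow(ps)) .parseChoices(ps$choices) else list()
        copyDraws <- lapply(choices, function(ch)
            ch[sample.int(length(ch), n, replace = TRUE)])
        flipped <- flipSsc(genome, structure)
        seqs <- character(n)
        for (i in seq_len(n)) {
            g <- if (isR[i]) flipped else genome
            if (isDup[i]) g <- applyIRDuplication(genome = g,
                                                  structure = structure,
                                                  sv = config@sv)
            s <- .seqChr(g)
            if (nrow(ps)) {
                ## apply per-molecule STR copies right-to-left so earlier
                ## positions stay valid
                for (j in order(-as.integer(ps$position))) {
                    p <- as.integer(ps$position[j])
                    unit <- toupper(as.character(ps$unit[j]))
                    refLen <- nchar(unit) * as.integer(ps$refCopies[j])
                    s <- paste0(substr(s, 1L, p - 1L),
                                strrep(unit, copyDraws[[j]][i]),
                                substr(s, p + refLen, nchar(s)))
                }
            }
            seqs[i] <- s
        }
        ids <- sprintf("mol%04d", seq_len(n))
        info <- data.frame(moleculeId = ids,
                           orientation = ifelse(isR, "R", "F"),
                           hasIrDup = isDup, stringsAsFactors = FALSE)
        if (nrow(ps))
            for (j in seq_len(nrow(ps)))
                info[[paste0("strCopies.", ps$position[j])]] <- copyDraws[[j]]
        seqs <- DNAStringSet(seqs)
        names(seqs) <- ids
        list(seqs = seqs, info = info)
    })
}

# apply uniform substitution/insertion/deletion errors to one read
.mutateRead <- function(s, errSub, errIns, errDel) {
    ch <- strsplit(s, "")[[1L]]
    bases <- c("A", "C", "G", "T")
    if (errDel > 0) ch <- ch[runif(length(ch)) >= errDel]
    n <- length(ch)
    if (n == 0L) return("")
    if (errSub > 0) {
        idx <- which(runif(n) < errSub)
        if (length(idx)) {
            repl <- bases[(match(ch[idx], bases) - 1L +
                           sample.int(3L, length(idx), replace = TRUE)) %% 4L + 1L]
            ch[idx] <- repl
        }
    }
    if (errIns > 0) {
        idx <- which(runif(n) < errIns)
        if (length(idx)) {
            ins <- sample(bases, length(idx), replace = TRUE)
            combined <- c(ch, ins)
            ch <- combined[order(c(seq_len(n), idx + 0.5))]
        }
    }
    paste(ch, collapse = "")
}

#' Simulate long reads from a molecule pool
#'
#' Per read: a molecule is picked uniformly, the start is uniform on the
#' circle, the length is lognormal (configured median and sigma, truncated
#' to the molecule length), the strand is uniform, and substitution /
#' insertion / deletion errors are applied at the configured per-base rates.
#' All reads are returned (length screening such as the full-scale 20-kb
#' rule happens downstream in [classifyReads()]) together with a provenance
#' table mapping each read to its source molecule, orientation, SV status,
#' start and strand.
#'
#' @param molecules list from [simulateMolecules()].
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @return list with `reads` (a named [Biostrings::DNAStringSet]) and
#'   `provenance` (a `data.frame`: readId, moleculeId, orientation,
#'   hasIrDup, start, strand, length).
#' @export
simulateReads <- function(molecules, config, seed = 1L) {
    stopifnot(is(config, "SimConfig"))
    withr::with_seed(as.integer(seed) + 2L, {
        seqs <- as.character(molecules$seqs)
        info <- molecules$info
        n <- config@nReads
        molIdx <- sample.int(length(seqs), n, replace = TRUE)
        lens <- pmax(50L, as.integer(round(
            rlnorm(n, meanlog = log(config@readLenMedian),
                   sdlog = config@readLenSigma))))
        out <- character(n)
        starts <- integer(n)
        strands <- character(n)
        for (i in seq_len(n)) {
            mol <- seqs[molIdx[i]]
            ml <- nchar(mol)
            len <- min(lens[i], ml)
            start <- sample.int(ml, 1L)
            r <- .circSubstr(mol, start, len)
            strand <- if (runif(1L) < 0.5) "+" else "-"
            if (strand == "-") r <- .revcompChr(r)
            if (config@errSub > 0 || config@errIns > 0 || config@errDel > 0)
                r <- .mutateRead(r, config@errSub, config@errIns,
                                 config@errDel)
            out[i] <- r
            starts[i] <- start
            strands[i] <- strand
        }
        ids <- sprintf("read%05d", seq_len(n))
        reads <- DNAStringSet(out)
        names(reads) <- ids
        prov <- data.frame(readId = ids,
                           moleculeId = info$moleculeId[molIdx],
                           orientation = info$orientation[molIdx],
                           hasIrDup = info$hasIrDup[molIdx],
                           start = starts, strand = strands,
                           length = nchar(out), stringsAsFactors = FALSE)
        list(reads = reads, provenance = prov)
    })
}
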