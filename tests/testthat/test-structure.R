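test_that("a planted maximal IR pair is partitioned exactly on the toy genome", {
    g <- toyQuadGenome()
    st <- findInvertedRepeats(g, minLen = 8, maxMismatchRate = 0)
    expect_identical(unname(regionWidths(st)), c(12L, 10L, 8L, 10L))
    expect_identical(canonicalOffset(st), 0L)
    expect_identical(irMismatches(st), 0L)
    expect_identical(start(lscRange(st)), 1L)
    expect_identical(start(ir1Range(st)), 13L)
    expect_identical(start(sscRange(st)), 23L)
    expect_identical(start(ir2Range(st)), 31L)
    ## agrees with the exhaustive oracle
    o <- oracleInvertedRepeat(as.character(genomeSeq(g)), 8)
    expect_identical(o$irLen, 10L)
    expect_identical(o$offset, 0L)
})

test_that("rotated input is restored by canonicalization, idempotently", {
    g <- toyQuadGenome()
    s <- as.character(genomeSeq(g))
    for (rot in c(7L, 23L, 39L)) {
        gr <- circularGenome(plastidSV:::.rotateLeft(s, rot))
        st <- findInvertedRepeats(gr, minLen = 8, maxMismatchRate = 0)
        can <- canonicalizeGenome(gr, st)
        expect_identical(as.character(genomeSeq(can$genome)), s)
        expect_identical(canonicalOffset(can$structure), 0L)
        can2 <- canonicalizeGenome(can$genome, can$structure)
        expect_identical(as.character(genomeSeq(can2$genome)), s)
    }
})

test_that("genomes without an adequate inverted repeat give a structured no-IR failure", {
    expect_error(findInvertedRepeats(circularGenome("ACGTACGTACGTACGT"),
                                     minLen = 8),
                 class = "noIRError")
    set.seed(5)
    ## random 1-kb sequence: no 100-bp IR
    s <- randomSeqChr(1000)
    expect_error(findInvertedRepeats(circularGenome(s), minLen = 100),
                 class = "noIRError")
    ## linear topology is rejected
    expect_error(findInvertedRepeats(
        circularGenome("ACGT", circular = FALSE), minLen = 1))
})

test_that("detection matches the brute-force oracle on random planted-IR genomes", {
    set.seed(424)
    for (case in seq_len(150)) {
        lsc <- sample(30:110, 1)
        ir <- sample(12:40, 1)
        ssc <- sample(10:min(lsc - 1L, 60), 1)
        s <- plantIRGenome(lsc, ir, ssc)
        o <- oracleInvertedRepeat(s, 10)
        st <- tryCatch(findInvertedRepeats(circularGenome(s), minLen = 10,
                                           maxMismatchRate = 0),
                       noIRError = function(e) NULL)
        if (is.null(o) || isTRUE(o$tie)) {
            expect_null(st)
        } else {
            expect_false(is.null(st))
            w <- regionWidths(st)
            expect_identical(unname(irLength(st)), o$irLen)
            expect_identical(unname(w[["lsc"]]), o$lscLen)
            expect_identical(unname(w[["ssc"]]), o$sscLen)
            expect_identical(unname(canonicalOffset(st)), o$offset)
        }
    }
})

test_that("detection tolerates IR mismatches within the budget and reports them", {
    set.seed(77)
    lsc <- randomSeqChr(400); ir <- randomSeqChr(120); ssc <- randomSeqChr(80)
    ir2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ir)))
    ## plant one substitution in the middle of IR2
    mid <- 60L
    old <- substr(ir2, mid, mid)
    substr(ir2, mid, mid) <- setdiff(c("A", "C", "G", "T"), old)[1]
    g <- circularGenome(paste0(lsc, ir, ssc, ir2))
    st <- findInvertedRepeats(g, minLen = 100, maxMismatchRate = 0.02)
    expect_identical(unname(irLength(st)), 120L)
    expect_identical(irMismatches(st), 1L)
    expect_lte(irMismatches(st), ceiling(0.02 * irLength(st)))
})

test_that("flipSsc reverse-complements exactly the SSC and is an involution", {
    g <- toyQuadGenome()
    st <- findInvertedRepeats(g, minLen = 8, maxMismatchRate = 0)
    f <- flipSsc(g, st)
    expect_identical(substr(as.character(genomeSeq(f)), 23, 30),
                     "CGGTAAAC")  # revcomp of GTTTACCG
    expect_identical(as.character(genomeSeq(flipSsc(f, st))),
                     as.character(genomeSeq(g)))
    ## property over random genomes
    set.seed(11)
    for (i in 1:10) {
        s <- plantIRGenome(200, 50, 80)
        st <- findInvertedRepeats(circularGenome(s), minLen = 40,
                                  maxMismatchRate = 0)
        can <- canonicalizeGenome(circularGenome(s), st)
        g2 <- flipSsc(can$genome, can$structure)
        expect_identical(as.character(genomeSeq(flipSsc(g2, can$structure))),
                         as.character(genomeSeq(can$genome)))
    }
})

test_that("haplotype pair members differ only inside the SSC and validate", {
    g <- toyQuadGenome()
    st <- findInvertedRepeats(g, minLen = 8, maxMismatchRate = 0)
    hp <- buildHaplotypePair(g, st)
    expect_true(validObject(hp))
    f <- as.character(genomeSeq(hapF(hp)))
    r <- as.character(genomeSeq(hapR(hp)))
    expect_identical(nchar(f), nchar(r))
    diffs <- which(strsplit(f, "")[[1]] != strsplit(r, "")[[1]])
    expect_true(all(diffs >= 23 & diffs <= 30))
})

test_that("IR duplication follows the insert-length contract and junction layout", {
    set.seed(303)
    lsc <- randomSeqChr(800); ir <- randomSeqChr(200); ssc <- randomSeqChr(100)
    g <- circularGenome(paste0(
        lsc, ir, ssc,
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(ir)))))
    st <- quadripartiteStructure(800, 200, 100)
    sv <- svSpec(d1Len = 30, i1Len = 50, insertPrefix = "ATTTT")
    mut <- applyIRDuplication(g, st, sv)
    expect_identical(seqLength(mut) - seqLength(g),
                     5L + 50L + 200L - 30L)
    ## junction organization IR1d - prefix - i1 - IR1
    ir1d <- substr(ir, 1, 170)
    i1 <- substr(lsc, 1, 50)
    expect_true(grepl(paste0(ir1d, "ATTTT", i1, ir),
                      as.character(genomeSeq(mut)), fixed = TRUE))
    ## degenerate spec duplicates IR in place
    mut0 <- applyIRDuplication(g, st, svSpec(0, 0, ""))
    expect_identical(seqLength(mut0) - seqLength(g), 200L)
    expect_true(grepl(paste0(ir, ir), as.character(genomeSeq(mut0)),
                      fixed = TRUE))
    ## length delta property over random specs
    for (i in 1:10) {
        d1 <- sample(0:150, 1); i1len <- sample(0:300, 1)
        pre <- randomSeqChr(sample(0:10, 1))
        m <- applyIRDuplication(g, st, svSpec(d1, i1len, pre))
        expect_identical(seqLength(m) - seqLength(g),
                         as.integer(nchar(pre) + i1len + 200L - d1))
    }
    expect_error(applyIRDuplication(g, st, svSpec(200, 10, "")), "d1Len")
})

test_that("IR loss removes one full IR copy and breaks re-detection", {
    g <- toyQuadGenome()
    st <- findInvertedRepeats(g, minLen = 8, maxMismatchRate = 0)
    mut <- applyIRLoss(g, st)
    expect_identical(seqLength(mut), 30L)
    expect_identical(as.character(genomeSeq(mut)),
                     paste0("ACGTACGTACGA", "AAGGCTAGCT", "GTTTACCG"))
    ## re-detection fails in a structured way (no disjoint second copy:
    ## either nothing adequate remains or only palindromic self-overlaps)
    err <- tryCatch(findInvertedRepeats(mut, minLen = 8, maxMismatchRate = 0),
                    condition = function(e) e)
    expect_true(inherits(err, "noIRError") || inherits(err, "palindromeError"))
})

test_that("rice-scale SV parameters reproduce the published arithmetic", {
    sv <- svSpec()   # d1 = 319, i1 = 2000, prefix ATTTT
    expect_identical(insertLength(sv, irLen = 20805L), 22810L)
    expect_identical(insertLength(sv, irLen = 20805L) - sv@d1Len, 22491L)
})
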