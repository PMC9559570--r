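test_that("an exact substring maps as a single full-identity block", {
    fx <- simFixture()
    s <- as.character(genomeSeq(fx$genome))
    read <- substr(s, 2001, 3000)
    aln <- mapRead(read, fx$genome, readId = "sub")
    expect_identical(length(aln@blocksRead), 1L)
    expect_equal(alignmentIdentity(aln), 1.0)
    expect_equal(alignedReadFraction(aln), 1.0)
    expect_identical(start(aln@blocksRef), 2001L)
    expect_identical(aln@strand, "+")
    ## reverse-complement maps on the minus strand at the same locus
    rc <- plastidSV:::.revcompChr(read)
    aln2 <- mapRead(rc, fx$genome, readId = "subrc")
    expect_identical(aln2@strand, "-")
    expect_identical(start(aln2@blocksRef), 2001L)
})

test_that("reads crossing the circle origin still align contiguously", {
    fx <- simFixture()
    s <- as.character(genomeSeq(fx$genome))
    L <- nchar(s)
    read <- plastidSV:::.circSubstr(s, L - 499L, 1200L)
    aln <- mapRead(read, fx$genome, readId = "wrap")
    expect_equal(alignedReadFraction(aln), 1.0)
    expect_equal(alignmentIdentity(aln), 1.0)
})

test_that("a junction-crossing read breaks at the junction on the wrong haplotype", {
    fx <- simFixture()
    st <- fx$structure
    sF <- as.character(genomeSeq(hapF(fx$pair)))
    s1 <- start(ir1Range(st)); e1 <- end(ir1Range(st))
    ## LSC(300) + all of IR1 + SSC(400), from the F haplotype
    read <- substr(sF, s1 - 300L, e1 + 400L)
    alnF <- mapRead(read, hapF(fx$pair), readId = "jx")
    expect_equal(alignedReadFraction(alnF), 1.0)
    expect_equal(alignmentIdentity(alnF), 1.0)
    ## on the R haplotype the alignment cannot bridge the flipped ssc: the
    ## best strand leaves the mismatching arm unaligned
    alnR <- mapRead(read, hapR(fx$pair), readId = "jx")
    expect_lt(alignedReadFraction(alnR), 0.9)
    ## without an LSC anchor an IR+SSC fragment is orientation-blind: it
    ## maps completely to both haplotypes (via opposite strands), which is
    ## exactly why classification demands full IR1 coverage plus both
    ## overhangs
    frag <- substr(sF, e1 - 599L, e1 + 400L)
    expect_equal(alignedReadFraction(
        mapRead(frag, hapF(fx$pair), readId = "fr")), 1.0)
    expect_equal(alignedReadFraction(
        mapRead(frag, hapR(fx$pair), readId = "fr")), 1.0)
})

test_that("substitution errors reduce identity proportionately", {
    fx <- simFixture()
    s <- as.character(genomeSeq(fx$genome))
    set.seed(55)
    read <- substr(s, 4001, 6000)
    ch <- strsplit(read, "")[[1]]
    idx <- sample(2000, 40)   # 2% substitutions
    ch[idx] <- vapply(ch[idx], function(b)
        setdiff(c("A", "C", "G", "T"), b)[sample(3, 1)], "")
    noisy <- paste(ch, collapse = "")
    aln <- mapRead(noisy, fx$genome, readId = "noisy")
    expect_gte(alignmentIdentity(aln), 0.97)
    expect_gte(alignedReadFraction(aln), 0.99)
})

test_that("mapping is deterministic and empty for foreign sequence", {
    fx <- simFixture()
    set.seed(66)
    read <- substr(as.character(genomeSeq(fx$genome)), 100, 1500)
    a1 <- mapRead(read, fx$genome, readId = "det")
    a2 <- mapRead(read, fx$genome, readId = "det")
    expect_identical(a1@blocksRef, a2@blocksRef)
    expect_identical(a1@nmatch, a2@nmatch)
    foreign <- randomSeqChr(800)
    a3 <- mapRead(foreign, fx$genome, readId = "foreign")
    expect_equal(alignedReadFraction(a3), 0)
})
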