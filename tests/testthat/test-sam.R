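writeSamFixture <- function(path) {
    rep50 <- function(b, n) paste(rep(b, n), collapse = "")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        "@SQ\tSN:hapF\tLN:2000",
        "@SQ\tSN:hapR\tLN:2000",
        paste0("r1\t0\thapF\t101\t60\t500M\t*\t0\t0\t",
               rep50("A", 500), "\t*\tNM:i:2"),
        paste0("r2\t0\thapF\t11\t60\t300M200S\t*\t0\t0\t",
               rep50("C", 500), "\t*\tNM:i:0"),
        paste0("r2\t2048\thapF\t401\t60\t300H200M\t*\t0\t0\t",
               rep50("C", 200), "\t*\tNM:i:0"),
        paste0("r4\t0\thapR\t51\t60\t10S100M5D40M\t*\t0\t0\t",
               rep50("G", 150), "\t*\tNM:i:5")
    ), path)
    path
}

test_that("SAM records import as block-structured alignments", {
    sam <- writeSamFixture(tempfile(fileext = ".sam"))
    alns <- importAlignments(sam, refNames = c("hapF", "hapR"))
    byId <- setNames(alns, vapply(alns, function(a) a@readId, ""))
    ## one primary 500M record: a single 500-bp block
    a <- byId[["r1"]]
    expect_identical(length(a@blocksRead), 1L)
    expect_identical(width(a@blocksRef), 500L)
    expect_identical(start(a@blocksRef), 101L)
    expect_equal(alignedReadFraction(a), 1.0)
    expect_equal(alignmentIdentity(a), 498 / 500)
    ## primary 300M + supplementary 200M merge to 500 aligned bp
    b <- byId[["r2"]]
    expect_identical(length(b@blocksRead), 2L)
    expect_identical(sum(width(b@blocksRead)), 500L)
    expect_identical(start(b@blocksRef), c(11L, 401L))
    expect_equal(alignedReadFraction(b), 1.0)
    ## deletions split reference blocks; soft clips dilute the fraction
    d <- byId[["r4"]]
    expect_identical(length(d@blocksRead), 2L)
    expect_identical(start(d@blocksRef), c(51L, 156L))
    expect_equal(alignedReadFraction(d), 140 / 150)
})

test_that("records naming an unknown reference are dropped", {
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        "@SQ\tSN:hapF\tLN:2000",
        "@SQ\tSN:decoy\tLN:500",
        paste0("ok\t0\thapF\t1\t60\t50M\t*\t0\t0\t",
               strrep("A", 50), "\t*"),
        paste0("bad\t0\tdecoy\t1\t60\t50M\t*\t0\t0\t",
               strrep("C", 50), "\t*")
    ), sam)
    expect_warning(alns <- importAlignments(sam, refNames = "hapF"),
                   "skipped")
    expect_identical(vapply(alns, function(a) a@readId, ""), "ok")
})

test_that("imported alignments drive junction classification like native ones", {
    fx <- simFixture()
    st <- fx$structure
    s1 <- start(ir1Range(st)); e1 <- end(ir1Range(st))
    sF <- as.character(genomeSeq(hapF(fx$pair)))
    read <- substr(sF, s1 - 300L, e1 + 300L)
    sam <- tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6\tSO:unsorted",
        paste0("@SQ\tSN:", genomeId(hapF(fx$pair)), "\tLN:",
               seqLength(hapF(fx$pair))),
        paste0("@SQ\tSN:", genomeId(hapR(fx$pair)), "\tLN:",
               seqLength(hapR(fx$pair))),
        paste0("jx\t0\t", genomeId(hapF(fx$pair)), "\t", s1 - 300L,
               "\t60\t", nchar(read), "M\t*\t0\t0\t", read, "\t*\tNM:i:0")
    ), sam)
    alns <- importAlignments(sam)
    expect_identical(length(alns), 1L)
    aR <- plastidSV:::.emptyAlignment("jx", genomeId(hapR(fx$pair)),
                                      nchar(read))
    call <- classifyJunctionRead(alns[[1]], aR, st)
    expect_identical(call$label, "forward")
})
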