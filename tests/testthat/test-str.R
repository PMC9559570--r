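test_that("STR loci are detected with hand-countable positions and copies", {
    loci <- findSTRLoci("GGAAAAAATC")
    expect_identical(nrow(loci), 1L)
    expect_identical(loci$position, 3L)
    expect_identical(loci$unit, "A")
    expect_identical(loci$refCopies, 6L)
    expect_identical(loci$notation, "3[A]6")
    loci2 <- findSTRLoci("ACACACAC", minCopies = c(6, 3))
    expect_identical(loci2$position, 1L)
    expect_identical(loci2$unit, "AC")
    expect_identical(loci2$refCopies, 4L)
    ## a 12-A run is one homopolymer locus, never an [AA] run
    loci3 <- findSTRLoci(paste0("GC", strrep("A", 12), "GC"))
    expect_identical(nrow(loci3), 1L)
    expect_identical(loci3$unit, "A")
    expect_identical(loci3$refCopies, 12L)
})

test_that("reported loci are maximal and units canonical", {
    set.seed(31)
    for (i in 1:20) {
        s <- paste0(randomSeqChr(40), strrep("TA", sample(3:6, 1)),
                    randomSeqChr(40), strrep("T", sample(6:10, 1)),
                    randomSeqChr(40))
        loci <- findSTRLoci(s)
        for (j in seq_len(nrow(loci))) {
            p <- loci$position[j]; u <- nchar(loci$unit[j])
            runLen <- loci$length[j]
            run <- substr(s, p, p + runLen - 1L)
            unitObs <- substr(s, p, p + u - 1L)
            ## the run is the unit repeated
            expect_identical(run, strrep(unitObs, loci$refCopies[j]))
            ## not extendable by one more full unit on either side
            before <- substr(s, p - u, p - 1L)
            after <- substr(s, p + runLen, p + runLen + u - 1L)
            expect_false(identical(before, unitObs))
            expect_false(identical(after,
                                   substr(strrep(unitObs, 2), 1L,
                                          nchar(after))) &&
                         nchar(after) == u)
            ## canonical unit is the least rotation
            expect_identical(loci$unit[j],
                             plastidSV:::.leastRotation(unitObs))
        }
    }
})

test_that("notation formatting and parsing round-trip, including subscripts", {
    paper <- c("11291[T]_7-8_", "31462[T]_7-8_", "36488[T]_9-10_",
               "49216[T]_10-15_", "63462[A]_6-9_", "80673[A]_2-3_",
               "102303[A]_6-8_", "107081[A]_6-7_", "111165[A]_6-8_")
    df <- parseStrNotation(paper)
    expect_identical(nrow(df), 9L)
    expect_identical(df$position[1], 11291L)
    expect_identical(df$copyMin[4], 10L)
    expect_identical(df$copyMax[4], 15L)
    expect_identical(formatStrNotation(df),
                     gsub("_", "", paper, fixed = TRUE))
    ## random round trips
    set.seed(8)
    rand <- data.frame(position = sample(1e5, 20),
                       unit = replicate(20, randomSeqChr(sample(1:4, 1))),
                       copyMin = sample(2:9, 20, replace = TRUE))
    rand$copyMax <- rand$copyMin + sample(0:5, 20, replace = TRUE)
    back <- parseStrNotation(formatStrNotation(rand))
    expect_identical(back[, c("position", "unit", "copyMin", "copyMax")],
                     rand[, c("position", "unit", "copyMin", "copyMax")])
    expect_error(parseStrNotation("x[T]7"), "malformed")
    expect_error(parseStrNotation("100[T]9-7"), "malformed")
})

test_that("planted homopolymer CNV is recovered exactly from error-free reads", {
    ps <- data.frame(position = c(2000L, 3200L), unit = c("T", "A"),
                     refCopies = c(7L, 8L), choices = c("7,8", "8"),
                     stringsAsFactors = FALSE)
    cfg <- simConfig(lscLen = 4000, irLen = 600, sscLen = 400,
                     readLenMedian = 1500, readLenSigma = 0.3,
                     nReads = 150, nMolecules = 40, plantedStrs = ps)
    sim <- simulateGenome(cfg, seed = 21)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 21)
    rd <- simulateReads(mols, cfg, seed = 21)
    idx <- buildMapIndex(sim$genome)
    alns <- lapply(seq_along(rd$reads), function(i)
        mapRead(as.character(rd$reads[[i]]), idx,
                readId = names(rd$reads)[i]))
    loci <- findSTRLoci(sim$genome)
    loci <- loci[loci$position %in% ps$position & loci$unit %in% ps$unit, ]
    expect_identical(nrow(loci), 2L)
    res <- strCopyNumbers(loci, rd$reads, alns, sim$genome)
    cnv <- res[res$position == 2000L, ]
    expect_true(cnv$callable)
    expect_identical(cnv$copyMin, 7L)
    expect_identical(cnv$copyMax, 8L)
    expect_true(cnv$isCnv)
    expect_identical(cnv$notation, "2000[T]7-8")
    fixed <- res[res$position == 3200L, ]
    expect_identical(fixed$copyMin, 8L)
    expect_identical(fixed$copyMax, 8L)
    expect_false(fixed$isCnv)
})

test_that("planted CNV survives 1% indel noise given enough spanning reads", {
    ps <- data.frame(position = 2000L, unit = "T", refCopies = 7L,
                     choices = "7,8", stringsAsFactors = FALSE)
    cfg <- simConfig(lscLen = 4000, irLen = 600, sscLen = 400,
                     readLenMedian = 1500, readLenSigma = 0.3,
                     nReads = 150, nMolecules = 40, plantedStrs = ps,
                     errIns = 0.005, errDel = 0.005)
    sim <- simulateGenome(cfg, seed = 33)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 33)
    rd <- simulateReads(mols, cfg, seed = 33)
    idx <- buildMapIndex(sim$genome)
    alns <- lapply(seq_along(rd$reads), function(i)
        mapRead(as.character(rd$reads[[i]]), idx,
                readId = names(rd$reads)[i]))
    loci <- data.frame(position = 2000L, unit = "T", refCopies = 7L)
    res <- strCopyNumbers(loci, rd$reads, alns, sim$genome)
    expect_gte(res$nSpanning, 20L)
    expect_true(res$callable)
    expect_lte(res$copyMin, 7L)
    expect_gte(res$copyMax, 8L)
    ## the two planted copy numbers are the best-supported ones
    sup <- do.call(rbind, lapply(strsplit(strsplit(res$support, ",")[[1]],
                                          ":"), as.integer))
    top2 <- sup[order(-sup[, 2])[1:2], 1]
    expect_setequal(top2, c(7L, 8L))
})

test_that("loci without spanning reads are uncallable, not errors", {
    loci <- data.frame(position = 3000L, unit = "T", refCopies = 7L)
    fx <- simFixture()
    res <- strCopyNumbers(loci, Biostrings::DNAStringSet(), list(),
                          fx$genome)
    expect_false(res$callable)
    expect_identical(res$nSpanning, 0L)
})
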