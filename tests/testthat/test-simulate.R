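test_that("the generator is deterministic per seed and sensitive to it", {
    cfg <- simConfig()
    g1 <- simulateGenome(cfg, seed = 7)
    g2 <- simulateGenome(cfg, seed = 7)
    g3 <- simulateGenome(cfg, seed = 8)
    expect_identical(as.character(genomeSeq(g1$genome)),
                     as.character(genomeSeq(g2$genome)))
    expect_false(identical(as.character(genomeSeq(g1$genome)),
                           as.character(genomeSeq(g3$genome))))
    ## byte-identical FASTA across runs
    f1 <- tempfile(); f2 <- tempfile()
    writeFasta(g1$genome, f1); writeFasta(g2$genome, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("structure detection recovers the planted partition exactly", {
    for (seed in c(1, 2, 3)) {
        sim <- simulateGenome(simConfig(), seed = seed)
        st <- findInvertedRepeats(sim$genome, minLen = 500)
        expect_identical(regionWidths(st), regionWidths(sim$structure))
        expect_identical(canonicalOffset(st), 0L)
        expect_identical(irMismatches(st), 0L)
    }
})

test_that("motif embedding produces the F signature and flips to R", {
    sim <- simulateGenome(simConfig(), seed = 19)
    expect_identical(
        screenJunctionSignature(sim$genome,
                                structure = sim$structure)$junctionType, "F")
    expect_identical(
        screenJunctionSignature(flipSsc(sim$genome, sim$structure),
                                structure = sim$structure)$junctionType, "R")
})

test_that("orientation and SV flags follow their configured probabilities", {
    sim <- simulateGenome(simConfig(), seed = 2)
    cfg0 <- simConfig(pReverse = 0, nMolecules = 40)
    m0 <- simulateMolecules(sim$genome, sim$structure, cfg0, seed = 2)
    expect_true(all(m0$info$orientation == "F"))
    cfgD <- simConfig(pIrDup = 1, nMolecules = 10)
    mD <- simulateMolecules(sim$genome, sim$structure, cfgD, seed = 2)
    delta <- insertLength(cfgD@sv, irLength(sim$structure)) - cfgD@sv@d1Len
    expect_true(all(width(mD$seqs) == seqLength(sim$genome) + delta))
    ## binomial bound at the default mixture
    cfgP <- simConfig(pReverse = 0.55, nMolecules = 400)
    mP <- simulateMolecules(sim$genome, sim$structure, cfgP, seed = 5)
    pHat <- mean(mP$info$orientation == "R")
    expect_lt(abs(pHat - 0.55), 3 * sqrt(0.55 * 0.45 / 400))
})

test_that("zero-error reads are exact circular substrings with true provenance", {
    fx <- simFixture()
    mols <- as.character(fx$molecules$seqs)
    prov <- fx$provenance
    for (i in sample(length(fx$reads), 25)) {
        mol <- mols[[prov$moleculeId[i]]]
        expected <- plastidSV:::.circSubstr(mol, prov$start[i],
                                            prov$length[i])
        if (prov$strand[i] == "-")
            expected <- plastidSV:::.revcompChr(expected)
        expect_identical(as.character(fx$reads[[i]]), expected)
    }
})

test_that("substitution errors hit at the configured rate", {
    sim <- simulateGenome(simConfig(), seed = 3)
    cfg <- simConfig(nMolecules = 5, nReads = 60, errSub = 0.01,
                     readLenMedian = 3000, readLenSigma = 0.1)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 3)
    rd <- simulateReads(mols, cfg, seed = 3)
    molSeqs <- as.character(mols$seqs)
    mism <- 0L; total <- 0L
    for (i in seq_along(rd$reads)) {
        p <- rd$provenance[i, ]
        src <- plastidSV:::.circSubstr(molSeqs[[p$moleculeId]], p$start,
                                       p$length)
        if (p$strand == "-") src <- plastidSV:::.revcompChr(src)
        obs <- as.character(rd$reads[[i]])
        mism <- mism + sum(utf8ToInt(obs) != utf8ToInt(src))
        total <- total + nchar(src)
    }
    expect_gte(total, 1e5)
    expect_gte(mism / total, 0.008)
    expect_lte(mism / total, 0.012)
})

test_that("read lengths reproduce the configured lognormal median", {
    sim <- simulateGenome(simConfig(), seed = 4)
    cfg <- simConfig(nMolecules = 3, nReads = 5000, readLenMedian = 4000)
    mols <- simulateMolecules(sim$genome, sim$structure, cfg, seed = 4)
    rd <- simulateReads(mols, cfg, seed = 4)
    expect_lt(abs(median(rd$provenance$length) - 4000) / 4000, 0.05)
})

test_that("invalid generator configurations are rejected", {
    expect_error(simConfig(lscLen = 100, sscLen = 200), "exceed")
    expect_error(simConfig(errSub = 0.5), "0.2")
    expect_error(simConfig(pReverse = 1.5), "\\[0, 1\\]")
    ps <- data.frame(position = 7995L, unit = "T", refCopies = 9L,
                     choices = "9")
    expect_error(simulateGenome(simConfig(plantedStrs = ps), seed = 1),
                 "does not fit")
})

test_that("the full-scale preset carries the published region lengths", {
    cfg <- simConfig(preset = "paper")
    expect_identical(cfg@lscLen, 80553L)
    expect_identical(cfg@irLen, 20805L)
    expect_identical(cfg@sscLen, 12346L)
    expect_identical(cfg@minReadLen, 20000L)
    expect_identical(cfg@sv@d1Len, 319L)
    expect_identical(insertLength(cfg@sv, cfg@irLen), 22810L)
})
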