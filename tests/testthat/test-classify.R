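test_that("constructed junction reads obey the spanning criteria", {
    fx <- simFixture()
    st <- fx$structure
    sF <- as.character(genomeSeq(hapF(fx$pair)))
    s1 <- start(ir1Range(st)); e1 <- end(ir1Range(st))
    idxF <- buildMapIndex(hapF(fx$pair))
    idxR <- buildMapIndex(hapR(fx$pair))
    classify <- function(read, ...) {
        aF <- mapRead(read, idxF, readId = "r")
        aR <- mapRead(read, idxR, readId = "r")
        classifyJunctionRead(aF, aR, st, ...)
    }
    ## LSC(300) - all of IR1 - SSC(300): a textbook forward junction read
    read <- substr(sF, s1 - 300L, e1 + 300L)
    expect_identical(classify(read)$label, "forward")
    ## same read on the flipped haplotype is a reverse junction read
    sR <- as.character(genomeSeq(hapR(fx$pair)))
    expect_identical(classify(substr(sR, s1 - 300L, e1 + 300L))$label,
                     "reverse")
    ## only 150 bp into the SSC: fails the 200-bp overhang rule
    expect_identical(classify(substr(sF, s1 - 300L, e1 + 150L))$label,
                     "non_junction")
    ## read entirely inside IR1: no overhangs at all
    expect_identical(classify(substr(sF, s1 + 100L, e1 - 100L))$label,
                     "non_junction")
    ## incomplete IR coverage fails the 100% rule
    expect_identical(classify(substr(sF, s1 + 10L, e1 + 300L))$label,
                     "non_junction")
})

test_that("classification is perfectly accurate on error-free provenance reads", {
    m <- classifiedFixture()
    jr <- m[m$label %in% c("forward", "reverse"), ]
    expect_gt(nrow(jr), 20)
    expect_identical(sum(m$label == "ambiguous"), 0L)
    expect_true(all((jr$label == "forward") == (jr$orientation == "F")))
})

test_that("raising the overhang threshold never gains junction reads", {
    fx <- simFixture()
    sub <- fx$reads[1:120]
    n <- sapply(c(100L, 200L, 400L), function(mo) {
        calls <- classifyReads(sub, fx$pair, minOverhang = mo)
        sum(calls$label %in% c("forward", "reverse"))
    })
    expect_true(all(diff(n) <= 0))
})

test_that("the read-length pre-filter drops short reads from classification", {
    fx <- simFixture()
    sub <- fx$reads[1:80]
    all <- classifyReads(sub, fx$pair)
    screened <- classifyReads(sub, fx$pair, minReadLen = 3000L)
    expect_identical(nrow(screened), sum(width(sub) >= 3000L))
    expect_lte(nrow(screened), nrow(all))
})

test_that("orientation summary reproduces the printed 82/99 arithmetic", {
    rep <- summarizeOrientation(nForward = 82, nReverse = 99)
    expect_equal(round(rep@propForward, 2), 0.45)
    expect_equal(round(rep@propReverse, 2), 0.55)
    expect_equal(rep@ratioPrinted, 0.82)
    expect_equal(rep@ratio, 82 / 99, tolerance = 1e-12)
    expect_true(rep@ciLow < 82 / 181 & rep@ciHigh > 82 / 181)
})

test_that("orientation summary handles symmetry and emptiness", {
    rep <- summarizeOrientation(nForward = 50, nReverse = 50)
    expect_equal(rep@ratio, 1)
    expect_equal(rep@ratioPrinted, 1)
    expect_equal(mean(c(rep@ciLow, rep@ciHigh)), 0.5, tolerance = 1e-9)
    rep0 <- summarizeOrientation(nForward = 0, nReverse = 0,
                                 nNonJunction = 5)
    expect_true(is.na(rep0@ratio))
    expect_true(is.na(rep0@propForward))
    expect_identical(rep0@nNonJunction, 5L)
})

test_that("the Wilson interval matches its closed form and stays in [0,1]", {
    ci <- wilsonInterval(82, 181)
    p <- 82 / 181; n <- 181; z <- qnorm(0.975)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    expect_equal(mean(ci), centre, tolerance = 1e-12)
    expect_true(all(wilsonInterval(0, 10) >= 0))
    expect_true(all(wilsonInterval(10, 10) <= 1))
})
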