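test_that("iid log-probability is the product of symbol frequencies", {
    u <- iidModel(setNames(rep(0.25, 4), c("A", "C", "G", "T")))
    expect_equal(iidLogProb(u, "ACG"), log(1 / 64))
    expect_equal(iidLogProb(u, ""), 0)
    m <- iidModel(c(A = 0.7, B = 0.3))
    expect_equal(iidLogProb(m, "AAB"), log(0.7 * 0.7 * 0.3))
    expect_error(iidLogProb(m, "AXB"), "position 2")
})

test_that("iid model enforces positive, normalized frequencies", {
    expect_error(new("IIDModel", alphabet = c("A", "B"),
                     freqs = c(A = 0.5, B = 0.6)), "sum to 1")
    expect_error(iidModel(c(A = 1, B = 0)), "positive")
})

test_that("iid sampling is reproducible and matches the frequencies", {
    m <- iidModel(c(A = 0.7, B = 0.3))
    expect_identical(sampleIID(m, 0), "")
    one <- iidModel(c(A = 1 - 1e-15, B = 1e-15))
    set.seed(1)
    expect_identical(sampleIID(iidModel(c(A = 1, B = 1e-300)), 5), "AAAAA")
    set.seed(7)
    n <- 1e5
    draws <- AlignTails:::seqChars(sampleIID(m, n))
    phat <- mean(draws == "A")
    se <- sqrt(0.7 * 0.3 / n)
    expect_lt(abs(phat - 0.7), 3 * se)
    set.seed(11)
    a <- sampleIID(m, 50)
    set.seed(11)
    expect_identical(sampleIID(m, 50), a)
})

test_that("a single-state HMM collapses to the i.i.d. chain", {
    em <- matrix(c(0.8, 0.2), 1, 2)
    h <- hiddenMarkovModel("s", 1, em, matrix(1, 1, 1),
                           alphabet = toyAlphabet2)
    x <- "ABBA"
    expect_equal(forwardLogProb(h, x)$log_prob,
                 iidLogProb(iidModel(c(A = 0.8, B = 0.2)), x))
    expect_identical(viterbiPath(h, x)$path, rep("s", 4))
})

test_that("forward equals brute-force path enumeration and is complete", {
    h <- toyHMM2()
    for (x in c("ABBA", "AAAA", "BABB")) {
        expect_equal(forwardLogProb(h, x)$log_prob,
                     log(AlignTails:::forwardBrute(h, x)))
    }
    for (L in 2:4) {
        tot <- sum(vapply(allSeqsOf(toyAlphabet2, L), function(s)
            exp(forwardLogProb(h, s)$log_prob), numeric(1)))
        expect_equal(tot, 1, tolerance = 1e-9)
    }
})

test_that("Viterbi equals enumeration and never exceeds forward", {
    set.seed(21)
    h <- toyHMM2()
    for (x in allSeqsOf(toyAlphabet2, 4)) {
        v <- viterbiPath(h, x)
        b <- AlignTails:::viterbiBrute(h, x)
        expect_equal(v$log_prob, log(b$prob))
        expect_identical(v$path, b$path)
    }
    for (i in 1:100) {
        hh <- randomToyHMM(K = sample(2:3, 1))
        x <- randomSeq(toyAlphabet2, 5)
        expect_lte(viterbiPath(hh, x)$log_prob,
                   forwardLogProb(hh, x)$log_prob + 1e-12)
    }
})

test_that("helix counting equals a run-length-encoding oracle", {
    h <- toyHMM2()
    expect_identical(countTMHelices(rep("loop", 5), h), 0L)
    expect_identical(countTMHelices(c("core", "core", "loop", "core"), h), 2L)
    set.seed(5)
    for (i in 1:50) {
        p <- sample(c("loop", "core"), 12, replace = TRUE)
        r <- rle(p)
        expect_identical(countTMHelices(p, h),
                         sum(r$values == "core"))
    }
})

test_that("HMM files round-trip bit-exactly and invalid rows are rejected", {
    h <- toyHMM2()
    f <- tempfile(fileext = ".hmm")
    writeHMM(h, f)
    h2 <- readHMM(f)
    expect_identical(h2@emissions, h@emissions)
    expect_identical(h2@transitions, h@transitions)
    expect_identical(h2@initial, h@initial)
    expect_identical(h2@helixCoreStates, h@helixCoreStates)
    ## corrupt one transition row so it sums to 0.9
    ln <- readLines(f)
    i <- grep("^trans loop", ln)
    ln[i] <- "trans loop 0.5 0.4"
    f2 <- tempfile()
    writeLines(ln, f2)
    expect_error(readHMM(f2), "trans.*loop.*sum|row loop")
    ## unknown tie reference
    ln2 <- readLines(f)
    writeLines(c(ln2, "tie loop nosuchstate"), f2)
    expect_error(readHMM(f2), "unknown state|tie")
})

test_that("HMM sampling produces sequences the model can emit", {
    set.seed(9)
    h <- toyHMM2()
    s <- sampleHMM(h, 20)
    expect_identical(nchar(s$seq), 20L)
    expect_identical(length(s$path), 20L)
    expect_true(all(s$path %in% h@states))
    expect_gt(forwardLogProb(h, s$seq)$log_prob, -Inf)
})
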