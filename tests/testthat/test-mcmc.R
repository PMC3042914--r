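test_that("the five elementary moves act exactly as specified", {
    s <- "LGQIWTAE"
    expect_identical(applyMove(s, "substitute", 5, "D"), "LGQIDTAE")
    expect_identical(applyMove(s, "insert_left_shift", 5, "D"), "GQIWDTAE")
    expect_identical(applyMove(s, "insert_right_shift", 5, "D"), "LGQIDWTA")
    expect_identical(applyMove(s, "delete_right_shift", 5, "D"), "DLGQITAE")
    expect_identical(applyMove(s, "delete_left_shift", 5, "D"), "LGQITAED")
    expect_error(applyMove(s, "substitute", 9, "D"), "out of range")
    expect_error(applyMove(s, "substitute", 0, "D"), "out of range")
})

test_that("compiled and reference move implementations agree", {
    set.seed(41)
    ab <- aaAlphabet()
    for (i in 1:200) {
        L <- sample(2:12, 1)
        x <- randomSeq(ab, L)
        kind <- sample(moveKinds(), 1)
        pos <- sample.int(L, 1)
        sym <- sample(ab, 1)
        ref <- applyMove(x, kind, pos, sym)
        got <- AlignTails:::cpp_apply_move(
            AlignTails:::seqToInt(x, ab),
            match(kind, moveKinds()) - 1L, pos,
            match(sym, ab) - 1L)
        expect_identical(AlignTails:::intToSeq(got, ab), ref)
    }
})

test_that("moves preserve length and edits are local", {
    set.seed(42)
    for (i in 1:50) {
        x <- randomSeq(toyAlphabet3, 8)
        k <- sample(moveKinds(), 1)
        y <- applyMove(x, k, sample.int(8, 1), sample(toyAlphabet3, 1))
        expect_identical(nchar(y), nchar(x))
    }
})

test_that("proposals use the prescribed kind and sequence probabilities", {
    set.seed(43)
    model <- toyIID2()
    n <- 1e5
    kinds <- character(n)
    which <- character(n)
    for (i in seq_len(n)) {
        p <- proposeMove("ABAB", "BABA", model)
        kinds[i] <- p$kind
        which[i] <- p$which
    }
    pk <- table(factor(kinds, levels = moveKinds())) / n
    expected <- c(0.5, 0.125, 0.125, 0.125, 0.125)
    for (j in 1:5) {
        se <- sqrt(expected[j] * (1 - expected[j]) / n)
        expect_lt(abs(pk[[j]] - expected[j]), 3.5 * se)
    }
    expect_lt(abs(mean(which == "x") - 0.5), 3.5 * sqrt(0.25 / n))
    ## fixed query: the subject is always chosen
    fq <- fixedQueryModel("ABAB", toyIID2())
    for (i in 1:100) expect_identical(proposeMove("ABAB", "BABA", fq)$which,
                                      "y")
})

test_that("frequency-weighted proposals cancel the null ratio exactly", {
    set.seed(44)
    model <- toyIID2()
    for (i in seq_len(2000)) {
        x <- randomSeq(toyAlphabet2, 6)
        y <- randomSeq(toyAlphabet2, 6)
        p <- proposeMove(x, y, model)
        x2 <- if (p$which == "x") p$candidate else x
        y2 <- if (p$which == "y") p$candidate else y
        dNull <- (iidLogProb(model, x2) + iidLogProb(model, y2)) -
            (iidLogProb(model, x) + iidLogProb(model, y))
        expect_equal(p$logRatio + dNull, 0, tolerance = 1e-12)
    }
})

test_that("uniform weights give Metropolis acceptance 1 everywhere", {
    set.seed(45)
    model <- toyIID2()
    sch <- toyScheme2()
    win <- scoreWindow(0, 8)
    lw <- matrix(0, 9, 1, dimnames = list(0:8, 0))
    st <- initialConfiguration(model, sch, win, 3, 3)
    out <- mhUpdate(st, model, sch, win, lw, nSteps = 2000)
    ## every proposal inside the window is accepted (window covers all
    ## reachable scores of this toy, so none are rejected at the boundary)
    expect_identical(attr(out, "accepted"), 2000)
})

test_that("the chain keeps lengths constant and its cached score exact", {
    set.seed(46)
    model <- toyIID2()
    sch <- toyScheme2()
    win <- scoreWindow(0, 8)
    lw <- matrix(rnorm(9, sd = 0.5), 9, 1, dimnames = list(0:8, 0))
    st <- initialConfiguration(model, sch, win, 4, 4)
    for (chunk in 1:10) {
        st <- mhUpdate(st, model, sch, win, lw, nSteps = 1000)
        expect_identical(length(st$x), 4L)
        expect_identical(length(st$y), 4L)
        seqs <- AlignTails:::stateSequences(st, model)
        expect_identical(st$score,
                         smithWatermanScore(seqs$x, seqs$y, sch))
        expect_equal(st$log_null,
                     iidLogProb(model, seqs$x) + iidLogProb(model, seqs$y),
                     tolerance = 1e-9)
    }
})

test_that("the kernel's long-run law matches the enumerated target", {
    set.seed(47)
    model <- toyIID2()
    sch <- toyScheme2()
    u <- toyUniverse(model, sch, 2, 2)
    win <- scoreWindow(0, 4)
    lw <- matrix(c(0.5, -0.3, 1.0, 0.2, -1.0), ncol = 1,
                 dimnames = list(0:4, 0))
    tmx <- chainTransitionMatrix(u, lw)
    st <- initialConfiguration(model, sch, win, 2, 2)
    h <- productionRun(model, sch, win, lw, nSamples = 2e5, LQ = 2, LS = 2,
                       thinning = 5L, state = st)
    qScore <- tapply(tmx$q, tmx$configs$score, sum)
    emp <- rowSums(h@counts)[names(qScore)] / h@nSamples
    tv <- 0.5 * sum(abs(emp - qScore))
    expect_lt(tv, 0.01)
})

test_that("every configuration of the tiny space is visited", {
    set.seed(48)
    model <- toyIID2()
    sch <- toyScheme2()
    win <- scoreWindow(0, 4)
    lw <- matrix(0, 5, 1, dimnames = list(0:4, 0))
    st <- initialConfiguration(model, sch, win, 2, 2)
    seen <- character(0)
    for (i in 1:3000) {
        st <- mhUpdate(st, model, sch, win, lw, nSteps = 1L)
        seqs <- AlignTails:::stateSequences(st, model)
        seen <- union(seen, paste(seqs$x, seqs$y))
    }
    expect_identical(length(seen), 16L)
})

test_that("HMM-mode updates track class and query probability", {
    set.seed(49)
    model <- hmmQueryModel(toyHMM2(), toyIID2())
    sch <- toyScheme2()
    win <- scoreWindow(0, 6, classes = 0:3)
    lw <- matrix(0, 7, 4, dimnames = list(0:6, 0:3))
    st <- initialConfiguration(model, sch, win, 3, 3)
    for (chunk in 1:5) {
        st <- mhUpdate(st, model, sch, win, lw, nSteps = 500)
        seqs <- AlignTails:::stateSequences(st, model)
        expect_identical(st$score, smithWatermanScore(seqs$x, seqs$y, sch))
        expect_equal(st$log_query,
                     forwardLogProb(model@hmm, seqs$x)$log_prob,
                     tolerance = 1e-9)
        expect_identical(
            st$n_tm,
            countTMHelices(viterbiPath(model@hmm, seqs$x)$path, model@hmm))
    }
})
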