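test_that("the bundled BLOSUM62 matches the published standard", {
    b <- blosum62()
    expect_identical(b@scores["A", "A"], 4L)
    expect_identical(b@scores["W", "W"], 11L)
    expect_true(isSymmetric(unname(b@scores)))
    ## independent copy of the standard matrix
    ref <- local({
        data(BLOSUM62, package = "Biostrings", envir = environment())
        BLOSUM62[aaAlphabet(), aaAlphabet()]
    })
    expect_true(all(b@scores == ref))
    expect_lt(expectedScore(b, swissprotFreqs()), 0)
})

test_that("matrix files reject ragged or non-integer input, round-trip", {
    f <- tempfile()
    writeLines(c("  A  B", "A  2 -1", "B -1"), f)   # lower-triangle style
    expect_error(readScoringMatrix(f), "entries")
    writeLines(c("  A  B", "A  2 -1", "B -1 0.5"), f)
    expect_error(readScoringMatrix(f), "non-integer")
    m <- toyMatrix3()
    writeScoringMatrix(m, f)
    m2 <- readScoringMatrix(f)
    expect_identical(m2@scores, m@scores)
})

test_that("the TM region matrix is non-symmetric with negative expectation", {
    tm <- tmSyntheticMatrix()
    expect_false(isSymmetric(unname(tm@scores)))
    expect_lt(expectedScore(tm, swissprotFreqs()), 0)
})

test_that("Smith-Waterman score equals exhaustive alignment enumeration", {
    sch <- toyScheme2()
    expect_identical(smithWatermanScore("", "AB", sch), 0L)
    expect_identical(smithWatermanScore("AB", "", sch), 0L)
    x <- "ABAB"
    expect_gte(smithWatermanScore(x, x, sch), 2L * nchar(x))
    ## exhaustive: every pair of non-empty 2-letter sequences up to 4-mers
    seqs <- unlist(lapply(1:4, function(L) allSeqsOf(toyAlphabet2, L)))
    for (x in seqs) for (y in seqs)
        expect_identical(smithWatermanScore(x, y, sch),
                         enumerateAlignments(x, y, sch))
    ## stochastic: 3-letter 6-mers with a different gap cost
    set.seed(33)
    sch3 <- toyScheme3()
    for (i in 1:500) {
        x <- randomSeq(toyAlphabet3, 6)
        y <- randomSeq(toyAlphabet3, 6)
        expect_identical(smithWatermanScore(x, y, sch3),
                         enumerateAlignments(x, y, sch3))
    }
})

test_that("local score is monotone under extension and translation", {
    set.seed(34)
    sch <- toyScheme3()
    up <- scoringMatrix(toyMatrix3()@scores + 2L, "shifted")
    schUp <- scoringScheme(up, gapOpen = 2L, gapExtend = 1L)
    for (i in 1:100) {
        x <- randomSeq(toyAlphabet3, 5)
        y <- randomSeq(toyAlphabet3, 5)
        s <- smithWatermanScore(x, y, sch)
        expect_gte(smithWatermanScore(paste0(x, "A"), y, sch), s)
        expect_gte(smithWatermanScore(x, paste0(y, "C"), sch), s)
        expect_gte(smithWatermanScore(x, y, schUp), s)
    }
})

test_that("bipartite scheme with identical matrices equals the plain score", {
    set.seed(35)
    sch <- toyScheme3()
    schR <- scoringScheme(toyMatrix3(), toyMatrix3(),
                          queryRegions = rbind(c(2L, 3L), c(5L, 6L)),
                          gapOpen = 2L, gapExtend = 1L)
    for (i in 1:200) {
        x <- randomSeq(toyAlphabet3, 6)
        y <- randomSeq(toyAlphabet3, 6)
        expect_identical(smithWatermanScore(x, y, schR),
                         smithWatermanScore(x, y, sch))
    }
})

test_that("region matrix is applied on query rows only", {
    ab <- toyAlphabet2
    strong <- scoringMatrix(matrix(c(9L, -9L, -9L, 9L), 2, 2,
                                   dimnames = list(ab, ab)), "strong")
    sch <- scoringScheme(toyMatrix2(), strong,
                         queryRegions = cbind(1L, 2L),
                         gapOpen = 5L, gapExtend = 5L)
    ## both positions of the query in the region: matches score 9 each
    expect_identical(smithWatermanScore("AB", "AB", sch), 18L)
    ## region beyond the query length is an error
    expect_error(smithWatermanScore("A", "AB", sch), "region")
})

test_that("explicit alignments are scored with internal affine gaps only", {
    sch <- toyScheme2()
    expect_identical(scoreAlignment("AB", "AB", NULL, sch), 0L)
    expect_identical(scoreAlignment("AB", "AB", cbind(1L, 1L), sch), 2L)
    expect_error(scoreAlignment("ABAB", "ABAB",
                                rbind(c(1L, 2L), c(2L, 1L)), sch),
                 "cross")
    ## the optimum over explicit alignments agrees with the DP:
    ## score the traceback alignment of random toys
    set.seed(36)
    sch3 <- toyScheme3()
    for (i in 1:100) {
        x <- randomSeq(toyAlphabet3, 6)
        y <- randomSeq(toyAlphabet3, 6)
        aln <- smithWatermanAlignment(x, y, sch3)
        expect_identical(scoreAlignment(x, y, aln$pairs, sch3), aln$score)
        expect_identical(aln$score, smithWatermanScore(x, y, sch3))
    }
})

test_that("gap lengths of the worked alignment example are {2, 3}", {
    expect_setequal(gapLengths("QGEGGDA---WC", "QG--GDATTTWC"), c(2L, 3L))
    expect_identical(length(gapLengths("QGEG", "QGEG")), 0L)
    expect_error(gapLengths("A-B", "A-B"), "both rows")
    expect_error(gapLengths("AB", "ABC"), "equal display length")
    set.seed(37)
    for (i in 1:50) {
        ## random gapped display rows without double-gap columns
        L <- 12
        gx <- runif(L) < 0.2
        gy <- !gx & runif(L) < 0.2
        cx <- ifelse(gx, "-", sample(toyAlphabet2, L, TRUE))
        cy <- ifelse(gy, "-", sample(toyAlphabet2, L, TRUE))
        got <- sort(gapLengths(paste(cx, collapse = ""),
                               paste(cy, collapse = "")))
        rl <- function(g) {
            r <- rle(g)
            r$lengths[r$values]
        }
        expect_identical(got, sort(as.integer(c(rl(gx), rl(gy)))))
    }
})

test_that("gap cost conventions differ by one extension per gap", {
    ab <- toyAlphabet2
    m <- scoringMatrix(matrix(c(5L, -2L, -2L, 5L), 2, 2,
                              dimnames = list(ab, ab)), "m")
    a <- scoringScheme(m, gapOpen = 3L, gapExtend = 1L,
                       gapConvention = "open_plus_len")
    b <- scoringScheme(m, gapOpen = 3L, gapExtend = 1L,
                       gapConvention = "open_plus_len_minus_1")
    ## the best alignment of these skips the middle B: one length-1 gap
    x <- "ABA"
    y <- "AA"
    expect_identical(smithWatermanScore(x, y, a), 10L - 4L)
    expect_identical(smithWatermanScore(x, y, b), 10L - 3L)
})

test_that("TM interval files parse to sorted 1-based intervals", {
    f <- tempfile()
    writeLines(c("q1\t8\t10", "q1\t2\t4", "q2\t1\t3"), f)
    iv <- readTMIntervals(f)
    expect_identical(names(iv), c("q1", "q2"))
    expect_identical(unname(iv$q1[, "start"]), c(2L, 8L))
    sch <- scoringScheme(toyMatrix2(), toyMatrix2(), queryRegions = iv$q2)
    expect_identical(nrow(sch@queryRegions), 1L)
})
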