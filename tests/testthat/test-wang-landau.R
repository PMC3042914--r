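test_that("the flatness criterion compares every bin with 0.6 of the mean", {
    expect_true(isFlat(c(10, 6, 8), 0.6))     # mean 8, threshold 4.8
    expect_false(isFlat(c(10, 4, 10), 0.6))   # 4 < 4.8
    expect_true(isFlat(rep(7, 5), 0.99))
    expect_false(isFlat(c(5, 5, 0, 5), 0.6))
    expect_error(isFlat(c(3), 0.6), "degenerate")
})

test_that("the sqrt schedule from exp(0.1) runs 9 levels above exp(2e-4)", {
    ## closed form: levels with 0.1 / 2^k > 2e-4, k = 0..8
    expect_identical(sum(0.1 / 2^(0:20) > 2e-4), 9L)
    set.seed(51)
    model <- toyIID2()
    sch <- toyFullScheme()
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4)
    expect_identical(length(wl@stepsPerLevel), 9L)
    ## the retained histogram belongs to the last level only (H is reset
    ## at each level change)
    expect_equal(sum(wl@H), wl@stepsPerLevel[9])
})

test_that("converged weights reproduce the exact pmf within factor 1.5", {
    set.seed(52)
    model <- toyIID2()
    sch <- toyScheme2()
    u <- toyUniverse(model, sch, 2, 2)
    ex <- exactScoreDistribution(u)
    win <- scoreWindow(0, 4)
    wl <- suppressWarnings(
        wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4))
    sup <- names(ex$marginal)[ex$marginal > 0]
    ## -logW ~ log P up to an additive constant: compare centred shapes
    ## (the weights carry a huge arbitrary offset, so work in logs)
    dev <- (-wl@logW[sup, 1]) - log(ex$marginal[sup])
    dev <- dev - mean(dev)
    expect_true(all(abs(dev) < log(1.5)))
    ## unreachable score bins were masked, not flattened
    expect_true(all(wl@masked[c("1", "3"), 1]))
})

test_that("warm starts do not bias the converged weights", {
    ## on enumerable toys the level times are dominated by histogram
    ## fluctuations rather than weight learning, so the warm-start
    ## speed-up is checked on the production-scale chain (see the
    ## calibration tests); here the estimator property is checked: an
    ## exact-inverse-pmf warm start leaves the converged shape unchanged
    set.seed(53)
    model <- toyIID2()
    sch <- toyFullScheme()
    u <- toyUniverse(model, sch, 2, 2)
    ex <- exactScoreDistribution(u)
    win <- scoreWindow(0, 4)
    cold <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4,
                       checkInterval = 200L)
    lw0 <- matrix(0, 5, 1, dimnames = list(0:4, 0))
    sup <- ex$marginal > 0
    lw0[sup, 1] <- -log(ex$marginal[sup])
    warm <- wlEstimate(model, sch, win, 2, 2, initLogW = lw0,
                       maxStepsPerLevel = 3e4, checkInterval = 200L)
    for (wl in list(cold, warm)) {
        dev <- (-wl@logW[names(ex$marginal)[sup], 1]) -
            log(ex$marginal[sup])
        dev <- dev - mean(dev)
        expect_true(all(abs(dev) < log(1.5)))
    }
})

test_that("uniform-weight production reduces to plain null sampling", {
    set.seed(54)
    model <- toyIID2()
    sch <- toyFullScheme()
    u <- toyUniverse(model, sch, 2, 2)
    ex <- exactScoreDistribution(u)
    win <- scoreWindow(0, 4)
    lw <- matrix(0, 5, 1, dimnames = list(0:4, 0))
    h <- productionRun(model, sch, win, lw, nSamples = 5e4, LQ = 2, LS = 2,
                       thinning = 5L)
    emp <- rowSums(h@counts) / h@nSamples
    expect_lt(0.5 * sum(abs(emp - ex$marginal[names(emp)])), 0.02)
})

test_that("WL + production + reweighting recovers the exact pmf (3 sigma)", {
    set.seed(55)
    model <- toyIID2()
    sch <- toyFullScheme()
    u <- toyUniverse(model, sch, 2, 2)
    ex <- exactScoreDistribution(u)
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4)
    h <- productionRun(model, sch, win, wl@logW, nSamples = 1e5,
                       LQ = 2, LS = 2, thinning = 5L,
                       state = wl@finalState)
    est <- reweight(h)
    for (s in names(ex$marginal)[ex$marginal > 0]) {
        p <- exp(est@logProbMarginal[s])
        sig <- p * est@relError[s, 1]
        expect_lt(abs(p - ex$marginal[s]), 3 * sig)
    }
    ## estimator consistency: deviations shrink with sample size
    h2 <- productionRun(model, sch, win, wl@logW, nSamples = 1e4,
                        LQ = 2, LS = 2, thinning = 5L)
    est2 <- reweight(h2)
    sup <- names(ex$marginal)[ex$marginal > 0]
    err1 <- sqrt(mean((exp(est@logProbMarginal[sup]) -
                       ex$marginal[sup])^2))
    err2 <- sqrt(mean((exp(est2@logProbMarginal[sup]) -
                       ex$marginal[sup])^2))
    expect_lt(err1, err2 + 0.01)
})

test_that("thinning k and 2k give statistically compatible estimates", {
    set.seed(56)
    model <- toyIID2()
    sch <- toyFullScheme()
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4)
    h1 <- productionRun(model, sch, win, wl@logW, nSamples = 3e4,
                        LQ = 2, LS = 2, thinning = 4L)
    h2 <- productionRun(model, sch, win, wl@logW, nSamples = 3e4,
                        LQ = 2, LS = 2, thinning = 8L)
    e1 <- reweight(h1)
    e2 <- reweight(h2)
    for (s in rownames(h1@counts)) {
        p1 <- exp(e1@logProbMarginal[s])
        p2 <- exp(e2@logProbMarginal[s])
        if (!is.finite(log(p1)) || !is.finite(log(p2))) next
        sig <- sqrt((p1 * e1@relError[s, 1])^2 +
                    (p2 * e2@relError[s, 1])^2)
        expect_lt(abs(p1 - p2), 4 * sig)
    }
})

test_that("round trips require touching both edges and are monotone", {
    set.seed(57)
    model <- toyIID2()
    sch <- toyFullScheme()
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 2e4)
    expect_gte(wl@roundTrips, 1)
    expect_identical(length(wl@rtStamps), as.integer(wl@roundTrips))
    expect_true(all(diff(wl@rtStamps) > 0))
})

test_that("weights transfer across windows by linear inter/extrapolation", {
    win1 <- scoreWindow(0, 10)
    lw <- matrix(-0.7 * (0:10), ncol = 1, dimnames = list(0:10, 0))
    ## identical window: identity
    same <- warmStartWeights(lw, win1)
    expect_equal(unname(same), unname(lw))
    ## shifted window with a linear tail: the slope is continued
    win2 <- scoreWindow(10, 20)
    ext <- warmStartWeights(lw, win2)
    expect_equal(unname(ext[, 1]), -0.7 * (10:20))
    ## disjoint windows fall back to uniform with a warning
    expect_warning(u <- warmStartWeights(lw, scoreWindow(50, 60)),
                   "disjoint")
    expect_true(all(u == 0))
})

test_that("the round-trip flatness criterion is usable", {
    set.seed(58)
    model <- toyIID2()
    sch <- toyFullScheme()
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, flatCriterion = "roundtrips",
                     minRoundTrips = 3L, maxStepsPerLevel = 3e4)
    expect_identical(length(wl@stepsPerLevel), 9L)
    expect_gte(wl@roundTrips, 27)
})
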