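test_that("reweighting with uniform weights is the empirical frequency", {
    set.seed(61)
    model <- toyIID2()
    sch <- toyFullScheme()
    win <- scoreWindow(0, 4)
    lw <- matrix(0, 5, 1, dimnames = list(0:4, 0))
    h <- productionRun(model, sch, win, lw, nSamples = 2e4, LQ = 2, LS = 2,
                       thinning = 3L)
    est <- reweight(h, errorMethod = "multinomial")
    cnt <- rowSums(h@counts)
    expect_equal(exp(est@logProbMarginal), cnt / h@nSamples,
                 tolerance = 1e-12)
    ## marginalization identity and overall normalization
    expect_equal(rowSums(exp(est@logProb)), exp(est@logProbMarginal),
                 tolerance = 1e-12)
    expect_equal(sum(exp(est@logProb)), 1, tolerance = 1e-9)
    ## empty histograms are rejected
    h0 <- h
    expect_error({
        h0@counts[] <- 0
        h0@nSamples <- 0
        reweight(h0)
    }, "empty|nSamples")
})

test_that("blocking reproduces known errors for iid and AR(1) series", {
    set.seed(62)
    n <- 2^15
    x <- rnorm(n, sd = 2)
    b <- blockingErrors(x)
    expect_lt(abs(b$plateau - 2 / sqrt(n)) / (2 / sqrt(n)), 0.2)
    expect_true(b$plateauDetected)
    ## perfectly correlated (constant) series
    expect_identical(blockingErrors(rep(3.3, 1024))$plateau, 0)
    ## AR(1) with rho = 0.9: sd_eff = sd * sqrt((1+rho)/(1-rho))
    rho <- 0.9
    ar <- numeric(n)
    ar[1] <- rnorm(1)
    innov <- rnorm(n, sd = sqrt(1 - rho^2))
    for (i in 2:n) ar[i] <- rho * ar[i - 1] + innov[i]
    ba <- blockingErrors(ar)
    target <- sqrt((1 + rho) / (1 - rho)) / sqrt(n)
    expect_lt(abs(ba$plateau - target) / target, 0.25)
    ## short series: naive error, flagged
    bs <- blockingErrors(rnorm(20))
    expect_false(bs$plateauDetected)
    expect_equal(bs$plateau, bs$naive)
})

test_that("the modified Gumbel fit recovers its generating parameters", {
    s0 <- 20; lam <- 0.27; lam2 <- 1e-4
    s <- seq(21, 70)
    logP <- log(lam) - lam * (s - s0) - lam2 * (s - s0)^2
    d <- data.frame(s = s, logProb = logP, relError = 0.02)
    f <- fitModifiedGumbel(d, LQ = 100, LS = 100)
    expect_equal(f@s0, s0, tolerance = 1e-6)
    expect_equal(f@lambda, lam, tolerance = 1e-6)
    expect_equal(f@lambda2, lam2, tolerance = 1e-4)
    expect_equal(f@K, exp(lam * s0) / 1e4, tolerance = 1e-4)
    ## 2% multiplicative noise on the probabilities, 50 bins
    set.seed(63)
    nRec <- 0
    for (rep in 1:5) {
        dn <- data.frame(s = s[1:50],
                         logProb = logP[1:50] + rnorm(50, sd = 0.02),
                         relError = 0.02)
        fn <- fitModifiedGumbel(dn, LQ = 100, LS = 100)
        ok <- abs(fn@s0 - s0) < 3 * fn@se["s0"] &&
            abs(fn@lambda - lam) < 3 * fn@se["lambda"] &&
            abs(fn@lambda2 - lam2) < 3 * fn@se["lambda2"]
        nRec <- nRec + ok
        expect_gt(fn@chisqRed, 0.4)
        expect_lt(fn@chisqRed, 2)
    }
    expect_gte(nRec, 4)  # 3-sigma joint recovery in >= 4 of 5 replicates
})

test_that("pure-Gumbel data yield lambda2 consistent with zero, and the
           constrained fit never beats the free fit", {
    set.seed(64)
    s <- seq(25, 80)
    logP <- log(0.3) - 0.3 * (s - 22)
    d <- data.frame(s = s, logProb = logP + rnorm(length(s), sd = 0.03),
                    relError = 0.03)
    free <- fitModifiedGumbel(d, LQ = 50, LS = 50)
    fixed <- fitModifiedGumbel(d, LQ = 50, LS = 50, fixLambda2 = TRUE)
    expect_lt(free@lambda2, 3 * free@se["lambda2"] + 1e-12)
    expect_gte(fixed@chisqRed * (nrow(d) - 2),
               free@chisqRed * (nrow(d) - 3) - 1e-9)
})

test_that("p-values are exact tail sums on the enumerable toy", {
    set.seed(65)
    model <- toyIID2()
    sch <- toyFullScheme()
    u <- toyUniverse(model, sch, 2, 2)
    ex <- exactScoreDistribution(u)
    win <- scoreWindow(0, 4)
    wl <- wlEstimate(model, sch, win, 2, 2, maxStepsPerLevel = 3e4)
    h <- productionRun(model, sch, win, wl@logW, nSamples = 5e4,
                       LQ = 2, LS = 2, thinning = 4L,
                       state = wl@finalState)
    est <- reweight(h)
    expect_equal(pValue(est, 0), 1, tolerance = 1e-9)
    ss <- 0:4
    pv <- pValue(est, ss)
    expect_true(all(diff(pv) <= 1e-12))
    for (s in ss) {
        exact <- sum(ex$marginal[as.numeric(names(ex$marginal)) >= s])
        expect_equal(pv[s + 1], exact, tolerance = 0.1)
    }
    expect_true(isTRUE(attr(pValue(est, -5), "belowWindow")))
})

test_that("analytic continuation extends the tail beyond the window", {
    f <- new("ModifiedGumbelFit", s0 = 20, lambda = 0.27, lambda2 = 1e-4,
             K = exp(0.27 * 20) / 1e4,
             se = c(s0 = 0, lambda = 0, lambda2 = 0, K = 0),
             covariance = matrix(0, 3, 3), fitWindow = c(21, 70),
             chisqRed = 1, LQ = 100L, LS = 100L, lambda2Fixed = FALSE)
    p1 <- pValue(f, 100)
    direct <- sum(exp(log(0.27) - 0.27 * ((100:400) - 20) -
                      1e-4 * ((100:400) - 20)^2))
    expect_equal(p1, direct, tolerance = 1e-6)
    expect_true(all(diff(pValue(f, c(50, 60, 70, 80))) < 0))
})

test_that("E-values are linear in the database size", {
    expect_identical(eValue(0, 100), 0)
    expect_identical(eValue(0.2, 1), 0.2)
    expect_equal(eValue(0.01, 300) + eValue(0.01, 700), eValue(0.01, 1000))
    expect_error(eValue(1.2, 10))
})

test_that("fit parameters interpolate linearly in the subject length", {
    mk <- function(LS, lambda, lambda2, K)
        new("ModifiedGumbelFit", s0 = log(K * 348 * LS) / lambda,
            lambda = lambda, lambda2 = lambda2, K = K,
            se = c(s0 = 0.1, lambda = 0.001, lambda2 = 1e-6, K = 1e-4),
            covariance = matrix(0, 3, 3), fitWindow = c(0, 1),
            chisqRed = 1, LQ = 348L, LS = as.integer(LS),
            lambda2Fixed = FALSE)
    ## linear lambda(LS) grid: exact recovery at the midpoint
    fits <- list(mk(100, 0.20, 2e-4, 0.02), mk(200, 0.18, 1.5e-4, 0.018),
                 mk(300, 0.16, 1.2e-4, 0.016))
    at <- interpolateParams(fits, 150)
    expect_equal(at@lambda, 0.19, tolerance = 1e-12)
    expect_equal(at@K, 0.019, tolerance = 1e-12)
    ## identity at a grid point
    g <- interpolateParams(fits, 200)
    expect_equal(g@lambda, 0.18, tolerance = 1e-12)
    expect_equal(g@lambda2, 1.5e-4, tolerance = 1e-12)
    ## lambda2 plateaus for subjects longer than the query: near-constant
    ## interpolation on a grid shaped like the published length scan
    plateau <- list(mk(360, 0.2678, 0.9883e-4, 0.0302),
                    mk(400, 0.2648, 1.0238e-4, 0.0248),
                    mk(500, 0.2638, 1.0248e-4, 0.0255))
    mid <- interpolateParams(plateau, 450)
    expect_lt(abs(mid@lambda2 - 1.02e-4) / 1.02e-4, 0.05)
    ## extrapolation beyond 20% of the covered range is flagged
    expect_warning(far <- interpolateParams(fits, 420), "beyond")
    expect_true(isTRUE(attr(far, "extrapolated")))
})
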