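#' Importance reweighting of a score histogram
#'
#' Turns biased-sampling counts into a normalized estimate of the null
#' pmf: `P(s, n) = counts(s, n) / w(s, n) / Z` with
#' `Z = sum counts / w`. All arithmetic is in log space; the estimated
#' probabilities routinely span more than 60 decades.
#'
#' Per-bin relative errors come from a blocking analysis of the recorded
#' indicator series (accounting for chain autocorrelation) or, for
#' independent samples, from the multinomial standard error.
#'
#' @param hist a [ScoreHistogram-class].
#' @param errorMethod `"blocking"` (default when a sample series is
#'   available) or `"multinomial"`.
#' @return A [DistributionEstimate-class].
#' @export
reweight <- function(hist, errorMethod = c("auto", "blocking",
                                           "multinomial")) {
    errorMethod <- match.arg(errorMethod)
    if (sum(hist@counts) == 0) stop("empty histogram")
    if (errorMethod == "auto")
        errorMethod <- if (nrow(hist@series) > 0 && hist@thinning > 0)
            "blocking" else "multinomial"
    counted <- hist@counts > 0
    if (any(!is.finite(hist@logW[counted])))
        stop("counted bin with non-finite log-weight")
    logUn <- matrix(-Inf, nrow(hist@counts), ncol(hist@counts),
                    dimnames = dimnames(hist@counts))
    logUn[counted] <- log(hist@counts[counted]) - hist@logW[counted]
    z <- logSumExp(logUn[counted])
    logProb <- logUn - z
    relErr <- matrix(NA_real_, nrow(logProb), ncol(logProb),
                     dimnames = dimnames(logProb))
    N <- hist@nSamples
    if (errorMethod == "multinomial") {
        relErr[counted] <- sqrt(pmax(1 - hist@counts[counted] / N, 0) /
                                hist@counts[counted])
    } else {
        win <- hist@window
        idx <- which(counted, arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
            s <- win@smin + idx[r, 1] - 1L
            n <- win@classes[idx[r, 2]]
            z01 <- as.numeric(hist@series[, 1] == s & hist@series[, 2] == n)
            be <- blockingErrors(z01)
            relErr[idx[r, 1], idx[r, 2]] <- be$plateau / mean(z01)
        }
    }
    lm_ <- apply(logProb, 1, logSumExp)
    new("DistributionEstimate", logProb = logProb,
        logProbMarginal = setNames(lm_, rownames(logProb)),
        relError = relErr, window = hist@window, nSamples = N)
}

#' Blocking (Flyvbjerg-Petersen) error estimate for a correlated series
#'
#' Repeatedly halves the series by pairwise averaging; at each level the
#' naive standard error of the mean is computed. For a correlated series
#' the naive error grows with the block size until blocks are effectively
#' independent, where it plateaus; the plateau is the error estimate.
#'
#' @param series numeric vector (chain measurements), length >= 32 for a
#'   meaningful plateau.
#' @return List with `errors` (per level), `blockSizes`, `plateau`,
#'   `plateauDetected` and `naive` (the level-0 error). Series shorter
#'   than 64 get the naive error with `plateauDetected = FALSE`.
#' @export
blockingErrors <- function(series) {
    x <- as.numeric(series)
    n <- length(x)
    if (n < 2) stop("series too short")
    errors <- numeric(0)
    sizes <- numeric(0)
    b <- 1
    while (length(x) >= 2) {
        errors <- c(errors, sd(x) / sqrt(length(x)))
        sizes <- c(sizes, b)
        if (length(x) < 4) break
        m <- floor(length(x) / 2)
        x <- (x[2 * seq_len(m) - 1] + x[2 * seq_len(m)]) / 2
        b <- 2 * b
    }
    if (all(errors == 0)) {
        return(list(errors = errors, blockSizes = sizes, plateau = 0,
                    plateauDetected = TRUE, naive = errors[1]))
    }
    nBlocks <- n / sizes
    win <- which(nBlocks >= 32 & nBlocks <= 128)
    if (n < 64 || length(win) == 0) {
        return(list(errors = errors, blockSizes = sizes,
                    plateau = errors[1], plateauDetected = FALSE,
                    naive = errors[1]))
    }
    plateau <- mean(errors[win])
    prev <- max(1, min(win) - 2)
    detected <- errors[min(win)] <= 1.3 * plateau &&
        plateau >= 0.8 * errors[prev]
    list(errors = errors, blockSizes = sizes, plateau = plateau,
         plateauDetected = detected, naive = errors[1])
}

## assemble (s, logP, sigma) fit data from an estimate or a data.frame
fitData <- function(est, class = NULL) {
    if (is.data.frame(est)) {
        stopifnot(all(c("s", "logProb") %in% names(est)))
        sig <- if ("relError" %in% names(est)) est$relError
               else rep(1, nrow(est))
        return(data.frame(s = est$s, logProb = est$logProb, sigma = sig))
    }
    stopifnot(is(est, "DistributionEstimate"))
    if (is.null(class)) {
        lp <- est@logProbMarginal
        ## marginal error: dominated by the leading class in each bin
        sig <- apply(est@relError, 1, function(v)
            if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
    } else {
        k <- match(class, est@window@classes)
        lp <- est@logProb[, k]
        sig <- est@relError[, k]
    }
    data.frame(s = as.numeric(names(est@logProbMarginal)),
               logProb = as.numeric(lp), sigma = sig)
}

#' Fit the modified Gumbel law to an estimated score distribution
#'
#' Weighted least squares of `log P(S = s)` against
#' `log(lambda) - lambda (s - s0) - lambda2 (s - s0)^2`. The per-bin
#' standard error of `log P` equals the relative error of `P`; bins with
#' relative error above `maxRelError` (default 50%) are excluded. With
#' `fixLambda2 = TRUE` the pure Gumbel tail (`lambda2 = 0`) is fitted for
#' comparison. The Karlin-Altschul-style amplitude is derived as
#' `K = exp(lambda * s0) / (LQ * LS)`.
#'
#' @param est a [DistributionEstimate-class], or a data.frame with columns
#'   `s`, `logProb` and optionally `relError`.
#' @param LQ,LS query and subject lengths (for K).
#' @param fitWindow optional numeric `c(lo, hi)` restricting the fitted
#'   score range (e.g. the bulk region for simple-sampling data).
#' @param fixLambda2 fit with `lambda2` fixed at zero.
#' @param class fit a single helix-class slice instead of the marginal.
#' @param maxRelError exclusion threshold for noisy bins.
#' @return A [ModifiedGumbelFit-class].
#' @export
fitModifiedGumbel <- function(est, LQ, LS, fitWindow = NULL,
                              fixLambda2 = FALSE, class = NULL,
                              maxRelError = 0.5) {
    d <- fitData(est, class)
    d <- d[is.finite(d$logProb) & !is.na(d$sigma) & d$sigma > 0 &
           d$sigma <= maxRelError, ]
    if (!is.null(fitWindow))
        d <- d[d$s >= fitWindow[1] & d$s <= fitWindow[2], ]
    if (nrow(d) < 5)
        stop("need at least 5 usable bins in the fit window")
    w <- 1 / d$sigma^2
    ## starting values from a weighted quadratic polynomial
    q <- stats::lm(logProb ~ s + I(s^2), data = d, weights = w)
    c2 <- min(coef(q)[3], -1e-12)
    l2.0 <- max(-c2, 1e-12)
    s0.0 <- d$s[which.max(d$logProb)]
    l.0 <- max(-(coef(q)[2] + 2 * l2.0 * s0.0), 0.01)
    ctl <- minpack.lm::nls.lm.control(maxiter = 500)
    if (fixLambda2) {
        fit <- minpack.lm::nlsLM(
            logProb ~ log(lambda) - lambda * (s - s0),
            data = d, weights = w,
            start = list(s0 = s0.0, lambda = l.0),
            lower = c(-Inf, 1e-8), control = ctl)
    } else {
        fit <- minpack.lm::nlsLM(
            logProb ~ log(lambda) - lambda * (s - s0) -
                lambda2 * (s - s0)^2,
            data = d, weights = w,
            start = list(s0 = s0.0, lambda = l.0, lambda2 = l2.0),
            lower = c(-Inf, 1e-8, 0), control = ctl)
    }
    cf <- coef(fit)
    if (cf["lambda"] <= 0) stop("fit invalid: lambda <= 0 at optimum")
    vc <- tryCatch(vcov(fit), error = function(e)
        matrix(NA_real_, length(cf), length(cf),
               dimnames = list(names(cf), names(cf))))
    dof <- nrow(d) - length(cf)
    chisq <- sum(w * (d$logProb - predict(fit, d))^2) / max(dof, 1)
    ## vcov of nls is scaled by the residual variance; undo that scaling so
    ## the parameter errors reflect the supplied per-bin errors
    if (all(is.finite(vc)) && chisq > 0) vcRaw <- vc / chisq else vcRaw <- vc
    se <- sqrt(diag(vcRaw))
    lambda2 <- if (fixLambda2) 0 else unname(cf["lambda2"])
    K <- exp(cf["lambda"] * cf["s0"]) / (LQ * LS)
    ## delta method for K(lambda, s0)
    seK <- NA_real_
    if (all(is.finite(vcRaw[1:2, 1:2]))) {
        g <- c(K * cf["lambda"], K * cf["s0"])  # d/ds0, d/dlambda
        seK <- sqrt(as.numeric(t(g) %*% vcRaw[c("s0", "lambda"),
                                              c("s0", "lambda")] %*% g))
    }
    seOut <- c(s0 = unname(se["s0"]), lambda = unname(se["lambda"]),
               lambda2 = if (fixLambda2) 0 else unname(se["lambda2"]),
               K = unname(seK))
    new("ModifiedGumbelFit", s0 = unname(cf["s0"]),
        lambda = unname(cf["lambda"]), lambda2 = lambda2,
        K = unname(K), se = seOut, covariance = vcRaw,
        fitWindow = if (is.null(fitWindow)) range(d$s) else fitWindow,
        chisqRed = chisq, LQ = as.integer(LQ), LS = as.integer(LS),
        lambda2Fixed = fixLambda2)
}

## modified Gumbel log pmf of a fit
fitLogPmf <- function(fit, s) {
    log(fit@lambda) - fit@lambda * (s - fit@s0) -
        fit@lambda2 * (s - fit@s0)^2
}

#' p-value of a score under an estimated (or fitted) null distribution
#'
#' `pval(s) = Prob(S >= s)`: a tail sum of the estimated pmf over its
#' supported range, analytically continued with the modified Gumbel fit
#' beyond it. For a score below the estimated window the p-value is 1
#' (with attribute `belowWindow = TRUE`).
#'
#' @param est a [DistributionEstimate-class] or [ModifiedGumbelFit-class].
#' @param s integer score (vectorized).
#' @param fit optional [ModifiedGumbelFit-class] used to continue the
#'   tail beyond the estimate's window.
#' @return Numeric p-value(s), monotone non-increasing in `s`.
#' @export
pValue <- function(est, s, fit = NULL) {
    if (is(est, "ModifiedGumbelFit")) {
        fit <- est
        est <- NULL
    }
    one <- function(sv) {
        if (!is.null(est)) {
            scores <- as.numeric(names(est@logProbMarginal))
            if (sv < min(scores)) return(structure(1, belowWindow = TRUE))
            inWin <- scores >= sv
            p <- if (any(inWin & is.finite(est@logProbMarginal)))
                exp(logSumExp(est@logProbMarginal[inWin])) else 0
            if (!is.null(fit) && sv > max(scores))
                p <- p + fitTailSum(fit, sv)
            else if (!is.null(fit))
                p <- p + fitTailSum(fit, max(scores) + 1)
            min(p, 1)
        } else {
            min(fitTailSum(fit, sv), 1)
        }
    }
    out <- vapply(s, function(sv) as.numeric(one(sv)), numeric(1))
    if (length(s) == 1 && !is.null(est) &&
        s[1] < min(as.numeric(names(est@logProbMarginal))))
        attr(out, "belowWindow") <- TRUE
    out
}

## sum of the fitted pmf over s' >= s (terms decay at least geometrically)
fitTailSum <- function(fit, s) {
    ss <- seq(s, by = 1, length.out = 10000L)
    lp <- fitLogPmf(fit, ss)
    keep <- lp > max(lp) - 60
    exp(logSumExp(lp[keep]))
}

#' E-value: expected number of database hits at a score threshold
#'
#' Linear convention `E = dbSize * p`, additive over database partitions.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param dbSize number of database sequences.
#' @export
eValue <- function(p, dbSize) {
    stopifnot(all(p >= 0), all(p <= 1))
    dbSize * p
}

#' Interpolate modified-Gumbel parameters across subject lengths
#'
#' Database subjects come in lengths not directly simulated; per-parameter
#' piecewise-linear interpolation in the subject length L_S of `lambda`,
#' `lambda2` and `K` (with `s0` recomputed from K and lambda, and
#' variances propagated linearly) gives a fit usable at intermediate
#' lengths. Extrapolating more than 20% beyond the covered range is
#' flagged.
#'
#' @param fits list of [ModifiedGumbelFit-class] objects for a common
#'   query (same LQ), keyed by their `LS`.
#' @param targetLS subject length of interest.
#' @return A [ModifiedGumbelFit-class] (attribute `extrapolated` if
#'   beyond the grid).
#' @export
interpolateParams <- function(fits, targetLS) {
    stopifnot(length(fits) >= 2)
    ls <- vapply(fits, function(f) as.numeric(f@LS), numeric(1))
    o <- order(ls)
    fits <- fits[o]
    ls <- ls[o]
    LQ <- fits[[1]]@LQ
    span <- diff(range(ls))
    extrap <- targetLS < min(ls) || targetLS > max(ls)
    if (targetLS < min(ls) - 0.2 * span || targetLS > max(ls) + 0.2 * span)
        warning("target subject length more than 20% beyond the fitted ",
                "grid; extrapolation unreliable")
    getp <- function(fn) vapply(fits, fn, numeric(1))
    lin <- function(v) {
        if (targetLS <= min(ls))
            v[1] + (v[2] - v[1]) / (ls[2] - ls[1]) * (targetLS - ls[1])
        else if (targetLS >= max(ls)) {
            m <- length(ls)
            v[m] + (v[m] - v[m - 1]) / (ls[m] - ls[m - 1]) *
                (targetLS - ls[m])
        } else approx(ls, v, xout = targetLS)$y
    }
    ## interpolation weights for variance propagation
    wts <- function() {
        if (targetLS <= min(ls)) c(1, rep(0, length(ls) - 1))
        else if (targetLS >= max(ls)) c(rep(0, length(ls) - 1), 1)
        else {
            i <- findInterval(targetLS, ls)
            w <- numeric(length(ls))
            t <- (targetLS - ls[i]) / (ls[i + 1] - ls[i])
            w[i] <- 1 - t
            w[i + 1] <- t
            w
        }
    }
    w <- wts()
    lambda <- lin(getp(function(f) f@lambda))
    lambda2 <- max(lin(getp(function(f) f@lambda2)), 0)
    K <- lin(getp(function(f) f@K))
    sevec <- function(nm) sqrt(sum(w^2 * getp(function(f)
        if (is.na(f@se[nm])) 0 else f@se[nm])^2))
    s0 <- log(K * LQ * targetLS) / lambda
    out <- new("ModifiedGumbelFit", s0 = s0, lambda = lambda,
               lambda2 = lambda2, K = K,
               se = c(s0 = NA_real_, lambda = sevec("lambda"),
                      lambda2 = sevec("lambda2"), K = sevec("K")),
               covariance = matrix(NA_real_, 3, 3),
               fitWindow = c(NA_real_, NA_real_), chisqRed = NA_real_,
               LQ = LQ, LS = as.integer(round(targetLS)),
               lambda2Fixed = all(vapply(fits, function(f) f@lambda2Fixed,
                                         logical(1))))
    attr(out, "extrapolated") <- extrap
    out
}

#' Simple-sampling estimate of the score distribution
#'
#' Draws independent sequence pairs from the null model and histograms
#' their Smith-Waterman scores: the classical calibration approach, valid
#' in the high-probability bulk (probabilities down to roughly 10 / n).
#'
#' @param model null model.
#' @param scheme a [ScoringScheme-class].
#' @param n number of pairs.
#' @param LQ,LS sequence lengths.
#' @return A [ScoreHistogram-class] with uniform weights (classes: helix
#'   counts for the HMM model, otherwise 0).
#' @export
sampleScoreDistribution <- function(model, scheme, n, LQ, LS) {
    mode <- samplerMode(model)
    ab <- modelAlphabet(model)
    f <- subjectFreqs(model)
    M <- length(ab)
    yi <- matrix(sample.int(M, n * LS, replace = TRUE, prob = f) - 1L,
                 nrow = LS)
    ns <- integer(n)
    if (mode == 0L) {
        xi <- matrix(sample.int(M, n * LQ, replace = TRUE, prob = f) - 1L,
                     nrow = LQ)
    } else if (mode == 1L) {
        xi <- matrix(seqToInt(model@query, ab), ncol = 1)
        LQ <- nrow(xi)
    } else {
        xs <- replicate(n, sampleHMM(model@hmm, LQ)$seq)
        xi <- vapply(xs, function(s) seqToInt(s, ab), integer(LQ))
        ns <- vapply(xs, function(s)
            countTMHelices(viterbiPath(model@hmm, s)$path, model@hmm),
            integer(1))
    }
    xregion <- regionMask(scheme, LQ)
    scores <- cpp_sw_score_many(xi, yi, scheme@defaultMatrix@scores,
                                scheme@regionMatrix@scores, xregion,
                                gapOpenCost(scheme), scheme@gapExtend)
    win <- scoreWindow(min(scores), max(scores) + 1L,
                       classes = sort(unique(ns)))
    counts <- emptyTable(win)
    for (i in seq_len(n)) {
        r <- scores[i] - win@smin + 1L
        c <- match(ns[i], win@classes)
        counts[r, c] <- counts[r, c] + 1
    }
    new("ScoreHistogram", counts = counts, window = win, nSamples = n,
        thinning = 0L, logW = emptyTable(win),
        series = cbind(s = scores, n = ns))
}

#' Bulk estimate of the Gumbel decay rate from simple-sampling data
#'
#' Fits the decay rate lambda of the score law to the right flank of a
#' simple-sampling histogram. Two passes: a crude pure-Gumbel fit just
#' right of the mode locates the center `s0`, then the final fit uses
#' only scores above `s0 + 3/lambda`, where the extreme-value law's
#' double-exponential factor (absent from the modified Gumbel tail
#' formula) is below 5%. The curvature parameter is fixed at zero: on
#' the short score range reachable by simple sampling it is not
#' identifiable and would destabilize lambda; full Wang-Landau runs fit
#' both parameters.
#'
#' @param hist a [ScoreHistogram-class] from [sampleScoreDistribution()].
#' @param LQ,LS sequence lengths.
#' @param minCount right truncation: last bin with at least this many
#'   counts.
#' @return A [ModifiedGumbelFit-class] with `lambda2Fixed = TRUE`.
#' @export
bulkLambdaFit <- function(hist, LQ, LS, minCount = 5) {
    est <- reweight(hist)
    s <- as.numeric(rownames(hist@counts))
    cnt <- rowSums(hist@counts)
    mode <- s[which.max(cnt)]
    hi <- max(s[cnt >= minCount])
    f1 <- fitModifiedGumbel(est, LQ, LS, fitWindow = c(mode + 3, hi),
                            fixLambda2 = TRUE)
    fitModifiedGumbel(est, LQ, LS,
                      fitWindow = c(f1@s0 + 3 / f1@lambda, hi),
                      fixLambda2 = TRUE)
}

#' Score range of the well-sampled bulk of a histogram
#'
#' Contiguous score range around the mode whose marginal counts all reach
#' `minCount`, the region where a simple-sampling fit is reliable.
#'
#' @param hist a [ScoreHistogram-class].
#' @param minCount minimum marginal count per bin.
#' @return Numeric `c(lo, hi)` usable as a `fitWindow`.
#' @export
bulkFitWindow <- function(hist, minCount = 20) {
    m <- rowSums(hist@counts)
    s <- as.numeric(rownames(hist@counts))
    ok <- m >= minCount
    i0 <- which.max(m)
    lo <- i0
    while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- i0
    while (hi < length(m) && ok[hi + 1]) hi <- hi + 1
    c(s[lo], s[hi])
}
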