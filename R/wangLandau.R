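#' Construct a score window
#'
#' The score range of interest for flat-histogram sampling, with unit
#' (integer) score bins, optionally crossed with helix-count classes for
#' the HMM null model.
#'
#' @param smin,smax integer score bounds, `smin < smax`.
#' @param classes helix-count classes covered (default 0, the only class
#'   for non-HMM models). Must be contiguous.
#' @export
scoreWindow <- function(smin, smax, classes = 0L) {
    classes <- sort(as.integer(classes))
    if (length(classes) > 1 && any(diff(classes) != 1L))
        stop("classes must be contiguous")
    new("ScoreWindow", smin = as.integer(smin), smax = as.integer(smax),
        classes = classes)
}

windowScores <- function(window) window@smin:window@smax

emptyTable <- function(window) {
    matrix(0, window@smax - window@smin + 1L, length(window@classes),
           dimnames = list(windowScores(window), window@classes))
}

#' Wang-Landau modification schedule
#'
#' The modification factor starts at `phiInitial`, is reduced by
#' `phi <- sqrt(phi)` whenever the histogram is flat, and the estimation
#' stops once `phi <= phiFinal`. The defaults (`exp(0.1)` down to
#' `exp(2e-4)`) are the range found effective for alignment-score
#' sampling.
#'
#' @param phiInitial,phiFinal initial/final modification factors (> 1).
#' @param flatness flatness fraction: a histogram slice is flat when every
#'   bin exceeds `flatness` times the mean bin count.
#' @export
wlSchedule <- function(phiInitial = exp(0.1), phiFinal = exp(2e-4),
                       flatness = 0.6) {
    stopifnot(phiInitial > 1, phiFinal > 1, phiInitial >= phiFinal,
              flatness > 0, flatness < 1)
    list(phiInitial = phiInitial, phiFinal = phiFinal, flatness = flatness)
}

#' Flatness criterion for a histogram slice
#'
#' A slice is flat when every bin count exceeds `fraction` times the mean
#' count over the window, e.g. `c(10, 6, 8)` is flat at fraction 0.6
#' (mean 8, threshold 4.8) while `c(10, 4, 10)` is not.
#'
#' @param h numeric vector of bin counts (one class slice; masked bins
#'   removed by the caller).
#' @param fraction flatness fraction in (0, 1).
#' @export
isFlat <- function(h, fraction = 0.6) {
    if (length(h) < 2) stop("window is degenerate")
    all(h > fraction * mean(h))
}

#' Estimate flat-histogram weights by the Wang-Landau iteration
#'
#' Runs the Metropolis-Hastings kernel while decrementing the log sampling
#' weight of every visited (score, class) bin by `log(phi)` and counting
#' visits in a histogram H. When H is flat (or, under
#' `flatCriterion = "roundtrips"`, once the walker has cycled
#' `minRoundTrips` times between the window edges), H is reset to zero,
#' `phi <- sqrt(phi)`, and the weights are kept; the iteration terminates
#' when `phi <= phiFinal`. The converged `exp(-logW)` approximates the
#' score pmf up to normalization, and `logW` is the input for a
#' detailed-balance production run.
#'
#' Bins that remain unvisited when a level hits `maxStepsPerLevel` are
#' treated as unsupported under the model and masked from the flatness
#' test from then on.
#'
#' @param model null model.
#' @param scheme a [ScoringScheme-class].
#' @param window a [ScoreWindow-class].
#' @param LQ,LS query/subject lengths.
#' @param schedule a [wlSchedule()].
#' @param initLogW optional warm-start log-weights (matrix as produced by
#'   a previous run or [warmStartWeights()]).
#' @param state optional initial sampler state (default:
#'   [initialConfiguration()]).
#' @param checkInterval steps between flatness checks.
#' @param maxStepsPerLevel guard against non-termination of a level.
#' @param flatCriterion `"fraction"` (histogram flatness) or
#'   `"roundtrips"`.
#' @param minRoundTrips round trips per level under
#'   `flatCriterion = "roundtrips"`.
#' @return A [WangLandauResult-class].
#' @export
wlEstimate <- function(model, scheme, window, LQ, LS,
                       schedule = wlSchedule(), initLogW = NULL,
                       state = NULL, checkInterval = 1000L,
                       maxStepsPerLevel = Inf,
                       flatCriterion = c("fraction", "roundtrips"),
                       minRoundTrips = 2L) {
    flatCriterion <- match.arg(flatCriterion)
    params <- chainParams(model, scheme, window)
    if (is.null(state))
        state <- initialConfiguration(model, scheme, window, LQ, LS)
    xregion <- regionMask(scheme, length(state$x))
    logW <- if (is.null(initLogW)) emptyTable(window)
            else {
                stopifnot(all(dim(initLogW) == dim(emptyTable(window))))
                initLogW + 0  # force a copy: the kernel updates in place
            }
    dimnames(logW) <- dimnames(emptyTable(window))
    H <- emptyTable(window)
    masked <- emptyTable(window) > 0  # all FALSE
    everVisited <- masked
    logPhi <- log(schedule$phiInitial)
    logPhiFinal <- log(schedule$phiFinal)
    rt <- list(phase = 0L, count = 0, offset = 0)
    rtStamps <- numeric(0)
    stepsPerLevel <- numeric(0)
    level <- 0L
    while (logPhi > logPhiFinal) {
        level <- level + 1L
        H[] <- 0
        levelSteps <- 0
        rtAtLevelStart <- rt$count
        repeat {
            res <- runSteps(state, checkInterval, params, xregion, logW, H,
                            logPhi, 0L, rt)
            state <- res[c("x", "y", "score", "n_tm", "log_query",
                           "log_null")]
            rt <- list(phase = res$rt_phase, count = res$rt_count,
                       offset = rt$offset + res$steps)
            rtStamps <- c(rtStamps, res$rt_stamps)
            levelSteps <- levelSteps + res$steps
            everVisited <- everVisited | (H > 0)
            flat <- if (flatCriterion == "roundtrips")
                rt$count - rtAtLevelStart >= minRoundTrips
            else
                all(vapply(seq_along(window@classes), function(k) {
                    hh <- H[!masked[, k], k]
                    length(hh) < 2 || isFlat(hh, schedule$flatness)
                }, logical(1)))
            if (flat) break
            if (levelSteps >= maxStepsPerLevel) {
                ## the first level is pure exploration: do not conclude
                ## unreachability from it
                newMask <- if (level > 1L) !everVisited & !masked
                           else masked & FALSE
                if (any(newMask)) {
                    masked <- masked | newMask
                    warning(sum(newMask), " unreachable bin(s) masked ",
                            "from the flatness test")
                }
                break
            }
        }
        stepsPerLevel <- c(stepsPerLevel, levelSteps)
        logPhi <- logPhi / 2  # phi <- sqrt(phi)
    }
    new("WangLandauResult", logW = logW, H = H, window = window,
        schedule = schedule, roundTrips = rt$count, rtStamps = rtStamps,
        stepsPerLevel = stepsPerLevel, finalState = state, masked = masked)
}

#' Fixed-weight (detailed balance) production run
#'
#' Runs the Metropolis-Hastings kernel with frozen weights (phi = 1), so
#' detailed balance holds, and records the (score, class) of every k-th
#' update. The thinned series is kept for blocking error analysis.
#'
#' @param model,scheme,window as in [wlEstimate()].
#' @param logW log-weight matrix (e.g. from [wlEstimate()]); a
#'   zero matrix reduces to plain null-model sampling on the window.
#' @param nSamples number of recorded samples N.
#' @param thinning record every k-th update (default `LQ + LS`, roughly
#'   one proposal per sequence position between records).
#' @param LQ,LS sequence lengths.
#' @param state optional initial sampler state.
#' @return A [ScoreHistogram-class] whose counts sum to `nSamples`;
#'   `attr(, "wl")` carries round-trip diagnostics.
#' @export
productionRun <- function(model, scheme, window, logW, nSamples,
                          LQ, LS, thinning = LQ + LS, state = NULL) {
    params <- chainParams(model, scheme, window)
    if (is.null(state))
        state <- initialConfiguration(model, scheme, window, LQ, LS)
    xregion <- regionMask(scheme, length(state$x))
    stopifnot(all(dim(logW) == dim(emptyTable(window))))
    logW <- logW + 0
    dimnames(logW) <- dimnames(emptyTable(window))
    H <- emptyTable(window)
    thinning <- as.integer(thinning)
    res <- runSteps(state, as.integer(nSamples) * thinning, params, xregion,
                    logW, H, 0, recordEvery = thinning)
    counts <- emptyTable(window)
    for (i in seq_along(res$rec_s)) {
        r <- res$rec_s[i] - window@smin + 1L
        c <- res$rec_n[i] - min(window@classes) + 1L
        counts[r, c] <- counts[r, c] + 1
    }
    hist <- new("ScoreHistogram", counts = counts, window = window,
                nSamples = length(res$rec_s), thinning = thinning,
                logW = logW, series = cbind(s = res$rec_s, n = res$rec_n))
    attr(hist, "state") <- res[c("x", "y", "score", "n_tm", "log_query",
                                 "log_null")]
    attr(hist, "accepted") <- res$accepted
    attr(hist, "roundTrips") <- res$rt_count
    hist
}

#' Transfer log-weights to a new score window
#'
#' Warm starts a Wang-Landau estimation from the weights (or the inverse
#' pmf) of a previous, nearby run: log-weights are interpolated linearly
#' in the score onto the new window and extrapolated beyond the covered
#' range using the edge slope (log-weights of alignment scores are close
#' to linear in the tail).
#'
#' @param source a [WangLandauResult-class], [DistributionEstimate-class]
#'   (whose inverse pmf is used) or a log-weight matrix with score
#'   rownames.
#' @param newWindow target [ScoreWindow-class].
#' @return Log-weight matrix over the new window; zero (uniform) with a
#'   warning if the windows are disjoint.
#' @export
warmStartWeights <- function(source, newWindow) {
    if (is(source, "WangLandauResult")) {
        lw <- source@logW
    } else if (is(source, "DistributionEstimate")) {
        lw <- -source@logProb
        lw[!is.finite(lw)] <- NA
    } else lw <- source
    src <- as.integer(rownames(lw))
    out <- emptyTable(newWindow)
    tgt <- windowScores(newWindow)
    if (max(src) < newWindow@smin || min(src) > newWindow@smax) {
        warning("source window disjoint from target; uniform weights")
        return(out)
    }
    for (k in seq_len(ncol(out))) {
        kk <- min(k, ncol(lw))
        v <- lw[, kk]
        ok <- is.finite(v)
        if (sum(ok) < 2) next
        sOK <- src[ok]
        vOK <- v[ok]
        inside <- approx(sOK, vOK, xout = tgt, rule = 1)$y
        nlo <- min(sOK)
        nhi <- max(sOK)
        slopeLo <- (vOK[2] - vOK[1]) / (sOK[2] - sOK[1])
        m <- length(vOK)
        slopeHi <- (vOK[m] - vOK[m - 1]) / (sOK[m] - sOK[m - 1])
        lo <- tgt < nlo
        hi <- tgt > nhi
        inside[lo] <- vOK[1] + slopeLo * (tgt[lo] - nlo)
        inside[hi] <- vOK[m] + slopeHi * (tgt[hi] - nhi)
        out[, k] <- inside
    }
    out
}
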