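## Brute-force oracles: independent reference implementations used by the
## test suite to validate the samplers and the alignment kernel on tiny,
## fully enumerable problems. They share no code with the paths they check.

#' Toy universe for exhaustive enumeration
#'
#' A tiny alphabet and sequence-length setting whose full configuration
#' space (all sequence pairs) can be enumerated, making exact score
#' distributions, transition matrices and stationary distributions
#' computable.
#'
#' @param model null model (toy-sized alphabet).
#' @param scheme scoring scheme over the same alphabet.
#' @param LQ,LS sequence lengths.
#' @return List with the pieces plus the enumerated sequence sets.
#' @export
toyUniverse <- function(model, scheme, LQ, LS) {
    ab <- modelAlphabet(model)
    M <- length(ab)
    if (M^(LQ + LS) > 1e6) stop("universe too large to enumerate")
    allSeqs <- function(L) {
        if (L == 0) return("")
        g <- do.call(expand.grid, rep(list(ab), L))
        apply(g, 1, paste, collapse = "")
    }
    list(model = model, scheme = scheme, LQ = LQ, LS = LS,
         xSeqs = allSeqs(LQ), ySeqs = allSeqs(LS), alphabet = ab)
}

## brute-force forward probability: sum over all state paths
forwardBrute <- function(hmm, seq) {
    idx <- seqToInt(seq, hmm@alphabet) + 1L
    K <- length(hmm@states)
    L <- length(idx)
    paths <- do.call(expand.grid, rep(list(seq_len(K)), L))
    tot <- 0
    for (r in seq_len(nrow(paths))) {
        z <- as.integer(paths[r, ])
        p <- hmm@initial[z[1]] * hmm@emissions[z[1], idx[1]]
        if (L > 1) for (i in 2:L)
            p <- p * hmm@transitions[z[i - 1], z[i]] *
                hmm@emissions[z[i], idx[i]]
        tot <- tot + p
    }
    unname(tot)
}

## brute-force Viterbi: best path by exhaustive enumeration
viterbiBrute <- function(hmm, seq) {
    idx <- seqToInt(seq, hmm@alphabet) + 1L
    K <- length(hmm@states)
    L <- length(idx)
    paths <- do.call(expand.grid, rep(list(seq_len(K)), L))
    best <- -Inf
    bestPath <- NULL
    for (r in seq_len(nrow(paths))) {
        z <- as.integer(paths[r, ])
        p <- hmm@initial[z[1]] * hmm@emissions[z[1], idx[1]]
        if (L > 1) for (i in 2:L)
            p <- p * hmm@transitions[z[i - 1], z[i]] *
                hmm@emissions[z[i], idx[i]]
        if (p > best) {
            best <- p
            bestPath <- z
        }
    }
    list(path = hmm@states[bestPath], prob = unname(best))
}

## null probability of a toy configuration
toyNullProb <- function(universe, x, y) {
    model <- universe$model
    mode <- samplerMode(model)
    if (mode == 0L)
        exp(iidLogProb(model, x) + iidLogProb(model, y))
    else if (mode == 1L) {
        if (x != model@query) 0
        else exp(iidLogProb(model@subjectModel, y))
    } else
        forwardBrute(model@hmm, x) * exp(iidLogProb(model@subjectModel, y))
}

toyClass <- function(universe, x) {
    model <- universe$model
    if (samplerMode(model) != 2L) return(0L)
    countTMHelices(viterbiBrute(model@hmm, x)$path, model@hmm)
}

#' Exact score (and class) distribution by enumeration
#'
#' Sums the null probability of every sequence pair into (score, class)
#' bins; the exact reference for the sampled estimators.
#'
#' @param universe a [toyUniverse()].
#' @return List with `pmf` (matrix scores x classes, dimnames give the
#'   values), `marginal`, and the score `support`.
#' @export
exactScoreDistribution <- function(universe) {
    xs <- universe$xSeqs
    if (samplerMode(universe$model) == 1L) xs <- universe$model@query
    recs <- list()
    for (x in xs) {
        px <- if (samplerMode(universe$model) == 2L)
            forwardBrute(universe$model@hmm, x)
        else if (samplerMode(universe$model) == 1L) 1
        else exp(iidLogProb(universe$model, x))
        n <- toyClass(universe, x)
        for (y in universe$ySeqs) {
            py <- exp(iidLogProb(
                if (samplerMode(universe$model) == 0L) universe$model
                else universe$model@subjectModel, y))
            s <- smithWatermanScore(x, y, universe$scheme)
            key <- paste(s, n)
            recs[[key]] <- (if (is.null(recs[[key]])) 0 else recs[[key]]) +
                px * py
        }
    }
    ks <- do.call(rbind, strsplit(names(recs), " "))
    ss <- as.integer(ks[, 1])
    nn <- as.integer(ks[, 2])
    srange <- min(ss):max(ss)
    nrange <- sort(unique(nn))
    pmf <- matrix(0, length(srange), length(nrange),
                  dimnames = list(srange, nrange))
    for (i in seq_along(recs))
        pmf[as.character(ss[i]), as.character(nn[i])] <- recs[[i]]
    list(pmf = pmf / sum(pmf), marginal = rowSums(pmf) / sum(pmf),
         support = srange)
}

#' Optimal local alignment score by exhaustive pair-set maximization
#'
#' Maximizes the alignment score over every valid set of non-crossing
#' index pairs, charging `open + extend * l` (per the scheme's convention)
#' for each internal run of unpaired positions, flanks free. A memoized
#' recursion over the last chosen pair; independent of the
#' Smith-Waterman dynamic program it validates.
#'
#' @param x,y sequences (length <= 8 each).
#' @param scheme a [ScoringScheme-class].
#' @return Integer optimal score (>= 0: the empty alignment is valid).
#' @export
enumerateAlignments <- function(x, y, scheme) {
    ab <- schemeAlphabet(scheme)
    xi <- seqToInt(x, ab) + 1L
    yi <- seqToInt(y, ab) + 1L
    lx <- length(xi)
    ly <- length(yi)
    if (lx > 8 || ly > 8) stop("sequences too long for enumeration")
    if (lx == 0 || ly == 0) return(0L)
    mask <- regionMask(scheme, lx)
    pairScore <- function(i, j) {
        m <- if (mask[i]) scheme@regionMatrix@scores
             else scheme@defaultMatrix@scores
        m[xi[i], yi[j]]
    }
    memo <- array(NA_real_, c(lx + 1, ly + 1))
    ## best additional score after having matched (iPrev, jPrev)
    rec <- function(iPrev, jPrev) {
        if (!is.na(memo[iPrev + 1, jPrev + 1]))
            return(memo[iPrev + 1, jPrev + 1])
        best <- 0  # stop here; trailing flank is free
        for (i in seq_len(lx)[seq_len(lx) > iPrev]) {
            for (j in seq_len(ly)[seq_len(ly) > jPrev]) {
                g <- 0
                if (iPrev > 0) {  # internal gaps only
                    g <- g + gapCost(scheme, i - iPrev - 1L) +
                        gapCost(scheme, j - jPrev - 1L)
                }
                best <- max(best, pairScore(i, j) - g + rec(i, j))
            }
        }
        memo[iPrev + 1, jPrev + 1] <<- best
        best
    }
    as.integer(rec(0L, 0L))
}

#' Explicit Metropolis-Hastings transition matrix on a toy universe
#'
#' Assembles the full transition matrix of the sampler kernel over every
#' configuration (sequence pair) from first principles: move proposal
#' probabilities (sequence choice, move kind, position, symbol) and the
#' acceptance ratio computed from the stationary target
#' q(x, y) = w(S, n) p(x, y). Enables exact detailed-balance and
#' stationary-distribution assertions.
#'
#' @param universe a [toyUniverse()].
#' @param logW log-weight matrix with score rownames and class colnames
#'   covering every reachable (score, class).
#' @return List with `T` (transition matrix), `q` (normalized stationary
#'   target), `configs` (data.frame of x, y, score, class).
#' @export
chainTransitionMatrix <- function(universe, logW) {
    model <- universe$model
    mode <- samplerMode(model)
    ab <- universe$alphabet
    M <- length(ab)
    f <- subjectFreqs(model)
    xs <- if (mode == 1L) universe$model@query else universe$xSeqs
    cfg <- expand.grid(x = xs, y = universe$ySeqs,
                       stringsAsFactors = FALSE)
    cfg$score <- mapply(function(x, y)
        smithWatermanScore(x, y, universe$scheme), cfg$x, cfg$y)
    cfg$class <- vapply(cfg$x, function(x) toyClass(universe, x),
                        integer(1))
    cfg$p <- mapply(function(x, y) toyNullProb(universe, x, y),
                    cfg$x, cfg$y)
    nC <- nrow(cfg)
    key <- paste(cfg$x, cfg$y)
    lw <- function(s, n) logW[as.character(s), as.character(n)]
    Tm <- matrix(0, nC, nC, dimnames = list(key, key))
    kindP <- c(0.5, 0.125, 0.125, 0.125, 0.125)
    for (a in seq_len(nC)) {
        for (whichSeq in c("x", "y")) {
            if (mode == 1L && whichSeq == "x") next
            seqP <- if (mode == 1L) 1 else 0.5
            seqA <- cfg[[whichSeq]][a]
            L <- nchar(seqA)
            uniformSym <- (mode == 2L && whichSeq == "x")
            for (k in seq_along(moveKinds())) {
                for (pos in seq_len(L)) {
                    for (sy in seq_len(M)) {
                        symP <- if (uniformSym) 1 / M else f[[ab[sy]]]
                        cand <- applyMove(seqA, moveKinds()[k], pos, ab[sy])
                        bKey <- if (whichSeq == "x")
                            paste(cand, cfg$y[a]) else paste(cfg$x[a], cand)
                        b <- match(bKey, key)
                        prob <- seqP * kindP[k] * (1 / L) * symP
                        ## acceptance from the target ratio: the kernel's
                        ## proposal construction makes the proposal ratio
                        ## cancel everything except w (and the HMM query
                        ## probability, whose proposals are uniform)
                        num <- lw(cfg$score[b], cfg$class[b])
                        den <- lw(cfg$score[a], cfg$class[a])
                        dl <- num - den
                        if (uniformSym) {
                            fx2 <- forwardBrute(model@hmm, cand)
                            fx1 <- forwardBrute(model@hmm, cfg$x[a])
                            dl <- dl + log(fx2) - log(fx1)
                        }
                        alpha <- min(1, exp(dl))
                        Tm[a, b] <- Tm[a, b] + prob * alpha
                        if (alpha < 1)
                            Tm[a, a] <- Tm[a, a] + prob * (1 - alpha)
                    }
                }
            }
        }
    }
    q <- cfg$p * exp(mapply(lw, cfg$score, cfg$class))
    list(T = Tm, q = q / sum(q), configs = cfg)
}
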