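#' HMM-query model constructor
#'
#' @param hmm query [HiddenMarkovModel-class].
#' @param subjectModel subject [IIDModel-class].
#' @export
hmmQueryModel <- function(hmm, subjectModel = iidModel()) {
    new("HMMQueryModel", hmm = hmm, subjectModel = subjectModel)
}

## mode codes shared with the compiled driver
samplerMode <- function(model) {
    if (is(model, "IIDModel")) 0L
    else if (is(model, "FixedQueryModel")) 1L
    else if (is(model, "HMMQueryModel")) 2L
    else stop("unsupported null model class: ", class(model))
}

modelAlphabet <- function(model) {
    switch(samplerMode(model) + 1L,
           model@alphabet,
           model@subjectModel@alphabet,
           model@subjectModel@alphabet)
}

subjectFreqs <- function(model) {
    if (is(model, "IIDModel")) model@freqs else model@subjectModel@freqs
}

#' The five elementary sequence moves
#'
#' Length-preserving Monte Carlo edits of a sequence: substitution of a
#' symbol at a position, insertion at a position with a left or right shift
#' (the first or last symbol drops off), and deletion at a position with a
#' right or left shift (a new symbol enters at the beginning or end).
#'
#' @return Character vector of the five move names.
#' @export
moveKinds <- function() {
    c("substitute", "insert_left_shift", "insert_right_shift",
      "delete_right_shift", "delete_left_shift")
}

#' Apply an elementary move to a sequence
#'
#' Deterministic application of one of the five moves; see [moveKinds()].
#' For example, inserting D at position 5 of `"LGQIWTAE"` with left shift
#' gives `"GQIWDTAE"`.
#'
#' @param seq sequence string.
#' @param kind one of [moveKinds()].
#' @param position 1-based position in `[1, nchar(seq)]`.
#' @param symbol replacement symbol (single character).
#' @return The edited sequence (same length).
#' @export
applyMove <- function(seq, kind, position, symbol) {
    ch <- seqChars(seq)
    L <- length(ch)
    if (position < 1 || position > L) stop("position out of range")
    kind <- match.arg(kind, moveKinds())
    out <- switch(kind,
        substitute = {
            ch[position] <- symbol
            ch
        },
        insert_left_shift =
            c(ch[seq_len(position)][-1], symbol,
              if (position < L) ch[(position + 1):L]),
        insert_right_shift =
            c(ch[seq_len(position - 1)], symbol,
              if (position < L) ch[position:(L - 1)]),
        delete_right_shift =
            c(symbol, ch[seq_len(position - 1)],
              if (position < L) ch[(position + 1):L]),
        delete_left_shift =
            c(ch[seq_len(position - 1)],
              if (position < L) ch[(position + 1):L], symbol))
    paste(out, collapse = "")
}

#' Draw a proposal for the Metropolis-Hastings kernel
#'
#' Chooses the sequence to edit (query or subject with probability 1/2
#' each, subject only for the fixed-query model), the move kind
#' (substitution with probability 1/2, each shift move 1/8), a uniform
#' position, and a replacement symbol from the null frequencies (or
#' uniformly for HMM-generated queries). Returns the candidate edit and
#' the proposal log-ratio `log(P_rev / P_fwd)`; for frequency-weighted
#' symbol proposals this ratio cancels the i.i.d. null-probability ratio
#' exactly, which is what makes the acceptance depend on the score alone.
#'
#' @param x,y current query and subject strings.
#' @param model the null model (decides policy).
#' @return List with `which` ("x" or "y"), `kind`, `position`, `symbol`,
#'   `removed` (the symbol leaving the sequence), `candidate` (the edited
#'   sequence) and `logRatio`.
#' @export
proposeMove <- function(x, y, model) {
    mode <- samplerMode(model)
    ab <- modelAlphabet(model)
    f <- subjectFreqs(model)
    which <- if (mode == 1L) "y" else if (runif(1) < 0.5) "x" else "y"
    seq <- if (which == "x") x else y
    L <- nchar(seq)
    kind <- if (runif(1) < 0.5) "substitute"
            else moveKinds()[1L + sample.int(4L, 1)]
    position <- sample.int(L, 1)
    uniformSym <- (mode == 2L && which == "x")
    symbol <- if (uniformSym) sample(ab, 1) else sample(ab, 1, prob = f)
    candidate <- applyMove(seq, kind, position, symbol)
    removed <- switch(kind,
        substitute = substr(seq, position, position),
        insert_left_shift = substr(seq, 1, 1),
        insert_right_shift = substr(seq, L, L),
        delete_right_shift = substr(seq, position, position),
        delete_left_shift = substr(seq, position, position))
    logRatio <- if (uniformSym) 0 else log(f[removed]) - log(f[symbol])
    list(which = which, kind = kind, position = position, symbol = symbol,
         removed = removed, candidate = candidate,
         logRatio = as.numeric(logRatio))
}

## ---- internal sampler state ------------------------------------------

## sampler state: integer sequences plus cached score/class/probabilities
newState <- function(model, scheme, x, y) {
    ab <- modelAlphabet(model)
    xi <- seqToInt(x, ab)
    yi <- seqToInt(y, ab)
    s <- smithWatermanScore(x, y, scheme)
    mode <- samplerMode(model)
    if (mode == 2L) {
        lq <- forwardLogProb(model@hmm, x)$log_prob
        vt <- viterbiPath(model@hmm, x)
        n <- countTMHelices(vt$path, model@hmm)
        ln <- lq + iidLogProb(model@subjectModel, y)
    } else {
        lq <- 0
        n <- 0L
        qm <- if (mode == 0L) model else model@subjectModel
        sm <- if (mode == 0L) model else model@subjectModel
        ln <- iidLogProb(qm, x) + iidLogProb(sm, y)
    }
    list(x = xi, y = yi, score = as.integer(s), n_tm = as.integer(n),
         log_query = lq, log_null = ln)
}

stateSequences <- function(state, model) {
    ab <- modelAlphabet(model)
    list(x = intToSeq(state$x, ab), y = intToSeq(state$y, ab))
}

## assemble the constant arguments of the compiled driver
chainParams <- function(model, scheme, window) {
    ab <- modelAlphabet(model)
    stopifnot(identical(ab, schemeAlphabet(scheme)))
    f <- subjectFreqs(model)
    mode <- samplerMode(model)
    if (mode == 2L) {
        hp <- hmmLogParams(model@hmm)
    } else {
        hp <- list(logEmis = matrix(0, 0, 0), logTrans = matrix(0, 0, 0),
                   logInit = numeric(0), isCore = logical(0))
    }
    list(mode = mode, freqs = as.numeric(f), logFreqs = log(as.numeric(f)),
         mdef = scheme@defaultMatrix@scores, mreg = scheme@regionMatrix@scores,
         openCost = gapOpenCost(scheme), extCost = scheme@gapExtend,
         smin = window@smin, smax = window@smax,
         nmin = min(window@classes), nmax = max(window@classes),
         hmm = hp)
}

## run the compiled kernel for nSteps; logW/H are modified in place
runSteps <- function(state, nSteps, params, xregion, logW, H, logPhi,
                     recordEvery = 0L, rt = list(phase = 0L, count = 0,
                                                 offset = 0)) {
    cpp_run_chain(state, as.integer(nSteps), params$mode, params$freqs,
                  params$logFreqs, params$mdef, params$mreg, xregion,
                  params$openCost, params$extCost, params$smin, params$smax,
                  params$nmin, params$nmax, logW, H, logPhi,
                  as.integer(recordEvery), params$hmm$logEmis,
                  params$hmm$logTrans, params$hmm$logInit, params$hmm$isCore,
                  rt$offset, rt$phase, rt$count)
}

#' One (or more) Metropolis-Hastings updates of the sampler
#'
#' Runs the sequence-space Metropolis-Hastings kernel under the biased
#' distribution q(x, y) = w(S(x, y), n) p(x, y). Proposals whose score or
#' class falls outside the window are rejected (the current bin is counted
#' again); the acceptance ratio reduces to w(S')/w(S) for i.i.d. symbol
#' proposals and includes the HMM query probability ratio otherwise.
#'
#' @param state sampler state from [initialConfiguration()] (or a previous
#'   call), carrying sequences, score, class and cached log-probabilities.
#' @param model null model ([IIDModel-class], [FixedQueryModel-class] or
#'   [HMMQueryModel-class]).
#' @param scheme a [ScoringScheme-class].
#' @param window a [ScoreWindow-class]; `logW` must cover it.
#' @param logW log-weight matrix (scores x classes); uniform (all zero)
#'   weights give plain null-model sampling restricted to the window.
#' @param nSteps number of elementary updates.
#' @return Updated state; `attr(, "accepted")` carries the acceptance count.
#' @export
mhUpdate <- function(state, model, scheme, window, logW, nSteps = 1L) {
    params <- chainParams(model, scheme, window)
    xregion <- regionMask(scheme, length(state$x))
    H <- matrix(0, nrow(logW), ncol(logW))
    res <- runSteps(state, nSteps, params, xregion, logW, H, 0)
    out <- res[c("x", "y", "score", "n_tm", "log_query", "log_null")]
    attr(out, "accepted") <- res$accepted
    out
}

#' Find an initial configuration inside the score window
#'
#' Draws sequence pairs from the null model; if none lands inside the
#' window, greedily hill-climbs (accepting any move that raises the score)
#' until the score reaches the window.
#'
#' @param model null model.
#' @param scheme scoring scheme.
#' @param window target [ScoreWindow-class].
#' @param LQ,LS sequence lengths (LQ ignored for a fixed query).
#' @param maxTries bound on null-model draws before hill-climbing.
#' @param maxClimb bound on hill-climbing proposals.
#' @return A sampler state (see [mhUpdate()]).
#' @export
initialConfiguration <- function(model, scheme, window, LQ, LS,
                                 maxTries = 200L, maxClimb = 1e6L) {
    mode <- samplerMode(model)
    drawPair <- function() {
        x <- switch(mode + 1L,
                    sampleIID(model, LQ),
                    model@query,
                    sampleHMM(model@hmm, LQ)$seq)
        y <- sampleIID(if (mode == 0L) model else model@subjectModel, LS)
        newState(model, scheme, x, y)
    }
    st <- drawPair()
    tries <- 1L
    while ((st$score < window@smin || st$score > window@smax ||
            !(st$n_tm %in% window@classes)) && tries < maxTries) {
        cand <- drawPair()
        tries <- tries + 1L
        if (cand$score > st$score && cand$score <= window@smax) st <- cand
        if (st$score >= window@smin && st$score <= window@smax &&
            st$n_tm %in% window@classes) break
    }
    if (st$score >= window@smin && st$score <= window@smax &&
        st$n_tm %in% window@classes) return(st)
    ## greedy hill climb: uphill moves only, within the class constraint
    ab <- modelAlphabet(model)
    f <- subjectFreqs(model)
    seqs <- stateSequences(st, model)
    climb <- 0L
    while (st$score < window@smin && climb < maxClimb) {
        climb <- climb + 1L
        prop <- proposeMove(seqs$x, seqs$y, model)
        x2 <- if (prop$which == "x") prop$candidate else seqs$x
        y2 <- if (prop$which == "y") prop$candidate else seqs$y
        s2 <- smithWatermanScore(x2, y2, scheme)
        if (s2 > st$score && s2 <= window@smax) {
            st2 <- newState(model, scheme, x2, y2)
            if (st2$n_tm %in% window@classes || mode != 2L) {
                st <- st2
                seqs <- list(x = x2, y = y2)
            }
        }
    }
    if (st$score < window@smin || st$score > window@smax)
        stop("could not reach the score window from the null model")
    st
}
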