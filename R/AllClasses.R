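#' Independent-letters (i.i.d.) sequence model
#'
#' Null model in which every position carries a symbol drawn independently
#' from a fixed frequency vector, the classical background model of local
#' alignment statistics.
#'
#' @slot alphabet character vector of single-letter symbols.
#' @slot freqs named numeric vector of positive symbol frequencies summing
#'   to one.
#' @exportClass IIDModel
setClass("IIDModel",
    representation(alphabet = "character", freqs = "numeric"),
    validity = function(object) {
        if (length(object@freqs) != length(object@alphabet))
            return("freqs and alphabet lengths differ")
        if (any(object@freqs <= 0))
            return("all frequencies must be strictly positive")
        if (abs(sum(object@freqs) - 1) > 1e-12)
            return("frequencies must sum to 1 (within 1e-12)")
        if (!identical(names(object@freqs), object@alphabet))
            return("freqs must be named by the alphabet, in order")
        TRUE
    })

#' Fixed-query null model
#'
#' The query sequence is held fixed; only the subject is random (i.i.d.).
#' This is the null model behind query-specific p-values for
#' position-dependent scoring schemes.
#'
#' @slot query fixed query sequence (single string).
#' @slot subjectModel an [IIDModel-class] for the subject.
#' @exportClass FixedQueryModel
setClass("FixedQueryModel",
    representation(query = "character", subjectModel = "IIDModel"),
    validity = function(object) {
        if (length(object@query) != 1L || nchar(object@query) < 1L)
            return("query must be a single non-empty sequence string")
        TRUE
    })

#' Hidden Markov model over sequences
#'
#' A discrete HMM with tied emission groups and a designated set of
#' helix-core states, as used to model transmembrane protein topology.
#' All probability parameters are stored on the natural scale; computations
#' are carried out in log space.
#'
#' @slot states ordered state names.
#' @slot initial named initial state distribution.
#' @slot emissions states-by-symbols emission probability matrix.
#' @slot transitions states-by-states stochastic transition matrix.
#' @slot tieGroups list of character vectors partitioning states that share
#'   an emission row.
#' @slot helixCoreStates states whose maximal runs along a path are counted
#'   as transmembrane helices.
#' @slot alphabet emission alphabet.
#' @exportClass HiddenMarkovModel
setClass("HiddenMarkovModel",
    representation(states = "character", initial = "numeric",
                   emissions = "matrix", transitions = "matrix",
                   tieGroups = "list", helixCoreStates = "character",
                   alphabet = "character"),
    validity = function(object) {
        K <- length(object@states)
        if (anyDuplicated(object@states)) return("duplicate state names")
        if (length(object@initial) != K) return("initial length mismatch")
        if (abs(sum(object@initial) - 1) > 1e-12)
            return("initial distribution must sum to 1")
        if (!all(dim(object@emissions) == c(K, length(object@alphabet))))
            return("emissions must be states x symbols")
        if (any(abs(rowSums(object@emissions) - 1) > 1e-12))
            return("every emission row must sum to 1 (within 1e-12)")
        if (!all(dim(object@transitions) == c(K, K)))
            return("transitions must be square states x states")
        if (any(abs(rowSums(object@transitions) - 1) > 1e-12))
            return("every transition row must sum to 1 (within 1e-12)")
        if (!all(unlist(object@tieGroups) %in% object@states))
            return("tie group refers to unknown state")
        for (g in object@tieGroups) {
            if (length(g) > 1) {
                rows <- object@emissions[g, , drop = FALSE]
                if (!all(apply(rows, 2, function(cc) all(cc == cc[1]))))
                    return("tied states must have identical emission rows")
            }
        }
        if (!all(object@helixCoreStates %in% object@states))
            return("helixCoreStates must be a subset of states")
        TRUE
    })

#' Integer substitution matrix
#'
#' @slot scores integer score matrix with symbol dimnames; need not be
#'   symmetric (transmembrane-specific matrices are not).
#' @slot name label for display and serialization.
#' @exportClass ScoringMatrix
setClass("ScoringMatrix",
    representation(scores = "matrix", name = "character"),
    validity = function(object) {
        s <- object@scores
        if (is.null(rownames(s)) || is.null(colnames(s)))
            return("scores must carry symbol dimnames")
        if (any(s != round(s))) return("scores must be integer-valued")
        TRUE
    })

#' Bipartite position-specific scoring scheme with affine gaps
#'
#' Query positions falling inside `queryRegions` (1-based inclusive
#' intervals, e.g. predicted transmembrane helices) are scored with
#' `regionMatrix`; all other positions with `defaultMatrix`. Subject
#' positions are homogeneous. A gap of length l costs
#' `gapOpen + gapExtend * l` under the default `"open_plus_len"` convention
#' or `gapOpen + gapExtend * (l - 1)` under `"open_plus_len_minus_1"`.
#'
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(defaultMatrix = "ScoringMatrix",
                   regionMatrix = "ScoringMatrix",
                   queryRegions = "matrix",
                   gapOpen = "integer", gapExtend = "integer",
                   gapConvention = "character"),
    validity = function(object) {
        if (object@gapOpen < 0 || object@gapExtend < 0)
            return("gap penalties must be non-negative")
        if (!object@gapConvention %in%
            c("open_plus_len", "open_plus_len_minus_1"))
            return("unknown gap cost convention")
        r <- object@queryRegions
        if (nrow(r) > 0) {
            if (any(r[, 1] > r[, 2])) return("region start > end")
            if (any(r[, 1] < 1)) return("regions must be 1-based positive")
            o <- order(r[, 1])
            if (nrow(r) > 1 && any(r[o[-nrow(r)], 2] >= r[o[-1], 1]))
                return("query regions must be non-overlapping")
        }
        TRUE
    })

#' Score window for flat-histogram sampling
#'
#' @slot smin,smax integer score range of interest (unit bins).
#' @slot classes helix-count classes covered (just 0 for non-HMM models).
#' @exportClass ScoreWindow
setClass("ScoreWindow",
    representation(smin = "integer", smax = "integer", classes = "integer"),
    validity = function(object) {
        if (object@smin >= object@smax) return("need smin < smax")
        if (length(object@classes) < 1) return("need at least one class")
        TRUE
    })

#' Histogram of sampled scores (and helix classes)
#'
#' Counts of recorded samples per (score, class) bin together with the
#' sampling weights in force, sufficient for importance reweighting.
#'
#' @exportClass ScoreHistogram
setClass("ScoreHistogram",
    representation(counts = "matrix", window = "ScoreWindow",
                   nSamples = "numeric", thinning = "integer",
                   logW = "matrix", series = "matrix"),
    validity = function(object) {
        if (abs(sum(object@counts) - object@nSamples) > 0.5)
            return("counts must sum to nSamples")
        TRUE
    })

#' Normalized probability estimate over (score, class) bins
#'
#' @slot logProb log joint pmf per (score, class); `-Inf` where unsupported.
#' @slot logProbMarginal log marginal pmf per score.
#' @slot relError relative standard error per bin (from blocking analysis).
#' @exportClass DistributionEstimate
setClass("DistributionEstimate",
    representation(logProb = "matrix", logProbMarginal = "numeric",
                   relError = "matrix", window = "ScoreWindow",
                   nSamples = "numeric"),
    validity = function(object) {
        z <- logSumExp(as.numeric(object@logProb))
        if (abs(exp(z) - 1) > 1e-9) return("pmf must sum to 1 (within 1e-9)")
        if (any(object@relError < 0, na.rm = TRUE))
            return("errors must be non-negative")
        TRUE
    })

#' Modified Gumbel fit of a score distribution
#'
#' Parameters of log P(S = s) = log(lambda) - lambda (s - s0) -
#' lambda2 (s - s0)^2, an extreme-value law with a Gaussian finite-size
#' correction, plus the derived Karlin-Altschul-style amplitude
#' K = exp(lambda * s0) / (LQ * LS).
#'
#' @exportClass ModifiedGumbelFit
setClass("ModifiedGumbelFit",
    representation(s0 = "numeric", lambda = "numeric", lambda2 = "numeric",
                   K = "numeric", se = "numeric", covariance = "matrix",
                   fitWindow = "numeric", chisqRed = "numeric",
                   LQ = "integer", LS = "integer", lambda2Fixed = "logical"),
    validity = function(object) {
        if (object@lambda <= 0) return("lambda must be positive")
        if (object@lambda2 < 0) return("lambda2 must be non-negative")
        TRUE
    })

#' Result of a Wang-Landau weight estimation
#'
#' @slot logW converged log sampling weights per (score, class) bin.
#' @slot H visit histogram of the last modification level.
#' @slot masked bins found unreachable and excluded from the flatness test.
#' @slot roundTrips completed traversals between the window edges, with
#'   cumulative step stamps (a mixing-time diagnostic).
#' @exportClass WangLandauResult
setClass("WangLandauResult",
    representation(logW = "matrix", H = "matrix", window = "ScoreWindow",
                   schedule = "list", roundTrips = "numeric",
                   rtStamps = "numeric", stepsPerLevel = "numeric",
                   finalState = "list", masked = "matrix"))

setMethod("show", "IIDModel", function(object) {
    cat("IIDModel over |alphabet| =", length(object@alphabet), "symbols\n")
    top <- sort(object@freqs, decreasing = TRUE)[1:3]
    cat("  top frequencies:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
})

setMethod("show", "HiddenMarkovModel", function(object) {
    cat("HiddenMarkovModel:", length(object@states), "states,",
        length(object@tieGroups), "emission tie groups,",
        length(object@helixCoreStates), "helix-core states\n")
})

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme:", object@defaultMatrix@name)
    if (nrow(object@queryRegions) > 0)
        cat(" +", object@regionMatrix@name, "on",
            nrow(object@queryRegions), "query region(s)")
    cat("; gaps ", object@gapOpen, "/", object@gapExtend, " (",
        object@gapConvention, ")\n", sep = "")
})

setMethod("show", "ScoreWindow", function(object) {
    cat("ScoreWindow [", object@smin, ", ", object@smax, "], classes ",
        paste(object@classes, collapse = ","), "\n", sep = "")
})

setMethod("show", "ScoreHistogram", function(object) {
    cat("ScoreHistogram:", format(object@nSamples, big.mark = ","),
        "samples (thinning", object@thinning, ") on")
    show(object@window)
})

setMethod("show", "DistributionEstimate", function(object) {
    sup <- is.finite(object@logProbMarginal)
    cat("DistributionEstimate on", sum(sup), "supported score bins;",
        "log10 P range [", round(min(object@logProbMarginal[sup]) / log(10), 2),
        ",", round(max(object@logProbMarginal[sup]) / log(10), 2), "]\n")
})

setMethod("show", "ModifiedGumbelFit", function(object) {
    cat(sprintf(
        "ModifiedGumbelFit: s0 = %.3f, lambda = %.4f (+/- %.4f), ",
        object@s0, object@lambda, object@se["lambda"]))
    if (object@lambda2Fixed) cat("lambda2 fixed at 0")
    else cat(sprintf("lambda2 = %.3e (+/- %.1e)", object@lambda2,
                     object@se["lambda2"]))
    cat(sprintf(", K = %.4g, reduced chi^2 = %.2f\n",
                object@K, object@chisqRed))
})

setMethod("show", "WangLandauResult", function(object) {
    cat("WangLandauResult:", length(object@stepsPerLevel),
        "modification levels,", sum(object@stepsPerLevel), "steps,",
        object@roundTrips, "round trips\n")
})

#' HMM-query null model
#'
#' The query is drawn from a hidden Markov model (e.g. a transmembrane
#' topology model) and classified by its Viterbi helix count; the subject
#' is i.i.d. Score statistics are estimated jointly per (score, class).
#'
#' @slot hmm query [HiddenMarkovModel-class].
#' @slot subjectModel subject [IIDModel-class].
#' @exportClass HMMQueryModel
setClass("HMMQueryModel",
    representation(hmm = "HiddenMarkovModel", subjectModel = "IIDModel"),
    validity = function(object) {
        if (!identical(object@hmm@alphabet, object@subjectModel@alphabet))
            return("query and subject models must share an alphabet")
        TRUE
    })
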