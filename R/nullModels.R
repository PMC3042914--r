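#' Construct an i.i.d. sequence model
#'
#' @param freqs named numeric vector of symbol frequencies (normalized
#'   internally). Defaults to the bundled SwissProt amino-acid composition.
#' @param alphabet symbol alphabet; defaults to the names of `freqs`.
#' @return An [IIDModel-class] object.
#' @examples
#' m <- iidModel(c(A = 0.7, B = 0.3))
#' iidLogProb(m, "AAB")
#' @export
iidModel <- function(freqs = swissprotFreqs(), alphabet = names(freqs)) {
    checkAlphabet(alphabet)
    freqs <- freqs[alphabet]
    if (anyNA(freqs)) stop("freqs must cover the whole alphabet")
    freqs <- freqs / sum(freqs)
    new("IIDModel", alphabet = alphabet,
        freqs = setNames(as.numeric(freqs), alphabet))
}

#' Construct a fixed-query null model
#'
#' @param query the fixed query sequence (string).
#' @param subjectModel an [IIDModel-class] for the random subject.
#' @export
fixedQueryModel <- function(query, subjectModel = iidModel()) {
    seqToInt(query, subjectModel@alphabet)  # validates symbols
    new("FixedQueryModel", query = query, subjectModel = subjectModel)
}

#' Background amino-acid frequencies (SwissProt composition)
#'
#' Average amino-acid composition of UniProtKB/Swiss-Prot, the standard
#' background for protein alignment statistics.
#'
#' @return Named numeric vector over [aaAlphabet()], summing to 1.
#' @export
swissprotFreqs <- function() {
    path <- system.file("extdata", "swissprot_freqs.tsv",
                        package = "AlignTails", mustWork = TRUE)
    readFrequencies(path)
}

#' Read a symbol-frequency table
#'
#' Two-column whitespace-delimited text: symbol, frequency. Comment lines
#' start with `#`. Frequencies are normalized to sum to 1.
#'
#' @param path file path.
#' @export
readFrequencies <- function(path) {
    tab <- read.table(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) != 2) stop("expected two columns: symbol, frequency")
    f <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
    if (any(f <= 0)) stop("frequencies must be positive")
    f / sum(f)
}

#' Log-probability of a sequence under an i.i.d. model
#'
#' @param model an [IIDModel-class].
#' @param seq sequence string (may be empty: log-probability 0).
#' @return The log-probability `sum(log f[seq_i])`.
#' @export
iidLogProb <- function(model, seq) {
    idx <- seqToInt(seq, model@alphabet)
    sum(log(model@freqs[idx + 1L]))
}

#' Sample a sequence from an i.i.d. model
#'
#' @param model an [IIDModel-class].
#' @param length number of positions (>= 0).
#' @return Sequence string of the requested length.
#' @export
sampleIID <- function(model, length) {
    stopifnot(length >= 0)
    if (length == 0) return("")
    paste(sample(model@alphabet, length, replace = TRUE,
                 prob = model@freqs), collapse = "")
}

#' Construct a hidden Markov model
#'
#' @param states state names.
#' @param initial initial distribution (named by states or in state order).
#' @param emissions states-by-symbols matrix of emission probabilities.
#' @param transitions states-by-states stochastic matrix.
#' @param tieGroups optional list of state groups sharing emission rows
#'   (default: every state its own group).
#' @param helixCoreStates states whose maximal runs count as TM helices.
#' @param alphabet emission alphabet (default [aaAlphabet()]).
#' @export
hiddenMarkovModel <- function(states, initial, emissions, transitions,
                              tieGroups = NULL, helixCoreStates = character(),
                              alphabet = aaAlphabet()) {
    if (is.null(tieGroups)) tieGroups <- as.list(states)
    initial <- setNames(as.numeric(initial), states)
    dimnames(emissions) <- list(states, alphabet)
    dimnames(transitions) <- list(states, states)
    new("HiddenMarkovModel", states = states, initial = initial,
        emissions = emissions, transitions = transitions,
        tieGroups = tieGroups, helixCoreStates = helixCoreStates,
        alphabet = checkAlphabet(alphabet))
}

hmmLogParams <- function(hmm) {
    list(logEmis = log(hmm@emissions), logTrans = log(hmm@transitions),
         logInit = log(hmm@initial),
         isCore = hmm@states %in% hmm@helixCoreStates)
}

#' Forward algorithm: total sequence log-probability under an HMM
#'
#' Computes `f_mu(i) = p(x_i | mu) * sum_tau f_tau(i-1) p(tau, mu)` in log
#' space, with `f_mu(1) = pi_mu p(x_1 | mu)`; the sequence probability is
#' the log-sum over the final column. Cost O(L |states|^2).
#'
#' @param hmm a [HiddenMarkovModel-class].
#' @param seq non-empty sequence string.
#' @return List with `log_prob` and the full log `table`
#'   (states x positions). A sequence the model cannot emit yields
#'   `log_prob = -Inf` (no error).
#' @export
forwardLogProb <- function(hmm, seq) {
    idx <- seqToInt(seq, hmm@alphabet)
    if (length(idx) == 0) stop("sequence must be non-empty")
    p <- hmmLogParams(hmm)
    res <- cpp_forward(idx, p$logEmis, p$logTrans, p$logInit)
    rownames(res$table) <- hmm@states
    res
}

#' Viterbi algorithm: most probable state path
#'
#' Computes `v_mu(i) = p(x_i | mu) * max_tau v_tau(i-1) p(tau, mu)` in log
#' space and recovers the best path by back-tracking. Ties are broken
#' deterministically towards the lowest state index.
#'
#' @inheritParams forwardLogProb
#' @return List with `path` (state names), `log_prob` of the best path and
#'   the log dynamic-programming `table`.
#' @export
viterbiPath <- function(hmm, seq) {
    idx <- seqToInt(seq, hmm@alphabet)
    if (length(idx) == 0) stop("sequence must be non-empty")
    p <- hmmLogParams(hmm)
    res <- cpp_viterbi(idx, p$logEmis, p$logTrans, p$logInit)
    res$path <- hmm@states[res$path]
    rownames(res$table) <- hmm@states
    res
}

#' Count transmembrane helices along a state path
#'
#' The helix count of a path is the number of maximal runs of helix-core
#' states, the class label of the joint (score, class) statistics.
#'
#' @param path character vector of state names (e.g. from [viterbiPath()]).
#' @param hmm the [HiddenMarkovModel-class] defining the core states.
#' @export
countTMHelices <- function(path, hmm) {
    if (!all(path %in% hmm@states)) stop("path contains unknown states")
    core <- path %in% hmm@helixCoreStates
    sum(core & !c(FALSE, core[-length(core)]))
}

#' Sample a sequence (and its hidden path) from an HMM
#'
#' @param hmm a [HiddenMarkovModel-class].
#' @param length number of positions to generate.
#' @return List with `seq` (string) and `path` (state names).
#' @export
sampleHMM <- function(hmm, length) {
    stopifnot(length >= 1)
    K <- length(hmm@states)
    z <- integer(length)
    z[1] <- sample.int(K, 1, prob = hmm@initial)
    if (length > 1)
        for (i in 2:length)
            z[i] <- sample.int(K, 1, prob = hmm@transitions[z[i - 1], ])
    sym <- vapply(z, function(k)
        sample(hmm@alphabet, 1, prob = hmm@emissions[k, ]), character(1))
    list(seq = paste(sym, collapse = ""), path = hmm@states[z])
}

#' Write an HMM to a structured text file
#'
#' Plain-text key-block format: alphabet, states, initial, helix-core flags,
#' tie groups, emission rows, transition rows (row-stochastic). Round-trips
#' bit-exactly through [readHMM()] (probabilities serialized at full
#' precision).
#'
#' @param hmm a [HiddenMarkovModel-class].
#' @param path output file.
#' @export
writeHMM <- function(hmm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    num <- function(x) sprintf("%.17g", x)
    writeLines(c(paste("alphabet", paste(hmm@alphabet, collapse = " ")),
                 paste("states", paste(hmm@states, collapse = " ")),
                 paste("initial", paste(num(hmm@initial), collapse = " ")),
                 paste("helix_core",
                       paste(hmm@helixCoreStates, collapse = " "))), con)
    for (g in hmm@tieGroups)
        writeLines(paste("tie", paste(g, collapse = " ")), con)
    for (s in hmm@states)
        writeLines(paste("emit", s,
                         paste(num(hmm@emissions[s, ]), collapse = " ")), con)
    for (s in hmm@states)
        writeLines(paste("trans", s,
                         paste(num(hmm@transitions[s, ]), collapse = " ")),
                   con)
    invisible(path)
}

#' Read an HMM from a structured text file
#'
#' Inverse of [writeHMM()]. All model invariants (stochastic rows, tied
#' emission rows bit-identical, known state references) are enforced; the
#' offending row is identified on failure.
#'
#' @param path input file.
#' @export
readHMM <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    tok <- strsplit(trimws(ln), "[ \t]+")
    key <- vapply(tok, `[`, character(1), 1)
    get1 <- function(k) {
        i <- which(key == k)
        if (length(i) != 1) stop("expected exactly one '", k, "' line")
        tok[[i]][-1]
    }
    alphabet <- get1("alphabet")
    states <- get1("states")
    initial <- as.numeric(get1("initial"))
    core <- get1("helix_core")
    if (length(core) == 1 && is.na(core)) core <- character()
    ties <- lapply(tok[key == "tie"], `[`, -1)
    K <- length(states)
    M <- length(alphabet)
    emissions <- matrix(NA_real_, K, M, dimnames = list(states, alphabet))
    transitions <- matrix(NA_real_, K, K, dimnames = list(states, states))
    for (t in tok[key == "emit"]) {
        if (!t[2] %in% states) stop("emission row for unknown state ", t[2])
        v <- as.numeric(t[-(1:2)])
        if (length(v) != M) stop("emission row ", t[2], ": wrong length")
        if (abs(sum(v) - 1) > 1e-12)
            stop("emission row ", t[2], " does not sum to 1")
        emissions[t[2], ] <- v
    }
    for (t in tok[key == "trans"]) {
        if (!t[2] %in% states) stop("transition row for unknown state ", t[2])
        v <- as.numeric(t[-(1:2)])
        if (length(v) != K) stop("transition row ", t[2], ": wrong length")
        if (abs(sum(v) - 1) > 1e-12)
            stop("transition row ", t[2], " does not sum to 1")
        transitions[t[2], ] <- v
    }
    if (anyNA(emissions)) stop("missing emission rows")
    if (anyNA(transitions)) stop("missing transition rows")
    hiddenMarkovModel(states, initial, emissions, transitions,
                      tieGroups = if (length(ties)) ties else NULL,
                      helixCoreStates = core, alphabet = alphabet)
}
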