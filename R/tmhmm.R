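## Transmembrane-topology HMM layout builder.
##
## The architecture follows the classical TM-protein HMM: membrane helices
## are modelled by a core block of up to 25 states entered at one of 21
## depths (core lengths 5..25), flanked by fixed 5-state caps on the
## cytoplasmic and non-cytoplasmic sides; connecting regions are loop
## modules (a ladder of 10 states into a self-looping globular state and a
## 10-state ladder out), one cytoplasmic and two (short/long)
## non-cytoplasmic. Emissions are tied within seven groups (helix core,
## two cap groups, three loop groups, globular); the core-entry jump
## distribution is tied across the two helix directions. The published
## parameter values of the original model are not redistributable here, so
## the default emission and transition values are a documented synthetic
## stand-in with the same layout (hydrophobicity-biased emissions); the
## *architecture*, and therefore the free-parameter count, is the real
## object of interest.

#' Kyte-Doolittle hydropathy scale
#' @noRd
kdHydropathy <- function() {
    c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
      G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
      P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Assemble the transmembrane-protein HMM layout
#'
#' Builds the full TM-topology architecture (see the package vignette for
#' the module diagram) with synthetic stand-in probability values, and
#' records the parameter-tying structure so that the number of independent
#' free parameters can be audited with [freeParameterCount()]. With the
#' default module sizes the layout has 216 free parameters: 7 emission
#' groups x 19, three loop modules x 20 free transitions, 20 core-entry
#' jumps (tied across helix directions), 1 short/long loop branch and 2
#' initial probabilities.
#'
#' @param coreStates number of helix-core states (maximum core length).
#' @param minCoreLength minimum helix-core length (entry depths =
#'   `coreStates - minCoreLength + 1`).
#' @param capLength cap length on either membrane side.
#' @param ladderLength loop-ladder length (each loop module has two).
#' @param alphabet emission alphabet.
#' @param freqs background frequencies used to build the synthetic
#'   emission rows.
#' @return A list of class `tmhmmLayout` with elements `model` (a
#'   [HiddenMarkovModel-class]), `emissionGroups`, `transitionTies`,
#'   `initialSupport`.
#' @export
tmhmmLayout <- function(coreStates = 25L, minCoreLength = 5L,
                        capLength = 5L, ladderLength = 10L,
                        alphabet = aaAlphabet(),
                        freqs = swissprotFreqs()) {
    stopifnot(coreStates >= minCoreLength, minCoreLength >= 1,
              capLength >= 1, ladderLength >= 2)
    f <- freqs[alphabet]
    f <- f / sum(f)
    loopMods <- c("cl", "sl", "ll")
    nm <- function(mod, part, i) paste0(mod, ".", part, i)
    states <- character(0)
    for (m in loopMods)
        states <- c(states, nm(m, "in", seq_len(ladderLength)),
                    paste0(m, ".glob"),
                    nm(m, "out", seq_len(ladderLength)))
    for (h in c("hio", "hoi")) {
        capIn <- if (h == "hio") "capc" else "capn"
        capOut <- if (h == "hio") "capn" else "capc"
        states <- c(states, nm(h, capIn, seq_len(capLength)),
                    nm(h, "core", seq_len(coreStates)),
                    nm(h, capOut, seq_len(capLength)))
    }
    K <- length(states)
    trans <- matrix(0, K, K, dimnames = list(states, states))
    ties <- list()
    ## loop modules: in-ladder with early exits to the globular state,
    ## globular self-loop, out-ladder with early exits to the next module
    exitOf <- c(cl = "hio.capc1", sl = "hoi.capn1", ll = "hoi.capn1")
    pCont <- 0.85
    pGlobStay <- 0.9
    for (m in loopMods) {
        ex <- exitOf[[m]]
        for (i in seq_len(ladderLength - 1)) {
            trans[nm(m, "in", i), nm(m, "in", i + 1)] <- pCont
            trans[nm(m, "in", i), paste0(m, ".glob")] <- 1 - pCont
            ties[[paste0(m, ".in", i)]] <-
                list(rows = nm(m, "in", i), choices = 2L)
        }
        last <- nm(m, "in", ladderLength)
        trans[last, paste0(m, ".glob")] <- 0.5
        trans[last, nm(m, "out", 1)] <- 0.5
        ties[[last]] <- list(rows = last, choices = 2L)
        trans[paste0(m, ".glob"), paste0(m, ".glob")] <- pGlobStay
        trans[paste0(m, ".glob"), nm(m, "out", 1)] <- 1 - pGlobStay
        ties[[paste0(m, ".glob")]] <-
            list(rows = paste0(m, ".glob"), choices = 2L)
        for (i in seq_len(ladderLength - 1)) {
            trans[nm(m, "out", i), nm(m, "out", i + 1)] <- pCont
            trans[nm(m, "out", i), ex] <- 1 - pCont
            ties[[paste0(m, ".out", i)]] <-
                list(rows = nm(m, "out", i), choices = 2L)
        }
        trans[nm(m, "out", ladderLength), ex] <- 1
    }
    ## helices: cap chain, tied core-entry jump, core chain, cap chain
    nEntry <- coreStates - minCoreLength + 1L
    len <- coreStates - seq_len(nEntry) + 1L  # resulting core lengths
    jump <- exp(-(len - 21)^2 / 18)
    jump <- jump / sum(jump)
    for (h in c("hio", "hoi")) {
        capIn <- if (h == "hio") "capc" else "capn"
        capOut <- if (h == "hio") "capn" else "capc"
        for (i in seq_len(capLength - 1))
            trans[nm(h, capIn, i), nm(h, capIn, i + 1)] <- 1
        for (k in seq_len(nEntry))
            trans[nm(h, capIn, capLength), nm(h, "core", k)] <- jump[k]
        for (i in seq_len(coreStates - 1))
            trans[nm(h, "core", i), nm(h, "core", i + 1)] <- 1
        trans[nm(h, "core", coreStates), nm(h, capOut, 1)] <- 1
        for (i in seq_len(capLength - 1))
            trans[nm(h, capOut, i), nm(h, capOut, i + 1)] <- 1
    }
    ties[["core.entry"]] <- list(
        rows = c(paste0("hio.capc", capLength),
                 paste0("hoi.capn", capLength)),
        choices = as.integer(nEntry))
    ## topology branching after an in->out helix: short or long ncyt loop
    trans[paste0("hio.capn", capLength), "sl.in1"] <- 0.5
    trans[paste0("hio.capn", capLength), "ll.in1"] <- 0.5
    ties[["ncyt.branch"]] <- list(rows = paste0("hio.capn", capLength),
                                  choices = 2L)
    trans[paste0("hoi.capc", capLength), "cl.in1"] <- 1
    ## emission groups with hydrophobicity-biased synthetic values
    grp <- list(
        helix_core = grep("\\.core", states, value = TRUE),
        cap_cyt = grep("\\.capc", states, value = TRUE),
        cap_ncyt = grep("\\.capn", states, value = TRUE),
        loop_cyt = grep("^cl\\.(in|out)", states, value = TRUE),
        loop_short_ncyt = grep("^sl\\.(in|out)", states, value = TRUE),
        loop_long_ncyt = grep("^ll\\.(in|out)", states, value = TRUE),
        globular = grep("\\.glob", states, value = TRUE))
    beta <- c(helix_core = 1.5, cap_cyt = 0.6, cap_ncyt = 0.6,
              loop_cyt = -0.5, loop_short_ncyt = -0.4,
              loop_long_ncyt = -0.6, globular = 0)
    hyd <- kdHydropathy()[alphabet]
    if (anyNA(hyd)) hyd <- setNames(rep(0, length(alphabet)), alphabet)
    emis <- matrix(0, K, length(alphabet),
                   dimnames = list(states, alphabet))
    for (g in names(grp)) {
        e <- f * exp(beta[[g]] * hyd / 4.5)
        emis[grp[[g]], ] <- matrix(e / sum(e), length(grp[[g]]),
                                   length(alphabet), byrow = TRUE)
    }
    init <- setNames(rep(0, K), states)
    init[c("cl.in1", "sl.in1", "ll.in1")] <- c(0.5, 0.25, 0.25)
    model <- hiddenMarkovModel(states, init, emis, trans,
                               tieGroups = unname(grp),
                               helixCoreStates = grp$helix_core,
                               alphabet = alphabet)
    structure(list(model = model, emissionGroups = grp,
                   transitionTies = ties, initialSupport = 3L),
              class = "tmhmmLayout")
}

#' Count the independent free parameters of an HMM layout
#'
#' Walks the layout's tying structure: each emission tie group contributes
#' `|alphabet| - 1` (one simplex constraint), each tied transition
#' distribution `choices - 1`, and the initial distribution
#' `support - 1`. Fixed (single-successor) transitions contribute nothing.
#'
#' @param layout a [tmhmmLayout()].
#' @return Integer count, with a breakdown in attribute `breakdown`.
#' @export
freeParameterCount <- function(layout) {
    stopifnot(inherits(layout, "tmhmmLayout"))
    M <- length(layout$model@alphabet)
    emis <- length(layout$emissionGroups) * (M - 1L)
    trans <- sum(vapply(layout$transitionTies,
                        function(t) t$choices - 1L, integer(1)))
    ## audit: every tied transition row must actually have that many
    ## choices in the assembled matrix, and tied rows must be identical
    tm <- layout$model@transitions
    for (t in layout$transitionTies) {
        for (r in t$rows)
            if (sum(tm[r, ] > 0) != t$choices)
                stop("tie audit failed for row ", r)
        if (length(t$rows) > 1) {
            vals <- apply(tm[t$rows, , drop = FALSE], 1,
                          function(v) paste(sort(v[v > 0]), collapse = ","))
            if (length(unique(vals)) != 1)
                stop("tied transition rows differ: ",
                     paste(t$rows, collapse = ", "))
        }
    }
    free <- sum(tm > 0) - nrow(tm)  # untied count, for the audit trail
    init <- layout$initialSupport - 1L
    out <- emis + trans + init
    attr(out, "breakdown") <- c(emissions = emis, transitions = trans,
                                initial = init, untiedTransitions = free)
    out
}
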