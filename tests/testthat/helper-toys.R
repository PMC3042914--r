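## Shared toy fixtures, built in code (seed-deterministic).

toyAlphabet2 <- c("A", "B")
toyAlphabet3 <- c("A", "B", "C")

toyMatrix2 <- function() {
    m <- matrix(c(2L, -1L, -1L, 2L), 2, 2,
                dimnames = list(toyAlphabet2, toyAlphabet2))
    scoringMatrix(m, "toy2")
}

toyMatrix3 <- function() {
    m <- matrix(c(3L, -1L, -2L,
                  -1L, 3L, -1L,
                  -2L, -1L, 2L), 3, 3, byrow = TRUE,
                dimnames = list(toyAlphabet3, toyAlphabet3))
    scoringMatrix(m, "toy3")
}

toyScheme2 <- function(gapOpen = 1L, gapExtend = 1L)
    scoringScheme(toyMatrix2(), gapOpen = gapOpen, gapExtend = gapExtend)

## every integer score in [0, 2L] is reachable under this matrix, so no
## window bin is unsupported (A:A = 2, B:B = 1, mismatch -1)
toyFullScheme <- function() {
    m <- matrix(c(2L, -1L, -1L, 1L), 2, 2,
                dimnames = list(toyAlphabet2, toyAlphabet2))
    scoringScheme(scoringMatrix(m, "toyfull"), gapOpen = 1L,
                  gapExtend = 1L)
}

toyScheme3 <- function(gapOpen = 2L, gapExtend = 1L)
    scoringScheme(toyMatrix3(), gapOpen = gapOpen, gapExtend = gapExtend)

toyIID2 <- function() iidModel(c(A = 0.6, B = 0.4))

toyHMM2 <- function() {
    em <- matrix(c(0.8, 0.2,
                   0.3, 0.7), 2, 2, byrow = TRUE)
    tr <- matrix(c(0.7, 0.3,
                   0.4, 0.6), 2, 2, byrow = TRUE)
    hiddenMarkovModel(c("loop", "core"), c(0.6, 0.4), em, tr,
                      helixCoreStates = "core", alphabet = toyAlphabet2)
}

## a random (row-stochastic) toy HMM over a 2-letter alphabet
randomToyHMM <- function(K = 2) {
    rdir <- function(n) {
        x <- -log(runif(n))
        x / sum(x)
    }
    em <- t(vapply(seq_len(K), function(i) rdir(2), numeric(2)))
    tr <- t(vapply(seq_len(K), function(i) rdir(K), numeric(K)))
    hiddenMarkovModel(paste0("s", seq_len(K)), rdir(K), em, tr,
                      helixCoreStates = "s1", alphabet = toyAlphabet2)
}

randomSeq <- function(alphabet, L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")

## all sequences over an alphabet up to (or exactly of) length L
allSeqsOf <- function(alphabet, L) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    apply(g, 1, paste, collapse = "")
}
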