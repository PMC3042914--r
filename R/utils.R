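#' @useDynLib AlignTails, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats runif rnorm setNames coef vcov approx var sd lm
#'   predict residuals
#' @importFrom utils read.table write.table head tail
NULL

#' The 20-letter amino-acid alphabet
#'
#' Ordered single-letter codes of the standard amino acids, the default
#' alphabet for all sequence models.
#'
#' @return Character vector of 20 single-letter symbols.
#' @export
aaAlphabet <- function() {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## split a sequence string into single characters
seqChars <- function(seq) {
    if (length(seq) == 1L && (nchar(seq) != 1L || is.na(seq)))
        strsplit(seq, "", fixed = TRUE)[[1]]
    else if (length(seq) == 1L && nchar(seq) == 1L)
        seq
    else as.character(seq)
}

## 0-based integer encoding used by the compiled kernels
seqToInt <- function(seq, alphabet) {
    ch <- seqChars(seq)
    if (length(ch) == 0L) return(integer(0))
    idx <- match(ch, alphabet)
    if (anyNA(idx)) {
        bad <- which(is.na(idx))[1]
        stop("unknown symbol '", ch[bad], "' at position ", bad)
    }
    idx - 1L
}

intToSeq <- function(idx, alphabet) {
    paste(alphabet[idx + 1L], collapse = "")
}

checkAlphabet <- function(alphabet) {
    stopifnot(is.character(alphabet), length(alphabet) >= 2,
              all(nchar(alphabet) == 1L), !anyDuplicated(alphabet))
    alphabet
}

## numerically stable log(sum(exp(x)))
logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}
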