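#' Construct a scoring matrix
#'
#' @param scores integer matrix with symbol dimnames.
#' @param name label.
#' @export
scoringMatrix <- function(scores, name = "custom") {
    storage.mode(scores) <- "integer"
    new("ScoringMatrix", scores = scores, name = name)
}

#' Read an NCBI-format substitution matrix
#'
#' Whitespace-delimited text with a header row of symbols and one labelled
#' row per symbol; `#` comment lines are ignored. Entries must be integers
#' and every row complete (lower-triangle-only files are rejected).
#' Symmetry is deliberately not enforced: transmembrane-specific matrices
#' are non-symmetric.
#'
#' @param path matrix file.
#' @param name label (defaults to the file name).
#' @return A [ScoringMatrix-class].
#' @export
readScoringMatrix <- function(path, name = basename(path)) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    if (length(ln) < 2) stop("matrix file too short")
    cols <- strsplit(trimws(ln[1]), "[ \t]+")[[1]]
    rows <- strsplit(trimws(ln[-1]), "[ \t]+")
    m <- matrix(NA_integer_, length(rows), length(cols),
                dimnames = list(vapply(rows, `[`, character(1), 1), cols))
    for (i in seq_along(rows)) {
        v <- rows[[i]][-1]
        if (length(v) != length(cols))
            stop("row '", rows[[i]][1], "' has ", length(v),
                 " entries, expected ", length(cols))
        num <- suppressWarnings(as.numeric(v))
        if (anyNA(num) || any(num != round(num)))
            stop("row '", rows[[i]][1], "' contains non-integer entries")
        m[i, ] <- as.integer(num)
    }
    scoringMatrix(m, name = name)
}

#' Write a scoring matrix in NCBI tabular format
#'
#' @param mat a [ScoringMatrix-class].
#' @param path output file.
#' @export
writeScoringMatrix <- function(mat, path) {
    s <- mat@scores
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(" ", paste(colnames(s), collapse = "  ")), con)
    for (i in seq_len(nrow(s)))
        writeLines(paste(rownames(s)[i],
                         paste(sprintf("%3d", s[i, ]), collapse = " ")), con)
    invisible(path)
}

#' The BLOSUM62 substitution matrix
#'
#' The standard general-purpose protein matrix, read from the bundled
#' NCBI-format file and restricted to the 20-letter alphabet.
#'
#' @export
blosum62 <- function() {
    m <- readScoringMatrix(system.file("extdata", "BLOSUM62.txt",
                                       package = "AlignTails",
                                       mustWork = TRUE), name = "BLOSUM62")
    aa <- aaAlphabet()
    scoringMatrix(m@scores[aa, aa], name = "BLOSUM62")
}

#' Synthetic transmembrane-region substitution matrix
#'
#' A non-symmetric stand-in for helix-specific matrices such as SLIM,
#' constructed from a hydrophobicity bias; bundled so that the bipartite
#' scoring scheme can be exercised without external data. It is synthetic:
#' it reproduces the *shape* of a TM-specific matrix (non-symmetric,
#' hydrophobic-pair rewarding), not any published matrix's values.
#'
#' @export
tmSyntheticMatrix <- function() {
    readScoringMatrix(system.file("extdata", "tm_synthetic.mat",
                                  package = "AlignTails", mustWork = TRUE),
                      name = "TM-synthetic")
}

#' Expected pair score under background frequencies
#'
#' Any matrix used as a default for local alignment must have a negative
#' expected score; this helper computes `sum_{a,b} f_a f_b s(a,b)`.
#'
#' @param mat a [ScoringMatrix-class].
#' @param freqs named background frequencies covering the matrix symbols.
#' @export
expectedScore <- function(mat, freqs) {
    sym <- rownames(mat@scores)
    f <- freqs[sym] / sum(freqs[sym])
    as.numeric(t(f) %*% mat@scores[, sym] %*% f)
}

#' Construct a (possibly bipartite) scoring scheme
#'
#' @param defaultMatrix general-purpose [ScoringMatrix-class].
#' @param regionMatrix matrix for query positions inside `queryRegions`
#'   (default: same as `defaultMatrix`).
#' @param queryRegions two-column matrix (or data.frame) of 1-based
#'   inclusive `(start, end)` intervals on the query.
#' @param gapOpen,gapExtend affine gap parameters (non-negative integers).
#' @param gapConvention `"open_plus_len"` (a gap of length l costs
#'   `gapOpen + gapExtend*l`; a length-1 gap costs 13 with 12/1) or
#'   `"open_plus_len_minus_1"`.
#' @export
scoringScheme <- function(defaultMatrix, regionMatrix = defaultMatrix,
                          queryRegions = NULL, gapOpen = 12L, gapExtend = 1L,
                          gapConvention = "open_plus_len") {
    if (is.null(queryRegions))
        queryRegions <- matrix(integer(0), 0, 2)
    queryRegions <- as.matrix(queryRegions)
    storage.mode(queryRegions) <- "integer"
    colnames(queryRegions) <- c("start", "end")
    new("ScoringScheme", defaultMatrix = defaultMatrix,
        regionMatrix = regionMatrix, queryRegions = queryRegions,
        gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
        gapConvention = gapConvention)
}

## first gap position cost under the scheme's convention
gapOpenCost <- function(scheme) {
    if (scheme@gapConvention == "open_plus_len")
        scheme@gapOpen + scheme@gapExtend
    else scheme@gapOpen
}

gapCost <- function(scheme, len) {
    if (len == 0) return(0L)
    gapOpenCost(scheme) + scheme@gapExtend * (len - 1L)
}

## per-query-position region indicator (0/1 integer vector)
regionMask <- function(scheme, lq) {
    mask <- integer(lq)
    r <- scheme@queryRegions
    for (i in seq_len(nrow(r))) {
        if (r[i, 2] > lq) stop("query region exceeds query length")
        mask[r[i, 1]:r[i, 2]] <- 1L
    }
    mask
}

schemeAlphabet <- function(scheme) rownames(scheme@defaultMatrix@scores)

#' Smith-Waterman local alignment score
#'
#' Score-only affine-gap Smith-Waterman with the bipartite matrix choice:
#' pair (i, j) is scored with the region matrix if query position i falls
#' in a query region, otherwise with the default matrix. The empty local
#' alignment is always feasible, so the score is non-negative; either
#' sequence may be empty (score 0).
#'
#' @param x query sequence (rows; selects the matrix).
#' @param y subject sequence.
#' @param scheme a [ScoringScheme-class].
#' @return Integer score.
#' @export
smithWatermanScore <- function(x, y, scheme) {
    ab <- schemeAlphabet(scheme)
    xi <- seqToInt(x, ab)
    yi <- seqToInt(y, ab)
    cpp_sw_score(xi, yi, scheme@defaultMatrix@scores,
                 scheme@regionMatrix@scores, regionMask(scheme, length(xi)),
                 gapOpenCost(scheme), scheme@gapExtend)
}

#' Score an explicit alignment
#'
#' The score of an alignment (a set of non-crossing index pairs) is the sum
#' of its pair scores minus the affine cost of every internal gap; for
#' local alignment the unaligned flanks are free. A gap is a maximal run of
#' unpaired positions between consecutive aligned pairs in either sequence.
#'
#' @param x,y sequences.
#' @param pairs two-column matrix of 1-based (i, j) index pairs, or an
#'   empty matrix / NULL for the empty alignment (score 0).
#' @param scheme a [ScoringScheme-class].
#' @return Integer score (may be negative for an arbitrary alignment).
#' @export
scoreAlignment <- function(x, y, pairs, scheme) {
    if (is.null(pairs) || NROW(pairs) == 0) return(0L)
    pairs <- matrix(as.integer(pairs), ncol = 2)
    o <- order(pairs[, 1])
    pairs <- pairs[o, , drop = FALSE]
    if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0))
        stop("alignment pairs must not cross")
    ab <- schemeAlphabet(scheme)
    xi <- seqToInt(x, ab) + 1L
    yi <- seqToInt(y, ab) + 1L
    if (max(pairs[, 1]) > length(xi) || max(pairs[, 2]) > length(yi))
        stop("alignment pair out of range")
    mask <- regionMask(scheme, length(xi))
    sc <- 0L
    for (k in seq_len(nrow(pairs))) {
        m <- if (mask[pairs[k, 1]]) scheme@regionMatrix@scores
             else scheme@defaultMatrix@scores
        sc <- sc + m[xi[pairs[k, 1]], yi[pairs[k, 2]]]
    }
    if (nrow(pairs) > 1) {
        gx <- diff(pairs[, 1]) - 1L
        gy <- diff(pairs[, 2]) - 1L
        for (g in c(gx[gx > 0], gy[gy > 0]))
            sc <- sc - gapCost(scheme, g)
    }
    as.integer(sc)
}

#' Gap lengths of a displayed (gapped) alignment
#'
#' Given the two rows of a printed alignment (gap character `-`), returns
#' the lengths of the maximal gap runs in either row. A column gapped in
#' both rows is invalid.
#'
#' @param alignedX,alignedY gapped strings of equal display length.
#' @param gapChar gap character.
#' @return Integer vector of gap lengths (empty if ungapped).
#' @examples
#' gapLengths("QGEGGDA---WC", "QG--GDATTTWC")  # 2 3
#' @export
gapLengths <- function(alignedX, alignedY, gapChar = "-") {
    cx <- seqChars(alignedX)
    cy <- seqChars(alignedY)
    if (length(cx) != length(cy))
        stop("aligned strings must have equal display length")
    gx <- cx == gapChar
    gy <- cy == gapChar
    if (any(gx & gy)) stop("column gapped in both rows")
    runs <- function(g) {
        r <- rle(g)
        r$lengths[r$values]
    }
    as.integer(c(runs(gx), runs(gy)))
}

#' Read transmembrane-helix intervals
#'
#' Tab-separated columns: query id, start, end (1-based inclusive).
#'
#' @param path file path.
#' @return Named list (by query id) of two-column interval matrices.
#' @export
readTMIntervals <- function(path) {
    tab <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(tab) != 3) stop("expected 3 columns: id, start, end")
    ids <- unique(tab[[1]])
    out <- lapply(ids, function(id) {
        m <- as.matrix(tab[tab[[1]] == id, 2:3])
        storage.mode(m) <- "integer"
        colnames(m) <- c("start", "end")
        m[order(m[, 1]), , drop = FALSE]
    })
    names(out) <- ids
    out
}

#' Smith-Waterman alignment with traceback
#'
#' Full dynamic-programming variant returning the optimal local alignment
#' itself (index pairs and gapped display strings) in addition to the
#' score. Intended for inspection; the samplers use the score-only kernel.
#'
#' @inheritParams smithWatermanScore
#' @return List with `score`, `pairs` (two-column matrix) and gapped
#'   strings `alignedX`, `alignedY`.
#' @export
smithWatermanAlignment <- function(x, y, scheme) {
    ab <- schemeAlphabet(scheme)
    xi <- seqToInt(x, ab) + 1L
    yi <- seqToInt(y, ab) + 1L
    lx <- length(xi)
    ly <- length(yi)
    empty <- list(score = 0L, pairs = matrix(integer(0), 0, 2),
                  alignedX = "", alignedY = "")
    if (lx == 0 || ly == 0) return(empty)
    mask <- regionMask(scheme, lx)
    oc <- gapOpenCost(scheme)
    ec <- scheme@gapExtend
    NEG <- -1e9
    H <- matrix(0, lx + 1, ly + 1)
    E <- matrix(NEG, lx + 1, ly + 1)  # gap in y (vertical move)
    F <- matrix(NEG, lx + 1, ly + 1)  # gap in x (horizontal move)
    md <- scheme@defaultMatrix@scores
    mr <- scheme@regionMatrix@scores
    for (i in 2:(lx + 1)) {
        m <- if (mask[i - 1]) mr else md
        for (j in 2:(ly + 1)) {
            E[i, j] <- max(E[i - 1, j] - ec, H[i - 1, j] - oc)
            F[i, j] <- max(F[i, j - 1] - ec, H[i, j - 1] - oc)
            H[i, j] <- max(0, H[i - 1, j - 1] + m[xi[i - 1], yi[j - 1]],
                           E[i, j], F[i, j])
        }
    }
    best <- which(H == max(H), arr.ind = TRUE)[1, ]
    score <- as.integer(max(H))
    if (score == 0) return(empty)
    i <- best[1]; j <- best[2]
    state <- "H"
    pairs <- NULL
    ax <- character(0); ay <- character(0)
    cx <- seqChars(x); cy <- seqChars(y)
    while (state != "H" || H[i, j] > 0) {
        if (state == "H") {
            m <- if (mask[i - 1]) mr else md
            if (H[i, j] == H[i - 1, j - 1] + m[xi[i - 1], yi[j - 1]]) {
                pairs <- rbind(c(i - 1L, j - 1L), pairs)
                ax <- c(cx[i - 1], ax); ay <- c(cy[j - 1], ay)
                i <- i - 1; j <- j - 1
            } else if (H[i, j] == E[i, j]) state <- "E"
            else state <- "F"
        } else if (state == "E") {
            ax <- c(cx[i - 1], ax); ay <- c("-", ay)
            if (E[i, j] == H[i - 1, j] - oc) state <- "H"
            i <- i - 1
        } else {
            ax <- c("-", ax); ay <- c(cy[j - 1], ay)
            if (F[i, j] == H[i, j - 1] - oc) state <- "H"
            j <- j - 1
        }
    }
    list(score = score, pairs = pairs,
         alignedX = paste(ax, collapse = ""),
         alignedY = paste(ay, collapse = ""))
}
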