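#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the alphabet; an
#' out-of-alphabet symbol is rejected with its record and position.
#'
#' @param path FASTA file.
#' @param alphabet permitted symbols (default the 20 amino acids).
#' @return Named character vector of sequences.
#' @export
readFastaAA <- function(path, alphabet = aaAlphabet()) {
    set <- Biostrings::readAAStringSet(path)
    if (length(set) == 0) stop("empty FASTA file")
    ids <- sub("\\s.*", "", names(set))
    if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                                 ids[duplicated(ids)][1])
    seqs <- toupper(as.character(set))
    names(seqs) <- ids
    for (i in seq_along(seqs)) {
        ch <- seqChars(seqs[i])
        bad <- which(!ch %in% alphabet)
        if (length(bad))
            stop("record '", ids[i], "': symbol '", ch[bad[1]],
                 "' at position ", bad[1], " not in the alphabet")
    }
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
writeFastaAA <- function(seqs, path) {
    set <- Biostrings::AAStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}

#' Read a run configuration (YAML)
#'
#' Keys: `mode` (RQGS/FQPS/HMM), `LQ`, `LS`, `smin`, `smax`, `classes`,
#' `nSamples`, `thinning`, `seed`, and mode-dependent paths (`query_fasta`,
#' `hmm_file`, `tm_intervals`, `matrix_file`, `region_matrix_file`,
#' `freqs_file`), plus gap parameters. Completeness is validated up front,
#' before any computation.
#'
#' @param path YAML file.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    need <- function(keys)
        for (k in keys) if (is.null(cfg[[k]]))
            stop("run config: missing key '", k, "'")
    need(c("mode", "LS", "smin", "smax", "nSamples"))
    cfg$mode <- match.arg(cfg$mode, c("RQGS", "FQPS", "HMM"))
    if (cfg$mode == "FQPS") need("query_fasta") else need("LQ")
    if (cfg$mode == "HMM") need("hmm_file")
    cfg$seed <- cfg$seed %||% 1L
    cfg$gapOpen <- cfg$gapOpen %||% 12L
    cfg$gapExtend <- cfg$gapExtend %||% 1L
    cfg$classes <- cfg$classes %||% 0L
    cfg$configHash <- as.character(tools::md5sum(path))
    cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## build model + scheme from a validated config
assembleRun <- function(cfg) {
    freqs <- if (!is.null(cfg$freqs_file)) readFrequencies(cfg$freqs_file)
             else swissprotFreqs()
    sub <- iidModel(freqs)
    mat <- if (!is.null(cfg$matrix_file))
        readScoringMatrix(cfg$matrix_file) else blosum62()
    regionMat <- if (!is.null(cfg$region_matrix_file))
        readScoringMatrix(cfg$region_matrix_file) else mat
    regions <- NULL
    if (cfg$mode == "FQPS") {
        q <- readFastaAA(cfg$query_fasta)
        query <- q[[1]]
        cfg$LQ <- nchar(query)
        if (!is.null(cfg$tm_intervals)) {
            iv <- readTMIntervals(cfg$tm_intervals)
            regions <- iv[[names(q)[1]]] %||% iv[[1]]
        }
        model <- fixedQueryModel(query, sub)
    } else if (cfg$mode == "HMM") {
        model <- hmmQueryModel(readHMM(cfg$hmm_file), sub)
    } else model <- sub
    scheme <- scoringScheme(mat, regionMat, queryRegions = regions,
                            gapOpen = cfg$gapOpen,
                            gapExtend = cfg$gapExtend)
    list(model = model, scheme = scheme,
         window = scoreWindow(cfg$smin, cfg$smax, cfg$classes),
         LQ = cfg$LQ, LS = cfg$LS)
}

writeStamped <- function(df, path, hash) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# config_hash ", hash), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readStamped <- function(path, hash = NULL) {
    first <- readLines(path, n = 1)
    fileHash <- sub("^# config_hash ", "", first)
    if (!is.null(hash) && !identical(fileHash, hash))
        stop("artifact ", basename(path), " was produced under a ",
             "different configuration (hash mismatch)")
    read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Run the full estimation pipeline
#'
#' Wang-Landau weight estimation, fixed-weight production run, importance
#' reweighting, modified-Gumbel fit and a p-value table, with all
#' artifacts written as tab-separated text stamped with the configuration
#' hash. A chain checkpoint (sampler state plus RNG state) is written
#' after the weight estimation, so an interrupted production phase can be
#' resumed reproducibly.
#'
#' @param cfg configuration list from [readRunConfig()].
#' @param outDir output directory (created).
#' @param quiet suppress progress messages.
#' @param resume restart from the post-estimation checkpoint in `outDir`
#'   (sampler state, weights and RNG state), skipping the Wang-Landau
#'   phase; the resumed production phase is bit-identical to an
#'   uninterrupted run.
#' @return Invisible list with the in-memory results (`wl`, `hist`,
#'   `est`, `fit`) and output paths.
#' @export
runPipeline <- function(cfg, outDir, quiet = FALSE, resume = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message(...)
    set.seed(cfg$seed)
    parts <- assembleRun(cfg)
    hash <- cfg$configHash %||% "unhashed"
    ckpt <- file.path(outDir, "checkpoint.txt")
    wlFile <- file.path(outDir, "weights.tsv")
    if (resume && file.exists(ckpt)) {
        say("resuming from checkpoint ...")
        ck <- dget(ckpt)
        if (!identical(ck$hash, hash))
            stop("checkpoint was produced under a different configuration")
        lwTab <- readStamped(wlFile, hash)
        logW <- emptyTable(parts$window)
        logW[cbind(as.character(lwTab$s), as.character(lwTab$n))] <-
            lwTab$log_w
        wl <- NULL
        chainState <- ck$state
        assign(".Random.seed", ck$seed, envir = globalenv())
    } else {
        say("Wang-Landau weight estimation ...")
        wl <- wlEstimate(parts$model, parts$scheme, parts$window,
                         parts$LQ, parts$LS,
                         schedule = wlSchedule(
                             phiInitial = cfg$phiInitial %||% exp(0.1),
                             phiFinal = cfg$phiFinal %||% exp(2e-4)),
                         maxStepsPerLevel = cfg$maxStepsPerLevel %||% Inf)
        logW <- wl@logW
        chainState <- wl@finalState
        lw <- data.frame(s = rep(windowScores(parts$window),
                                 length(parts$window@classes)),
                         n = rep(parts$window@classes,
                                 each = nrow(wl@logW)),
                         log_w = as.numeric(wl@logW))
        writeStamped(lw, wlFile, hash)
        dput(list(state = chainState, seed = .Random.seed, hash = hash),
             file = ckpt)
    }
    say("production run (", cfg$nSamples, " samples) ...")
    hist <- productionRun(parts$model, parts$scheme, parts$window,
                          logW, cfg$nSamples, parts$LQ, parts$LS,
                          thinning = cfg$thinning %||%
                              (parts$LQ + parts$LS),
                          state = chainState)
    writeStamped(data.frame(s = rep(windowScores(parts$window),
                                    length(parts$window@classes)),
                            n = rep(parts$window@classes,
                                    each = nrow(hist@counts)),
                            count = as.numeric(hist@counts)),
                 file.path(outDir, "histogram.tsv"), hash)
    est <- reweight(hist)
    sup <- is.finite(est@logProbMarginal)
    writeStamped(data.frame(s = windowScores(parts$window)[sup],
                            log10_prob =
                                est@logProbMarginal[sup] / log(10)),
                 file.path(outDir, "estimate.tsv"), hash)
    fit <- tryCatch(
        fitModifiedGumbel(est, LQ = parts$LQ, LS = parts$LS),
        error = function(e) {
            say("fit failed: ", conditionMessage(e))
            NULL
        })
    if (!is.null(fit)) {
        writeStamped(data.frame(
            param = c("s0", "lambda", "lambda2", "K", "chisq_red"),
            value = c(fit@s0, fit@lambda, fit@lambda2, fit@K,
                      fit@chisqRed),
            se = c(fit@se[c("s0", "lambda", "lambda2", "K")], NA)),
            file.path(outDir, "fit.tsv"), hash)
        ss <- seq(parts$window@smin, parts$window@smax, by = 5L)
        writeStamped(data.frame(s = ss, pvalue = pValue(est, ss, fit)),
                     file.path(outDir, "pvalues.tsv"), hash)
    }
    meta <- c(paste0("# config_hash ", hash),
              paste0("seed\t", cfg$seed),
              paste0("mode\t", cfg$mode),
              paste0("LQ\t", parts$LQ), paste0("LS\t", cfg$LS),
              paste0("window\t", parts$window@smin, ":",
                     parts$window@smax),
              paste0("nSamples\t", hist@nSamples),
              paste0("thinning\t", hist@thinning),
              paste0("roundTrips\t",
                     if (is.null(wl)) "resumed" else wl@roundTrips),
              paste0("wlStepsPerLevel\t",
                     if (is.null(wl)) "resumed"
                     else paste(wl@stepsPerLevel, collapse = ",")),
              paste0("package\t", as.character(
                  utils::packageVersion("AlignTails"))))
    writeLines(meta, file.path(outDir, "run_metadata.tsv"))
    invisible(list(wl = wl, hist = hist, est = est, fit = fit,
                   outDir = outDir))
}
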