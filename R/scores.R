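#' GC content of a sequence
#'
#' `(#G + #C) / length`; `N` bases count in the denominator only.
#'
#' @param seq non-empty nucleotide string.
#' @return fraction in `[0, 1]`.
#' @export
gcContent <- function(seq) {
    L <- nchar(seq)
    if (L == 0L) stop("gcContent: empty sequence")
    gc <- Biostrings::letterFrequency(Biostrings::DNAString(seq), "GC")
    unname(as.numeric(gc)) / L
}

#' Aggregate a per-base score track over transcript-space intervals
#'
#' Maps each requested 5'UTR base to genomic space through the model's exon
#' structure and averages the track scores found there. Bases with no score
#' are excluded from numerator and denominator; zero covered bases yields
#' `NA`, never 0. When several score rows exist at one base (e.g. one CADD
#' score per alternative allele) they are first summarised per base
#' (`perBase = "mean"` by default, `"max"` as the configurable alternative)
#' before interval averaging, so the aggregate is an unweighted mean over
#' covered bases, invariant to how the interval is split across exons.
#'
#' @param model a [TranscriptModel-class].
#' @param track a [ScoreTrack-class] in genomic space.
#' @param intervals data.frame/list with `start`, `end` (transcript-space,
#'   0-based half-open) or `NULL` for the whole 5'UTR. Several intervals are
#'   pooled: all their bases enter one mean.
#' @param perBase `"mean"` or `"max"` summarisation of multi-valued bases.
#' @return list with `mean` (numeric or `NA`) and `coverage` (covered bases /
#'   requested bases).
#' @export
aggregateTrack <- function(model, track, intervals = NULL,
                           perBase = c("mean", "max")) {
    perBase <- match.arg(perBase)
    L <- utr5Length(model)
    if (is.null(intervals))
        intervals <- data.frame(start = 0L, end = L)
    offs <- unlist(lapply(seq_along(intervals$start), function(i) {
        s <- intervals$start[i]; e <- intervals$end[i]
        if (e <= s) integer(0) else seq.int(s, e - 1L)
    }))
    offs <- unique(offs)
    if (!length(offs)) return(list(mean = NA_real_, coverage = 0))
    gpos <- transcriptToGenomic(model, offs)
    onContig <- track@contig == model@contig
    tpos <- track@pos[onContig]
    tval <- track@score[onContig]
    if (!length(tpos)) return(list(mean = NA_real_, coverage = 0))
    # summarise multi-valued bases first, then look up the requested bases
    if (perBase == "mean") {
        sums <- rowsum(tval, tpos)
        cnts <- rowsum(rep(1, length(tpos)), tpos)
        perBaseVal <- sums[, 1L] / cnts[, 1L]
        posKeys <- as.integer(rownames(sums))
    } else {
        byPos <- split(tval, tpos)
        perBaseVal <- vapply(byPos, max, numeric(1))
        posKeys <- as.integer(names(byPos))
    }
    vals <- perBaseVal[match(gpos, posKeys)]
    covered <- sum(!is.na(vals))
    list(mean = if (covered) mean(vals, na.rm = TRUE) else NA_real_,
         coverage = covered / length(offs))
}

#' Minimum free energy of a 5'UTR via an external folding backend
#'
#' The package deliberately contains no folding thermodynamics: the spliced
#' full-length 5'UTR is handed to an external executable speaking the RNAfold
#' dialect (sequence on stdin, an output line containing the energy in
#' parentheses, e.g. `"....((..)). ( -1.20)"`). The default backend is
#' `RNAfold` if found on the `PATH`. A function backend (taking the sequence,
#' returning a numeric energy) is accepted for testing. When no backend is
#' available, or its output cannot be parsed, the result is `NA` and the
#' pipeline continues.
#'
#' @param seq nucleotide string (spliced full 5'UTR; folding is never
#'   per-exon).
#' @param backend executable name/path, a function, or `NULL` for the default.
#' @return energy in kcal/mol (<= 0 for foldable sequences) or `NA`.
#' @export
foldMFE <- function(seq, backend = NULL) {
    if (is.function(backend)) {
        val <- tryCatch(backend(seq), error = function(e) NA_real_)
        return(as.numeric(val))
    }
    exe <- if (is.null(backend)) Sys.which("RNAfold") else Sys.which(backend)
    if (!nzchar(exe)) return(NA_real_)
    out <- tryCatch(
        system2(exe, args = "--noPS", input = seq, stdout = TRUE,
                stderr = FALSE),
        error = function(e) character(0), warning = function(w) character(0))
    .parseFoldEnergy(out)
}

# last parenthesised number in the backend's output, whitespace-tolerant
.parseFoldEnergy <- function(lines) {
    m <- unlist(regmatches(
        lines,
        regexpr("\\(\\s*-?[0-9]+(\\.[0-9]+)?\\s*\\)\\s*$", lines)))
    if (!length(m)) return(NA_real_)
    as.numeric(gsub("[()[:space:]]", "", m[length(m)]))
}

#' Restrict a feature table to a 5'UTR length window
#'
#' Keeps genes with `lo <= utr_length <= hi`; bounds are inclusive on both
#' ends (a 100-nt 5'UTR is retained by the window `[100, 300]`).
#'
#' @param features data.frame with a `utr_length` column.
#' @param lo,hi window bounds in nucleotides.
#' @return the retained subset.
#' @export
lengthRestrictedView <- function(features, lo, hi) {
    stopifnot(lo <= hi)
    features[!is.na(features$utr_length) &
             features$utr_length >= lo & features$utr_length <= hi, ,
             drop = FALSE]
}
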