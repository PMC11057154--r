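.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a 5'UTR for upstream AUGs and classify them
#'
#' Finds every `ATG` occurrence in the spliced 5'UTR and classifies it:
#'
#' * `start_stop` -- the AUG is immediately followed by a stop codon
#'   (`TAA`/`TAG`/`TGA`), a 6-nt pausing element;
#' * `uORF` -- the first in-frame stop codon lies wholly within the 5'UTR
#'   (the element runs start codon through that stop codon; several uAUGs
#'   sharing one stop are all emitted as separate uORFs);
#' * `oORF_out_of_frame` / `NTE` -- no in-frame stop within the 5'UTR, so the
#'   reading frame runs into the CDS; it is an N-terminal extension (`NTE`)
#'   when the uAUG is in frame with the CDS, i.e.
#'   `(utr_length - utr_offset) %% 3 == 0`, otherwise out-of-frame.
#'
#' Codons containing `N` are unclassifiable and never act as stops. The four
#' classes are mutually exclusive and exhaustive over `ATG` occurrences.
#'
#' @param utr5Seq spliced 5'UTR (uppercase `ACGTN`).
#' @param cdsSeq spliced CDS, used for Kozak context at the UTR/CDS junction.
#' @return A data.frame with one row per uAUG, ordered by
#'   position: `utr_offset` (0-based position of the A), `klass`,
#'   `stop_offset` (0-based, one past the stop codon; `NA` for oORF/NTE),
#'   `length_bp` (start through stop inclusive), `distance_to_cds` (one past
#'   the stop codon to the CDS start; 0 = abutting), `kozak`,
#'   `evidence_matched` (initialised `FALSE`).
#' @examples
#' scanUpstreamAUGs("ATGAAATAGC", "ATGCCC")   # one uORF, 9 bp, 1 nt from CDS
#' scanUpstreamAUGs("ATGTAACC", "ATGCCC")     # a start-stop
#' @export
scanUpstreamAUGs <- function(utr5Seq, cdsSeq = "") {
    L <- nchar(utr5Seq)
    empty <- data.frame(
        utr_offset = integer(0), klass = character(0),
        stop_offset = integer(0), length_bp = integer(0),
        distance_to_cds = integer(0), kozak = character(0),
        evidence_matched = logical(0))
    if (L < 3L) return(empty)

    starts1 <- .findAll(utr5Seq, "ATG")            # 1-based
    if (!length(starts1)) return(empty)

    # 1-based positions of stop codons fully inside the UTR, split by frame
    codonStarts <- seq_len(L - 2L)
    codons <- substring(utr5Seq, codonStarts, codonStarts + 2L)
    stop1 <- codonStarts[codons %in% .STOP_CODONS]
    stopByFrame <- split(stop1, (stop1 - 1L) %% 3L)

    n <- length(starts1)
    klass <- character(n); stopOff <- rep(NA_integer_, n)
    lenBp <- rep(NA_integer_, n); dist <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        s <- starts1[i]
        frame <- as.character((s - 1L) %% 3L)
        cand <- stopByFrame[[frame]]
        cand <- cand[cand >= s + 3L]
        if (length(cand)) {
            j <- cand[1L]
            stopOff[i] <- j + 2L                       # 0-based one-past-stop
            lenBp[i] <- j + 2L - (s - 1L)
            dist[i] <- L - stopOff[i]
            klass[i] <- if (j == s + 3L) "start_stop" else "uORF"
        } else {
            klass[i] <- if ((L - (s - 1L)) %% 3L == 0L) "NTE"
                        else "oORF_out_of_frame"
        }
    }
    data.frame(
        utr_offset = starts1 - 1L, klass = klass, stop_offset = stopOff,
        length_bp = lenBp, distance_to_cds = dist,
        kozak = kozakStrength(utr5Seq, starts1 - 1L, cdsSeq),
        evidence_matched = logical(n))
}

# all (possibly overlapping) 1-based match positions of a fixed pattern
.findAll <- function(seq, pattern) {
    hits <- gregexpr(pattern, seq, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Kozak context strength of a uAUG
#'
#' Applies the classical -3/+4 rule: *strong* when the base three positions
#' 5' of the AUG is `A` or `G` *and* the base immediately 3' of it is `G`;
#' *moderate* when exactly one condition holds; *weak* otherwise. When the
#' uAUG sits fewer than three bases from the 5' end, the -3 position is
#' unavailable and counts as non-matching. The +4 base is drawn from the CDS
#' when the uAUG abuts the UTR/CDS junction.
#'
#' @param utr5Seq spliced 5'UTR.
#' @param utrOffset 0-based position(s) of the A of the AUG (vectorised).
#' @param cdsSeq spliced CDS.
#' @return character vector in `c("strong", "moderate", "weak")`.
#' @export
kozakStrength <- function(utr5Seq, utrOffset, cdsSeq = "") {
    combined <- paste0(utr5Seq, cdsSeq)
    m3 <- ifelse(utrOffset >= 3L,
                 substring(combined, utrOffset - 2L, utrOffset - 2L), "")
    p4 <- substring(combined, utrOffset + 4L, utrOffset + 4L)
    c1 <- m3 %in% c("A", "G")
    c2 <- p4 == "G"
    ifelse(c1 & c2, "strong", ifelse(c1 | c2, "moderate", "weak"))
}

#' Translational-efficiency lookup for a uAUG context
#'
#' Assembles the initiation-context key (`upstream` bases, the AUG, then
#' `downstream` bases, the latter drawn from the CDS when the window runs
#' past the 5'UTR end) and looks it up in a measured efficiency table. uAUGs
#' too close to the 5' end to complete the upstream window are excluded
#' (status `"too_close"`); contexts absent from the table are excluded with
#' the distinct status `"unmatched"`.
#'
#' @param utr5Seq,cdsSeq spliced sequences.
#' @param utrOffset 0-based position of the A of the AUG.
#' @param teTable named numeric vector mapping context strings to efficiency
#'   values (see [readTETable()]).
#' @param window integer pair `c(upstream, downstream)`; default `c(6, 2)`.
#' @return list with `te` (numeric or `NA`) and `status` (`"ok"`,
#'   `"too_close"`, `"unmatched"`).
#' @export
lookupTE <- function(utr5Seq, cdsSeq, utrOffset, teTable, window = c(6L, 2L)) {
    if (utrOffset < window[1L])
        return(list(te = NA_real_, status = "too_close"))
    combined <- paste0(utr5Seq, cdsSeq)
    key <- substring(combined, utrOffset - window[1L] + 1L,
                     utrOffset + 3L + window[2L])
    if (nchar(key) < window[1L] + 3L + window[2L])
        return(list(te = NA_real_, status = "unmatched"))
    val <- unname(teTable[key])
    if (is.null(val) || is.na(val))
        return(list(te = NA_real_, status = "unmatched"))
    list(te = val, status = "ok")
}

#' Read a translational-efficiency context table
#'
#' @param path TSV `context<TAB>efficiency` (no header required; a header
#'   line `context efficiency` is tolerated).
#' @return named numeric vector; all keys share one width with `ATG` at the
#'   designated slot.
#' @export
readTETable <- function(path) {
    x <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE,
                           col.names = c("context", "efficiency"))
    if (identical(tolower(x$context[1L]), "context")) x <- x[-1L, ]
    v <- as.numeric(x$efficiency)
    if (anyNA(v)) stop("unparseable efficiency value in ", path)
    if (length(unique(nchar(x$context))) > 1L)
        stop("TE table contexts must all have the same width")
    stats::setNames(v, toupper(x$context))
}

#' Codon optimality score of a uORF body
#'
#' Fraction of codons flagged optimal in a binary per-codon optimality table
#' (tRNA-adaptation-index derived). A trailing stop codon and a leading
#' `ATG` start codon are excluded from the denominator, so an empty body (a
#' start-stop element) yields `NA`, not 0.
#'
#' @param uorfSeq in-frame element sequence, length divisible by 3.
#' @param optimalTable named integer vector codon -> 0/1 covering the 61
#'   sense codons (see [readOptimalCodonTable()]).
#' @return fraction in `[0, 1]`, or `NA` for an empty body.
#' @export
codonOptimality <- function(uorfSeq, optimalTable) {
    L <- nchar(uorfSeq)
    if (L %% 3L != 0L) stop("uORF sequence length must be divisible by 3")
    if (L == 0L) return(NA_real_)
    starts <- seq(1L, L - 2L, by = 3L)
    codons <- substring(uorfSeq, starts, starts + 2L)
    n <- length(codons)
    if (codons[n] %in% .STOP_CODONS) codons <- codons[-n]
    if (length(codons) && codons[1L] == "ATG") codons <- codons[-1L]
    if (!length(codons)) return(NA_real_)
    vals <- optimalTable[codons]
    if (anyNA(vals))
        warning("codon(s) absent from optimality table: ",
                paste(unique(codons[is.na(vals)]), collapse = ","))
    mean(vals, na.rm = TRUE)
}

#' Read a binary codon-optimality table
#'
#' @param path TSV `codon<TAB>0|1`.
#' @return named integer vector over codons.
#' @export
readOptimalCodonTable <- function(path) {
    x <- utils::read.delim(path, stringsAsFactors = FALSE, header = FALSE,
                           col.names = c("codon", "optimal"))
    if (identical(tolower(x$codon[1L]), "codon")) x <- x[-1L, ]
    stats::setNames(as.integer(x$optimal), toupper(x$codon))
}

#' Match predicted elements against an evidence uORF set
#'
#' Flags each predicted uORF/start-stop whose transcript-space coordinates
#' equal an evidence record's (strict start *and* end equality by default;
#' `by = "start"` relaxes to start-only overlap). Evidence records with
#' non-canonical start codons can never match a predicted AUG element and are
#' tallied separately.
#'
#' @param elements output of [scanUpstreamAUGs()].
#' @param evidence data.frame from [loadEvidenceUORFs()] restricted to one
#'   transcript, with 0-based half-open `start`, `end`.
#' @param by `"both"` (default) or `"start"`.
#' @return `elements` with `evidence_matched` filled, plus attributes
#'   `matchedFraction` (of predicted uORF/start-stop elements),
#'   `nEvidenceUnmatched` and `nNonCanonical`.
#' @export
matchEvidence <- function(elements, evidence, by = c("both", "start")) {
    by <- match.arg(by)
    isOrf <- elements$klass %in% c("uORF", "start_stop")
    evCanon <- evidence[evidence$canonical, , drop = FALSE]
    key <- function(s, e) paste(s, e, sep = ":")
    if (by == "both") {
        hit <- isOrf & key(elements$utr_offset, elements$stop_offset) %in%
            key(evCanon$start, evCanon$end)
        evHit <- key(evCanon$start, evCanon$end) %in%
            key(elements$utr_offset[isOrf], elements$stop_offset[isOrf])
    } else {
        hit <- isOrf & elements$utr_offset %in% evCanon$start
        evHit <- evCanon$start %in% elements$utr_offset[isOrf]
    }
    elements$evidence_matched <- hit
    attr(elements, "matchedFraction") <-
        if (any(isOrf)) mean(hit[isOrf]) else NA_real_
    attr(elements, "nEvidenceUnmatched") <-
        sum(!evHit) + sum(!evidence$canonical)
    attr(elements, "nNonCanonical") <- sum(!evidence$canonical)
    elements
}
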