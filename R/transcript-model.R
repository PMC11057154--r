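#' Construct a TranscriptModel
#'
#' @param geneId,transcriptId identifiers.
#' @param contig genomic sequence name.
#' @param strand `"+"` or `"-"`.
#' @param utr5Exons [IRanges::IRanges] of 5'UTR exon blocks in genomic
#'   coordinates (1-based inclusive), ordered 5' to 3' in transcript space.
#' @param utr5Seq,cdsSeq spliced sequences on the transcript strand.
#' @param mrnaLength total spliced mRNA length (defaults to
#'   `nchar(utr5Seq) + nchar(cdsSeq)` when no 3'UTR is modelled).
#'
#' @return A [TranscriptModel-class] object.
#' @examples
#' m <- TranscriptModel("g1", "t1", "chr_t", "+",
#'     IRanges::IRanges(start = c(1, 11), end = c(4, 14)),
#'     utr5Seq = "ACGTTTAG", cdsSeq = "ATGAAATGA")
#' utr5Length(m)
#' @export
TranscriptModel <- function(geneId, transcriptId, contig, strand, utr5Exons,
                            utr5Seq, cdsSeq,
                            mrnaLength = nchar(utr5Seq) + nchar(cdsSeq)) {
    new("TranscriptModel",
        geneId = as.character(geneId),
        transcriptId = as.character(transcriptId),
        contig = as.character(contig),
        strand = strand,
        utr5Exons = utr5Exons,
        utr5Seq = toupper(utr5Seq),
        cdsSeq = toupper(cdsSeq),
        mrnaLength = as.integer(mrnaLength),
        utr5IntronCount = max(0L, length(utr5Exons) - 1L),
        canonicalStart = nchar(cdsSeq) >= 3L &&
            substr(toupper(cdsSeq), 1L, 3L) == "ATG")
}

#' @rdname TranscriptModel
#' @param object,x a `TranscriptModel`.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname TranscriptModel
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)

#' @rdname TranscriptModel
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))
#' @rdname TranscriptModel
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)

#' @rdname TranscriptModel
#' @export
setGeneric("utr5Seq", function(x) standardGeneric("utr5Seq"))
#' @rdname TranscriptModel
#' @export
setMethod("utr5Seq", "TranscriptModel", function(x) x@utr5Seq)

#' @rdname TranscriptModel
#' @export
setGeneric("cdsSeq", function(x) standardGeneric("cdsSeq"))
#' @rdname TranscriptModel
#' @export
setMethod("cdsSeq", "TranscriptModel", function(x) x@cdsSeq)

#' @rdname TranscriptModel
#' @export
setGeneric("utr5Exons", function(x) standardGeneric("utr5Exons"))
#' @rdname TranscriptModel
#' @export
setMethod("utr5Exons", "TranscriptModel", function(x) x@utr5Exons)

#' @rdname TranscriptModel
#' @export
setGeneric("utr5Length", function(x) standardGeneric("utr5Length"))
#' @rdname TranscriptModel
#' @export
setMethod("utr5Length", "TranscriptModel", function(x) nchar(x@utr5Seq))

#' @rdname TranscriptModel
#' @export
setGeneric("mrnaLength", function(x) standardGeneric("mrnaLength"))
#' @rdname TranscriptModel
#' @export
setMethod("mrnaLength", "TranscriptModel", function(x) x@mrnaLength)

#' @rdname TranscriptModel
#' @export
setGeneric("utr5IntronCount", function(x) standardGeneric("utr5IntronCount"))
#' @rdname TranscriptModel
#' @export
setMethod("utr5IntronCount", "TranscriptModel", function(x) x@utr5IntronCount)

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel:", object@geneId, "/", object@transcriptId, "\n")
    cat("  ", object@contig, "(", object@strand, "), 5'UTR ",
        nchar(object@utr5Seq), " nt in ", length(object@utr5Exons),
        " exon block(s), CDS ", nchar(object@cdsSeq), " nt, mRNA ",
        object@mrnaLength, " nt\n", sep = "")
})

#' Build a TranscriptModelList
#'
#' @param models a (possibly named) list of [TranscriptModel-class] objects.
#' @return A [TranscriptModelList-class], named by gene id and sorted by it.
#' @export
TranscriptModelList <- function(models = list()) {
    nm <- vapply(models, geneId, character(1))
    models <- models[order(nm)]
    out <- new("TranscriptModelList", S4Vectors::SimpleList(models))
    names(out) <- sort(nm)
    out
}

#' Map between genomic and transcript coordinates of a 5'UTR
#'
#' `genomicToTranscript()` converts a 0-based genomic position to the 0-based
#' offset of that base within the spliced 5'UTR, returning `NA` for intronic
#' positions or positions outside the 5'UTR (absence is a value, not an
#' error). `transcriptToGenomic()` is its inverse on valid offsets.
#' Both are strictly monotone along transcript order.
#'
#' @param model a [TranscriptModel-class].
#' @param genomicPos integer vector of 0-based genomic positions.
#' @param offset integer vector of 0-based spliced-5'UTR offsets.
#' @return Integer vector (0-based), with `NA` where unmapped.
#' @examples
#' m <- TranscriptModel("g1", "t1", "chr_t", "+",
#'     IRanges::IRanges(start = c(1, 11), end = c(4, 14)),
#'     utr5Seq = "ACGTTTAG", cdsSeq = "ATGAAATGA")
#' genomicToTranscript(m, c(0, 5, 10))   # 0, NA, 4
#' transcriptToGenomic(m, 0:7)
#' @export
genomicToTranscript <- function(model, genomicPos) {
    ex <- model@utr5Exons
    w <- IRanges::width(ex)
    cum <- c(0L, cumsum(w))
    out <- rep(NA_integer_, length(genomicPos))
    g1 <- as.integer(genomicPos) + 1L   # to 1-based
    for (i in seq_along(ex)) {
        s <- IRanges::start(ex)[i]; e <- IRanges::end(ex)[i]
        hit <- !is.na(g1) & g1 >= s & g1 <= e
        if (!any(hit)) next
        out[hit] <- if (model@strand == "+") cum[i] + (g1[hit] - s)
                    else                     cum[i] + (e - g1[hit])
    }
    out
}

#' @rdname genomicToTranscript
#' @export
transcriptToGenomic <- function(model, offset) {
    ex <- model@utr5Exons
    w <- IRanges::width(ex)
    cum <- c(0L, cumsum(w))
    off <- as.integer(offset)
    out <- rep(NA_integer_, length(off))
    idx <- findInterval(off, cum, rightmost.closed = FALSE)
    ok <- !is.na(off) & off >= 0L & off < cum[length(cum)]
    for (i in seq_along(ex)) {
        hit <- ok & idx == i
        if (!any(hit)) next
        within <- off[hit] - cum[i]
        out[hit] <- if (model@strand == "+") IRanges::start(ex)[i] - 1L + within
                    else                     IRanges::end(ex)[i] - 1L - within
    }
    out
}
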