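#' @import methods
NULL

#' TranscriptModel: one gene's representative transcript
#'
#' Container for a single representative (e.g. MANE-Select-like) transcript:
#' the genomic exon structure of its 5'UTR, the spliced 5'UTR and CDS
#' sequences (transcript strand, uppercase `ACGTN`), and the quantities the
#' feature layer needs (spliced mRNA length, 5'UTR intron count).
#'
#' Exon intervals are stored as an [IRanges::IRanges] in genomic coordinates
#' (1-based, inclusive, the Bioconductor convention), ordered 5' to 3' in
#' transcript space -- genomic-ascending on `+` transcripts and
#' genomic-descending on `-` transcripts. The 5'UTR intron count is the
#' number of exon-exon junctions strictly internal to the 5'UTR, i.e.
#' `length(utr5Exons) - 1`; a junction shared between the last UTR base and
#' the first CDS base of the same exon does not count.
#'
#' @slot geneId stable gene identifier.
#' @slot transcriptId transcript identifier.
#' @slot contig name of the genomic sequence the transcript lies on.
#' @slot strand `"+"` or `"-"`.
#' @slot utr5Exons [IRanges::IRanges] of 5'UTR exon blocks (genomic, 1-based
#'   inclusive, transcript order).
#' @slot utr5Seq spliced 5'UTR sequence (character, transcript strand).
#' @slot cdsSeq spliced CDS sequence (character, transcript strand).
#' @slot mrnaLength total spliced mRNA length in nucleotides.
#' @slot utr5IntronCount number of introns internal to the 5'UTR.
#' @slot canonicalStart `TRUE` when the CDS begins with `ATG`.
#'
#' @seealso [loadTranscripts()], [genomicToTranscript()], [buildFeatures()]
#' @export
setClass("TranscriptModel",
    representation(
        geneId = "character",
        transcriptId = "character",
        contig = "character",
        strand = "character",
        utr5Exons = "IRanges",
        utr5Seq = "character",
        cdsSeq = "character",
        mrnaLength = "integer",
        utr5IntronCount = "integer",
        canonicalStart = "logical"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character(0)
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be \"+\" or \"-\"")
    if (nchar(object@utr5Seq) == 0L)
        msg <- c(msg, "utr5Seq must be non-empty (empty-5'UTR transcripts are excluded upstream)")
    if (sum(IRanges::width(object@utr5Exons)) != nchar(object@utr5Seq))
        msg <- c(msg, "sum of utr5Exons widths must equal nchar(utr5Seq)")
    if (object@utr5IntronCount != max(0L, length(object@utr5Exons) - 1L))
        msg <- c(msg, "utr5IntronCount must equal number of 5'UTR exon blocks minus one")
    if (grepl("[^ACGTN]", object@utr5Seq) || grepl("[^ACGTN]", object@cdsSeq))
        msg <- c(msg, "sequences must be uppercase over the alphabet ACGTN")
    if (nchar(object@cdsSeq) >= 3L) {
        isATG <- substr(object@cdsSeq, 1L, 3L) == "ATG"
        if (isATG != object@canonicalStart)
            msg <- c(msg, "canonicalStart flag inconsistent with cdsSeq")
    }
    if (object@mrnaLength < nchar(object@utr5Seq) + nchar(object@cdsSeq))
        msg <- c(msg, "mrnaLength smaller than utr5 + CDS")
    if (length(msg)) msg else TRUE
})

#' List of TranscriptModel objects
#'
#' A [S4Vectors::SimpleList] subclass holding one [TranscriptModel] per gene,
#' named by `geneId` and ordered deterministically by gene identifier.
#' `metadata()` carries the exclusion accounting from [loadTranscripts()]
#' (`excludedEmptyUTR`, `skippedNoCDS`, `transcriptsSeen`).
#'
#' @export
setClass("TranscriptModelList",
    contains = "SimpleList",
    prototype = prototype(elementType = "TranscriptModel")
)

#' ScoreTrack: sparse per-base numeric scores in genomic space
#'
#' Holds per-base scores (conservation, deleteriousness) addressed by
#' `(contig, 0-based position)`. Positions may be missing; a missing position
#' is distinguishable from a score of zero. Several rows per position are
#' allowed (e.g. one CADD score per alternative allele); per-base
#' summarisation happens at aggregation time.
#'
#' @slot contig character vector of contig names, one per score row.
#' @slot pos integer vector of 0-based genomic positions.
#' @slot score numeric scores.
#'
#' @seealso [readScoreTrack()], [aggregateTrack()]
#' @export
setClass("ScoreTrack",
    representation(contig = "character", pos = "integer", score = "numeric")
)

setValidity("ScoreTrack", function(object) {
    n <- length(object@score)
    if (length(object@contig) != n || length(object@pos) != n)
        return("contig, pos and score must have equal length")
    if (any(object@pos < 0L, na.rm = TRUE))
        return("positions must be 0-based and non-negative")
    TRUE
})
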