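#' Configuration for a synthetic 5'UTR cohort
#'
#' Defines the statistical structure of a generated cohort. The defaults
#' emulate the study conditions the analysis layer expects as planted ground
#' truth: per-decile mean 5'UTR length interpolating linearly so the extreme
#' constraint quintiles average 269 nt (most LoF intolerant) versus 162 nt
#' (most tolerant); per-decile GC averaging 0.673 versus 0.599 at the
#' extremes; uORF presence probability 0.462 versus 0.278 and start-stop
#' presence 0.068 versus 0.045 (oORF presence decile-independent, a null
#' feature); conservation uplift at planted element start/stop codons;
#' negative-binomial CAGE peak counts and log-normal expression (both
#' decile-trending and decile-flat pieces respectively). The numeric
#' defaults are generator parameters, not claims about real genomes.
#'
#' @param nGenes cohort size (spread evenly over 10 constraint deciles).
#' @param lengthQuintileMeans target mean 5'UTR lengths (nt) for the extreme
#'   quintiles, `c(intolerant, tolerant)`.
#' @param lengthSdlog log-normal spread of lengths.
#' @param gcQuintileMeans target GC fractions at the extreme quintiles.
#' @param dinucBias named multipliers on transition probabilities (first
#'   order Markov); default depletes CpG. `NULL` gives the i.i.d. null
#'   preset.
#' @param uorfPrev,startStopPrev presence probabilities at the extreme
#'   quintiles, `c(intolerant, tolerant)`.
#' @param oorfPrev decile-independent oORF presence probability.
#' @param nteFraction fraction of planted oORFs that are in-frame NTEs.
#' @param extraUorfMean Poisson mean of additional uORFs when present.
#' @param uorfBodyCodonMean Poisson mean of uORF body codons (length is
#'   `3 * (3 + body)` bp).
#' @param phylopBase per-decile baseline PhyloP means at the extreme
#'   quintiles; `phylopUplift` additive Gaussian mean at planted element
#'   start/stop codons (sd `phylopUpliftSd`), `phylopSd` per-base noise.
#' @param caddBase CADD baseline means at the extreme quintiles (three
#'   scores per base, one per alternative allele, sd `caddSd`).
#' @param cageMeans negative-binomial means at the extreme quintiles,
#'   `cageSize` the dispersion size.
#' @param tpmMeanlog,tpmSdlog log-normal expression (decile-independent, a
#'   null feature).
#' @param genesetFrac fraction of the cohort in each disease gene set.
#' @param evidenceMatchProb probability a planted uORF also appears in the
#'   emitted Ribo-seq-style evidence set.
#' @param nonCanonEvidenceProb probability a gene carries one additional
#'   non-canonical (CUG-start) evidence uORF.
#' @param intronProb probability the 5'UTR is split by one intron.
#' @param minusStrandProb fraction of genes emitted on the minus strand.
#' @param uaugGainProb fraction of genes carrying one planted uAUG-gained
#'   SNV; `ustopLostProb` the fraction *of uORF-bearing genes* staged for a
#'   planted uSTOP-lost SNV.
#' @param cdsMeanlog,cdsSdlog,utr3Meanlog,utr3Sdlog log-normal CDS and 3'UTR
#'   lengths (mRNA length = 5'UTR + CDS + 3'UTR).
#' @return list of class `cohortConfig`.
#' @export
cohortConfig <- function(nGenes = 500L,
                         lengthQuintileMeans = c(269, 162),
                         lengthSdlog = 0.6,
                         gcQuintileMeans = c(0.673, 0.599),
                         dinucBias = c(CG = 0.35),
                         uorfPrev = c(0.462, 0.278),
                         startStopPrev = c(0.068, 0.045),
                         oorfPrev = 0.15,
                         nteFraction = 0.4,
                         extraUorfMean = 0.4,
                         uorfBodyCodonMean = 12,
                         phylopBase = c(1.2, 0.6),
                         phylopUplift = 2.5, phylopUpliftSd = 0.5,
                         phylopSd = 1,
                         caddBase = c(9, 6), caddSd = 2,
                         cageMeans = c(6, 2.2), cageSize = 2,
                         tpmMeanlog = 2, tpmSdlog = 1,
                         genesetFrac = c(DD_dominant = 0.04,
                                         DD_recessive = 0.04,
                                         oncogene = 0.03, TSG = 0.03,
                                         HS = 0.08, TS = 0.05),
                         evidenceMatchProb = 0.3,
                         nonCanonEvidenceProb = 0.15,
                         intronProb = 0.25,
                         minusStrandProb = 0.3,
                         uaugGainProb = 0.12,
                         ustopLostProb = 0.25,
                         cdsMeanlog = 7.0, cdsSdlog = 0.45,
                         utr3Meanlog = 6.4, utr3Sdlog = 0.5) {
    if (nGenes <= 0L) stop("cohortConfig: nGenes must be positive")
    cfg <- as.list(environment())
    class(cfg) <- "cohortConfig"
    cfg
}

# linear per-decile value whose extreme-quintile means hit the two targets
.decileLine <- function(quintileMeans) {
    b <- (quintileMeans[2] - quintileMeans[1]) / 8
    a <- quintileMeans[1] - 1.5 * b
    a + b * (1:10)
}

# first-order Markov transition matrix targeting a base composition, with
# multiplicative dinucleotide bias; fixed-point-calibrated so the stationary
# composition matches the target despite the bias
.markovMatrix <- function(gc, bias = NULL) {
    target <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    pb <- target
    build <- function(pb) {
        M <- matrix(rep(pb, each = 4), 4, 4,
                    dimnames = list(names(pb), names(pb)))
        if (!is.null(bias))
            for (d in names(bias))
                M[substr(d, 1, 1), substr(d, 2, 2)] <-
                    M[substr(d, 1, 1), substr(d, 2, 2)] * bias[[d]]
        M / rowSums(M)
    }
    M <- build(pb)
    for (it in seq_len(12)) {
        P <- M
        for (k in seq_len(6)) P <- P %*% P      # M^64: stationary rows
        st <- as.vector(rep(0.25, 4) %*% P)
        pb <- pb * target / pmax(st, 1e-9)
        pb <- pb / sum(pb)
        M <- build(pb)
    }
    list(trans = M, init = pb)
}

# vectorised Markov chain sequences sharing one transition matrix
.markovSeqs <- function(lengths, mk) {
    n <- length(lengths)
    maxL <- max(lengths)
    cum <- t(apply(mk$trans, 1, cumsum))
    cur <- findInterval(stats::runif(n), cumsum(mk$init)) + 1L
    cur <- pmin(cur, 4L)
    M <- matrix(NA_integer_, n, maxL)
    M[, 1L] <- cur
    if (maxL >= 2L) for (t in 2:maxL) {
        act <- which(lengths >= t)
        if (!length(act)) next
        u <- stats::runif(length(act))
        cc <- cum[cur[act], , drop = FALSE]
        nxt <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
        cur[act] <- nxt
        M[act, t] <- nxt
    }
    vapply(seq_len(n), function(i)
        paste(.NT[M[i, seq_len(lengths[i])]], collapse = ""), character(1))
}

# remove every ATG by rewriting its middle base to C (a C can never be part
# of an ATG, so one pass suffices and no new ATG can arise)
.scrubATGs <- function(seq) {
    hits <- .findAll(seq, "ATG")
    if (!length(hits)) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    chars[hits + 1L] <- "C"
    paste(chars, collapse = "")
}

#' Plant an upstream element of a requested class into a 5'UTR
#'
#' Edits the sequence so that [scanUpstreamAUGs()] finds an element of
#' exactly the requested class at the requested position, without
#' introducing unintended new ATGs around the edit window. For `uORF` and
#' `start_stop` the element body is written explicitly (body codons `CAC`,
#' stop `TAA`); for `oORF_out_of_frame` and `NTE` every in-frame stop codon
#' downstream of the start is defused (first base rewritten to `C`, which
#' can never create an ATG). Unachievable requests -- an NTE at a
#' frame-incompatible offset, a strong Kozak on a start-stop (the +4 base is
#' the stop's `T`), an element that does not fit -- raise an error. The
#' result is verified by rescanning before return.
#'
#' @param seq 5'UTR sequence to edit.
#' @param klass one of `"uORF"`, `"start_stop"`, `"oORF_out_of_frame"`,
#'   `"NTE"`.
#' @param position 0-based offset for the A of the planted ATG.
#' @param kozak requested Kozak class (`"strong"`, `"moderate"`, `"weak"`);
#'   `"strong"` and `"moderate"` need `position >= 3` for the -3 base.
#' @param lengthBp element length for `uORF` (default 15; forced 6 for
#'   `start_stop`).
#' @param soleStop for `uORF`: also defuse all same-frame stops downstream
#'   of the planted stop, making it the element's only in-UTR stop (used to
#'   stage uSTOP-lost variants).
#' @return the edited sequence.
#' @export
plantUORF <- function(seq, klass, position, kozak = "moderate",
                      lengthBp = 15L, soleStop = FALSE) {
    L <- nchar(seq)
    p <- as.integer(position)
    if (klass == "start_stop") lengthBp <- 6L
    if (klass %in% c("uORF", "start_stop")) {
        if (lengthBp %% 3L != 0L || lengthBp < 6L)
            stop("plantUORF: element length must be a positive multiple of 3, >= 6")
        if (klass == "uORF" && lengthBp < 9L)
            stop("plantUORF: a uORF (non start-stop) needs length >= 9")
        if (p < 0L || p + lengthBp > L)
            stop("plantUORF: element does not fit in the 5'UTR")
    } else {
        if (p < 0L || p + 3L > L)
            stop("plantUORF: start codon does not fit")
        inFrame <- (L - p) %% 3L == 0L
        if (klass == "NTE" && !inFrame)
            stop("plantUORF: NTE unachievable at frame-incompatible offset ", p)
        if (klass == "oORF_out_of_frame" && inFrame)
            stop("plantUORF: out-of-frame oORF unachievable at in-frame offset ", p)
        lengthBp <- 3L
    }
    if (klass == "start_stop" && kozak == "strong")
        stop("plantUORF: strong Kozak unachievable for a start-stop (+4 is the stop's T)")
    if (kozak %in% c("strong", "moderate") && p < 3L)
        stop("plantUORF: ", kozak, " Kozak needs position >= 3")

    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    chars[p + 1:3] <- c("A", "T", "G")
    if (klass %in% c("uORF", "start_stop")) {
        nBody <- lengthBp / 3L - 2L
        if (nBody > 0L)
            chars[p + 3L + seq_len(3L * nBody)] <- rep(c("C", "A", "C"), nBody)
        chars[p + lengthBp - 2:0] <- c("T", "A", "A")
    }
    # Kozak: -3 (1-based index p - 2) and +4 (1-based index p + 4)
    if (kozak == "strong") {
        chars[p - 2L] <- "A"
        chars[p + 4L] <- "G"
    } else if (kozak == "moderate") {
        chars[p - 2L] <- "A"
        if (klass %in% c("oORF_out_of_frame", "NTE") &&
            p + 4L <= L && chars[p + 4L] == "G") chars[p + 4L] <- "C"
    } else {
        if (p >= 3L) chars[p - 2L] <- "C"
        if (p + 4L <= L && chars[p + 4L] == "G") chars[p + 4L] <- "C"
    }
    if (klass %in% c("oORF_out_of_frame", "NTE") || soleStop) {
        killFrom <- if (klass == "uORF") p + lengthBp else p + 3L
        js <- seq.int(killFrom, by = 3L, length.out = max(0L, (L - killFrom) %/% 3L))
        for (j in js)
            if (paste(chars[j + 1:3], collapse = "") %in% .STOP_CODONS)
                chars[j + 1L] <- "C"
    }
    # defuse ATGs created at the edit-window boundaries; a C never takes
    # part in an ATG, so these rewrites are terminal
    win <- seq.int(max(0L, p - 5L), min(L - 3L, p + lengthBp + 2L))
    for (q in .findAll(paste(chars, collapse = ""), "ATG") - 1L) {
        if (q == p || !(q %in% win)) next
        if (q + 1L >= p && q + 1L < p + lengthBp) {
            # middle base inside the planted element: rewrite the outside base
            tgt <- if (q < p) q else q + 2L
            chars[tgt + 1L] <- "C"
        } else chars[q + 2L] <- "C"
    }
    out <- paste(chars, collapse = "")

    got <- scanUpstreamAUGs(out)
    hit <- which(got$utr_offset == p)
    if (!length(hit) || got$klass[hit] != klass ||
        (klass %in% c("uORF", "start_stop") && got$length_bp[hit] != lengthBp))
        stop("plantUORF: verification failed for ", klass, " at ", p)
    out
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates per-gene 5'UTR/CDS sequences (first-order Markov background
#' with all incidental ATGs removed, so the upstream element landscape is
#' exactly the planted one), transcript models with optional 5'UTR introns
#' and minus-strand layout on per-gene contigs, constraint scores and
#' metadata, per-base conservation/deleteriousness tracks with uplift at
#' planted element codons, a Ribo-seq-style evidence set, planted
#' uAUG-gained / uSTOP-lost SNVs whose effect labels hold by construction,
#' and machine-readable truth tables for recovery testing. All randomness
#' draws from the R RNG: `set.seed(s)` before the call makes the bundle
#' reproducible.
#'
#' @param config a [cohortConfig()].
#' @return list of class `utrCohort` with components `models`
#'   ([TranscriptModelList-class]), `meta` (data.frame incl. LOEUF, deciles,
#'   gene sets, CAGE, TPM, CDS length), `phylop`, `cadd`
#'   ([ScoreTrack-class]), `evidence`, `variants` (with truth `label`),
#'   `truthElements`, `genome` ([Biostrings::DNAStringSet]), `gtf`
#'   (GRanges), `config`.
#' @seealso [writeCohort()] to emit the bundle as the file dialects the
#'   pipeline consumes.
#' @export
simulateCohort <- function(config = cohortConfig()) {
    cfg <- config
    n <- as.integer(cfg$nGenes)
    if (n <= 0L) stop("simulateCohort: zero genes requested")
    ids <- sprintf("G%05d", seq_len(n))
    decile <- sort(rep(1:10, length.out = n))
    # LOEUF consistent with the decile, so deciles are recoverable by rank
    loeuf <- (decile - 1L) * 0.2 + stats::runif(n, 0.001, 0.199)

    lenMeans <- .decileLine(cfg$lengthQuintileMeans)
    gcMeans <- .decileLine(cfg$gcQuintileMeans)
    uorfP <- .decileLine(cfg$uorfPrev)
    ssP <- .decileLine(cfg$startStopPrev)
    phyloBase <- .decileLine(cfg$phylopBase)
    caddBase <- .decileLine(cfg$caddBase)
    cageMu <- .decileLine(cfg$cageMeans)

    meanlog <- log(lenMeans[decile]) - cfg$lengthSdlog^2 / 2
    utrLen <- as.integer(pmax(25L, pmin(2500L,
        round(stats::rlnorm(n, meanlog, cfg$lengthSdlog)))))

    utrSeq <- character(n)
    for (d in 1:10) {
        idx <- which(decile == d)
        if (!length(idx)) next
        mk <- .markovMatrix(gcMeans[d], cfg$dinucBias)
        utrSeq[idx] <- .markovSeqs(utrLen[idx], mk)
    }
    utrSeq <- vapply(utrSeq, .scrubATGs, character(1), USE.NAMES = FALSE)

    cdsLen <- as.integer(3L * pmax(60L, round(
        stats::rlnorm(n, cfg$cdsMeanlog, cfg$cdsSdlog) / 3)))
    utr3Len <- as.integer(pmax(30L, round(
        stats::rlnorm(n, cfg$utr3Meanlog, cfg$utr3Sdlog))))
    mkCds <- .markovMatrix(0.5, cfg$dinucBias)
    cdsBody <- .markovSeqs(cdsLen - 6L, mkCds)
    cdsSeq <- paste0("ATG", cdsBody, "TAA")

    # ---- element planting -------------------------------------------------
    gainGene <- stats::runif(n) < cfg$uaugGainProb
    ustopDraw <- stats::runif(n) < cfg$ustopLostProb
    truth <- list()
    soleInfo <- vector("list", n)
    for (i in seq_len(n)) {
        d <- decile[i]
        nU <- if (stats::runif(1) < uorfP[d])
            1L + stats::rpois(1, cfg$extraUorfMean) else 0L
        wantSole <- ustopDraw[i] && nU > 0L
        plan <- list()
        if (nU > 0L) for (k in seq_len(nU))
            plan[[length(plan) + 1L]] <- list(klass = "uORF")
        if (stats::runif(1) < ssP[d])
            plan[[length(plan) + 1L]] <- list(klass = "start_stop")
        # oORF-like planting rewrites downstream stops; in sole-stop genes
        # that would interact with the staged uSTOP-lost variant, so skip it
        if (!wantSole && stats::runif(1) < cfg$oorfPrev)
            plan[[length(plan) + 1L]] <- list(
                klass = if (stats::runif(1) < cfg$nteFraction) "NTE"
                        else "oORF_out_of_frame")
        planted <- .plantPlan(utrSeq[i], plan, cfg, soleStop = wantSole)
        utrSeq[i] <- planted$seq
        if (length(planted$rows)) {
            rows <- do.call(rbind, planted$rows)
            rows$gene_id <- ids[i]
            truth[[length(truth) + 1L]] <- rows
        }
        soleInfo[i] <- list(planted$soleStopElement)
    }
    truthElements <- if (length(truth)) do.call(rbind, truth) else
        data.frame(utr_offset = integer(0), klass = character(0),
                   length_bp = integer(0), kozak = character(0),
                   gene_id = character(0))

    # ---- genomic layout, models, GTF, genome ------------------------------
    strand <- ifelse(stats::runif(n) < cfg$minusStrandProb, "-", "+")
    hasIntron <- stats::runif(n) < cfg$intronProb & utrLen >= 60L
    layout <- .layoutGenes(ids, utrSeq, cdsSeq, utr3Len, strand, hasIntron)
    models <- TranscriptModelList(layout$models)

    meta <- data.frame(
        gene_id = ids, loeuf = loeuf, loeuf_decile = decile,
        stringsAsFactors = FALSE)
    for (s in names(cfg$genesetFrac)) {
        w <- switch(s,
            DD_dominant = seq(10, 1, length.out = 10),
            DD_recessive = c(1, 2, 4, 7, 9, 9, 7, 4, 2, 1),
            seq(8, 2, length.out = 10))
        pr <- cfg$genesetFrac[[s]] * w[decile] / mean(w)
        meta[[s]] <- stats::runif(n) < pmin(1, pr)
    }
    meta$cage_peaks <- as.integer(stats::rnbinom(n, size = cfg$cageSize,
                                                 mu = cageMu[decile]))
    meta$mean_tpm <- stats::rlnorm(n, cfg$tpmMeanlog, cfg$tpmSdlog)
    meta$cds_length <- cdsLen

    tracks <- .makeTracks(models, truthElements, decile, phyloBase,
                          caddBase, cfg)
    evidence <- .makeEvidence(models, truthElements, cfg)
    variants <- .plantVariants(models, truthElements, soleInfo,
                               gainGene, ids)

    structure(list(models = models, meta = meta,
                   phylop = tracks$phylop, cadd = tracks$cadd,
                   evidence = evidence, variants = variants,
                   truthElements = truthElements,
                   genome = layout$genome, gtf = layout$gtf,
                   config = cfg),
              class = "utrCohort")
}

# place and plant a per-gene element plan; returns edited sequence + truth
# rows. The sole-stop uORF (variant staging) is planted last, in the final
# third, with all earlier elements confined upstream of it, so its
# downstream-stop defusing never touches another planted window.
.plantPlan <- function(seq, plan, cfg, soleStop = FALSE) {
    L <- nchar(seq)
    rows <- list()
    soleStopElement <- NULL
    if (!length(plan))
        return(list(seq = seq, rows = rows, soleStopElement = NULL))
    isO <- vapply(plan, function(e)
        e$klass %in% c("oORF_out_of_frame", "NTE"), logical(1))
    plan <- plan[order(isO)]
    soleIdx <- 0L
    if (soleStop) {
        uIdx <- which(vapply(plan, function(e) e$klass == "uORF", logical(1)))
        if (length(uIdx)) {
            # move one uORF to the end of the plan and mark it sole
            plan <- c(plan[-uIdx[1L]], plan[uIdx[1L]])
            soleIdx <- length(plan)
        }
    }
    occEnd <- 0L     # 0-based end (exclusive) of the rightmost planted window
    occ <- IRanges::IRanges()
    for (k in seq_along(plan)) {
        e <- plan[[k]]
        isSole <- k == soleIdx
        lenBp <- switch(e$klass,
            start_stop = 6L,
            uORF = {
                want <- 3L * (3L + stats::rpois(1, cfg$uorfBodyCodonMean))
                max(9L, min(want, 3L * ((L - 9L) %/% 3L)))
            },
            3L)
        if (isSole) {
            # the sole-stop uORF lives in the final third; shrink it to fit
            # there, falling back to an ordinary uORF when it cannot
            roomSole <- 3L * ((L - max(3L, occEnd, (2L * L) %/% 3L) - 3L) %/% 3L)
            if (roomSole >= 9L) lenBp <- min(lenBp, roomSole)
            else { isSole <- FALSE; soleIdx <- 0L }
        }
        for (try in seq_len(40L)) {
            lo <- 3L; hi <- L - lenBp - 3L
            if (e$klass %in% c("oORF_out_of_frame", "NTE"))
                lo <- max(lo, occEnd)      # downstream of every window
            if (isSole) lo <- max(lo, occEnd, (2L * L) %/% 3L)
            if (soleStop && !isSole && soleIdx > 0L)
                hi <- min(hi, (2L * L) %/% 3L - lenBp - 8L)
            if (hi < lo) break
            p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
            if (e$klass == "NTE" && (L - p) %% 3L != 0L)
                p <- p - (L - p) %% 3L
            if (e$klass == "oORF_out_of_frame" && (L - p) %% 3L == 0L)
                p <- p - 1L
            if (p < lo || p + lenBp > L) next
            span <- IRanges::IRanges(max(1L, p - 4L), p + lenBp + 6L)
            if (length(occ) && sum(IRanges::countOverlaps(span, occ))) next
            res <- tryCatch(
                plantUORF(seq, e$klass, p, kozak = "moderate",
                          lengthBp = lenBp, soleStop = isSole),
                error = function(err) NULL)
            if (is.null(res)) next
            seq <- res
            occ <- c(occ, span)
            occEnd <- max(occEnd, p + lenBp + 7L)
            rows[[length(rows) + 1L]] <- data.frame(
                utr_offset = p, klass = e$klass,
                length_bp = if (e$klass %in% c("uORF", "start_stop")) lenBp
                            else NA_integer_,
                kozak = "moderate", stringsAsFactors = FALSE)
            if (isSole) soleStopElement <- list(offset = p, lengthBp = lenBp)
            break
        }
    }
    list(seq = seq, rows = rows, soleStopElement = soleStopElement)
}

# lay each gene on its own contig: N flank + 5'UTR (optionally split by one
# 40-nt intron) + CDS + 3'UTR + N flank; minus-strand genes are emitted as
# the reverse complement with coordinates flipped accordingly
.layoutGenes <- function(ids, utrSeq, cdsSeq, utr3Len, strand, hasIntron) {
    n <- length(ids)
    mk <- .markovMatrix(0.5, NULL)
    utr3Seq <- .markovSeqs(utr3Len, mk)
    intronSeq <- .markovSeqs(rep(40L, n), mk)
    flank <- 10L
    models <- vector("list", n)
    genome <- character(n)
    gtfRows <- vector("list", n)
    for (i in seq_len(n)) {
        u <- utrSeq[i]; L <- nchar(u)
        if (hasIntron[i]) {
            cut <- 20L + sample.int(L - 40L, 1L)
            plus <- paste0(substr(u, 1L, cut), intronSeq[i],
                           substring(u, cut + 1L))
            utrBlocksPlus <- IRanges::IRanges(
                start = c(flank + 1L, flank + cut + 40L + 1L),
                end = c(flank + cut, flank + 40L + L))
        } else {
            plus <- u
            utrBlocksPlus <- IRanges::IRanges(flank + 1L, flank + L)
        }
        body <- paste0(cdsSeq[i], utr3Seq[i])
        plusContig <- paste0(strrep("N", flank), plus, body,
                             strrep("N", flank))
        tailStart <- flank + nchar(plus) + 1L
        cdsPlus <- IRanges::IRanges(tailStart,
                                    tailStart + nchar(cdsSeq[i]) - 1L)
        exonsPlus <- utrBlocksPlus
        lastB <- length(exonsPlus)   # last UTR block continues into CDS+3'UTR
        IRanges::end(exonsPlus)[lastB] <- tailStart + nchar(body) - 1L

        tot <- nchar(plusContig)
        if (strand[i] == "-") {
            genome[i] <- .revcomp(plusContig)
            flipR <- function(r) IRanges::IRanges(
                tot - IRanges::end(r) + 1L, tot - IRanges::start(r) + 1L)
            utrBlocks <- flipR(utrBlocksPlus)  # transcript order preserved
            exons <- flipR(exonsPlus)
            cdsR <- flipR(cdsPlus)
        } else {
            genome[i] <- plusContig
            utrBlocks <- utrBlocksPlus
            exons <- exonsPlus
            cdsR <- cdsPlus
        }
        models[[i]] <- TranscriptModel(
            geneId = ids[i], transcriptId = paste0(ids[i], ".t1"),
            contig = ids[i], strand = strand[i],
            utr5Exons = utrBlocks, utr5Seq = u, cdsSeq = cdsSeq[i],
            mrnaLength = L + nchar(body))
        exOrd <- exons[order(IRanges::start(exons))]
        cdsOrd <- cdsR[order(IRanges::start(cdsR))]
        gtfRows[[i]] <- data.frame(
            contig = ids[i],
            start = c(IRanges::start(exOrd), IRanges::start(cdsOrd)),
            end = c(IRanges::end(exOrd), IRanges::end(cdsOrd)),
            type = c(rep("exon", length(exOrd)), rep("CDS", length(cdsOrd))),
            strand = strand[i], gene = ids[i],
            tx = paste0(ids[i], ".t1"), stringsAsFactors = FALSE)
    }
    gtfDf <- do.call(rbind, gtfRows)
    gtf <- GenomicRanges::GRanges(
        seqnames = gtfDf$contig,
        ranges = IRanges::IRanges(gtfDf$start, gtfDf$end),
        strand = gtfDf$strand,
        type = gtfDf$type, gene_id = gtfDf$gene, transcript_id = gtfDf$tx,
        phase = ifelse(gtfDf$type == "CDS", 0L, NA_integer_))
    genomeSet <- Biostrings::DNAStringSet(genome)
    names(genomeSet) <- ids
    list(models = models, genome = genomeSet, gtf = gtf)
}

.makeTracks <- function(models, truthElements, decile, phyloBase,
                        caddBase, cfg) {
    contig <- list(); pos <- list(); val <- list()
    cContig <- list(); cPos <- list(); cVal <- list()
    for (i in seq_along(models)) {
        m <- models[[i]]
        L <- utr5Length(m)
        d <- decile[i]          # gene ids generated pre-sorted by decile
        gpos <- transcriptToGenomic(m, 0:(L - 1L))
        base <- stats::rnorm(L, phyloBase[d], cfg$phylopSd)
        te <- truthElements[truthElements$gene_id == geneId(m), ,
                            drop = FALSE]
        if (nrow(te)) for (r in seq_len(nrow(te))) {
            offs <- if (te$klass[r] %in% c("uORF", "start_stop"))
                c(te$utr_offset[r] + 0:2,
                  te$utr_offset[r] + te$length_bp[r] - 3:1)
            else te$utr_offset[r] + 0:2
            offs <- offs[offs < L]
            base[offs + 1L] <- base[offs + 1L] +
                stats::rnorm(length(offs), cfg$phylopUplift,
                             cfg$phylopUpliftSd)
        }
        contig[[i]] <- rep(geneId(m), L); pos[[i]] <- gpos; val[[i]] <- base
        cContig[[i]] <- rep(geneId(m), 3L * L)
        cPos[[i]] <- rep(gpos, each = 3L)
        cVal[[i]] <- stats::rnorm(3L * L, caddBase[d], cfg$caddSd)
    }
    list(phylop = ScoreTrack(unlist(contig), unlist(pos), unlist(val)),
         cadd = ScoreTrack(unlist(cContig), unlist(cPos), unlist(cVal)))
}

.makeEvidence <- function(models, truthElements, cfg) {
    rows <- list()
    for (mi in seq_along(models)) {
        m <- models[[mi]]
        gid <- geneId(m)
        te <- truthElements[truthElements$gene_id == gid &
                            truthElements$klass %in%
                                c("uORF", "start_stop"), , drop = FALSE]
        if (nrow(te)) for (r in seq_len(nrow(te))) {
            if (stats::runif(1) < cfg$evidenceMatchProb)
                rows[[length(rows) + 1L]] <- data.frame(
                    gene_id = gid, start = te$utr_offset[r],
                    end = te$utr_offset[r] + te$length_bp[r],
                    type = "uORF", start_codon = "ATG",
                    stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < cfg$nonCanonEvidenceProb &&
            utr5Length(m) > 40L) {
            s <- sample.int(utr5Length(m) - 35L, 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                gene_id = gid, start = s, end = s + 30L,
                type = "uORF", start_codon = "CTG",
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows))
        return(data.frame(gene_id = character(0), start = integer(0),
                          end = integer(0), type = character(0),
                          start_codon = character(0),
                          canonical = logical(0)))
    out <- do.call(rbind, rows)
    out$canonical <- out$start_codon == "ATG"
    out
}

# Planted SNVs whose labels hold structurally: a uAUG-gained SNV completes
# an ATG at a site where neither the reference nor the altered base takes
# part in any stop codon (so no existing element can change class, and the
# occupancy margin keeps Kozak contexts of planted elements untouched); a
# uSTOP-lost SNV rewrites the first base of a sole-stop uORF's stop to C
# (destroys exactly that stop, creates no ATG and no stop).
.plantVariants <- function(models, truthElements, soleInfo, gainGene, ids) {
    rows <- list()
    for (i in seq_along(ids)) {
        gid <- ids[i]
        m <- models[[gid]]
        u <- utr5Seq(m)
        L <- nchar(u)
        te <- truthElements[truthElements$gene_id == gid, , drop = FALSE]
        occMask <- logical(L)
        if (nrow(te)) for (r in seq_len(nrow(te))) {
            lenr <- if (is.na(te$length_bp[r])) 3L else te$length_bp[r]
            span <- max(1L, te$utr_offset[r] - 7L + 1L):
                min(L, te$utr_offset[r] + lenr + 8L)
            occMask[span] <- TRUE
        }
        if (gainGene[i] && L >= 15L) {
            q <- .gainCandidate(u, occMask)
            if (!is.na(q)) {
                tri <- strsplit(substr(u, q + 1L, q + 3L), "")[[1L]]
                bad <- which(tri != c("A", "T", "G"))[1L]
                rows[[length(rows) + 1L]] <- .variantRow(
                    m, q + bad - 1L, tri[bad], c("A", "T", "G")[bad],
                    "uAUG_gained")
            }
        }
        info <- soleInfo[[i]]
        if (!is.null(info)) {
            stopOff <- info$offset + info$lengthBp - 3L   # first stop base
            rows[[length(rows) + 1L]] <- .variantRow(
                m, stopOff, "T", "C", "uSTOP_lost")
        }
    }
    if (!length(rows))
        return(data.frame(gene_id = character(0), contig = character(0),
                          pos = integer(0), ref = character(0),
                          alt = character(0), label = character(0)))
    do.call(rbind, rows)
}

# a 0-based offset q where one SNV turns the triplet into ATG and neither
# the reference nor the altered base participates in any stop codon
.gainCandidate <- function(u, occMask) {
    L <- nchar(u)
    if (L < 12L) return(NA_integer_)
    qs <- 3:(L - 7L)
    c1 <- substring(u, qs + 1L, qs + 1L)
    c2 <- substring(u, qs + 2L, qs + 2L)
    c3 <- substring(u, qs + 3L, qs + 3L)
    mism <- (c1 != "A") + (c2 != "T") + (c3 != "G")
    occCum <- cumsum(occMask)
    winBad <- vapply(qs, function(q) {
        a <- max(1L, q - 3L); b <- min(L, q + 8L)
        (occCum[b] - if (a > 1L) occCum[a - 1L] else 0L) > 0L
    }, numeric(1)) > 0
    cand <- qs[mism == 1L & !winBad]
    if (!length(cand)) return(NA_integer_)
    cand <- cand[sample.int(length(cand))]
    for (q in cand) {
        tri <- strsplit(substr(u, q + 1L, q + 3L), "")[[1L]]
        bad <- which(tri != c("A", "T", "G"))[1L]
        b <- q + bad - 1L                       # 0-based changed position
        refOK <- altOK <- TRUE
        for (w in (b - 2L):b) {
            if (w < 0L || w + 3L > L) next
            refCodon <- substr(u, w + 1L, w + 3L)
            altTri <- strsplit(refCodon, "")[[1L]]
            altTri[b - w + 1L] <- c("A", "T", "G")[bad]
            if (refCodon %in% .STOP_CODONS) refOK <- FALSE
            if (paste(altTri, collapse = "") %in% .STOP_CODONS)
                altOK <- FALSE
        }
        if (refOK && altOK) return(q)
    }
    NA_integer_
}

# one planted SNV row: transcript-space edit expressed in VCF genomic terms
.variantRow <- function(m, utrOffset, refTx, altTx, label) {
    gpos <- transcriptToGenomic(m, utrOffset)
    if (m@strand == "-") {
        ref <- .revcomp(refTx); alt <- .revcomp(altTx)
    } else {
        ref <- refTx; alt <- altTx
    }
    data.frame(gene_id = geneId(m), contig = m@contig, pos = gpos + 1L,
               ref = ref, alt = alt, label = label,
               stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk in standard dialects
#'
#' Emits the exact file formats the pipeline consumes: `genome.fa`,
#' `annot.gtf`, `loeuf.tsv`, `genesets.tsv`, `cage.tsv`, `tpm.tsv`,
#' per-base `phylop.tsv` and `cadd.tsv` score tracks (0-based positions),
#' `evidence.tsv`, `variants.vcf`, and the truth tables
#' `truth_elements.tsv` / `truth_variants.tsv`.
#'
#' @param bundle output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(dir, f)
    Biostrings::writeXStringSet(bundle$genome, fp("genome.fa"))
    rtracklayer::export(bundle$gtf, fp("annot.gtf"), format = "gtf")
    wt <- function(d, f) utils::write.table(
        d, fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(bundle$meta[c("gene_id", "loeuf")], "loeuf.tsv")
    wt(bundle$meta[c("gene_id", "DD_dominant", "DD_recessive", "oncogene",
                     "TSG", "HS", "TS")], "genesets.tsv")
    wt(bundle$meta[c("gene_id", "cage_peaks")], "cage.tsv")
    wt(bundle$meta[c("gene_id", "mean_tpm")], "tpm.tsv")
    ph <- bundle$phylop
    wt(data.frame(contig = ph@contig, pos = ph@pos, score = ph@score),
       "phylop.tsv")
    cd <- bundle$cadd
    wt(data.frame(contig = cd@contig, pos = cd@pos, score = cd@score),
       "cadd.tsv")
    wt(bundle$evidence[c("gene_id", "start", "end", "type", "start_codon")],
       "evidence.tsv")
    writeVariantVCF(bundle$variants, fp("variants.vcf"))
    wt(bundle$truthElements, "truth_elements.tsv")
    wt(bundle$variants, "truth_variants.tsv")
    invisible(dir)
}
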