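.NT <- c("A", "C", "G", "T")

#' Dinucleotide-composition-preserving sequence shuffle
#'
#' Shuffles a sequence while preserving its exact dinucleotide multiset
#' (hence also its length, mononucleotide composition, and first and last
#' nucleotides) using the Eulerian-walk construction: the sequence is viewed
#' as an Eulerian trail on the 4-vertex dinucleotide multigraph; a random
#' in-tree (arborescence) towards the final nucleotide is drawn with
#' probability proportional to edge multiplicities, the reserved tree edge is
#' placed last in each vertex's otherwise uniformly permuted out-edge list,
#' and the trail is walked from the first nucleotide. This samples uniformly
#' over all distinct dinucleotide-preserving permutations; swap-based
#' approximations are not used. Draws consume the R RNG stream, so
#' `set.seed()` gives reproducible output.
#'
#' @param seq string over `ACGT`, length >= 2. Sequences containing `N` are
#'   not shuffleable and raise an error (callers exclude them with a reason).
#' @param n number of shuffles to draw.
#' @return character vector of `n` shuffled sequences.
#' @examples
#' set.seed(1)
#' dinucleotideShuffle("ACACGT", 3)
#' @export
dinucleotideShuffle <- function(seq, n = 1L) {
    prep <- .shufflePrep(seq)
    vapply(seq_len(n), function(i) .shuffleDraw(prep), character(1))
}

# precompute the dinucleotide multigraph and the weighted set of valid
# last-edge in-trees; reused across draws for one sequence
.shufflePrep <- function(seq) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    x <- match(chars, .NT)
    if (anyNA(x))
        stop("dinucleotideShuffle: sequence contains non-ACGT characters")
    L <- length(x)
    if (L < 2L) stop("dinucleotideShuffle: sequence length must be >= 2")
    adj <- lapply(1:4, function(v) x[-1L][x[-L] == v])
    root <- x[L]
    nr <- setdiff(which(lengths(adj) > 0L), root)

    if (length(nr) == 0L) {
        combos <- matrix(integer(0), nrow = 1L)
        weights <- 1
    } else {
        cand <- lapply(nr, function(v) unique(adj[[v]]))
        grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
        ok <- logical(nrow(grid)); wts <- numeric(nrow(grid))
        for (r in seq_len(nrow(grid))) {
            f <- stats::setNames(grid[r, ], nr)
            # every non-root vertex must reach the root via reserved edges
            reaches <- vapply(nr, function(v) {
                for (step in seq_len(length(nr) + 1L)) {
                    v <- f[[as.character(v)]]
                    if (v == root) return(TRUE)
                }
                FALSE
            }, logical(1))
            ok[r] <- all(reaches)
            wts[r] <- prod(vapply(seq_along(nr), function(i)
                sum(adj[[nr[i]]] == grid[r, i]), numeric(1)))
        }
        combos <- grid[ok, , drop = FALSE]
        weights <- wts[ok]
    }
    list(x = x, L = L, adj = adj, root = root, nr = nr,
         combos = combos, weights = weights)
}

.shuffleDraw <- function(prep) {
    x <- prep$x; L <- prep$L; adj <- prep$adj
    root <- prep$root; nr <- prep$nr
    pick <- if (nrow(prep$combos) > 1L)
        sample.int(nrow(prep$combos), 1L, prob = prep$weights) else 1L
    ord <- vector("list", 4L)
    for (v in which(lengths(adj) > 0L)) {
        edges <- adj[[v]]
        if (v %in% nr) {
            last <- prep$combos[pick, match(v, nr)]
            rest <- edges[-match(last, edges)]
            ord[[v]] <- c(rest[sample.int(length(rest))], last)
        } else {
            ord[[v]] <- edges[sample.int(length(edges))]
        }
    }
    out <- integer(L)
    out[1L] <- x[1L]
    ptr <- rep(1L, 4L)
    cur <- x[1L]
    for (i in 2:L) {
        nxt <- ord[[cur]][ptr[cur]]
        ptr[cur] <- ptr[cur] + 1L
        out[i] <- nxt
        cur <- nxt
    }
    paste(.NT[out], collapse = "")
}

#' Overlapping codon (3-mer) counts
#'
#' Counts all 64 triplets over every position `0..L-3` (overlapping, not
#' frame-restricted), so the counts sum to `L - 2` for an `N`-free sequence.
#' Sequences shorter than 3 yield all zeros.
#'
#' @param seq string over `ACGT`.
#' @param frameRestricted count only frame-0 codons instead (an exposed
#'   alternative; the depletion statistic targets AUGs at any offset, so the
#'   overlapping count is the default).
#' @return named integer vector over the 64 codons (Biostrings order).
#' @export
codonCounts <- function(seq, frameRestricted = FALSE) {
    if (nchar(seq) < 3L) {
        codons <- Biostrings::mkAllStrings(.NT, 3L)
        return(stats::setNames(integer(64L), codons))
    }
    step <- if (frameRestricted) 3L else 1L
    cnt <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAString(seq), width = 3L, step = step)
    stats::setNames(as.integer(cnt), names(cnt))
}

#' Observed/expected codon counts for one 5'UTR
#'
#' The expected count of each codon is its mean count over `nShuffles`
#' dinucleotide-preserving shuffles of the sequence; `oe = observed /
#' expected` where the expectation is positive, and `NA` (missing, excluded
#' from cohort means -- no pseudocount) where it is zero.
#'
#' @param seq string over `ACGT`, length >= 3.
#' @param nShuffles number of shuffles (the full-scale analysis uses 1000).
#' @return list with named 64-vectors `observed`, `expected`, `oe`.
#' @export
observedExpected <- function(seq, nShuffles = 1000L) {
    stopifnot(nShuffles >= 1L)
    obs <- codonCounts(seq)
    draws <- dinucleotideShuffle(seq, n = nShuffles)
    mat <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(draws), width = 3L, step = 1L)
    expd <- colSums(mat) / nShuffles
    oe <- ifelse(expd > 0, obs / expd, NA_real_)
    list(observed = obs, expected = expd,
         oe = stats::setNames(as.numeric(oe), names(obs)))
}

#' Cohort-level observed/expected codon depletion
#'
#' Runs [observedExpected()] per sequence and reports, per codon, the
#' unweighted mean o/e across genes with a defined ratio together with the
#' number of contributing genes. Sequences containing `N` (or shorter than
#' 3 nt) are excluded with a reason.
#'
#' @param seqs character vector (or named vector) of 5'UTR sequences.
#' @param nShuffles shuffles per sequence.
#' @return data.frame `codon`, `cohort_oe`, `n_genes`, with the exclusion
#'   table in `attr(, "excluded")`.
#' @export
cohortOE <- function(seqs, nShuffles = 1000L) {
    stopifnot(length(seqs) >= 1L)
    usable <- !grepl("[^ACGT]", seqs) & nchar(seqs) >= 3L
    excl <- data.frame(
        index = which(!usable),
        reason = ifelse(grepl("[^ACGT]", seqs[!usable]),
                        "contains_N", "too_short"))
    if (!sum(usable)) stop("cohortOE: no usable sequences")
    oeMat <- vapply(seqs[usable],
                    function(s) observedExpected(s, nShuffles)$oe,
                    numeric(64L))
    oeMat <- matrix(oeMat, nrow = 64L,
                    dimnames = list(names(codonCounts("AAA")), NULL))
    out <- data.frame(
        codon = rownames(oeMat),
        cohort_oe = rowMeans(oeMat, na.rm = TRUE),
        n_genes = as.integer(rowSums(!is.na(oeMat))),
        row.names = NULL)
    out$cohort_oe[out$n_genes == 0L] <- NA_real_
    attr(out, "excluded") <- excl
    out
}
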