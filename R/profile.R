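#' Scoring parameters for local alignment and Karlin-Altschul statistics
#'
#' Defaults are the conventional gapped protein-search settings: BLOSUM62,
#' affine gaps costing open + k * extend for a gap of length k (open 11,
#' extend 1), and the standard gapped Karlin-Altschul constants
#' lambda = 0.267, K = 0.041 for the bit-score transform
#' S' = (lambda S - ln K) / ln 2.
#'
#' @param matrix name of the substitution matrix (a data set of the
#'   Biostrings package, e.g. \code{"BLOSUM62"}).
#' @param gap_open,gap_extend positive gap penalties,
#'   \code{gap_extend <= gap_open}.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @param evalue_max hits with E-value above this are zeroed in profiles.
#' @param cons_min_percent conservation scores below this percentage are
#'   zeroed.
#' @return a validated list of class \code{"ScoringParams"}.
#' @export
scoringParams <- function(matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, lambda = 0.267, K = 0.041,
                          evalue_max = 1e-5, cons_min_percent = 10) {
    if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
    if (gap_open <= 0 || gap_extend <= 0 || gap_extend > gap_open)
        stop("need 0 < gap_extend <= gap_open")
    mat <- .loadMatrix(matrix)
    structure(list(matrix = matrix, mat = mat, gap_open = gap_open,
                   gap_extend = gap_extend, lambda = lambda, K = K,
                   evalue_max = evalue_max,
                   cons_min_percent = cons_min_percent),
              class = "ScoringParams")
}

.loadMatrix <- function(name) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    get(name, envir = e)
}

# map ambiguity codes to X, reject anything else outside the 20 + X alphabet
.cleanSeq <- function(x) {
    x <- toupper(as.character(x))
    x <- chartr("BZUO", "XXXX", x)
    bad <- setdiff(unique(strsplit(x, "")[[1]]), c(AA20, "X"))
    if (length(bad))
        stop("illegal residue(s): ", paste(bad, collapse = ", "))
    x
}

#' Exact Smith-Waterman local alignment score
#'
#' Maximum local alignment score of two protein sequences under the
#' substitution matrix with affine gaps (a gap of length k costs
#' open + k * extend); computed exactly (no seeding heuristics) via
#' [Biostrings::pairwiseAlignment()]. Scores are floored at zero, the
#' score of the empty local alignment. Ambiguous residues (B, Z, U, O) are
#' mapped to X and scored with the matrix's X column.
#'
#' @param seqA,seqB protein sequences (character or \code{AAString}).
#' @param params a [scoringParams()] list.
#' @return list with \code{score} (non-negative) and \code{alignment} (the
#'   \code{PairwiseAlignments} object, NULL when the best score is empty).
#' @examples
#' swAlign("HEAGAWGHEE", "PAWHEAE")$score
#' @export
swAlign <- function(seqA, seqB, params = scoringParams()) {
    a <- .cleanSeq(seqA); b <- .cleanSeq(seqB)
    if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        type = "local", substitutionMatrix = params$mat,
        gapOpening = params$gap_open, gapExtension = params$gap_extend)
    s <- Biostrings::score(pa)
    if (s <= 0) list(score = 0, alignment = NULL)
    else list(score = s, alignment = pa)
}

#' Karlin-Altschul bit score
#'
#' \code{S' = (lambda * S - ln K) / ln 2}; strictly increasing in the raw
#' score.
#'
#' @param S non-negative raw alignment score.
#' @param params a [scoringParams()] list (supplies lambda and K).
#' @return bit score (real).
#' @examples
#' bitScore(100)   # about 43.1 bits with the default constants
#' @export
bitScore <- function(S, params = scoringParams()) {
    if (any(S < 0)) stop("raw scores must be >= 0")
    (params$lambda * S - log(params$K)) / log(2)
}

#' E-value of a bit score
#'
#' Expected number of chance alignments of at least the given bit score in
#' a search space of \code{m * n} residue pairs: \code{E = m n 2^(-S')}.
#' \code{m} is the query length, \code{n} the total residue count of the
#' searched proteome; no edge-length correction is applied.
#'
#' @param bits bit score.
#' @param m,n positive integers.
#' @return E-value (non-negative real).
#' @export
eValue <- function(bits, m, n) {
    if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
    as.numeric(m) * as.numeric(n) * 2^(-bits)
}

#' Best hit of a query within one organism's proteome
#'
#' Aligns the query against every protein of the organism and returns the
#' protein maximizing the bit score; ties break to the lexicographically
#' smaller protein id.
#'
#' @param query query sequence (character or \code{AAString}).
#' @param proteome an \code{AAStringSet} with unique protein ids as names.
#' @param params a [scoringParams()] list.
#' @return list: \code{protein}, \code{raw_score}, \code{bits},
#'   \code{evalue} (computed with n = total residues of the proteome).
#' @export
bestHit <- function(query, proteome, params = scoringParams()) {
    if (length(proteome) == 0) stop("empty organism proteome")
    qc <- .cleanSeq(query)
    scores <- vapply(seq_along(proteome), function(i)
        swAlign(qc, as.character(proteome[[i]]), params)$score, numeric(1))
    bits <- bitScore(scores, params)
    ord <- order(-bits, names(proteome))
    best <- ord[1]
    nRes <- sum(Biostrings::width(proteome))
    list(protein = names(proteome)[best], raw_score = scores[best],
         bits = bits[best],
         evalue = eValue(bits[best], nchar(qc), nRes))
}

#' Conservation-score phylogenetic profile of a query protein
#'
#' For each organism, the best-hit bit score Pab is expressed as a
#' percentage of the query's self-alignment bit score Paa
#' (score = 100 * Pab / Paa), then zeroed when the hit's E-value exceeds
#' \code{evalue_max} and again when the score falls below
#' \code{cons_min_percent}. An organism containing the query verbatim
#' scores 100.
#'
#' @param query an \code{AAStringSet} of length 1 (named) or a character
#'   sequence.
#' @param collection a [ProteomeCollection-class].
#' @param params a [scoringParams()] list.
#' @return a [ConservationProfile-class].
#' @export
conservationProfile <- function(query, collection,
                                params = scoringParams()) {
    stopifnot(methods::is(collection, "ProteomeCollection"))
    qid <- "query"
    if (methods::is(query, "AAStringSet")) {
        if (!is.null(names(query))) qid <- names(query)[1]
        query <- as.character(query[[1]])
    }
    qc <- .cleanSeq(query)
    paa <- bitScore(swAlign(qc, qc, params)$score, params)
    if (paa <= 0) stop("degenerate query: self bit score is not positive")

    clades <- cladeOf(collection)
    orgs <- organisms(collection)
    rows <- lapply(orgs, function(org) {
        h <- bestHit(qc, proteomeOf(collection, org), params)
        score <- 100 * (h$bits / paa)   # Pab == Paa gives exactly 100
        if (h$evalue > params$evalue_max) score <- 0
        if (score < params$cons_min_percent) score <- 0
        S4Vectors::DataFrame(organism = org, clade = clades[[org]],
                             best_protein = h$protein,
                             raw_score = h$raw_score, bits = h$bits,
                             evalue = h$evalue, conservation_score = score)
    })
    hits <- do.call(rbind, rows)
    rownames(hits) <- hits$organism
    methods::new("ConservationProfile", hits = hits, query = qid,
                 selfBits = paa,
                 params = params[setdiff(names(params), "mat")])
}

#' Clade-restriction call on a conservation profile
#'
#' Counts, per clade, the organisms whose conservation score exceeds the
#' threshold. When all such organisms belong to a single clade the profile
#' is called restricted to it.
#'
#' @param profile a [ConservationProfile-class].
#' @param threshold conservation-score threshold (strict; default 10).
#' @return list: \code{clade_counts} (named integer vector),
#'   \code{n_above}, \code{restricted_to} (clade name or \code{NA}).
#' @export
cladeRestriction <- function(profile, threshold = 10) {
    stopifnot(methods::is(profile, "ConservationProfile"))
    h <- profile@hits
    if (any(is.na(h$clade))) stop("unlabeled organism in profile")
    above <- h$conservation_score > threshold
    counts <- vapply(split(above, h$clade), sum, numeric(1))
    hitClades <- names(counts)[counts > 0]
    list(clade_counts = counts, n_above = sum(above),
         restricted_to = if (length(hitClades) == 1) hitClades else
             NA_character_)
}

#' @describeIn ConservationProfile-class named conservation scores
#'   (percent) per organism.
#' @export
setMethod("conservationScores", "ConservationProfile", function(object, ...)
    stats::setNames(object@hits$conservation_score, object@hits$organism))

#' @describeIn ConservationProfile-class Paa, the query's self bit score.
#' @export
setMethod("selfBits", "ConservationProfile", function(object, ...)
    object@selfBits)

setMethod("show", "ConservationProfile", function(object) {
    cat("ConservationProfile of", object@query, "over",
        nrow(object@hits), "organisms\n")
    cat("  Paa (self bit score):", format(object@selfBits, digits = 5), "\n")
    nz <- sum(object@hits$conservation_score > 0)
    cat("  organisms with nonzero score:", nz, "\n")
    invisible(NULL)
})
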