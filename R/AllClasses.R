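#' CountExperiment: petal RNA-seq counts with a stage/time sample sheet
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' first assay, \code{"counts"}, holds non-negative integer read counts and
#' whose \code{colData} carries the factorial design of the study:
#' developmental \code{stage} (\code{"bud"} or \code{"flower_1DPA"}),
#' sampling \code{time} (\code{"morning"} or \code{"evening"}) and a
#' \code{replicate} index. \code{rowData} may carry gene annotation such as
#' the \code{wd40} flag used by the candidate screen.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso [CountExperiment()] for the validating constructor,
#'   [simulateCounts()] to generate one synthetically.
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

.validCountExperiment <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    for (col in c("stage", "time", "replicate"))
        if (!(col %in% colnames(cd)))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
    if (is.null(msg)) TRUE else msg
}
setValidity("CountExperiment", .validCountExperiment)

#' DEResult: per-gene two-group negative-binomial contrast results
#'
#' Holds one contrast's per-gene table: unshrunk log2 fold change, its
#' standard error, the Wald statistic, raw and BH-adjusted p-values, the two
#' group means of normalized counts, the gene-wise dispersion used, and the
#' DEG \code{status} call (\code{"up"}, \code{"down"}, \code{"ns"} or
#' \code{"low_count"}).
#'
#' @slot results a \code{DFrame} with one row per gene.
#' @slot contrast character description of the contrast (B vs A).
#' @slot thresholds the [degThresholds()] list used for the status call
#'   (empty until [callDEGs()] has been applied).
#' @slot useAdjusted logical; whether status used BH-adjusted p-values.
#' @export
setClass("DEResult",
    slots = c(results = "DFrame", contrast = "character",
              thresholds = "list", useAdjusted = "logical"),
    prototype = list(contrast = "", thresholds = list(), useAdjusted = TRUE))

.validDEResult <- function(object) {
    msg <- NULL
    need <- c("gene", "baseMeanA", "baseMeanB", "log2FC", "SE", "stat", "pvalue")
    miss <- setdiff(need, colnames(object@results))
    if (length(miss))
        msg <- c(msg, paste("missing result columns:", paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(object@results$gene))
            msg <- c(msg, "duplicate gene ids in results")
        p <- object@results$pvalue
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "p-values outside [0,1]")
    }
    if ("status" %in% colnames(object@results)) {
        bad <- setdiff(unique(object@results$status),
                       c("up", "down", "ns", "low_count"))
        if (length(bad)) msg <- c(msg, "invalid status labels")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("DEResult", .validDEResult)

#' SetReport: named gene-set sizes and the derived percentage arithmetic
#'
#' Carries the named integer counts (expressed per stage, stage-specific
#' genes, morning/evening DEG sets and their overlaps) together with the
#' percentages derived from them under the package's rounding rules, plus
#' two unrounded ratios quantifying how much larger the diurnal
#' transcriptomic response is in open flowers than in buds.
#'
#' @slot counts named numeric vector of set sizes.
#' @slot percentages named numeric vector; integer-rounded (half-up) except
#'   \code{pct_me_bud}, reported to one decimal.
#' @slot ratios named numeric vector of unrounded ratios.
#' @slot sets named list of gene-id character vectors (may be empty when the
#'   report was built from published sizes rather than from data).
#' @export
setClass("SetReport",
    slots = c(counts = "numeric", percentages = "numeric",
              ratios = "numeric", sets = "list"),
    prototype = list(sets = list()))

.validSetReport <- function(object) {
    msg <- NULL
    pct <- object@percentages
    if (any(pct < 0 | pct > 100, na.rm = TRUE))
        msg <- c(msg, "percentages must lie in [0, 100]")
    if (any(object@counts < 0))
        msg <- c(msg, "set sizes must be non-negative")
    if (is.null(msg)) TRUE else msg
}
setValidity("SetReport", .validSetReport)

#' ProteomeCollection: per-organism protein sets with clade labels
#'
#' A list of [Biostrings::AAStringSet] objects, one per organism, together
#' with an organism-to-clade map. The phylogenetic-profiling functions take
#' the query's best hit within each organism.
#'
#' @slot proteomes named list of \code{AAStringSet}, one element per
#'   organism; element names are organism ids.
#' @slot cladeMap \code{DFrame} with columns \code{organism} and
#'   \code{clade} covering every organism.
#' @export
setClass("ProteomeCollection",
    slots = c(proteomes = "list", cladeMap = "DFrame"))

.validProteomeCollection <- function(object) {
    msg <- NULL
    if (length(object@proteomes)) {
        if (is.null(names(object@proteomes)) ||
            anyDuplicated(names(object@proteomes)))
            msg <- c(msg, "proteomes must be uniquely named by organism id")
        if (!all(vapply(object@proteomes, methods::is, logical(1), "AAStringSet")))
            msg <- c(msg, "each proteome must be an AAStringSet")
    }
    cm <- object@cladeMap
    if (!all(c("organism", "clade") %in% colnames(cm)))
        msg <- c(msg, "cladeMap needs 'organism' and 'clade' columns")
    else if (!all(names(object@proteomes) %in% cm$organism))
        msg <- c(msg, "every organism needs a clade label")
    if (is.null(msg)) TRUE else msg
}
setValidity("ProteomeCollection", .validProteomeCollection)

#' ConservationProfile: bit-score-ratio phylogenetic profile of a query
#'
#' Per-organism best-hit alignment statistics for one query protein: raw
#' Smith-Waterman score, Karlin-Altschul bit score (Pab), E-value, and the
#' conservation score 100 x Pab/Paa after the zeroing rules (score 0 when
#' the E-value exceeds the cutoff or the ratio falls below the minimum
#' percentage). Paa is the query's self-alignment bit score.
#'
#' @slot hits \code{DFrame} with columns organism, clade, best_protein,
#'   raw_score, bits, evalue, conservation_score.
#' @slot query query protein id.
#' @slot selfBits Paa, the self-alignment bit score (positive).
#' @slot params the [scoringParams()] list used.
#' @export
setClass("ConservationProfile",
    slots = c(hits = "DFrame", query = "character",
              selfBits = "numeric", params = "list"))

.validConservationProfile <- function(object) {
    msg <- NULL
    need <- c("organism", "clade", "best_protein", "raw_score", "bits",
              "evalue", "conservation_score")
    if (!all(need %in% colnames(object@hits)))
        msg <- c(msg, "hits table is missing required columns")
    else {
        sc <- object@hits$conservation_score
        cmin <- object@params$cons_min_percent
        if (is.null(cmin)) cmin <- 10
        if (any(sc < 0, na.rm = TRUE))
            msg <- c(msg, "conservation scores must be non-negative")
        if (any(sc > 0 & sc < cmin, na.rm = TRUE))
            msg <- c(msg, "nonzero conservation scores must be >= the minimum percent")
        if (any(object@hits$evalue < 0, na.rm = TRUE))
            msg <- c(msg, "E-values must be non-negative")
    }
    if (length(object@selfBits) != 1L || object@selfBits <= 0)
        msg <- c(msg, "selfBits (Paa) must be a single positive value")
    if (is.null(msg)) TRUE else msg
}
setValidity("ConservationProfile", .validConservationProfile)
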