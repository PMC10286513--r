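#' Construct a CountExperiment
#'
#' Validating constructor bundling a gene x sample integer count matrix with
#' the stage/time/replicate sample sheet and optional gene annotation.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sampleData data.frame (or DataFrame) with one row per sample and
#'   columns \code{stage}, \code{time}, \code{replicate}.
#' @param rowData optional data.frame of gene annotation (e.g. a logical
#'   \code{wd40} column and a \code{description}).
#' @return a [CountExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(40, 50), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' sd <- data.frame(stage = rep(c("bud", "flower_1DPA"), each = 2),
#'                  time = rep(c("morning", "evening"), 2),
#'                  replicate = 1L)
#' ce <- CountExperiment(cts, sd)
#' @export
CountExperiment <- function(counts, sampleData, rowData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    cd <- S4Vectors::DataFrame(sampleData)
    if (is.null(rownames(cd)) || all(rownames(cd) == as.character(seq_len(nrow(cd)))))
        rownames(cd) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(rowData)
    methods::new("CountExperiment", se)
}

#' @describeIn CountExperiment the raw count matrix.
#' @param object a \code{CountExperiment}.
#' @export
countsMatrix <- function(object) {
    SummarizedExperiment::assay(object, "counts")
}

#' @describeIn CountExperiment sample ids matching a stage/time selection;
#'   either filter may be \code{NULL} to select both levels.
#' @param stage,time optional level to select.
#' @export
samplesFor <- function(object, stage = NULL, time = NULL) {
    cd <- SummarizedExperiment::colData(object)
    keep <- rep(TRUE, nrow(cd))
    if (!is.null(stage)) {
        if (!stage %in% cd$stage) stop("unknown stage label: ", stage)
        keep <- keep & cd$stage == stage
    }
    if (!is.null(time)) {
        if (!time %in% cd$time) stop("unknown time label: ", time)
        keep <- keep & cd$time == time
    }
    rownames(cd)[keep]
}

#' @describeIn CountExperiment the stage:time condition factor over samples.
#' @export
conditionFactor <- function(object) {
    cd <- SummarizedExperiment::colData(object)
    factor(paste(cd$stage, cd$time, sep = ":"))
}

setMethod("show", "CountExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    cat("CountExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  stages:", paste(unique(cd$stage), collapse = ", "), "\n")
    cat("  times: ", paste(unique(cd$time), collapse = ", "), "\n")
    if ("wd40" %in% colnames(SummarizedExperiment::rowData(object)))
        cat("  WD40-flagged genes:",
            sum(SummarizedExperiment::rowData(object)$wd40), "\n")
    invisible(NULL)
})
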