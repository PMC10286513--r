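#' Screen for WD40 candidate genes
#'
#' Applies the candidate filters: WD40-annotated genes that are
#' developmentally upregulated (status "up" in 1DPA-vs-bud at either time
#' point) and expressed above the screen floor at 1DPA (the larger of the
#' two time-point mean normalized counts >= \code{screen_count_min},
#' default 100). The 1DPA time-point means are taken from the 1DPA
#' morning/evening contrast's group means.
#'
#' @param deDev a [DEResult-class] of 1DPA-vs-bud, or a list of them (one
#'   per time point); "up" in any of them qualifies.
#' @param deMe1DPA [DEResult-class] of evening-vs-morning within 1DPA
#'   (group A = morning, group B = evening).
#' @param annotation data.frame/DataFrame with rownames (or a \code{gene}
#'   column) covering the gene universe and a logical \code{wd40} column.
#' @param thresholds a [degThresholds()] list.
#' @return \code{DFrame} candidate table: gene, count_morning,
#'   count_evening, me_log2FC, me_status, group (NA until
#'   [groupByTiming()]), representative flag.
#' @export
screenCandidates <- function(deDev, deMe1DPA, annotation,
                             thresholds = degThresholds()) {
    if (methods::is(deDev, "DEResult")) deDev <- list(deDev)
    ann <- as.data.frame(annotation)
    if (!is.null(ann$gene)) rownames(ann) <- ann$gene
    me <- deTable(deMe1DPA)
    genes <- me$gene
    if (!all(genes %in% rownames(ann)))
        stop("annotation does not cover the gene universe")
    for (d in deDev)
        if (!setequal(deTable(d)$gene, genes))
            stop("DE tables are on different gene universes")

    devUp <- Reduce(`|`, lapply(deDev, function(d) {
        st <- degStatus(d)[genes]
        st == "up"
    }))
    wd40 <- ann[genes, "wd40"]
    countM <- me$baseMeanA; countE <- me$baseMeanB
    floorOk <- pmax(countM, countE) >= thresholds$screen_count_min

    keep <- wd40 & devUp & floorOk
    out <- S4Vectors::DataFrame(
        gene = genes[keep],
        count_morning = countM[keep], count_evening = countE[keep],
        me_log2FC = me$log2FC[keep],
        me_status = degStatus(deMe1DPA)[genes[keep]],
        group = NA_character_, representative = FALSE)
    rownames(out) <- out$gene
    out
}

#' Group candidates by the timing of their highest expression
#'
#' Candidates go to the \code{"evening"} group when their 1DPA
#' evening/morning expression ratio is at least \code{me_fold} (default
#' 1.5) and the m/e contrast calls them up; to \code{"morning"} when the
#' morning/evening ratio is at least \code{me_fold} and the contrast calls
#' them down; otherwise to \code{"no_change"}. With \code{foldOnly = TRUE}
#' the DEG-status requirement is dropped and the ratio alone decides.
#'
#' @param candidates candidate table from [screenCandidates()].
#' @param thresholds a [degThresholds()] list (supplies \code{me_fold}).
#' @param foldOnly logical; group on the fold ratio alone.
#' @return the candidate table with the \code{group} column filled.
#' @export
groupByTiming <- function(candidates, thresholds = degThresholds(),
                          foldOnly = FALSE) {
    fold <- 2^candidates$me_log2FC          # evening / morning
    eveOk <- fold >= thresholds$me_fold
    morOk <- (1 / fold) >= thresholds$me_fold
    if (!foldOnly) {
        eveOk <- eveOk & candidates$me_status == "up"
        morOk <- morOk & candidates$me_status == "down"
    }
    grp <- rep("no_change", nrow(candidates))
    grp[eveOk] <- "evening"
    grp[morOk] <- "morning"
    candidates$group <- grp
    candidates
}

#' Select one representative candidate per timing group
#'
#' Flags, within each non-empty group, the candidate with the highest 1DPA
#' expression (the larger of its two time-point mean normalized counts);
#' ties break to the lexicographically smaller gene id.
#'
#' @param candidates grouped candidate table from [groupByTiming()].
#' @param rule selection rule; only \code{"max_1DPA_expression"} is
#'   implemented.
#' @return the candidate table with the \code{representative} flags set
#'   (exactly one per non-empty group).
#' @export
selectRepresentatives <- function(candidates,
                                  rule = "max_1DPA_expression") {
    rule <- match.arg(rule)
    if (nrow(candidates) == 0) return(candidates)
    if (any(is.na(candidates$group)))
        stop("assign groups with groupByTiming() first")
    expr <- pmax(candidates$count_morning, candidates$count_evening)
    repFlag <- logical(nrow(candidates))
    for (g in unique(candidates$group)) {
        idx <- which(candidates$group == g)
        ord <- idx[order(-expr[idx], candidates$gene[idx])]
        repFlag[ord[1]] <- TRUE
    }
    candidates$representative <- repFlag
    candidates
}
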