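#' Genes expressed in a condition or stage
#'
#' A gene counts as expressed in a condition when its mean normalized count
#' over that condition's replicates reaches the threshold (inclusive). A
#' gene is expressed in a developmental stage when it is expressed at
#' either time point of that stage.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param sampleData data.frame/DataFrame with \code{stage} and \code{time}
#'   columns, rownames = sample ids.
#' @param stage stage label.
#' @param time optional time label; omit to apply the either-time-point
#'   rule for the whole stage.
#' @param threshold minimum mean normalized count (default 30).
#' @return character vector of gene ids.
#' @export
expressedSet <- function(normalized, sampleData, stage, time = NULL,
                         threshold = 30) {
    normalized <- as.matrix(normalized)
    sampleData <- as.data.frame(sampleData)
    if (!stage %in% sampleData$stage) stop("unknown stage label: ", stage)
    if (!is.null(time) && !time %in% sampleData$time)
        stop("unknown time label: ", time)
    times <- if (is.null(time)) unique(sampleData$time) else time
    hit <- rep(FALSE, nrow(normalized))
    for (tm in times) {
        ids <- rownames(sampleData)[sampleData$stage == stage &
                                    sampleData$time == tm]
        if (!length(ids)) next
        hit <- hit | rowMeans(normalized[, ids, drop = FALSE]) >= threshold
    }
    rownames(normalized)[hit]
}

#' Two-set Venn partition
#'
#' @param setA,setB character vectors of gene ids.
#' @return list with the member vectors \code{only_a}, \code{only_b},
#'   \code{shared} and a named \code{sizes} vector (only_a, only_b, shared,
#'   union, a, b) satisfying \code{only_a + shared = |A|},
#'   \code{only_b + shared = |B|}, \code{union = |A| + |B| - shared}.
#' @examples
#' vennPartition(c("a", "b"), c("b", "c"))$sizes
#' @export
vennPartition <- function(setA, setB) {
    setA <- unique(setA); setB <- unique(setB)
    shared <- intersect(setA, setB)
    onlyA <- setdiff(setA, setB)
    onlyB <- setdiff(setB, setA)
    list(only_a = onlyA, only_b = onlyB, shared = shared,
         sizes = c(only_a = length(onlyA), only_b = length(onlyB),
                   shared = length(shared),
                   union = length(setA) + length(setB) - length(shared),
                   a = length(setA), b = length(setB)))
}

.statusOf <- function(de) {
    if (methods::is(de, "DEResult")) degStatus(de) else de
}

#' Partition DEGs by the time points at which they are called
#'
#' Splits the union of two DEG sets (the same contrast evaluated in the
#' morning and in the evening) into morning-only, evening-only and
#' both-time-point groups, with per-direction (up/down) variants.
#'
#' @param deMorning,deEvening [DEResult-class] objects (or named status
#'   vectors) over the same gene universe.
#' @return list of character vectors: \code{morning_only},
#'   \code{evening_only}, \code{both}, plus \code{up} and \code{down}
#'   sublists with the same three components.
#' @export
partitionByTime <- function(deMorning, deEvening) {
    sm <- .statusOf(deMorning); se <- .statusOf(deEvening)
    if (!setequal(names(sm), names(se)))
        stop("gene universes differ between the two DE tables")
    degM <- names(sm)[sm %in% c("up", "down")]
    degE <- names(se)[se %in% c("up", "down")]
    split3 <- function(a, b)
        list(morning_only = setdiff(a, b), evening_only = setdiff(b, a),
             both = intersect(a, b))
    out <- split3(degM, degE)
    out$up <- split3(names(sm)[sm == "up"], names(se)[se == "up"])
    out$down <- split3(names(sm)[sm == "down"], names(se)[se == "down"])
    out
}

#' Direction-reversal gene groups
#'
#' Genes called in opposite directions at the two time points: upregulated
#' in the morning and downregulated in the evening, or vice versa. The two
#' groups are disjoint by construction.
#'
#' @inheritParams partitionByTime
#' @return list of character vectors \code{up_m_down_e} and
#'   \code{down_m_up_e}.
#' @export
reversalGroups <- function(deMorning, deEvening) {
    sm <- .statusOf(deMorning); se <- .statusOf(deEvening)
    if (!setequal(names(sm), names(se)))
        stop("gene universes differ between the two DE tables")
    se <- se[names(sm)]
    list(up_m_down_e = names(sm)[sm == "up" & se == "down"],
         down_m_up_e = names(sm)[sm == "down" & se == "up"])
}

#' Percentage report over named gene-set sizes
#'
#' Derives the headline percentages of the stage/time analysis from the
#' named set sizes. Percentages are rounded half-up to integers, except the
#' bud morning/evening DEG percentage which is reported to one decimal.
#' Two unrounded ratios are also emitted, quantifying how much larger the
#' diurnal transcriptomic response is in open flowers than in buds (count
#' ratio and percentage-point ratio).
#'
#' @param sizes named numeric vector with elements
#'   \code{expressed_1DPA}, \code{expressed_bud}, \code{expressed_shared},
#'   \code{dev_deg} (developmental DEGs), \code{me_deg_1DPA},
#'   \code{me_deg_bud}, \code{me_deg_shared} (m/e DEGs at both stages) and
#'   \code{me_deg_1DPA_expressed_both} (1DPA m/e DEGs expressed in both
#'   stages).
#' @param sets optional named list of the underlying gene-id vectors.
#' @return a [SetReport-class].
#' @examples
#' setPercentages(summaryPercentages(petuniaSetSizes()))
#' @export
summaryPercentages <- function(sizes, sets = list()) {
    need <- c("expressed_1DPA", "expressed_bud", "expressed_shared",
              "dev_deg", "me_deg_1DPA", "me_deg_bud", "me_deg_shared",
              "me_deg_1DPA_expressed_both")
    miss <- setdiff(need, names(sizes))
    if (length(miss))
        stop("missing set sizes: ", paste(miss, collapse = ", "))
    if (any(sizes[need] < 0)) stop("set sizes must be non-negative")
    s <- as.list(sizes[need])
    union <- s$expressed_1DPA + s$expressed_bud - s$expressed_shared
    meUnion <- s$me_deg_1DPA + s$me_deg_bud - s$me_deg_shared
    dens <- c(union, s$expressed_1DPA, s$expressed_bud,
              s$me_deg_1DPA, s$me_deg_bud)
    if (any(dens == 0)) stop("undefined percentage: zero denominator")
    pct <- c(
        pct_total_dev_DEG  = roundHalfUp(100 * s$dev_deg / union),
        pct_me_1DPA        = roundHalfUp(100 * s$me_deg_1DPA / s$expressed_1DPA),
        pct_me_bud         = roundHalfUp(100 * s$me_deg_bud / s$expressed_bud, 1),
        pct_shared_of_1DPA = roundHalfUp(100 * s$me_deg_shared / s$me_deg_1DPA),
        pct_shared_of_bud  = roundHalfUp(100 * s$me_deg_shared / s$me_deg_bud),
        pct_both_stage_expr = roundHalfUp(
            100 * s$me_deg_1DPA_expressed_both / s$me_deg_1DPA),
        pct_me_union       = roundHalfUp(100 * meUnion / union))
    counts <- c(unlist(s), expressed_union = union, me_deg_union = meUnion,
                stage_specific_1DPA = s$expressed_1DPA - s$expressed_shared,
                stage_specific_bud = s$expressed_bud - s$expressed_shared)
    ratios <- c(
        me_response_count_ratio = s$me_deg_1DPA / s$me_deg_bud,
        me_response_pct_ratio = (100 * s$me_deg_1DPA / s$expressed_1DPA) /
            (100 * s$me_deg_bud / s$expressed_bud))
    methods::new("SetReport", counts = counts, percentages = pct,
                 ratios = ratios, sets = sets)
}

#' Published petal gene-set sizes
#'
#' The printed set sizes of the petunia petal study this pipeline models:
#' genes expressed per stage (normalized count >= 30), their overlap,
#' developmental DEGs, and morning/evening DEG sets per stage with their
#' overlap. Feeding them to [summaryPercentages()] reproduces the study's
#' headline percentages (42 percent of 1DPA-expressed genes are
#' morning/evening DEGs, 17.2 percent in buds, and so on).
#'
#' @return named numeric vector suitable for [summaryPercentages()].
#' @export
petuniaSetSizes <- function() {
    c(expressed_1DPA = 15174, expressed_bud = 15436,
      expressed_shared = 14102, dev_deg = 11503,
      me_deg_1DPA = 6386, me_deg_bud = 2656, me_deg_shared = 1729,
      me_deg_1DPA_expressed_both = 5875)
}

#' Build the full stage/time report from data
#'
#' Runs the set arithmetic on actual pipeline outputs: expressed sets from
#' normalized counts, morning/evening DEG sets per stage from the two m/e
#' contrasts, and a developmental DEG universe from the two
#' stage contrasts.
#'
#' @param normalized normalized count matrix.
#' @param sampleData sample sheet (rownames = sample ids).
#' @param deMeBud,deMe1DPA [DEResult-class] of evening-vs-morning within
#'   each stage.
#' @param deDevMorning,deDevEvening [DEResult-class] of 1DPA-vs-bud at each
#'   time point.
#' @param threshold expressed-gene threshold.
#' @return a [SetReport-class] whose \code{sets} slot holds the underlying
#'   gene sets.
#' @export
stageTimeReport <- function(normalized, sampleData, deMeBud, deMe1DPA,
                            deDevMorning, deDevEvening, threshold = 30) {
    expr1 <- expressedSet(normalized, sampleData, "flower_1DPA",
                          threshold = threshold)
    exprB <- expressedSet(normalized, sampleData, "bud", threshold = threshold)
    meB <- degSet(deMeBud); me1 <- degSet(deMe1DPA)
    dev <- union(degSet(deDevMorning), degSet(deDevEvening))
    sets <- list(expressed_1DPA = expr1, expressed_bud = exprB,
                 expressed_shared = intersect(expr1, exprB),
                 dev_deg = dev, me_deg_1DPA = me1, me_deg_bud = meB,
                 me_deg_shared = intersect(me1, meB),
                 me_deg_1DPA_expressed_both =
                     intersect(me1, intersect(expr1, exprB)))
    summaryPercentages(vapply(sets, length, numeric(1)), sets = sets)
}

#' @describeIn SetReport-class named set sizes.
#' @export
setMethod("setCounts", "SetReport", function(object, ...) object@counts)

#' @describeIn SetReport-class named, rounded percentages.
#' @export
setMethod("setPercentages", "SetReport", function(object, ...)
    object@percentages)

setMethod("show", "SetReport", function(object) {
    cat("SetReport\n  counts:\n")
    for (nm in names(object@counts))
        cat(sprintf("    %-28s %d\n", nm, as.integer(object@counts[[nm]])))
    cat("  percentages:\n")
    for (nm in names(object@percentages))
        cat(sprintf("    %-28s %g\n", nm, object@percentages[[nm]]))
    cat("  ratios:\n")
    for (nm in names(object@ratios))
        cat(sprintf("    %-28s %.3f\n", nm, object@ratios[[nm]]))
    invisible(NULL)
})
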