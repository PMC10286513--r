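#' DEG thresholds
#'
#' The working thresholds of the analysis: a DEG must reach adjusted (or
#' raw) p <= 0.05, |log2FC| >= 0.585 (i.e. a 1.5-fold change, since
#' log2(1.5) = 0.585 to three decimals) and a group mean normalized count
#' >= 30; the candidate screen additionally requires >= 100 normalized
#' counts at 1DPA; conservation profiling zeroes scores with E-value >
#' 1e-5 or below 10 percent.
#'
#' @param p_max maximum p-value (inclusive).
#' @param lfc_min minimum |log2 fold change| (inclusive).
#' @param count_min minimum group mean normalized count (inclusive).
#' @param screen_count_min expression floor for the candidate screen.
#' @param me_fold morning/evening fold used by the timing grouping.
#' @param evalue_max E-value cutoff for conservation profiling.
#' @param cons_min minimum conservation score (percent).
#' @return a validated list of class \code{"Thresholds"}.
#' @examples
#' degThresholds()$lfc_min   # 0.585
#' @export
degThresholds <- function(p_max = 0.05, lfc_min = 0.585, count_min = 30,
                          screen_count_min = 100, me_fold = 1.5,
                          evalue_max = 1e-5, cons_min = 10) {
    vals <- c(p_max, lfc_min, count_min, screen_count_min, me_fold,
              evalue_max, cons_min)
    if (any(vals <= 0)) stop("all thresholds must be positive")
    if (abs(lfc_min - log2(me_fold)) > 5e-4)
        stop("lfc_min must equal log2(me_fold) to within 5e-4")
    structure(list(p_max = p_max, lfc_min = lfc_min, count_min = count_min,
                   screen_count_min = screen_count_min, me_fold = me_fold,
                   evalue_max = evalue_max, cons_min = cons_min),
              class = "Thresholds")
}

#' Median-of-ratios size factors
#'
#' For each sample j, \code{s_j = median_g count_gj / geomean_g}, the median
#' taken over genes with strictly positive counts in every sample (the only
#' genes whose geometric mean is positive).
#'
#' @param counts integer count matrix (genes x samples) or a
#'   [CountExperiment-class].
#' @return named positive numeric vector of per-sample size factors.
#' @examples
#' m <- cbind(a = c(10, 0), b = c(20, 5))
#' estimateSizeFactorsMoR(m)   # 1/sqrt(2), sqrt(2): gene 2 is excluded
#' @export
estimateSizeFactorsMoR <- function(counts) {
    if (methods::is(counts, "CountExperiment")) counts <- countsMatrix(counts)
    counts <- as.matrix(counts)
    logGeo <- rowMeans(log(counts))
    ok <- is.finite(logGeo)
    if (!any(ok))
        stop("no reference gene: no gene has strictly positive counts in all samples")
    sf <- apply(counts[ok, , drop = FALSE], 2, function(cj)
        stats::median(cj / exp(logGeo[ok])))
    sf
}

#' Normalize counts by size factors
#'
#' @param counts count matrix (genes x samples) or [CountExperiment-class].
#' @param sizeFactors per-sample positive size factors (defaults to
#'   [estimateSizeFactorsMoR()] of the input).
#' @return matrix of normalized counts \code{count_gj / s_j}.
#' @export
normalizeCounts <- function(counts, sizeFactors = estimateSizeFactorsMoR(counts)) {
    if (methods::is(counts, "CountExperiment")) counts <- countsMatrix(counts)
    counts <- as.matrix(counts)
    if (length(sizeFactors) != ncol(counts))
        stop("size factor / sample dimension mismatch")
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    sweep(counts, 2, sizeFactors, "/")
}

#' Gene-wise method-of-moments NB dispersion
#'
#' Estimates the per-gene dispersion alpha of the NB model
#' variance = mu + alpha mu^2 from normalized counts:
#' \code{alpha_g = max(floor, (pooledVar_g - mean_g) / mean_g^2)}, the
#' within-group variance pooled across all levels of \code{groups} (the
#' full stage x time design when available, which maximizes the residual
#' degrees of freedom). The returned vector carries the residual df
#' (samples - groups) as attribute \code{"df"}; downstream Wald p-values
#' use it as the reference-distribution df.
#'
#' @param normalized normalized count matrix (genes x samples).
#' @param groups factor (or coercible) of length \code{ncol(normalized)}
#'   giving each sample's experimental condition; every level needs >= 2
#'   samples.
#' @param floor lower bound for alpha.
#' @return named numeric vector of dispersions with attribute \code{df}.
#' @examples
#' # within-group variance 600 at mean 100 -> alpha = 0.05
#' @export
estimateDispersionsMoM <- function(normalized, groups, floor = 1e-8) {
    normalized <- as.matrix(normalized)
    groups <- as.factor(groups)
    if (length(groups) != ncol(normalized))
        stop("'groups' must label every sample")
    sizes <- table(groups)
    if (any(sizes < 2))
        stop("insufficient replicates: every group needs >= 2 samples")
    num <- 0
    for (lv in levels(groups)) {
        sub <- normalized[, groups == lv, drop = FALSE]
        v <- apply(sub, 1, stats::var)
        num <- num + (ncol(sub) - 1) * v
    }
    df <- ncol(normalized) - nlevels(groups)
    pooledVar <- num / df
    m <- rowMeans(normalized)
    alpha <- ifelse(m > 0, pmax(floor, (pooledVar - m) / m^2), floor)
    names(alpha) <- rownames(normalized)
    attr(alpha, "df") <- df
    alpha
}

#' Two-group negative-binomial Wald contrast
#'
#' Computes, per gene, the unshrunk log2 fold change of group B over group
#' A on pseudocounted group means of normalized counts, a delta-method
#' standard error under the NB model \code{Var(K_j) = mu_j + alpha mu_j^2},
#' and a two-sided p-value for the Wald statistic. The reference
#' distribution is Student t with the dispersion-estimation residual df
#' (normal when \code{df = Inf}), which keeps the test calibrated at small
#' replicate numbers where a plug-in dispersion makes the normal reference
#' anticonservative.
#'
#' @param counts raw count matrix or [CountExperiment-class].
#' @param sizeFactors per-sample size factors (named like the columns).
#' @param dispersions per-gene alpha from [estimateDispersionsMoM()]; its
#'   \code{"df"} attribute supplies the default \code{df}.
#' @param samplesA,samplesB disjoint non-empty character vectors of sample
#'   ids (A is the reference/denominator group).
#' @param pseudocount added to each group mean of normalized counts before
#'   the log2 ratio, so fold changes stay finite for all-zero groups. At
#'   pseudocount 0 the log2FC is exactly invariant to rescaling any single
#'   library; a nonzero pseudocount perturbs that invariance at the
#'   pc/mean level because median-of-ratios normalization rescales all
#'   normalized counts when one library is rescaled.
#' @param df reference-distribution degrees of freedom.
#' @param contrast label stored on the result.
#' @return a [DEResult-class] (no status column yet; see [callDEGs()]).
#' @export
waldContrast <- function(counts, sizeFactors, dispersions,
                         samplesA, samplesB, pseudocount = 0.5,
                         df = NULL, contrast = "B_vs_A") {
    if (methods::is(counts, "CountExperiment")) counts <- countsMatrix(counts)
    counts <- as.matrix(counts)
    if (length(samplesA) == 0 || length(samplesB) == 0)
        stop("contrast groups must be non-empty")
    if (length(intersect(samplesA, samplesB)))
        stop("contrast groups must be disjoint")
    if (!all(c(samplesA, samplesB) %in% colnames(counts)))
        stop("unknown sample ids in contrast groups")
    if (is.null(df)) df <- attr(dispersions, "df")
    if (is.null(df)) df <- Inf
    alpha <- as.numeric(dispersions)

    sfA <- sizeFactors[samplesA]; sfB <- sizeFactors[samplesB]
    nA <- length(samplesA); nB <- length(samplesB)
    mA <- rowMeans(sweep(counts[, samplesA, drop = FALSE], 2, sfA, "/"))
    mB <- rowMeans(sweep(counts[, samplesB, drop = FALSE], 2, sfB, "/"))

    # Var(mean_norm) = (1/n^2) sum_j (m/s_j + alpha m^2)
    vA <- (mA * sum(1 / sfA) + nA * alpha * mA^2) / nA^2
    vB <- (mB * sum(1 / sfB) + nB * alpha * mB^2) / nB^2

    mApc <- mA + pseudocount
    mBpc <- mB + pseudocount
    l2 <- log2(mBpc / mApc)
    se <- sqrt(vA / mApc^2 + vB / mBpc^2) / log(2)
    stat <- ifelse(se > 0, l2 / se, 0)
    p <- 2 * stats::pt(-abs(stat), df = df)

    res <- S4Vectors::DataFrame(
        gene = rownames(counts), baseMeanA = mA, baseMeanB = mB,
        log2FC = l2, SE = se, stat = stat, pvalue = p,
        dispersion = alpha)
    rownames(res) <- rownames(counts)
    methods::new("DEResult", results = res, contrast = contrast,
                 thresholds = list(), useAdjusted = TRUE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (capped at 1, monotone in raw-p rank order);
#' a domain-checking front end to \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))   # all 0.03
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call DEG status
#'
#' Applies the DEG rule to a Wald contrast: a gene is \code{"up"} when
#' p <= p_max, log2FC >= lfc_min and the larger of the two group mean
#' normalized counts >= count_min; \code{"down"} symmetrically;
#' \code{"low_count"} whenever the count rule fails (regardless of p);
#' otherwise \code{"ns"}. All comparisons are boundary-inclusive. By
#' default the BH-adjusted p is the working p-value; set
#' \code{useAdjusted = FALSE} for the literal raw-p reading.
#'
#' @param de a [DEResult-class] from [waldContrast()].
#' @param thresholds a [degThresholds()] list.
#' @param useAdjusted logical; test the BH-adjusted p (default) or raw p.
#' @return the [DEResult-class] with added \code{padj} and \code{status}
#'   columns.
#' @export
callDEGs <- function(de, thresholds = degThresholds(), useAdjusted = TRUE) {
    stopifnot(methods::is(de, "DEResult"), inherits(thresholds, "Thresholds"))
    res <- de@results
    res$padj <- bhAdjust(res$pvalue)
    pEff <- if (useAdjusted) res$padj else res$pvalue
    hasCount <- pmax(res$baseMeanA, res$baseMeanB) >= thresholds$count_min
    sig <- !is.na(pEff) & pEff <= thresholds$p_max
    status <- rep("ns", nrow(res))
    status[!hasCount] <- "low_count"
    status[hasCount & sig & res$log2FC >= thresholds$lfc_min] <- "up"
    status[hasCount & sig & res$log2FC <= -thresholds$lfc_min] <- "down"
    res$status <- status
    methods::initialize(de, results = res,
                        thresholds = unclass(thresholds),
                        useAdjusted = useAdjusted)
}

#' Run a full two-group contrast on a CountExperiment
#'
#' Convenience pipeline: median-of-ratios size factors over all samples,
#' gene-wise method-of-moments dispersions pooled across the stage x time
#' conditions, Wald contrast between two levels of \code{variable}
#' (optionally holding the other factor fixed via \code{at}), BH
#' adjustment and DEG status.
#'
#' @param ce a [CountExperiment-class].
#' @param variable \code{"stage"} or \code{"time"}.
#' @param numerator,denominator the level whose expression is in the
#'   numerator (B) and denominator (A) of the fold change.
#' @param at optional named value fixing the other factor, e.g.
#'   \code{c(time = "morning")}.
#' @param thresholds a [degThresholds()] list.
#' @param useAdjusted logical; DEG rule on adjusted (default) or raw p.
#' @param pseudocount see [waldContrast()].
#' @return a [DEResult-class] with status calls.
#' @examples
#' sim <- simulateCounts(experimentDesign(n_genes = 300), effectConfig(seed = 2))
#' de <- runDE(sim$ce, "stage", "flower_1DPA", "bud", at = c(time = "morning"))
#' table(degStatus(de))
#' @export
runDE <- function(ce, variable = c("stage", "time"), numerator, denominator,
                  at = NULL, thresholds = degThresholds(),
                  useAdjusted = TRUE, pseudocount = 0.5) {
    stopifnot(methods::is(ce, "CountExperiment"))
    variable <- match.arg(variable)
    cd <- SummarizedExperiment::colData(ce)
    for (lev in c(numerator, denominator))
        if (!lev %in% cd[[variable]])
            stop("unknown ", variable, " label: ", lev)
    sel <- function(level) {
        keep <- cd[[variable]] == level
        if (!is.null(at)) {
            other <- names(at)
            if (!other %in% colnames(cd)) stop("unknown factor in 'at'")
            keep <- keep & cd[[other]] == at[[1]]
        }
        rownames(cd)[keep]
    }
    sf <- estimateSizeFactorsMoR(ce)
    norm <- normalizeCounts(ce, sf)
    disp <- estimateDispersionsMoM(norm, conditionFactor(ce))
    lbl <- sprintf("%s:%s-vs-%s%s", variable, numerator, denominator,
                   if (is.null(at)) "" else
                       sprintf(" at %s:%s", names(at), at[[1]]))
    de <- waldContrast(ce, sf, disp, sel(denominator), sel(numerator),
                       pseudocount = pseudocount, contrast = lbl)
    callDEGs(de, thresholds, useAdjusted)
}

#' @describeIn DEResult-class the per-gene results as a \code{DFrame}.
#' @export
setMethod("deTable", "DEResult", function(object, ...) object@results)

#' @describeIn DEResult-class named status vector (requires [callDEGs()]).
#' @export
setMethod("degStatus", "DEResult", function(object, ...) {
    if (!"status" %in% colnames(object@results))
        stop("no status column; run callDEGs() first")
    stats::setNames(object@results$status, object@results$gene)
})

#' @describeIn DEResult-class gene ids with the given status
#'   (\code{direction} one of "any" = up or down, "up", "down").
#' @param direction which DEGs to return.
#' @export
setMethod("degSet", "DEResult", function(object, direction = c("any", "up",
                                                               "down"), ...) {
    direction <- match.arg(direction)
    st <- degStatus(object)
    keep <- if (direction == "any") st %in% c("up", "down") else st == direction
    names(st)[keep]
})

setMethod("show", "DEResult", function(object) {
    cat("DEResult:", nrow(object@results), "genes, contrast",
        object@contrast, "\n")
    if ("status" %in% colnames(object@results)) {
        tab <- table(object@results$status)
        cat("  status:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                               collapse = ", "), "\n")
        cat("  p-values:", if (object@useAdjusted) "BH-adjusted" else "raw",
            "\n")
    }
    invisible(NULL)
})
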