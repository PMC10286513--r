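#' Experiment design for the synthetic petal RNA-seq generator
#'
#' The study design is factorial: two developmental stages (4.5-cm bud and
#' flower one day post-anthesis) by two times of day (morning 1000 h,
#' evening 1900 h), with three biological replicates per condition.
#'
#' @param stages character vector of stage labels.
#' @param times character vector of time labels.
#' @param replicates positive integer, replicates per stage x time condition.
#' @param n_genes positive integer, number of genes to simulate.
#' @return a validated list of class \code{"ExperimentDesign"}.
#' @examples
#' experimentDesign(n_genes = 500)
#' @export
experimentDesign <- function(stages = c("bud", "flower_1DPA"),
                             times = c("morning", "evening"),
                             replicates = 3L, n_genes = 2000L) {
    if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
        stop("invalid design: n_genes must be a positive integer")
    if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
        stop("invalid design: replicates must be a positive integer")
    if (anyDuplicated(stages) || anyDuplicated(times))
        stop("invalid design: stage/time labels must be unique")
    structure(list(stages = stages, times = times,
                   replicates = as.integer(replicates),
                   n_genes = as.integer(n_genes)),
              class = "ExperimentDesign")
}

#' Effect configuration for the synthetic count generator
#'
#' Controls which fractions of genes receive planted developmental and
#' diurnal effects and the distributions the generator draws from. The
#' defaults emulate the structure observed in petunia petals: a large
#' developmental response split across time-of-day categories (roughly 20
#' percent morning-only, 30 percent evening-only, 50 percent both), and a
#' diurnal response that is substantially larger in open flowers than in
#' buds.
#'
#' @param frac_stage_de fraction of genes with a developmental
#'   (stage) effect.
#' @param frac_time_de_bud fraction with a morning/evening effect in buds.
#' @param frac_time_de_flower fraction with a morning/evening effect in
#'   1DPA flowers.
#' @param stage_timing_split length-3 fractions (morning_only,
#'   evening_only, both) partitioning the stage-DE genes by the time points
#'   at which the developmental effect is present; must sum to 1.
#' @param lfc_distribution c(mean, sd) of planted |log2 fold changes|;
#'   signs are drawn at random.
#' @param baseline_log_mean_sd c(meanlog, sdlog) of per-gene log-normal
#'   baseline expression (bud morning condition).
#' @param dispersion_log_mean_sd c(meanlog, sdlog) of per-gene log-normal
#'   NB dispersion alpha (variance = mu + alpha mu^2).
#' @param size_factor_range c(lo, hi) of uniform per-sample size factors;
#'   the first sample is pinned to 1 to fix the scale.
#' @param frac_wd40 fraction of genes annotated as WD40 proteins.
#' @param plant_candidates logical; plant three WD40 screen candidates
#'   (developmentally upregulated, high expression) with morning/evening
#'   fold changes given by \code{candidate_folds}.
#' @param candidate_folds named evening/morning expression ratios at 1DPA
#'   for the three planted candidates (evening-peaking, morning-peaking,
#'   unchanged).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class \code{"EffectConfig"}.
#' @export
effectConfig <- function(frac_stage_de = 0.4,
                         frac_time_de_bud = 0.1,
                         frac_time_de_flower = 0.25,
                         stage_timing_split = c(morning_only = 0.2,
                                                evening_only = 0.3,
                                                both = 0.5),
                         lfc_distribution = c(mean = 1.5, sd = 0.5),
                         baseline_log_mean_sd = c(mean = 4.5, sd = 1.5),
                         dispersion_log_mean_sd = c(mean = log(0.05), sd = 0.8),
                         size_factor_range = c(0.7, 1.3),
                         frac_wd40 = 0.02,
                         plant_candidates = TRUE,
                         candidate_folds = c(evening = 2, morning = 0.5,
                                             none = 1),
                         seed = 1L) {
    .assertFraction(frac_stage_de, "frac_stage_de")
    .assertFraction(frac_time_de_bud, "frac_time_de_bud")
    .assertFraction(frac_time_de_flower, "frac_time_de_flower")
    .assertFraction(stage_timing_split, "stage_timing_split")
    .assertFraction(frac_wd40, "frac_wd40")
    if (abs(sum(stage_timing_split) - 1) > 1e-8)
        stop("'stage_timing_split' must sum to 1")
    if (lfc_distribution[2] < 0 || baseline_log_mean_sd[2] < 0 ||
        dispersion_log_mean_sd[2] < 0)
        stop("sd values must be >= 0")
    if (size_factor_range[1] > size_factor_range[2] ||
        size_factor_range[1] <= 0)
        stop("invalid size_factor_range")
    structure(list(frac_stage_de = frac_stage_de,
                   frac_time_de_bud = frac_time_de_bud,
                   frac_time_de_flower = frac_time_de_flower,
                   stage_timing_split = stage_timing_split,
                   lfc_distribution = lfc_distribution,
                   baseline_log_mean_sd = baseline_log_mean_sd,
                   dispersion_log_mean_sd = dispersion_log_mean_sd,
                   size_factor_range = size_factor_range,
                   frac_wd40 = frac_wd40,
                   plant_candidates = isTRUE(plant_candidates),
                   candidate_folds = candidate_folds,
                   seed = as.integer(seed)),
              class = "EffectConfig")
}

# deterministic allocation: first ceiling(frac * n) indices of a seeded
# shuffle, so truth-table counts are exact rather than Bernoulli-random
.takeFirst <- function(shuffled, frac) {
    k <- ceiling(frac * length(shuffled))
    if (k == 0) integer(0) else shuffled[seq_len(k)]
}

#' Simulate a petal RNA-seq count experiment with known truth
#'
#' Draws gene x sample counts from a negative-binomial model
#' (variance = mu + alpha mu^2) over the factorial stage x time design,
#' with planted developmental and diurnal log2 fold changes recorded
#' exactly in a truth table. Per-gene cell means are
#' \code{baseline * 2^(planted effects)} and per-sample means are scaled by
#' library size factors. DE genes are assigned by deterministic count after
#' a seeded shuffle, so the truth table sizes are exact.
#'
#' @param design an [experimentDesign()].
#' @param cfg an [effectConfig()]; \code{cfg$seed} drives all randomness.
#' @return a list with elements:
#' \describe{
#'   \item{ce}{a [CountExperiment-class]; \code{rowData} carries the
#'     \code{wd40} flag and a description.}
#'   \item{truth}{\code{DFrame}, one row per gene: baseline mean,
#'     dispersion, realized log2FCs (stage effect at each time, time effect
#'     within each stage), WD40 flag and planted-candidate label.}
#'   \item{cellMeans}{matrix of true per-condition means (before size
#'     factors).}
#'   \item{sizeFactors}{the true per-sample size factors.}
#' }
#' @examples
#' sim <- simulateCounts(experimentDesign(n_genes = 200), effectConfig(seed = 7))
#' sim$ce
#' @export
simulateCounts <- function(design = experimentDesign(), cfg = effectConfig()) {
    stopifnot(inherits(design, "ExperimentDesign"),
              inherits(cfg, "EffectConfig"))
    if (!setequal(design$stages, c("bud", "flower_1DPA")) ||
        !setequal(design$times, c("morning", "evening")))
        stop("invalid design: stages must be {bud, flower_1DPA} and times ",
             "{morning, evening}")
    withSeed(cfg$seed, {
        n <- design$n_genes
        genes <- sprintf("gene_%05d", seq_len(n))

        base <- stats::rlnorm(n, cfg$baseline_log_mean_sd[1],
                              cfg$baseline_log_mean_sd[2])
        alpha <- stats::rlnorm(n, cfg$dispersion_log_mean_sd[1],
                               cfg$dispersion_log_mean_sd[2])

        drawLfc <- function(k) {
            if (k == 0) return(numeric(0))
            mag <- abs(stats::rnorm(k, cfg$lfc_distribution[1],
                                    cfg$lfc_distribution[2]))
            mag * sample(c(-1, 1), k, replace = TRUE)
        }

        sh1 <- sample.int(n)
        stageIdx <- .takeFirst(sh1, cfg$frac_stage_de)
        # partition stage-DE genes into timing classes by deterministic count
        k <- length(stageIdx)
        cuts <- diff(c(0, floor(cumsum(cfg$stage_timing_split) * k)))
        timing <- rep(c("morning_only", "evening_only", "both"), cuts)
        timeBudIdx <- .takeFirst(sample.int(n), cfg$frac_time_de_bud)
        timeFloIdx <- .takeFirst(sample.int(n), cfg$frac_time_de_flower)

        A <- numeric(n)                      # stage effect magnitude
        A[stageIdx] <- drawLfc(k)
        Am <- Ae <- numeric(n)               # stage effect applied per time
        Am[stageIdx] <- A[stageIdx] *
            as.numeric(timing %in% c("morning_only", "both"))
        Ae[stageIdx] <- A[stageIdx] *
            as.numeric(timing %in% c("evening_only", "both"))
        Bb <- Bf <- numeric(n)               # evening-vs-morning per stage
        Bb[timeBudIdx] <- drawLfc(length(timeBudIdx))
        Bf[timeFloIdx] <- drawLfc(length(timeFloIdx))

        wd40 <- rep(FALSE, n)
        wd40[.takeFirst(sample.int(n), cfg$frac_wd40)] <- TRUE
        candidate <- rep(NA_character_, n)

        if (cfg$plant_candidates && n >= 3) {
            # clean spike-ins: high expression, typical low dispersion, so
            # their recovery measures the screen logic, not sampling noise
            cand <- rev(sh1)[1:3]            # least likely to carry effects
            Am[cand] <- Ae[cand] <- 2        # clearly dev-upregulated
            Bb[cand] <- 0
            Bf[cand] <- log2(cfg$candidate_folds)
            base[cand] <- pmax(base[cand], 600)  # well above the screen floor
            alpha[cand] <- 0.02
            wd40[cand] <- TRUE
            candidate[cand] <- names(cfg$candidate_folds)
        }

        # cell means: bud_morning is the baseline cell
        cm <- cbind("bud:morning"          = base,
                    "bud:evening"          = base * 2^Bb,
                    "flower_1DPA:morning"  = base * 2^Am,
                    "flower_1DPA:evening"  = base * 2^(Ae + Bf))
        # realized truth log2FCs, exact from the cell means
        lfcStageM <- log2(cm[, 3] / cm[, 1])
        lfcStageE <- log2(cm[, 4] / cm[, 2])
        lfcTimeB <- log2(cm[, 2] / cm[, 1])
        lfcTimeF <- log2(cm[, 4] / cm[, 3])

        conds <- as.vector(outer(design$stages, design$times, paste, sep = ":"))
        sampleData <- data.frame(
            stage = rep(rep(design$stages, each = length(design$times)),
                        each = design$replicates),
            time = rep(rep(design$times, times = length(design$stages)),
                       each = design$replicates),
            replicate = rep(seq_len(design$replicates),
                            times = length(conds)))
        sampleIds <- paste(sampleData$stage, sampleData$time,
                           sampleData$replicate, sep = "_")
        rownames(sampleData) <- sampleIds

        nS <- nrow(sampleData)
        sf <- stats::runif(nS, cfg$size_factor_range[1],
                           cfg$size_factor_range[2])
        sf[1] <- 1
        names(sf) <- sampleIds

        condOfSample <- paste(sampleData$stage, sampleData$time, sep = ":")
        mu <- cm[, condOfSample, drop = FALSE]
        mu <- sweep(mu, 2, sf, "*")
        counts <- matrix(stats::rnbinom(n * nS, mu = mu,
                                        size = rep(1 / alpha, nS)),
                         nrow = n, dimnames = list(genes, sampleIds))

        rowAnn <- S4Vectors::DataFrame(
            wd40 = wd40,
            description = ifelse(wd40, "WD40 repeat protein",
                                 "hypothetical protein"))
        ce <- CountExperiment(counts, sampleData, rowData = rowAnn)

        truth <- S4Vectors::DataFrame(
            gene = genes, base_mean = base, dispersion = alpha,
            lfc_stage_morning = lfcStageM, lfc_stage_evening = lfcStageE,
            lfc_time_bud = lfcTimeB, lfc_time_flower = lfcTimeF,
            wd40 = wd40, candidate = candidate)
        rownames(truth) <- genes

        list(ce = ce, truth = truth, cellMeans = cm, sizeFactors = sf)
    })
}
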