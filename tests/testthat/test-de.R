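test_that("median-of-ratios size factors match hand-computed values", {
    m <- matrix(c(5, 8, 11, 5, 8, 11), nrow = 3,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    expect_equal(unname(estimateSizeFactorsMoR(m)), c(1, 1))

    # sample B = 2 x sample A gene-wise: factors 1/sqrt(2), sqrt(2)
    m2 <- cbind(A = c(10, 50, 200), B = c(20, 100, 400))
    expect_equal(unname(estimateSizeFactorsMoR(m2)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

    # gene with a zero is excluded from the reference set
    m3 <- rbind(c(10, 20), c(0, 5))
    expect_equal(unname(estimateSizeFactorsMoR(m3)),
                 c(10 / sqrt(200), 20 / sqrt(200)), tolerance = 1e-12)

    expect_error(estimateSizeFactorsMoR(rbind(c(0, 5), c(3, 0))),
                 "no reference gene")
})

test_that("size factors agree with the reference implementation", {
    set.seed(42)
    # odd gene count: the median is a single ratio, so the arithmetic and
    # log-scale median conventions coincide exactly
    m <- matrix(rnbinom(201 * 6, mu = 80, size = 5), nrow = 201,
                dimnames = list(NULL, paste0("s", 1:6)))
    m <- m + 1   # all-positive so both methods use every gene
    expect_equal(unname(estimateSizeFactorsMoR(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
})

test_that("normalization divides by size factors", {
    m <- cbind(a = c(60, 10), b = c(30, 40))
    expect_equal(normalizeCounts(m, c(1, 1)), m)
    norm <- normalizeCounts(m, c(2, 1))
    expect_equal(unname(norm[1, "a"]), 30)  # 60/2 sits on the threshold
    expect_equal(colSums(norm), colSums(m) / c(a = 2, b = 1))
    expect_error(normalizeCounts(m, c(1, 2, 3)), "mismatch")
})

test_that("method-of-moments dispersion recovers planted moments", {
    # two groups of 3 with group means 100 and pooled variance 600
    a <- sqrt(600)
    x <- rbind(g1 = c(100 - a, 100, 100 + a, 100 - a, 100, 100 + a))
    groups <- rep(c("u", "v"), each = 3)
    d <- estimateDispersionsMoM(x, groups)
    expect_equal(unname(d["g1"]), (600 - 100) / 100^2, tolerance = 1e-12)
    expect_equal(attr(d, "df"), 4)

    # Poisson-like (variance = mean) and all-zero genes hit the floor
    b <- sqrt(100)
    y <- rbind(g1 = c(100 - b, 100, 100 + b, 100 - b, 100, 100 + b),
               g2 = rep(0, 6))
    d2 <- estimateDispersionsMoM(y, groups)
    expect_equal(unname(d2), c(1e-8, 1e-8), ignore_attr = TRUE)

    expect_error(estimateDispersionsMoM(x, c("u", "u", "u", "u", "u", "v")),
                 "insufficient replicates")
})

test_that("Wald contrast handles degenerate groups sanely", {
    m <- rbind(equal = rep(100, 6),
               zeroA = c(0, 0, 0, 50, 60, 70),
               allzero = rep(0, 6))
    colnames(m) <- paste0("s", 1:6)
    sf <- setNames(rep(1, 6), colnames(m))
    disp <- setNames(rep(0.05, 3), rownames(m))
    de <- waldContrast(m, sf, disp, paste0("s", 1:3), paste0("s", 4:6))
    tab <- as.data.frame(deTable(de))
    expect_equal(tab["equal", "log2FC"], 0, ignore_attr = TRUE)
    expect_equal(tab["equal", "pvalue"], 1, ignore_attr = TRUE)
    expect_true(is.finite(tab["zeroA", "log2FC"]))
    expect_gt(tab["zeroA", "log2FC"], 0)
    expect_equal(tab["allzero", "log2FC"], 0, ignore_attr = TRUE)
    expect_equal(tab["allzero", "pvalue"], 1, ignore_attr = TRUE)
    expect_error(waldContrast(m, sf, disp, character(0), "s4"), "non-empty")
    expect_error(waldContrast(m, sf, disp, c("s1", "s2"), c("s2", "s3")),
                 "disjoint")
})

test_that("planted log2FC of 2 is recovered nearly unbiasedly", {
    set.seed(77)
    n <- 500
    muA <- 200; muB <- 200 * 2^2; alphaTrue <- 0.05
    cts <- cbind(matrix(rnbinom(n * 3, mu = muA, size = 1 / alphaTrue), n),
                 matrix(rnbinom(n * 3, mu = muB, size = 1 / alphaTrue), n))
    dimnames(cts) <- list(paste0("g", 1:n), paste0("s", 1:6))
    sf <- setNames(rep(1, 6), colnames(cts))
    disp <- estimateDispersionsMoM(cts, rep(c("A", "B"), each = 3))
    de <- waldContrast(cts, sf, disp, paste0("s", 1:3), paste0("s", 4:6))
    expect_lt(abs(mean(deTable(de)$log2FC) - 2), 0.15)
})

test_that("BH adjustment matches hand step-up and is order-invariant", {
    expect_equal(bhAdjust(0.04), 0.04)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(c(0.001, 1.0)), c(0.002, 1.0))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

    set.seed(8)
    p <- runif(50)^2
    perm <- sample.int(50)
    adjPerm <- bhAdjust(p[perm])
    expect_equal(adjPerm[order(perm)], bhAdjust(p))
    # monotone non-decreasing in raw-p rank order
    expect_true(all(diff(bhAdjust(p)[order(p)]) >= -1e-15))
})

test_that("DEG status applies every threshold boundary-inclusively", {
    mk <- function(l2, p, count) {
        res <- S4Vectors::DataFrame(gene = "g", baseMeanA = 10,
                                    baseMeanB = count, log2FC = l2,
                                    SE = 1, stat = 0, pvalue = p)
        methods::new("DEResult", results = res, contrast = "t",
                     thresholds = list(), useAdjusted = TRUE)
    }
    st <- function(l2, p, count)
        unname(degStatus(callDEGs(mk(l2, p, count)))["g"])
    expect_equal(st(0.585, 0.05, 30), "up")       # every boundary inclusive
    expect_equal(st(-0.585, 0.05, 30), "down")
    expect_equal(st(0.58, 0.001, 1000), "ns")     # below the LFC threshold
    expect_equal(st(3, 0.001, 29), "low_count")   # count rule beats p and FC
    expect_equal(st(0.585, 0.051, 30), "ns")
})

test_that("fold changes are exactly invariant to rescaling one library", {
    set.seed(15)
    n <- 300
    cts <- matrix(rnbinom(n * 6, mu = 150, size = 10), n,
                  dimnames = list(paste0("g", 1:n), paste0("s", 1:6)))
    groups <- rep(c("A", "B"), each = 3)
    run <- function(m, pc) {
        sf <- estimateSizeFactorsMoR(m)
        disp <- estimateDispersionsMoM(normalizeCounts(m, sf), groups)
        list(sf = sf, l2 = deTable(waldContrast(m, sf, disp,
             paste0("s", 1:3), paste0("s", 4:6), pseudocount = pc))$log2FC)
    }
    cts2 <- cts; cts2[, "s2"] <- cts2[, "s2"] * 10
    # s2's factor grows 10-fold relative to every other sample ...
    r1 <- run(cts, 0.5); r2 <- run(cts2, 0.5)
    expect_equal(unname(r2$sf["s2"] / r2$sf["s1"]),
                 unname(10 * r1$sf["s2"] / r1$sf["s1"]), tolerance = 1e-12)
    # ... log2FC is exactly invariant at pseudocount 0 ...
    expect_equal(run(cts2, 0)$l2, run(cts, 0)$l2, tolerance = 1e-9)
    # ... and invariant up to the pc/mean perturbation at the default
    expect_equal(r2$l2, r1$l2, tolerance = 0.01)
})

test_that("runDE wires the full pipeline and flags labels it cannot find", {
    sim <- simulateCounts(experimentDesign(n_genes = 300),
                          effectConfig(seed = 6))
    de <- runDE(sim$ce, "stage", "flower_1DPA", "bud",
                at = c(time = "morning"))
    expect_s4_class(de, "DEResult")
    expect_true(all(c("padj", "status") %in% colnames(deTable(de))))
    expect_error(runDE(sim$ce, "stage", "open", "bud"), "unknown stage")
    raw <- runDE(sim$ce, "stage", "flower_1DPA", "bud",
                 at = c(time = "morning"), useAdjusted = FALSE)
    # the raw-p reading can only call more DEGs than the adjusted one
    expect_gte(length(degSet(raw)), length(degSet(de)))
})
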