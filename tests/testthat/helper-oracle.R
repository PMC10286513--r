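# Independent brute-force local-alignment oracle (Gotoh three-state DP,
# affine gaps: a gap of length k costs open + k * extend). Kept deliberately
# naive and separate from the package's alignment path.
swOracle <- function(a, b, mat, gapOpen, gapExtend) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
    Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
    best <- 0
    for (i in 2:(n + 1)) {
        for (j in 2:(m + 1)) {
            X[i, j] <- max(M[i - 1, j] - gapOpen - gapExtend,
                           X[i - 1, j] - gapExtend)
            Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExtend,
                           Y[i, j - 1] - gapExtend)
            s <- mat[a[i - 1], b[j - 1]]
            M[i, j] <- max(0,
                           max(M[i - 1, j - 1], X[i - 1, j - 1],
                               Y[i - 1, j - 1]) + s)
            if (M[i, j] > best) best <- M[i, j]
        }
    }
    best
}

randomProtein <- function(len) {
    paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V"),
                 len, replace = TRUE), collapse = "")
}

# minimal hand-built DEResult with a status column, for set/screen tests
makeDE <- function(gene, status, log2FC = 0, baseMeanA = 100,
                   baseMeanB = 100, pvalue = 1, contrast = "test") {
    k <- length(gene)
    res <- S4Vectors::DataFrame(
        gene = gene,
        baseMeanA = rep_len(baseMeanA, k), baseMeanB = rep_len(baseMeanB, k),
        log2FC = rep_len(log2FC, k), SE = rep_len(1, k),
        stat = rep_len(0, k), pvalue = rep_len(pvalue, k),
        padj = rep_len(pvalue, k), status = status)
    rownames(res) <- gene
    methods::new("DEResult", results = res, contrast = contrast,
                 thresholds = unclass(degThresholds()), useAdjusted = TRUE)
}

# fraction of exact sequence identity between two same-length sequences
seqIdentity <- function(a, b) {
    a <- strsplit(as.character(a), "")[[1]]
    b <- strsplit(as.character(b), "")[[1]]
    mean(a == b)
}
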