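.checkCtTable <- function(ct) {
    ct <- as.data.frame(ct)
    need <- c("condition", "target_ct", "reference_ct")
    miss <- setdiff(need, colnames(ct))
    if (length(miss))
        stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
    if (any(!is.finite(ct$target_ct)))
        stop("non-finite target Ct values")
    if (any(!is.finite(ct$reference_ct)))
        stop("missing reference: every sample needs a finite reference Ct")
    ct
}

#' Per-sample dCt relative expression
#'
#' \code{dCt = Ct_target - Ct_reference}; relative expression =
#' \code{2^-dCt} (one cycle = a factor of two, amplification efficiency
#' fixed at 2).
#'
#' @param ct a Ct table: data.frame with columns \code{condition},
#'   \code{target_ct}, \code{reference_ct} (as produced by
#'   [simulateCtTable()]).
#' @return the table with added \code{dct} and \code{rel_expr} columns.
#' @examples
#' ct <- data.frame(condition = "a", target_ct = 21, reference_ct = 20)
#' deltaCt(ct)$rel_expr   # 0.5
#' @export
deltaCt <- function(ct) {
    ct <- .checkCtTable(ct)
    ct$dct <- ct$target_ct - ct$reference_ct
    ct$rel_expr <- 2^(-ct$dct)
    ct
}

#' 2^-ddCt fold change between two conditions
#'
#' \code{ddCt = mean dCt(treatment) - mean dCt(control)} with replicate
#' dCt values averaged on the cycle scale before exponentiation;
#' fold = \code{2^-ddCt}. Swapping treatment and control inverts the fold
#' exactly.
#'
#' @param ct a Ct table (see [deltaCt()]).
#' @param treatment,control condition labels.
#' @return list: \code{fold}, \code{ddct}, \code{n_treatment},
#'   \code{n_control}.
#' @examples
#' ct <- data.frame(condition = c("t", "c"), target_ct = c(20, 22),
#'                  reference_ct = 15)
#' deltaDeltaCt(ct, "t", "c")$fold   # 4
#' @export
deltaDeltaCt <- function(ct, treatment, control) {
    ct <- deltaCt(ct)
    for (lbl in c(treatment, control))
        if (!lbl %in% ct$condition) stop("unknown condition label: ", lbl)
    dT <- ct$dct[ct$condition == treatment]
    dC <- ct$dct[ct$condition == control]
    ddct <- mean(dT) - mean(dC)
    list(fold = 2^(-ddct), ddct = ddct,
         n_treatment = length(dT), n_control = length(dC))
}

#' Normalize values to their maximum
#'
#' Scales a vector of (relative-expression) values so the maximum is 1,
#' the normalize-to-maximum convention used when plotting expression over
#' conditions.
#'
#' @param values numeric vector with at least one positive entry.
#' @return values divided by their maximum.
#' @examples
#' normalizeToMax(c(2, 4, 8))
#' @export
normalizeToMax <- function(values) {
    mx <- max(values)
    if (!is.finite(mx) || mx <= 0)
        stop("degenerate normalization: no positive value")
    values / mx
}
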