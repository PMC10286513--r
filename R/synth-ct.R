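#' Simulate a qPCR Ct table with planted fold changes
#'
#' Generates target/reference Ct pairs per condition under the inverse of
#' the ddCt model: \code{Ct_target = Ct_ref + dCt_baseline - log2(fold) +
#' noise}, so that the 2^-ddCt analysis recovers the planted folds exactly
#' at zero noise.
#'
#' @param fold_config named numeric vector: true expression fold change per
#'   condition, relative to a fold-1 baseline condition.
#' @param noise_sd standard deviation (cycles) of Gaussian noise added to
#'   the target Ct.
#' @param seed integer seed.
#' @param replicates technical/biological replicates per condition.
#' @param ct_reference reference-gene Ct (cycles), constant across samples.
#' @param dct_baseline baseline dCt (cycles) of the target at fold 1.
#' @return a \code{data.frame} with columns \code{sample},
#'   \code{condition}, \code{replicate}, \code{target_ct},
#'   \code{reference_ct} (a valid Ct table for [deltaCt()] /
#'   [deltaDeltaCt()]).
#' @examples
#' ct <- simulateCtTable(c(control = 1, treated = 4), noise_sd = 0, seed = 1)
#' deltaDeltaCt(ct, "treated", "control")$fold   # exactly 4
#' @export
simulateCtTable <- function(fold_config, noise_sd = 0.1, seed = 1L,
                            replicates = 3L, ct_reference = 20,
                            dct_baseline = 2) {
    if (is.null(names(fold_config)) || any(!nzchar(names(fold_config))))
        stop("invalid config: fold_config must be named by condition")
    if (any(fold_config <= 0)) stop("invalid config: folds must be positive")
    if (!is.numeric(noise_sd) || noise_sd < 0)
        stop("invalid config: noise_sd must be >= 0")
    withSeed(seed, {
        conds <- rep(names(fold_config), each = replicates)
        repl <- rep(seq_len(replicates), times = length(fold_config))
        tct <- ct_reference + dct_baseline -
            log2(fold_config[conds]) +
            stats::rnorm(length(conds), 0, noise_sd)
        data.frame(sample = paste(conds, repl, sep = "_"),
                   condition = conds, replicate = repl,
                   target_ct = as.numeric(tct),
                   reference_ct = ct_reference,
                   row.names = NULL)
    })
}
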