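#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; the percentage report instead
#' rounds halves up, matching how the headline figures were printed.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfUp(0.5)    # 1
#' roundHalfUp(17.25, 1)
#' @export
roundHalfUp <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}

# run expr with a local, restored RNG state seeded from `seed`
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    expr
}

.assertFraction <- function(x, what) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
        stop(sprintf("'%s' must lie in [0, 1]", what))
    invisible(x)
}
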