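AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Configuration for the clade-structured proteome simulator
#'
#' Emulates the structure behind a clade-restriction finding: homologs of a
#' root (query) protein exist only in some clades, diverged from the root by
#' per-site substitution, and every organism additionally carries unrelated
#' decoy proteins of matched length and residue composition. The defaults
#' plant homologs only in the green-plant clade, with unrelated clades
#' carrying decoys alone.
#'
#' @param clades named integer vector: organisms per clade.
#' @param root_length length of the root/query protein (residues).
#' @param divergence named per-clade expected substitutions per site in
#'   [0, 1).
#' @param homolog_presence named per-clade probability that an organism
#'   carries a homolog.
#' @param decoys_per_organism number of unrelated decoy proteins per
#'   organism.
#' @param seed integer seed.
#' @return a validated list of class \code{"CladeSimConfig"}.
#' @export
cladeSimConfig <- function(clades = c(Viridiplantae = 6L, Metazoa = 5L,
                                      Fungi = 4L),
                           root_length = 150L,
                           divergence = c(Viridiplantae = 0.25,
                                          Metazoa = 0.6, Fungi = 0.6),
                           homolog_presence = c(Viridiplantae = 1,
                                                Metazoa = 0, Fungi = 0),
                           decoys_per_organism = 3L,
                           seed = 1L) {
    if (length(clades) == 0)
        stop("invalid config: empty clade list")
    if (is.null(names(clades)) || anyDuplicated(names(clades)))
        stop("invalid config: clades must be uniquely named")
    .assertFraction(homolog_presence, "homolog_presence")
    if (any(divergence < 0) || any(divergence >= 1))
        stop("invalid config: divergence must lie in [0, 1)")
    if (!all(names(clades) %in% names(divergence)) ||
        !all(names(clades) %in% names(homolog_presence)))
        stop("invalid config: divergence and homolog_presence must cover every clade")
    if (root_length < 1 || decoys_per_organism < 0)
        stop("invalid config: root_length >= 1 and decoys_per_organism >= 0 required")
    structure(list(clades = clades, root_length = as.integer(root_length),
                   divergence = divergence,
                   homolog_presence = homolog_presence,
                   decoys_per_organism = as.integer(decoys_per_organism),
                   seed = as.integer(seed)),
              class = "CladeSimConfig")
}

.mutateSeq <- function(chars, p) {
    if (p <= 0) return(chars)
    hit <- stats::runif(length(chars)) < p
    if (any(hit))
        chars[hit] <- vapply(chars[hit], function(a)
            sample(setdiff(AA20, a), 1L), character(1))
    chars
}

#' Simulate a clade-structured proteome collection with known truth
#'
#' Generates one designated query protein (the root sequence) and, per
#' organism, a homolog of the root mutated at the clade's per-site
#' substitution probability (present with the clade's homolog-presence
#' probability) plus decoy proteins drawn from the root's residue
#' composition. Substitution-only divergence; no indels.
#'
#' @param cfg a [cladeSimConfig()]; \code{cfg$seed} drives all randomness.
#' @return a list with elements:
#' \describe{
#'   \item{query}{an [Biostrings::AAStringSet] of length 1 (the root).}
#'   \item{collection}{a [ProteomeCollection-class].}
#'   \item{truth}{\code{DFrame}: organism, clade, homolog_present,
#'     divergence.}
#' }
#' @examples
#' sim <- simulateProteomes(cladeSimConfig(seed = 3))
#' sim$collection
#' @export
simulateProteomes <- function(cfg = cladeSimConfig()) {
    stopifnot(inherits(cfg, "CladeSimConfig"))
    withSeed(cfg$seed, {
        root <- sample(AA20, cfg$root_length, replace = TRUE)
        query <- Biostrings::AAStringSet(paste(root, collapse = ""))
        names(query) <- "query"

        orgIds <- character(0); cladeOfOrg <- character(0)
        present <- logical(0); divg <- numeric(0)
        proteomes <- list()
        for (cl in names(cfg$clades)) {
            for (i in seq_len(cfg$clades[[cl]])) {
                org <- sprintf("%s_org%02d", cl, i)
                seqs <- character(0)
                hasHom <- stats::runif(1) < cfg$homolog_presence[[cl]]
                if (hasHom) {
                    hom <- .mutateSeq(root, cfg$divergence[[cl]])
                    seqs <- c(seqs, stats::setNames(
                        paste(hom, collapse = ""), paste0(org, "_hom")))
                }
                for (d in seq_len(cfg$decoys_per_organism)) {
                    dec <- sample(root, cfg$root_length, replace = TRUE)
                    seqs <- c(seqs, stats::setNames(
                        paste(dec, collapse = ""),
                        sprintf("%s_dec%02d", org, d)))
                }
                aas <- Biostrings::AAStringSet(seqs)
                proteomes[[org]] <- aas
                orgIds <- c(orgIds, org); cladeOfOrg <- c(cladeOfOrg, cl)
                present <- c(present, hasHom)
                divg <- c(divg, cfg$divergence[[cl]])
            }
        }
        cladeMap <- S4Vectors::DataFrame(organism = orgIds,
                                         clade = cladeOfOrg)
        truth <- S4Vectors::DataFrame(organism = orgIds, clade = cladeOfOrg,
                                      homolog_present = present,
                                      divergence = divg)
        coll <- methods::new("ProteomeCollection", proteomes = proteomes,
                             cladeMap = cladeMap)
        list(query = query, collection = coll, truth = truth)
    })
}

#' @describeIn ProteomeCollection organism ids.
#' @export
setMethod("organisms", "ProteomeCollection", function(object, ...)
    names(object@proteomes))

#' @describeIn ProteomeCollection named clade label vector over organisms.
#' @export
setMethod("cladeOf", "ProteomeCollection", function(object, ...)
    stats::setNames(as.character(object@cladeMap$clade),
                    object@cladeMap$organism))

#' @describeIn ProteomeCollection the \code{AAStringSet} of one organism.
#' @param organism organism id.
#' @export
proteomeOf <- function(object, organism) {
    stopifnot(methods::is(object, "ProteomeCollection"))
    if (!organism %in% names(object@proteomes))
        stop("unknown organism: ", organism)
    object@proteomes[[organism]]
}

setMethod("show", "ProteomeCollection", function(object) {
    cl <- cladeOf(object)
    cat("ProteomeCollection:", length(object@proteomes), "organisms,",
        length(unique(cl)), "clades\n")
    tab <- table(cl)
    cat(paste(sprintf("  %s: %d organisms", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
    invisible(NULL)
})
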