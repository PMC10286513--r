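#' Write / read a CountExperiment as TSV files
#'
#' Plain-text interchange: a genes x samples counts TSV (first column
#' \code{gene}), a sample sheet TSV (sample, stage, time, replicate) and,
#' when annotation is present, an annotation TSV (gene, wd40, description).
#'
#' @param ce a [CountExperiment-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCountExperiment <- function(ce, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cts <- data.frame(gene = rownames(ce), countsMatrix(ce),
                      check.names = FALSE)
    cPath <- file.path(dir, "counts.tsv")
    utils::write.table(cts, cPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(ce))
    sPath <- file.path(dir, "samples.tsv")
    utils::write.table(data.frame(sample = rownames(cd), cd),
                       sPath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(counts = cPath, samples = sPath)
    rd <- SummarizedExperiment::rowData(ce)
    if (ncol(rd)) {
        aPath <- file.path(dir, "annotation.tsv")
        utils::write.table(data.frame(gene = rownames(ce),
                                      as.data.frame(rd)),
                           aPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, annotation = aPath)
    }
    invisible(paths)
}

#' @rdname writeCountExperiment
#' @param countsFile,samplesFile,annotationFile TSV paths as written by
#'   \code{writeCountExperiment} (annotation optional).
#' @export
readCountExperiment <- function(countsFile, samplesFile,
                                annotationFile = NULL) {
    cts <- utils::read.delim(countsFile, check.names = FALSE)
    m <- as.matrix(cts[, -1, drop = FALSE])
    rownames(m) <- cts[[1]]
    sd <- utils::read.delim(samplesFile)
    rownames(sd) <- sd$sample
    sd$sample <- NULL
    rd <- NULL
    if (!is.null(annotationFile)) {
        ann <- utils::read.delim(annotationFile)
        rownames(ann) <- ann$gene
        rd <- ann[rownames(m), setdiff(colnames(ann), "gene"), drop = FALSE]
    }
    CountExperiment(m[, rownames(sd), drop = FALSE], sd, rowData = rd)
}

#' Write a DE result table as TSV
#'
#' @param de a [DEResult-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeDEResult <- function(de, file) {
    tab <- as.data.frame(deTable(de))
    tab$contrast <- de@contrast
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Write / read a proteome collection
#'
#' One FASTA per organism (\code{<organism>.fasta}) plus a clade-map TSV
#' (organism, clade).
#'
#' @param collection a [ProteomeCollection-class].
#' @param dir directory.
#' @return invisibly, the directory.
#' @export
writeProteomes <- function(collection, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (org in organisms(collection))
        Biostrings::writeXStringSet(proteomeOf(collection, org),
                                    file.path(dir, paste0(org, ".fasta")))
    cm <- as.data.frame(collection@cladeMap)
    utils::write.table(cm, file.path(dir, "clades.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeProteomes
#' @export
readProteomes <- function(dir) {
    cm <- utils::read.delim(file.path(dir, "clades.tsv"))
    proteomes <- lapply(cm$organism, function(org)
        Biostrings::readAAStringSet(file.path(dir, paste0(org, ".fasta"))))
    names(proteomes) <- cm$organism
    methods::new("ProteomeCollection", proteomes = proteomes,
                 cladeMap = S4Vectors::DataFrame(cm))
}

#' Write a conservation profile as TSV (plus a restriction report JSON)
#'
#' @param profile a [ConservationProfile-class].
#' @param file TSV output path; a sibling \code{.json} restriction report
#'   is written when \code{reportJson} is TRUE.
#' @param reportJson logical.
#' @param threshold clade-restriction threshold.
#' @return invisibly, the TSV path.
#' @export
writeProfile <- function(profile, file, reportJson = TRUE, threshold = 10) {
    utils::write.table(as.data.frame(profile@hits), file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (reportJson) {
        rep <- cladeRestriction(profile, threshold)
        jsonlite::write_json(
            list(query = profile@query, self_bits = profile@selfBits,
                 threshold = threshold,
                 clade_counts = as.list(rep$clade_counts),
                 restricted_to = rep$restricted_to),
            sub("\\.tsv$", ".json", file), auto_unbox = TRUE, digits = NA)
    }
    invisible(file)
}

#' Write / read a Ct table as TSV
#'
#' @param ct a Ct table data.frame.
#' @param file path.
#' @return invisibly (write) the path; (read) the data.frame.
#' @export
writeCtTable <- function(ct, file) {
    utils::write.table(ct, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeCtTable
#' @export
readCtTable <- function(file) {
    .checkCtTable(utils::read.delim(file))
}

#' Write a SetReport as JSON
#'
#' @param report a [SetReport-class].
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeSetReport <- function(report, file) {
    jsonlite::write_json(
        list(counts = as.list(setCounts(report)),
             percentages = as.list(setPercentages(report)),
             ratios = as.list(report@ratios)),
        file, auto_unbox = TRUE, digits = NA)
    invisible(file)
}
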