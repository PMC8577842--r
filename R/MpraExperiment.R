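#' Construct an MpraExperiment
#'
#' Bundles a raw amplicon count matrix, an amplicon catalog and a sample sheet
#' into a single validated container.
#'
#' @param counts Integer-like matrix of raw de-duplicated read counts, rows
#'   named by amplicon id, columns named by sample id.
#' @param catalog A \code{GRanges} amplicon catalog as returned by
#'   [simulateTruth()] or [readAmpliconCatalog()]; metadata columns must
#'   include \code{amplicon_id}, \code{group}, \code{gc} and may include
#'   \code{ascertained_enhancer}.
#' @param sampleInfo \code{data.frame} or \code{DataFrame} with columns
#'   \code{sample_id}, \code{kind} (\code{library}, \code{DNA} or \code{RNA}),
#'   \code{replicate} and optionally \code{technical_of}.
#'
#' @return An [MpraExperiment-class] object.
#' @examples
#' sim <- simulateMpra(simConfig(n_amplicons = 40, seed = 7))
#' sim$mpra
#' @export
MpraExperiment <- function(counts, catalog, sampleInfo) {
    counts <- as.matrix(counts)
    sampleInfo <- as.data.frame(sampleInfo)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have amplicon row names and sample column names")
    ids <- mcols(catalog)$amplicon_id
    if (!setequal(rownames(counts), ids))
        stop("row names of 'counts' must match catalog amplicon_id")
    catalog <- catalog[match(rownames(counts), ids)]
    if (!setequal(colnames(counts), sampleInfo$sample_id))
        stop("column names of 'counts' must match sampleInfo$sample_id")
    sampleInfo <- sampleInfo[match(colnames(counts), sampleInfo$sample_id), ,
                             drop = FALSE]
    if (is.null(sampleInfo$technical_of)) sampleInfo$technical_of <- NA_character_
    cd <- DataFrame(kind = as.character(sampleInfo$kind),
                    replicate = as.integer(sampleInfo$replicate),
                    technical_of = as.character(sampleInfo$technical_of),
                    row.names = sampleInfo$sample_id)
    names(catalog) <- mcols(catalog)$amplicon_id
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = catalog, colData = cd)
    new("MpraExperiment", se)
}

#' @describeIn MpraExperiment Raw count matrix accessor.
#' @param object,x An \code{MpraExperiment}.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "MpraExperiment", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' Accessors for MpraExperiment components
#'
#' \code{ampliconCatalog} returns the catalog \code{GRanges};
#' \code{ampliconIds} the amplicon identifiers; \code{sampleKind} the
#' per-sample role; \code{isTechnical} a logical flag for technical
#' replicates; \code{dnaSamples}/\code{rnaSamples} the ids of biological DNA
#' and RNA samples (technical replicates excluded); \code{librarySamples} the
#' previral library sample ids.
#'
#' @param x An [MpraExperiment-class].
#' @return See individual descriptions.
#' @name mpra-accessors
NULL

#' @rdname mpra-accessors
#' @export
ampliconCatalog <- function(x) rowRanges(x)

#' @rdname mpra-accessors
#' @export
ampliconIds <- function(x) mcols(rowRanges(x))$amplicon_id

#' @rdname mpra-accessors
#' @export
sampleKind <- function(x) {
    k <- colData(x)$kind
    names(k) <- rownames(colData(x))
    k
}

#' @rdname mpra-accessors
#' @export
isTechnical <- function(x) {
    tech <- !is.na(colData(x)$technical_of)
    names(tech) <- rownames(colData(x))
    tech
}

#' @rdname mpra-accessors
#' @export
dnaSamples <- function(x)
    rownames(colData(x))[sampleKind(x) == "DNA" & !isTechnical(x)]

#' @rdname mpra-accessors
#' @export
rnaSamples <- function(x)
    rownames(colData(x))[sampleKind(x) == "RNA" & !isTechnical(x)]

#' @rdname mpra-accessors
#' @export
librarySamples <- function(x) rownames(colData(x))[sampleKind(x) == "library"]

setMethod("show", "MpraExperiment", function(object) {
    k <- sampleKind(object)
    cat(sprintf("MpraExperiment: %d amplicons x %d samples\n",
                nrow(object), ncol(object)))
    cat(sprintf("  samples: %d library, %d DNA, %d RNA (%d technical)\n",
                sum(k == "library"), sum(k == "DNA"), sum(k == "RNA"),
                sum(isTechnical(object))))
    grp <- table(mcols(rowRanges(object))$group)
    cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = " "),
        "\n")
    if (!is.null(metadata(object)$exclusionLog))
        cat(sprintf("  filtered: %d amplicons excluded\n",
                    nrow(metadata(object)$exclusionLog)))
    invisible(NULL)
})
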