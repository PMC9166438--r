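#' Accessors for transportome classes
#'
#' Small accessor generics so slots are never reached into directly:
#' `sampleId()` and `nGenes()` for [ExpressionTable-class] and
#' [DiscoveryTable-class]; `geneIds()`, `geneSymbols()` and `tpm()` for
#' [ExpressionTable-class]; `setName()` and `members()` for
#' [GeneSet-class]; `catalogEntries()` for [GeneCatalog-class];
#' `discoveryRows()` for [DiscoveryTable-class]; `networkNodes()` and
#' `networkEdges()` for [AssociationNetwork-class].
#'
#' @param x object.
#' @return The respective slot content (see above), copied, never a
#'   reference into the object.
#' @name accessors
#' @aliases sampleId nGenes geneIds geneSymbols tpm members setName
#'   catalogEntries discoveryRows networkNodes networkEdges
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname accessors
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))
#' @rdname accessors
#' @export
setGeneric("discoveryRows", function(x) standardGeneric("discoveryRows"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
setMethod("sampleId", "ExpressionTable", function(x) x@sampleId)
#' @rdname accessors
setMethod("nGenes", "ExpressionTable", function(x) nrow(x@genes))
#' @rdname accessors
setMethod("geneIds", "ExpressionTable", function(x) x@genes$gene_id)
#' @rdname accessors
setMethod("geneSymbols", "ExpressionTable",
          function(x) stats::setNames(x@genes$symbol, x@genes$gene_id))
#' @rdname accessors
setMethod("tpm", "ExpressionTable",
          function(x) stats::setNames(x@genes$tpm, x@genes$gene_id))

#' @rdname accessors
setMethod("members", "GeneSet", function(x) x@members)
#' @rdname accessors
setMethod("setName", "GeneSet", function(x) x@name)
#' @rdname accessors
setMethod("nGenes", "GeneSet", function(x) length(x@members))

#' @rdname accessors
setMethod("catalogEntries", "GeneCatalog", function(x) x@entries)
#' @rdname accessors
setMethod("nGenes", "GeneCatalog", function(x) nrow(x@entries))

#' @rdname accessors
setMethod("sampleId", "DiscoveryTable", function(x) x@sampleId)
#' @rdname accessors
setMethod("nGenes", "DiscoveryTable", function(x) nrow(x@table))
#' @rdname accessors
setMethod("discoveryRows", "DiscoveryTable", function(x) x@table)

#' @rdname accessors
setMethod("networkNodes", "AssociationNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "AssociationNetwork", function(x) x@edges)

setMethod("show", "ExpressionTable", function(object) {
    cat("ExpressionTable '", object@sampleId, "': ", nrow(object@genes),
        " genes\n", sep = "")
    t <- object@genes$tpm
    if (length(t))
        cat(sprintf("  TPM sum %.6g, range [%.4g, %.4g]\n",
                    sum(t), min(t), max(t)))
})

setMethod("show", "GeneCatalog", function(object) {
    e <- object@entries
    cat("GeneCatalog: ", nrow(e), " genes; ",
        sum(lengths(e$go_terms) > 0L), " with GO annotation\n", sep = "")
})

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "': ", length(object@members),
        " members\n", sep = "")
})

setMethod("show", "CategoryRule", function(object) {
    cat("CategoryRule '", object@name, "': ", length(object@sourceLists),
        " source list(s)",
        if (object@applyPmFilter) ", plasma-membrane filter on" else "",
        "\n", sep = "")
})

setMethod("show", "DiscoveryTable", function(object) {
    cat("DiscoveryTable '", object@category, "' in sample '",
        object@sampleId, "': ", nrow(object@table), " ranked genes\n",
        sep = "")
    cr <- grep("^rank\\.", names(object@table), value = TRUE)
    if (length(cr))
        cat("  cross-rank columns:",
            paste(sub("^rank\\.", "", cr), collapse = ", "), "\n")
})

setMethod("show", "OverlapResult", function(object) {
    if (object@degenerate) {
        cat("OverlapResult: degenerate (an empty side)\n")
        return(invisible(NULL))
    }
    cat(sprintf("OverlapResult: %d vs %d genes, shared %d (left) / %d (right)\n",
                object@nLeft, object@nRight, object@nSharedLeft,
                object@nSharedRight))
    cat(sprintf("  pct shared: left %.1f%%, right %.1f%%\n",
                object@pctSharedLeft, object@pctSharedRight))
})

setMethod("show", "AssociationNetwork", function(object) {
    cat("AssociationNetwork (targets: ", object@targetsName, "): ",
        nrow(object@nodes), " nodes, ", nrow(object@edges),
        " edges, scores in [", object@scoreInterval[1], ", ",
        object@scoreInterval[2], "]\n", sep = "")
})

setMethod("show", "SyntheticTruth", function(object) {
    ids <- vapply(object@samples, `[[`, "", "sample_id")
    cat("SyntheticTruth (seed ", object@seed, "): samples ",
        paste(ids, collapse = " vs "), ", planted sharing ",
        object@sharedFraction, "%\n", sep = "")
})
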