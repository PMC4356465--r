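#' Accessors for pgptProfiler containers
#'
#' Small accessor generics used across the package: read identifiers,
#' sample identifiers and lengths of a \linkS4class{ReadSet}; the hit
#' data.frame and search type of a \linkS4class{HitTable}; the gene
#' table and subject map of a \linkS4class{GeneCatalog}; the lineage
#' table of a \linkS4class{TaxonMap}.
#'
#' @param x An object of the documented class.
#' @return See the individual methods.
#' @name accessors
#' @aliases readIds sampleIds readLengths hits searchType geneInfo
#'   subjectMap lineages
NULL

#' @rdname accessors
#' @export
setGeneric("readIds", function(x) standardGeneric("readIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("readLengths", function(x) standardGeneric("readLengths"))

#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname accessors
#' @export
setGeneric("searchType", function(x) standardGeneric("searchType"))

#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))

#' @rdname accessors
#' @export
setGeneric("subjectMap", function(x) standardGeneric("subjectMap"))

#' @rdname accessors
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname accessors
setMethod("readIds", "ReadSet", function(x) names(x@sequences))

#' @rdname accessors
setMethod("sampleIds", "ReadSet", function(x) x@sampleId)

#' @rdname accessors
setMethod("readLengths", "ReadSet", function(x) {
    w <- Biostrings::width(x@sequences)
    names(w) <- names(x@sequences)
    w
})

#' @rdname accessors
setMethod("hits", "HitTable", function(x) x@hits)

#' @rdname accessors
setMethod("searchType", "HitTable", function(x) x@searchType)

#' @rdname accessors
setMethod("geneInfo", "GeneCatalog", function(x) x@genes)

#' @rdname accessors
setMethod("subjectMap", "GeneCatalog", function(x) x@subjectMap)

#' @rdname accessors
setMethod("lineages", "TaxonMap", function(x) x@lineages)

setMethod("show", "ReadSet", function(object) {
    ns <- table(object@sampleId)
    cat(sprintf("ReadSet with %d reads across %d sample(s)\n",
                length(object@sequences), length(ns)))
    for (s in names(ns))
        cat(sprintf("  %s: %d reads\n", s, ns[[s]]))
})

setMethod("show", "HitTable", function(object) {
    cat(sprintf("HitTable (%s) with %d hits over %d queries\n",
                object@searchType, nrow(object@hits),
                length(unique(object@hits$qseqid))))
})

setMethod("show", "GeneCatalog", function(object) {
    cat(sprintf("GeneCatalog with %d genes in %d categories, %d mapped subjects\n",
                nrow(object@genes), length(unique(object@genes$category)),
                nrow(object@subjectMap)))
})

setMethod("show", "TaxonMap", function(object) {
    cat(sprintf("TaxonMap for %d subjects\n", nrow(object@lineages)))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  samples: %d x %d reads, length ~N(%g, %g) bp\n",
                object@nSamples, object@readsPerSample,
                object@readLengthMeanBp, object@readLengthSdBp))
    cat(sprintf("  hostFraction: %g  hitRate: %g  decoyHitRate: %g\n",
                object@hostFraction, object@hitRate, object@decoyHitRate))
    cat(sprintf("  %d genes, %d genera, seed %d\n",
                length(object@geneAbundanceWeights),
                length(object@taxonWeights), object@seed))
})
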