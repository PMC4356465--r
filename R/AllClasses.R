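#' @import methods
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
NULL

.HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

.SEARCH_TYPES <- c("nucl_nucl", "prot_translated", "translated_prot")

.TAXON_RANKS <- c("phylum", "class", "order", "family", "genus")

#' ReadSet: metagenomic reads with sample membership
#'
#' A thin container pairing a \linkS4class{DNAStringSet} of reads with a
#' per-read sample identifier. Read identifiers are the names of the
#' underlying string set and must be unique within each sample.
#'
#' @slot sequences A \linkS4class{DNAStringSet}; names are read identifiers.
#' @slot sampleId Character vector parallel to \code{sequences} giving the
#'   sample each read belongs to.
#' @exportClass ReadSet
setClass("ReadSet",
    representation(sequences = "DNAStringSet", sampleId = "character"))

setValidity("ReadSet", function(object) {
    msg <- character()
    if (length(object@sampleId) != length(object@sequences))
        msg <- c(msg, "sampleId must have one entry per read")
    ids <- names(object@sequences)
    if (length(object@sequences) > 0L && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msg <- c(msg, "every read must carry a non-empty identifier")
    if (length(object@sequences) > 0L && !is.null(ids)) {
        dup <- tapply(ids, object@sampleId, function(x) anyDuplicated(x) > 0L)
        if (any(unlist(dup)))
            msg <- c(msg, "read identifiers must be unique within a sample")
    }
    if (length(msg)) msg else TRUE
})

#' HitTable: tabular homology search results
#'
#' One row per alignment in the standard 12-column tabular dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, E-value, bit score).
#' \code{searchType} records which search produced the table:
#' \code{nucl_nucl} (nucleotide query vs nucleotide database),
#' \code{prot_translated} (translated nucleotide query vs protein
#' database) or \code{translated_prot} (protein query vs translated
#' nucleotide database). \code{alignment length} is in the search's
#' native unit: amino-acid columns for the two translated searches.
#'
#' @slot hits data.frame with columns \code{qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore}.
#' @slot searchType One of \code{"nucl_nucl"}, \code{"prot_translated"},
#'   \code{"translated_prot"}.
#' @exportClass HitTable
setClass("HitTable",
    representation(hits = "data.frame", searchType = "character"))

setValidity("HitTable", function(object) {
    msg <- character()
    h <- object@hits
    if (!identical(colnames(h), .HIT_COLUMNS))
        msg <- c(msg, sprintf("hits must have exactly the columns: %s",
                              paste(.HIT_COLUMNS, collapse = ", ")))
    if (length(object@searchType) != 1L ||
        !object@searchType %in% .SEARCH_TYPES)
        msg <- c(msg, sprintf("searchType must be one of: %s",
                              paste(.SEARCH_TYPES, collapse = ", ")))
    if (length(msg) == 0L && nrow(h) > 0L) {
        if (any(h$evalue < 0)) msg <- c(msg, "evalue must be >= 0")
        if (any(h$pident < 0 | h$pident > 100))
            msg <- c(msg, "pident must lie in [0, 100]")
        if (any(h$length <= 0L)) msg <- c(msg, "alignment length must be positive")
        if (any(h$mismatch < 0L) || any(h$gapopen < 0L))
            msg <- c(msg, "mismatch and gapopen must be nonnegative")
        if (any(h$qstart < 1L | h$qend < 1L | h$sstart < 1L | h$send < 1L))
            msg <- c(msg, "coordinates are 1-based and must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' GeneCatalog: curated PGPT gene targets
#'
#' Catalog of target genes, one row per gene: name, KEGG Orthology
#' identifier (may be empty), UniRef cluster identifier, representative
#' gene length in kbp (used for length normalization of detection
#' frequencies), and functional category (e.g. "Siderophore"). The
#' catalog also carries the subject-to-gene map that resolves database
#' subject identifiers in hit tables to catalog genes.
#'
#' @slot genes data.frame with columns \code{gene_name, ko_id,
#'   uniref_id, length_kbp, category}.
#' @slot subjectMap data.frame with columns \code{subject_id,
#'   gene_name}; each subject maps to exactly one gene.
#' @exportClass GeneCatalog
setClass("GeneCatalog",
    representation(genes = "data.frame", subjectMap = "data.frame"))

setValidity("GeneCatalog", function(object) {
    msg <- character()
    g <- object@genes
    need <- c("gene_name", "ko_id", "uniref_id", "length_kbp", "category")
    if (!all(need %in% colnames(g)))
        msg <- c(msg, sprintf("genes must have columns: %s",
                              paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(g$gene_name))
            msg <- c(msg, "gene_name must be unique within a catalog")
        bad <- g$gene_name[!is.finite(g$length_kbp) | g$length_kbp <= 0]
        if (length(bad))
            msg <- c(msg, sprintf("nonpositive length_kbp for gene(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    sm <- object@subjectMap
    if (!all(c("subject_id", "gene_name") %in% colnames(sm)))
        msg <- c(msg, "subjectMap must have columns subject_id, gene_name")
    else if (nrow(sm) > 0L) {
        ngene <- tapply(sm$gene_name, sm$subject_id,
                        function(x) length(unique(x)))
        if (any(ngene > 1L))
            msg <- c(msg, sprintf("subject(s) mapped to two genes: %s",
                                  paste(names(ngene)[ngene > 1L], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' TaxonMap: subject-to-lineage lookup
#'
#' Maps database subject identifiers to taxonomic lineages over the five
#' canonical ranks phylum, class, order, family, genus. Absent ranks are
#' \code{NA}.
#'
#' @slot lineages data.frame with columns \code{subject_id} plus one
#'   column per canonical rank.
#' @exportClass TaxonMap
setClass("TaxonMap", representation(lineages = "data.frame"))

setValidity("TaxonMap", function(object) {
    msg <- character()
    l <- object@lineages
    if (!identical(colnames(l), c("subject_id", .TAXON_RANKS)))
        msg <- c(msg, sprintf("lineages must have columns: subject_id, %s",
                              paste(.TAXON_RANKS, collapse = ", ")))
    else if (anyDuplicated(l$subject_id))
        msg <- c(msg, "duplicate subject_id in taxon map")
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Holds every knob of the generator that emulates the study design the
#' pipeline was built for: three composite samples of pyrosequencing
#' reads (~46k-80k reads each, mean length ~645 bp), ~2% host-plant
#' reads, gene-family reads drawn from weighted gene and genus pools,
#' and hit tables in which 54% of reads carry a protein-database hit.
#' All stochastic draws are governed by \code{seed}.
#'
#' @slot nSamples Number of composite samples (default 3).
#' @slot readsPerSample Reads simulated per sample.
#' @slot readLengthMeanBp,readLengthSdBp Mean and SD of the read-length
#'   distribution (truncated Normal on [100, 1200] bp).
#' @slot hostFraction Probability a read is of host-plant origin.
#' @slot geneAbundanceWeights Named nonnegative weights over catalog genes.
#' @slot taxonWeights Named nonnegative weights over genera.
#' @slot hitRate Probability a gene-origin read receives a true-origin
#'   protein-search hit.
#' @slot decoyHitRate Probability a hit-bearing read additionally
#'   receives a strictly worse decoy hit.
#' @slot identityMeanPct,identitySdPct Percent-identity model for true
#'   hits (Normal, clipped to [20, 100]).
#' @slot seed Integer seed governing all draws.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(nSamples = "integer", readsPerSample = "integer",
                   readLengthMeanBp = "numeric", readLengthSdBp = "numeric",
                   hostFraction = "numeric",
                   geneAbundanceWeights = "numeric", taxonWeights = "numeric",
                   hitRate = "numeric", decoyHitRate = "numeric",
                   identityMeanPct = "numeric", identitySdPct = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chkProb <- function(x, what) {
        if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
            sprintf("%s must be a single value in [0, 1]", what)
        else character()
    }
    if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
    if (object@readsPerSample < 0L) msg <- c(msg, "readsPerSample must be >= 0")
    if (object@readLengthMeanBp <= 0) msg <- c(msg, "readLengthMeanBp must be > 0")
    if (object@readLengthSdBp < 0) msg <- c(msg, "readLengthSdBp must be >= 0")
    msg <- c(msg, chkProb(object@hostFraction, "hostFraction"),
             chkProb(object@hitRate, "hitRate"),
             chkProb(object@decoyHitRate, "decoyHitRate"))
    chkW <- function(w, what) {
        if (length(w) == 0L || is.null(names(w)) || any(names(w) == ""))
            sprintf("%s must be a non-empty named vector", what)
        else if (any(w < 0) || all(w == 0))
            sprintf("%s must be nonnegative with at least one positive entry", what)
        else character()
    }
    msg <- c(msg, chkW(object@geneAbundanceWeights, "geneAbundanceWeights"),
             chkW(object@taxonWeights, "taxonWeights"))
    if (length(msg)) msg else TRUE
})
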