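#' Construct a ReadSet
#'
#' @param sequences A \linkS4class{DNAStringSet} (or named character
#'   vector) of reads; names are read identifiers.
#' @param sampleId Sample identifier(s): either one per read or a single
#'   value recycled over all reads.
#' @return A \linkS4class{ReadSet}.
#' @examples
#' rs <- ReadSet(c(r1 = "ACGTACGTAC", r2 = "ACGT"), sampleId = "S1")
#' readLengths(rs)
#' @export
ReadSet <- function(sequences, sampleId) {
    if (!methods::is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    if (length(sampleId) == 1L)
        sampleId <- rep(sampleId, length(sequences))
    methods::new("ReadSet", sequences = sequences,
                 sampleId = as.character(sampleId))
}

#' Construct a HitTable
#'
#' @param hits data.frame in the standard 12-column tabular layout; see
#'   \linkS4class{HitTable}.
#' @param searchType One of \code{"nucl_nucl"}, \code{"prot_translated"},
#'   \code{"translated_prot"}.
#' @return A \linkS4class{HitTable}.
#' @export
HitTable <- function(hits = emptyHitFrame(), searchType) {
    hits <- as.data.frame(hits)
    rownames(hits) <- NULL
    methods::new("HitTable", hits = hits, searchType = searchType)
}

#' An empty hit data.frame in the standard 12-column layout
#'
#' @return A zero-row data.frame with the standard tabular columns.
#' @export
emptyHitFrame <- function() {
    data.frame(qseqid = character(), sseqid = character(),
               pident = numeric(), length = integer(),
               mismatch = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(),
               sstart = integer(), send = integer(),
               evalue = numeric(), bitscore = numeric(),
               stringsAsFactors = FALSE)
}

#' Construct a GeneCatalog
#'
#' @param genes data.frame with columns \code{gene_name, ko_id,
#'   uniref_id, length_kbp, category}.
#' @param subjectMap data.frame with columns \code{subject_id,
#'   gene_name} resolving database subjects to catalog genes; defaults
#'   to the identity map (subject id equals gene name).
#' @return A \linkS4class{GeneCatalog}.
#' @examples
#' cat <- GeneCatalog(data.frame(
#'     gene_name = "GDH", ko_id = "K00117",
#'     uniref_id = "UniRef50_P27175", length_kbp = 2.427,
#'     category = "Phosphate solubilization"))
#' geneInfo(cat)
#' @export
GeneCatalog <- function(genes, subjectMap = NULL) {
    genes <- as.data.frame(genes)
    rownames(genes) <- NULL
    if (is.null(subjectMap))
        subjectMap <- data.frame(subject_id = genes$gene_name,
                                 gene_name = genes$gene_name,
                                 stringsAsFactors = FALSE)
    subjectMap <- as.data.frame(subjectMap)
    rownames(subjectMap) <- NULL
    methods::new("GeneCatalog", genes = genes, subjectMap = subjectMap)
}

#' Construct a TaxonMap
#'
#' @param lineages data.frame with a \code{subject_id} column and any of
#'   the canonical rank columns \code{phylum, class, order, family,
#'   genus}; missing rank columns are added as \code{NA}.
#' @return A \linkS4class{TaxonMap}.
#' @export
TaxonMap <- function(lineages = data.frame(subject_id = character())) {
    lineages <- as.data.frame(lineages)
    extra <- setdiff(colnames(lineages), c("subject_id", .TAXON_RANKS))
    if (length(extra))
        stop("unsupported rank column(s): ", paste(extra, collapse = ", "))
    for (r in .TAXON_RANKS)
        if (!r %in% colnames(lineages))
            lineages[[r]] <- rep(NA_character_, nrow(lineages))
    lineages <- lineages[, c("subject_id", .TAXON_RANKS), drop = FALSE]
    rownames(lineages) <- NULL
    methods::new("TaxonMap", lineages = lineages)
}

#' Canonical taxonomic ranks used by the package
#'
#' @return Character vector \code{c("phylum", "class", "order",
#'   "family", "genus")}.
#' @export
taxonRanks <- function() .TAXON_RANKS
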