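#' Best hit for one query
#'
#' Selects the best alignment among the hits of a single query: maximal
#' bit score, ties broken by minimal E-value, then by lexicographically
#' smallest subject id. This is the assignment rule used throughout the
#' pipeline for both functional and taxonomic calls.
#'
#' @param queryHits data.frame of hits (12-column layout) all sharing
#'   one \code{qseqid}.
#' @return A one-row data.frame, or \code{NULL} for empty input.
#' @export
bestHit <- function(queryHits) {
    if (is.null(queryHits) || nrow(queryHits) == 0L) return(NULL)
    if (length(unique(queryHits$qseqid)) != 1L)
        stop("bestHit expects hits of a single query")
    o <- order(-queryHits$bitscore, queryHits$evalue, queryHits$sseqid)
    queryHits[o[1L], , drop = FALSE]
}

#' Best hit per query over a whole table
#'
#' Vectorized version of \code{\link{bestHit}}: one row per distinct
#' query, same tie-break order.
#'
#' @param hitTable A \linkS4class{HitTable} or a hit data.frame.
#' @return data.frame with one best hit per query.
#' @export
bestHitPerQuery <- function(hitTable) {
    h <- if (methods::is(hitTable, "HitTable")) hitTable@hits else hitTable
    if (nrow(h) == 0L) return(h)
    o <- order(h$qseqid, -h$bitscore, h$evalue, h$sseqid)
    h <- h[o, , drop = FALSE]
    h <- h[!duplicated(h$qseqid), , drop = FALSE]
    rownames(h) <- NULL
    h
}

#' Remove host-plant reads by best nucleotide hit
#'
#' A read is removed if and only if its best nucleotide-search hit,
#' after discarding hits at or above the E-value cutoff, resolves to a
#' lineage containing \code{hostLabel} at any rank. Reads with no
#' qualifying hit are retained, so the screen is conservative towards
#' keeping reads. Retained plus removed always equals the input count.
#'
#' @param reads A \linkS4class{ReadSet}.
#' @param nuclHits A \linkS4class{HitTable} with
#'   \code{searchType == "nucl_nucl"}.
#' @param taxonMap A \linkS4class{TaxonMap} resolving subjects.
#' @param evalueCutoff Hits with \code{evalue >= evalueCutoff} are
#'   ignored (default \code{1e-10}).
#' @param hostLabel Clade name marking host origin (default
#'   \code{"Streptophyta"}); matched at any rank of the lineage.
#' @return List with elements \code{retained} (a \linkS4class{ReadSet}),
#'   \code{removedIds} (character) and \code{removedCount}.
#' @export
filterHostReads <- function(reads, nuclHits, taxonMap,
                            evalueCutoff = 1e-10,
                            hostLabel = "Streptophyta") {
    stopifnot(methods::is(reads, "ReadSet"), methods::is(nuclHits, "HitTable"))
    if (searchType(nuclHits) != "nucl_nucl")
        stop("host filtering uses nucleotide-vs-nucleotide hits")
    h <- nuclHits@hits
    h <- h[h$evalue < evalueCutoff, , drop = FALSE]
    removed <- character()
    if (nrow(h) > 0L) {
        best <- bestHitPerQuery(h)
        l <- taxonMap@lineages
        idx <- match(best$sseqid, l$subject_id)
        isHost <- vapply(seq_along(idx), function(i) {
            if (is.na(idx[i])) return(FALSE)
            any(l[idx[i], .TAXON_RANKS] == hostLabel, na.rm = TRUE)
        }, logical(1L))
        removed <- best$qseqid[isHost]
    }
    keep <- !(readIds(reads) %in% removed)
    retained <- methods::new("ReadSet",
                             sequences = reads@sequences[keep],
                             sampleId = reads@sampleId[keep])
    list(retained = retained,
         removedIds = readIds(reads)[!keep],
         removedCount = sum(!keep))
}

#' Screen translated-query protein-database hits by E-value
#'
#' Keeps hits with \code{evalue} strictly below the cutoff, the
#' criterion applied to the main protein-database screen. A hit at
#' exactly the cutoff is rejected.
#'
#' @param hitTable A \linkS4class{HitTable} with
#'   \code{searchType == "prot_translated"}.
#' @param evalueCutoff Strict E-value cutoff (default \code{1e-10}).
#' @return A \linkS4class{HitTable} of surviving hits, in input order.
#' @export
screenHitsBlastx <- function(hitTable, evalueCutoff = 1e-10) {
    stopifnot(methods::is(hitTable, "HitTable"))
    if (searchType(hitTable) != "prot_translated")
        stop("expected a prot_translated hit table")
    h <- hitTable@hits
    HitTable(h[h$evalue < evalueCutoff, , drop = FALSE],
             searchType = hitTable@searchType)
}

#' Screen protein-query translated-database hits
#'
#' The re-screening rule for gene families missed by the primary
#' protein-database screen: a hit survives only if its E-value is
#' strictly below the cutoff, its alignment spans strictly more than
#' \code{minHitBp} nucleotides, and its percent identity is strictly
#' above \code{minIdentity}. Alignment length is native to the search
#' (amino-acid columns) and is converted to nucleotides as columns x 3.
#'
#' @param hitTable A \linkS4class{HitTable} with
#'   \code{searchType == "translated_prot"}.
#' @param evalueCutoff Strict E-value cutoff (default \code{1e-10}).
#' @param minHitBp Minimum alignment span in bp, exclusive (default 250).
#' @param minIdentity Minimum percent identity, exclusive (default 40).
#' @return A \linkS4class{HitTable} of surviving hits, in input order.
#' @export
screenHitsTblastn <- function(hitTable, evalueCutoff = 1e-10,
                              minHitBp = 250, minIdentity = 40) {
    stopifnot(methods::is(hitTable, "HitTable"))
    if (searchType(hitTable) != "translated_prot")
        stop("expected a translated_prot hit table")
    h <- hitTable@hits
    keep <- h$evalue < evalueCutoff &
        (h$length * 3L) > minHitBp &
        h$pident > minIdentity
    HitTable(h[keep, , drop = FALSE], searchType = hitTable@searchType)
}

#' Per-read gene assignment from screened hits
#'
#' Each read is assigned to at most one catalog gene: the gene of its
#' best surviving hit. Reads whose best hit maps to no catalog subject
#' are left unassigned (dropped from the result).
#'
#' @param screenedHits A screened \linkS4class{HitTable}.
#' @param catalog A \linkS4class{GeneCatalog} whose subject map resolves
#'   \code{sseqid} values.
#' @return data.frame with columns \code{read_id}, \code{gene_name},
#'   \code{subject_id}.
#' @export
readGeneAssignments <- function(screenedHits, catalog) {
    stopifnot(methods::is(catalog, "GeneCatalog"))
    best <- bestHitPerQuery(screenedHits)
    if (nrow(best) == 0L)
        return(data.frame(read_id = character(), gene_name = character(),
                          subject_id = character(), stringsAsFactors = FALSE))
    sm <- catalog@subjectMap
    gene <- sm$gene_name[match(best$sseqid, sm$subject_id)]
    keep <- !is.na(gene)
    data.frame(read_id = best$qseqid[keep], gene_name = gene[keep],
               subject_id = best$sseqid[keep], stringsAsFactors = FALSE)
}

#' Count reads per catalog gene
#'
#' Aggregates \code{\link{readGeneAssignments}} into per-gene read
#' counts for one sample; every catalog gene appears, with count 0 if
#' undetected. A read is counted for exactly one gene (its best hit).
#'
#' @param reads A \linkS4class{ReadSet} (used only to stamp the sample
#'   id; may contain several samples, in which case counts are split).
#' @param screenedHits A screened \linkS4class{HitTable}.
#' @param catalog A \linkS4class{GeneCatalog}.
#' @return data.frame with columns \code{sample_id}, \code{gene_name},
#'   \code{read_count}.
#' @export
assignReadsToGenes <- function(reads, screenedHits, catalog) {
    stopifnot(methods::is(reads, "ReadSet"))
    asg <- readGeneAssignments(screenedHits, catalog)
    sampleOf <- stats::setNames(sampleIds(reads), readIds(reads))
    asg$sample_id <- unname(sampleOf[asg$read_id])
    asg <- asg[!is.na(asg$sample_id), , drop = FALSE]
    samples <- unique(sampleIds(reads))
    genes <- catalog@genes$gene_name
    grid <- expand.grid(gene_name = genes, sample_id = samples,
                        stringsAsFactors = FALSE)
    key <- paste(asg$sample_id, asg$gene_name, sep = "\r")
    tab <- table(key)
    gk <- paste(grid$sample_id, grid$gene_name, sep = "\r")
    grid$read_count <- as.integer(ifelse(gk %in% names(tab), tab[gk], 0L))
    grid[, c("sample_id", "gene_name", "read_count")]
}

#' Per-sample summary statistics
#'
#' Totals per sample: read count, summed length in bp, average read
#' length (floor of total bp over total reads) and the number of reads
#' with at least one surviving protein-search hit.
#'
#' @param reads A \linkS4class{ReadSet} (one or more samples).
#' @param screenedHits A screened \linkS4class{HitTable}, or \code{NULL}
#'   to report zero similarity counts.
#' @return data.frame with columns \code{sample_id}, \code{total_reads},
#'   \code{total_bp}, \code{avg_length_bp}, \code{reads_with_similarity}.
#' @export
sampleSummary <- function(reads, screenedHits = NULL) {
    stopifnot(methods::is(reads, "ReadSet"))
    samples <- unique(sampleIds(reads))
    hitIds <- character()
    if (!is.null(screenedHits)) {
        h <- if (methods::is(screenedHits, "HitTable")) screenedHits@hits
             else screenedHits
        hitIds <- unique(h$qseqid)
    }
    rows <- lapply(samples, function(s) {
        sel <- sampleIds(reads) == s
        n <- sum(sel)
        bp <- sum(as.numeric(readLengths(reads)[sel]))
        data.frame(sample_id = s, total_reads = n, total_bp = bp,
                   avg_length_bp = if (n > 0L) floor(bp / n) else 0,
                   reads_with_similarity =
                       sum(readIds(reads)[sel] %in% hitIds),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sample_id = character(), total_reads = integer(),
                          total_bp = numeric(), avg_length_bp = numeric(),
                          reads_with_similarity = integer())
    out
}

#' Build a summary row from published totals
#'
#' Convenience constructor for a per-sample summary when only the
#' totals are known (e.g. transcribed from a published table): the
#' average read length is recomputed by floor division, the same rule
#' \code{\link{sampleSummary}} applies to raw reads.
#'
#' @param sampleId Sample label.
#' @param totalReads Total read count.
#' @param totalBp Summed read length in bp.
#' @param readsWithSimilarity Reads with a surviving protein hit
#'   (default \code{NA}).
#' @return One-row data.frame in the \code{\link{sampleSummary}} layout.
#' @export
summaryFromTotals <- function(sampleId, totalReads, totalBp,
                              readsWithSimilarity = NA_integer_) {
    stopifnot(totalReads >= 0, totalBp >= 0)
    data.frame(sample_id = sampleId, total_reads = totalReads,
               total_bp = totalBp,
               avg_length_bp = if (totalReads > 0)
                   floor(totalBp / totalReads) else 0,
               reads_with_similarity = readsWithSimilarity,
               stringsAsFactors = FALSE)
}

#' Pool per-sample summaries into a study-level row
#'
#' Sums reads, bp and similarity counts over samples and recomputes the
#' average read length by floor division on the pooled totals.
#'
#' @param summaries data.frame as returned by \code{\link{sampleSummary}}.
#' @param label Sample id of the pooled row (default \code{"Sum"}).
#' @return One-row data.frame in the same layout.
#' @export
poolSampleSummaries <- function(summaries, label = "Sum") {
    stopifnot(nrow(summaries) > 0L)
    n <- sum(summaries$total_reads)
    bp <- sum(summaries$total_bp)
    data.frame(sample_id = label, total_reads = n, total_bp = bp,
               avg_length_bp = if (n > 0L) floor(bp / n) else 0,
               reads_with_similarity = sum(summaries$reads_with_similarity),
               stringsAsFactors = FALSE)
}
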