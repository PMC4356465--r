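#' Best-hit taxonomic assignment of reads
#'
#' Assigns each hit-bearing read the lineage of its best surviving hit
#' (same tie-break as \code{\link{bestHit}}). Reads with no surviving
#' hit, or whose best subject is absent from the taxon map, are left
#' unassigned; missing subjects additionally raise a warning.
#'
#' @param reads A \linkS4class{ReadSet}.
#' @param screenedHits A screened \linkS4class{HitTable}.
#' @param taxonMap A \linkS4class{TaxonMap}.
#' @return data.frame with columns \code{read_id}, \code{sample_id},
#'   \code{assigned} (logical) and one column per canonical rank.
#' @export
assignTaxa <- function(reads, screenedHits, taxonMap) {
    stopifnot(methods::is(reads, "ReadSet"), methods::is(taxonMap, "TaxonMap"))
    best <- bestHitPerQuery(screenedHits)
    out <- data.frame(read_id = readIds(reads),
                      sample_id = sampleIds(reads),
                      assigned = FALSE, stringsAsFactors = FALSE)
    for (r in .TAXON_RANKS) out[[r]] <- NA_character_
    if (nrow(best) == 0L) return(out)
    l <- taxonMap@lineages
    bi <- match(out$read_id, best$qseqid)
    subj <- best$sseqid[bi]
    li <- match(subj, l$subject_id)
    unmapped <- unique(subj[!is.na(bi) & is.na(li)])
    if (length(unmapped))
        warning("subject(s) missing from taxon map, reads left unassigned: ",
                paste(unmapped, collapse = ", "))
    ok <- !is.na(li)
    out$assigned[ok] <- TRUE
    for (r in .TAXON_RANKS) out[[r]][ok] <- l[[r]][li[ok]]
    out
}

#' Rank-wise relative abundance with "Others" pooling
#'
#' Per sample, the percentage of assigned reads carrying each taxon
#' name at the requested rank; the denominator is the number of reads
#' whose lineage names that rank (unassigned reads and reads lacking
#' the rank are excluded). Taxa are ordered by decreasing mean
#' percentage (ties broken alphabetically); the top \code{nMajor} are
#' listed and the remainder pooled into an "Others" row, so the
#' unrounded per-sample percentages always sum to exactly 100.
#'
#' @param assignments data.frame from \code{\link{assignTaxa}}.
#' @param rank One of the canonical ranks.
#' @param nMajor Number of named major groups (default 3).
#' @return data.frame with columns \code{taxon}, one
#'   \code{pct.<sample>} per sample, \code{mean}, \code{sd}.
#' @export
relativeAbundance <- function(assignments, rank, nMajor = 3L) {
    if (!rank %in% .TAXON_RANKS)
        stop("rank must be one of: ", paste(.TAXON_RANKS, collapse = ", "))
    a <- assignments[assignments$assigned & !is.na(assignments[[rank]]), ,
                     drop = FALSE]
    if (nrow(a) == 0L)
        stop("no read carries rank '", rank, "' in its lineage")
    samples <- sort(unique(assignments$sample_id))
    if (length(samples) < 2L)
        stop("relative abundance summaries require >= 2 samples")
    taxa <- sort(unique(a[[rank]]))
    pct <- sapply(samples, function(s) {
        sub <- a[a$sample_id == s, , drop = FALSE]
        cnt <- table(factor(sub[[rank]], levels = taxa))
        as.numeric(100 * cnt / max(1L, nrow(sub)))
    })
    pct <- matrix(pct, nrow = length(taxa),
                  dimnames = list(taxa, paste0("pct.", samples)))
    mu <- rowMeans(pct)
    ord <- order(-mu, rownames(pct))
    major <- ord[seq_len(min(nMajor, length(ord)))]
    rest <- setdiff(seq_along(taxa), major)
    rows <- pct[major, , drop = FALSE]
    others <- if (length(rest)) colSums(pct[rest, , drop = FALSE])
              else stats::setNames(rep(0, length(samples)), colnames(pct))
    m <- rbind(rows, Others = others)
    agg <- apply(m, 1L, aggregateSamples)
    out <- data.frame(taxon = rownames(m), as.data.frame(m),
                      mean = vapply(agg, `[[`, numeric(1L), "mean"),
                      sd = vapply(agg, `[[`, numeric(1L), "sd"),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Monte-Carlo rarefaction of taxon richness
#'
#' Subsamples the assigned reads without replacement at each requested
#' depth, \code{replicates} times, and counts the distinct taxa at the
#' chosen rank. Deterministic for a given \code{seed}. At full depth
#' the curve equals the observed richness with zero spread.
#'
#' @param assignments data.frame from \code{\link{assignTaxa}}.
#' @param depths Integer vector of subsampling depths, each at most the
#'   number of rank-bearing assigned reads.
#' @param replicates Subsamples per depth (default 100).
#' @param seed Integer seed.
#' @param rank Rank at which to count distinct taxa (default genus).
#' @return data.frame with columns \code{depth}, \code{mean_richness},
#'   \code{sd_richness}.
#' @export
rarefactionCurve <- function(assignments, depths, replicates = 100L,
                             seed = 1L, rank = "genus") {
    if (!rank %in% .TAXON_RANKS)
        stop("rank must be one of: ", paste(.TAXON_RANKS, collapse = ", "))
    taxa <- assignments[[rank]][assignments$assigned]
    taxa <- taxa[!is.na(taxa)]
    n <- length(taxa)
    if (any(depths < 1L) || any(depths > n))
        stop("depths must lie in [1, ", n, "]")
    set.seed(seed)
    rows <- lapply(sort(unique(as.integer(depths))), function(d) {
        rich <- vapply(seq_len(replicates), function(i)
            length(unique(taxa[sample.int(n, d)])), numeric(1L))
        data.frame(depth = d, mean_richness = mean(rich),
                   sd_richness = stats::sd(rich))
    })
    do.call(rbind, rows)
}

#' Expected rarefied richness (closed form)
#'
#' Hypergeometric expectation of the number of distinct taxa in a
#' random subsample of size \code{depth} drawn without replacement:
#' \eqn{\sum_i 1 - C(N - N_i, d)/C(N, d)} over taxon counts
#' \eqn{N_i}. Used as the analytic counterpart of
#' \code{\link{rarefactionCurve}}.
#'
#' @param counts Integer vector of per-taxon read counts.
#' @param depth Subsample size.
#' @return Expected richness (numeric).
#' @export
expectedRichness <- function(counts, depth) {
    N <- sum(counts)
    if (depth > N) stop("depth exceeds total count")
    sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Cross-tabulation of catalog genes by genus
#'
#' For each catalog gene, the number of contributing reads assigned to
#' each genus; both inputs must derive from the same screened hit set
#' so that row sums equal the per-gene read counts.
#'
#' @param geneAssignments data.frame from
#'   \code{\link{readGeneAssignments}}.
#' @param taxonAssignments data.frame from \code{\link{assignTaxa}}.
#' @return data.frame cross-tab with columns \code{gene_name},
#'   \code{genus}, \code{read_count} (zero rows omitted).
#' @export
pgptTaxonBreakdown <- function(geneAssignments, taxonAssignments) {
    if (nrow(geneAssignments) == 0L)
        return(data.frame(gene_name = character(), genus = character(),
                          read_count = integer(), stringsAsFactors = FALSE))
    g <- taxonAssignments$genus[match(geneAssignments$read_id,
                                      taxonAssignments$read_id)]
    df <- data.frame(gene_name = geneAssignments$gene_name,
                     genus = ifelse(is.na(g), "unassigned", g),
                     stringsAsFactors = FALSE)
    tab <- as.data.frame(table(df$gene_name, df$genus),
                         stringsAsFactors = FALSE)
    colnames(tab) <- c("gene_name", "genus", "read_count")
    tab <- tab[tab$read_count > 0L, , drop = FALSE]
    tab <- tab[order(tab$gene_name, tab$genus), , drop = FALSE]
    rownames(tab) <- NULL
    tab
}
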