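#' Read nucleotide reads from a FASTA file
#'
#' Parses a (possibly gzipped) FASTA file into a \linkS4class{ReadSet}.
#' The read identifier is the first whitespace-delimited token of the
#' header line. Duplicate identifiers and sequence lines appearing
#' before any header are rejected with informative errors.
#'
#' @param path Path to the FASTA file.
#' @param sampleId Sample identifier attached to every read.
#' @return A \linkS4class{ReadSet}.
#' @export
readFasta <- function(path, sampleId = "sample1") {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    nonblank <- which(!grepl("^\\s*$", lines))
    if (length(nonblank)) {
        first <- nonblank[1L]
        if (!startsWith(lines[first], ">"))
            stop(sprintf("malformed FASTA: sequence before any header at line %d",
                         first))
    }
    if (length(nonblank) == 0L)
        return(ReadSet(Biostrings::DNAStringSet(), character()))
    seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
    ids <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(ids))
        stop("duplicate read id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids
    ReadSet(seqs, sampleId = rep(sampleId, length(seqs)))
}

#' Write a ReadSet to FASTA
#'
#' @param reads A \linkS4class{ReadSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(reads, path) {
    stopifnot(methods::is(reads, "ReadSet"))
    Biostrings::writeXStringSet(reads@sequences, filepath = path)
    invisible(path)
}

#' Read an aligned amino-acid FASTA file
#'
#' All records must have equal aligned length (gaps included).
#'
#' @param path Path to the aligned FASTA file.
#' @return An \linkS4class{AAStringSet} with one record per label.
#' @export
readAlignedFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    aln <- Biostrings::readAAStringSet(path, format = "fasta")
    names(aln) <- sub("\\s.*$", "", names(aln))
    if (length(aln) && length(unique(Biostrings::width(aln))) != 1L)
        stop("aligned sequences must all have equal length")
    aln
}

.parseNumericField <- function(x, what, lineno) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x))
    if (length(bad))
        stop(sprintf("non-numeric value '%s' in column %s at line %d",
                     x[bad[1L]], what, lineno[bad[1L]]))
    v
}

#' Read a 12-column tabular homology hit table
#'
#' Accepts the standard tab-separated tabular dialect: one alignment per
#' line with exactly twelve fields (query, subject, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' E-value, bit score). Lines starting with \code{#} are ignored. Any
#' other column count is an error (silently dropping columns would hide
#' upstream misconfiguration), reported with its line number.
#'
#' @param path Path to the tab-separated hit table.
#' @param searchType Which search produced the table; see
#'   \linkS4class{HitTable}.
#' @return A \linkS4class{HitTable}; record order follows file order.
#' @export
readHitTable <- function(path, searchType) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & !grepl("^\\s*$", lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (length(lines) == 0L)
        return(HitTable(emptyHitFrame(), searchType = searchType))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L)) {
        i <- which(nf != 12L)[1L]
        stop(sprintf("expected 12 tab-separated columns, found %d at line %d",
                     nf[i], lineno[i]))
    }
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    df <- data.frame(
        qseqid = m[, 1L], sseqid = m[, 2L],
        pident = .parseNumericField(m[, 3L], "pident", lineno),
        length = as.integer(.parseNumericField(m[, 4L], "length", lineno)),
        mismatch = as.integer(.parseNumericField(m[, 5L], "mismatch", lineno)),
        gapopen = as.integer(.parseNumericField(m[, 6L], "gapopen", lineno)),
        qstart = as.integer(.parseNumericField(m[, 7L], "qstart", lineno)),
        qend = as.integer(.parseNumericField(m[, 8L], "qend", lineno)),
        sstart = as.integer(.parseNumericField(m[, 9L], "sstart", lineno)),
        send = as.integer(.parseNumericField(m[, 10L], "send", lineno)),
        evalue = .parseNumericField(m[, 11L], "evalue", lineno),
        bitscore = .parseNumericField(m[, 12L], "bitscore", lineno),
        stringsAsFactors = FALSE)
    HitTable(df, searchType = searchType)
}

#' Write a HitTable in the 12-column tabular dialect
#'
#' @param hitTable A \linkS4class{HitTable}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeHitTable <- function(hitTable, path) {
    stopifnot(methods::is(hitTable, "HitTable"))
    h <- hitTable@hits
    h$evalue <- formatC(h$evalue, format = "g", digits = 6)
    utils::write.table(h, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a gene catalog TSV
#'
#' The catalog mirrors the layout of a curated target-gene table: one
#' row per gene with its KEGG Orthology id, UniRef cluster id,
#' representative length in kbp (deduced from the UniRef cluster) and
#' functional category. A nonpositive length is rejected naming the
#' offending gene. An optional second TSV supplies the subject-to-gene
#' map (columns \code{subject_id}, \code{gene_name}).
#'
#' @param path Path to a TSV with header columns \code{gene_name,
#'   ko_id, uniref_id, length_kbp, category}.
#' @param subjectMapPath Optional path to the subject-to-gene map TSV.
#' @return A \linkS4class{GeneCatalog}.
#' @export
readGeneCatalog <- function(path, subjectMapPath = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    g <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    need <- c("gene_name", "ko_id", "uniref_id", "length_kbp", "category")
    if (!all(need %in% colnames(g)))
        stop("gene catalog must have columns: ", paste(need, collapse = ", "))
    g$length_kbp <- as.numeric(g$length_kbp)
    sm <- NULL
    if (!is.null(subjectMapPath)) {
        sm <- utils::read.delim(subjectMapPath, stringsAsFactors = FALSE,
                                colClasses = "character")
        if (!all(c("subject_id", "gene_name") %in% colnames(sm)))
            stop("subject map must have columns subject_id, gene_name")
    }
    GeneCatalog(g[, need], subjectMap = sm)
}

#' Write a GeneCatalog to TSV
#'
#' Writes the gene table to \code{path}; the subject map, if non-empty,
#' goes to \code{subjectMapPath}.
#'
#' @param catalog A \linkS4class{GeneCatalog}.
#' @param path Output path for the gene table.
#' @param subjectMapPath Optional output path for the subject map.
#' @return Invisibly, \code{path}.
#' @export
writeGeneCatalog <- function(catalog, path, subjectMapPath = NULL) {
    utils::write.table(catalog@genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(subjectMapPath))
        utils::write.table(catalog@subjectMap, subjectMapPath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    invisible(path)
}

.parseLineage <- function(s, subject) {
    out <- stats::setNames(rep(NA_character_, length(.TAXON_RANKS)),
                           .TAXON_RANKS)
    if (is.na(s) || s == "") return(out)
    toks <- strsplit(s, ";", fixed = TRUE)[[1L]]
    toks <- toks[toks != ""]
    for (tk in toks) {
        kv <- strsplit(tk, ":", fixed = TRUE)[[1L]]
        if (length(kv) != 2L)
            stop(sprintf("malformed lineage token '%s' for subject %s",
                         tk, subject))
        rank <- trimws(kv[1L])
        if (!rank %in% .TAXON_RANKS)
            stop(sprintf("unsupported rank '%s' for subject %s (allowed: %s)",
                         rank, subject, paste(.TAXON_RANKS, collapse = ", ")))
        out[[rank]] <- trimws(kv[2L])
    }
    out
}

#' Read a subject-to-lineage map
#'
#' Two tab-separated columns: subject id, then a semicolon-delimited
#' \code{rank:name} lineage restricted to the canonical ranks (phylum,
#' class, order, family, genus). Duplicated subjects are allowed only if
#' their lineages agree.
#'
#' @param path Path to the TSV (no header).
#' @return A \linkS4class{TaxonMap}.
#' @export
readTaxonMap <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & !grepl("^\\s*$", lines)]
    if (length(lines) == 0L) return(TaxonMap())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 2L))
        stop("taxon map lines must have exactly 2 tab-separated columns")
    subj <- vapply(fields, `[[`, character(1L), 1L)
    lin <- t(mapply(.parseLineage, vapply(fields, `[[`, character(1L), 2L),
                    subj))
    df <- data.frame(subject_id = subj, lin, stringsAsFactors = FALSE,
                     row.names = NULL)
    colnames(df) <- c("subject_id", .TAXON_RANKS)
    if (anyDuplicated(df$subject_id)) {
        key <- apply(df[, .TAXON_RANKS], 1L, paste, collapse = "|")
        conf <- tapply(key, df$subject_id, function(x) length(unique(x)) > 1L)
        if (any(conf))
            stop("conflicting lineages for subject(s): ",
                 paste(names(conf)[conf], collapse = ", "))
        df <- df[!duplicated(df$subject_id), , drop = FALSE]
    }
    TaxonMap(df)
}

#' Write a TaxonMap as a two-column lineage TSV
#'
#' @param taxonMap A \linkS4class{TaxonMap}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTaxonMap <- function(taxonMap, path) {
    l <- taxonMap@lineages
    lin <- apply(l[, .TAXON_RANKS, drop = FALSE], 1L, function(row) {
        keep <- !is.na(row)
        paste(paste(.TAXON_RANKS[keep], row[keep], sep = ":"),
              collapse = ";")
    })
    writeLines(paste(l$subject_id, lin, sep = "\t"), path)
    invisible(path)
}

.newickNode <- function(tree, node, ntips) {
    if (node <= ntips) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    parts <- vapply(kids, function(k) {
        len <- tree$edge.length[which(tree$edge[, 2L] == k)]
        sprintf("%s:%.6f", .newickNode(tree, k, ntips), len)
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
}

#' Serialize a phylogenetic tree to Newick
#'
#' Writes an \code{ape} \code{phylo} tree as a Newick string with branch
#' lengths formatted to six decimal places. The tree must have at least
#' two labelled leaves and nonnegative branch lengths; the output
#' round-trips through \code{ape::read.tree} to an isomorphic tree.
#'
#' @param tree An \code{ape} \code{phylo} object with branch lengths.
#' @param path Output path; \code{NULL} returns the string instead.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, path = NULL) {
    stopifnot(inherits(tree, "phylo"))
    if (length(tree$tip.label) < 2L)
        stop("tree must have at least 2 leaves")
    if (any(is.na(tree$tip.label) | tree$tip.label == ""))
        stop("all leaves must carry non-empty labels")
    if (is.null(tree$edge.length) || any(tree$edge.length < 0))
        stop("tree must have nonnegative branch lengths")
    root <- length(tree$tip.label) + 1L
    s <- paste0(.newickNode(tree, root, length(tree$tip.label)), ";")
    if (is.null(path)) return(s)
    writeLines(s, path)
    invisible(s)
}
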