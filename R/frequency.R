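#' Gene-length-normalized detection frequency per 100,000 reads
#'
#' The pipeline's central statistic. For a gene detected in
#' \code{readCount} reads of a sample of \code{totalReads} reads, the
#' detection frequency is
#' \deqn{(readCount / geneLengthKbp) \times (100000 / totalReads)}
#' i.e. reads per kbp of gene, rescaled to a nominal sample of 1e5
#' reads so that samples of different depth are comparable.
#'
#' @param readCount Nonnegative integer count of reads assigned to the
#'   gene.
#' @param geneLengthKbp Representative gene length in kbp (> 0).
#' @param totalReads Total reads in the sample (> 0).
#' @return Nonnegative numeric frequency; zero iff \code{readCount} is 0.
#' @examples
#' detectionFrequency(7, 1.020, 46605)
#' @export
detectionFrequency <- function(readCount, geneLengthKbp, totalReads) {
    if (any(geneLengthKbp <= 0)) stop("geneLengthKbp must be > 0")
    if (any(totalReads <= 0)) stop("totalReads must be > 0")
    if (any(readCount < 0)) stop("readCount must be >= 0")
    (readCount / geneLengthKbp) * (100000 / totalReads)
}

#' Mean and sample standard deviation across samples
#'
#' @param perSample Numeric vector of per-sample values (>= 2 samples;
#'   the SD uses the n-1 denominator and is undefined for fewer).
#' @return Named list with \code{mean} and \code{sd}.
#' @examples
#' aggregateSamples(c(0.6, 0.7, 0.8))
#' @export
aggregateSamples <- function(perSample) {
    perSample <- as.numeric(perSample)
    if (length(perSample) < 2L)
        stop("at least 2 samples are required for a mean +/- SD summary")
    list(mean = mean(perSample), sd = stats::sd(perSample))
}

#' Per-gene detection-frequency table
#'
#' Combines per-sample gene counts, the catalog's gene lengths and the
#' per-sample read totals into one record per gene: per-sample
#' frequencies plus their cross-sample mean and sample SD. By default
#' the denominator is each sample's raw total read count (host reads
#' included); pass totals computed after host filtering to change that.
#'
#' @param geneCounts data.frame from \code{\link{assignReadsToGenes}}.
#' @param catalog A \linkS4class{GeneCatalog}.
#' @param totalReads Named numeric vector: total reads per sample id.
#' @return data.frame with columns \code{gene_name}, \code{category},
#'   \code{length_kbp}, one \code{freq.<sample>} column per sample,
#'   \code{mean}, \code{sd}, and \code{detected} (any nonzero count).
#' @export
frequencyTable <- function(geneCounts, catalog, totalReads) {
    stopifnot(methods::is(catalog, "GeneCatalog"))
    samples <- sort(unique(geneCounts$sample_id))
    if (is.null(names(totalReads)) || !all(samples %in% names(totalReads)))
        stop("totalReads must be named with every sample id")
    g <- catalog@genes
    out <- g[, c("gene_name", "ko_id", "uniref_id", "category", "length_kbp")]
    freqs <- sapply(samples, function(s) {
        cnt <- geneCounts[geneCounts$sample_id == s, , drop = FALSE]
        n <- cnt$read_count[match(g$gene_name, cnt$gene_name)]
        n[is.na(n)] <- 0L
        detectionFrequency(n, g$length_kbp, totalReads[[s]])
    })
    freqs <- matrix(freqs, nrow = nrow(g),
                    dimnames = list(NULL, paste0("freq.", samples)))
    out <- cbind(out, as.data.frame(freqs))
    if (length(samples) >= 2L) {
        agg <- apply(freqs, 1L, aggregateSamples)
        out$mean <- vapply(agg, `[[`, numeric(1L), "mean")
        out$sd <- vapply(agg, `[[`, numeric(1L), "sd")
    } else {
        out$mean <- as.numeric(freqs[, 1L])
        out$sd <- NA_real_
    }
    out$detected <- rowSums(freqs) > 0
    rownames(out) <- NULL
    out
}

#' Category totals over unrounded member frequencies
#'
#' Sums the unrounded per-sample frequencies of each category's member
#' genes, then summarizes across samples. Means are additive over
#' members; SDs are computed on the summed per-sample totals, never by
#' summing member SDs.
#'
#' @param freqTable data.frame from \code{\link{frequencyTable}}.
#' @return data.frame with \code{category}, per-sample
#'   \code{freq.<sample>} totals, \code{mean}, \code{sd},
#'   \code{detected}.
#' @export
categoryTotals <- function(freqTable) {
    fcols <- grep("^freq\\.", colnames(freqTable), value = TRUE)
    cats <- unique(freqTable$category)
    rows <- lapply(cats, function(cc) {
        sub <- freqTable[freqTable$category == cc, , drop = FALSE]
        tot <- colSums(sub[, fcols, drop = FALSE])
        agg <- if (length(fcols) >= 2L) aggregateSamples(tot)
               else list(mean = unname(tot[1L]), sd = NA_real_)
        df <- data.frame(category = cc, stringsAsFactors = FALSE)
        df[fcols] <- as.list(tot)
        df$mean <- agg$mean
        df$sd <- agg$sd
        df$detected <- any(sub$detected)
        df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

# Round half away from zero (base round() is round-half-even).
.roundHalfAway <- function(x, digits = 0L) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a mean +/- SD frequency for display
#'
#' Display rule of the rendered frequency table: values at or above 1
#' are rounded to the nearest integer (half away from zero); values
#' below 1 keep one decimal place. Undetected genes render as "ND".
#'
#' @param mean,sd Numeric summary of a gene or category.
#' @param detected Logical; \code{FALSE} renders "ND".
#' @return Character scalar like \code{"9+/-6"} (with a plus-minus sign).
#' @export
formatFrequency <- function(mean, sd, detected = TRUE) {
    fmt1 <- function(v) {
        if (abs(v) >= 1) sprintf("%d", as.integer(.roundHalfAway(v)))
        else sprintf("%.1f", .roundHalfAway(v, 1L))
    }
    mapply(function(m, s, d) {
        if (!d) return("ND")
        paste0(fmt1(m), "±", fmt1(s))
    }, mean, sd, detected, USE.NAMES = FALSE)
}

#' Render the frequency table for display
#'
#' Produces the human-readable table (one row per gene, category rows
#' interleaved before their members) with the display rounding of
#' \code{\link{formatFrequency}}; the unrounded values remain available
#' in the inputs and can be written alongside.
#'
#' @param freqTable data.frame from \code{\link{frequencyTable}}.
#' @param catTotals data.frame from \code{\link{categoryTotals}}.
#' @return data.frame with columns \code{row_type} (category/gene),
#'   \code{name}, \code{ko_id}, \code{uniref_id}, \code{length_kbp},
#'   \code{frequency} (formatted).
#' @export
renderFrequencyTable <- function(freqTable, catTotals) {
    rows <- list()
    for (i in seq_len(nrow(catTotals))) {
        cc <- catTotals$category[i]
        rows[[length(rows) + 1L]] <- data.frame(
            row_type = "category", name = cc, ko_id = "", uniref_id = "",
            length_kbp = NA_real_,
            frequency = formatFrequency(catTotals$mean[i], catTotals$sd[i],
                                        catTotals$detected[i]),
            stringsAsFactors = FALSE)
        sub <- freqTable[freqTable$category == cc, , drop = FALSE]
        for (j in seq_len(nrow(sub))) {
            rows[[length(rows) + 1L]] <- data.frame(
                row_type = "gene", name = sub$gene_name[j],
                ko_id = if ("ko_id" %in% colnames(sub)) sub$ko_id[j] else "",
                uniref_id = if ("uniref_id" %in% colnames(sub))
                                sub$uniref_id[j] else "",
                length_kbp = sub$length_kbp[j],
                frequency = formatFrequency(sub$mean[j], sub$sd[j],
                                            sub$detected[j]),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
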