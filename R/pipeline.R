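#' Assemble a pipeline configuration
#'
#' Exactly one of \code{synthetic} (a \linkS4class{SimulationConfig})
#' or \code{inputs} (paths to real data) must be given. Thresholds
#' default to the screening values the pipeline is built around:
#' E-value cutoff 1e-10 for both searches, alignment span > 250 bp and
#' identity > 40\% for the protein-query re-screen.
#'
#' @param synthetic Optional \linkS4class{SimulationConfig}; when set,
#'   all inputs are simulated.
#' @param inputs Optional named list of paths: \code{reads} (named
#'   character vector, one FASTA per sample), \code{nuclHits},
#'   \code{protHits}, \code{catalog}, \code{subjectMap},
#'   \code{taxonMap}, and optionally \code{mdhAlignment},
#'   \code{mdhRoles}.
#' @param outdir Output directory (created if absent).
#' @param evalueCutoff,minHitBp,minIdentity Screening thresholds.
#' @param hostLabel Host clade name for the host filter.
#' @param freqDenominator \code{"raw"} (default; per-sample totals
#'   before host filtering) or \code{"hostFiltered"}.
#' @param nMajor Major taxa per rank in abundance tables.
#' @param rarefactionDepths Optional integer vector of depths;
#'   \code{NULL} picks six depths up to the assigned-read count.
#' @param rarefactionReplicates Subsamples per depth.
#' @param isotope Optional list of two \code{\link{isotopeGroup}}s.
#' @param tTestVariant \code{"welch"} or \code{"student"}.
#' @param writeInputs Write the simulated inputs (FASTA, hit tables,
#'   catalog, taxon map, truth) under \code{outdir/inputs}.
#' @param seed Integer seed for the pipeline's own randomness
#'   (rarefaction); the generator uses the seed in \code{synthetic}.
#' @return A validated config list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(synthetic = NULL, inputs = NULL, outdir,
                           evalueCutoff = 1e-10, minHitBp = 250,
                           minIdentity = 40,
                           hostLabel = "Streptophyta",
                           freqDenominator = c("raw", "hostFiltered"),
                           nMajor = 3L, rarefactionDepths = NULL,
                           rarefactionReplicates = 50L,
                           isotope = NULL,
                           tTestVariant = c("welch", "student"),
                           writeInputs = FALSE, seed = 1L) {
    if (is.null(synthetic) == is.null(inputs))
        stop("exactly one of 'synthetic' or 'inputs' must be given")
    if (!is.null(synthetic)) stopifnot(methods::is(synthetic,
                                                   "SimulationConfig"))
    cfg <- list(synthetic = synthetic, inputs = inputs, outdir = outdir,
                evalueCutoff = evalueCutoff, minHitBp = minHitBp,
                minIdentity = minIdentity, hostLabel = hostLabel,
                freqDenominator = match.arg(freqDenominator),
                nMajor = as.integer(nMajor),
                rarefactionDepths = rarefactionDepths,
                rarefactionReplicates = as.integer(rarefactionReplicates),
                isotope = isotope,
                tTestVariant = match.arg(tTestVariant),
                writeInputs = isTRUE(writeInputs),
                seed = as.integer(seed))
    class(cfg) <- "pipelineConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
             call. = FALSE))
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

.loadRealInputs <- function(inputs) {
    readSets <- mapply(function(p, s) readFasta(p, sampleId = s),
                       inputs$reads, names(inputs$reads), SIMPLIFY = FALSE)
    seqs <- do.call(c, unname(lapply(readSets, function(r) r@sequences)))
    samp <- unlist(lapply(readSets, sampleIds), use.names = FALSE)
    list(reads = ReadSet(seqs, sampleId = samp),
         nucl = readHitTable(inputs$nuclHits, searchType = "nucl_nucl"),
         prot = readHitTable(inputs$protHits,
                             searchType = "prot_translated"),
         catalog = readGeneCatalog(inputs$catalog, inputs$subjectMap),
         taxonMap = readTaxonMap(inputs$taxonMap),
         truth = NULL)
}

#' Run the full profiling pipeline
#'
#' Stage order: (simulate or load inputs) -> host-read filter ->
#' protein-hit screening -> per-sample summaries -> gene assignment ->
#' detection frequencies and category totals -> taxonomy (abundance
#' per rank, rarefaction, gene-by-genus breakdown) -> optional MDH
#' typing -> optional isotope test. All tables are written as TSV under
#' \code{cfg$outdir}, plus a \code{manifest.json} echoing the
#' configuration, thresholds, per-stage status and summary numbers.
#' With a fixed seed the outputs are byte-identical across runs.
#'
#' @param cfg A config from \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the in-memory results and the
#'   manifest.
#' @export
runPipeline <- function(cfg) {
    stopifnot(inherits(cfg, "pipelineConfig"))
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = cfg$seed,
                     thresholds = list(evalueCutoff = cfg$evalueCutoff,
                                       minHitBp = cfg$minHitBp,
                                       minIdentity = cfg$minIdentity,
                                       hostLabel = cfg$hostLabel),
                     freqDenominator = cfg$freqDenominator,
                     stages = list(), warnings = 0L)
    nWarn <- 0L
    withCallingHandlers({
    if (!is.null(cfg$synthetic)) {
        sim <- cfg$synthetic
        refdb <- .stage("simulate", generateReferenceDb(sim))
        simReads <- .stage("simulate", simulateReads(refdb, sim))
        hitTabs <- .stage("simulate",
                          simulateHitTable(simReads, refdb, sim))
        dat <- list(reads = simReads$reads, nucl = hitTabs$nucl,
                    prot = hitTabs$prot, catalog = refdb$catalog,
                    taxonMap = refdb$taxonMap, truth = simReads$truth)
        manifest$stages$simulate <- "ok"
        manifest$simulation <- list(
            nSamples = sim@nSamples, readsPerSample = sim@readsPerSample,
            hostFraction = sim@hostFraction, hitRate = sim@hitRate,
            seed = sim@seed)
        if (cfg$writeInputs) {
            idir <- file.path(cfg$outdir, "inputs")
            dir.create(idir, showWarnings = FALSE)
            for (s in unique(sampleIds(dat$reads))) {
                sel <- sampleIds(dat$reads) == s
                writeFasta(methods::new("ReadSet",
                               sequences = dat$reads@sequences[sel],
                               sampleId = dat$reads@sampleId[sel]),
                           file.path(idir, paste0(s, ".fasta")))
            }
            writeHitTable(dat$nucl, file.path(idir, "nucl_hits.tsv"))
            writeHitTable(dat$prot, file.path(idir, "prot_hits.tsv"))
            writeGeneCatalog(dat$catalog, file.path(idir, "catalog.tsv"),
                             file.path(idir, "subject_map.tsv"))
            writeTaxonMap(dat$taxonMap, file.path(idir, "taxon_map.tsv"))
            .writeTsv(dat$truth, file.path(idir, "truth.tsv"))
        }
    } else {
        dat <- .stage("load", .loadRealInputs(cfg$inputs))
        manifest$stages$load <- "ok"
        manifest$inputDigests <- lapply(
            Filter(function(x) is.character(x) && all(file.exists(x)),
                   cfg$inputs),
            function(p) unname(tools::md5sum(p)))
    }

    hostRes <- .stage("hostFilter",
        filterHostReads(dat$reads, dat$nucl, dat$taxonMap,
                        evalueCutoff = cfg$evalueCutoff,
                        hostLabel = cfg$hostLabel))
    manifest$stages$hostFilter <- "ok"
    manifest$hostFilter <- list(
        input = length(dat$reads@sequences),
        removed = hostRes$removedCount,
        removedFraction = hostRes$removedCount /
            max(1L, length(dat$reads@sequences)))

    screened <- .stage("screen",
        screenHitsBlastx(dat$prot, evalueCutoff = cfg$evalueCutoff))
    manifest$stages$screen <- "ok"

    summaries <- .stage("summary", {
        s <- sampleSummary(dat$reads, screened)
        rbind(s, poolSampleSummaries(s))
    })
    .writeTsv(summaries, file.path(cfg$outdir, "sample_summary.tsv"))
    manifest$stages$summary <- "ok"

    counts <- .stage("assign",
        assignReadsToGenes(hostRes$retained, screened, dat$catalog))
    .writeTsv(counts, file.path(cfg$outdir, "gene_counts.tsv"))
    manifest$stages$assign <- "ok"

    freq <- .stage("frequency", {
        base <- if (cfg$freqDenominator == "raw") dat$reads
                else hostRes$retained
        tot <- table(sampleIds(base))
        totalReads <- stats::setNames(as.numeric(tot), names(tot))
        frequencyTable(counts, dat$catalog, totalReads)
    })
    cats <- .stage("frequency", categoryTotals(freq))
    .writeTsv(freq, file.path(cfg$outdir, "frequency_unrounded.tsv"))
    .writeTsv(cats, file.path(cfg$outdir, "category_totals.tsv"))
    .writeTsv(renderFrequencyTable(freq, cats),
              file.path(cfg$outdir, "frequency_table.tsv"))
    manifest$stages$frequency <- "ok"

    taxa <- .stage("taxonomy",
        assignTaxa(hostRes$retained, screened, dat$taxonMap))
    abundance <- list()
    for (r in taxonRanks()) {
        ab <- .stage("taxonomy",
            relativeAbundance(taxa, rank = r, nMajor = cfg$nMajor))
        abundance[[r]] <- ab
        .writeTsv(ab, file.path(cfg$outdir,
                                sprintf("abundance_%s.tsv", r)))
    }
    nAssigned <- sum(taxa$assigned & !is.na(taxa$genus))
    depths <- cfg$rarefactionDepths
    if (is.null(depths))
        depths <- unique(pmax(1L, floor(seq_len(6L) / 6 * nAssigned)))
    rare <- .stage("taxonomy",
        rarefactionCurve(taxa, depths = depths,
                         replicates = cfg$rarefactionReplicates,
                         seed = cfg$seed, rank = "genus"))
    .writeTsv(rare, file.path(cfg$outdir, "rarefaction.tsv"))
    geneAsg <- .stage("taxonomy", readGeneAssignments(screened,
                                                      dat$catalog))
    .writeTsv(pgptTaxonBreakdown(geneAsg, taxa),
              file.path(cfg$outdir, "gene_by_genus.tsv"))
    manifest$stages$taxonomy <- "ok"

    mdh <- NULL
    if (!is.null(cfg$inputs) && !is.null(cfg$inputs$mdhAlignment)) {
        mdh <- .stage("mdhTyping", {
            aln <- readAlignedFasta(cfg$inputs$mdhAlignment)
            roles <- readRoles(cfg$inputs$mdhRoles)
            typeAll(aln, roles)
        })
        .writeTsv(mdh$calls, file.path(cfg$outdir, "mdh_calls.tsv"))
        manifest$stages$mdhTyping <- "ok"
        manifest$mdhCounts <- as.list(mdh$counts)
    } else manifest$stages$mdhTyping <- "skipped (no alignment supplied)"

    iso <- NULL
    if (!is.null(cfg$isotope)) {
        iso <- .stage("isotope",
            isotopeTTest(cfg$isotope[[1L]], cfg$isotope[[2L]],
                         variant = cfg$tTestVariant))
        .writeTsv(data.frame(group1 = cfg$isotope[[1L]]$label,
                             group2 = cfg$isotope[[2L]]$label,
                             t = iso$t, df = iso$df, p = iso$p,
                             call = iso$call, variant = iso$variant),
                  file.path(cfg$outdir, "isotope_test.tsv"))
        manifest$stages$isotope <- "ok"
    } else manifest$stages$isotope <- "skipped (no isotope data)"
    }, warning = function(w) {
        nWarn <<- nWarn + 1L
        invokeRestart("muffleWarning")
    })

    manifest$warnings <- nWarn
    jsonlite::write_json(manifest,
                         file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(summaries = summaries, geneCounts = counts,
                   frequency = freq, categories = cats,
                   abundance = abundance, rarefaction = rare,
                   taxa = taxa, mdh = mdh, isotope = iso,
                   hostFilter = hostRes, manifest = manifest))
}
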