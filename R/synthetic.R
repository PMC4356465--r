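## Built-in genus lineages used by the generator. Genera outside this
## table get a deterministic synthetic lineage (family "<Genus>aceae").
.GENUS_LINEAGES <- data.frame(
    genus  = c("Mesorhizobium", "Bradyrhizobium", "Streptomyces",
               "Rhizobium", "Sphingomonas", "Methylobacterium",
               "Burkholderia", "Pseudomonas"),
    phylum = c("Proteobacteria", "Proteobacteria", "Actinobacteria",
               "Proteobacteria", "Proteobacteria", "Proteobacteria",
               "Proteobacteria", "Proteobacteria"),
    class  = c("Alphaproteobacteria", "Alphaproteobacteria",
               "Actinobacteria", "Alphaproteobacteria",
               "Alphaproteobacteria", "Alphaproteobacteria",
               "Betaproteobacteria", "Gammaproteobacteria"),
    order  = c("Rhizobiales", "Rhizobiales", "Actinomycetales",
               "Rhizobiales", "Sphingomonadales", "Rhizobiales",
               "Burkholderiales", "Pseudomonadales"),
    family = c("Phyllobacteriaceae", "Bradyrhizobiaceae",
               "Streptomycetaceae", "Rhizobiaceae", "Sphingomonadaceae",
               "Methylobacteriaceae", "Burkholderiaceae",
               "Pseudomonadaceae"),
    stringsAsFactors = FALSE)

.DEFAULT_GENE_WEIGHTS <- c(
    acdS = 1, iaaM = 1, ipdC = 1, gdh = 1, pchB = 1, bglA = 1,
    chiA = 1, proX = 1)

.DEFAULT_GENE_CATEGORIES <- c(
    acdS = "ACC deaminase", iaaM = "IAA", ipdC = "IAA",
    gdh = "Phosphate solubilization", pchB = "Siderophore",
    bglA = "Plant disease suppression",
    chiA = "Plant disease suppression", proX = "Betaine utilization")

.DEFAULT_TAXON_WEIGHTS <- c(
    Mesorhizobium = 14, Bradyrhizobium = 11, Streptomyces = 9,
    Rhizobium = 8, Sphingomonas = 7, Methylobacterium = 5)

.CATEGORY_POOL <- c("Plant disease suppression", "Phosphate solubilization",
                    "Siderophore", "Methanol utilization", "ACC deaminase",
                    "IAA", "Betaine utilization", "Sucrose utilization")

.HOST_SUBJECT <- "host|Streptophyta"

#' Build a SimulationConfig
#'
#' Defaults emulate the study design the pipeline targets: three
#' composite samples, pyrosequencing-scale depth, mean read length 645
#' bp, 2\% host-plant reads, and a 54\% protein-database hit rate.
#'
#' @param nSamples Number of samples (default 3).
#' @param readsPerSample Reads per sample (default 60000, the scale of
#'   a one-region pyrosequencing run).
#' @param readLengthMeanBp,readLengthSdBp Read-length model (defaults
#'   645 and 130 bp; truncated Normal on [100, 1200]).
#' @param hostFraction Host-read probability (default 0.02).
#' @param geneAbundanceWeights Named nonnegative gene weights (default:
#'   eight PGPT genes, equal weights).
#' @param taxonWeights Named nonnegative genus weights (default: six
#'   genera weighted like a root-associated alphaproteobacterial
#'   community).
#' @param hitRate Probability a gene read gets a true protein hit
#'   (default 0.54).
#' @param decoyHitRate Probability a hit-bearing read also gets a
#'   strictly worse decoy hit (default 0.3).
#' @param identityMeanPct,identitySdPct Percent-identity model for true
#'   hits (defaults 75 and 10).
#' @param seed Integer seed (default 1).
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 3L, readsPerSample = 60000L,
                             readLengthMeanBp = 645, readLengthSdBp = 130,
                             hostFraction = 0.02,
                             geneAbundanceWeights = .DEFAULT_GENE_WEIGHTS,
                             taxonWeights = .DEFAULT_TAXON_WEIGHTS,
                             hitRate = 0.54, decoyHitRate = 0.3,
                             identityMeanPct = 75, identitySdPct = 10,
                             seed = 1L) {
    methods::new("SimulationConfig",
        nSamples = as.integer(nSamples),
        readsPerSample = as.integer(readsPerSample),
        readLengthMeanBp = readLengthMeanBp,
        readLengthSdBp = readLengthSdBp,
        hostFraction = hostFraction,
        geneAbundanceWeights = geneAbundanceWeights,
        taxonWeights = taxonWeights,
        hitRate = hitRate, decoyHitRate = decoyHitRate,
        identityMeanPct = identityMeanPct, identitySdPct = identitySdPct,
        seed = as.integer(seed))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.randomAA <- function(n) paste(sample(.AA20, n, replace = TRUE),
                               collapse = "")

.genusLineage <- function(genus) {
    i <- match(genus, .GENUS_LINEAGES$genus)
    if (!is.na(i)) return(.GENUS_LINEAGES[i, c("phylum", "class",
                                               "order", "family")])
    j <- (utils::head(utils::tail(as.integer(charToRaw(genus)), 1L), 1L) %%
          nrow(.GENUS_LINEAGES)) + 1L
    out <- .GENUS_LINEAGES[j, c("phylum", "class", "order", "family")]
    out$family <- paste0(genus, "aceae")
    out
}

#' Generate a mock reference database
#'
#' Produces, deterministically from the config seed, one amino-acid
#' subject per (gene, genus) pair, a gene catalog whose lengths are
#' consistent with the emitted sequences (kbp = 3 x aa / 1000, rounded
#' to 3 decimals), and a subject-to-lineage map that also carries a
#' host-plant subject (lineage containing Streptophyta) for the host
#' filter.
#'
#' @param cfg A \linkS4class{SimulationConfig}.
#' @return List with \code{catalog} (\linkS4class{GeneCatalog}),
#'   \code{proteins} (\linkS4class{AAStringSet}), \code{taxonMap}
#'   (\linkS4class{TaxonMap}) and \code{hostSubject} (its id).
#' @export
generateReferenceDb <- function(cfg) {
    stopifnot(methods::is(cfg, "SimulationConfig"))
    methods::validObject(cfg)
    set.seed(cfg@seed)
    genes <- names(cfg@geneAbundanceWeights)
    genera <- names(cfg@taxonWeights)
    aaLen <- stats::setNames(sample(150:600, length(genes), replace = TRUE),
                             genes)
    cat <- data.frame(
        gene_name = genes,
        ko_id = sprintf("K%05d", seq_along(genes)),
        uniref_id = sprintf("UniRef50_SYN%04d", seq_along(genes)),
        length_kbp = round(3 * aaLen / 1000, 3L),
        category = ifelse(genes %in% names(.DEFAULT_GENE_CATEGORIES),
                          .DEFAULT_GENE_CATEGORIES[genes],
                          .CATEGORY_POOL[(seq_along(genes) - 1L) %%
                                         length(.CATEGORY_POOL) + 1L]),
        stringsAsFactors = FALSE)
    grid <- expand.grid(gene = genes, genus = genera,
                        stringsAsFactors = FALSE)
    subj <- paste(grid$gene, grid$genus, sep = "|")
    seqs <- vapply(grid$gene, function(g) .randomAA(aaLen[[g]]),
                   character(1L))
    proteins <- Biostrings::AAStringSet(stats::setNames(seqs, subj))
    sm <- data.frame(subject_id = subj, gene_name = grid$gene,
                     stringsAsFactors = FALSE)
    lin <- do.call(rbind, lapply(grid$genus, .genusLineage))
    tm <- data.frame(subject_id = subj, lin, genus = grid$genus,
                     stringsAsFactors = FALSE, row.names = NULL)
    tm <- rbind(tm, data.frame(subject_id = .HOST_SUBJECT,
                               phylum = "Streptophyta",
                               class = NA_character_, order = NA_character_,
                               family = "Amaranthaceae", genus = "Beta",
                               stringsAsFactors = FALSE))
    list(catalog = GeneCatalog(cat, subjectMap = sm),
         proteins = proteins,
         taxonMap = TaxonMap(tm),
         hostSubject = .HOST_SUBJECT)
}

.truncNorm <- function(n, mean, sd, lo, hi) {
    if (n == 0L) return(numeric())
    if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
    out <- stats::rnorm(n, mean, sd)
    bad <- which(out < lo | out > hi)
    while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), mean, sd)
        bad <- bad[out[bad] < lo | out[bad] > hi]
    }
    out
}

#' Simulate reads with truth labels
#'
#' Per sample, each read is of host-plant origin with probability
#' \code{hostFraction}, otherwise it originates from a (gene, genus)
#' pair drawn from the config weights. Lengths follow a truncated
#' Normal on [100, 1200] bp; sequence content is random nucleotides
#' (the pipeline consumes hit tables, not alignments). Deterministic
#' given the config seed.
#'
#' @param refdb Output of \code{\link{generateReferenceDb}}.
#' @param cfg A \linkS4class{SimulationConfig}.
#' @return List with \code{reads} (a multi-sample
#'   \linkS4class{ReadSet}) and \code{truth} (data.frame with
#'   \code{read_id}, \code{sample_id}, \code{origin} in
#'   \{gene, host\}, \code{origin_gene}, \code{origin_genus},
#'   \code{origin_subject}).
#' @export
simulateReads <- function(refdb, cfg) {
    stopifnot(methods::is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 1L)
    nS <- cfg@nSamples
    n <- cfg@readsPerSample
    gW <- cfg@geneAbundanceWeights / sum(cfg@geneAbundanceWeights)
    tW <- cfg@taxonWeights / sum(cfg@taxonWeights)
    allSeqs <- character()
    allIds <- character()
    allSamp <- character()
    truth <- vector("list", nS)
    for (s in seq_len(nS)) {
        sid <- sprintf("S%d", s)
        if (n == 0L) {
            truth[[s]] <- data.frame(read_id = character(),
                                     sample_id = character(),
                                     origin = character(),
                                     origin_gene = character(),
                                     origin_genus = character(),
                                     origin_subject = character(),
                                     stringsAsFactors = FALSE)
            next
        }
        ids <- sprintf("%s_R%06d", sid, seq_len(n))
        isHost <- stats::runif(n) < cfg@hostFraction
        gene <- rep(NA_character_, n)
        genus <- rep(NA_character_, n)
        ng <- sum(!isHost)
        gene[!isHost] <- sample(names(gW), ng, replace = TRUE, prob = gW)
        genus[!isHost] <- sample(names(tW), ng, replace = TRUE, prob = tW)
        len <- as.integer(round(.truncNorm(n, cfg@readLengthMeanBp,
                                           cfg@readLengthSdBp, 100, 1200)))
        big <- paste(sample(c("A", "C", "G", "T"), sum(len), replace = TRUE),
                     collapse = "")
        ends <- cumsum(len)
        starts <- ends - len + 1L
        seqs <- substring(big, starts, ends)
        allSeqs <- c(allSeqs, seqs)
        allIds <- c(allIds, ids)
        allSamp <- c(allSamp, rep(sid, n))
        truth[[s]] <- data.frame(
            read_id = ids, sample_id = sid,
            origin = ifelse(isHost, "host", "gene"),
            origin_gene = gene, origin_genus = genus,
            origin_subject = ifelse(isHost, refdb$hostSubject,
                                    paste(gene, genus, sep = "|")),
            stringsAsFactors = FALSE)
    }
    reads <- ReadSet(Biostrings::DNAStringSet(
                         stats::setNames(allSeqs, allIds)),
                     sampleId = allSamp)
    list(reads = reads, truth = do.call(rbind, truth))
}

# Bit score as a strictly decreasing function of the E-value.
.bitFromEvalue <- function(evalue) round(30 - 1.8 * log10(evalue), 1L)

#' Simulate hit tables consistent with the truth labels
#'
#' Gene-origin reads receive, with probability \code{hitRate}, a
#' true-origin protein-search hit (E-value log-uniform on
#' [1e-60, 1e-12], identity Normal clipped to [20, 100], alignment
#' length about a third of the read length); with probability
#' \code{decoyHitRate} a hit-bearing read also gets a decoy hit to a
#' random other subject with a strictly larger E-value and strictly
#' lower bit score, so best-hit selection always recovers the true
#' origin. Host reads receive a nucleotide-search hit to the host
#' subject. Bit scores decrease strictly in E-value within every read.
#'
#' @param simReads Output of \code{\link{simulateReads}}.
#' @param refdb Output of \code{\link{generateReferenceDb}}.
#' @param cfg A \linkS4class{SimulationConfig}.
#' @return List with \code{prot} (a \code{prot_translated}
#'   \linkS4class{HitTable} over all samples) and \code{nucl} (a
#'   \code{nucl_nucl} \linkS4class{HitTable}).
#' @export
simulateHitTable <- function(simReads, refdb, cfg) {
    stopifnot(methods::is(cfg, "SimulationConfig"))
    set.seed(cfg@seed + 2L)
    truth <- simReads$truth
    lens <- readLengths(simReads$reads)
    subjects <- names(refdb$proteins)
    mkRow <- function(qid, sid, pident, alen, evalue) {
        data.frame(qseqid = qid, sseqid = sid, pident = pident,
                   length = alen, mismatch = as.integer(
                       round(alen * (1 - pident / 100))),
                   gapopen = 0L, qstart = 1L, qend = alen * 3L,
                   sstart = 1L, send = alen,
                   evalue = evalue, bitscore = .bitFromEvalue(evalue),
                   stringsAsFactors = FALSE)
    }
    gidx <- which(truth$origin == "gene")
    hasHit <- gidx[stats::runif(length(gidx)) < cfg@hitRate]
    prot <- emptyHitFrame()
    if (length(hasHit)) {
        rl <- as.integer(lens[truth$read_id[hasHit]])
        alen <- pmax(1L, rl %/% 3L)
        ev <- 10^stats::runif(length(hasHit), -60, -12)
        pid <- pmin(100, pmax(20, stats::rnorm(length(hasHit),
                                               cfg@identityMeanPct,
                                               cfg@identitySdPct)))
        prot <- mkRow(truth$read_id[hasHit], truth$origin_subject[hasHit],
                      pid, alen, ev)
        hasDecoy <- which(stats::runif(length(hasHit)) < cfg@decoyHitRate)
        if (length(hasDecoy)) {
            tsub <- truth$origin_subject[hasHit[hasDecoy]]
            dsub <- vapply(tsub, function(ss) {
                pool <- subjects[subjects != ss]
                pool[sample.int(length(pool), 1L)]
            }, character(1L), USE.NAMES = FALSE)
            dev <- ev[hasDecoy] * 10^stats::runif(length(hasDecoy), 2, 10)
            dpid <- pmin(100, pmax(0, pid[hasDecoy] -
                                          stats::runif(length(hasDecoy),
                                                       5, 25)))
            prot <- rbind(prot, mkRow(truth$read_id[hasHit[hasDecoy]],
                                      dsub, dpid, alen[hasDecoy], dev))
        }
    }
    hidx <- which(truth$origin == "host")
    nucl <- emptyHitFrame()
    if (length(hidx)) {
        rl <- as.integer(lens[truth$read_id[hidx]])
        ev <- 10^stats::runif(length(hidx), -60, -20)
        pid <- pmin(100, pmax(80, stats::rnorm(length(hidx), 96, 2)))
        nucl <- data.frame(qseqid = truth$read_id[hidx],
                           sseqid = refdb$hostSubject, pident = pid,
                           length = rl, mismatch = as.integer(
                               round(rl * (1 - pid / 100))),
                           gapopen = 0L, qstart = 1L, qend = rl,
                           sstart = 1L, send = rl, evalue = ev,
                           bitscore = .bitFromEvalue(ev),
                           stringsAsFactors = FALSE)
    }
    list(prot = HitTable(prot, searchType = "prot_translated"),
         nucl = HitTable(nucl, searchType = "nucl_nucl"))
}

.mutateAA <- function(seq, rate) {
    ch <- strsplit(seq, "")[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(.AA20, ch[i]), 1L)
    paste(ch, collapse = "")
}

#' Simulate an aligned set for phylogenetic MDH typing
#'
#' Builds two reference clusters (xoxF-like and mxaF-like) as mutated
#' copies of a common ancestor, an unrelated random outgroup, and
#' queries that are either mutated copies of a reference of the chosen
#' type or fully random sequences (which should land basally and be
#' called undetermined).
#'
#' @param nRefsPerType References per type (default 3).
#' @param nQueries Number of query sequences.
#' @param queryType \code{"xoxF"}, \code{"mxaF"} or \code{"random"}.
#' @param queryDivergence Per-site mutation rate applied to the source
#'   reference when deriving a query (default 0.1).
#' @param typeDivergence Per-site rate separating each type from the
#'   common ancestor (default 0.2, so the two types sit ~0.35 apart).
#' @param refNoise Per-site rate among references of one type
#'   (default 0.05).
#' @param alnLength Alignment length in residues (default 200).
#' @param seed Integer seed.
#' @return List with \code{aln} (named character vector of aligned
#'   sequences) and \code{roles} (label -> role).
#' @export
simulateTypingAlignment <- function(nRefsPerType = 3L, nQueries = 1L,
                                    queryType = c("xoxF", "mxaF", "random"),
                                    queryDivergence = 0.1,
                                    typeDivergence = 0.2,
                                    refNoise = 0.05,
                                    alnLength = 200L, seed = 1L) {
    queryType <- match.arg(queryType)
    set.seed(seed)
    anc <- .randomAA(alnLength)
    xAnc <- .mutateAA(anc, typeDivergence)
    mAnc <- .mutateAA(anc, typeDivergence)
    refs <- character()
    roles <- character()
    for (i in seq_len(nRefsPerType)) {
        refs[[sprintf("xoxF_ref%d", i)]] <- .mutateAA(xAnc, refNoise)
        roles[[sprintf("xoxF_ref%d", i)]] <- "ref_xoxF"
        refs[[sprintf("mxaF_ref%d", i)]] <- .mutateAA(mAnc, refNoise)
        roles[[sprintf("mxaF_ref%d", i)]] <- "ref_mxaF"
    }
    refs[["outgroup1"]] <- .randomAA(alnLength)
    roles[["outgroup1"]] <- "outgroup"
    for (i in seq_len(nQueries)) {
        lab <- sprintf("query%d", i)
        refs[[lab]] <- switch(queryType,
            xoxF = .mutateAA(refs[[sprintf("xoxF_ref%d",
                       (i - 1L) %% nRefsPerType + 1L)]], queryDivergence),
            mxaF = .mutateAA(refs[[sprintf("mxaF_ref%d",
                       (i - 1L) %% nRefsPerType + 1L)]], queryDivergence),
            random = .randomAA(alnLength))
        roles[[lab]] <- "query"
    }
    list(aln = unlist(refs), roles = unlist(roles))
}
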