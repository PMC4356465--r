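mkHits <- function(..., searchType = "prot_translated") {
    rows <- list(...)
    df <- do.call(rbind, lapply(rows, function(r) {
        data.frame(qseqid = r$q, sseqid = r$s,
                   pident = if (is.null(r$pid)) 90 else r$pid,
                   length = if (is.null(r$len)) 100L else as.integer(r$len),
                   mismatch = 5L, gapopen = 0L, qstart = 1L, qend = 300L,
                   sstart = 1L, send = 100L, evalue = r$e,
                   bitscore = r$b, stringsAsFactors = FALSE)
    }))
    HitTable(df, searchType = searchType)
}

test_that("bestHit maximizes bitscore with the documented tie-breaks", {
    expect_null(bestHit(NULL))
    expect_null(bestHit(emptyHitFrame()))

    ht <- mkHits(list(q = "r1", s = "a", e = 1e-30, b = 180),
                 list(q = "r1", s = "b", e = 1e-50, b = 90))
    expect_equal(bestHit(hits(ht))$bitscore, 180)

    # equal bitscore: lower evalue wins regardless of subject order
    tie <- mkHits(list(q = "r1", s = "b", e = 1e-20, b = 100),
                  list(q = "r1", s = "a", e = 1e-30, b = 100))
    expect_equal(bestHit(hits(tie))$evalue, 1e-30)
    expect_equal(bestHit(hits(tie))$sseqid, "a")

    # full tie: smallest subject id
    tie2 <- mkHits(list(q = "r1", s = "b", e = 1e-20, b = 100),
                   list(q = "r1", s = "a", e = 1e-20, b = 100))
    expect_equal(bestHit(hits(tie2))$sseqid, "a")

    mixed <- mkHits(list(q = "r1", s = "a", e = 1e-20, b = 100),
                    list(q = "r2", s = "a", e = 1e-20, b = 100))
    expect_error(bestHit(hits(mixed)), "single query")
})

test_that("bestHit agrees with brute-force enumeration of the tie-break order", {
    set.seed(9)
    for (i in 1:20) {
        n <- sample(2:6, 1L)
        df <- data.frame(qseqid = "q", sseqid = sample(letters[1:3], n, TRUE),
                         pident = 90, length = 100L, mismatch = 0L,
                         gapopen = 0L, qstart = 1L, qend = 300L, sstart = 1L,
                         send = 100L,
                         evalue = sample(c(1e-10, 1e-20, 1e-30), n, TRUE),
                         bitscore = sample(c(50, 100), n, TRUE),
                         stringsAsFactors = FALSE)
        # oracle: scan all rows keeping the winner under the stated order
        best <- 1L
        for (j in seq_len(n)[-1L]) {
            b <- df[best, ]; c2 <- df[j, ]
            better <- c2$bitscore > b$bitscore ||
                (c2$bitscore == b$bitscore && c2$evalue < b$evalue) ||
                (c2$bitscore == b$bitscore && c2$evalue == b$evalue &&
                 c2$sseqid < b$sseqid)
            if (better) best <- j
        }
        expect_equal(bestHit(df), df[best, , drop = FALSE],
                     ignore_attr = TRUE)
    }
})

test_that("host filtering removes exactly best-hit host reads", {
    reads <- ReadSet(c(r1 = "ACGTACGT", r2 = "ACGTACGTAA",
                       r3 = "ACGTACGTCC"), sampleId = "S1")
    tm <- TaxonMap(data.frame(
        subject_id = c("chloro", "bact"),
        phylum = c("Streptophyta", "Proteobacteria"),
        genus = c("Beta", "Rhizobium")))

    noHits <- HitTable(emptyHitFrame(), searchType = "nucl_nucl")
    res <- filterHostReads(reads, noHits, tm)
    expect_equal(res$removedCount, 0L)
    expect_equal(length(readIds(res$retained)), 3L)

    ht <- mkHits(list(q = "r1", s = "chloro", e = 1e-40, b = 200),
                 list(q = "r2", s = "chloro", e = 1e-40, b = 50),
                 list(q = "r2", s = "bact", e = 1e-60, b = 200),
                 searchType = "nucl_nucl")
    res2 <- filterHostReads(reads, ht, tm)
    expect_equal(res2$removedIds, "r1")     # r2's best hit is bacterial
    expect_equal(res2$removedCount + length(readIds(res2$retained)), 3L)

    # hits at or above the cutoff never count
    weak <- mkHits(list(q = "r1", s = "chloro", e = 1e-10, b = 200),
                   searchType = "nucl_nucl")
    expect_equal(filterHostReads(reads, weak, tm)$removedCount, 0L)
})

test_that("E-value screening is strict at the cutoff", {
    ht <- mkHits(list(q = "r1", s = "a", e = 1e-10, b = 100),
                 list(q = "r2", s = "a", e = 1e-11, b = 100),
                 list(q = "r3", s = "a", e = 1e-9, b = 100),
                 list(q = "r4", s = "a", e = 1e-30, b = 100),
                 list(q = "r5", s = "a", e = 0.001, b = 100))
    out <- hits(screenHitsBlastx(ht))
    expect_equal(out$qseqid, c("r2", "r4"))  # exactly-at-cutoff rejected
})

test_that("protein-query re-screen applies all three strict thresholds", {
    ht <- mkHits(list(q = "r1", s = "a", e = 1e-12, b = 100, pid = 40.0,
                      len = 100),
                 list(q = "r2", s = "a", e = 1e-12, b = 100, pid = 45,
                      len = 84),
                 list(q = "r3", s = "a", e = 1e-30, b = 100, pid = 90,
                      len = 83),
                 searchType = "translated_prot")
    out <- hits(screenHitsTblastn(ht))
    # identity 40 fails >40; 84 aa = 252 bp passes >250; 83 aa = 249 fails
    expect_equal(out$qseqid, "r2")
})

test_that("screening is monotone in its thresholds", {
    set.seed(13)
    n <- 200L
    df <- data.frame(qseqid = sprintf("r%03d", 1:n), sseqid = "s",
                     pident = runif(n, 20, 100),
                     length = sample(50:150, n, TRUE), mismatch = 0L,
                     gapopen = 0L, qstart = 1L, qend = 1L, sstart = 1L,
                     send = 1L, evalue = 10^runif(n, -40, -5),
                     bitscore = runif(n, 50, 200), stringsAsFactors = FALSE)
    ht <- HitTable(df, searchType = "translated_prot")
    loose <- hits(screenHitsTblastn(ht, 1e-8, 200, 30))$qseqid
    for (args in list(list(1e-12, 200, 30), list(1e-8, 300, 30),
                      list(1e-8, 200, 60))) {
        tight <- hits(screenHitsTblastn(ht, args[[1]], args[[2]],
                                        args[[3]]))$qseqid
        expect_true(all(tight %in% loose))
    }
})

test_that("gene assignment counts each read once for its best hit", {
    catalog <- GeneCatalog(
        data.frame(gene_name = c("A", "B"), ko_id = "", uniref_id = "",
                   length_kbp = 1, category = "X"),
        subjectMap = data.frame(subject_id = c("sA", "sB"),
                                gene_name = c("A", "B")))
    reads <- ReadSet(setNames(rep("ACGT", 5), paste0("r", 1:5)),
                     sampleId = "S1")

    none <- assignReadsToGenes(reads,
        HitTable(emptyHitFrame(), "prot_translated"), catalog)
    expect_true(all(none$read_count == 0L))

    ht <- mkHits(list(q = "r1", s = "sA", e = 1e-20, b = 100),
                 list(q = "r2", s = "sA", e = 1e-20, b = 100),
                 list(q = "r3", s = "sA", e = 1e-20, b = 100),
                 list(q = "r4", s = "sB", e = 1e-20, b = 100),
                 list(q = "r5", s = "sB", e = 1e-20, b = 100),
                 list(q = "r5", s = "sA", e = 1e-25, b = 150))
    cnt <- assignReadsToGenes(reads, ht, catalog)
    expect_equal(cnt$read_count[cnt$gene_name == "A"], 4L)  # r5 via best hit
    expect_equal(cnt$read_count[cnt$gene_name == "B"], 1L)
    expect_lte(sum(cnt$read_count), length(unique(hits(ht)$qseqid)))

    # equal-bitscore tie resolved exactly as bestHit resolves it
    tie <- mkHits(list(q = "r1", s = "sB", e = 1e-20, b = 100),
                  list(q = "r1", s = "sA", e = 1e-20, b = 100))
    cntTie <- assignReadsToGenes(reads, tie, catalog)
    pick <- bestHit(hits(tie))$sseqid
    expect_equal(cntTie$read_count[cntTie$gene_name == "A"],
                 as.integer(pick == "sA"))
})

test_that("assignment recovers all hit-bearing gene reads despite decoys", {
    cfg <- simulationConfig(nSamples = 1L, readsPerSample = 3000L,
                            hostFraction = 0, decoyHitRate = 0.8, seed = 21L)
    db <- generateReferenceDb(cfg)
    sim <- simulateReads(db, cfg)
    ht <- simulateHitTable(sim, db, cfg)
    screened <- screenHitsBlastx(ht$prot)
    asg <- readGeneAssignments(screened, db$catalog)
    truthGene <- setNames(sim$truth$origin_gene, sim$truth$read_id)
    expect_equal(asg$gene_name, unname(truthGene[asg$read_id]))
    expect_equal(nrow(asg), length(unique(hits(screened)$qseqid)))
})

test_that("sample summaries use floor division and count hit-bearing reads", {
    reads <- ReadSet(c(r1 = "ACGTACGTAC", r2 = "ACGTACG", r3 = "ACG"),
                     sampleId = "S1")
    ht <- mkHits(list(q = "r1", s = "a", e = 1e-20, b = 100),
                 list(q = "r1", s = "b", e = 1e-22, b = 110),
                 list(q = "r3", s = "a", e = 1e-20, b = 100))
    s <- sampleSummary(reads, ht)
    expect_equal(s$total_reads, 3L)
    expect_equal(s$total_bp, 20)
    expect_equal(s$avg_length_bp, floor(20 / 3))
    expect_equal(s$reads_with_similarity, 2L)

    s0 <- sampleSummary(ReadSet(Biostrings::DNAStringSet(), character()))
    expect_equal(nrow(s0), 0L)
})

test_that("summaryFromTotals and pooling reproduce floor-average lengths", {
    rows <- rbind(summaryFromTotals("NPK9", 46605, 29467018, 25914),
                  summaryFromTotals("NPK10", 57341, 37031295, 31528),
                  summaryFromTotals("NPK12", 79808, 52179838, 42611))
    expect_equal(rows$avg_length_bp, c(632, 645, 653))
    pooled <- poolSampleSummaries(rows)
    expect_equal(pooled$total_reads, 183754)
    expect_equal(pooled$total_bp, 118678151)
    expect_equal(pooled$avg_length_bp, 645)
})
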