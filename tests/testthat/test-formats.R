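writeTmp <- function(lines, ext = ".txt") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

test_that("readFasta parses records, tokenizes ids and computes lengths", {
    p <- writeTmp(c(">r1 some description text", "ACGTACGTAC",
                    ">r2", "ACGT", "ACGTACGTACGTACGT"), ".fasta")
    rs <- readFasta(p, sampleId = "S1")
    expect_equal(readIds(rs), c("r1", "r2"))
    expect_equal(unname(readLengths(rs)), c(10L, 20L))
    expect_equal(unique(sampleIds(rs)), "S1")

    empty <- writeTmp(character(), ".fasta")
    expect_equal(length(readIds(readFasta(empty))), 0L)
})

test_that("readFasta rejects duplicates and sequence before header", {
    p <- writeTmp(c(">r1", "ACGT", ">r1 again", "GGGG"), ".fasta")
    expect_error(readFasta(p), "r1")
    p2 <- writeTmp(c("ACGT", ">r1", "ACGT"), ".fasta")
    expect_error(readFasta(p2), "line 1")
})

test_that("FASTA writing round-trips reads", {
    rs <- ReadSet(c(a = "ACGTAC", b = "TTTTGGGGCC"), sampleId = "S1")
    p <- tempfile(fileext = ".fasta")
    writeFasta(rs, p)
    back <- readFasta(p, sampleId = "S1")
    expect_equal(readIds(back), readIds(rs))
    expect_equal(as.character(back@sequences), as.character(rs@sequences))
})

test_that("readHitTable maps the 12 tabular fields and keeps order", {
    p <- writeTmp(c("# a comment",
                    "r1\tg7\t91.2\t100\t8\t1\t1\t300\t5\t104\t1e-40\t180",
                    "r2\tg1\t80\t50\t10\t0\t1\t150\t1\t50\t1e-20\t90",
                    "r3\tg2\t70.5\t60\t17\t2\t1\t180\t1\t60\t1e-15\t75"))
    ht <- readHitTable(p, searchType = "prot_translated")
    h <- hits(ht)
    expect_equal(nrow(h), 3L)
    expect_equal(h$qseqid, c("r1", "r2", "r3"))
    expect_equal(h$evalue[1L], 1e-40)
    expect_equal(h$bitscore[1L], 180)
    expect_equal(h$pident[1L], 91.2)
    expect_equal(h$send[1L], 104L)

    onlyComments <- writeTmp(c("# x", "# y"))
    expect_equal(nrow(hits(readHitTable(onlyComments, "nucl_nucl"))), 0L)
})

test_that("readHitTable reports malformed lines with line numbers", {
    p <- writeTmp(c("r1\tg7\t91.2\t100\t8\t1\t1\t300\t5\t104\t1e-40\t180",
                    "r2\tg1\tbroken"))
    expect_error(readHitTable(p, "nucl_nucl"), "line 2")
    p2 <- writeTmp("r1\tg7\tNOTNUM\t100\t8\t1\t1\t300\t5\t104\t1e-40\t180")
    expect_error(readHitTable(p2, "nucl_nucl"), "pident")
    # extra columns are an error, never silently dropped
    p3 <- writeTmp(paste(c("r1", "g7", "91.2", 100, 8, 1, 1, 300, 5, 104,
                           "1e-40", 180, "extra"), collapse = "\t"))
    expect_error(readHitTable(p3, "nucl_nucl"), "13")
})

test_that("hit tables round-trip through write and read", {
    set.seed(42)
    n <- 25L
    df <- data.frame(
        qseqid = sprintf("r%02d", sample.int(15L, n, replace = TRUE)),
        sseqid = sprintf("g%d", sample.int(6L, n, replace = TRUE)),
        pident = round(runif(n, 20, 100), 2),
        length = sample.int(300L, n), mismatch = sample.int(40L, n),
        gapopen = sample(0:3, n, replace = TRUE),
        qstart = sample.int(100L, n), qend = sample.int(900L, n),
        sstart = sample.int(100L, n), send = sample.int(500L, n),
        evalue = 10^runif(n, -60, -5), bitscore = round(runif(n, 40, 300), 1),
        stringsAsFactors = FALSE)
    ht <- HitTable(df, searchType = "prot_translated")
    p <- tempfile(fileext = ".tsv")
    writeHitTable(ht, p)
    back <- hits(readHitTable(p, "prot_translated"))
    expect_equal(back$qseqid, df$qseqid)
    expect_equal(back$evalue, df$evalue, tolerance = 1e-6)
    expect_equal(back$bitscore, df$bitscore)
    expect_equal(back$send, df$send)
})

test_that("gene catalog parsing validates lengths and fields", {
    p <- writeTmp(c("gene_name\tko_id\tuniref_id\tlength_kbp\tcategory",
                    "GDH\tK00117\tUniRef50_P27175\t2.427\tPhosphate solubilization",
                    "ACC deaminase\tK01505\tUniRef50_A5EJ46\t1.020\tACC deaminase"))
    cat <- readGeneCatalog(p)
    g <- geneInfo(cat)
    expect_equal(g$length_kbp[g$gene_name == "GDH"], 2.427)
    expect_equal(g$ko_id[g$gene_name == "GDH"], "K00117")
    expect_equal(g$uniref_id[g$gene_name == "GDH"], "UniRef50_P27175")
    expect_equal(g$length_kbp[g$gene_name == "ACC deaminase"], 1.020)

    bad <- writeTmp(c("gene_name\tko_id\tuniref_id\tlength_kbp\tcategory",
                      "broken\tK1\tU1\t0\tX"))
    expect_error(readGeneCatalog(bad), "broken")
})

test_that("taxon map parsing enforces the canonical rank set", {
    p <- writeTmp(
        "g7\tphylum:Proteobacteria;class:Alphaproteobacteria;genus:Bradyrhizobium")
    tm <- readTaxonMap(p)
    l <- lineages(tm)
    expect_equal(nrow(l), 1L)
    expect_equal(l$phylum, "Proteobacteria")
    expect_equal(l$genus, "Bradyrhizobium")
    expect_true(is.na(l$order))

    expect_equal(nrow(lineages(readTaxonMap(writeTmp(character())))), 0L)
    expect_error(readTaxonMap(writeTmp("g1\tspecies:Foo")), "species")
    expect_error(readTaxonMap(writeTmp(c("g1\tgenus:A", "g1\tgenus:B"))),
                 "conflicting")
    # identical duplicates are tolerated and deduplicated
    tm2 <- readTaxonMap(writeTmp(c("g1\tgenus:A", "g1\tgenus:A")))
    expect_equal(nrow(lineages(tm2)), 1L)
})

test_that("taxon map round-trips through write and read", {
    tm <- TaxonMap(data.frame(subject_id = c("s1", "s2"),
                              phylum = c("Proteobacteria", NA),
                              genus = c("Rhizobium", "Streptomyces")))
    p <- tempfile(fileext = ".tsv")
    writeTaxonMap(tm, p)
    expect_equal(lineages(readTaxonMap(p)), lineages(tm))
})

test_that("writeNewick emits fixed six-decimal branch lengths", {
    tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
    expect_equal(writeNewick(tr), "(A:0.100000,B:0.200000);")

    bad <- ape::read.tree(text = "(A:0.1,:0.2);")
    expect_error(writeNewick(bad), "label")
})

test_that("newick serialization round-trips to an isomorphic tree", {
    set.seed(7)
    for (i in 1:5) {
        tr <- ape::rtree(sample(4:10, 1L))
        tr$edge.length <- round(tr$edge.length, 6L)  # serializer precision
        p <- tempfile(fileext = ".nwk")
        writeNewick(tr, p)
        back <- ape::read.tree(p)
        expect_setequal(back$tip.label, tr$tip.label)
        d1 <- cophenetic(tr)
        d2 <- cophenetic(back)[rownames(d1), colnames(d1)]
        expect_lt(max(abs(d1 - d2)), 1e-6)
    }
})
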