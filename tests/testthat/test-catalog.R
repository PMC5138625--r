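test_that("GTF coordinates import as 1-based inclusive ranges and round-trip", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste(
    c("chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";",
      "chr1\tsrc\texon\t301\t450\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"),
    collapse = "\n"), gtf)
  cat1 <- readTranscriptGTF(gtf)
  ex <- exonsByTx(cat1)[["t1"]]
  expect_equal(start(ex), c(101, 301))
  expect_equal(width(ex), c(100, 150))

  out <- tempfile(fileext = ".gtf")
  writeTranscriptGTF(cat1, out)
  back <- readTranscriptGTF(out)
  expect_identical(txIds(back), txIds(cat1))
  expect_identical(geneIds(back), geneIds(cat1))
  expect_equal(as.data.frame(unlist(exonsByTx(back)))[1:4],
               as.data.frame(unlist(exonsByTx(cat1)))[1:4])
})

test_that("exon lines are reassembled per transcript regardless of order", {
  sim <- defaultSim()
  f <- tempfile(fileext = ".gtf")
  writeTranscriptGTF(sim$catalog, f)
  ## text oracle: transcript count = unique transcript_id attributes
  lines <- grep('transcript_id "', readLines(f), fixed = TRUE, value = TRUE)
  ids <- unique(sub('.*transcript_id "([^"]+)".*', "\\1", lines))
  expect_equal(length(sim$catalog), length(ids))
  ## shuffle exon lines: same catalog
  shuf <- tempfile(fileext = ".gtf")
  writeLines(sample(lines), shuf)
  back <- readTranscriptGTF(shuf)
  expect_setequal(txIds(back), txIds(sim$catalog))
  i <- txIds(sim$catalog)[7]
  expect_equal(start(exonsByTx(back)[[i]]), start(exonsByTx(sim$catalog)[[i]]))
})

test_that("malformed GTF input is rejected with informative errors", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id \"g1\";", gtf)
  expect_error(readTranscriptGTF(gtf), "transcript_id")
  ## overlapping exons within one transcript
  bad <- GRangesList(t1 = GRanges("chr1", IRanges(c(1, 50), c(100, 160)), "+"))
  expect_error(TranscriptCatalog(bad, geneIds = "g1"), "overlap")
})

test_that("transcript statistics report spliced length, not genomic span", {
  gr <- GRangesList(
    t1 = GRanges("chr1", IRanges(c(101, 301), c(200, 450)), "+"),
    t2 = GRanges("chr1", IRanges(1, 200), "-"))
  cat1 <- TranscriptCatalog(gr, geneIds = c("g1", "g2"))
  st <- transcriptStats(cat1)
  expect_equal(st$exon_count, c(2L, 1L))
  expect_equal(st$transcript_length, c(250, 200))
  expect_equal(st$exon_lengths[[1]], c(100, 150))
})

test_that("novelty classification follows intron-chain and strand rules", {
  ref <- TranscriptCatalog(GRangesList(
    r1 = randomTx("chr1", 1000, c(200, 300, 150), c(500, 400), "+"),
    r2 = randomTx("chr1", 20000, c(250, 250), 600, "-")),
    geneIds = c("gr1", "gr2"))

  known <- randomTx("chr1", 1000, c(200, 300, 150), c(500, 400), "+")
  start(known)[1] <- 950          # extended terminal exon
  end(known)[3] <- end(known)[3] + 80
  sameStrandOv <- GRanges("chr1", IRanges(c(1100, 1800), c(1250, 1900)), "+")
  antisense <- GRanges("chr1", IRanges(c(1100, 1800), c(1250, 1900)), "-")
  far <- randomTx("chr1", 50000, c(300, 300), 500, "+")

  qry <- TranscriptCatalog(GRangesList(k = known, ov = sameStrandOv,
                                       anti = antisense, novel = far),
                           geneIds = paste0("q", 1:4))
  nov <- classifyNovelty(qry, ref)
  got <- setNames(as.character(nov$status), nov$transcript_id)
  expect_equal(got[["k"]], "known_match")
  expect_equal(nov$evidence[nov$transcript_id == "k"], "r1")
  expect_equal(got[["ov"]], "exonic_overlap")
  ## antisense overlap is NOT known/overlap at this stage
  expect_equal(got[["anti"]], "novel")
  expect_equal(got[["novel"]], "novel")
  ## partition property
  expect_equal(sum(table(nov$status)), length(qry))
})

test_that("distance to nearest gene matches arithmetic and a brute-force scan", {
  ref <- TranscriptCatalog(GRangesList(
    r1 = GRanges("chr1", IRanges(1, 1000), "+"),
    r2 = GRanges("chr1", IRanges(30000, 35000), "-")),
    geneIds = c("g1", "g2"))
  qry <- TranscriptCatalog(GRangesList(
    a = GRanges("chr1", IRanges(1500, 2000), "+"),     # gap 499
    b = GRanges("chr1", IRanges(900, 1200), "-"),      # overlaps
    c = GRanges("chr2", IRanges(5, 50), "+")),         # other chrom
    geneIds = paste0("q", 1:3))
  d <- distanceToNearestGene(qry, ref)
  expect_equal(unname(d[c("a", "b")]), c(499, 0))
  expect_equal(unname(d[["c"]]), Inf)
  ## empty reference sentinel
  empty <- ref[integer(0)]
  expect_true(all(is.infinite(distanceToNearestGene(qry, empty))))

  ## random placements vs O(n^2) oracle
  set.seed(11)
  genes <- GRanges("chr1", IRanges(sort(sample(1:200000, 15)), width = 500))
  names(genes) <- paste0("g", 1:15)
  refR <- TranscriptCatalog(
    GRangesList(lapply(seq_along(genes), function(i) {
      g <- genes[i]; strand(g) <- "+"; g
    })) |> setNames(names(genes)), geneIds = names(genes))
  spans <- GRanges("chr1", IRanges(sample(1:200000, 30), width = 300),
                   strand = "+")
  names(spans) <- paste0("t", 1:30)
  expect_equal(unname(distanceToNearestGene(spans, refR)),
               bruteMinDistance(spans, geneSpans(refR)))
})

test_that("TSS positions honor strand and drive TSS distances", {
  plus <- GRanges("chr1", IRanges(101, 500), "+"); names(plus) <- "p"
  minus <- GRanges("chr1", IRanges(101, 500), "-"); names(minus) <- "m"
  expect_equal(unname(tssPositions(plus)[1]), 101)
  expect_equal(unname(tssPositions(minus)[1]), 500)   # last base = first transcribed
  expect_equal(tssDistance(plus, minus), 399)
  expect_equal(tssDistance(plus, plus), 0)
  unstranded <- GRanges("chr1", IRanges(1, 10), "*"); names(unstranded) <- "u"
  expect_error(tssPositions(unstranded), "unstranded")
  other <- GRanges("chr2", IRanges(1, 10), "+"); names(other) <- "o"
  expect_true(is.na(tssDistance(plus, other)))
})

test_that("neighbor pairs apply a strict 10 kb gap rule, ignoring strand", {
  a <- GRanges("chr1", IRanges(c(1, 1, 1), c(1000, 1000, 1000)),
               strand = "+")
  names(a) <- paste0("a", 1:3)
  b <- GRanges("chr1", IRanges(c(11000, 11002, 1501), c(12000, 12002, 2000)),
               strand = "-")
  names(b) <- paste0("b", 1:3)
  ## gaps: 9999 (in), 10001 (out), 500 (in)
  pr <- neighborPairs(a[1], b)
  expect_setequal(pr$id_b, c("b1", "b3"))
  expect_equal(pr$gap[pr$id_b == "b1"], 9999)
  expect_equal(pr$gap[pr$id_b == "b3"], 500)

  ## synthetic catalog vs O(n^2) oracle
  set.seed(7)
  ga <- GRanges(sample(c("chr1", "chr2"), 40, TRUE),
                IRanges(sample(1:300000, 40), width = sample(200:3000, 40)),
                strand = sample(c("+", "-"), 40, TRUE))
  names(ga) <- paste0("A", 1:40)
  gb <- GRanges(sample(c("chr1", "chr2"), 40, TRUE),
                IRanges(sample(1:300000, 40), width = sample(200:3000, 40)),
                strand = sample(c("+", "-"), 40, TRUE))
  names(gb) <- paste0("B", 1:40)
  got <- neighborPairs(ga, gb)
  want <- bruteNeighborPairs(ga, gb)
  keyG <- paste(got$id_a, got$id_b)
  keyW <- paste(want$id_a, want$id_b)
  expect_setequal(keyG, keyW)
  expect_equal(got$gap[match(keyW, keyG)], want$gap)
})

test_that("interval index agrees with brute-force overlap on a synthetic catalog", {
  sim <- defaultSim()
  spans <- txSpans(sim$catalog)
  genes <- geneSpans(sim$reference)
  expect_equal(unname(distanceToNearestGene(sim$catalog, sim$reference)),
               bruteMinDistance(spans, genes))
})
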